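#' Select recurrent DMCs across a twin cohort
#'
#' Applies the two-criterion selector for probes recurrently discordant
#' across pairs: (1) the standard deviation of beta across samples must
#' exceed `sd_threshold`, and (2) the mean over pairs of the absolute
#' within-pair methylation difference must exceed `delta_threshold`; both
#' comparisons are strict. The absolute difference is used in criterion (2)
#' because the divergence direction is arbitrary per pair, so signed means
#' cancel across pairs.
#'
#' Criterion (1) is computed by default over all non-missing sample betas
#' (`sd_mode = "samples"`, an across-cohort variability filter, n - 1
#' denominator); `sd_mode = "pair_deltas"` instead takes the SD of the
#' signed delta-beta across pairs. Probes valid in fewer than
#' `min_pair_fraction` of pairs are flagged ineligible and never selected
#' (default 1: complete cases only).
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param deltas a `pair_deltas` object derived from `beta`.
#' @param sd_threshold,delta_threshold beta-scale cutoffs in (0, 1);
#'   both default 0.05.
#' @param min_pair_fraction minimum fraction of pairs in which a probe must
#'   be valid to be eligible for selection.
#' @param sd_mode `"samples"` (default) or `"pair_deltas"`; see Details.
#' @return data.frame of class `recurrent_dmc_table`, one row per probe,
#'   sorted by descending `mean_abs_delta` (ties by `probe_id`), with
#'   columns `probe_id`, `mean_abs_delta`, `mean_signed_delta`,
#'   `cross_sample_sd`, `n_pairs_valid`, `eligible`, `selected`. Selection
#'   parameters are recorded in the `"params"` attribute.
#' @export
select_recurrent_dmcs <- function(beta, deltas,
                                  sd_threshold = 0.05,
                                  delta_threshold = 0.05,
                                  min_pair_fraction = 1,
                                  sd_mode = c("samples", "pair_deltas")) {
  stopifnot(inherits(deltas, "pair_deltas"))
  sd_mode <- match.arg(sd_mode)
  for (th in c(sd_threshold, delta_threshold)) {
    if (!is.numeric(th) || th <= 0 || th >= 1)
      config_error("thresholds must lie in (0, 1)")
  }
  if (min_pair_fraction < 0 || min_pair_fraction > 1)
    config_error("min_pair_fraction must lie in [0, 1]")
  if (!identical(rownames(beta), rownames(deltas$delta)))
    contract_error("probe universe mismatch between beta matrix and pair deltas")

  d <- deltas$delta
  n_pairs <- ncol(d)
  valid <- !is.na(d)
  n_pairs_valid <- rowSums(valid)
  mean_abs_delta <- rowMeans(abs(d), na.rm = TRUE)
  mean_signed_delta <- rowMeans(d, na.rm = TRUE)
  mean_abs_delta[n_pairs_valid == 0] <- NA_real_
  mean_signed_delta[n_pairs_valid == 0] <- NA_real_

  cross_sample_sd <- if (sd_mode == "samples") {
    apply(beta, 1, stats::sd, na.rm = TRUE)
  } else {
    apply(d, 1, stats::sd, na.rm = TRUE)
  }

  eligible <- n_pairs_valid >= min_pair_fraction * n_pairs
  selected <- eligible &
    !is.na(cross_sample_sd) & cross_sample_sd > sd_threshold &
    !is.na(mean_abs_delta) & mean_abs_delta > delta_threshold

  out <- data.frame(probe_id = rownames(beta),
                    mean_abs_delta = mean_abs_delta,
                    mean_signed_delta = mean_signed_delta,
                    cross_sample_sd = cross_sample_sd,
                    n_pairs_valid = n_pairs_valid,
                    eligible = eligible, selected = selected,
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(-replace(out$mean_abs_delta, is.na(out$mean_abs_delta), -Inf),
               out$probe_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(sd_threshold = sd_threshold,
                              delta_threshold = delta_threshold,
                              min_pair_fraction = min_pair_fraction,
                              sd_mode = sd_mode)
  class(out) <- c("recurrent_dmc_table", "data.frame")
  out
}

#' Sensitivity and false discovery proportion against planted truth
#'
#' Compares the selected recurrent DMCs with the planted probes of a
#' synthetic cohort: sensitivity is the fraction of planted probes
#' selected, and the false discovery proportion the fraction of selected
#' probes that were not planted (0 when nothing is selected).
#'
#' @param table a `recurrent_dmc_table` from [select_recurrent_dmcs()].
#' @param truth the `truth` element of a [generate_cohort()] result, or a
#'   character vector of planted probe IDs.
#' @return list with `sensitivity`, `fdp`, `n_selected` and `n_planted`.
#' @export
recovery_report <- function(table, truth) {
  planted <- if (is.character(truth)) truth else truth$planted
  if (!all(planted %in% table$probe_id))
    contract_error("planted probes missing from the selection table: probe universes differ")
  selected <- table$probe_id[table$selected]
  n_sel <- length(selected)
  n_pl <- length(planted)
  sens <- if (n_pl == 0) NA_real_ else
    length(intersect(selected, planted)) / n_pl
  fdp <- length(setdiff(selected, planted)) / max(1L, n_sel)
  list(sensitivity = sens, fdp = fdp,
       n_selected = n_sel, n_planted = n_pl)
}
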