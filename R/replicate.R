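#' Cross-cohort replication of recurrent DMCs
#'
#' Intersects the selected probe sets of a discovery and a replication
#' cohort, both produced by [select_recurrent_dmcs()] under the same
#' thresholds (a mismatch in recorded parameters triggers a warning, not an
#' error). A probe replicates when it is independently selected in the
#' second cohort; no effect-direction concordance is required because
#' within-pair signs are arbitrary.
#'
#' @param discovery,replication `recurrent_dmc_table` objects.
#' @return list of class `replication_result` with `n_discovery`,
#'   `n_replication`, `n_overlap`, `overlap` (data.frame `probe_id`,
#'   `mean_abs_delta_discovery`, `mean_abs_delta_replication`, sorted by
#'   `probe_id`), and `discovery_only` / `replication_only` ID vectors.
#' @export
replicate_dmcs <- function(discovery, replication) {
  p1 <- attr(discovery, "params"); p2 <- attr(replication, "params")
  if (!is.null(p1) && !is.null(p2) && !identical(p1, p2))
    warning("discovery and replication tables were produced with different selection parameters",
            call. = FALSE)
  s1 <- discovery$probe_id[discovery$selected]
  s2 <- replication$probe_id[replication$selected]
  if (length(s1) == 0 || length(s2) == 0)
    warning("empty selected set in one cohort; overlap is empty", call. = FALSE)
  ids <- sort(intersect(s1, s2))
  overlap <- data.frame(
    probe_id = ids,
    mean_abs_delta_discovery =
      discovery$mean_abs_delta[match(ids, discovery$probe_id)],
    mean_abs_delta_replication =
      replication$mean_abs_delta[match(ids, replication$probe_id)],
    stringsAsFactors = FALSE)
  structure(list(n_discovery = length(s1), n_replication = length(s2),
                 n_overlap = length(ids), overlap = overlap,
                 discovery_only = sort(setdiff(s1, s2)),
                 replication_only = sort(setdiff(s2, s1))),
            class = "replication_result")
}

#' Rank replicated recurrent DMCs as candidate markers
#'
#' Builds the top-n candidate marker panel from the replication overlap.
#' The default rank score is the arithmetic mean of the two cohorts' mean
#' absolute delta-beta; `"min"` (worst cohort) and `"discovery"` (discovery
#' cohort only) are alternatives. Rows are sorted by descending score with
#' ties broken by ascending probe ID; annotation columns are joined from
#' the manifest when one is supplied.
#'
#' @param result a `replication_result` from [replicate_dmcs()].
#' @param manifest optional manifest data.frame for annotation columns.
#' @param n_top number of markers to return (default 20).
#' @param score ranking rule: `"mean"` (default), `"min"` or
#'   `"discovery"`.
#' @return data.frame of class `marker_panel` with the ranked rows.
#' @export
rank_markers <- function(result, manifest = NULL, n_top = 20,
                         score = c("mean", "min", "discovery")) {
  score <- match.arg(score)
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top <= 0)
    config_error("n_top must be a positive number")
  ov <- result$overlap
  if (nrow(ov) == 0)
    validation_error("rank_markers: replication overlap is empty")
  ov$rank_score <- switch(score,
    mean = (ov$mean_abs_delta_discovery + ov$mean_abs_delta_replication) / 2,
    min = pmin(ov$mean_abs_delta_discovery, ov$mean_abs_delta_replication),
    discovery = ov$mean_abs_delta_discovery)
  ov <- ov[order(-ov$rank_score, ov$probe_id), , drop = FALSE]
  ov <- utils::head(ov, n_top)
  if (!is.null(manifest)) {
    idx <- match(ov$probe_id, manifest$probe_id)
    ov$chrom <- manifest$chrom[idx]
    ov$pos <- manifest$pos[idx]
    ov$gene_symbol <- manifest$gene_symbol[idx]
    ov$gene_structure <- manifest$gene_structure[idx]
    ov$cgi_relation <- manifest$cgi_relation[idx]
  }
  rownames(ov) <- NULL
  attr(ov, "score") <- score
  class(ov) <- c("marker_panel", "data.frame")
  ov
}
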