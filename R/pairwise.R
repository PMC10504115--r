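#' Compute within-pair delta-beta values
#'
#' For every twin pair, computes the signed methylation difference
#' `beta_A - beta_B` at each probe. A probe is invalid for a pair when
#' either member's beta is missing (e.g. masked by detection p-value).
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param sheet sample sheet data.frame binding samples into pairs (columns
#'   `sample_id`, `pair_id`, `member`, `age`, `sex`).
#' @return object of class `pair_deltas`: list with `delta` (signed
#'   probes x pairs matrix, `NA` where invalid) and `pairs` (data.frame
#'   with `pair_id`, `sample_A`, `sample_B`, `age`, `sex`).
#' @export
compute_pair_deltas <- function(beta, sheet) {
  validate_sample_sheet(sheet)
  absent <- setdiff(sheet$sample_id, colnames(beta))
  if (length(absent) > 0)
    contract_error(paste0("sample(s) in sheet absent from beta matrix: ",
                          paste(absent, collapse = ", ")))
  a <- sheet[sheet$member == "A", ]
  b <- sheet[sheet$member == "B", ]
  b <- b[match(a$pair_id, b$pair_id), ]
  pairs <- data.frame(pair_id = a$pair_id, sample_A = a$sample_id,
                      sample_B = b$sample_id, age = a$age, sex = a$sex,
                      stringsAsFactors = FALSE)
  delta <- beta[, pairs$sample_A, drop = FALSE] -
    beta[, pairs$sample_B, drop = FALSE]
  colnames(delta) <- pairs$pair_id
  structure(list(delta = delta, pairs = pairs), class = "pair_deltas")
}

#' Call per-pair DMCs at a delta-beta threshold
#'
#' A probe is a DMC for a pair when its within-pair absolute methylation
#' difference is strictly greater than the threshold (the "higher than
#' 0.05" rule on the average-beta scale).
#'
#' @param deltas a `pair_deltas` object from [compute_pair_deltas()].
#' @param threshold beta-scale cutoff in (0, 1); default 0.05.
#' @return data.frame with one row per pair: `pair_id`, `dmc_count`,
#'   `n_valid_probes`, `age`, `sex`.
#' @export
call_pair_dmcs <- function(deltas, threshold = 0.05) {
  stopifnot(inherits(deltas, "pair_deltas"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    config_error("threshold must be a single value in (0, 1)")
  ad <- abs(deltas$delta)
  data.frame(pair_id = deltas$pairs$pair_id,
             dmc_count = colSums(ad > threshold, na.rm = TRUE),
             n_valid_probes = colSums(!is.na(ad)),
             age = deltas$pairs$age, sex = deltas$pairs$sex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare DMC counts between male and female twin pairs
#'
#' Two-sample t test (Student's pooled-variance form by default) on the
#' per-pair DMC count by pair sex. Pairs are the unit of analysis.
#'
#' @param summaries per-pair summary data.frame from [call_pair_dmcs()].
#' @param welch use Welch's t instead of the pooled form.
#' @return list with `statistic`, `df` and `p_value` (two-sided).
#' @export
sex_group_ttest <- function(summaries, welch = FALSE) {
  m <- summaries$dmc_count[summaries$sex == "M"]
  f <- summaries$dmc_count[summaries$sex == "F"]
  if (length(m) < 2L || length(f) < 2L)
    validation_error("sex_group_ttest: each sex group needs at least 2 pairs")
  pooled_t_test(m, f, welch = welch)
}

#' Correlate DMC count with pair age
#'
#' Pearson product-moment correlation between pair age and per-pair DMC
#' count, with the two-sided p-value from the t transform on n - 2 degrees
#' of freedom.
#'
#' @param summaries per-pair summary data.frame from [call_pair_dmcs()].
#' @return list with `estimate` (r), `df` and `p_value`.
#' @export
age_count_correlation <- function(summaries) {
  if (nrow(summaries) < 3L)
    validation_error("age_count_correlation: need at least 3 pairs")
  pearson_cor_test(summaries$age, summaries$dmc_count)
}
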