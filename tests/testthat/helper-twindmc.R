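# Shared fixture builders and independent oracles.

# Write a probes x samples matrix as the TSV layout the readers expect.
write_matrix_tsv <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(probes))
    probes <- if (!is.null(rownames(m))) rownames(m) else
      sprintf("cg%08d", seq_len(nrow(m)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(m))) colnames(m) else
      sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  m
}

make_sheet <- function(n_pairs, ages = NULL, sexes = NULL) {
  if (is.null(ages)) ages <- seq(20, by = 5, length.out = n_pairs)
  if (is.null(sexes)) sexes <- rep(c("M", "F"), length.out = n_pairs)
  pair_id <- sprintf("P%03d", seq_len(n_pairs))
  data.frame(
    sample_id = as.vector(rbind(paste0(pair_id, "_A"), paste0(pair_id, "_B"))),
    pair_id = rep(pair_id, each = 2),
    member = rep(c("A", "B"), n_pairs),
    age = rep(ages, each = 2),
    sex = rep(sexes, each = 2),
    stringsAsFactors = FALSE)
}

# Random beta matrix + matching sheet for property tests.
random_instance <- function(n_probes, n_pairs, na_rate = 0) {
  sheet <- make_sheet(n_pairs)
  m <- matrix(runif(n_probes * 2 * n_pairs), n_probes, 2 * n_pairs,
              dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                              sheet$sample_id))
  if (na_rate > 0) m[runif(length(m)) < na_rate] <- NA_real_
  list(beta = m, sheet = sheet)
}

# Brute-force recurrent-DMC oracle: explicit double loop over probes and
# pairs, applying both criteria independently of the vectorized path.
oracle_select <- function(beta, sheet, sd_th = 0.05, delta_th = 0.05,
                          min_pair_fraction = 1) {
  pair_ids <- unique(sheet$pair_id)
  selected <- character(0)
  for (p in rownames(beta)) {
    abs_deltas <- c()
    n_valid <- 0
    for (pr in pair_ids) {
      sa <- sheet$sample_id[sheet$pair_id == pr & sheet$member == "A"]
      sb <- sheet$sample_id[sheet$pair_id == pr & sheet$member == "B"]
      va <- beta[p, sa]; vb <- beta[p, sb]
      if (!is.na(va) && !is.na(vb)) {
        abs_deltas <- c(abs_deltas, abs(va - vb))
        n_valid <- n_valid + 1
      }
    }
    if (n_valid < min_pair_fraction * length(pair_ids)) next
    if (n_valid == 0) next
    vals <- beta[p, ][!is.na(beta[p, ])]
    if (length(vals) >= 2 && sd(vals) > sd_th &&
        mean(abs_deltas) > delta_th) {
      selected <- c(selected, p)
    }
  }
  selected
}
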