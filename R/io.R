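#' Read a beta-value matrix from TSV
#'
#' Reads a probes-by-samples grid of average-beta methylation values. The
#' first column holds probe IDs, the header row sample IDs; comment lines
#' starting with `#` are skipped. Values must lie in \[0, 1\] or be the
#' missing token.
#'
#' @param path path to a tab-separated file.
#' @param missing token representing a missing value (default `"NA"`).
#' @return numeric matrix with probe IDs as rownames and sample IDs as
#'   colnames; missing entries are `NA`.
#' @export
read_beta_matrix <- function(path, missing = "NA") {
  m <- read_value_matrix(path, missing)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    validation_error(sprintf(
      "beta value %g outside [0, 1] at probe '%s', sample '%s' in %s",
      m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
      colnames(m)[bad[1, 2]], path))
  }
  m
}

#' Read a detection p-value matrix from TSV
#'
#' Same layout as [read_beta_matrix()]; values are per-probe, per-sample
#' detection p-values in \[0, 1\].
#'
#' @inheritParams read_beta_matrix
#' @return numeric matrix of p-values.
#' @export
read_detection_p <- function(path, missing = "NA") {
  m <- read_value_matrix(path, missing)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    validation_error(sprintf(
      "detection p-value %g outside [0, 1] at probe '%s', sample '%s' in %s",
      m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
      colnames(m)[bad[1, 2]], path))
  }
  m
}

read_value_matrix <- function(path, missing) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          na.strings = missing, colClasses = "character",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error(paste0("no sample columns in ", path))
  probe_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(probe_ids))
    format_error(sprintf("duplicate probe ID '%s' in %s",
                         probe_ids[duplicated(probe_ids)][1], path))
  if (anyDuplicated(sample_ids))
    format_error(sprintf("duplicate sample ID '%s' in %s",
                         sample_ids[duplicated(sample_ids)][1], path))
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(probe_ids, sample_ids))
  raw_na <- vapply(df[-1], function(col) is.na(col), logical(nrow(df)))
  raw_na <- matrix(raw_na, nrow = nrow(df))
  if (any(is.na(vals) & !raw_na)) {
    idx <- which(is.na(vals) & !raw_na, arr.ind = TRUE)
    format_error(sprintf(
      "non-numeric cell at probe '%s', sample '%s' in %s",
      probe_ids[idx[1, 1]], sample_ids[idx[1, 2]], path))
  }
  vals
}

#' Mask beta values that failed detection
#'
#' Sets to missing every entry whose detection p-value is not below `alpha`;
#' a probe/sample measurement counts as a significant signal above
#' background only when its detection p-value is strictly less than the
#' threshold. Entries with a missing detection p-value are treated as
#' failed.
#'
#' @param beta numeric beta matrix (probes x samples).
#' @param detp detection p-value matrix with identical dimnames.
#' @param alpha detection threshold in (0, 1]; default 0.05.
#' @return the beta matrix with failed entries set to `NA`.
#' @export
apply_detection_mask <- function(beta, detp, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    config_error("alpha must be a single value in (0, 1]")
  if (!identical(dim(beta), dim(detp)) ||
      !identical(rownames(beta), rownames(detp)) ||
      !identical(colnames(beta), colnames(detp)))
    contract_error("beta and detection-p matrices must have identical dimensions and identifiers")
  beta[is.na(detp) | detp >= alpha] <- NA_real_
  beta
}

#' Read a twin-pair sample sheet from TSV
#'
#' Expects columns `sample_id`, `pair_id`, `member`, `age`, `sex`. Each
#' pair must occur exactly twice, once as member A and once as member B.
#' MZ twins share a birth date, so differing age or sex within a pair is
#' flagged with a warning.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with the five validated columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  needed <- c("sample_id", "pair_id", "member", "age", "sex")
  miss <- setdiff(needed, colnames(df))
  if (length(miss) > 0)
    format_error(paste0("sample sheet missing column(s): ",
                        paste(miss, collapse = ", ")))
  df <- df[needed]
  df$sample_id <- as.character(df$sample_id)
  df$pair_id <- as.character(df$pair_id)
  df$member <- as.character(df$member)
  df$sex <- as.character(df$sex)
  df$age <- as.numeric(df$age)
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    validation_error(sprintf("duplicate sample_id '%s'",
                             df$sample_id[duplicated(df$sample_id)][1]))
  bad_member <- setdiff(unique(df$member), c("A", "B"))
  if (length(bad_member) > 0)
    validation_error(sprintf(
      "member must be 'A' or 'B'; found '%s'", bad_member[1]))
  bad_sex <- setdiff(unique(df$sex), c("M", "F"))
  if (length(bad_sex) > 0)
    validation_error(sprintf("sex must be 'M' or 'F'; found '%s'", bad_sex[1]))
  if (any(!is.finite(df$age)) || any(df$age < 0))
    validation_error("age must be a non-negative number for every sample")
  for (p in unique(df$pair_id)) {
    members <- sort(df$member[df$pair_id == p])
    if (!identical(members, c("A", "B")))
      validation_error(sprintf(
        "pair '%s' must have exactly one member A and one member B", p))
    sub <- df[df$pair_id == p, ]
    if (length(unique(sub$age)) > 1L || length(unique(sub$sex)) > 1L)
      warning(sprintf(
        "pair '%s' has differing age or sex between members; MZ twins share both",
        p), call. = FALSE)
  }
  invisible(df)
}

# The field mixes spellings for the Illumina annotation tokens
# ("body"/"Body", "3'UTR" with ASCII or typographic apostrophes); normalize
# to one canonical token per category on read.
normalize_gene_structure <- function(x) {
  x <- gsub("′", "'", trimws(as.character(x)))
  key <- tolower(gsub("'", "", x))
  map <- c(tss1500 = "TSS1500", tss200 = "TSS200", "1stexon" = "1stExon",
           body = "Body", intergenic = "Intergenic", exonbnd = "ExonBnd",
           "3utr" = "3UTR", "5utr" = "5UTR")
  out <- unname(map[key])
  if (anyNA(out) && length(x) > 0) {
    bad <- unique(x[is.na(out)])
    validation_error(sprintf(
      "unknown gene_structure token '%s'; allowed: %s",
      bad[1], paste(GENE_STRUCTURE_LEVELS, collapse = ", ")))
  }
  out
}

normalize_cgi_relation <- function(x) {
  key <- tolower(gsub("[ _]", "", trimws(as.character(x))))
  map <- c(island = "Island", nshore = "N_Shore", sshore = "S_Shore",
           nshelf = "N_Shelf", sshelf = "S_Shelf", opensea = "OpenSea")
  out <- unname(map[key])
  if (anyNA(out) && length(x) > 0) {
    bad <- unique(x[is.na(out)])
    validation_error(sprintf(
      "unknown cgi_relation token '%s'; allowed: %s",
      bad[1], paste(CGI_RELATION_LEVELS, collapse = ", ")))
  }
  out
}

#' Read a probe manifest from TSV
#'
#' Expects columns `probe_id`, `chrom`, `pos`, `gene_symbol`,
#' `gene_structure`, `cgi_relation`. Gene-structure tokens are one of
#' TSS1500, TSS200, 1stExon, Body, Intergenic, ExonBnd, 3UTR, 5UTR and
#' CGI-relation tokens one of Island, N_Shore, S_Shore, N_Shelf, S_Shelf,
#' OpenSea; common spelling variants (`body`, `3'UTR`, `open sea`) are
#' normalized on read. Positions are 1-based coordinates.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with the six validated columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("probe_id", "chrom", "pos", "gene_symbol",
              "gene_structure", "cgi_relation")
  miss <- setdiff(needed, colnames(df))
  if (length(miss) > 0)
    format_error(paste0("manifest missing column(s): ",
                        paste(miss, collapse = ", ")))
  df <- df[needed]
  if (anyDuplicated(df$probe_id))
    validation_error(sprintf("duplicate probe_id '%s' in manifest",
                             df$probe_id[duplicated(df$probe_id)][1]))
  df$pos <- as.integer(df$pos)
  if (nrow(df) > 0 && (any(is.na(df$pos)) || any(df$pos < 1)))
    validation_error("manifest pos must be a positive 1-based integer")
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  df$gene_structure <- normalize_gene_structure(df$gene_structure)
  df$cgi_relation <- normalize_cgi_relation(df$cgi_relation)
  df
}

#' Write a result table or matrix as TSV
#'
#' Writes tab-separated output with an optional leading `#` comment line
#' recording the package version and the parameters that produced the
#' table. Matrices are written with their rownames as a leading `probe_id`
#' column; missing values use the configured token.
#'
#' @param x data.frame or matrix.
#' @param path output file path.
#' @param params optional named list recorded in the comment line.
#' @param missing token used for missing values (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, params = NULL, missing = "NA") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- paste0("# twindmc ", TWINDMC_VERSION)
  if (length(params) > 0) {
    kv <- paste(names(params), vapply(params, format, character(1)),
                sep = "=", collapse = " ")
    header <- paste0(header, " | ", kv)
  }
  writeLines(header, con)
  if (is.matrix(x)) {
    df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = missing)
  invisible(path)
}
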