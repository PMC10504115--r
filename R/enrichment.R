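#' Annotate probes with gene-structure and CGI categories
#'
#' Joins a set of probe IDs against a manifest. Probes absent from the
#' manifest are dropped with a warning and listed in the `"unannotated"`
#' attribute of the result.
#'
#' @param probes character vector of probe IDs.
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @return data.frame with `probe_id`, `chrom`, `pos`, `gene_symbol`,
#'   `gene_structure`, `cgi_relation` for the probes found, in input order.
#' @export
annotate_probes <- function(probes, manifest) {
  probes <- as.character(probes)
  idx <- match(probes, manifest$probe_id)
  missing <- probes[is.na(idx)]
  if (length(missing) > 0)
    warning(sprintf("%d probe(s) absent from manifest (e.g. '%s'); left unannotated",
                    length(missing), missing[1]), call. = FALSE)
  out <- manifest[idx[!is.na(idx)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated") <- missing
  out
}

#' Category enrichment of DMCs versus background by chi-square
#'
#' Tests whether selected (recurrent DMC) probes are distributed across
#' gene-structure or CGI-relation categories differently from background
#' (non-DMC) probes, with the Pearson chi-square statistic and no
#' continuity correction. Categories with zero probes in both groups are
#' dropped with a warning. Besides the omnibus test over the
#' categories x 2 table, a per-category 2x2 test (category vs rest) is
#' reported so the direction of each enrichment can be read off the
#' proportions.
#'
#' @param dmc_annot annotated table for the DMC group (from
#'   [annotate_probes()]).
#' @param non_dmc_annot annotated table for the background group.
#' @param scheme `"gene_structure"` or `"cgi_relation"`.
#' @return list of class `category_enrichment` with `scheme`, `counts`
#'   (per-category counts and proportions in both groups plus per-category
#'   chi-square and p), `chi2_stat`, `df`, `p_value`.
#' @export
chisq_proportions <- function(dmc_annot, non_dmc_annot,
                              scheme = c("gene_structure", "cgi_relation")) {
  scheme <- match.arg(scheme)
  levels <- if (scheme == "gene_structure") GENE_STRUCTURE_LEVELS else
    CGI_RELATION_LEVELS
  g1 <- dmc_annot[[scheme]]
  g2 <- non_dmc_annot[[scheme]]
  if (length(g1) == 0 || length(g2) == 0)
    validation_error("chisq_proportions: both groups must be non-empty")
  c1 <- table(factor(g1, levels = levels))
  c2 <- table(factor(g2, levels = levels))
  empty <- c1 + c2 == 0
  if (any(empty)) {
    warning(sprintf("dropping category(ies) absent from both groups: %s",
                    paste(levels[empty], collapse = ", ")), call. = FALSE)
    c1 <- c1[!empty]; c2 <- c2[!empty]
  }
  if (length(c1) < 2L)
    validation_error("chisq_proportions: need at least 2 categories present")
  tab <- cbind(dmc = as.numeric(c1), non_dmc = as.numeric(c2))
  rownames(tab) <- names(c1)
  omnibus <- chisq_stat(tab)

  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  per_cat <- t(vapply(rownames(tab), function(cat) {
    a <- tab[cat, 1]; b <- tab[cat, 2]
    t22 <- matrix(c(a, n1 - a, b, n2 - b), 2, 2)
    if (any(rowSums(t22) == 0) || any(colSums(t22) == 0))
      return(c(NA_real_, NA_real_))
    r <- chisq_stat(t22)
    c(r$statistic, r$p_value)
  }, numeric(2)))
  counts <- data.frame(category = rownames(tab),
                       count_dmc = tab[, 1], count_non_dmc = tab[, 2],
                       proportion_dmc = tab[, 1] / n1,
                       proportion_non_dmc = tab[, 2] / n2,
                       chi2_2x2 = per_cat[, 1], p_2x2 = per_cat[, 2],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scheme = scheme, counts = counts,
                 chi2_stat = omnibus$statistic, df = omnibus$df,
                 p_value = omnibus$p_value),
            class = "category_enrichment")
}
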