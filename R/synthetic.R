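#' Simulation configuration for a synthetic paired-twin cohort
#'
#' Collects and validates the parameters of the synthetic methylome
#' generator. Defaults emulate a blood EPIC-array MZ-twin study: 47 pairs,
#' a bimodal beta baseline, small within-pair noise that grows with pair
#' age, a planted subset of probes with recurrent within-pair divergence,
#' no sex effect, and sporadic detection failures.
#'
#' @param n_pairs number of twin pairs (2 * n_pairs samples).
#' @param n_probes number of probes.
#' @param n_recurrent number of planted recurrent DMC probes.
#' @param delta_effect mean planted within-pair divergence on the beta
#'   scale.
#' @param baseline_mixture list with `weights` (named low/mid/high, summing
#'   to 1) and the `low`, `mid`, `high` beta ranges of the baseline mixture.
#' @param noise_sd within-pair technical/biological noise SD on the beta
#'   scale at age 0, for all probes.
#' @param between_sd SD of the per-pair baseline shift (shared by both
#'   twins) on the beta scale; models inter-individual methylation
#'   variability.
#' @param age_range numeric length-2, min and max pair age in years.
#' @param age_gamma multiplicative growth of within-pair noise per year of
#'   age: the noise SD for a pair of age a is `noise_sd * (1 + age_gamma * a)`.
#' @param recurrence_fraction fraction of pairs in which each planted probe
#'   diverges (default 1 = all pairs).
#' @param delta_jitter_sd SD of the multiplicative jitter applied to
#'   `delta_effect` per probe/pair.
#' @param detp_fail_rate fraction of entries with a failed detection
#'   p-value.
#' @param seed integer random seed; the whole cohort is reproducible from
#'   it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 47,
                       n_probes = 20000,
                       n_recurrent = 500,
                       delta_effect = 0.10,
                       baseline_mixture = list(
                         weights = c(low = 0.45, mid = 0.10, high = 0.45),
                         low = c(0.05, 0.15),
                         mid = c(0.25, 0.75),
                         high = c(0.85, 0.95)),
                       noise_sd = 0.017,
                       between_sd = 0.03,
                       age_range = c(18, 65),
                       age_gamma = 0.02,
                       recurrence_fraction = 1,
                       delta_jitter_sd = 0.15,
                       detp_fail_rate = 0.001,
                       seed = 1) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
              n_recurrent = as.integer(n_recurrent),
              delta_effect = delta_effect,
              baseline_mixture = baseline_mixture, noise_sd = noise_sd,
              between_sd = between_sd, age_range = as.numeric(age_range),
              age_gamma = age_gamma,
              recurrence_fraction = recurrence_fraction,
              delta_jitter_sd = delta_jitter_sd,
              detp_fail_rate = detp_fail_rate, seed = as.integer(seed))
  if (cfg$n_pairs < 1L) config_error("n_pairs must be >= 1")
  if (cfg$n_recurrent > cfg$n_probes)
    config_error("n_recurrent cannot exceed n_probes")
  if (cfg$n_recurrent < 0L || cfg$n_probes < 0L)
    config_error("n_probes and n_recurrent must be non-negative")
  if (cfg$noise_sd < 0 || cfg$between_sd < 0)
    config_error("noise_sd and between_sd must be non-negative")
  for (nm in c("delta_effect", "recurrence_fraction", "detp_fail_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      config_error(paste0(nm, " must be in [0, 1]"))
  }
  w <- cfg$baseline_mixture$weights
  if (!setequal(names(w), c("low", "mid", "high")) ||
      abs(sum(w) - 1) > 1e-8 || any(w < 0))
    config_error("baseline_mixture$weights must be named low/mid/high and sum to 1")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2] ||
      cfg$age_range[1] < 0)
    config_error("age_range must be non-negative (min, max) with min <= max")
  if (cfg$age_gamma < 0) config_error("age_gamma must be non-negative")
  structure(cfg, class = "sim_config")
}

# Default category frequencies, loosely matching the EPIC array's genomic
# footprint (gene bodies and open sea dominate).
default_category_weights <- function() {
  list(
    gene_structure = c(TSS1500 = 0.13, TSS200 = 0.07, "1stExon" = 0.04,
                       Body = 0.33, Intergenic = 0.30, ExonBnd = 0.01,
                       "3UTR" = 0.03, "5UTR" = 0.09),
    cgi_relation = c(Island = 0.19, N_Shore = 0.09, S_Shore = 0.08,
                     N_Shelf = 0.05, S_Shelf = 0.05, OpenSea = 0.54))
}

#' Generate a synthetic probe manifest
#'
#' Draws gene-structure and CGI-relation categories i.i.d. from the given
#' weights, assigns probes to chromosomes with strictly increasing 1-based
#' positions within each chromosome, and invents gene symbols for
#' non-intergenic probes.
#'
#' @param n_probes number of probes.
#' @param category_weights list with named numeric vectors `gene_structure`
#'   (over the eight structure tokens) and `cgi_relation` (over the six CGI
#'   tokens), each summing to 1. Defaults emulate EPIC-array frequencies.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return manifest data.frame (`probe_id`, `chrom`, `pos`, `gene_symbol`,
#'   `gene_structure`, `cgi_relation`).
#' @export
generate_manifest <- function(n_probes, category_weights = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(category_weights)) category_weights <- default_category_weights()
  gw <- category_weights$gene_structure
  cw <- category_weights$cgi_relation
  if (is.null(gw) || is.null(cw) ||
      !all(names(gw) %in% GENE_STRUCTURE_LEVELS) ||
      !all(names(cw) %in% CGI_RELATION_LEVELS) ||
      abs(sum(gw) - 1) > 1e-8 || abs(sum(cw) - 1) > 1e-8 ||
      any(gw < 0) || any(cw < 0))
    config_error("category_weights must be non-negative named vectors over the gene_structure and cgi_relation tokens, each summing to 1")
  n_probes <- as.integer(n_probes)
  if (n_probes == 0L) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = integer(), gene_symbol = character(),
                      gene_structure = character(),
                      cgi_relation = character(),
                      stringsAsFactors = FALSE))
  }
  probe_id <- sprintf("cg%08d", sort(sample.int(99999999L, n_probes)))
  chrom <- paste0("chr", sort(sample.int(22L, n_probes, replace = TRUE)))
  pos <- integer(n_probes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample.int(10000L, length(idx), replace = TRUE) + 100L)
  }
  gene_structure <- sample(names(gw), n_probes, replace = TRUE, prob = gw)
  cgi_relation <- sample(names(cw), n_probes, replace = TRUE, prob = cw)
  gene_symbol <- ifelse(gene_structure == "Intergenic", "",
                        sprintf("GENE%04d",
                                sample.int(4000L, n_probes, replace = TRUE)))
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             gene_symbol = gene_symbol, gene_structure = gene_structure,
             cgi_relation = cgi_relation, stringsAsFactors = FALSE)
}

#' Generate a synthetic paired-twin methylome cohort
#'
#' Simulates a beta matrix, detection p-value matrix, sample sheet and
#' probe manifest for `n_pairs` MZ twin pairs, with `n_recurrent` planted
#' recurrent DMC probes and known ground truth.
#'
#' Each probe gets a baseline beta from a bimodal mixture (planted probes
#' draw from the intermediate component, where a divergence of
#' `delta_effect` on the beta scale is realizable). Per pair, a baseline
#' shift (SD `between_sd`) is shared by both twins, and the twins differ by
#' zero-mean noise with SD `noise_sd * (1 + age_gamma * age)`; planted
#' probes additionally diverge by `delta_effect` (jittered, sign random per
#' pair) in a `recurrence_fraction` of pairs. Perturbations are applied on
#' the logit scale, scaled by the local slope so their magnitude is
#' preserved on the beta scale, and final values are clipped to
#' \[0.001, 0.999\]. Sex is assigned per pair and never influences the
#' betas. Detection failures (p >= 0.05) are placed uniformly at rate
#' `detp_fail_rate`.
#'
#' @param config a [sim_config()] object.
#' @param manifest optional probe manifest to reuse, e.g. to simulate two
#'   cohorts profiled on the same array; must have `n_probes` rows. A new
#'   manifest is generated when `NULL`.
#' @param planted_probes optional character vector naming the probes to
#'   plant (must be manifest probe IDs and match `n_recurrent` in length);
#'   lets two cohorts share recurrent DMCs, as replicating biology would.
#'   Chosen uniformly at random when `NULL`.
#' @return list of class `twin_cohort` with elements `beta`, `detp`
#'   (matrices), `sheet`, `manifest` (data.frames), `truth` (list with
#'   `planted` probe IDs, `realized` signed divergence matrix
#'   planted-probes x pairs, and `recurring` logical matrix), and `config`.
#' @export
generate_cohort <- function(config = sim_config(), manifest = NULL,
                            planted_probes = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_probes
  npair <- config$n_pairs

  if (is.null(manifest)) {
    manifest <- generate_manifest(np)
  } else if (nrow(manifest) != np) {
    config_error("supplied manifest must have n_probes rows")
  }
  probe_ids <- manifest$probe_id

  pair_id <- sprintf("P%03d", seq_len(npair))
  age <- round(stats::runif(npair, config$age_range[1], config$age_range[2]))
  sex <- sample(c("M", "F"), npair, replace = TRUE)
  sample_A <- paste0(pair_id, "_A")
  sample_B <- paste0(pair_id, "_B")
  sheet <- data.frame(
    sample_id = as.vector(rbind(sample_A, sample_B)),
    pair_id = rep(pair_id, each = 2),
    member = rep(c("A", "B"), npair),
    age = rep(age, each = 2),
    sex = rep(sex, each = 2),
    stringsAsFactors = FALSE)

  # Baselines: bimodal mixture; planted probes forced to the intermediate
  # component, where a delta_effect-sized divergence fits inside [0, 1].
  mix <- config$baseline_mixture
  comp <- sample(c("low", "mid", "high"), np, replace = TRUE,
                 prob = mix$weights[c("low", "mid", "high")])
  mu <- numeric(np)
  for (k in c("low", "mid", "high")) {
    idx <- comp == k
    mu[idx] <- stats::runif(sum(idx), mix[[k]][1], mix[[k]][2])
  }
  if (is.null(planted_probes)) {
    planted_idx <- if (config$n_recurrent > 0)
      sort(sample.int(np, config$n_recurrent)) else integer(0)
  } else {
    planted_idx <- sort(match(planted_probes, probe_ids))
    if (anyNA(planted_idx))
      config_error("planted_probes must all be manifest probe IDs")
    if (length(planted_idx) != config$n_recurrent)
      config_error("length(planted_probes) must equal n_recurrent")
  }
  mu[planted_idx] <- stats::runif(length(planted_idx),
                                  mix$mid[1], mix$mid[2])

  # Perturbations on the logit scale, scaled by 1 / (mu (1 - mu)) so that a
  # beta-scale offset d maps to ~d after the inverse transform.
  logit_mu <- stats::qlogis(mu)
  slope <- 1 / (mu * (1 - mu))
  sd_pair <- config$noise_sd * (1 + config$age_gamma * age)

  noise <- matrix(stats::rnorm(np * npair), np, npair) *
    rep(sd_pair, each = np)
  shift <- matrix(stats::rnorm(np * npair, sd = config$between_sd),
                  np, npair)

  plant <- matrix(0, np, npair)
  recurring <- matrix(FALSE, length(planted_idx), npair)
  if (length(planted_idx) > 0 && config$delta_effect > 0) {
    nr <- length(planted_idx)
    recurring <- matrix(
      stats::runif(nr * npair) < config$recurrence_fraction, nr, npair)
    sign_mat <- matrix(sample(c(-1, 1), nr * npair, replace = TRUE),
                       nr, npair)
    jitter <- matrix(pmax(stats::rnorm(nr * npair, 1, config$delta_jitter_sd),
                          0.1), nr, npair)
    plant[planted_idx, ] <- recurring * sign_mat * config$delta_effect * jitter
  }

  half <- (noise + plant) / 2
  beta_A <- stats::plogis(logit_mu + (shift + half) * slope)
  beta_B <- stats::plogis(logit_mu + (shift - half) * slope)
  beta_A <- pmin(pmax(beta_A, 0.001), 0.999)
  beta_B <- pmin(pmax(beta_B, 0.001), 0.999)

  beta <- matrix(NA_real_, np, 2 * npair,
                 dimnames = list(probe_ids, sheet$sample_id))
  beta[, sample_A] <- beta_A
  beta[, sample_B] <- beta_B

  n_cells <- length(beta)
  detp <- matrix(stats::runif(n_cells, 0, 0.049999), np, 2 * npair,
                 dimnames = dimnames(beta))
  fail <- stats::runif(n_cells) < config$detp_fail_rate
  detp[fail] <- stats::runif(sum(fail), 0.05, 1)

  truth <- list(
    planted = probe_ids[planted_idx],
    realized = matrix(beta_A[planted_idx, , drop = FALSE] -
                        beta_B[planted_idx, , drop = FALSE],
                      length(planted_idx), npair,
                      dimnames = list(probe_ids[planted_idx], pair_id)),
    recurring = matrix(recurring, length(planted_idx), npair,
                       dimnames = list(probe_ids[planted_idx], pair_id)))

  structure(list(beta = beta, detp = detp, sheet = sheet,
                 manifest = manifest, truth = truth, config = config),
            class = "twin_cohort")
}

#' Write a synthetic cohort to a directory as TSV files
#'
#' Writes `beta.tsv`, `detp.tsv`, `sample_sheet.tsv`, `manifest.tsv` and
#' `ground_truth.tsv` (planted probe IDs with per-pair realized signed
#' divergence).
#'
#' @param cohort a `twin_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = cohort$config$seed)
  write_table(cohort$beta, file.path(dir, "beta.tsv"), params)
  write_table(cohort$detp, file.path(dir, "detp.tsv"), params)
  write_table(cohort$sheet, file.path(dir, "sample_sheet.tsv"), params)
  write_table(cohort$manifest, file.path(dir, "manifest.tsv"), params)
  gt <- data.frame(probe_id = rownames(cohort$truth$realized),
                   cohort$truth$realized, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(gt, file.path(dir, "ground_truth.tsv"), params)
  invisible(dir)
}
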