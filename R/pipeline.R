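#' Default pipeline configuration
#'
#' Returns the full configuration skeleton with every threshold at its
#' default (detection alpha 0.05; per-pair delta, cross-sample SD and mean
#' delta cutoffs all 0.05 on the beta scale) so deviations are auditable in
#' the run manifest.
#'
#' @param discovery named list of input paths (`beta`, `sheet`, `manifest`,
#'   optionally `detp`).
#' @param replication optional named list of the same shape.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
pipeline_config <- function(discovery, replication = NULL, out_dir) {
  list(cohorts = list(discovery = discovery, replication = replication),
       thresholds = list(detection_alpha = 0.05, pair_delta = 0.05,
                         sd = 0.05, mean_delta = 0.05),
       selector = list(sd_mode = "samples", min_pair_fraction = 1.0),
       panel = list(score = "mean", n_top = 20),
       out_dir = out_dir, seed = 1)
}

merge_defaults <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- merge_defaults(cfg[[nm]], defaults[[nm]])
    }
  }
  cfg
}

load_cohort_inputs <- function(paths, alpha) {
  for (nm in c("beta", "sheet", "manifest")) {
    if (is.null(paths[[nm]]))
      config_error(paste0("cohort input '", nm, "' missing from config"))
  }
  beta <- read_beta_matrix(paths$beta)
  if (!is.null(paths$detp)) {
    detp <- read_detection_p(paths$detp)
    beta <- apply_detection_mask(beta, detp, alpha)
  }
  list(beta = beta,
       sheet = read_sample_sheet(paths$sheet),
       manifest = read_manifest(paths$manifest))
}

run_cohort_stages <- function(name, inputs, th, sel, out_dir, log) {
  deltas <- compute_pair_deltas(inputs$beta, inputs$sheet)
  summaries <- call_pair_dmcs(deltas, th$pair_delta)
  rec <- select_recurrent_dmcs(inputs$beta, deltas,
                               sd_threshold = th$sd,
                               delta_threshold = th$mean_delta,
                               min_pair_fraction = sel$min_pair_fraction,
                               sd_mode = sel$sd_mode)
  params <- c(list(cohort = name, pair_delta = th$pair_delta),
              attr(rec, "params"))
  write_table(summaries,
              file.path(out_dir, paste0("pair_dmc_summary_", name, ".tsv")),
              params)
  write_table(as.data.frame(rec),
              file.path(out_dir, paste0("recurrent_", name, ".tsv")), params)
  log(sprintf("[%s] %d probes x %d pairs; per-pair DMC counts %d-%d; %d recurrent DMCs selected",
              name, nrow(inputs$beta), nrow(summaries),
              min(summaries$dmc_count), max(summaries$dmc_count),
              sum(rec$selected)))
  list(deltas = deltas, summaries = summaries, recurrent = rec)
}

#' Run the full twin-methylome discrimination pipeline
#'
#' Orchestrates detection-p masking, per-pair delta-beta and DMC calling,
#' recurrent-DMC selection, category enrichment of the discovery set and —
#' when a replication cohort is configured — cross-cohort replication and
#' marker-panel ranking. All stage outputs are written as TSV to the output
#' directory together with a machine-readable run manifest (parameters,
#' input checksums, stage row counts) and a human-readable summary. The run
#' is deterministic: re-running the same configuration reproduces every
#' output byte for byte.
#'
#' @param config a configuration list (see [pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_config(discovery = list(), out_dir = ".")
  defaults$cohorts <- NULL
  config <- merge_defaults(config, defaults)
  if (is.null(config$cohorts$discovery))
    config_error("config must define cohorts$discovery")
  th <- config$thresholds
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] > 1)
      config_error(paste0("threshold '", nm, "' must lie in (0, 1]"))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary_lines <- character(0)
  log <- function(msg) {
    summary_lines <<- c(summary_lines, msg)
    message(msg)
  }

  input_files <- unlist(config$cohorts, use.names = TRUE)
  for (f in input_files) {
    if (!file.exists(f)) config_error(paste0("input file not found: ", f))
  }

  disc_in <- load_cohort_inputs(config$cohorts$discovery, th$detection_alpha)
  disc <- run_cohort_stages("discovery", disc_in, th, config$selector,
                            out_dir, log)

  rec <- disc$recurrent
  dmc_ids <- rec$probe_id[rec$selected]
  bg_ids <- rec$probe_id[rec$eligible & !rec$selected]
  enrich <- NULL
  if (length(dmc_ids) > 0 && length(bg_ids) > 0) {
    dmc_annot <- annotate_probes(dmc_ids, disc_in$manifest)
    bg_annot <- annotate_probes(bg_ids, disc_in$manifest)
    enrich <- lapply(c("gene_structure", "cgi_relation"), function(scheme) {
      e <- chisq_proportions(dmc_annot, bg_annot, scheme)
      write_table(e$counts,
                  file.path(out_dir, paste0("enrichment_", scheme, ".tsv")),
                  list(scheme = scheme, chi2 = e$chi2_stat, df = e$df,
                       p = e$p_value))
      log(sprintf("[enrichment] %s omnibus chi2 = %.3f (df %d, p = %.3g)",
                  scheme, e$chi2_stat, e$df, e$p_value))
      e
    })
    names(enrich) <- c("gene_structure", "cgi_relation")
  } else {
    log("[enrichment] skipped: empty DMC or background set")
  }

  repl <- NULL; panel <- NULL
  if (!is.null(config$cohorts$replication)) {
    repl_in <- load_cohort_inputs(config$cohorts$replication,
                                  th$detection_alpha)
    repl_stage <- run_cohort_stages("replication", repl_in, th,
                                    config$selector, out_dir, log)
    repl <- replicate_dmcs(rec, repl_stage$recurrent)
    venn <- data.frame(set = c("discovery_only", "overlap", "replication_only"),
                       count = c(length(repl$discovery_only), repl$n_overlap,
                                 length(repl$replication_only)),
                       stringsAsFactors = FALSE)
    write_table(venn, file.path(out_dir, "venn_summary.tsv"))
    log(sprintf("[replicate] %d of %d discovery recurrent DMCs replicated (replication set: %d)",
                repl$n_overlap, repl$n_discovery, repl$n_replication))
    if (repl$n_overlap > 0) {
      panel <- rank_markers(repl, disc_in$manifest,
                            n_top = config$panel$n_top,
                            score = config$panel$score)
      write_table(as.data.frame(panel),
                  file.path(out_dir, "marker_panel.tsv"),
                  list(score = config$panel$score, n_top = config$panel$n_top))
      log(sprintf("[panel] top %d markers; best rank score %.4f (%s)",
                  nrow(panel), panel$rank_score[1], panel$probe_id[1]))
    }
  }

  manifest_out <- list(
    pipeline_version = TWINDMC_VERSION,
    parameters = list(thresholds = th, selector = config$selector,
                      panel = config$panel, seed = config$seed),
    input_checksums = as.list(tools::md5sum(input_files)),
    stage_rows = list(
      pair_summaries_discovery = nrow(disc$summaries),
      recurrent_table_discovery = nrow(rec),
      recurrent_selected_discovery = sum(rec$selected),
      replication_overlap = if (is.null(repl)) NULL else repl$n_overlap,
      marker_panel = if (is.null(panel)) NULL else nrow(panel)))
  yaml::write_yaml(manifest_out, file.path(out_dir, "run_manifest.yaml"))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(out_dir = out_dir, discovery = disc, enrichment = enrich,
                 replication = repl, panel = panel,
                 run_manifest = manifest_out))
}
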