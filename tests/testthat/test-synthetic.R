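test_that("cohort generation is fully reproducible from the seed", {
  cfg <- sim_config(n_pairs = 6, n_probes = 300, n_recurrent = 20, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$detp, b$detp)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(sim_config(n_pairs = 6, n_probes = 300,
                                  n_recurrent = 20, seed = 100))
  expect_false(identical(a$beta, c$beta))
})

test_that("zero noise and zero effect produce identical twins", {
  co <- generate_cohort(sim_config(n_pairs = 5, n_probes = 200,
                                   n_recurrent = 10, delta_effect = 0,
                                   noise_sd = 0, seed = 1))
  d <- compute_pair_deltas(co$beta, co$sheet)
  expect_true(all(abs(d$delta) == 0))
})

test_that("planted divergence is calibrated to delta_effect on the beta scale", {
  co <- generate_cohort(sim_config(n_pairs = 47, n_probes = 20000,
                                   n_recurrent = 500, delta_effect = 0.10,
                                   noise_sd = 0.02, seed = 3))
  # ground truth realized divergences agree with the matrix itself
  d <- compute_pair_deltas(co$beta, co$sheet)
  expect_equal(d$delta[co$truth$planted, ], co$truth$realized)
  # mean over planted probes of mean within-pair |dB| ~ delta_effect;
  # noise and logit-scale curvature perturb it by well under 0.01
  expect_lt(abs(mean(abs(co$truth$realized)) - 0.10), 0.01)
})

test_that("planted probes diverge more than background and structure is valid", {
  co <- generate_cohort(sim_config(n_pairs = 10, n_probes = 2000,
                                   n_recurrent = 100, seed = 5))
  expect_true(all(co$beta >= 0.001 & co$beta <= 0.999))
  expect_length(co$truth$planted, 100)
  expect_true(all(co$truth$planted %in% co$manifest$probe_id))
  expect_silent(twindmc:::validate_sample_sheet(co$sheet))

  d <- compute_pair_deltas(co$beta, co$sheet)
  mad <- rowMeans(abs(d$delta))
  planted <- rownames(d$delta) %in% co$truth$planted
  expect_gt(min(mad[planted]), max(mad[!planted]) * 0.5)
  expect_gt(mean(mad[planted]), mean(mad[!planted]) + 0.05)
})

test_that("per-pair DMC counts rise with age when age_gamma > 0 and sex never enters", {
  co <- generate_cohort(sim_config(n_pairs = 40, n_probes = 3000,
                                   n_recurrent = 0, age_gamma = 0.02,
                                   seed = 11))
  s <- call_pair_dmcs(compute_pair_deltas(co$beta, co$sheet))
  expect_gt(age_count_correlation(s)$estimate, 0.5)

  # permuting sex labels cannot change counts: betas never read sex
  sheet2 <- co$sheet
  perm <- sample(unique(sheet2$pair_id))
  sheet2$sex <- rep(co$sheet$sex[match(perm, co$sheet$pair_id)], each = 2)
  s2 <- call_pair_dmcs(compute_pair_deltas(co$beta, sheet2))
  expect_identical(s$dmc_count, s2$dmc_count)
})

test_that("detection failures appear at the configured rate", {
  co <- generate_cohort(sim_config(n_pairs = 20, n_probes = 5000,
                                   n_recurrent = 0, detp_fail_rate = 0.01,
                                   seed = 13))
  rate <- mean(co$detp >= 0.05)
  se <- sqrt(0.01 * 0.99 / length(co$detp))
  expect_lt(abs(rate - 0.01), 4 * se)
  masked <- apply_detection_mask(co$beta, co$detp, 0.05)
  expect_equal(sum(is.na(masked)), sum(co$detp >= 0.05))
})

test_that("generate_manifest respects weights, ordering, and edge cases", {
  # point mass
  w <- list(gene_structure = c(Body = 1), cgi_relation = c(OpenSea = 1))
  mf <- generate_manifest(50, w, seed = 1)
  expect_true(all(mf$gene_structure == "Body"))
  expect_true(all(mf$cgi_relation == "OpenSea"))

  # empty manifest
  mf0 <- generate_manifest(0)
  expect_equal(nrow(mf0), 0)
  expect_named(mf0, c("probe_id", "chrom", "pos", "gene_symbol",
                      "gene_structure", "cgi_relation"))

  # default weights: empirical frequencies within 3 binomial sd
  mf <- generate_manifest(10000, seed = 2)
  w <- twindmc:::default_category_weights()
  for (scheme in names(w)) {
    freq <- table(factor(mf[[scheme]], levels = names(w[[scheme]]))) / 10000
    se <- sqrt(w[[scheme]] * (1 - w[[scheme]]) / 10000)
    expect_true(all(abs(freq - w[[scheme]]) <= 3 * se + 1e-9))
  }

  # unique probes; positions strictly increasing within each chromosome
  expect_false(anyDuplicated(mf$probe_id) > 0)
  for (ch in unique(mf$chrom)) {
    expect_true(all(diff(mf$pos[mf$chrom == ch]) > 0))
  }

  bad <- list(gene_structure = c(Body = 0.5), cgi_relation = c(OpenSea = 1))
  expect_error(generate_manifest(10, bad), class = "twindmc_config_error")
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_probes = 10, n_recurrent = 20),
               class = "twindmc_config_error")
  expect_error(sim_config(detp_fail_rate = 1.5),
               class = "twindmc_config_error")
  expect_error(sim_config(age_range = c(50, 20)),
               class = "twindmc_config_error")
})
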