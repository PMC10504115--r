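test_that("two-criterion selection matches hand-set expectations", {
  sheet <- make_sheet(4)
  # cg1: constant 0.5 -> sd 0, never selected despite deltas being 0
  # cg2: +-0.10 deltas -> mean_abs 0.10 > 0.05, signed mean 0; variable
  # cg3: tiny deltas -> fails criterion (2)
  beta <- make_beta(rbind(
    cg1 = rep(0.5, 8),
    cg2 = c(0.60, 0.50, 0.50, 0.60, 0.62, 0.50, 0.48, 0.60),
    cg3 = c(0.30, 0.31, 0.70, 0.69, 0.30, 0.31, 0.70, 0.69)),
    samples = sheet$sample_id)
  d <- compute_pair_deltas(beta, sheet)
  rec <- select_recurrent_dmcs(beta, d)
  row2 <- rec[rec$probe_id == "cg2", ]
  expect_equal(row2$mean_abs_delta, mean(c(0.10, 0.10, 0.12, 0.12)))
  expect_equal(row2$mean_signed_delta, mean(c(0.10, -0.10, 0.12, -0.12)))
  expect_true(row2$selected)
  expect_false(rec$selected[rec$probe_id == "cg1"])
  expect_equal(rec[rec$probe_id == "cg1", "cross_sample_sd"], 0)
  expect_false(rec$selected[rec$probe_id == "cg3"])
  # sorted by descending mean_abs_delta
  expect_equal(rec$probe_id[1], "cg2")
  expect_true(all(diff(rec$mean_abs_delta) <= 0))
})

test_that("selection equals the brute-force double-loop oracle with missing data", {
  set.seed(31)
  for (i in 1:10) {
    inst <- random_instance(sample(3:10, 1), sample(2:5, 1),
                            na_rate = 0.15)
    d <- compute_pair_deltas(inst$beta, inst$sheet)
    for (mpf in c(1, 0.5)) {
      rec <- select_recurrent_dmcs(inst$beta, d, min_pair_fraction = mpf)
      expect_setequal(rec$probe_id[rec$selected],
                      oracle_select(inst$beta, inst$sheet,
                                    min_pair_fraction = mpf))
    }
  }
})

test_that("selection is invariant to pair order and member swaps, monotone in thresholds", {
  set.seed(32)
  inst <- random_instance(50, 6)
  d <- compute_pair_deltas(inst$beta, inst$sheet)
  rec <- select_recurrent_dmcs(inst$beta, d)

  # reorder pairs and swap all member labels
  sh <- inst$sheet[order(rev(seq_len(nrow(inst$sheet)))), ]
  sh$member <- ifelse(sh$member == "A", "B", "A")
  rec2 <- select_recurrent_dmcs(inst$beta, compute_pair_deltas(inst$beta, sh))
  expect_equal(rec$probe_id, rec2$probe_id)
  expect_equal(rec$selected, rec2$selected)
  expect_equal(rec$mean_abs_delta, rec2$mean_abs_delta)
  expect_equal(rec$mean_signed_delta, -rec2$mean_signed_delta)

  # monotone: selected set shrinks as either threshold rises
  for (mode in c("sd_threshold", "delta_threshold")) {
    prev <- NULL
    for (th in c(0.05, 0.15, 0.3)) {
      args <- list(beta = inst$beta, deltas = d); args[[mode]] <- th
      sel <- do.call(select_recurrent_dmcs, args)
      ids <- sel$probe_id[sel$selected]
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }

  # probe universe mismatch is a contract error
  expect_error(select_recurrent_dmcs(inst$beta[-1, ], d),
               class = "twindmc_contract_error")
})

test_that("sd_mode pair_deltas uses the SD of signed deltas across pairs", {
  set.seed(33)
  inst <- random_instance(30, 5)
  d <- compute_pair_deltas(inst$beta, inst$sheet)
  rec <- select_recurrent_dmcs(inst$beta, d, sd_mode = "pair_deltas")
  for (p in rec$probe_id[1:5]) {
    expect_equal(rec$cross_sample_sd[rec$probe_id == p],
                 sd(d$delta[p, ]))
  }
  expect_identical(attr(rec, "params")$sd_mode, "pair_deltas")
})

test_that("recovery report is exact set arithmetic against planted truth", {
  tab <- data.frame(probe_id = paste0("cg", 1:6),
                    selected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  # selected == planted
  r <- recovery_report(tab, paste0("cg", 1:3))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$fdp, 0)
  # partial overlap
  r <- recovery_report(tab, c("cg1", "cg4"))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$fdp, 2 / 3)
  # nothing selected
  none <- tab; none$selected <- FALSE
  r <- recovery_report(none, c("cg1", "cg2"))
  expect_equal(r$sensitivity, 0)
  expect_equal(r$fdp, 0)
  # planted probe outside the table universe
  expect_error(recovery_report(tab, c("cg1", "cgX")),
               class = "twindmc_contract_error")
})

test_that("selector recovers planted recurrent DMCs on a synthetic cohort", {
  co <- generate_cohort(sim_config(n_pairs = 20, n_probes = 4000,
                                   n_recurrent = 150, delta_effect = 0.10,
                                   noise_sd = 0.02, seed = 8))
  d <- compute_pair_deltas(co$beta, co$sheet)
  rec <- select_recurrent_dmcs(co$beta, d)
  r <- recovery_report(rec, co$truth)
  # independent set-arithmetic check
  sel <- rec$probe_id[rec$selected]
  expect_equal(r$sensitivity,
               sum(co$truth$planted %in% sel) / length(co$truth$planted))
  expect_equal(r$fdp, sum(!(sel %in% co$truth$planted)) / length(sel))
  expect_gte(r$sensitivity, 0.9)
  expect_lte(r$fdp, 0.1)
})
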