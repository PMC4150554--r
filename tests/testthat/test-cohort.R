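test_that("default configuration carries the published study conditions", {
  cfg <- cohort_config()
  expect_equal(cfg$n_total, 702)
  expect_equal(cfg$n_positive, 29)
  vt <- cfg$variables
  expect_equal(unname(unlist(vt["sbp", c("pos_mean", "pos_sd")])), c(124, 31))
  expect_equal(unname(unlist(vt["sbp", c("neg_mean", "neg_sd")])), c(142, 28))
  expect_equal(vt["arr", "neg_mean"], 0.831)
  expect_equal(vt["avhr", "pos_mean"], 86.122)
  expect_length(cfg$signal_variables, 12)
})

test_that("configuration rejects inconsistent settings", {
  expect_error(cohort_config(n_total = 20, n_positive = 20), "n_positive")
  expect_error(cohort_config(signal_variables = c("sbp", "nonesuch")),
               "unknown signal")
  vt <- default_variable_table()
  vt["sbp", "lower"] <- 400
  expect_error(cohort_config(variables = vt), "bounds")
})

test_that("prevalence is exact and generation is seed-deterministic", {
  coh <- generate_cohort(cohort_config(), seed = 5)
  expect_equal(nrow(coh), 702)
  expect_equal(sum(coh$outcome), 29)
  expect_false(any(duplicated(coh$id)))
  coh2 <- generate_cohort(cohort_config(), seed = 5)
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
  coh3 <- generate_cohort(cohort_config(), seed = 6)
  expect_false(identical(coh$sbp, coh3$sbp))
})

test_that("large-cohort group moments match the configured distributions", {
  cfg <- cohort_config(n_total = 5000, n_positive = 500)
  coh <- generate_cohort(cfg, seed = 20)
  pos <- coh$outcome == 1
  vt <- cfg$variables
  for (v in c("sbp", "dbp", "pulse", "resp", "arr", "avhr", "tri_index",
              "lf_norm", "temp", "spo2")) {
    for (g in c("neg", "pos")) {
      idx <- if (g == "pos") pos else !pos
      # the generator's contract is the moment-matched truncated normal;
      # its achievable mean equals the configured (printed) mean except
      # where the bounded family cannot reach the printed SD
      tm <- macerisk:::trunc_moments(vt[v, paste0(g, "_mu")],
                                     vt[v, paste0(g, "_sigma")],
                                     vt[v, "lower"], vt[v, "upper"])
      g_ok <- if (v %in% cfg$signal_variables) g else "neg"
      se <- vt[v, paste0(g_ok, "_sd")] / sqrt(sum(idx))
      if (g == "neg" || v %in% cfg$signal_variables)
        expect_lt(abs(mean(coh[[v]][idx]) - tm["mean"]), 3 * se)
    }
  }
  # and for well-inside-bounds variables the achievable mean IS the
  # printed mean
  for (v in c("sbp", "avhr", "arr", "tri_index")) {
    expect_lt(abs(mean(coh[[v]][pos]) - vt[v, "pos_mean"]),
              3 * vt[v, "pos_sd"] / sqrt(sum(pos)))
    expect_lt(abs(mean(coh[[v]][!pos]) - vt[v, "neg_mean"]),
              3 * vt[v, "neg_sd"] / sqrt(sum(!pos)))
  }
})

test_that("structural couplings hold record by record", {
  coh <- generate_cohort(cohort_config(n_total = 400, n_positive = 40),
                         seed = 8)
  expect_equal(coh$lf_norm + coh$hf_norm, rep(100, 400))
  expect_equal(coh$lf_hf, coh$lf / coh$hf, tolerance = 1e-10)
  expect_equal(coh$lf + coh$hf + coh$vlf, coh$total_power,
               tolerance = 1e-10)
  expect_lt(cor(coh$arr, coh$avhr), -0.8)
  expect_true(all(coh$gcs >= 3 & coh$gcs <= 15))
  expect_true(all(coh$spo2 <= 100))
  expect_true(all(coh$pain >= 0 & coh$pain <= 10))
})

test_that("outcome sub-events have exact counts and cover every positive", {
  coh <- generate_cohort(cohort_config(), seed = 13)
  ev <- as.matrix(coh[coh$outcome == 1,
                      c("mace_death", "mace_cardiac_arrest", "mace_vt",
                        "mace_hypotension")])
  expect_equal(unname(colSums(ev)), c(9, 10, 8, 16))
  expect_true(all(rowSums(ev) >= 1))
  expect_true(all(!as.matrix(coh[coh$outcome == 0, colnames(ev)])))
})

test_that("larger configured separation increases the Mann-Whitney effect", {
  pvals <- sapply(c(0, 10, 25), function(shift) {
    vt <- default_variable_table()
    vt["sbp", "pos_mean"] <- vt["sbp", "neg_mean"] - shift
    mean(sapply(1:5, function(s) {
      coh <- generate_cohort(
        cohort_config(n_total = 300, n_positive = 30, variables = vt,
                      signal_variables = "sbp"), seed = s)
      mann_whitney_p(coh$sbp[coh$outcome == 1], coh$sbp[coh$outcome == 0])
    }))
  })
  expect_gt(pvals[1], pvals[2])
  expect_gt(pvals[2], pvals[3])
})

test_that("synthetic RR series honour their construction contract", {
  const <- generate_rr_series(0.8, 60)
  expect_true(all(abs(as.numeric(const) - 0.8) < 1e-12))
  expect_equal(hrv_time_domain(const)$arr, 0.8)

  lfm <- generate_rr_series(0.8, 300, lf_amp = 0.05, seed = 2)
  expect_gt(hrv_frequency(lfm)$lf_norm, 90)

  # positive-group mean RR recovered within 2% over 5 minutes
  rr <- generate_rr_series(0.723, 300, lf_amp = 0.02, hf_amp = 0.02,
                           noise_sd = 0.01, seed = 3)
  expect_lt(abs(hrv_time_domain(rr)$arr - 0.723) / 0.723, 0.02)

  expect_error(generate_rr_series(0.8, 300, noise_sd = 0.9), "infeasible")
  expect_error(generate_rr_series(-1, 300), "positive")
})

test_that("rr_series mode recomputes HRV columns consistently with targets", {
  cfg <- cohort_config(n_total = 40, n_positive = 8, mode = "rr_series",
                       duration_s = 300)
  coh <- generate_cohort(cfg, seed = 9)
  rr <- attr(coh, "rr")
  expect_length(rr, 40)
  profiles <- t(sapply(rr, function(s) unlist(hrv_profile(s))[c("arr", "std")]))
  expect_equal(unname(coh$arr), unname(profiles[, "arr"]))
  # targeted group mean recovered at cohort level
  expect_lt(abs(mean(coh$arr) - mean(profiles[, "arr"])), 1e-12)
  expect_lt(abs(mean(profiles[, "arr"]) -
                  cfg$variables["arr", "neg_mean"]) /
              cfg$variables["arr", "neg_mean"], 0.1)
})

test_that("cohort writer and reader round-trip the feature table", {
  coh <- generate_cohort(cohort_config(n_total = 50, n_positive = 6),
                         seed = 4)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$sbp, coh$sbp)
  expect_equal(back$outcome, coh$outcome)
  expect_true(all(mace_variables() %in% names(back)))
})
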