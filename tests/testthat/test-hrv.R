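test_that("time-domain parameters match hand computations", {
  td <- hrv_time_domain(rr_series(rep(0.8, 10)))
  expect_equal(td$arr, 0.8)
  expect_equal(td$avhr, 75)
  expect_equal(td$std, 0)
  expect_equal(td$sdhr, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$nn50, 0)
  expect_equal(td$pnn50, 0)

  td <- hrv_time_domain(rr_series(c(0.7, 0.8, 0.9)))
  expect_equal(td$arr, 0.8)
  expect_equal(td$nn50, 2)
  expect_equal(td$pnn50, 100)
  expect_equal(td$rmssd, 0.1)
  expect_equal(td$avhr, (60 / 0.7 + 60 / 0.8 + 60 / 0.9) / 3)
})

test_that("NN50 and RMSSD agree with brute-force loops on random series", {
  set.seed(42)
  for (i in 1:200) {
    x <- runif(sample(5:60, 1), 0.4, 1.4)
    td <- hrv_time_domain(rr_series(x))
    expect_equal(td$nn50, nn50_brute(x))
    expect_equal(td$rmssd, rmssd_brute(x))
  }
})

test_that("avHR dominates 60/aRR by convexity, with equality for constant series", {
  expect_equal(hrv_time_domain(rr_series(rep(0.73, 8)))$avhr, 60 / 0.73)
  set.seed(7)
  for (i in 1:50) {
    x <- runif(sample(5:40, 1), 0.4, 1.4)
    td <- hrv_time_domain(rr_series(x))
    expect_gte(td$avhr, 60 / td$arr - 1e-12)
  }
})

test_that("time-domain and geometric measures are scale equivariant", {
  set.seed(11)
  x <- runif(120, 0.5, 1.1)
  for (c_scale in c(0.5, 1.3)) {
    a <- hrv_time_domain(rr_series(x))
    b <- hrv_time_domain(rr_series(c_scale * x))
    expect_equal(b$arr, c_scale * a$arr)
    expect_equal(b$std, c_scale * a$std)
    expect_equal(b$rmssd, c_scale * a$rmssd)
    expect_equal(b$avhr, a$avhr / c_scale)
    ga <- hrv_geometric(rr_series(x), bin_width = 1 / 128)
    gb <- hrv_geometric(rr_series(c_scale * x), bin_width = c_scale / 128)
    expect_equal(gb$tinn, c_scale * ga$tinn, tolerance = 1e-10)
    expect_equal(gb$tri_index, ga$tri_index)
  }
})

test_that("triangular index equals count over modal bin height", {
  # 100 intervals spread evenly over exactly 4 bins of width 1/128 s
  bw <- 1 / 128
  centers <- 0.8 + (0:3) * bw + bw / 2
  x <- rep(centers, each = 25)
  g <- hrv_geometric(rr_series(sample(x)), bin_width = bw)
  expect_equal(g$tri_index, 4)

  # independent histogram oracle on random series
  set.seed(3)
  for (i in 1:50) {
    y <- runif(sample(20:200, 1), 0.5, 1.2)
    g <- hrv_geometric(rr_series(y), bin_width = bw)
    lo <- floor(min(y) / bw) * bw
    edges <- seq(lo, ceiling(max(y) / bw) * bw + bw / 2, by = bw)
    counts <- tabulate(findInterval(y, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1)
    expect_equal(g$tri_index, length(y) / max(counts))
  }
})

test_that("TINN is zero for degenerate histograms and matches the exhaustive oracle", {
  expect_equal(hrv_geometric(rr_series(rep(0.8, 50)))$tinn, 0)

  bw <- 1 / 128
  # symmetric triangular histogram: counts 1,2,3,2,1 across 5 bins
  centers <- 0.8 + (0:4) * bw + bw / 2
  x <- rep(centers, times = c(1, 2, 3, 2, 1))
  expect_equal(hrv_geometric(rr_series(x), bin_width = bw)$tinn,
               tinn_brute(x, bw))

  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(sample(30:120, 1), 0.8, 0.05)
    y <- y[y > 0.3]
    expect_equal(hrv_geometric(rr_series(y), bin_width = bw)$tinn,
                 tinn_brute(y, bw))
  }
})

test_that("spectral bands isolate the modulation frequency", {
  for (method in c("lomb_scargle", "resample_welch")) {
    lfm <- generate_rr_series(0.8, 300, lf_amp = 0.05, hf_amp = 0,
                              lf_freq = 0.10, seed = 1)
    fd <- hrv_frequency(lfm, method = method)
    expect_gt(fd$lf_norm, 90)
    expect_equal(fd$lf_norm + fd$hf_norm, 100, tolerance = 1e-6)

    hfm <- generate_rr_series(0.8, 300, lf_amp = 0, hf_amp = 0.05,
                              hf_freq = 0.25, seed = 1)
    fd <- hrv_frequency(hfm, method = method)
    expect_gt(fd$hf_norm, 90)
    expect_lt(fd$lf_hf, 0.15)
  }
})

test_that("spectral powers are non-negative and norms sum to 100 when defined", {
  set.seed(9)
  for (i in 1:10) {
    rr <- generate_rr_series(runif(1, 0.6, 1.0), 180,
                             lf_amp = runif(1, 0, 0.04),
                             hf_amp = runif(1, 0, 0.04),
                             noise_sd = runif(1, 0.002, 0.02))
    fd <- hrv_frequency(rr)
    expect_true(all(c(fd$vlf, fd$lf, fd$hf, fd$total_power) >= 0))
    if (!is.na(fd$lf_norm))
      expect_equal(fd$lf_norm + fd$hf_norm, 100, tolerance = 1e-6)
    if (!is.na(fd$lf_hf) && fd$hf > 0)
      expect_equal(fd$lf_hf, fd$lf / fd$hf)
  }
})

test_that("frequency analysis enforces its preconditions", {
  expect_error(hrv_frequency(rr_series(rep(0.8, 10))), "16 intervals")
  expect_error(hrv_frequency(rr_series(rep(0.8, 20))), "60 s")
})

test_that("full profile flags undefined spectra and composes sub-operations", {
  p <- hrv_profile(rr_series(rep(0.8, 400)))
  expect_equal(p$arr, 0.8)
  expect_equal(p$avhr, 75)
  expect_equal(p$std, 0)
  expect_true(is.na(p$lf_norm))
  expect_true(is.na(p$lf_hf))

  rr <- generate_rr_series(0.85, 200, lf_amp = 0.03, hf_amp = 0.02,
                           noise_sd = 0.01, seed = 4)
  p1 <- hrv_profile(rr)
  p2 <- hrv_profile(rr)
  expect_identical(p1, p2)   # deterministic

  td <- hrv_time_domain(rr)
  gd <- hrv_geometric(rr)
  fd <- hrv_frequency(rr)
  for (f in names(td)) expect_equal(p1[[f]], td[[f]])
  for (f in names(gd)) expect_equal(p1[[f]], gd[[f]])
  for (f in names(fd)) expect_equal(p1[[f]], fd[[f]])
})

test_that("profile writer emits conventional column names", {
  rr <- generate_rr_series(0.8, 120, lf_amp = 0.02, hf_amp = 0.02,
                           noise_sd = 0.005, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_hrv(list(p1 = hrv_profile(rr)), tmp)
  d <- read.csv(tmp)
  expect_true(all(c("aRR", "STD", "avHR", "RMSSD", "NN50", "pNN50",
                    "TI", "TINN", "LF", "HF", "LFnorm", "HFnorm",
                    "LF_HF") %in% names(d)))
})
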