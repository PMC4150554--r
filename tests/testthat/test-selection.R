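test_that("balanced subsets pair every positive with an equal negative draw", {
  coh <- generate_cohort(cohort_config(n_total = 150, n_positive = 12),
                         seed = 1)
  subs <- balanced_subsets(coh, n_subsets = 20, seed = 3)
  expect_length(subs, 20)
  for (idx in subs) {
    expect_length(idx, 24)
    expect_equal(sum(coh$outcome[idx] == 1), 12)
    neg <- idx[coh$outcome[idx] == 0]
    expect_false(any(duplicated(neg)))   # without replacement within subset
  }
  expect_identical(balanced_subsets(coh, 5, seed = 7),
                   balanced_subsets(coh, 5, seed = 7))
})

test_that("a cohort with as many negatives as positives forces identical subsets", {
  d <- toy_cohort(n_pos = 10, n_neg = 10)
  subs <- balanced_subsets(d, 6, seed = 1)
  for (idx in subs) expect_setequal(idx, 1:20)
  expect_error(balanced_subsets(toy_cohort(n_pos = 10, n_neg = 5), 3),
               "fewer negatives")
})

test_that("a perfectly separating variable tops the forest ranking", {
  vars <- c("sep", paste0("noise", 1:6))
  for (s in 1:10) {
    set.seed(s)
    d <- data.frame(outcome = rep(0:1, each = 20))
    d$sep <- d$outcome * 4 + rnorm(40, sd = 0.1)
    for (v in vars[-1]) d[[v]] <- rnorm(40)
    top <- rank_subset(d, vars, selection_params(trees = 100, top_k = 3))
    expect_equal(top[1], "sep")
  }
})

test_that("top_k equal to the variable count returns every variable", {
  d <- toy_cohort()
  vars <- setdiff(names(d), "outcome")
  set.seed(1)
  top <- rank_subset(d, vars, selection_params(trees = 50,
                                               top_k = length(vars)))
  expect_setequal(top, vars)
})

test_that("permuting outcome labels destroys the ranking concentration", {
  vars <- c("sep", paste0("noise", 1:6))
  firsts <- sapply(1:12, function(s) {
    set.seed(s)
    d <- data.frame(outcome = sample(rep(0:1, each = 20)))
    d$sep <- rep(0:1, each = 20) * 4 + rnorm(40, sd = 0.1)
    for (v in vars[-1]) d[[v]] <- rnorm(40)
    d$outcome <- sample(d$outcome)   # break the association
    rank_subset(d, vars, selection_params(trees = 60, top_k = 1))
  })
  expect_lt(mean(firsts == "sep"), 0.8)
})

test_that("occurrence tallies conserve mass and respect the subset bound", {
  d <- toy_cohort(n_pos = 15, n_neg = 60)
  p <- selection_params(n_subsets = 25, trees = 40, top_k = 4, seed = 2)
  occ <- ensemble_occurrences(d, p, variables = setdiff(names(d), "outcome"))
  expect_equal(sum(occ$occurrence), 4 * 25)
  expect_lte(max(occ$occurrence), 25)
  # single-subset run: exactly top_k ones
  occ1 <- ensemble_occurrences(d, selection_params(n_subsets = 1, trees = 40,
                                                   top_k = 4, seed = 2),
                               variables = setdiff(names(d), "outcome"))
  expect_equal(sort(occ1$occurrence, decreasing = TRUE)[1:4], rep(1L, 4))
  expect_equal(sum(occ1$occurrence), 4L)
})

test_that("selection has no systematic variable preference under the null", {
  # Within one fixed cohort the 29 positives' chance separations persist
  # across balanced subsets, so occurrences concentrate conditionally.
  # Across independent null cohorts the procedure must be exchangeable:
  # tally one forest ranking per fresh iid-noise cohort and test the
  # aggregate for uniformity.
  vars <- paste0("x", 1:12)
  counts <- setNames(integer(12), vars)
  for (run in 1:60) {
    set.seed(100 + run)
    d <- data.frame(outcome = rep(c(1L, 0L), c(12, 36)))
    for (v in vars) d[[v]] <- rnorm(48)
    p <- selection_params(n_subsets = 1, trees = 40, top_k = 4,
                          seed = 100 + run)
    occ <- ensemble_occurrences(d, p, variables = vars)
    counts[occ$variable] <- counts[occ$variable] + occ$occurrence
  }
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("Mann-Whitney p-values match enumeration, convention, and asymptotics", {
  expect_equal(mann_whitney_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(mann_whitney_p(rep(2, 5), rep(2, 7)), 1)
  set.seed(17)
  expect_lt(mann_whitney_p(rnorm(300), rnorm(300) + 2), 1e-6)
  # exhaustive-enumeration oracle for small untied samples
  for (i in 1:30) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    expect_equal(mann_whitney_p(x, y), mw_enum_p(x, y), tolerance = 1e-10)
  }
})

test_that("selection keeps significant top-ranked variables and audits exclusions", {
  # three strong signal variables, clearly recoverable design
  d <- toy_cohort(n_pos = 40, n_neg = 160, n_signal = 3, n_noise = 9,
                  delta = 1.2, seed = 5)
  p <- selection_params(n_subsets = 40, trees = 60, top_k = 5, seed = 5)
  sel <- select_variables(d, p, variables = setdiff(names(d), "outcome"))
  expect_true(all(c("sig1", "sig2", "sig3") %in% sel$selected))
  expect_true(all(sel$selected %in%
                    head(sel$occurrences$variable, p$top_k)))
  expect_true(all(sel$p_values[sel$selected] < p$alpha))

  # a variable forced into the top ranks but with equal group
  # distributions must be excluded by the significance refinement
  set.seed(6)
  d2 <- toy_cohort(n_pos = 30, n_neg = 90, n_signal = 2, n_noise = 2,
                   delta = 2, seed = 6)
  p2 <- selection_params(n_subsets = 20, trees = 50, top_k = 4, seed = 6)
  sel2 <- select_variables(d2, p2, variables = setdiff(names(d2), "outcome"))
  top4 <- head(sel2$occurrences$variable, 4)
  nulls <- setdiff(top4, c("sig1", "sig2"))
  excluded_nulls <- intersect(nulls[sel2$p_values[nulls] >= 0.05],
                              sel2$excluded$variable)
  expect_setequal(excluded_nulls, nulls[sel2$p_values[nulls] >= 0.05])
})

test_that("selection is deterministic given seed and warns when empty", {
  d <- toy_cohort(n_pos = 12, n_neg = 48, n_signal = 1, delta = 1, seed = 2)
  p <- selection_params(n_subsets = 10, trees = 30, top_k = 3, seed = 9)
  s1 <- select_variables(d, p, variables = setdiff(names(d), "outcome"))
  s2 <- select_variables(d, p, variables = setdiff(names(d), "outcome"))
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$selected, s2$selected)

  dn <- toy_cohort(n_pos = 10, n_neg = 40, n_signal = 0, n_noise = 4,
                   seed = 3)
  expect_warning(
    sel <- select_variables(dn, selection_params(n_subsets = 5, trees = 30,
                                                 top_k = 2, alpha = 1e-6,
                                                 seed = 1),
                            variables = setdiff(names(dn), "outcome")),
    "no top-ranked")
  expect_length(sel$selected, 0)
})

test_that("occurrence rank of a signal variable grows with its effect size", {
  rank_of <- sapply(c(0.3, 1.0, 2.5), function(delta) {
    mean(sapply(1:3, function(s) {
      d <- toy_cohort(n_pos = 20, n_neg = 60, n_signal = 1, n_noise = 7,
                      delta = delta, seed = s)
      occ <- ensemble_occurrences(
        d, selection_params(n_subsets = 15, trees = 40, top_k = 3, seed = s),
        variables = setdiff(names(d), "outcome"))
      which(occ$variable == "sig1")
    }))
  })
  expect_true(rank_of[3] <= rank_of[2])
  expect_true(rank_of[3] < rank_of[1])
})

test_that("selection report writers emit readable artifacts", {
  d <- toy_cohort(n_pos = 15, n_neg = 45)
  p <- selection_params(n_subsets = 8, trees = 30, top_k = 3, seed = 1)
  sel <- select_variables(d, p, variables = setdiff(names(d), "outcome"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_selection(sel$occurrences, csv)
  write_selection(sel, js)
  occ <- read.csv(csv)
  expect_equal(sum(occ$occurrence), 3 * 8)
  rep <- jsonlite::read_json(js)
  expect_equal(unlist(rep$selected), sel$selected)
})
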