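# Rank-based AUC with ties counted 1/2: the Mann-Whitney probability that
# a random positive outscores a random negative.
auc_value <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated risk scores
#'
#' For each record, the entire scoring pipeline -- min-max bounds, class
#' centers and the SVM refiner -- is refitted on the remaining n - 1
#' records and the held-out record is scored by that model, so no record
#' ever influences its own training fold.
#'
#' @param data Cohort data frame with `outcome` and the model variables.
#' @param formula Model formula passed to [risk_score()].
#' @param lambda,kernel,cost,gamma Passed to [risk_score()].
#' @return Numeric vector of held-out scores, one per record, in input
#'   order.
#' @export
loocv_scores <- function(data, formula, lambda = 0.5, kernel = "radial",
                         cost = 1, gamma = NULL) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 3) stop("need at least 3 records for leave-one-out evaluation")
  y <- as.integer(data$outcome)
  if (min(sum(y == 1), sum(y == 0)) < 2)
    stop("a training fold would lose a class: need at least 2 records per class")
  vapply(seq_len(n), function(i) {
    m <- risk_score(formula, data[-i, , drop = FALSE], lambda = lambda,
                    kernel = kernel, cost = cost, gamma = gamma)
    stats::predict(m, data[i, , drop = FALSE])
  }, numeric(1))
}

#' ROC curve and AUC with confidence interval
#'
#' Builds the ROC curve over the threshold grid formed by midpoints
#' between consecutive distinct scores plus sentinels beyond the score
#' range (classification rule: score >= threshold is called positive).
#' The AUC is the rank-based Mann-Whitney probability with ties counted
#' one half; its confidence interval uses the DeLong method by default,
#' or a stratified bootstrap.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (1 = positive).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap CI.
#' @return A `roc_result`: list with `points` (data frame of `threshold`,
#'   `fpr`, `sensitivity`, `specificity`), `auc`, `ci`, `n_positive`,
#'   `n_negative`, and the input scores/labels.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    conf_level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pts <- do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = mean(pred[labels == 1]),
               specificity = mean(!pred[labels == 0]))
  }))
  pts$fpr <- 1 - pts$specificity
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  auc <- auc_value(scores, labels)
  ci <- if (ci_method == "delong") {
    r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                   quiet = TRUE)
    suppressWarnings(as.numeric(
      pROC::ci.auc(r, conf.level = conf_level, method = "delong")))[c(1, 3)]
  } else {
    set.seed(seed)
    pos <- which(labels == 1); neg <- which(labels == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      auc_value(scores[idx], labels[idx])
    }, numeric(1))
    stats::quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    names = FALSE)
  }
  structure(list(points = pts[, c("threshold", "fpr", "sensitivity",
                                  "specificity")],
                 auc = auc, ci = pmin(pmax(ci, 0), 1),
                 conf_level = conf_level, ci_method = ci_method,
                 n_positive = sum(labels == 1), n_negative = sum(labels == 0),
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d%% CI %.3f - %.3f, %s), %d positive / %d negative\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$ci_method, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Wald confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to [0, 1].
#'
#' @param p Point estimate.
#' @param n Sample size.
#' @param conf_level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(p, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  pmin(pmax(c(p - hw, p + hw), 0), 1)
}

#' Operating point nearest the upper-left ROC corner
#'
#' Selects the threshold minimizing the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)` to the ideal corner
#' (0, 1); ties go to the candidate with higher sensitivity. Sensitivity
#' and specificity receive Wald confidence intervals at the ROC's
#' configured level.
#'
#' @param roc A [roc_auc()] result.
#' @return A `cutoff_result`: list with `threshold`, `sensitivity`,
#'   `specificity`, their CIs, and the corner `distance`.
#' @export
optimal_cutoff <- function(roc) {
  pts <- roc$points
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  best <- which(d <= min(d) + 1e-12)
  best <- best[which.max(pts$sensitivity[best])]
  sens <- pts$sensitivity[best]
  spec <- pts$specificity[best]
  structure(list(threshold = pts$threshold[best],
                 sensitivity = sens,
                 sensitivity_ci = wald_ci(sens, roc$n_positive,
                                          roc$conf_level),
                 specificity = spec,
                 specificity_ci = wald_ci(spec, roc$n_negative,
                                          roc$conf_level),
                 distance = d[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cutoff %.3g: sensitivity %.1f%% (%.1f - %.1f), specificity %.1f%% (%.1f - %.1f)\n",
              x$threshold, 100 * x$sensitivity,
              100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2],
              100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  invisible(x)
}

#' LOOCV performance of nested variable prefixes
#'
#' For each k, evaluates the risk score built on the first k variables of
#' an occurrence-ranked list by leave-one-out cross-validation, reporting
#' the AUC and its confidence interval -- the model-size sweep used to
#' pick how many top-ranked variables to keep.
#'
#' @param data Cohort data frame.
#' @param ranked Character vector of variables, most important first.
#' @param lambda,kernel,cost,gamma Passed to [risk_score()].
#' @param ci_method Passed to [roc_auc()].
#' @return Data frame with columns `k`, `variables`, `auc`, `ci_lower`,
#'   `ci_upper`; the row index of the best AUC is stored in the
#'   `best` attribute.
#' @export
prefix_performance <- function(data, ranked, lambda = 0.5, kernel = "radial",
                               cost = 1, gamma = NULL,
                               ci_method = "delong") {
  stopifnot(length(ranked) >= 1)
  rows <- lapply(seq_along(ranked), function(k) {
    vars <- ranked[seq_len(k)]
    sc <- loocv_scores(data, stats::reformulate(vars, response = "outcome"),
                       lambda = lambda, kernel = kernel, cost = cost,
                       gamma = gamma)
    r <- roc_auc(sc, data$outcome, ci_method = ci_method)
    data.frame(k = k, variables = paste(vars, collapse = ", "),
               auc = r$auc, ci_lower = r$ci[1], ci_upper = r$ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$auc)
  out
}

#' Paired bootstrap comparison of two AUCs
#'
#' Resamples patients with replacement, stratified by outcome class, and
#' recomputes both models' AUCs on each replicate (the same replicate for
#' both, so the comparison is paired). The two-sided p-value comes from
#' the normal approximation of the replicate difference distribution:
#' `p = 2 * pnorm(-|AUC_A - AUC_B| / sd(replicate differences))`.
#'
#' @param scores_a,scores_b Two score vectors over the same patients.
#' @param labels Binary outcomes.
#' @param n_boot Bootstrap replicates (default 2000; fewer than 100 draws
#'   a warning).
#' @param seed Integer seed.
#' @return A `comparison_result`: list with `auc_a`, `auc_b`, `diff`
#'   (A - B), `p`, `n_boot`, `seed`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels,
                                  n_boot = 2000, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  d0 <- auc_value(scores_a, labels) - auc_value(scores_b, labels)
  set.seed(seed)
  pos <- which(labels == 1); neg <- which(labels == 0)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_value(scores_a[idx], labels[idx]) -
      auc_value(scores_b[idx], labels[idx])
  }, numeric(1))
  sd_d <- stats::sd(reps)
  p <- if (sd_d == 0) as.numeric(d0 == 0) else 2 * stats::pnorm(-abs(d0) / sd_d)
  structure(list(auc_a = auc_value(scores_a, labels),
                 auc_b = auc_value(scores_b, labels),
                 diff = d0, p = p, n_boot = n_boot, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f: diff %.3f, bootstrap p = %.3g (%d replicates)\n",
              x$auc_a, x$auc_b, x$diff, x$p, x$n_boot))
  invisible(x)
}

#' Pairwise AUC comparison matrix
#'
#' Runs [compare_auc_bootstrap()] for every pair of named score vectors,
#' returning the long-format table of differences and p-values.
#'
#' @param score_list Named list of score vectors over the same patients.
#' @param labels Binary outcomes.
#' @param n_boot,seed Passed to [compare_auc_bootstrap()].
#' @return Data frame with columns `model_a`, `model_b`, `diff`, `p`.
#' @export
pairwise_auc <- function(score_list, labels, n_boot = 2000, seed = 1L) {
  nm <- names(score_list)
  stopifnot(length(nm) >= 2)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    cmp <- compare_auc_bootstrap(score_list[[pr[1]]], score_list[[pr[2]]],
                                 labels, n_boot = n_boot, seed = seed)
    data.frame(model_a = pr[1], model_b = pr[2], diff = cmp$diff, p = cmp$p)
  }))
}

#' Group-conditional summary of cohort variables
#'
#' One row per variable: group summaries formatted as `mean (SD)` --
#' or `median (q1 to q3)` for the ordinal variables (GCS, pain score) --
#' plus the two-sided Mann-Whitney p-value between outcome groups.
#'
#' @param cohort Cohort data frame with `outcome`.
#' @param variables Variables to summarize (default the 23 candidates).
#' @param median_vars Variables summarized as median (IQR).
#' @return Data frame with columns `variable`, `negative`, `positive`,
#'   `p`, plus numeric columns `neg_mean`/`neg_sd`/`pos_mean`/`pos_sd`.
#' @export
summarize_groups <- function(cohort,
                             variables = intersect(mace_variables(),
                                                   names(cohort)),
                             median_vars = c("gcs", "pain")) {
  pos <- cohort$outcome == 1
  fmt <- function(v, idx) {
    x <- cohort[[v]][idx]
    if (v %in% median_vars) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 2)
      sprintf("%g (%g to %g)", q[2], q[1], q[3])
    } else {
      sprintf("%.3g (%.3g)", mean(x), stats::sd(x))
    }
  }
  do.call(rbind, lapply(variables, function(v) {
    data.frame(variable = v,
               negative = fmt(v, !pos), positive = fmt(v, pos),
               p = mann_whitney_p(cohort[[v]][pos], cohort[[v]][!pos]),
               neg_mean = mean(cohort[[v]][!pos]),
               neg_sd = stats::sd(cohort[[v]][!pos]),
               pos_mean = mean(cohort[[v]][pos]),
               pos_sd = stats::sd(cohort[[v]][pos]))
  }))
}
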