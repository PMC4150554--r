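#' Fit min-max normalization bounds
#'
#' Records each variable's training minimum and maximum; the associated
#' transform maps the training range onto [-1, 1]. Variables that are
#' constant in training carry no geometry and are dropped with a warning.
#'
#' @param x Data frame or matrix of raw feature columns.
#' @return A `minmax` object: data frame with columns `min` and `max`,
#'   one row per retained variable.
#' @export
fit_minmax <- function(x) {
  x <- as.data.frame(x)
  rng <- t(vapply(x, range, numeric(2)))
  keep <- rng[, 2] > rng[, 1]
  if (!all(keep))
    warning("dropping constant variable(s): ",
            paste(rownames(rng)[!keep], collapse = ", "))
  if (!any(keep)) stop("no variable with at least 2 distinct training values")
  structure(data.frame(min = rng[keep, 1], max = rng[keep, 2],
                       row.names = rownames(rng)[keep]),
            class = c("minmax", "data.frame"))
}

#' Apply min-max normalization
#'
#' Maps each retained variable through
#' `x -> 2 * (x - min) / (max - min) - 1` using the training bounds.
#' Values outside the training range (possible at test time) are clipped
#' to [-1, 1] so the distance geometry stays bounded.
#'
#' @param bounds A [fit_minmax()] object.
#' @param x New data containing the bound variables.
#' @return Numeric matrix of normalized features in [-1, 1].
#' @export
apply_minmax <- function(bounds, x) {
  x <- as.data.frame(x)
  vars <- rownames(bounds)
  missing <- setdiff(vars, names(x))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  out <- vapply(vars, function(v) {
    z <- 2 * (x[[v]] - bounds[v, "min"]) /
      (bounds[v, "max"] - bounds[v, "min"]) - 1
    pmin(pmax(z, -1), 1)
  }, numeric(nrow(x)))
  matrix(out, nrow = nrow(x), dimnames = list(NULL, vars))
}

#' Class centroids in normalized feature space
#'
#' Each class center is the arithmetic mean of its members' normalized
#' feature vectors, i.e. the point minimizing the sum of squared Euclidean
#' distances to them. A singleton class's center is that single point.
#'
#' @param xn Normalized feature matrix.
#' @param outcome Binary labels (1 = positive).
#' @return List with numeric vectors `positive` and `negative`.
#' @export
cluster_centers <- function(xn, outcome) {
  outcome <- as.integer(outcome)
  if (!any(outcome == 1) || !any(outcome == 0))
    stop("both classes must be present")
  list(positive = colMeans(xn[outcome == 1, , drop = FALSE]),
       negative = colMeans(xn[outcome == 0, , drop = FALSE]))
}

#' Distance-based initial risk score
#'
#' For each sample the Euclidean distances to the positive and negative
#' class centers, d+ and d-, give the initial score
#' `S0 = 100 * d- / (d+ + d-)`: 100 at the positive center, 0 at the
#' negative center, 50 on the equidistant hyperplane (including the
#' degenerate case of coincident centers).
#'
#' @param xn Normalized feature matrix (columns must match the centers).
#' @param centers A [cluster_centers()] list.
#' @return Numeric vector of scores in [0, 100].
#' @export
distance_score <- function(xn, centers) {
  xn <- rbind(xn)
  if (ncol(xn) != length(centers$positive))
    stop("feature dimension does not match the fitted centers")
  dp <- sqrt(colSums((t(xn) - centers$positive)^2))
  dn <- sqrt(colSums((t(xn) - centers$negative)^2))
  s <- ifelse(dp + dn == 0, 50, 100 * dn / (dp + dn))
  unname(s)
}

#' Fit the SVM score refiner
#'
#' Trains a soft-margin SVM on the normalized training data (class weights
#' inversely proportional to class frequency, since the full imbalanced
#' training fold is used here) and fits a Platt-style logistic map from
#' the SVM decision values to [0, 1] on the training outputs. The refined
#' score is `S1 = 100 * calibrated probability`.
#'
#' @param xn Normalized feature matrix.
#' @param outcome Binary labels (1 = positive).
#' @param kernel,cost,gamma SVM hyperparameters; `gamma = NULL` uses the
#'   radial-basis default 1/p.
#' @return A `score_refiner`: list holding the fitted SVM and the
#'   calibration coefficients.
#' @export
fit_refiner <- function(xn, outcome, kernel = "radial", cost = 1,
                        gamma = NULL) {
  y <- factor(as.integer(outcome), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2 || any(table(y) == 0))
    stop("both classes must be present")
  n <- length(y)
  w <- n / (2 * table(y))
  if (is.null(gamma)) gamma <- 1 / ncol(xn)
  fit <- e1071::svm(xn, y, kernel = kernel, cost = cost, gamma = gamma,
                    class.weights = c("0" = unname(w["0"]),
                                      "1" = unname(w["1"])),
                    scale = FALSE)
  dec <- refiner_decision(fit, xn)
  cal <- suppressWarnings(
    stats::glm((y == 1) ~ dec, family = stats::binomial()))
  structure(list(svm = fit, platt = unname(stats::coef(cal)),
                 kernel = kernel, cost = cost, gamma = gamma),
            class = "score_refiner")
}

# Decision values with a fixed orientation (as returned by e1071).
refiner_decision <- function(fit, xn) {
  as.numeric(attr(stats::predict(fit, xn, decision.values = TRUE),
                  "decision.values"))
}

#' @rdname fit_refiner
#' @param refiner A fitted `score_refiner`.
#' @param xn Normalized feature matrix to score.
#' @return `predict_refined` returns scores `S1` in [0, 100].
#' @export
predict_refined <- function(refiner, xn) {
  dec <- refiner_decision(refiner$svm, rbind(xn))
  100 * stats::plogis(refiner$platt[1] + refiner$platt[2] * dec)
}

#' Fit a geometric distance-based risk score model
#'
#' Fits the full scoring pipeline on a training cohort: min-max
#' normalization of the selected variables onto [-1, 1], class centroids
#' in the normalized space giving a distance-based initial score S0, an
#' SVM refiner giving a calibrated score S1, and the blend
#' `S = (1 - lambda) * S0 + lambda * S1`, clipped to [0, 100]. `lambda = 0`
#' is the pure distance score, `lambda = 1` the pure calibrated SVM score.
#'
#' @param formula A formula such as `outcome ~ sbp + avhr + arr` naming
#'   the binary outcome and the predictor variables.
#' @param data Training data frame.
#' @param lambda Blend weight in [0, 1] (default 0.5).
#' @param kernel,cost,gamma Passed to [fit_refiner()]; ignored when
#'   `lambda = 0`.
#' @return A fitted `risk_score` model.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 120, n_positive = 12), seed = 2)
#' m <- risk_score(outcome ~ sbp + avhr + arr, coh)
#' m
#' head(predict(m, coh))
#' @export
risk_score <- function(formula, data, lambda = 0.5, kernel = "radial",
                       cost = 1, gamma = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  mf <- stats::model.frame(formula, as.data.frame(data))
  y <- as.integer(stats::model.response(mf))
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
  x <- mf[, -1, drop = FALSE]
  bounds <- fit_minmax(x)
  xn <- apply_minmax(bounds, x)
  centers <- cluster_centers(xn, y)
  refiner <- if (lambda > 0)
    fit_refiner(xn, y, kernel = kernel, cost = cost, gamma = gamma)
  else NULL
  obj <- structure(list(
    variables = rownames(bounds), bounds = bounds, centers = centers,
    refiner = refiner, lambda = lambda, call = match.call(),
    n = length(y), n_positive = sum(y)
  ), class = "risk_score")
  obj$train_scores <- stats::predict(obj, data)
  obj$train_outcome <- y
  obj
}

#' Predict risk scores from a fitted model
#'
#' @param object A fitted [risk_score()] model.
#' @param newdata Data frame containing the model variables.
#' @param type `"score"` for the blended 0-100 score (default),
#'   `"initial"` for the distance score S0, `"refined"` for the SVM score
#'   S1.
#' @param ... Unused.
#' @return Numeric vector of scores in [0, 100].
#' @export
predict.risk_score <- function(object, newdata,
                               type = c("score", "initial", "refined"),
                               ...) {
  type <- match.arg(type)
  xn <- apply_minmax(object$bounds, newdata)
  s0 <- distance_score(xn, object$centers)
  if (type == "initial") return(s0)
  s1 <- if (!is.null(object$refiner)) predict_refined(object$refiner, xn)
        else rep(NA_real_, nrow(xn))
  if (type == "refined") return(s1)
  s <- if (object$lambda == 0) s0
       else if (object$lambda == 1) s1
       else (1 - object$lambda) * s0 + object$lambda * s1
  pmin(pmax(s, 0), 100)
}

#' @export
print.risk_score <- function(x, ...) {
  cat("Distance-based MACE risk score model\n")
  cat(sprintf("  variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  trained on %d records (%d positive), lambda = %.2f\n",
              x$n, x$n_positive, x$lambda))
  invisible(x)
}

#' @export
summary.risk_score <- function(object, ...) {
  sep <- object$centers$positive - object$centers$negative
  out <- list(
    model = object,
    centers = rbind(positive = object$centers$positive,
                    negative = object$centers$negative),
    separation = sep,
    train_auc = if (length(unique(object$train_outcome)) == 2)
      auc_value(object$train_scores, object$train_outcome) else NA_real_
  )
  class(out) <- "summary.risk_score"
  out
}

#' @export
print.summary.risk_score <- function(x, ...) {
  print(x$model)
  cat("Class centers (normalized space):\n")
  print(round(x$centers, 3))
  cat("Center separation (positive - negative):\n")
  print(round(x$separation, 3))
  cat(sprintf("Apparent (training) AUC: %.3f\n", x$train_auc))
  invisible(x)
}

#' @export
coef.risk_score <- function(object, ...) {
  object$centers$positive - object$centers$negative
}

#' @export
plot.risk_score <- function(x, ...) {
  graphics::boxplot(x$train_scores ~ factor(x$train_outcome,
                                            labels = c("no MACE", "MACE")),
                    ylab = "risk score", xlab = "", ylim = c(0, 100), ...)
  invisible(x)
}

#' Persist a risk score model as JSON
#'
#' Serializes the normalization bounds, class centers, blend weight and
#' the refiner (kernel parameters, support vectors, dual coefficients,
#' intercept and Platt calibration coefficients) so a model can be
#' reloaded and applied without the original training data.
#'
#' @param model A fitted [risk_score()].
#' @param path Output JSON path.
#' @export
write_risk_score <- function(model, path) {
  ref <- model$refiner
  obj <- list(
    variables = model$variables,
    min = unname(model$bounds$min), max = unname(model$bounds$max),
    center_positive = unname(model$centers$positive),
    center_negative = unname(model$centers$negative),
    lambda = model$lambda
  )
  if (!is.null(ref)) {
    s <- ref$svm
    obj$svm <- list(kernel = ref$kernel, cost = ref$cost, gamma = ref$gamma,
                    rho = s$rho,
                    coefs = as.numeric(s$coefs),
                    sv = as.numeric(t(s$SV)), sv_dim = ncol(s$SV),
                    platt = ref$platt)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a risk score model written by [write_risk_score()]
#'
#' The reloaded model evaluates the SVM decision function directly from
#' the stored support vectors, so predictions agree with the original
#' fitted object.
#'
#' @param path JSON path.
#' @return A `risk_score` model usable with [predict.risk_score()].
#' @export
read_risk_score <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- unlist(obj$variables)
  bounds <- structure(data.frame(min = unlist(obj$min),
                                 max = unlist(obj$max), row.names = vars),
                      class = c("minmax", "data.frame"))
  refiner <- NULL
  if (!is.null(obj$svm)) {
    s <- obj$svm
    sv <- matrix(unlist(s$sv), ncol = s$sv_dim, byrow = TRUE)
    refiner <- structure(list(
      svm = structure(list(SV = sv, coefs = unlist(s$coefs), rho = s$rho,
                           gamma = s$gamma, kernel = s$kernel),
                      class = "raw_svm"),
      platt = unlist(s$platt), kernel = s$kernel, cost = s$cost,
      gamma = s$gamma), class = "score_refiner")
  }
  structure(list(
    variables = vars, bounds = bounds,
    centers = list(positive = stats::setNames(unlist(obj$center_positive), vars),
                   negative = stats::setNames(unlist(obj$center_negative), vars)),
    refiner = refiner, lambda = obj$lambda, call = NULL,
    n = NA_integer_, n_positive = NA_integer_
  ), class = "risk_score")
}

# decision function evaluated from stored support vectors
#' @export
predict.raw_svm <- function(object, newdata, decision.values = TRUE, ...) {
  x <- rbind(newdata)
  k <- if (object$kernel == "linear") {
    x %*% t(object$SV)
  } else {
    d2 <- outer(rowSums(x^2), rowSums(object$SV^2), "+") -
      2 * x %*% t(object$SV)
    exp(-object$gamma * pmax(d2, 0))
  }
  dec <- as.numeric(k %*% object$coefs - object$rho)
  structure(factor(as.integer(dec < 0), levels = c(0, 1)),
            decision.values = matrix(dec))
}
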