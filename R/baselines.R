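#' Names of the seven TIMI (UA/NSTEMI) items
#'
#' Age at least 65; three or more coronary risk factors; known coronary
#' stenosis of at least 50%; aspirin use in the prior 7 days; at least two
#' anginal episodes in 24 h; ST deviation of at least 0.5 mm; elevated
#' cardiac markers.
#'
#' @return Character vector of item names, in the cohort column naming
#'   (`timi_` prefix).
#' @export
timi_items <- function() {
  c("timi_age65", "timi_risk_factors3", "timi_stenosis50", "timi_aspirin7d",
    "timi_angina24h", "timi_st_deviation", "timi_markers")
}

#' TIMI risk score
#'
#' One point per positive item, giving an integer from 0 to 7.
#'
#' @param items A data frame or matrix with one logical column per TIMI
#'   item (e.g. the `timi_*` columns of a generated cohort), or a single
#'   logical vector of length 7.
#' @return Integer score(s) 0-7.
#' @examples
#' timi_score(c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))  # 3
#' @export
timi_score <- function(items) {
  if (is.vector(items) && is.logical(items)) items <- rbind(items)
  items <- as.matrix(items)
  if (ncol(items) != 7) stop("TIMI needs exactly 7 items")
  if (any(is.na(items))) stop("all TIMI items must be resolved")
  as.integer(rowSums(items))
}

#' Default MEWS point bands
#'
#' Banded points for the modified early warning score: systolic BP, heart
#' rate, respiratory rate, temperature and AVPU consciousness. Each entry
#' is a list of `(lower, upper, points)` bands that partition the
#' physiological range (`upper` exclusive except the last band). The
#' tables are configuration data, not code: edit, or load alternatives
#' with [read_score_table()].
#'
#' @return Nested list of band tables.
#' @export
mews_table <- function() {
  list(
    sbp = list(c(-Inf, 71, 3), c(71, 81, 2), c(81, 101, 1),
               c(101, 200, 0), c(200, Inf, 2)),
    pulse = list(c(-Inf, 40, 2), c(40, 51, 1), c(51, 101, 0),
                 c(101, 111, 1), c(111, 130, 2), c(130, Inf, 3)),
    resp = list(c(-Inf, 9, 2), c(9, 15, 0), c(15, 21, 1),
                c(21, 30, 2), c(30, Inf, 3)),
    temp = list(c(-Inf, 35, 2), c(35, 38.5, 0), c(38.5, Inf, 2)),
    avpu = c(alert = 0, voice = 1, pain = 2, unresponsive = 3)
  )
}

band_points <- function(value, bands) {
  for (b in bands) if (value >= b[1] && value < b[2]) return(b[3])
  stop("value ", value, " falls outside every configured band")
}

#' Map Glasgow Coma Scale to AVPU
#'
#' Conventional mapping used when consciousness is recorded as GCS:
#' 15 = alert, 13-14 = responds to voice, 9-12 = responds to pain,
#' 8 and below = unresponsive.
#'
#' @param gcs Integer GCS values in 3-15.
#' @return Character vector of AVPU levels.
#' @export
gcs_to_avpu <- function(gcs) {
  stopifnot(all(gcs >= 3 & gcs <= 15))
  cut_lab <- c("unresponsive", "pain", "voice", "alert")
  cut_lab[findInterval(gcs, c(3, 9, 13, 15))]
}

#' Modified early warning score
#'
#' Sums banded points over systolic BP, pulse rate, respiratory rate,
#' temperature and consciousness. Consciousness may be given directly as
#' AVPU or as GCS (mapped through [gcs_to_avpu()]).
#'
#' @param sbp,pulse,resp,temp Vital sign vectors.
#' @param avpu AVPU level (`"alert"`, `"voice"`, `"pain"`,
#'   `"unresponsive"`); alternatively supply `gcs`.
#' @param gcs GCS values, used when `avpu` is missing.
#' @param table Point-band configuration, defaults to [mews_table()].
#' @return Integer score(s).
#' @examples
#' mews_score(sbp = 120, pulse = 80, resp = 12, temp = 36.5, gcs = 15)  # 0
#' @export
mews_score <- function(sbp, pulse, resp, temp, avpu = NULL, gcs = NULL,
                       table = mews_table()) {
  if (is.null(avpu)) {
    if (is.null(gcs)) stop("provide avpu or gcs")
    avpu <- gcs_to_avpu(gcs)
  }
  if (!all(avpu %in% names(table$avpu)))
    stop("unknown AVPU level(s)")
  n <- length(sbp)
  stopifnot(length(pulse) == n, length(resp) == n, length(temp) == n,
            length(avpu) == n)
  pts <- vapply(seq_len(n), function(i) {
    band_points(sbp[i], table$sbp) + band_points(pulse[i], table$pulse) +
      band_points(resp[i], table$resp) + band_points(temp[i], table$temp) +
      table$avpu[[avpu[i]]]
  }, numeric(1))
  as.integer(pts)
}

#' Read a score point table from YAML
#'
#' Loads a banded point table in the layout of [mews_table()]: per-vital
#' lists of `[lower, upper, points]` triples plus a named `avpu` map.
#'
#' @param path YAML file path.
#' @return A point-table list.
#' @export
read_score_table <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw[setdiff(names(raw), "avpu")], function(v)
    lapply(v, function(b) {
      b <- vapply(b, function(x)
        if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x), numeric(1))
      if (is.na(b[1])) b[1] <- -Inf
      if (is.na(b[2])) b[2] <- Inf
      b
    }))
  out$avpu <- unlist(raw$avpu)
  out
}

#' Baseline scores for a generated cohort
#'
#' Convenience wrappers applying [timi_score()] and [mews_score()] to the
#' columns of a [generate_cohort()] data frame.
#'
#' @param cohort A `mace_cohort`.
#' @return Integer score vector, one per patient.
#' @export
timi_from_cohort <- function(cohort) {
  timi_score(cohort[, timi_items()])
}

#' @rdname timi_from_cohort
#' @export
mews_from_cohort <- function(cohort) {
  mews_score(cohort$sbp, cohort$pulse, cohort$resp, cohort$temp,
             gcs = cohort$gcs)
}

#' Forward-selection logistic regression
#'
#' Builds a linear logistic model by forward selection: starting from the
#' intercept-only model, repeatedly adds the candidate variable with the
#' smallest likelihood-ratio p-value, as long as that p-value is below
#' `entry_alpha`. There is no removal step. Predicted probabilities lie
#' in [0, 1] and serve directly as a 0-1 risk score. If the final model
#' shows complete separation, a small ridge penalty is refitted as a
#' fallback (with a warning) when the glmnet package is available.
#'
#' @param data Data frame with the outcome and candidate columns.
#' @param outcome Name of the binary outcome column (default
#'   `"outcome"`).
#' @param candidates Candidate variable names (at least 2).
#' @param entry_alpha Entry threshold for the likelihood-ratio p-value.
#' @return A `forward_logistic`: list with `selected` (in entry order),
#'   the fitted `model`, and `fitted` probabilities.
#' @export
logistic_forward <- function(data, outcome = "outcome",
                             candidates, entry_alpha = 0.05) {
  stopifnot(length(candidates) >= 2, all(candidates %in% names(data)))
  data <- as.data.frame(data)
  y <- as.integer(data[[outcome]])
  if (length(unique(y)) < 2) stop("both classes must be present")
  selected <- character(0)
  remaining <- candidates
  fit <- stats::glm(stats::reformulate("1", response = outcome),
                    family = stats::binomial(), data = data)
  while (length(remaining) > 0 && entry_alpha > 0) {
    ps <- vapply(remaining, function(v) {
      f1 <- suppressWarnings(stats::glm(
        stats::reformulate(c(selected, v), response = outcome),
        family = stats::binomial(), data = data))
      stats::pchisq(fit$deviance - f1$deviance, df = 1, lower.tail = FALSE)
    }, numeric(1))
    best <- which.min(ps)
    if (ps[best] >= entry_alpha) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    fit <- suppressWarnings(stats::glm(
      stats::reformulate(selected, response = outcome),
      family = stats::binomial(), data = data))
  }
  prob <- as.numeric(stats::fitted(fit))
  separated <- length(selected) > 0 &&
    (any(prob > 1 - 1e-8) || any(prob < 1e-8)) &&
    max(abs(stats::coef(fit)[-1])) > 20
  if (separated) {
    warning("separation detected; refitting with a small ridge penalty")
    if (requireNamespace("glmnet", quietly = TRUE)) {
      x <- as.matrix(data[, selected, drop = FALSE])
      gfit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                             lambda = 1e-2)
      prob <- as.numeric(stats::predict(gfit, x, type = "response"))
      fit <- gfit
    }
  }
  structure(list(selected = selected, model = fit, fitted = prob,
                 entry_alpha = entry_alpha, outcome = outcome),
            class = "forward_logistic")
}

#' @export
print.forward_logistic <- function(x, ...) {
  cat("Forward-selection logistic regression\n")
  if (length(x$selected))
    cat("  selected: ", paste(x$selected, collapse = ", "), "\n")
  else cat("  intercept-only model (no candidate entered)\n")
  invisible(x)
}

#' @export
predict.forward_logistic <- function(object, newdata, ...) {
  if (inherits(object$model, "glmnet")) {
    x <- as.matrix(newdata[, object$selected, drop = FALSE])
    as.numeric(stats::predict(object$model, x, type = "response"))
  } else {
    as.numeric(stats::predict(object$model, newdata = newdata,
                              type = "response"))
  }
}
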