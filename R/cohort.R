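#' Names of the candidate predictor variables
#'
#' The 23 candidate predictors used throughout the package: eight triage
#' clinical signs and fifteen HRV parameters.
#'
#' @return Character vector of column names.
#' @export
mace_variables <- function() {
  c("gcs", "temp", "pulse", "resp", "sbp", "dbp", "spo2", "pain",
    "arr", "std", "avhr", "sdhr", "rmssd", "pnn50", "nn50",
    "tri_index", "tinn", "lf", "hf", "total_power",
    "lf_norm", "hf_norm", "lf_hf")
}

# Group-conditional location/scale defaults for the continuous variables,
# with physiological truncation bounds. Negative group = no event within
# 72 h, positive group = MACE within 72 h.
default_variable_table <- function() {
  tab <- rbind(
    temp        = c(36.4,  0.6,   36.4,  0.5,   34,    41),
    pulse       = c(79,    17,    86,    15,    30,    200),
    resp        = c(18,    3,     20,    5,     6,     50),
    sbp         = c(142,   28,    124,   31,    60,    260),
    dbp         = c(77,    15,    67,    17,    30,    160),
    spo2        = c(98,    4,     97,    4,     70,    100),
    arr         = c(0.831, 0.171, 0.723, 0.139, 0.3,   2.0),
    std         = c(0.038, 0.028, 0.034, 0.020, 0.002, 0.5),
    avhr        = c(75.545, 15.862, 86.122, 15.927, 30, 200),
    sdhr        = c(3.618, 2.735, 4.328, 2.886, 0.05,  30),
    rmssd       = c(0.037, 0.039, 0.039, 0.307, 0.001, 0.6),
    pnn50       = c(7.294, 12.617, 7.978, 9.695, 0,    100),
    nn50        = c(23,    41,    31,    44,    0,     600),
    tri_index   = c(3.009, 1.233, 2.481, 0.969, 1,     20),
    tinn        = c(0.134, 0.086, 0.105, 0.069, 0,     1),
    lf          = c(0.128, 0.074, 0.106, 0.092, 0.001, 2),
    hf          = c(0.125, 0.075, 0.139, 0.080, 0.001, 2),
    total_power = c(0.489, 0.110, 0.434, 0.177, 0.01,  3),
    lf_norm     = c(51.173, 20.535, 40.947, 22.966, 2, 95),
    hf_norm     = c(48.827, 20.535, 59.053, 22.996, 0, 100),
    lf_hf       = c(1.641, 1.869, 1.018, 0.910, 0.2,   12),
    vlf         = c(0.236, 0.080, 0.189, 0.080, 0.005, 1),
    age         = c(60.6,  13.0,  61.0,  11.6,  30,    100)
  )
  colnames(tab) <- c("neg_mean", "neg_sd", "pos_mean", "pos_sd",
                     "lower", "upper")
  as.data.frame(tab)
}

default_demographics <- function() {
  list(
    male = c(neg = 445 / 673, pos = 18 / 29),
    race = list(neg = c(chinese = 434, malay = 132, indian = 89, other = 18) / 673,
                pos = c(chinese = 20, malay = 6, indian = 2, other = 1) / 29),
    history = rbind(
      ihd          = c(292 / 673, 10 / 29),
      diabetes     = c(241 / 673, 13 / 29),
      hypertension = c(432 / 673, 17 / 29),
      dyslipidemia = c(403 / 673, 13 / 29),
      stroke       = c(50 / 673, 3 / 29),
      cancer       = c(28 / 673, 1 / 29),
      renal_failure = c(79 / 673, 9 / 29),
      chf          = c(37 / 673, 3 / 29),
      resp_disease = c(18 / 673, 0 / 29),
      mi           = c(96 / 673, 6 / 29),
      pci          = c(149 / 673, 4 / 29),
      cabg         = c(62 / 673, 1 / 29)
    )
  )
}

# Per-group Bernoulli rates for the six TIMI items other than age >= 65
# (which is derived from the generated age). Item-level rates are not
# published; these defaults give a median TIMI around 2 and a modest
# positive-group shift consistent with the weak discrimination reported
# for TIMI at triage.
default_timi_rates <- function() {
  rbind(
    risk_factors3 = c(0.35, 0.45),
    stenosis50    = c(0.30, 0.35),
    aspirin7d     = c(0.30, 0.32),
    angina24h     = c(0.25, 0.30),
    st_deviation  = c(0.10, 0.25),
    markers       = c(0.15, 0.35)
  )
}

#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the published study conditions: 702 patients of whom
#' 29 met the composite MACE outcome within 72 h, group-conditional
#' means/SDs for the 23 candidate predictors, demographic proportions, and
#' the composition of the outcome events (9 deaths, 10 cardiac arrests, 8
#' sustained VT, 16 hypotension requiring inotropes/IABP, overlapping
#' within the 29). `signal_variables` names the variables allowed to
#' differ between outcome groups; the default is the twelve predictors
#' reported as significant (p < 0.05): GCS, pulse rate, respiratory rate,
#' systolic and diastolic BP, aRR, avHR, triangular index, LF power, LF
#' and HF normalized power, and LF/HF. All other variables are drawn from
#' the negative-group distribution for both groups.
#'
#' @param n_total,n_positive Cohort size and exact number of positives.
#' @param variables Data frame of per-variable group-conditional
#'   parameters (`neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`, `lower`,
#'   `upper`), rows named by variable.
#' @param signal_variables Variables allowed to differ between groups.
#' @param demographics Demographic and medical-history proportions.
#' @param timi_rates Per-group Bernoulli rates for the six non-age TIMI
#'   items.
#' @param mace_events Named counts of the outcome sub-events among
#'   positives.
#' @param arr_avhr_rho Gaussian-copula correlation tying aRR and avHR
#'   (negative: long mean RR goes with low mean heart rate).
#' @param gcs_low_prob Per-group probability of a GCS below 15.
#' @param pain Per-group location/scale for the discretized 0-10 pain
#'   score.
#' @param mode `"feature_table"` draws the HRV columns directly;
#'   `"rr_series"` additionally synthesizes a per-patient RR recording and
#'   recomputes the HRV columns from it via [hrv_profile()].
#' @param duration_s RR recording length for `rr_series` mode.
#' @param seed Default seed used by [generate_cohort()] when none is
#'   given.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 702, n_positive = 29,
                          variables = default_variable_table(),
                          signal_variables = c("gcs", "pulse", "resp",
                                               "sbp", "dbp", "arr", "avhr",
                                               "tri_index", "lf", "lf_norm",
                                               "hf_norm", "lf_hf"),
                          demographics = default_demographics(),
                          timi_rates = default_timi_rates(),
                          mace_events = c(death = 9, cardiac_arrest = 10,
                                          vt = 8, hypotension = 16),
                          arr_avhr_rho = -0.95,
                          gcs_low_prob = c(neg = 0.02, pos = 0.25),
                          pain = rbind(neg = c(2.2, 2.5), pos = c(2.9, 2.8)),
                          mode = c("feature_table", "rr_series"),
                          duration_s = 300, seed = 1L) {
  mode <- match.arg(mode)
  if (!(n_positive > 0 && n_positive < n_total))
    stop("need 0 < n_positive < n_total")
  if (any(variables$neg_sd < 0) || any(variables$pos_sd < 0))
    stop("scales must be non-negative")
  if (any(variables$lower >= variables$upper))
    stop("inconsistent truncation bounds")
  known <- c(mace_variables(), "age")
  if (!all(signal_variables %in% known))
    stop("unknown signal variable(s): ",
         paste(setdiff(signal_variables, known), collapse = ", "))
  variables <- match_variable_table(variables)
  structure(list(
    n_total = n_total, n_positive = n_positive, variables = variables,
    signal_variables = signal_variables, demographics = demographics,
    timi_rates = timi_rates, mace_events = mace_events,
    arr_avhr_rho = arr_avhr_rho, gcs_low_prob = gcs_low_prob, pain = pain,
    mode = mode, duration_s = duration_s, seed = seed
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d patients, %d positive (%.1f%%), mode %s\n",
              x$n_total, x$n_positive, 100 * x$n_positive / x$n_total, x$mode))
  cat(sprintf("  signal variables: %s\n",
              paste(x$signal_variables, collapse = ", ")))
  invisible(x)
}

# Truncated-normal draws by inverse CDF; exact marginals. Computed in
# whichever tail keeps the probabilities well away from 1, so draws stay
# finite even when the underlying mean sits far outside the bounds.
rtrunc_norm <- function(n, mean, sd, lower, upper, u = stats::runif(n)) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- if (a > 0) {
    qlo <- stats::pnorm(a, lower.tail = FALSE)
    qhi <- stats::pnorm(b, lower.tail = FALSE)
    stats::qnorm(qlo - u * (qlo - qhi), lower.tail = FALSE)
  } else {
    plo <- stats::pnorm(a)
    phi <- stats::pnorm(b)
    stats::qnorm(plo + u * (phi - plo))
  }
  pmin(pmax(mean + sd * z, lower), upper)
}

# Mean and SD of a normal(mu, sigma) truncated to [lower, upper].
trunc_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sigma^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) whose truncation to [lower, upper] has the target
# mean and SD, so generated variables reproduce the configured moments
# despite physiological bounds. Falls back to the closest achievable
# moments when the target SD exceeds what the bounded support admits.
match_trunc_params <- function(m, s, lower, upper) {
  if (s <= 0) return(c(mu = m, sigma = 0))
  obj <- function(p) {
    tm <- trunc_moments(p[1], exp(p[2]), lower, upper)
    ((tm[1] - m) / s)^2 + ((tm[2] - s) / s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Augment the variable table with moment-matched underlying parameters.
match_variable_table <- function(vt) {
  for (g in c("neg", "pos")) {
    mu <- numeric(nrow(vt)); sigma <- numeric(nrow(vt))
    for (i in seq_len(nrow(vt))) {
      p <- match_trunc_params(vt[i, paste0(g, "_mean")],
                              vt[i, paste0(g, "_sd")],
                              vt[i, "lower"], vt[i, "upper"])
      mu[i] <- p[1]; sigma[i] <- p[2]
    }
    vt[[paste0(g, "_mu")]] <- mu
    vt[[paste0(g, "_sigma")]] <- sigma
  }
  vt
}

# Draw one group's worth of records (continuous + discrete variables).
draw_group <- function(n, config, group) {
  vt <- config$variables
  sig <- config$signal_variables
  pick <- function(v) {
    g <- if (v %in% sig) group else "neg"
    unlist(vt[v, paste0(g, c("_mu", "_sigma"))], use.names = FALSE)
  }
  draw <- function(v, u = stats::runif(n)) {
    p <- pick(v)
    rtrunc_norm(n, p[1], p[2], vt[v, "lower"], vt[v, "upper"], u = u)
  }
  out <- data.frame(row.names = seq_len(n))
  # aRR and avHR through a Gaussian copula: strongly negatively correlated
  # so a record's mean heart rate is consistent with its mean RR width,
  # while both keep their configured marginals.
  rho <- config$arr_avhr_rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  out$arr <- draw("arr", u = stats::pnorm(z1))
  out$avhr <- draw("avhr", u = stats::pnorm(z2))
  for (v in c("age", "temp", "pulse", "resp", "sbp", "dbp", "spo2",
              "std", "sdhr", "rmssd", "pnn50", "tri_index", "tinn",
              "total_power", "vlf", "lf_norm"))
    out[[v]] <- draw(v)
  out$nn50 <- round(draw("nn50"))
  # Spectral structure: LF norm, total power and VLF are drawn; the band
  # powers and the LF/HF ratio follow from the spectral identities
  # (LF + HF = total - VLF, LF norm = 100 LF / (total - VLF),
  # LF/HF = LF norm / HF norm), so every identity holds record by record.
  out$vlf <- pmin(out$vlf, out$total_power - 0.02)
  s_power <- out$total_power - out$vlf
  out$lf <- s_power * out$lf_norm / 100
  out$hf <- s_power * (100 - out$lf_norm) / 100
  out$hf_norm <- 100 - out$lf_norm
  out$lf_hf <- out$lf_norm / (100 - out$lf_norm)
  # GCS: almost always 15; occasional depressed values, more often among
  # positives. Published summary is median 15 (IQR 15-15) in both groups
  # with a significant rank difference, i.e. a tail effect.
  glow <- config$gcs_low_prob[[if (group == "pos" && "gcs" %in% sig) "pos" else "neg"]]
  low <- stats::runif(n) < glow
  gcs <- rep(15L, n)
  if (any(low))
    gcs[low] <- sample(3:14, sum(low), replace = TRUE,
                       prob = c(1, 1, 1, 1, 1, 1, 2, 3, 4, 6, 8, 10))
  out$gcs <- gcs
  pr <- config$pain[if (group == "pos" && "pain" %in% sig) "pos" else "neg", ]
  out$pain <- pmin(pmax(round(stats::rnorm(n, pr[1], pr[2])), 0), 10)
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with exactly `n_positive` positive (MACE) records.
#' Continuous variables come from truncated normals with the configured
#' group-conditional means/SDs; aRR and avHR are tied through a negative
#' Gaussian-copula correlation; HF power is derived as LF / (LF/HF) and
#' normalized HF power as 100 - LF norm, so the spectral identities hold
#' record by record. Variables outside `signal_variables` share the
#' negative-group distribution across groups. Demographics, medical
#' history, TIMI item flags and the outcome sub-event flags are drawn from
#' the configured proportions; every positive record carries at least one
#' sub-event and the sub-event counts are exact. Output is deterministic
#' given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to the seed stored in the config.
#' @return A `mace_cohort`: a data frame with one row per patient holding
#'   id, demographics, history flags, the 23 candidate predictors, TIMI
#'   item flags, outcome sub-event flags and the binary `outcome`. In
#'   `rr_series` mode the RR recordings are attached as the `rr` attribute
#'   (a list of [rr_series()]) and the HRV columns are recomputed from
#'   them.
#' @examples
#' coh <- generate_cohort(cohort_config(n_total = 60, n_positive = 8), seed = 1)
#' table(coh$outcome)
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n_pos <- config$n_positive
  n_neg <- config$n_total - n_pos
  pos <- draw_group(n_pos, config, "pos")
  neg <- draw_group(n_neg, config, "neg")
  d <- rbind(pos, neg)
  d$outcome <- rep(c(1L, 0L), c(n_pos, n_neg))
  d$id <- sprintf("P%04d", seq_len(nrow(d)))

  dem <- config$demographics
  grp <- ifelse(d$outcome == 1, "pos", "neg")
  d$sex <- ifelse(stats::runif(nrow(d)) <
                    ifelse(grp == "pos", dem$male[["pos"]], dem$male[["neg"]]),
                  "male", "female")
  race_of <- function(g, n) sample(names(dem$race[[g]]), n, replace = TRUE,
                                   prob = dem$race[[g]])
  d$race <- NA_character_
  d$race[grp == "pos"] <- race_of("pos", sum(grp == "pos"))
  d$race[grp == "neg"] <- race_of("neg", sum(grp == "neg"))
  for (h in rownames(dem$history)) {
    p <- ifelse(grp == "pos", dem$history[h, 2], dem$history[h, 1])
    d[[paste0("hx_", h)]] <- stats::runif(nrow(d)) < p
  }

  d$timi_age65 <- d$age >= 65
  for (it in rownames(config$timi_rates)) {
    p <- ifelse(grp == "pos", config$timi_rates[it, 2],
                config$timi_rates[it, 1])
    d[[paste0("timi_", it)]] <- stats::runif(nrow(d)) < p
  }

  ev <- assign_mace_events(n_pos, config$mace_events)
  for (e in colnames(ev)) {
    d[[paste0("mace_", e)]] <- FALSE
    d[[paste0("mace_", e)]][d$outcome == 1] <- ev[, e]
  }

  rr <- NULL
  if (config$mode == "rr_series") {
    rr <- lapply(seq_len(nrow(d)), function(i) {
      amp <- rr_modulation(d$std[i], lf_fraction = d$lf_norm[i] / 100)
      generate_rr_series(mean_rr = d$arr[i], duration_s = config$duration_s,
                         lf_amp = amp["lf_amp"], hf_amp = amp["hf_amp"],
                         noise_sd = amp["noise_sd"])
    })
    names(rr) <- d$id
    hrv <- do.call(rbind, lapply(rr, function(s)
      as.data.frame(unclass(hrv_profile(s)))))
    for (v in setdiff(names(hrv), "vlf")) d[[v]] <- hrv[[v]]
  }

  first <- c("id", "age", "sex", "race")
  d <- d[, c(first, setdiff(names(d), first))]
  rownames(d) <- NULL
  structure(d, class = c("mace_cohort", "data.frame"),
            config = config, seed = seed, rr = rr)
}

# Exact-count overlapping sub-event assignment: each event's member set is
# sampled, then membership is repaired so every positive has >= 1 event.
assign_mace_events <- function(n_pos, counts) {
  counts <- pmin(counts, n_pos)
  ev <- matrix(FALSE, n_pos, length(counts),
               dimnames = list(NULL, names(counts)))
  for (j in seq_along(counts)) ev[sample(n_pos, counts[j]), j] <- TRUE
  uncovered <- which(rowSums(ev) == 0)
  for (i in uncovered) {
    donors <- which(rowSums(ev) >= 2)
    j <- which(ev[donors[1], ])[1]
    ev[donors[1], j] <- FALSE
    ev[i, j] <- TRUE
  }
  ev
}

#' @export
print.mace_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MACE cohort: %d patients, %d positive (%.1f%%)\n",
              nrow(x), sum(x$outcome), 100 * mean(x$outcome)))
  if (!is.null(attr(x, "rr"))) cat("  RR recordings attached\n")
  invisible(x)
}

# Sinusoidal modulation amplitudes reproducing a target RR standard
# deviation: a fixed fraction of the variance is white noise, the rest is
# split between the LF and HF oscillations (a sinusoid of amplitude a
# carries variance a^2/2).
rr_modulation <- function(target_sd, lf_fraction = 0.5, noise_fraction = 0.2) {
  v <- target_sd^2
  osc <- (1 - noise_fraction) * v
  c(lf_amp = sqrt(2 * osc * lf_fraction),
    hf_amp = sqrt(2 * osc * (1 - lf_fraction)),
    noise_sd = sqrt(noise_fraction * v))
}

#' Synthesize an RR-interval recording
#'
#' Generates a beat sequence whose interval lengths follow a mean level
#' plus sinusoidal modulations in the LF band (default 0.095 Hz) and HF
#' band (default 0.25 Hz) plus white noise, truncated away from zero, run
#' until the cumulative duration reaches `duration_s`. With zero noise and
#' modulation the output is a constant series at `mean_rr`.
#'
#' @param mean_rr Mean interval in seconds.
#' @param duration_s Target recording length in seconds.
#' @param lf_amp,hf_amp Modulation amplitudes in seconds.
#' @param noise_sd White-noise standard deviation in seconds; must be
#'   smaller than `mean_rr`.
#' @param lf_freq,hf_freq Modulation frequencies in Hz.
#' @param seed Optional seed for the noise draw.
#' @return An [rr_series()].
#' @export
generate_rr_series <- function(mean_rr, duration_s = 300, lf_amp = 0,
                               hf_amp = 0, noise_sd = 0,
                               lf_freq = 0.095, hf_freq = 0.25, seed = NULL) {
  if (mean_rr <= 0 || duration_s <= 0) stop("mean_rr and duration_s must be positive")
  if (noise_sd >= mean_rr)
    stop("infeasible parameters: noise_sd must be below mean_rr")
  if (!is.null(seed)) set.seed(seed)
  floor_rr <- 0.1 * mean_rr
  n_guess <- ceiling(duration_s / mean_rr) + 16L
  t <- 0
  out <- numeric(0)
  while (t < duration_s) {
    eps <- if (noise_sd > 0) stats::rnorm(n_guess, 0, noise_sd) else numeric(n_guess)
    for (i in seq_len(n_guess)) {
      rr <- mean_rr +
        lf_amp * sin(2 * pi * lf_freq * t) +
        hf_amp * sin(2 * pi * hf_freq * t + pi / 3) + eps[i]
      rr <- max(rr, floor_rr)
      out <- c(out, rr)
      t <- t + rr
      if (t >= duration_s) break
    }
  }
  rr_series(out)
}

#' Write a cohort feature table (and optionally RR recordings) to disk
#'
#' The feature table is written as CSV with one row per patient and an
#' `outcome` column coded 0/1. In `rr_series` mode the attached recordings
#' can be written as one long-format CSV per patient under `rr_dir`.
#'
#' @param cohort A `mace_cohort`.
#' @param path Output CSV path.
#' @param rr_dir Optional directory for per-patient RR CSV files.
#' @export
write_cohort <- function(cohort, path, rr_dir = NULL) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  rr <- attr(cohort, "rr")
  if (!is.null(rr_dir) && !is.null(rr)) {
    dir.create(rr_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(rr))
      write_rr(rr[id], file.path(rr_dir, paste0(id, ".csv")))
  }
  invisible(path)
}

#' Read a cohort feature table written by [write_cohort()]
#'
#' @param path CSV path.
#' @return A `mace_cohort` data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("mace_cohort", "data.frame"))
}
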