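#' Time-domain HRV parameters
#'
#' Computes the time-domain heart rate variability summary of an RR series:
#' mean and standard deviation of the RR intervals (`arr`, `std`, seconds),
#' mean and standard deviation of the instantaneous heart rate `60/RR`
#' (`avhr`, `sdhr`, beats/min), the root mean square of successive
#' differences (`rmssd`, seconds), and the count and percentage of
#' successive interval pairs differing by more than 50 ms (`nn50`,
#' `pnn50`). `pnn50` uses the number of successive pairs (n - 1) as its
#' denominator.
#'
#' @param series An [rr_series()].
#' @return Named list with elements `arr`, `std`, `avhr`, `sdhr`, `rmssd`,
#'   `nn50`, `pnn50`.
#' @examples
#' hrv_time_domain(rr_series(c(0.7, 0.8, 0.9)))
#' @export
hrv_time_domain <- function(series) {
  x <- unclass(series)
  hr <- 60 / x
  d <- diff(x)
  nn50 <- sum(abs(d) > 0.050)
  list(
    arr   = mean(x),
    std   = stats::sd(x),
    avhr  = mean(hr),
    sdhr  = stats::sd(hr),
    rmssd = sqrt(mean(d^2)),
    nn50  = nn50,
    pnn50 = 100 * nn50 / (length(x) - 1L)
  )
}

#' Geometric HRV parameters
#'
#' Builds a histogram of the RR intervals with fixed bin width and derives
#' the triangular index -- total interval count divided by the modal bin
#' count -- and TINN, the baseline width of the best least-squares
#' triangular interpolation of the histogram. The triangle's apex is fixed
#' at the modal bin (center X, height Y); its base endpoints (N', M) are
#' searched exhaustively over the histogram bin edges flanking the mode,
#' minimizing the squared error between the triangle and the bin counts
#' over all bins. TINN = M - N'. A histogram with a single occupied bin has
#' no triangular structure and returns TINN = 0 by convention.
#'
#' @param series An [rr_series()].
#' @param bin_width Histogram bin width in seconds. Default 1/128 s
#'   (7.8125 ms), the conventional sampling-grid width for short-term HRV
#'   histograms.
#' @return Named list with elements `tri_index` and `tinn` (seconds).
#' @export
hrv_geometric <- function(series, bin_width = 1 / 128) {
  stopifnot(bin_width > 0)
  x <- unclass(series)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + bin_width / 2
  tri_index <- length(x) / max(counts)
  tinn <- tinn_fit(counts, centers, edges)
  list(tri_index = tri_index, tinn = tinn)
}

# Exhaustive least-squares triangular fit of the RR histogram.
# Apex fixed at the modal bin; base endpoints searched over bin edges.
tinn_fit <- function(counts, centers, edges) {
  occupied <- which(counts > 0)
  if (length(occupied) < 2) return(0)
  m <- which.max(counts)
  X <- centers[m]
  Y <- counts[m]
  n_cand <- edges[seq_len(m)]              # left of (or at) the mode bin
  m_cand <- edges[seq(m + 1L, length(edges))]  # right of the mode bin
  best <- Inf
  best_w <- 0
  for (np in n_cand) {
    up <- ifelse(centers > np & centers <= X, Y * (centers - np) / (X - np), NA)
    for (mm in m_cand) {
      q <- ifelse(centers <= np | centers >= mm, 0,
                  ifelse(centers <= X, up, Y * (mm - centers) / (mm - X)))
      err <- sum((counts - q)^2)
      if (err < best - 1e-12) {
        best <- err
        best_w <- mm - np
      }
    }
  }
  best_w
}

#' Spectral band configuration for HRV analysis
#'
#' Frequency bands in Hz for short (about 5 minute) recordings: VLF
#' 0.003-0.04, LF 0.04-0.15, HF 0.15-0.40. Total power is integrated over
#' 0.003-0.40 Hz. The 0.003 Hz floor is the short-recording convention; at
#' 5 minutes nothing below it is resolvable.
#'
#' @param vlf,lf,hf Numeric length-2 vectors, band limits in Hz.
#' @return A list of bands usable by [hrv_frequency()].
#' @export
hrv_bands <- function(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                      hf = c(0.15, 0.40)) {
  list(vlf = vlf, lf = lf, hf = hf)
}

#' Frequency-domain HRV parameters
#'
#' Estimates the power spectrum of the RR tachogram and integrates it over
#' the VLF, LF and HF bands. Powers are reported in s^2. Two estimators are
#' available: `"lomb_scargle"` evaluates the Lomb-Scargle periodogram
#' directly on the unevenly sampled tachogram (no resampling distortion,
#' the default), and `"resample_welch"` cubic-spline resamples the
#' tachogram at 4 Hz and uses a tapered periodogram. Either spectrum is
#' rescaled so that its integral over the resolvable frequency range equals
#' the tachogram variance.
#'
#' Normalized powers divide by total power minus VLF:
#' `lf_norm = 100 * LF / (total - VLF)` and correspondingly for `hf_norm`,
#' so `lf_norm + hf_norm = 100` whenever defined. When the spectrum carries
#' no power above the VLF band the normalized quantities and the LF/HF
#' ratio are undefined and reported as `NA` rather than 0.
#'
#' @param series An [rr_series()] with at least 16 intervals spanning at
#'   least 60 s.
#' @param method Spectral estimator, see above.
#' @param bands Band limits from [hrv_bands()].
#' @param oversample Frequency oversampling factor for the Lomb-Scargle
#'   grid.
#' @return Named list with elements `vlf`, `lf`, `hf`, `total_power` (s^2),
#'   `lf_norm`, `hf_norm` (normalized units) and `lf_hf`.
#' @export
hrv_frequency <- function(series,
                          method = c("lomb_scargle", "resample_welch"),
                          bands = hrv_bands(), oversample = 4) {
  method <- match.arg(method)
  x <- unclass(series)
  if (length(x) < 16)
    stop("frequency-domain analysis needs at least 16 intervals")
  if (attr(series, "duration") < 60)
    stop("frequency-domain analysis needs at least 60 s of recording")
  t <- cumsum(x)
  fmax <- max(bands$hf[2], bands$lf[2], bands$vlf[2])
  if (stats::var(x) < .Machine$double.eps) {
    ps <- list(freq = numeric(0), power = numeric(0), df = NA_real_)
  } else if (method == "lomb_scargle") {
    ps <- lomb_psd(t, x, fmax = fmax, oversample = oversample)
  } else {
    ps <- resample_psd(t, x, fs = 4, fmax = fmax)
  }
  bp <- function(b) band_power(ps, b[1], b[2])
  vlf <- bp(bands$vlf); lf <- bp(bands$lf); hf <- bp(bands$hf)
  total <- band_power(ps, bands$vlf[1], fmax)
  s <- total - vlf
  out <- list(vlf = vlf, lf = lf, hf = hf, total_power = total)
  if (s <= .Machine$double.eps) {
    out$lf_norm <- NA_real_
    out$hf_norm <- NA_real_
  } else {
    out$lf_norm <- 100 * lf / s
    out$hf_norm <- 100 * hf / s
  }
  out$lf_hf <- if (hf <= .Machine$double.eps) NA_real_ else lf / hf
  out
}

# Lomb-Scargle periodogram of an unevenly sampled, demeaned signal,
# rescaled so the integral over the evaluated grid equals var(x).
lomb_psd <- function(t, x, fmax, oversample = 4) {
  x <- x - mean(x)
  span <- t[length(t)] - t[1]
  df <- 1 / (oversample * span)
  fnyq <- length(x) / (2 * span)   # mean-rate pseudo-Nyquist
  freq <- seq(df, max(fmax, min(fmax * 2, fnyq)), by = df)
  p <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  tot <- sum(p) * df
  scale <- if (tot > 0) stats::var(x) / tot else 0
  list(freq = freq, power = p * scale, df = df)
}

# Cubic-spline resampling of the tachogram to an even 4 Hz grid followed
# by a tapered periodogram, rescaled the same way as lomb_psd.
resample_psd <- function(t, x, fs = 4, fmax) {
  x <- x - mean(x)
  tt <- seq(t[1], t[length(t)], by = 1 / fs)
  xi <- stats::spline(t, x, xout = tt, method = "fmm")$y
  xi <- xi - mean(xi)
  sp <- stats::spec.pgram(stats::ts(xi, frequency = fs), taper = 0.1,
                          detrend = TRUE, plot = FALSE)
  df <- diff(sp$freq[1:2])
  tot <- sum(sp$spec) * df
  scale <- if (tot > 0) stats::var(xi) / tot else 0
  list(freq = sp$freq, power = sp$spec * scale, df = df)
}

band_power <- function(ps, lo, hi) {
  if (!length(ps$freq)) return(0)
  sel <- ps$freq > lo & ps$freq <= hi
  sum(ps$power[sel]) * ps$df
}

#' Full HRV profile of an RR series
#'
#' Assembles the complete set of HRV parameters -- seven time-domain, two
#' geometric and the frequency-domain set -- into one `hrv_profile`
#' object. Output is deterministic given the series and configuration.
#' When the series is too short for spectral analysis (fewer than 16
#' intervals or under 60 s) or carries no variability, the
#' frequency-domain fields are reported as `NA` rather than an error, so
#' profiles of degenerate recordings can still be tabulated.
#'
#' @param series An [rr_series()], normally the output of [filter_rr()].
#' @param method,bands,bin_width Passed to [hrv_frequency()] and
#'   [hrv_geometric()].
#' @return An `hrv_profile`: a named list of the parameters
#'   `arr, std, avhr, sdhr, rmssd, nn50, pnn50, tri_index, tinn, lf, hf,
#'   vlf, total_power, lf_norm, hf_norm, lf_hf`.
#' @examples
#' set.seed(1)
#' rr <- generate_rr_series(mean_rr = 0.8, duration_s = 120, lf_amp = 0.03,
#'                          hf_amp = 0.02, noise_sd = 0.01)
#' hrv_profile(rr)
#' @export
hrv_profile <- function(series, method = c("lomb_scargle", "resample_welch"),
                        bands = hrv_bands(), bin_width = 1 / 128) {
  method <- match.arg(method)
  td <- hrv_time_domain(series)
  gd <- hrv_geometric(series, bin_width = bin_width)
  fd <- if (length(series) >= 16 && attr(series, "duration") >= 60) {
    hrv_frequency(series, method = method, bands = bands)
  } else {
    list(vlf = NA_real_, lf = NA_real_, hf = NA_real_,
         total_power = NA_real_, lf_norm = NA_real_, hf_norm = NA_real_,
         lf_hf = NA_real_)
  }
  structure(c(td, gd, fd), class = "hrv_profile")
}

#' @export
print.hrv_profile <- function(x, digits = 4, ...) {
  cat("HRV profile\n")
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' Write HRV profiles as a CSV table
#'
#' One row per profile, columns labelled with the conventional parameter
#' names (aRR, STD, avHR, sdHR, RMSSD, NN50, pNN50, TI, TINN, LF, HF, VLF,
#' TotalPower, LFnorm, HFnorm, LF_HF).
#'
#' @param profiles A single `hrv_profile` or a named list of them.
#' @param path Output file path.
#' @export
write_hrv <- function(profiles, path) {
  if (inherits(profiles, "hrv_profile")) profiles <- list(`1` = profiles)
  d <- do.call(rbind, lapply(profiles, function(p) as.data.frame(unclass(p))))
  labels <- c(arr = "aRR", std = "STD", avhr = "avHR", sdhr = "sdHR",
              rmssd = "RMSSD", nn50 = "NN50", pnn50 = "pNN50",
              tri_index = "TI", tinn = "TINN", lf = "LF", hf = "HF",
              vlf = "VLF", total_power = "TotalPower", lf_norm = "LFnorm",
              hf_norm = "HFnorm", lf_hf = "LF_HF")
  names(d) <- labels[names(d)]
  d <- cbind(patient_id = names(profiles), d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
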