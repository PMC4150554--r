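# Independent brute-force oracles used to cross-check the package's
# computations on small instances.

# AUC as the literal concordant-pair fraction (ties count 1/2).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# NN50 by an explicit loop over successive pairs.
nn50_brute <- function(x) {
  n <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > 0.050) n <- n + 1
  n
}

# RMSSD by an explicit loop.
rmssd_brute <- function(x) {
  acc <- 0
  for (i in 2:length(x)) acc <- acc + (x[i] - x[i - 1])^2
  sqrt(acc / (length(x) - 1))
}

# Two-sided Mann-Whitney p by exhaustive enumeration of all group
# assignments (no ties assumed): P(|U - EU| >= |U_obs - EU|).
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">"))
  }
  eu <- n1 * n2 / 2
  u_obs <- sum(outer(x, y, ">"))
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - eu) >= abs(u_obs - eu))
}

# Exhaustive triangular-fit search over bin-edge endpoint pairs,
# written independently of the package internals.
tinn_brute <- function(x, bin_width) {
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + bin_width / 2
  if (sum(counts > 0) < 2) return(0)
  m <- which.max(counts)
  X <- centers[m]; Y <- counts[m]
  best_err <- Inf; best_w <- 0
  for (np in edges[seq_len(m)]) {
    for (mm in edges[seq(m + 1, length(edges))]) {
      q <- numeric(length(centers))
      for (j in seq_along(centers)) {
        cc <- centers[j]
        q[j] <- if (cc <= np || cc >= mm) 0
        else if (cc <= X) Y * (cc - np) / (X - np)
        else Y * (mm - cc) / (mm - X)
      }
      err <- sum((counts - q)^2)
      if (err < best_err - 1e-12) { best_err <- err; best_w <- mm - np }
    }
  }
  best_w
}

# Small synthetic two-class feature table with a configurable number of
# informative columns, for selection/scoring machinery tests.
toy_cohort <- function(n_pos = 25, n_neg = 75, n_signal = 3, n_noise = 7,
                       delta = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  out <- data.frame(outcome = rep(c(1L, 0L), c(n_pos, n_neg)))
  for (j in seq_len(n_signal))
    out[[paste0("sig", j)]] <- rnorm(n) + delta * out$outcome
  for (j in seq_len(n_noise))
    out[[paste0("noise", j)]] <- rnorm(n)
  out
}
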