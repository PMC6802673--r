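# independent brute-force oracles; deliberately avoid the package's own
# code paths (and stats::quantile / stats::ave) so agreement is evidence

# linear-interpolation quantile computed directly from sorted order
# statistics: h = (n-1)p + 1, interpolate between floor(h) and ceil(h)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_robust_scale <- function(x) {
  med <- oracle_quantile(x, 0.5)
  iqr <- oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25)
  if (iqr == 0) rep(0, length(x)) else (x - med) / iqr
}

# group mean minus value by explicit double loop
oracle_moving_average <- function(records, protein, axes) {
  n <- nrow(records)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in seq_len(n)) {
      same <- TRUE
      for (a in axes) same <- same && records[[a]][i] == records[[a]][j]
      if (same) { acc <- acc + records[[protein]][j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt - records[[protein]][i]
  }
  out
}

# explicit refit-n-times LOOCV with its own scaling, calling the
# underlying libraries directly
oracle_loocv <- function(x, y, fit_fun) {
  n <- nrow(x)
  correct <- 0
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; xte <- x[i, , drop = FALSE]
    med <- apply(xtr, 2, oracle_quantile, p = 0.5)
    iqr <- apply(xtr, 2, oracle_quantile, p = 0.75) -
           apply(xtr, 2, oracle_quantile, p = 0.25)
    sc <- function(m) {
      for (j in seq_len(ncol(m))) {
        m[, j] <- if (iqr[j] == 0) 0 else (m[, j] - med[j]) / iqr[j]
      }
      m
    }
    pred <- fit_fun(sc(xtr), y[-i], sc(xte))
    correct <- correct + (pred == y[i])
  }
  correct / n
}
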