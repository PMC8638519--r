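# Small numeric helpers shared across modules.

# OLS slope of y (vector, or matrix rows) against x.
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom <= 0) abort("cannot fit a slope: window has no spread in x")
  if (is.matrix(y)) {
    as.numeric(y %*% xc) / denom
  } else {
    sum(xc * y) / denom
  }
}

# Trapezoidal integral of y over x (both sorted by x).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Indices of x falling inside [lo, hi], boundaries inclusive.
in_window <- function(x, window) {
  which(x >= window[1] - 1e-9 & x <= window[2] + 1e-9)
}

check_window <- function(window, arg = "window") {
  if (!is.numeric(window) || length(window) != 2 || !all(is.finite(window)) ||
      window[1] >= window[2]) {
    abort(sprintf("`%s` must be a numeric interval c(lo, hi) with lo < hi", arg))
  }
  invisible(window)
}
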