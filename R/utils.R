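# Internal numerical helpers shared by the PET and CTP forward models.

# Cumulative trapezoid integral of y sampled on a uniform grid with spacing dt.
# Returns a vector the same length as y; first element 0.
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dt
}

# Exact convolution of a piecewise-linear signal `ca` (uniform grid, spacing dt)
# with the kernel exp(-alpha * t).  Each step contributes the closed-form
# integral of the linear segment against the exponential, and the running
# result is propagated with the one-step decay factor (a linear recurrence,
# evaluated in C via stats::filter).  y[1] corresponds to t = 0 and is 0.
conv_exp_uniform <- function(ca, alpha, dt) {
  n <- length(ca)
  if (n < 2L) return(rep(0, n))
  if (alpha <= 0) return(cumtrapz_uniform(ca, dt))
  a <- ca[-n]
  b <- ca[-1L]
  d <- exp(-alpha * dt)
  seg <- a * (1 - d) / alpha + (b - a) * (1 / alpha - (1 - d) / (alpha^2 * dt))
  y <- stats::filter(seg, d, method = "recursive")
  c(0, as.numeric(y))
}

# Running integral over a trailing window of width `width`:
#   out(t) = integral of y over [t - width, t],
# for y piecewise linear on a uniform grid. width = 0 gives 0.
conv_box_uniform <- function(y, width, dt, t) {
  if (width <= 0) return(rep(0, length(y)))
  ci <- cumtrapz_uniform(y, dt)
  lag <- stats::approx(t, ci, xout = t - width, yleft = 0, rule = 2)$y
  ci - lag
}

# Linear interpolation of y (on grid t) at t - shift; 0 before the origin.
shift_curve <- function(y, t, shift) {
  if (shift == 0) return(y)
  stats::approx(t, y, xout = t - shift, yleft = 0, rule = 2)$y
}

# Inverse-CDF truncated-normal draws; errors out when the requested truncation
# leaves essentially no probability mass (infeasible generator configuration).
rtruncnorm_icdf <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-10) {
    stop("infeasible truncated-normal configuration: interval [", lower, ", ",
         upper, "] carries no mass under N(", mean, ", ", sd, ")")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Largest-remainder apportionment of n into length(fractions) integer counts.
apportion_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
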