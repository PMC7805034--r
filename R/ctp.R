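#' CT-perfusion parameters
#'
#' Perfusion quantities of the Johnson-Wilson (adiabatic approximation)
#' model. Blood volume and the permeability-surface product are never
#' independent inputs: they are derived from the fitted quantities via the
#' central volume principle and the Crone-Renkin relation,
#' \deqn{BV = BF \cdot MTT / 60, \qquad PS = -BF \ln(1 - E),}
#' with the factor 60 converting MTT from seconds to minutes.
#'
#' @param BF blood flow, mL/min/100 g, >= 0.
#' @param MTT mean (capillary) transit time, s, >= 0.
#' @param E extraction fraction, unitless, in \[0, 1).
#' @param ke interstitial clearance rate, 1/s, >= 0.
#' @param delay arterial arrival delay relative to the tissue curve, s.
#' @return A `perfusion_params` object with derived `BV` (mL/100 g) and `PS`
#'   (mL/min/100 g).
#' @examples
#' perfusion_params(BF = 50, MTT = 6, E = 0.3)  # BV 5, PS 17.83
#' @export
perfusion_params <- function(BF, MTT, E = 0, ke = 0, delay = 0) {
  if (BF < 0 || MTT < 0 || ke < 0) stop("BF, MTT and ke must be >= 0")
  if (E < 0 || E >= 1) stop("E must lie in [0, 1)")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(BF = BF, MTT = MTT, E = E, ke = ke, delay = delay,
                 BV = BF * MTT / 60, PS = -BF * log1p(-E)),
            class = "perfusion_params")
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf("Perfusion parameters: BF = %.4g mL/min/100g, BV = %.4g mL/100g, MTT = %.4g s\n",
              x$BF, x$BV, x$MTT))
  cat(sprintf("  E = %.3g, PS = %.4g mL/min/100g, ke = %.4g /s, delay = %.3g s\n",
              x$E, x$PS, x$ke, x$delay))
  invisible(x)
}

#' Johnson-Wilson impulse residue function
#'
#' Adiabatic-approximation impulse residue:
#' \deqn{R(t) = 1 \ \mathrm{for}\ 0 \le t < MTT, \qquad
#'       R(t) = E\,e^{-k_e (t - MTT)} \ \mathrm{for}\ t \ge MTT,}
#' i.e. the whole bolus resides in the capillary for one transit time, after
#' which the extracted fraction `E` washes out of the interstitium at rate
#' `ke`. `R` is right-continuous and monotone non-increasing, with
#' \eqn{R(0) = 1} and \eqn{\int_0^\infty R = MTT + E/k_e}.
#'
#' @param t times (s); negative times return 0.
#' @param MTT mean transit time, s, >= 0.
#' @param E extraction fraction in \[0, 1).
#' @param ke interstitial clearance rate, 1/s, >= 0.
#' @return Unitless residue values.
#' @export
jw_impulse_residue <- function(t, MTT, E = 0, ke = 0) {
  if (MTT < 0 || ke < 0) stop("MTT and ke must be >= 0")
  if (E < 0 || E >= 1) stop("E must lie in [0, 1)")
  out <- numeric(length(t))
  vascular <- t >= 0 & t < MTT
  out[vascular] <- 1
  tail <- t >= MTT
  out[tail] <- E * exp(-ke * (t[tail] - MTT))
  out
}

#' Tissue enhancement curve container
#'
#' Baseline-subtracted contrast-enhancement samples (HU above baseline)
#' at instantaneous sample times (s).
#'
#' @param times sorted non-negative sample times (s).
#' @param values enhancement values (HU), finite.
#' @return An `enhancement_curve` object (a data frame).
#' @export
enhancement_curve <- function(times, values) {
  stopifnot(length(times) == length(values), all(is.finite(values)),
            !is.unsorted(times), all(times >= 0))
  out <- data.frame(times = as.numeric(times), values = as.numeric(values))
  class(out) <- c("enhancement_curve", "data.frame")
  out
}

# Continuous CTP tissue curve on a uniform grid (internal).
# tissue(t) = BF/6000 * [ int_{t-MTT}^t Ca du + E * (Ca (x) e^{-ke .})(t - MTT) ]
# with Ca in HU, t in seconds; BF/6000 converts mL/min/100g to mL/s/g.
ctp_curve_grid <- function(BF, MTT, E, ke, ca, t, dt) {
  box <- conv_box_uniform(ca, MTT, dt, t)
  if (E > 0) {
    washout <- E * shift_curve(conv_exp_uniform(ca, ke, dt), t, MTT)
  } else {
    washout <- 0
  }
  BF / 6000 * (box + washout)
}

#' Simulate a CT-perfusion tissue enhancement curve
#'
#' Convolves the arterial enhancement curve with the Johnson-Wilson impulse
#' residue, scaled by blood flow (density 1 g/mL, so 100 g of tissue occupies
#' 100 mL):
#' \deqn{C_t(t) = \frac{BF}{60 \cdot 100}\,
#'       (C_a \otimes R)(t - \mathrm{delay}).}
#' The curve is linear in the arterial amplitude and causal: tissue
#' enhancement is zero before arterial onset plus delay. For a purely
#' intravascular tracer (`E = 0`) with complete venous washout, the ratio of
#' tissue to arterial areas equals `BV / 100`.
#'
#' @param params a [perfusion_params()] object.
#' @param arterial an `aif` object (typically [aif_gamma_variate()]) or an
#'   [enhancement_curve()] covering the requested times.
#' @param times sample times (s), default [ctp_sampling_times()].
#' @param dt internal grid spacing (s); must divide the sample times.
#' @return An [enhancement_curve()] of tissue enhancement (HU).
#' @export
forward_ctp <- function(params, arterial, times = ctp_sampling_times(),
                        dt = 0.1) {
  stopifnot(inherits(params, "perfusion_params"), all(times >= 0))
  end_s <- max(times)
  if (max(abs(round(times / dt) * dt - times)) > 1e-6) {
    stop("`dt` must divide the requested sample times")
  }
  t <- seq(0, end_s, by = dt)
  ca <- if (inherits(arterial, "enhancement_curve")) {
    sample_input(list(times = arterial$times, values = arterial$values),
                 t - params$delay, end_s)
  } else {
    sample_input(arterial, t - params$delay, end_s)
  }
  ct <- ctp_curve_grid(params$BF, params$MTT, params$E, params$ke, ca, t, dt)
  idx <- round(times / dt) + 1L
  enhancement_curve(times, ct[idx])
}

#' Fit the Johnson-Wilson model to a tissue enhancement curve
#'
#' Deterministic multi-start bounded Levenberg-Marquardt least squares for
#' (BF, MTT, E, ke); BV and PS are derived from the fit via the central
#' volume principle and Crone-Renkin relation, never independently estimated,
#' so the [perfusion_params()] invariants hold to machine precision by
#' construction. The objective is screened on a fixed start grid and full
#' optimisation run from the best `n_polish` starts.
#'
#' @param tissue an [enhancement_curve()] with at least 15 samples spanning
#'   the first pass.
#' @param arterial arterial input, as in [forward_ctp()].
#' @param free parameters to fit, subset of `c("BF","MTT","E","ke","delay")`
#'   (delay fixed at `start$delay` by default).
#' @param start named list of fixed values / nuisance starts.
#' @param bounds named list of `c(lower, upper)`; defaults BF \[0.1, 300\],
#'   MTT \[0.5, 30\] s, E \[0, 0.95\], ke \[1e-5, 0.2\] 1/s, delay \[0, 15\] s.
#' @param init_grid data frame of starting values for the free parameters.
#' @param n_polish number of screened starts polished to convergence.
#' @param dt internal grid spacing (s).
#' @return A `ctp_fit` object: `params` ([perfusion_params()]), `fitted`
#'   values, `diagnostics` (rss, convergence flag, `e_at_bound` flag when the
#'   extraction fraction is pinned at a bound, covariance estimate).
#' @export
fit_ctp <- function(tissue, arterial,
                    free = c("BF", "MTT", "E", "ke"),
                    start = list(delay = 0),
                    bounds = NULL, init_grid = NULL, n_polish = 4L,
                    dt = 0.1) {
  stopifnot(inherits(tissue, "enhancement_curve"))
  if (nrow(tissue) < 15L) stop("need at least 15 samples to fit")
  free <- match.arg(free, c("BF", "MTT", "E", "ke", "delay"),
                    several.ok = TRUE)
  default_bounds <- list(BF = c(0.1, 300), MTT = c(0.5, 30), E = c(0, 0.95),
                         ke = c(1e-5, 0.2), delay = c(0, 15))
  bounds <- utils::modifyList(default_bounds, bounds %||% list())
  base <- utils::modifyList(list(BF = 50, MTT = 6, E = 0.2, ke = 0.01,
                                 delay = 0),
                            start %||% list())
  if (is.null(init_grid)) {
    init_grid <- expand.grid(BF = c(15, 50, 150), MTT = c(3, 8, 16),
                             E = c(0.05, 0.2, 0.5), ke = c(0.003, 0.02))
  }

  times <- tissue$times
  end_s <- max(times)
  grid_t <- seq(0, end_s, by = dt)
  idx <- round(times / dt) + 1L
  if (max(abs(grid_t[idx] - times)) > 1e-6) {
    stop("`dt` must divide the tissue sample times")
  }
  ca_cache <- new.env(parent = emptyenv())
  get_ca <- function(delay) {
    key <- sprintf("%.9g", delay)
    if (is.null(ca_cache[[key]])) {
      ca_cache[[key]] <- if (inherits(arterial, "enhancement_curve")) {
        sample_input(list(times = arterial$times, values = arterial$values),
                     grid_t - delay, end_s)
      } else {
        sample_input(arterial, grid_t - delay, end_s)
      }
    }
    ca_cache[[key]]
  }
  obs <- tissue$values
  full_par <- function(theta) {
    p <- base
    p[free] <- as.list(theta)
    p
  }
  model_at <- function(p) {
    ctp_curve_grid(p$BF, p$MTT, p$E, p$ke, get_ca(p$delay), grid_t, dt)[idx]
  }
  resid_fun <- function(theta) model_at(full_par(theta)) - obs

  lower <- vapply(bounds[free], `[`, numeric(1), 1L)
  upper <- vapply(bounds[free], `[`, numeric(1), 2L)
  starts <- lapply(seq_len(nrow(init_grid)), function(i) {
    th <- unlist(base[free])
    g <- init_grid[i, , drop = FALSE]
    for (nm in intersect(free, names(init_grid))) th[nm] <- g[[nm]]
    pmin(pmax(th, lower), upper)
  })
  starts <- unique(starts)
  screen_rss <- vapply(starts, function(th) sum(resid_fun(th)^2), numeric(1))
  polish_idx <- order(screen_rss)[seq_len(min(n_polish, length(starts)))]

  best <- NULL
  any_converged <- FALSE
  for (i in polish_idx) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    any_converged <- any_converged || ok
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss, ok = ok)
    }
  }
  if (is.null(best)) stop("all optimisation starts failed")

  theta <- best$fit$par
  p <- full_par(theta)
  params <- perfusion_params(p$BF, p$MTT, p$E, p$ke, p$delay)
  e_at_bound <- "E" %in% free &&
    (abs(p$E - bounds$E[1L]) < 1e-8 || abs(p$E - bounds$E[2L]) < 1e-8)
  dof <- max(length(obs) - length(free), 1L)
  covariance <- tryCatch({
    v <- (best$rss / dof) * solve(best$fit$hessian)
    dimnames(v) <- list(free, free)
    v
  }, error = function(e) NULL)

  structure(list(
    params = params, fitted = model_at(p),
    diagnostics = list(rss = best$rss, converged = any_converged,
                       e_at_bound = e_at_bound, info = best$fit$info,
                       n_starts = length(starts), covariance = covariance)),
    class = "ctp_fit")
}

#' @export
print.ctp_fit <- function(x, ...) {
  cat("Johnson-Wilson impulse-residue fit\n")
  print(x$params)
  d <- x$diagnostics
  cat(sprintf("  RSS %.4g, converged: %s%s\n", d$rss, d$converged,
              if (isTRUE(d$e_at_bound)) " (E pinned at bound)" else ""))
  invisible(x)
}
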