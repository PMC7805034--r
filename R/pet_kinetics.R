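#' Kinetic parameters of the flow-modified two-tissue compartment model
#'
#' Container with validity checks for the micro rate constants of the FDG
#' model used throughout the package. The standard two-tissue exchange
#' (free and phosphorylated tracer pools) is augmented by a vascular
#' transit-time plateau of duration `Tc` that models flow-limited delivery
#' through the capillary bed, plus a fractional blood volume `vb` and an
#' input delay.
#'
#' @param K1 influx rate constant, mL/min/g, >= 0.
#' @param k2 efflux rate constant, 1/min, > 0.
#' @param k3 binding (phosphorylation) rate constant, 1/min, >= 0.
#' @param k4 dissociation (dephosphorylation) rate constant, 1/min, >= 0.
#' @param vb fractional blood volume, unitless, in \[0, 1).
#' @param Tc vascular (capillary) transit time, s, >= 0.
#' @param delay input-function delay, s, >= 0.
#' @return A `kinetic_params` object.
#' @seealso [impulse_response()], [forward_tac()], [fit_tac()],
#'   [macro_parameters()]
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vb = 0, Tc = 0, delay = 0) {
  stopifnot(is.numeric(K1), is.numeric(k2))
  if (K1 < 0) stop("K1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  if (k3 < 0 || k4 < 0) stop("k3 and k4 must be >= 0")
  if (vb < 0 || vb >= 1) stop("vb must lie in [0, 1)")
  if (Tc < 0 || delay < 0) stop("Tc and delay must be >= 0")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb, Tc = Tc,
                 delay = delay),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: K1 = %.4g mL/min/g, k2 = %.4g, k3 = %.4g, k4 = %.4g /min\n",
    x$K1, x$k2, x$k3, x$k4))
  cat(sprintf("  vb = %.3g, Tc = %.3g s, delay = %.3g s\n", x$vb, x$Tc, x$delay))
  invisible(x)
}

# Eigenvalues of the two-tissue exchange matrix:
#   alpha_{1,2} = [(k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)] / 2.
# The discriminant is (k2+k3+k4)^2 - 4 k2 k4 = (k2-k4)^2 + k3^2 + 2 k3 (k2+k4)
# >= 0 for non-negative rates, so real eigenvalues are guaranteed.
two_tissue_eigen <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  stopifnot(disc >= -1e-12)
  r <- sqrt(max(disc, 0))
  list(alpha1 = (s - r) / 2, alpha2 = (s + r) / 2)
}

# Two-exponential tissue impulse response of the plain two-tissue model,
# h(t) = K1/(a2-a1) * [(k3+k4-a1) e^{-a1 t} + (a2-k3-k4) e^{-a2 t}],
# t in minutes; h(0) = K1. Falls back to the confluent (equal-eigenvalue)
# limit K1 e^{-a t} [1 + (k3+k4-a) t] when the eigenvalue gap underflows.
two_tissue_response <- function(K1, k2, k3, k4, t_min) {
  ev <- two_tissue_eigen(k2, k3, k4)
  a1 <- ev$alpha1; a2 <- ev$alpha2
  if (a2 - a1 < 1e-10 * max(a2, 1)) {
    a <- (a1 + a2) / 2
    return(K1 * exp(-a * t_min) * (1 + (k3 + k4 - a) * t_min))
  }
  K1 / (a2 - a1) * ((k3 + k4 - a1) * exp(-a1 * t_min) +
                      (a2 - k3 - k4) * exp(-a2 * t_min))
}

#' Tissue impulse response of the flow-modified two-tissue model
#'
#' Impulse residue of the kinetic model: a vascular plateau of height `K1`
#' and duration `Tc` (flow-limited delivery through the capillary) followed by
#' the analytic two-exponential response of the two-tissue compartment system
#' with eigenvalues
#' \deqn{\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp
#'       \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}}{2}.}
#' Because the plain two-tissue response also starts at `K1`, the combined
#' response is continuous at `Tc`, right-continuous everywhere, non-negative,
#' and with `k3 = 0` monotone non-increasing after the plateau. With
#' `Tc = 0` it reduces exactly to the standard two-tissue model.
#'
#' @param params a [kinetic_params()] object (`vb` and `delay` are not part of
#'   the tissue response; they enter in [forward_tac()]).
#' @param t times (s) at which to evaluate, >= 0.
#' @return Response values in mL/min/g (the `K1`-scaled residue).
#' @examples
#' p <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.05, k4 = 0.01, Tc = 6)
#' impulse_response(p, c(0, 3, 6, 60, 600))
#' @export
impulse_response <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"), all(t >= 0))
  Tc_s <- params$Tc
  out <- numeric(length(t))
  plateau <- t < Tc_s
  out[plateau] <- params$K1
  if (any(!plateau)) {
    tau_min <- (t[!plateau] - Tc_s) / 60
    out[!plateau] <- two_tissue_response(params$K1, params$k2, params$k3,
                                         params$k4, tau_min)
  }
  out
}

#' Time-activity curve container
#'
#' Couples frame-averaged activity values (kBq/mL) to a [frame_schedule()],
#' with optional non-negative fitting weights (one per frame).
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric activity per frame (kBq/mL), finite.
#' @param weights optional non-negative fitting weights; default is frame
#'   duration (a variance proxy: longer frames average more counts).
#' @return A `time_curve` object.
#' @export
time_curve <- function(schedule, values, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"),
            length(values) == nrow(schedule), all(is.finite(values)))
  if (is.null(weights)) {
    weights <- schedule$frame_duration / mean(schedule$frame_duration)
  }
  stopifnot(length(weights) == length(values), all(weights >= 0))
  structure(list(schedule = schedule, values = as.numeric(values),
                 weights = as.numeric(weights)),
            class = "time_curve")
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("Time-activity curve: %d frames over %g s, peak %.3g kBq/mL\n",
              nrow(x$schedule), sum(x$schedule$frame_duration),
              max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.time_curve <- function(x, ...) {
  data.frame(frame_start = x$schedule$frame_start,
             frame_duration = x$schedule$frame_duration,
             value = x$values, weight = x$weights)
}

# Continuous tissue curve on a uniform grid (internal workhorse shared by
# forward_tac and the fit objective).  `ca` is the input function already
# sampled on the grid (kBq/mL); rates are per minute, grid in seconds.
#   Ct(t) = (1 - vb) * (Ca (x) h)(t) + vb * Ca(t)
# with (Ca (x) h)(t) = K1 * int_{t-Tc}^{t} Ca du  (plateau term)
#                    + [A e^{-a1 .} + B e^{-a2 .}] convolution shifted by Tc.
# Convolution integrals run in minutes so units come out kBq/mL.
tissue_curve_grid <- function(K1, k2, k3, k4, vb, Tc, ca, t, dt) {
  dt_min <- dt / 60
  # plateau term: K1 * trailing integral of Ca over [t - Tc, t], in minutes
  ci <- cumtrapz_uniform(ca, dt_min)
  box <- K1 * (ci - stats::approx(t, ci, xout = t - Tc, yleft = 0,
                                  rule = 2)$y)
  ev <- two_tissue_eigen(k2, k3, k4)
  a1 <- ev$alpha1; a2 <- ev$alpha2
  if (a2 - a1 < 1e-10 * max(a2, 1)) {
    # confluent limit: h = K1 e^{-a t}[1 + (k3+k4-a) t]; approximate by
    # perturbing the eigenvalues symmetrically (relative split 1e-6).
    eps <- 1e-6 * max(a2, 1e-6)
    a1 <- a1 - eps / 2
    a2 <- a2 + eps / 2
  }
  A <- K1 * (k3 + k4 - a1) / (a2 - a1)
  B <- K1 * (a2 - k3 - k4) / (a2 - a1)
  conv <- A * conv_exp_uniform(ca, a1, dt_min) +
    B * conv_exp_uniform(ca, a2, dt_min)
  conv <- shift_curve(conv, t, Tc)
  (1 - vb) * (box + conv) + vb * ca
}

# Frame averages of a gridded curve; frame boundaries must align with the grid
# up to rounding (enforced by choosing dt to divide the frame boundaries).
frame_average_grid <- function(y, t, dt, schedule) {
  ci <- cumtrapz_uniform(y, dt)
  i0 <- round(schedule$frame_start / dt) + 1L
  i1 <- round(frame_ends(schedule) / dt) + 1L
  stopifnot(max(i1) <= length(y))
  (ci[i1] - ci[i0]) / schedule$frame_duration
}

#' Simulate a frame-averaged tissue time-activity curve
#'
#' Forward measurement model for the kinetic model: the continuous tissue
#' concentration
#' \deqn{C_T(t) = (1 - v_b)\,[C_a(t - \mathrm{delay}) \otimes h](t) +
#'       v_b\, C_a(t - \mathrm{delay})}
#' (with \eqn{h} the [impulse_response()]) is computed on a fine uniform grid
#' and averaged over each acquisition frame. The curve is linear in the input
#' amplitude; `vb = 1` is not admissible in [kinetic_params()] but the model
#' degenerates continuously to the frame-averaged input as `vb` approaches 1.
#'
#' @param params a [kinetic_params()] object.
#' @param aif an `aif` object, or a `data.frame`/list with elements `times`
#'   (s) and `values` covering the schedule span (interpolated linearly).
#' @param schedule a [frame_schedule()]; defaults to [pet_frame_schedule()].
#' @param dt integration grid spacing (s); must divide all frame boundaries.
#' @return A [time_curve()] of frame-averaged activity (kBq/mL).
#' @export
forward_tac <- function(params, aif, schedule = pet_frame_schedule(),
                        dt = 0.25) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "frame_schedule"))
  end_s <- max(frame_ends(schedule))
  if (max(abs(round(c(schedule$frame_start, end_s) / dt) * dt -
                c(schedule$frame_start, end_s))) > 1e-9) {
    stop("`dt` must divide the frame boundaries")
  }
  t <- seq(0, end_s, by = dt)
  ca <- sample_input(aif, t - params$delay, end_s)
  ct <- tissue_curve_grid(params$K1, params$k2, params$k3, params$k4,
                          params$vb, params$Tc, ca, t, dt)
  time_curve(schedule, frame_average_grid(ct, t, dt, schedule))
}

# Sample an input function (parametric or tabulated) at times `tq` (s);
# 0 before its support, error beyond it for tabulated curves.
sample_input <- function(aif, tq, end_s) {
  if (inherits(aif, "aif")) {
    tq2 <- pmax(tq, 0)
    v <- evaluate_aif(aif, tq2)
    v[tq < 0] <- 0
    return(v)
  }
  if ((is.list(aif) || is.data.frame(aif)) &&
      all(c("times", "values") %in% names(aif))) {
    if (max(aif$times) < end_s - 1e-9) {
      stop("schedule extends beyond the support of the supplied input curve")
    }
    return(stats::approx(aif$times, aif$values, xout = tq, yleft = 0,
                         rule = 2)$y)
  }
  stop("`aif` must be an aif object or a list with times/values")
}

#' Macro kinetic parameters
#'
#' Net uptake (metabolic) rate constant and distribution volume:
#' \deqn{K_i = \frac{K_1 k_3}{k_2 + k_3 + k_4}, \qquad
#'       DV = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right).}
#' In the irreversible limit `k4 = 0`, `Ki` is evaluated with `k4 = 0` and
#' `DV` is undefined (returned as `NA`).
#'
#' @param params a [kinetic_params()] object (requires `k2 > 0`).
#' @return List with `Ki` (mL/min/g) and `DV` (mL/g, `NA` when `k4 = 0`).
#' @examples
#' macro_parameters(kinetic_params(0.1, 0.2, 0.05, 0.01))  # Ki 0.01923, DV 3
#' @export
macro_parameters <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 <= 0) stop("macro parameters are undefined for k2 <= 0")
  Ki <- params$K1 * params$k3 / (params$k2 + params$k3 + params$k4)
  DV <- if (params$k4 > 0) {
    (params$K1 / params$k2) * (1 + params$k3 / params$k4)
  } else {
    NA_real_
  }
  list(Ki = Ki, DV = DV)
}

#' Standardized uptake value from the late static window
#'
#' Averages the last six 300 s frames (the 30-minute window starting 30 min
#' post-injection, \[1800, 3600) s) of a max-voxel and a mean-voxel ROI curve
#' and converts to SUV with the 1 g/mL tissue-density convention:
#' \deqn{SUV = \frac{\bar C\ \mathrm{(kBq/mL)}}
#'       {\mathrm{dose\ (MBq)} / \mathrm{weight\ (kg)}}\quad \mathrm{g/mL},}
#' where dose/weight in MBq/kg equals kBq/g.
#'
#' @param tac_max [time_curve()] of the maximum-voxel ROI activity.
#' @param tac_mean optional [time_curve()] of the mean-voxel activity on the
#'   same schedule; defaults to `tac_max`.
#' @param dose_MBq injected dose (MBq), > 0 (the acquisition protocol injects
#'   5 MBq/kg).
#' @param weight_kg body weight (kg), > 0.
#' @return List with `suv_max`, `suv_mean` (g/mL) and the averaging window
#'   `window_start`, `window_end` (s). Requires `suv_max >= suv_mean`.
#' @export
suv_from_frames <- function(tac_max, tac_mean = NULL, dose_MBq, weight_kg) {
  stopifnot(inherits(tac_max, "time_curve"))
  if (dose_MBq <= 0 || weight_kg <= 0) {
    stop("injected dose and body weight must be positive")
  }
  if (is.null(tac_mean)) tac_mean <- tac_max
  sched <- tac_max$schedule
  late <- which(sched$frame_start >= 1800 - 1e-9)
  if (length(late) != 6L || any(sched$frame_duration[late] != 300) ||
      abs(max(frame_ends(sched)[late]) - 3600) > 1e-9) {
    stop("schedule must contain the six 300 s frames covering [1800, 3600) s")
  }
  conc_max <- mean(tac_max$values[late])
  conc_mean <- mean(tac_mean$values[late])
  suv_max <- conc_max * weight_kg / dose_MBq
  suv_mean <- conc_mean * weight_kg / dose_MBq
  if (suv_max < suv_mean - 1e-9) {
    stop("suv_max must be >= suv_mean; check that the max-voxel curve dominates")
  }
  list(suv_max = suv_max, suv_mean = suv_mean,
       window_start = 1800, window_end = 3600)
}

#' Percent change of a biomarker
#'
#' `100 * (post - pre) / pre`; the convention used for \eqn{\Delta SUV_{max}}
#' and all other pre/post biomarker changes.
#'
#' @param pre baseline value, > 0.
#' @param post follow-up value.
#' @return Percent change (negative for a decrease).
#' @examples
#' percent_change(10, 5)  # -50
#' @export
percent_change <- function(pre, post) {
  if (any(pre <= 0)) stop("`pre` must be positive")
  100 * (post - pre) / pre
}
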