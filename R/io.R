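# Plain-text serialisation of curves and fit results.

#' Read and write time-activity curves as CSV
#'
#' CSV layout: columns `frame_start_s`, `frame_duration_s`,
#' `value_kBq_per_mL` and `weight`.
#'
#' @param tac a [time_curve()].
#' @param path file path.
#' @return `write_tac()` returns `path` invisibly; `read_tac()` a
#'   [time_curve()].
#' @export
write_tac <- function(tac, path) {
  stopifnot(inherits(tac, "time_curve"))
  utils::write.csv(
    data.frame(frame_start_s = tac$schedule$frame_start,
               frame_duration_s = tac$schedule$frame_duration,
               value_kBq_per_mL = tac$values,
               weight = tac$weights),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  d <- utils::read.csv(path)
  time_curve(frame_schedule(d$frame_start_s, d$frame_duration_s),
             d$value_kBq_per_mL, d$weight)
}

#' Read and write enhancement curves as CSV
#'
#' CSV layout: columns `time_s` and `hu` (baseline-subtracted enhancement).
#'
#' @param curve an [enhancement_curve()].
#' @param path file path.
#' @return `write_enhancement()` returns `path` invisibly;
#'   `read_enhancement()` an [enhancement_curve()].
#' @export
write_enhancement <- function(curve, path) {
  stopifnot(inherits(curve, "enhancement_curve"))
  utils::write.csv(data.frame(time_s = curve$times, hu = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enhancement
#' @export
read_enhancement <- function(path) {
  d <- utils::read.csv(path)
  enhancement_curve(d$time_s, d$hu)
}

#' Serialise a kinetic or perfusion fit to JSON
#'
#' Writes the estimated parameters, derived macro/derived quantities and fit
#' diagnostics of a [fit_tac()] or [fit_ctp()] result as a JSON object.
#'
#' @param fit a `kinetic_fit` or `ctp_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- if (inherits(fit, "kinetic_fit")) {
    list(model = "flow_modified_two_tissue",
         params = unclass(fit$params), macro = fit$macro,
         diagnostics = fit$diagnostics[c("rss", "converged", "degenerate",
                                         "n_starts")])
  } else if (inherits(fit, "ctp_fit")) {
    list(model = "johnson_wilson",
         params = unclass(fit$params),
         diagnostics = fit$diagnostics[c("rss", "converged", "e_at_bound",
                                         "n_starts")])
  } else {
    stop("`fit` must be a kinetic_fit or ctp_fit")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
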