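# Valinomycin/KCl-step calibration of potentiometric-dye traces.
#
# Valinomycin clamps the membrane at E_K, so after each KCl addition the
# plateau fluorescence corresponds to a known Nernst voltage. Pairing the
# plateau fluorescences with those anchor voltages and interpolating
# linearly converts arbitrary fluorescence units to mV, absorbing the
# gain/offset of each individual recording.

# Default cumulative KCl concentrations after each doubling aliquot added
# to the initial 5 mM: 5 + 2.25, +4.5, +9, +18 mM. At 37 C with
# [K+]i = 120 mM these give anchor voltages of -75.0, -62.1, -46.9 and
# -30.2 mV (the starting 5 mM sits at -84.9 mV).
.CAL_K_STEPS <- c(7.25, 11.75, 20.75, 38.75)

#' Potentiometric-dye fluorescence trace
#'
#' @param time time stamps, s, strictly increasing.
#' @param fluorescence fluorescence, arbitrary units (AU).
#' @param events data frame with columns `time_s`, `label`, `K_out_after`
#'   (mM); rows describe the valinomycin addition and each KCl step.
#' @param condition optional condition label/spec.
#' @return An object of class `"fluor_trace"`.
#' @export
fluor_trace <- function(time, fluorescence, events, condition = NULL) {
  time <- as.numeric(time); fluorescence <- as.numeric(fluorescence)
  if (length(time) != length(fluorescence))
    stop("time and fluorescence must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  need <- c("time_s", "label", "K_out_after")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop("events must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  events <- events[order(events$time_s), , drop = FALSE]
  kcl <- events$K_out_after[!grepl("valinomycin", events$label,
                                   ignore.case = TRUE)]
  if (length(kcl) > 1L && any(diff(kcl) <= 0))
    stop("KCl-step events must have strictly increasing K_out_after",
         call. = FALSE)
  structure(list(time = time, fluorescence = fluorescence, events = events,
                 condition = condition),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat("Fluorescence trace: ", length(x$time), " samples over ",
      round(diff(range(x$time)), 1), " s, ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' Theoretical calibration voltages for a KCl-step series
#'
#' Per-step K+ Nernst potentials (delegating to [nernst_potential()]), the
#' anchor voltages of the valinomycin calibration.
#'
#' @param K_steps external K+ after each step, mM, strictly increasing.
#' @param K_in internal K+, mM (120 mM by convention).
#' @param temperature_C temperature, degrees Celsius.
#' @return Numeric vector of anchor voltages, mV.
#' @export
#' @examples
#' theoretical_calibration_voltages(c(5, 7.25, 11.75, 20.75, 38.75))
theoretical_calibration_voltages <- function(K_steps, K_in = 120,
                                             temperature_C = 37) {
  if (!is.numeric(K_steps) || anyNA(K_steps) || any(K_steps <= 0))
    stop("K_steps must be positive", call. = FALSE)
  if (length(K_steps) > 1L && any(diff(K_steps) <= 0))
    stop("K_steps must be strictly increasing", call. = FALSE)
  vapply(K_steps, function(k)
    nernst_potential(C_in = K_in, C_out = k, valence = 1L,
                     temperature_C = temperature_C), numeric(1))
}

#' Build a fluorescence-to-voltage calibration from a trace
#'
#' Locates the valinomycin event and the subsequent KCl steps, summarizes
#' the plateau after each (median over a fixed-length window ending just
#' before the next event, or at the end of the trace), and pairs each
#' plateau fluorescence with the theoretical Nernst voltage of its K+
#' concentration. The valinomycin plateau itself provides the first anchor
#' at the pre-addition K+ concentration.
#'
#' @param trace a [fluor_trace()].
#' @param K_in internal K+, mM.
#' @param mode `"piecewise"` (linear interpolation through the anchors; the
#'   default) or `"line"` (single least-squares line through the anchors).
#' @param plateau_window plateau window length, s.
#' @param K_initial external K+ before any addition, mM.
#' @param temperature_C temperature, degrees Celsius.
#' @return An object of class `"ghk_calibration"` with elements `anchors`
#'   (data frame `K_out`, `Em`, `F`), `mode`, `slope` (dF/dEm of a line
#'   through the anchors), `dye_slope_ok` (fluorescence falls with
#'   hyperpolarization, i.e. dF/dEm > 0) and `warnings`.
#' @export
build_calibration <- function(trace, K_in = 120,
                              mode = c("piecewise", "line"),
                              plateau_window = 30, K_initial = 5,
                              temperature_C = 37) {
  stopifnot(inherits(trace, "fluor_trace"))
  mode <- match.arg(mode)
  ev <- trace$events
  ival <- grep("valinomycin", ev$label, ignore.case = TRUE)
  if (!length(ival))
    stop("calibration error: no valinomycin event in trace", call. = FALSE)
  ival <- ival[1]
  steps <- ev[seq_len(nrow(ev)) > ival, , drop = FALSE]
  if (nrow(steps) < 2L)
    stop("calibration error: need at least 2 KCl-step events after ",
         "valinomycin", call. = FALSE)

  # one segment per anchor: valinomycin plateau (at K_initial), then each step
  starts <- c(ev$time_s[ival], steps$time_s)
  ends <- c(steps$time_s, max(trace$time))
  K_anchor <- c(K_initial, steps$K_out_after)
  F_anchor <- vapply(seq_along(starts), function(i) {
    lo <- max(starts[i], ends[i] - plateau_window)
    sel <- trace$time >= lo & trace$time < ends[i]
    if (!any(sel)) return(NA_real_)
    stats::median(trace$fluorescence[sel])
  }, numeric(1))

  ok <- is.finite(F_anchor)
  if (sum(ok) < 2L)
    stop("calibration error: fewer than 2 usable anchors", call. = FALSE)
  K_anchor <- K_anchor[ok]; F_anchor <- F_anchor[ok]
  Em_anchor <- theoretical_calibration_voltages(K_anchor, K_in = K_in,
                                                temperature_C = temperature_C)

  warnings <- character(0)
  dFa <- diff(F_anchor)   # anchors are ordered by K_out, hence by Em
  if (!(all(dFa > 0) || all(dFa < 0)))
    warnings <- c(warnings,
                  "plateau fluorescence is not monotone in anchor voltage")
  slope <- unname(stats::coef(stats::lm(F_anchor ~ Em_anchor))[2])
  dye_slope_ok <- is.finite(slope) && slope > 0
  if (!dye_slope_ok)
    warnings <- c(warnings, paste(
      "recovered dF/dEm is not positive: fluorescence should fall upon",
      "hyperpolarization for a quenching-mode potentiometric dye"))

  structure(list(anchors = data.frame(K_out = K_anchor, Em = Em_anchor,
                                      F = F_anchor),
                 mode = mode, slope = slope, dye_slope_ok = dye_slope_ok,
                 warnings = warnings),
            class = "ghk_calibration")
}

#' @export
print.ghk_calibration <- function(x, ...) {
  cat("Fluorescence calibration (", x$mode, " mode, ",
      nrow(x$anchors), " anchors)\n", sep = "")
  print(x$anchors, row.names = FALSE)
  cat(sprintf("dF/dEm = %.3f AU/mV%s\n", x$slope,
              if (x$dye_slope_ok) "" else "  ** wrong sign **"))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

# piecewise-linear interpolation with linear extrapolation using the
# terminal segment slopes (stats::approx cannot extrapolate this way)
.pw_linear <- function(x, y, xout) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  i <- findInterval(xout, x, all.inside = TRUE)
  y[i] + (xout - x[i]) * (y[i + 1] - y[i]) / (x[i + 1] - x[i])
}

#' Convert fluorescence to membrane potential
#'
#' Piecewise-linear interpolation of Em between the bracketing calibration
#' anchors; beyond the end anchors the terminal segment slope is used for
#' linear extrapolation (capacitated membrane potentials can be more
#' negative than the most hyperpolarized anchor). In `"line"` mode a single
#' least-squares line through the anchors is used instead.
#'
#' @param curve a [build_calibration()] result.
#' @param F fluorescence value(s), AU.
#' @return Membrane potential(s), mV.
#' @export
fluorescence_to_em <- function(curve, F) {
  stopifnot(inherits(curve, "ghk_calibration"))
  a <- curve$anchors
  if (any(duplicated(a$F)))
    stop("degenerate calibration: equal anchor fluorescences", call. = FALSE)
  if (curve$mode == "line") {
    fit <- stats::lm(Em ~ F, data = a)
    return(unname(stats::predict(fit, data.frame(F = F))))
  }
  dF <- diff(a$F[order(a$Em)])
  if (!(all(dF > 0) || all(dF < 0)))
    stop("anchor fluorescence is not monotone in Em; use mode = \"line\"",
         call. = FALSE)
  .pw_linear(a$F, a$Em, F)
}

#' Resting membrane potential of a trace
#'
#' Maps the steady-state fluorescence preceding the first event (median
#' over a fixed-length window ending just before it) through a calibration
#' curve.
#'
#' @param trace a [fluor_trace()].
#' @param curve a [build_calibration()] result (built from the same trace,
#'   typically).
#' @param window steady-state window length, s.
#' @return Resting membrane potential, mV.
#' @export
trace_resting_em <- function(trace, curve, window = 30) {
  stopifnot(inherits(trace, "fluor_trace"))
  t1 <- min(trace$events$time_s)
  sel <- trace$time >= (t1 - window) & trace$time < t1
  if (!any(sel))
    stop("no samples in the pre-event steady-state window", call. = FALSE)
  fluorescence_to_em(curve, stats::median(trace$fluorescence[sel]))
}

#' Write / read a fluorescence trace
#'
#' The trace samples go to a CSV (`time_s`, `fluorescence_au`), the events
#' to a JSON sidecar (same path with extension `.events.json`).
#'
#' @param trace a [fluor_trace()].
#' @param path CSV path.
#' @return `path` (write) or a `"fluor_trace"` (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              fluorescence_au = trace$fluorescence),
                   path, row.names = FALSE)
  jsonlite::write_json(trace$events, sub("\\.csv$", ".events.json", path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  ev <- jsonlite::read_json(sub("\\.csv$", ".events.json", path),
                            simplifyVector = TRUE)
  fluor_trace(d$time_s, d$fluorescence_au, as.data.frame(ev))
}
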