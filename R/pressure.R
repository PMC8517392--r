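# Non-invasive LV pressure curve: a normalized reference pressure template on
# phase-normalized time is stretched to the subject's isovolumic and ejection
# phase durations (from valve-event timings) and scaled so its peak equals the
# cuff systolic pressure.

#' Valve-event timings for one cardiac cycle
#'
#' The four anchor events partitioning the cycle: mitral valve closure (MVC,
#' cycle start), aortic valve opening (AVO), aortic valve closure (AVC) and
#' mitral valve opening (MVO). MVC\eqn{\to}AVO is isovolumic contraction,
#' AVO\eqn{\to}AVC ejection, AVC\eqn{\to}MVO isovolumic relaxation.
#'
#' @param t_mvc,t_avo,t_avc,t_mvo event times in seconds from cycle start;
#'   must be finite, non-negative and strictly ordered
#'   `t_mvc < t_avo < t_avc < t_mvo`.
#' @return an object of class `valve_events`.
#' @examples
#' valve_events(0, 0.06, 0.36, 0.44)
#' @export
valve_events <- function(t_mvc, t_avo, t_avc, t_mvo) {
  ts <- c(t_mvc = t_mvc, t_avo = t_avo, t_avc = t_avc, t_mvo = t_mvo)
  if (!all(is.finite(ts)) || any(ts < 0)) {
    stop("timing error: valve-event times must be finite and non-negative", call. = FALSE)
  }
  if (!(t_mvc < t_avo && t_avo < t_avc && t_avc < t_mvo)) {
    stop("timing error: valve events must be strictly ordered MVC < AVO < AVC < MVO",
         call. = FALSE)
  }
  structure(as.list(ts), class = "valve_events")
}

#' @export
print.valve_events <- function(x, ...) {
  cat(sprintf("Valve events (s): MVC %.4f | AVO %.4f | AVC %.4f | MVO %.4f\n",
              x$t_mvc, x$t_avo, x$t_avc, x$t_mvo))
  cat(sprintf("  IVC %.3f  ejection %.3f  IVR %.3f\n",
              x$t_avo - x$t_mvc, x$t_avc - x$t_avo, x$t_mvo - x$t_avc))
  invisible(x)
}

#' Brachial cuff blood pressure
#'
#' @param sbp,dbp systolic and diastolic pressure in mmHg; `sbp > dbp > 0`.
#' @return an object of class `cuff_pressure`.
#' @export
cuff_pressure <- function(sbp, dbp) {
  if (!is.finite(sbp) || !is.finite(dbp) || !(sbp > dbp) || !(dbp > 0)) {
    stop("cuff pressure must satisfy sbp > dbp > 0", call. = FALSE)
  }
  structure(list(sbp = sbp, dbp = dbp), class = "cuff_pressure")
}

# Phase coordinate convention: u in [0, 3] with u in [0,1] isovolumic
# contraction, [1,2] ejection, [2,3] isovolumic relaxation. The shape is a
# fixed piecewise raised-cosine profile chosen to match the qualitative LV
# pressure morphology (slow rise in IVC, rounded systolic peak early in
# ejection, fall through IVR); it is a named constant so an alternative
# template can be swapped in.
PSL_TEMPLATE_ANCHORS <- c(mvc = 0, avo = 0.90, peak = 1, avc = 0.55, mvo = 0.10)
PSL_TEMPLATE_PEAK_FRACTION <- 0.3  # peak at 30% of the ejection phase

psl_reference_shape <- function(u) {
  a <- PSL_TEMPLATE_ANCHORS
  pf <- PSL_TEMPLATE_PEAK_FRACTION
  u <- pmin(pmax(u, 0), 3)
  v <- numeric(length(u))
  i <- u <= 1
  v[i] <- a[["avo"]] * (1 - cos(pi * u[i])) / 2
  i <- u > 1 & u <= 1 + pf
  s <- (u[i] - 1) / pf
  v[i] <- a[["avo"]] + (a[["peak"]] - a[["avo"]]) * (1 - cos(pi * s)) / 2
  i <- u > 1 + pf & u <= 2
  s <- (u[i] - 1 - pf) / (1 - pf)
  v[i] <- a[["avc"]] + (a[["peak"]] - a[["avc"]]) * (1 + cos(pi * s)) / 2
  i <- u > 2
  s <- u[i] - 2
  v[i] <- a[["mvo"]] + (a[["avc"]] - a[["mvo"]]) * (1 + cos(pi * s)) / 2
  v
}

#' Build the normalized reference pressure template
#'
#' Samples the closed-form raised-cosine reference shape on phase-normalized
#' time: value 0 at MVC, rising through isovolumic contraction to 0.90 at AVO,
#' a raised-cosine systolic arch peaking at 1 at 30% of ejection, 0.55 at AVC,
#' and a half-cosine fall to 0.10 at MVO. The returned object carries the
#' closed-form evaluator used when scaling to a subject's cycle, so phase
#' boundaries map exactly regardless of `n_samples`.
#'
#' @param n_samples number of phase samples (at least 16).
#' @return an object of class `pressure_template` with elements `phase`
#'   (phase coordinate in `[0, 3]`, one unit per cardiac phase), `value`
#'   (normalized pressure in `[0, 1]`), `shape` (the closed-form evaluator)
#'   and `peak_phase`.
#' @examples
#' tpl <- build_reference_curve(1000)
#' max(tpl$value)    # 1 at the ejection peak
#' @export
build_reference_curve <- function(n_samples) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples < 16) {
    stop("invalid resolution: n_samples must be at least 16", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  peak_phase <- 1 + PSL_TEMPLATE_PEAK_FRACTION
  phase <- sort(unique(c(seq(0, 3, length.out = n_samples), peak_phase)))
  structure(
    list(phase = phase, value = psl_reference_shape(phase),
         shape = psl_reference_shape, peak_phase = peak_phase),
    class = "pressure_template"
  )
}

#' Scale the reference template to one subject's cardiac cycle
#'
#' Each cardiac phase of the template is independently and affinely stretched
#' in time so that the template phase boundaries fall exactly on the subject's
#' MVC/AVO/AVC/MVO times, and the amplitude is scaled so the peak equals the
#' cuff systolic pressure (peak systolic LV pressure is taken equal to peak
#' brachial pressure). The diastolic cuff pressure is not used by the curve;
#' the template is anchored at 0 mmHg at MVC.
#'
#' @param template a `pressure_template` from [build_reference_curve()].
#' @param events a [valve_events()] object.
#' @param cuff a [cuff_pressure()] object.
#' @param dt target sampling step in seconds; defaults to the cycle span
#'   (MVC to MVO) divided by 2000. Each phase keeps at least 1025 samples so
#'   linear interpolation error stays below `1e-6` of the systolic pressure.
#' @return an object of class `lv_pressure_curve` with strictly increasing
#'   `times` spanning `[t_mvc, t_mvo]` and `pressures` in mmHg, plus the
#'   generating `events`, `sbp` and `shape`.
#' @examples
#' ev <- valve_events(0, 0.06, 0.36, 0.44)
#' curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(120, 78))
#' max(curve$pressures)  # 120
#' @export
scale_to_cycle <- function(template, events, cuff, dt = NULL) {
  stopifnot(inherits(template, "pressure_template"),
            inherits(events, "valve_events"),
            inherits(cuff, "cuff_pressure"))
  span <- events$t_mvo - events$t_mvc
  if (is.null(dt)) dt <- span / 2000
  if (!is.finite(dt) || dt <= 0 || dt >= (events$t_avo - events$t_mvc)) {
    stop("invalid resolution: dt must be positive and finer than the isovolumic contraction phase",
         call. = FALSE)
  }
  bounds <- c(events$t_mvc, events$t_avo, events$t_avc, events$t_mvo)
  times <- numeric(0)
  phase <- numeric(0)
  for (k in 1:3) {
    a <- bounds[k]; b <- bounds[k + 1]
    n_k <- max(ceiling((b - a) / dt) + 1, 1025)
    tk <- seq(a, b, length.out = n_k)
    uk <- (k - 1) + (tk - a) / (b - a)
    if (k > 1) { tk <- tk[-1]; uk <- uk[-1] }  # phase boundary kept once
    times <- c(times, tk)
    phase <- c(phase, uk)
  }
  # anchor the exact ejection-peak instant so max(pressures) == sbp
  t_peak <- events$t_avo + PSL_TEMPLATE_PEAK_FRACTION * (events$t_avc - events$t_avo)
  if (!any(abs(times - t_peak) < 1e-12)) {
    times <- c(times, t_peak)
    phase <- c(phase, template$peak_phase)
    o <- order(times)
    times <- times[o]; phase <- phase[o]
  }
  pressures <- cuff$sbp * template$shape(phase)
  new_lv_pressure_curve(times, pressures, events, cuff$sbp, template$shape)
}

new_lv_pressure_curve <- function(times, pressures, events, sbp, shape) {
  stopifnot(length(times) == length(pressures), all(diff(times) > 0))
  if (any(pressures < 0)) stop("pressure curve must be non-negative", call. = FALSE)
  if (abs(max(pressures) - sbp) > 1e-6 * sbp) {
    stop("pressure curve peak does not match systolic pressure", call. = FALSE)
  }
  structure(list(times = times, pressures = pressures, events = events,
                 sbp = sbp, shape = shape),
            class = "lv_pressure_curve")
}

#' @export
print.lv_pressure_curve <- function(x, ...) {
  cat(sprintf("LV pressure curve: %d samples on [%.4f, %.4f] s, peak %.2f mmHg\n",
              length(x$times), x$times[1], x$times[length(x$times)], max(x$pressures)))
  invisible(x)
}

#' Evaluate the LV pressure curve at arbitrary times
#'
#' Piecewise-linear interpolation between the stored grid samples.
#'
#' @param curve an `lv_pressure_curve`.
#' @param t times in seconds, all within `[t_mvc, t_mvo]`.
#' @return pressures in mmHg at `t`.
#' @export
pressure_at <- function(curve, t) {
  stopifnot(inherits(curve, "lv_pressure_curve"))
  lo <- curve$times[1]; hi <- curve$times[length(curve$times)]
  if (any(t < lo - 1e-12) || any(t > hi + 1e-12)) {
    stop("domain error: t outside the pressure curve domain [MVC, MVO]", call. = FALSE)
  }
  stats::approx(curve$times, curve$pressures, xout = pmin(pmax(t, lo), hi))$y
}
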