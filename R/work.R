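# Segmental and global myocardial work from strain traces and the LV pressure
# curve. Sign convention: longitudinal strain is negative during shortening,
# so instantaneous power w(t) = -(de/dt) * P(t) is positive for physiologic
# systolic shortening, giving positive work in mmHg.%.

#' Longitudinal strain trace for one myocardial segment
#'
#' @param segment_id integer segment number in the standard 17-segment model.
#' @param times strictly increasing sample times (s), starting at cycle start
#'   (mitral valve closure).
#' @param strain longitudinal strain in percent (negative = shortening);
#'   must be finite, below 50% in magnitude, and 0 at the first sample.
#' @return an object of class `strain_trace`.
#' @examples
#' tr <- strain_trace(1, seq(0, 0.4, by = 0.01), -15 * seq(0, 0.4, by = 0.01))
#' @export
strain_trace <- function(segment_id, times, strain) {
  if (length(segment_id) != 1L || is.na(segment_id) ||
      segment_id != as.integer(segment_id) || segment_id < 1 || segment_id > 17) {
    stop("segment_id must be an integer in 1..17", call. = FALSE)
  }
  if (length(times) != length(strain)) stop("times and strain lengths differ", call. = FALSE)
  if (!all(is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(strain)) || max(abs(strain)) >= 50) {
    stop("strain must be finite with |strain| < 50%", call. = FALSE)
  }
  if (abs(strain[1]) > 1e-6) {
    stop("strain must be referenced to 0 at cycle start (mitral valve closure)",
         call. = FALSE)
  }
  structure(list(segment_id = as.integer(segment_id),
                 times = as.numeric(times), strain = as.numeric(strain)),
            class = "strain_trace")
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("Strain trace, segment %d: %d samples on [%.3f, %.3f] s, peak %.2f%%\n",
              x$segment_id, length(x$times), x$times[1],
              x$times[length(x$times)], min(x$strain)))
  invisible(x)
}

#' Strain rate of a trace
#'
#' Time derivative of longitudinal strain on the trace's own grid: central
#' differences at interior points, second-order one-sided differences at the
#' endpoints.
#'
#' @param trace a [strain_trace()].
#' @return strain rate in %/s at the trace sample times.
#' @export
strain_rate <- function(trace) {
  stopifnot(inherits(trace, "strain_trace"))
  if (length(trace$times) < 3) {
    stop("insufficient data: at least 3 samples required", call. = FALSE)
  }
  central_diff(trace$times, trace$strain)
}

#' Myocardial work of one segment
#'
#' Resamples the strain trace and pressure curve onto a common uniform grid
#' over the work window (mitral valve closure to mitral valve opening),
#' forms the instantaneous power `w(t) = -(de/dt) P(t)`, and integrates with
#' the trapezoid rule. Constructive and wasted work follow the phase rules of
#' the pressure-strain-loop method: during systole (MVC to AVC) shortening
#' (positive `w`) is constructive and lengthening wasted; during isovolumic
#' relaxation (AVC to MVO) the roles invert, so lengthening is constructive
#' and post-systolic shortening wasted. The net work index is constructive
#' minus wasted by construction (both integrate the same phase-adjusted
#' power partition).
#'
#' @param trace a [strain_trace()] whose time span covers the work window.
#' @param pressure an `lv_pressure_curve` from [scale_to_cycle()].
#' @param events a [valve_events()] object.
#' @param dt integration step (s); default: work window / 2000.
#' @return an object of class `segment_work` with `segment_id`, `work_index`,
#'   `constructive` and `wasted`, all in mmHg.%.
#' @export
segment_work <- function(trace, pressure, events, dt = NULL) {
  stopifnot(inherits(trace, "strain_trace"),
            inherits(pressure, "lv_pressure_curve"),
            inherits(events, "valve_events"))
  t0 <- events$t_mvc; t1 <- events$t_mvo
  eps <- 1e-9
  if (trace$times[1] > t0 + eps || trace$times[length(trace$times)] < t1 - eps) {
    stop("domain error: strain trace does not cover the work window [MVC, MVO]",
         call. = FALSE)
  }
  plo <- pressure$times[1]; phi <- pressure$times[length(pressure$times)]
  if (plo > t0 + eps || phi < t1 - eps) {
    stop("domain error: pressure curve does not cover the work window [MVC, MVO]",
         call. = FALSE)
  }
  if (is.null(dt)) dt <- (t1 - t0) / 2000
  if (!is.finite(dt) || dt <= 0) stop("invalid resolution: dt must be positive", call. = FALSE)
  grid <- work_grid(events, pressure, dt)
  work_core(trace, grid)
}

# Shared uniform work grid with interpolated pressure and phase signs; built
# once per subject and reused across the 17 segments.
work_grid <- function(events, pressure, dt) {
  t0 <- events$t_mvc; t1 <- events$t_mvo
  n <- max(ceiling((t1 - t0) / dt), 64)
  g <- seq(t0, t1, length.out = n + 1)
  plo <- pressure$times[1]; phi <- pressure$times[length(pressure$times)]
  p <- stats::approx(pressure$times, pressure$pressures,
                     xout = pmin(pmax(g, plo), phi))$y
  # a sample belongs to isovolumic relaxation once its difference stencil lies
  # entirely past AVC, so the phase sign never flips a systolic stencil
  prev <- c(-Inf, g[-length(g)])
  sgn <- ifelse(prev >= events$t_avc - 1e-12, -1, 1)
  list(g = g, p = p, sgn = sgn)
}

work_core <- function(trace, grid) {
  strain_g <- stats::approx(trace$times, trace$strain, xout = grid$g)$y
  rate <- central_diff(grid$g, strain_g)
  v <- -rate * grid$p * grid$sgn
  constructive <- trapz(grid$g, pmax(v, 0))
  wasted <- trapz(grid$g, pmax(-v, 0))
  structure(list(segment_id = trace$segment_id,
                 work_index = constructive - wasted,
                 constructive = constructive, wasted = wasted),
            class = "segment_work")
}

#' Peak systolic strain of a segment
#'
#' Minimum strain (most negative, i.e. greatest shortening) over the systolic
#' window from mitral valve closure to aortic valve closure, including the
#' interpolated value at AVC.
#'
#' @param trace a [strain_trace()].
#' @param events a [valve_events()] object.
#' @return peak systolic strain in percent (typically negative).
#' @export
peak_systolic_strain <- function(trace, events) {
  stopifnot(inherits(trace, "strain_trace"), inherits(events, "valve_events"))
  sel <- trace$times >= events$t_mvc - 1e-12 & trace$times <= events$t_avc + 1e-12
  at_avc <- stats::approx(trace$times, trace$strain, xout = events$t_avc)$y
  min(c(trace$strain[sel], at_avc))
}

#' Aggregate segmental work into global indices
#'
#' GWI/GCW/GWW are the arithmetic means over the 17 segments of the segmental
#' net, constructive and wasted work; GWE = 100 GCW / (GCW + GWW); GLS is the
#' weighted mean of the 17 peak systolic strains (equal weights by default,
#' apex counted once).
#'
#' @param seg_works list of 17 [segment_work()] results, one per segment
#'   (any order; all of segments 1..17 must be present exactly once).
#' @param peak_strains numeric vector of 17 peak systolic strains (%), in
#'   segment order 1..17.
#' @param weights GLS weights over the 17 segments; default equal.
#' @return an object of class `global_work_set` with `gls`, `gwi`, `gcw`,
#'   `gww` (mmHg.%) and `gwe` (%).
#' @examples
#' sw <- lapply(1:17, function(i)
#'   structure(list(segment_id = i, work_index = 1500,
#'                  constructive = 1550, wasted = 50), class = "segment_work"))
#' aggregate_global(sw, rep(-18, 17))
#' @export
aggregate_global <- function(seg_works, peak_strains, weights = NULL) {
  if (length(seg_works) != 17L ||
      !all(vapply(seg_works, inherits, logical(1), "segment_work"))) {
    stop("incomplete segmentation: exactly 17 segment_work objects required",
         call. = FALSE)
  }
  ids <- vapply(seg_works, function(s) s$segment_id, integer(1))
  if (!identical(sort(ids), 1:17)) {
    stop("incomplete segmentation: segments 1..17 must each appear once", call. = FALSE)
  }
  if (length(peak_strains) != 17L || !all(is.finite(peak_strains))) {
    stop("incomplete segmentation: 17 finite peak strains required", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, 17)
  if (length(weights) != 17L || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be 17 non-negative values with positive sum", call. = FALSE)
  }
  gwi <- mean(vapply(seg_works, function(s) s$work_index, numeric(1)))
  gcw <- mean(vapply(seg_works, function(s) s$constructive, numeric(1)))
  gww <- mean(vapply(seg_works, function(s) s$wasted, numeric(1)))
  gwe <- if (gcw + gww > 0) 100 * gcw / (gcw + gww) else NA_real_
  gls <- sum(weights * peak_strains) / sum(weights)
  structure(list(gls = gls, gwi = gwi, gcw = gcw, gww = gww, gwe = gwe),
            class = "global_work_set")
}

#' @export
print.global_work_set <- function(x, ...) {
  cat(sprintf("Global myocardial work: GLS %.2f%%  GWI %.1f  GCW %.1f  GWW %.1f mmHg%%  GWE %.2f%%\n",
              x$gls, x$gwi, x$gcw, x$gww, x$gwe))
  invisible(x)
}

#' Global myocardial work for one subject
#'
#' Convenience wrapper: builds the subject's LV pressure curve, computes the
#' 17 segmental works and peak systolic strains, and aggregates.
#'
#' @param traces list of 17 [strain_trace()] objects (segments 1..17).
#' @param events a [valve_events()] object.
#' @param cuff a [cuff_pressure()] object.
#' @param dt work-grid step (s); default work window / 2000.
#' @param weights GLS weights, see [aggregate_global()].
#' @param template pressure template; default [build_reference_curve()]`(64)`
#'   (the curve uses the closed-form shape, so the template sample count is
#'   immaterial).
#' @return a `global_work_set`.
#' @export
subject_work <- function(traces, events, cuff, dt = NULL, weights = NULL,
                         template = build_reference_curve(64)) {
  curve <- scale_to_cycle(template, events, cuff, dt = dt)
  ids <- vapply(traces, function(tr) tr$segment_id, integer(1))
  traces <- traces[order(ids)]
  if (is.null(dt)) dt <- (events$t_mvo - events$t_mvc) / 2000
  grid <- work_grid(events, curve, dt)
  seg <- lapply(traces, function(tr) {
    if (tr$times[1] > events$t_mvc + 1e-9 ||
        tr$times[length(tr$times)] < events$t_mvo - 1e-9) {
      stop("domain error: strain trace does not cover the work window [MVC, MVO]",
           call. = FALSE)
    }
    work_core(tr, grid)
  })
  peaks <- vapply(traces, peak_systolic_strain, numeric(1), events = events)
  aggregate_global(seg, peaks, weights = weights)
}
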