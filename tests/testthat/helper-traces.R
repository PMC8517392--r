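# Shared fixture builders: all test inputs are constructed in code.

default_events <- function() valve_events(0, 0.06, 0.36, 0.44)

# piecewise-linear systolic shortening to `peak`, flat through IVR; samples
# placed so the profile is exactly linear near both window ends
linear_trace <- function(events, peak = -15, segment_id = 1) {
  t_sys <- seq(events$t_mvc, events$t_avc, length.out = 37)
  t_ivr <- seq(events$t_avc, events$t_mvo, length.out = 9)[-1]
  strain_trace(segment_id,
               c(t_sys, t_ivr),
               c(peak * (t_sys - events$t_mvc) / (events$t_avc - events$t_mvc),
                 rep(peak, length(t_ivr))))
}

# constant-pressure curve over the cycle window (oracle input)
flat_pressure <- function(events, p = 100) {
  tt <- seq(events$t_mvc, events$t_mvo, length.out = 2001)
  structure(list(times = tt, pressures = rep(p, length(tt)),
                 events = events, sbp = p, shape = NULL),
            class = "lv_pressure_curve")
}

# smooth random trace: raised-cosine contraction plus low-frequency sinusoids
random_smooth_trace <- function(events, segment_id = 1) {
  tt <- seq(events$t_mvc, events$t_mvo, length.out = 441)
  peak <- stats::runif(1, -24, -10)
  g <- ifelse(tt <= events$t_avc,
              (1 - cos(pi * tt / events$t_avc)) / 2,
              1 - 0.2 * (1 - cos(pi * (tt - events$t_avc) /
                                   (events$t_mvo - events$t_avc))) / 2)
  wig <- stats::runif(1, 0, 1.5) *
    sin(2 * pi * stats::runif(1, 4, 12) * tt + stats::runif(1, 0, 2 * pi)) *
    sin(pi * tt / events$t_mvo)
  strain <- peak * g + wig
  strain[1] <- 0
  strain_trace(segment_id, tt, strain)
}

# exhaustive pair-count Mann-Whitney U (independent oracle)
brute_force_u <- function(x1, x2) {
  u <- 0
  for (a in x1) for (b in x2) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# rescale a sample to exact target moments (affine standardization)
with_moments <- function(x, mean, sd) {
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}
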