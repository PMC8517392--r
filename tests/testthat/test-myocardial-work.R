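test_that("strain rate reproduces closed-form derivatives", {
  tt <- seq(0, 0.4, by = 0.01)
  lin <- strain_trace(1, tt, -10 * tt)
  expect_equal(strain_rate(lin), rep(-10, length(tt)), tolerance = 1e-9)

  const <- strain_trace(2, tt, rep(0, length(tt)))
  expect_equal(strain_rate(const), rep(0, length(tt)), tolerance = 1e-12)

  t1k <- seq(0, 1, by = 1e-3)
  s <- -5 * sin(2 * pi * t1k)
  tr <- strain_trace(3, t1k, s)
  expect_lt(max(abs(strain_rate(tr) - (-10 * pi * cos(2 * pi * t1k)))), 1e-3)
})

test_that("strain rate needs at least three samples", {
  expect_error(strain_rate(strain_trace(1, c(0, 0.1), c(0, -1))),
               "insufficient data")
})

test_that("constant-pressure work equals pressure times strain excursion", {
  ev <- default_events()
  p <- flat_pressure(ev, 100)
  tr <- linear_trace(ev, peak = -15)
  sw <- segment_work(tr, p, ev)
  expect_equal(sw$work_index, 1500, tolerance = 1e-9)
  expect_equal(sw$constructive, 1500, tolerance = 1e-9)
  expect_lt(sw$wasted, 1e-9)

  # pure systolic lengthening: all the work is wasted
  rev <- strain_trace(1, tr$times, -tr$strain)
  swr <- segment_work(rev, p, ev)
  expect_equal(swr$wasted, 1500, tolerance = 1e-9)
  expect_lt(swr$constructive, 1e-9)
  expect_equal(swr$work_index, -1500, tolerance = 1e-9)
})

test_that("default-grid work matches 16-fold refined quadrature", {
  ev <- default_events()
  curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(121, 78))
  dt0 <- (ev$t_mvo - ev$t_mvc) / 2000
  set.seed(42)
  for (i in 1:12) {
    tr <- random_smooth_trace(ev)
    a <- segment_work(tr, curve, ev, dt = dt0)
    b <- segment_work(tr, curve, ev, dt = dt0 / 16)
    expect_equal(a$work_index, b$work_index, tolerance = 5e-3)
    expect_equal(a$constructive, b$constructive, tolerance = 5e-3)
    # wasted work is a small difference quantity; grid agreement is measured
    # on the scale of the total work handled by the segment
    expect_lt(abs(a$wasted - b$wasted), 5e-3 * b$constructive)
  }
})

test_that("post-systolic shortening produces wasted work that refines stably", {
  ev <- default_events()
  curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(120, 78))
  tt <- seq(ev$t_mvc, ev$t_mvo, length.out = 441)
  g <- ifelse(tt <= ev$t_avc, (1 - cos(pi * tt / ev$t_avc)) / 2, 1)
  s <- pmin(pmax((tt - ev$t_avc) / (ev$t_mvo - ev$t_avc), 0), 1)
  pss <- ifelse(tt > ev$t_avc, 2 * (1 - cos(2 * pi * s)) / 2, 0)  # 2% mid-IVR dip
  tr <- strain_trace(1, tt, -18 * g - pss)
  dt0 <- (ev$t_mvo - ev$t_mvc) / 2000
  a <- segment_work(tr, curve, ev, dt = dt0)
  b <- segment_work(tr, curve, ev, dt = dt0 / 16)
  expect_gt(a$wasted, 0)
  expect_equal(a$wasted, b$wasted, tolerance = 5e-3)
  expect_equal(a$constructive, b$constructive, tolerance = 5e-3)
})

test_that("ideal contraction with on-grid valve closure wastes nothing", {
  ev <- default_events()
  curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(118, 76))
  t_sys <- seq(ev$t_mvc, ev$t_avc, length.out = 201)
  t_ivr <- seq(ev$t_avc, ev$t_mvo, length.out = 45)[-1]
  g <- c((1 - cos(pi * t_sys / ev$t_avc)) / 2,
         1 - 0.15 * (1 - cos(pi * (t_ivr - ev$t_avc) / (ev$t_mvo - ev$t_avc))) / 2)
  tr <- strain_trace(1, c(t_sys, t_ivr), -19 * g)
  sw <- segment_work(tr, curve, ev)
  # bounded by the stencil-attribution residue around AVC: < 0.003% of GCW
  expect_lt(sw$wasted, 0.05)
  expect_identical(sw$work_index, sw$constructive - sw$wasted)
})

test_that("refinement convergence: halving dt moves integrals by < 1e-3", {
  ev <- default_events()
  curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(121, 78))
  dt0 <- (ev$t_mvo - ev$t_mvc) / 2000
  set.seed(7)
  tr <- random_smooth_trace(ev)
  a <- segment_work(tr, curve, ev, dt = dt0)
  b <- segment_work(tr, curve, ev, dt = dt0 / 2)
  expect_lt(abs(a$work_index - b$work_index) / abs(b$work_index), 1e-3)
  expect_lt(abs(a$constructive - b$constructive) / b$constructive, 1e-3)
})

test_that("work decomposition identity and bounds hold for random segments", {
  ev <- default_events()
  curve <- scale_to_cycle(build_reference_curve(64), ev, cuff_pressure(119, 75))
  set.seed(11)
  for (i in 1:50) {
    sw <- segment_work(random_smooth_trace(ev), curve, ev)
    expect_identical(sw$work_index, sw$constructive - sw$wasted)
    expect_gte(sw$constructive, 0)
    expect_gte(sw$wasted, 0)
  }
})

test_that("work scales linearly with pressure; GWE and GLS do not", {
  ev <- default_events()
  tpl <- build_reference_curve(64)
  set.seed(3)
  traces <- lapply(1:17, function(i) random_smooth_trace(ev, segment_id = i))
  g1 <- subject_work(traces, ev, cuff_pressure(100, 70))
  g2 <- subject_work(traces, ev, cuff_pressure(130, 70))
  k <- 1.3
  expect_equal(g2$gwi, k * g1$gwi, tolerance = 1e-9)
  expect_equal(g2$gcw, k * g1$gcw, tolerance = 1e-9)
  expect_equal(g2$gww, k * g1$gww, tolerance = 1e-9)
  expect_equal(g2$gwe, g1$gwe, tolerance = 1e-9)
  expect_identical(g2$gls, g1$gls)
})

test_that("global aggregation is the segment mean and is order invariant", {
  sw <- lapply(1:17, function(i)
    structure(list(segment_id = i, work_index = 1500, constructive = 1550,
                   wasted = 50), class = "segment_work"))
  g <- aggregate_global(sw, rep(-18, 17))
  expect_identical(g$gwi, 1500)
  expect_identical(g$gls, -18)

  set.seed(5)
  wi <- stats::runif(17, 1000, 2200)
  cw <- wi + stats::runif(17, 0, 100)
  sw2 <- lapply(1:17, function(i)
    structure(list(segment_id = i, work_index = wi[i], constructive = cw[i],
                   wasted = cw[i] - wi[i]), class = "segment_work"))
  peaks <- stats::runif(17, -25, -10)
  g2 <- aggregate_global(sw2, peaks)
  expect_equal(g2$gwi, mean(wi), tolerance = 1e-12)
  perm <- sample(17)
  g3 <- aggregate_global(sw2[perm], peaks)
  expect_equal(g3$gwi, g2$gwi, tolerance = 1e-12)
  expect_equal(g3$gcw, g2$gcw, tolerance = 1e-12)
  expect_equal(g3$gwe, g2$gwe, tolerance = 1e-12)
})

test_that("work efficiency follows its defining ratio", {
  sw <- lapply(1:17, function(i)
    structure(list(segment_id = i, work_index = 1900, constructive = 1950,
                   wasted = 50), class = "segment_work"))
  g <- aggregate_global(sw, rep(-19, 17))
  expect_equal(g$gwe, 97.5, tolerance = 1e-12)
  sw0 <- lapply(sw, function(s) { s$wasted <- 0; s$work_index <- s$constructive; s })
  expect_identical(aggregate_global(sw0, rep(-19, 17))$gwe, 100)
})

test_that("incomplete segmentation and domain mismatches are rejected", {
  sw <- lapply(1:16, function(i)
    structure(list(segment_id = i, work_index = 1, constructive = 1,
                   wasted = 0), class = "segment_work"))
  expect_error(aggregate_global(sw, rep(-18, 16)), "incomplete segmentation")
  ev <- default_events()
  short <- strain_trace(1, seq(0, 0.3, by = 0.01), rep(0, 31))
  expect_error(segment_work(short, flat_pressure(ev), ev), "domain error")
})

test_that("strain trace validation enforces the physiologic envelope", {
  expect_error(strain_trace(0, 0:2, c(0, -1, -2)), "1..17")
  expect_error(strain_trace(1, c(0, 1, 1), c(0, -1, -2)), "strictly increasing")
  expect_error(strain_trace(1, 0:2, c(0, -60, -2)), "50")
  expect_error(strain_trace(1, 0:2, c(1, -1, -2)), "referenced to 0")
})

test_that("uniform depression of peak strain lowers GLS magnitude and work", {
  ev <- default_events()
  set.seed(9)
  base <- lapply(1:17, function(i) random_smooth_trace(ev, segment_id = i))
  vals <- lapply(c(1, 0.8, 0.6), function(k) {
    traces <- lapply(base, function(tr) strain_trace(tr$segment_id, tr$times, k * tr$strain))
    subject_work(traces, ev, cuff_pressure(120, 78))
  })
  gls <- sapply(vals, function(g) abs(g$gls))
  gwi <- sapply(vals, function(g) g$gwi)
  gcw <- sapply(vals, function(g) g$gcw)
  expect_true(all(diff(gls) < 0))
  expect_true(all(diff(gwi) < 0))
  expect_true(all(diff(gcw) < 0))
})
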