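# prf_models module: overlap oracle, drives, CSS/CST/DoG/DN-ST behaviour.

test_that("rect_overlap matches brute-force quadrature and edge cases", {
  prf <- spatial_prf(4, 4, 2)
  rect <- c(x_min = 2.59, x_max = 4.59, y_min = 2.59, y_max = 4.59)
  # midpoint quadrature oracle at 0.005 deg
  xs <- seq(rect["x_min"] + 0.0025, rect["x_max"], by = 0.005)
  oracle <- sum(outer(stats::dnorm(xs, 4, 2), stats::dnorm(xs, 4, 2))) *
    0.005^2
  expect_lt(abs(rect_overlap(prf, rect) - oracle), 1e-5)
  # tiny pRF fully inside a square
  expect_equal(rect_overlap(spatial_prf(3.5, 3.5, 0.01), rect), 1,
               tolerance = 1e-6)
  # centre exactly on one edge, sigma much smaller than the square
  expect_equal(rect_overlap(spatial_prf(2.59, 3.5, 0.05), rect), 0.5,
               tolerance = 1e-6)
  expect_warning(
    z <- rect_overlap(prf, c(x_min = 1, x_max = 1, y_min = 0, y_max = 2)),
    "degenerate"
  )
  expect_equal(z, 0)
  expect_error(spatial_prf(0, 0, -1), "sigma")
})

test_that("spatial drive equals the rasterized dot product", {
  seqn <- fx_sequences()[[1]]
  sc <- fx_schedules()[[1]]
  prf <- spatial_prf(4, 4, 2)
  drive <- spatial_drive(prf, seqn)
  # 0.01 deg/pixel grid aligns pixel boundaries with all square edges
  g <- grid_spec(24, 0.01)
  gx <- stats::dnorm(g$x, prf$x0, prf$sigma)
  gy <- stats::dnorm(g$y, prf$y0, prf$sigma)
  G <- outer(gy, gx) * g$px_deg^2
  # sample times across blanks and several conditions
  times <- c(2000, sc$onset_s[c(1, 4, 7, 12)] * 1000 + c(150, 700, 2500,
                                                         4200))
  ras <- rasterize(seqn, g, times)
  for (k in seq_along(times)) {
    o <- sum(G * ras[, , k])
    expect_lt(abs(o - drive[times[k] + 1]), 1e-4 * max(drive[times[k] + 1],
                                                       1e-3))
  }
  # blank run is all-zero; drive is bounded by 2 (two unit-volume quadrants)
  expect_true(all(drive[1:12000] == 0))
  expect_true(all(drive >= 0 & drive <= 2))
})

test_that("SIM plateau is the sum of per-square overlaps", {
  seqn <- fx_sequences()[[1]]
  sc <- fx_schedules()[[1]]
  prf <- spatial_prf(5, 5, 3)
  b <- sc$block[sc$label == "sim_long_small"][1]
  ev <- seqn$events
  e <- ev[ev$block == b & ev$trial == 1 & ev$quadrant == "upper_right", ]
  o <- sum(vapply(seq_len(4), function(i) {
    rect_overlap(prf, e[i, c("x_min", "x_max", "y_min", "y_max")])
  }, numeric(1)))
  t_mid <- e$on_ms[1] + 500
  # far-quadrant squares are also on at t_mid; add their overlap
  e_far <- ev[ev$block == b & ev$quadrant == "lower_left" &
                ev$on_ms <= t_mid & t_mid < ev$off_ms, ]
  o_far <- sum(vapply(seq_len(nrow(e_far)), function(i) {
    rect_overlap(prf, e_far[i, c("x_min", "x_max", "y_min", "y_max")])
  }, numeric(1)))
  expect_equal(spatial_drive(prf, seqn)[t_mid + 1], o + o_far,
               tolerance = 1e-12)
})

test_that("CSS reduces to LSS at n = 1 and is subadditive below", {
  seqn <- fx_sequences()[[1]]
  prf <- spatial_prf(5, 5, 2)
  expect_equal(predict_css(prf, 1, seqn), predict_lss(prf, seqn))
  expect_error(predict_css(prf, 0.001, seqn), "css_n")
  # (4 o)^n < 4 o^n for n < 1: the subadditivity driving CSS suppression
  o <- 0.2
  for (n in c(0.25, 0.5, 0.75, 0.99)) {
    expect_lt((4 * o)^n, 4 * o^n)
  }
  # scale equivariance: doubling overlaps doubles LSS, scales CSS by 2^n
  d <- spatial_drive(prf, seqn)
  expect_equal(max(2 * d) / max(d), 2)
  expect_equal(max((2 * d)^0.4) / max(d^0.4), 2^0.4, tolerance = 1e-12)
})

test_that("temporal IRFs have the stated areas, peak, and shape", {
  irfs <- fx_irfs()
  expect_equal(sum(irfs$sustained), 1, tolerance = 1e-6)
  expect_lt(abs(sum(irfs$on_transient)), 1e-6)
  expect_equal(irfs$off_transient, -irfs$on_transient)
  # sustained gamma peaks at (n - 1) kappa tau ~ 39 ms, inside 40 +- 10 ms
  peak_ms <- which.max(irfs$sustained) - 1
  expect_gte(peak_ms, 30)
  expect_lte(peak_ms, 50)
  expect_equal(peak_ms, round(8 * 1 * 4.93))
  # on-transient is biphasic: exactly one sign change
  v <- irfs$on_transient[abs(irfs$on_transient) > 1e-12]
  expect_equal(sum(diff(sign(v)) != 0), 1L)
})

test_that("CST channels respond to onsets/offsets and reduce to LSS", {
  irfs <- fx_irfs()
  sq <- step_sequence(on_ms = 1000, off_ms = 1200, duration_ms = 4000)
  prf <- spatial_prf(4, 4, 1)
  out <- predict_cst(prf, 0.5, sq, irfs)
  # a 200-ms pulse yields exactly two transient response lobes (onset +
  # offset): count local maxima above 10% of the peak
  tr <- out$transient
  peaks <- which(diff(sign(diff(tr))) == -2) + 1L
  expect_equal(sum(tr[peaks] > 0.1 * max(tr)), 2L)
  # zero stimulus -> zero channels
  blank <- step_sequence(on_ms = 0, off_ms = 0, duration_ms = 2000)
  blank$events <- blank$events[0, ]
  out0 <- predict_cst(prf, 0.5, blank, irfs)
  expect_true(all(out0$sustained == 0) && all(out0$transient == 0))
  # cst_n = 1 sustained channel equals sustained-filtered LSS drive
  sq1 <- step_sequence(on_ms = 500, off_ms = 1500, duration_ms = 4000)
  out1 <- predict_cst(prf, 1, sq1, irfs)
  d <- spatial_drive(prf, sq1)
  conv <- stats::convolve(d, rev(irfs$sustained), type = "open")
  expect_equal(out1$sustained, pmax(conv[seq_along(d)], 0),
               tolerance = 1e-8)
  expect_error(predict_cst(prf, 0.05, sq1, irfs), "cst_n")
})

test_that("DoG drive is balanced, centre-positive, and SEQ/SIM-matched", {
  seqn <- fx_sequences()[[1]]
  sc <- fx_schedules()[[1]]
  prf <- spatial_prf(4, 4, 1.5)
  # full-field stimulus drives a balanced DoG to ~0
  full <- step_sequence(on_ms = 100, off_ms = 1100, duration_ms = 2000,
                        rect = c(-200, 200, -200, 200))
  expect_lt(max(abs(predict_dog(prf, 7.4, full))), 1e-9)
  # tiny stimulus at the centre: positive drive
  tiny <- step_sequence(on_ms = 100, off_ms = 1100, duration_ms = 2000,
                        rect = c(3.9, 4.1, 3.9, 4.1))
  expect_gt(max(predict_dog(prf, 7.4, tiny)), 0)
  # linearity: equal block-integrated drive for SEQ and SIM pair members
  dog <- predict_dog(prf, 7.4, seqn)
  for (pair in c("long_small", "short_big")) {
    bs <- sc$block[sc$label == paste0("seq_", pair)][1]
    bb <- sc$block[sc$label == paste0("sim_", pair)][1]
    idx <- function(b) (sc$onset_s[b] * 1000 + 1):(sc$onset_s[b] * 1000 +
                                                     9000)
    expect_equal(sum(dog[idx(bs)]), sum(dog[idx(bb)]), tolerance = 1e-9,
                 info = pair)
  }
  expect_error(predict_dog(prf, 0.9, seqn), "surround_scale")
  expect_equal(dog_surround_scale("V2"), 6.8)
  expect_error(dog_surround_scale("TO1"), "surround")
})

test_that("DN-ST matches the scalar fixed point and stays bounded", {
  sq <- step_sequence(on_ms = 500, off_ms = 3500, duration_ms = 5000)
  prf <- spatial_prf(4, 4, 1.5)
  o <- rect_overlap(prf, c(x_min = 3, x_max = 5, y_min = 3, y_max = 5))
  out <- predict_dnst(prf, tau1_ms = 70, tau2_ms = 100, sigma_dn = 0.05,
                      n_dn = 2, sq)
  # steady state at t >> tau1, tau2: o^n / (sigma^n + o^n)
  expect_equal(out[3400], o^2 / (0.05^2 + o^2), tolerance = 1e-9)
  expect_true(all(is.finite(out)) && all(out >= 0))
  expect_lt(max(out[1:450]), 1e-12)  # pre-onset ~ zero
  # output decreases monotonically in sigma_dn at every time point
  out2 <- predict_dnst(prf, 70, 100, 0.2, 2, sq)
  expect_true(all(out2 <= out + 1e-12))
  expect_error(predict_dnst(prf, -1, 100, 0.05, 2, sq), "positive")
})

test_that("single-square footprints see identical SEQ and SIM series", {
  # onset-matched design: a pRF inside one square cannot distinguish
  # sequential from simultaneous presentation
  d <- seqsim_design(seed = 3L, onset_matched = TRUE)
  run <- generate_seqsim_run(d, 1)
  sc <- run$schedule
  prf <- spatial_prf(3.6, 3.6, 0.2)
  drive <- spatial_drive(prf, run$sequence)
  for (pair in c("long_small", "short_small", "long_big", "short_big")) {
    bs <- sc$block[sc$label == paste0("seq_", pair)][1]
    bb <- sc$block[sc$label == paste0("sim_", pair)][1]
    seg <- function(b) drive[(sc$onset_s[b] * 1000 + 1):
                               (sc$onset_s[b] * 1000 + 9000)]
    expect_equal(seg(bs), seg(bb), tolerance = 1e-9, info = pair)
  }
})

test_that("effective pRF size follows sigma / sqrt(css_n)", {
  expect_equal(effective_prf_size(2, 0.25), 4)
  expect_equal(effective_prf_size(1.7, 1), 1.7)
})
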