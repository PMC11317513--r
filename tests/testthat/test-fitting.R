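# fitting module: OLS, cross-validation, exponent grid-fit, retinotopy
# fit, reliability, voxel selection.

test_that("OLS recovers exact linear relations", {
  set.seed(2)
  pred <- stats::runif(200)
  beta <- fit_ols(pred, 3 * pred + 2)
  expect_equal(unname(beta), c(2, 3), tolerance = 1e-9)
  # orthogonal data: slope ~ 0
  y <- rep(c(-1, 1), 100)
  expect_lt(abs(fit_ols(pred - mean(pred), y - mean(y))[2]), 0.2)
  # CST-style two-channel recovery on non-collinear regressors
  X <- cbind(s = stats::runif(200), t = stats::runif(200))
  b2 <- fit_ols(X, 1.5 * X[, 1] + 0.5 * X[, 2])
  expect_equal(unname(b2), c(0, 1.5, 0.5), tolerance = 1e-6)
  expect_warning(fit_ols(cbind(pred, pred), 3 * pred), "rank")
})

test_that("split-half cross-validation behaves as a proper score", {
  set.seed(3)
  pred <- stats::runif(300)
  perfect <- crossval_fit(pred, list(2 * pred + 1, 2 * pred + 1))
  expect_equal(perfect$cv_r2, 100)
  expect_equal(unname(perfect$betas), c(1, 2), tolerance = 1e-9)
  # cv_r2 is invariant to affine rescaling of the prediction
  resc <- crossval_fit(0.2 * pred + 5, list(2 * pred + 1, 2 * pred + 1))
  expect_equal(resc$cv_r2, 100)
  # independent noise halves: cv_r2 ~ 0 in expectation up to the O(k/n)
  # small-sample bias of out-of-sample R2, and cv R2 never exceeds the
  # within-half R2 on average
  set.seed(4)
  n_rep <- 300
  n_half <- 100
  cvs <- numeric(n_rep)
  diffs <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- stats::rnorm(n_half)
    b <- stats::rnorm(n_half)
    f <- crossval_fit(pred[seq_len(n_half)], list(a, b))
    cvs[i] <- f$cv_r2
    within <- mean(c(
      summary(stats::lm(a ~ pred[seq_len(n_half)]))$r.squared,
      summary(stats::lm(b ~ pred[seq_len(n_half)]))$r.squared
    )) * 100
    diffs[i] <- f$cv_r2 - within
  }
  expect_lt(abs(mean(cvs)), 100 * 4 / n_half)
  expect_lt(mean(diffs), 0)
  # constant data: undefined cv_r2 reported as missing
  expect_true(is.na(crossval_fit(pred[1:50],
                                 list(rep(1, 50), rep(1, 50)))$cv_r2))
})

test_that("CST exponent grid-fit recovers the generating exponent", {
  hrf <- fx_hrf()
  irfs <- fx_irfs()
  seqs <- fx_sequences()
  params <- list(x0 = 5, y0 = 5, sigma = 3)
  # noiseless on-grid voxel: exact recovery
  reg <- predict_model_regressors("cst", c(params, cst_n = 0.45), seqs,
                                  hrf, 1, irfs)
  y <- drop(normalize_max(reg) %*% c(1.2, 0.9)) + 0.3
  g <- gridfit_cst_exponent(params, seqs, list(y, y), hrf, irfs = irfs)
  expect_equal(g$best_cst_n, 0.45)
  expect_equal(g$fit$cv_r2, 100, tolerance = 0.1)
  expect_equal(unname(g$fit$betas), c(0.3, 1.2, 0.9), tolerance = 1e-6)
  # linear limit: cst_n = 1 with a sustained-only voxel
  reg1 <- predict_model_regressors("cst", c(params, cst_n = 1), seqs,
                                   hrf, 1, irfs)
  y1 <- drop(normalize_max(reg1) %*% c(1, 0))
  g1 <- gridfit_cst_exponent(params, seqs, list(y1, y1), hrf, irfs = irfs)
  expect_equal(g1$best_cst_n, 1)
})

test_that("grid-fit recovers a noisy voxel within 0.1 in most runs", {
  # reliability ~ 0.5 voxel; channel regressors are precomputed per grid
  # exponent so each simulation only repeats the regression stage
  hrf <- fx_hrf()
  irfs <- fx_irfs()
  seqs <- fx_sequences()
  grid <- seq(0.1, 1, by = 0.05)
  params <- list(x0 = 5, y0 = 5, sigma = 3.5)
  prf <- spatial_prf(params$x0, params$y0, params$sigma)
  channels <- lapply(seqs, function(s) {
    seqsimprf:::cst_channels(spatial_drive(prf, s), irfs)
  })
  regs <- lapply(grid, function(n) {
    normalize_max(do.call(rbind, lapply(channels, function(ch) {
      cbind(neural_to_bold(ch$sustained^n, hrf),
            neural_to_bold(ch$on^n + ch$off^n, hrf))
    })))
  })
  truth <- 0.40
  signal <- drop(regs[[which(abs(grid - truth) < 1e-9)]] %*% c(1, 1))
  noise_sd <- sqrt(stats::var(signal) * 0.5 / 1.5)  # reliability ~ 0.5
  set.seed(5)
  n_sim <- 60
  hits <- 0
  for (i in seq_len(n_sim)) {
    halves <- list(signal + stats::rnorm(length(signal), 0, noise_sd),
                   signal + stats::rnorm(length(signal), 0, noise_sd))
    r2 <- vapply(regs, function(r) crossval_fit(r, halves)$cv_r2,
                 numeric(1))
    hits <- hits + (abs(grid[which.max(r2)] - truth) <= 0.10)
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("retinotopy CSS fit recovers centres and effective size", {
  hrf <- fx_hrf()
  bar <- fixture("bar", function() generate_retinotopy_run())
  # on-(fitter-)grid truth: exact stage-1 recovery
  y <- predict_css_bar(bar, 4.25, 2.25, 3, 0.5, hrf, px_deg = 0.5)
  fit <- fit_css_retinotopy(bar, y, hrf)
  expect_equal(unlist(fit$coarse[c("x0", "y0", "sigma", "css_n")]),
               c(x0 = 4.25, y0 = 2.25, sigma = 3, css_n = 0.5))
  # off-grid truth: stage 2 recovers the centre within 0.1 deg; sigma and
  # exponent trade off along the sigma/sqrt(n) ridge, so only the
  # effective size is identified
  y2 <- predict_css_bar(bar, 3.3, -2.1, 1.7, 0.45, hrf)
  fit2 <- fit_css_retinotopy(bar, 2.5 + 1.3 * y2, hrf)
  expect_lt(abs(fit2$x0 - 3.3), 0.1)
  expect_lt(abs(fit2$y0 - -2.1), 0.1)
  eff_truth <- effective_prf_size(1.7, 0.45)
  expect_lt(abs(effective_prf_size(fit2$sigma, fit2$css_n) - eff_truth) /
              eff_truth, 0.1)
  expect_gt(fit2$r2, 99.9)
  # voxel outside the stimulated aperture: no fit
  set.seed(6)
  flat <- stats::rnorm(length(y), 0, 1e-3)
  fit3 <- fit_css_retinotopy(bar, flat, hrf)
  expect_lt(fit3$r2, 20)
  expect_error(fit_css_retinotopy(bar, c(y[-1], NA), hrf), "finite")
})

test_that("split-half reliability tracks noise level", {
  set.seed(7)
  signal <- as.vector(stats::filter(stats::rnorm(300), rep(0.2, 5),
                                    sides = 1))
  signal[is.na(signal)] <- 0
  expect_equal(split_half_reliability(cbind(signal, signal)), 100)
  # reliability decreases monotonically (in expectation) with noise SD
  rel_at <- function(sd) {
    mean(vapply(1:40, function(i) {
      runs <- sapply(1:4, function(r) signal + stats::rnorm(300, 0, sd))
      split_half_reliability(runs)
    }, numeric(1)))
  }
  rels <- vapply(c(0.05, 0.2, 0.6), rel_at, numeric(1))
  expect_true(all(diff(rels) < 0))
  # pure noise: ~ 0 in expectation (E[cor^2] = 1 / (n - 1))
  noise_rel <- vapply(1:60, function(i) {
    split_half_reliability(sapply(1:4, function(r) stats::rnorm(100)))
  }, numeric(1))
  expect_lt(mean(noise_rel), 3)
  expect_error(split_half_reliability(cbind(signal)), "2 runs")
})

test_that("voxel selection applies all inclusion rules", {
  vox <- data.frame(
    x0 = c(5, 0.5, 5, 5, -5, 5, 9.6),
    y0 = c(5, 5, 5, 5, -5, -5, 5),
    ret_r2 = c(90, 90, 10, 90, 90, 90, 90),
    reliability = c(50, 50, 50, 5, 50, 50, 50),
    tau_ms = c(100, 100, 100, 100, 1500, 100, 100)
  )
  out <- select_voxels(vox)
  expect_equal(out$keep,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$exclusion_reason[2], "outside_stimulus_box")
  expect_equal(out$exclusion_reason[3], "low_retinotopy_r2")
  expect_equal(out$exclusion_reason[4], "low_reliability")
  expect_equal(out$exclusion_reason[5], "tau_too_large")
  # mixed-sign centre (x > 0, y < 0) is outside both quadrants
  expect_equal(out$exclusion_reason[6], "outside_stimulus_box")
  expect_equal(out$exclusion_reason[7], "outside_stimulus_box")
})

test_that("noiseless full-pipeline fit reaches 100% cv-R2", {
  # forward oracle: fitting the generating model to its own noiseless
  # output recovers betas and explains everything
  hrf <- fx_hrf()
  seqs <- fx_sequences()
  for (m in c("lss", "css")) {
    params <- list(x0 = 4, y0 = 4, sigma = 1.5, css_n = 0.4)
    reg <- normalize_max(predict_model_regressors(m, params, seqs, hrf))
    y <- drop(reg) * 1.7 + 0.2
    fit <- crossval_fit(reg, list(y, y))
    expect_equal(fit$cv_r2, 100, tolerance = 0.1, info = m)
    expect_equal(unname(fit$betas), c(0.2, 1.7), tolerance = 1e-3, info = m)
  }
})
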