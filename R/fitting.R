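# Model fitting: OLS with an offset column, split-half cross-validation,
# CST exponent grid-fit, reliability and voxel selection.

#' Ordinary least squares with an offset column
#'
#' Prepends a column of 1's (response offset) to the prediction
#' regressors and solves by QR; rank-deficient designs fall back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param pred numeric vector or matrix of prediction regressors
#'   (max-normalized upstream).
#' @param data observed series.
#' @return named numeric beta vector (`b0` first).
#' @export
fit_ols <- function(pred, data) {
  X <- cbind(b0 = 1, as.matrix(pred))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("rank-deficient design; using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% data) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrx, data)
  }
  names(beta) <- colnames(X)
  beta
}

#' Split-half cross-validated fit
#'
#' Fits beta weights on one half, scores the scaled prediction on the
#' other half with the weights fixed (no refitting), in both directions,
#' and averages cv-R2 and betas. The adjusted variant penalizes for the
#' number of time points and regressors.
#'
#' @param pred prediction regressors: a matrix used for both halves, or a
#'   list of two matrices (one per half).
#' @param data_halves list of two observed series of equal length.
#' @return list with `betas` (averaged), `cv_r2` and `adj_cv_r2`
#'   (percent; `NA` for zero-variance data), and `per_direction` details.
#' @export
crossval_fit <- function(pred, data_halves) {
  stopifnot(length(data_halves) == 2L,
            length(data_halves[[1]]) == length(data_halves[[2]]))
  preds <- if (is.list(pred) && !is.data.frame(pred)) pred else list(pred, pred)
  preds <- lapply(preds, as.matrix)
  n <- length(data_halves[[1]])
  p <- ncol(preds[[1]]) + 1L
  one_dir <- function(train, test) {
    beta <- fit_ols(preds[[train]], data_halves[[train]])
    yhat <- drop(cbind(1, preds[[test]]) %*% beta)
    r2 <- r2_percent(data_halves[[test]], yhat)
    adj <- if (is.na(r2)) NA_real_ else {
      100 * (1 - (1 - r2 / 100) * (n - 1) / (n - p))
    }
    list(beta = beta, r2 = r2, adj = adj)
  }
  d12 <- one_dir(1L, 2L)
  d21 <- one_dir(2L, 1L)
  list(
    betas = (d12$beta + d21$beta) / 2,
    cv_r2 = mean(c(d12$r2, d21$r2)),
    adj_cv_r2 = mean(c(d12$adj, d21$adj)),
    per_direction = list(d12, d21)
  )
}

#' Grid-fit of the CST compressive exponent
#'
#' Evaluates the cross-validated goodness-of-fit of the CST prediction for
#' exponents on a grid (default 0.1 to 1 in 0.05 steps) and returns the
#' exponent maximizing cv-R2 (ties broken toward the smallest exponent).
#' The spatial drive and channel convolutions are computed once; only the
#' static nonlinearity and HRF stage are repeated per grid value.
#'
#' @param params voxel spatial parameters (`x0`, `y0`, `sigma` =
#'   effective size).
#' @param sequences list of `stim_sequence` runs.
#' @param data_halves list of two observed concatenated half series.
#' @param hrf HRF kernel.
#' @param tr_s TR (s).
#' @param grid exponent grid.
#' @param irfs CST temporal kernels.
#' @return list with `best_cst_n`, `fit` (the [crossval_fit()] result at
#'   the optimum), and `grid_r2` (named cv-R2 per exponent).
#' @export
gridfit_cst_exponent <- function(params, sequences, data_halves, hrf,
                                 tr_s = 1, grid = seq(0.1, 1, by = 0.05),
                                 irfs = make_temporal_irfs()) {
  prf <- spatial_prf(params$x0, params$y0, params$sigma)
  channels <- lapply(sequences, function(seqn) {
    cst_channels(spatial_drive(prf, seqn), irfs)
  })
  eval_n <- function(n) {
    reg <- do.call(rbind, lapply(channels, function(ch) {
      cbind(sustained = neural_to_bold(ch$sustained^n, hrf, tr_s),
            transient = neural_to_bold(ch$on^n + ch$off^n, hrf, tr_s))
    }))
    crossval_fit(normalize_max(reg), data_halves)
  }
  fits <- lapply(grid, eval_n)
  r2 <- vapply(fits, `[[`, numeric(1), "cv_r2")
  names(r2) <- format(grid)
  if (all(is.na(r2))) stop("all grid exponents produced undefined cv-R2")
  best <- which(r2 >= max(r2, na.rm = TRUE) - 1e-12)[1]
  list(best_cst_n = grid[best], fit = fits[[best]], grid_r2 = r2)
}

#' Split-half reliability (noise ceiling)
#'
#' Averages the odd and even runs and computes the variance explained
#' between the two half means: the squared correlation, in percent (the
#' in-sample R2 of regressing either half on the other, so it is
#' symmetric, 100 for identical halves, and ~0 for pure noise). Used for
#' the >= 10 percent inclusion filter and as the noise ceiling.
#'
#' @param runs numeric matrix (TRs x runs) or list of run vectors.
#' @return reliability in percent; `NA` for zero-variance halves.
#' @export
split_half_reliability <- function(runs) {
  if (is.list(runs)) runs <- do.call(cbind, runs)
  runs <- as.matrix(runs)
  if (ncol(runs) < 2L) stop("need at least 2 runs")
  odd <- rowMeans(runs[, seq(1, ncol(runs), by = 2), drop = FALSE])
  even <- rowMeans(runs[, seq(2, ncol(runs), by = 2), drop = FALSE])
  if (stats::sd(odd) == 0 || stats::sd(even) == 0) return(NA_real_)
  100 * stats::cor(odd, even)^2
}

#' Voxel selection filters
#'
#' Applies the inclusion rules used before suppression analysis: variance
#' explained in the retinotopy experiment >= `min_ret_r2`; pRF centre
#' within the big-square bounding box of a quadrant (|x| and |y| both in
#' `center_box`, with x and y in the same quadrant); split-half
#' reliability >= `min_reliability`; and, when a `tau_ms` column is
#' present (spatiotemporal workflows), time constants <= `max_tau_ms`.
#'
#' @param voxels data.frame with columns `x0`, `y0`, `ret_r2`,
#'   `reliability`, optionally `tau_ms`.
#' @param center_box inner/outer extent of the big-square box (deg).
#' @param min_ret_r2,min_reliability,max_tau_ms thresholds.
#' @return `voxels` with logical column `keep` and character column
#'   `exclusion_reason` (`""` for kept voxels).
#' @export
select_voxels <- function(voxels, center_box = c(0.59, 9.41),
                          min_ret_r2 = 20, min_reliability = 10,
                          max_tau_ms = 1000) {
  reason <- character(nrow(voxels))
  bad_r2 <- voxels$ret_r2 < min_ret_r2
  in_box <- abs(voxels$x0) >= center_box[1] &
    abs(voxels$x0) <= center_box[2] &
    abs(voxels$y0) >= center_box[1] &
    abs(voxels$y0) <= center_box[2] &
    sign(voxels$x0) == sign(voxels$y0)
  bad_rel <- voxels$reliability < min_reliability
  reason[bad_rel] <- "low_reliability"
  reason[!in_box] <- "outside_stimulus_box"
  reason[bad_r2] <- "low_retinotopy_r2"
  if (!is.null(voxels$tau_ms)) {
    bad_tau <- voxels$tau_ms > max_tau_ms
    reason[bad_tau & reason == ""] <- "tau_too_large"
  }
  voxels$keep <- reason == ""
  voxels$exclusion_reason <- reason
  voxels
}
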