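# Spatial pRF estimation from the retinotopy bar protocol with the
# compressive spatial summation model: exhaustive coarse grid-fit followed
# by a derivative-free fine search.

# Exact TR-resolution response matrix of the bar frames: column f is the
# TR-binned causal convolution of frame f's boxcar indicator with the
# millisecond HRF, so frame-constant neural drives map to BOLD exactly as
# in neural_to_bold().
bar_response_matrix <- function(bar_seq, hrf, tr_s = 1,
                                dt_ms = attr(hrf, "dt_ms")) {
  n_ms <- bar_seq$duration_ms / dt_ms
  samples_per_tr <- round(tr_s * 1000 / dt_ms)
  n_tr <- floor(n_ms / samples_per_tr)
  C <- cumsum(as.numeric(hrf))
  len <- length(C)
  cfun <- function(k) {
    k <- pmin(k, len)
    out <- numeric(length(k))
    pos <- k > 0
    out[pos] <- C[k[pos]]
    out
  }
  t_idx <- seq_len(n_tr * samples_per_tr)
  fr <- bar_seq$frames
  A <- matrix(0, n_tr, nrow(fr))
  for (f in seq_len(nrow(fr))) {
    y <- cfun(t_idx - fr$on_ms[f] / dt_ms) - cfun(t_idx - fr$off_ms[f] / dt_ms)
    A[, f] <- colMeans(matrix(y, nrow = samples_per_tr))
  }
  A
}

# binary masks of all bar frames on a pixel grid, as a (pixels x frames)
# matrix (column-major over the (y, x) raster)
bar_frame_masks <- function(bar_seq, grid) {
  fr <- bar_seq$frames
  nx <- length(grid$x)
  ny <- length(grid$y)
  xx <- matrix(grid$x, ny, nx, byrow = TRUE)
  yy <- matrix(grid$y, ny, nx)
  apert <- as.vector(xx^2 + yy^2 <= (bar_seq$fov_deg / 2)^2)
  M <- matrix(0, ny * nx, nrow(fr))
  for (f in seq_len(nrow(fr))) {
    a <- fr$orientation[f] * pi / 180
    u <- cos(a) * xx + sin(a) * yy
    M[, f] <- (abs(as.vector(u) - fr$position[f]) <=
                 bar_seq$bar_width_deg / 2) & apert
  }
  M
}

# per-frame Gaussian drive for one pRF on a pixel grid
bar_drive <- function(masks, grid, x0, y0, sigma) {
  nx <- length(grid$x)
  ny <- length(grid$y)
  gx <- stats::dnorm(grid$x, x0, sigma)
  gy <- stats::dnorm(grid$y, y0, sigma)
  g <- as.vector(outer(gy, gx)) * grid$px_deg^2
  drop(crossprod(masks, g))
}

#' Predict the BOLD response of a CSS pRF to the bar protocol
#'
#' Forward model used by (and consistent with) the retinotopy fitter:
#' Gaussian-bar overlap per frame on a pixel grid, compressive exponent,
#' exact boxcar-times-HRF convolution, TR binning.
#'
#' @param bar_seq a [generate_retinotopy_run()] sequence.
#' @param x0,y0,sigma,css_n CSS pRF parameters.
#' @param hrf HRF kernel.
#' @param tr_s TR (s).
#' @param px_deg raster resolution (deg/pixel).
#' @return numeric vector, one value per TR.
#' @export
predict_css_bar <- function(bar_seq, x0, y0, sigma, css_n, hrf, tr_s = 1,
                            px_deg = 0.25) {
  grid <- grid_spec(bar_seq$fov_deg, px_deg)
  masks <- bar_frame_masks(bar_seq, grid)
  A <- bar_response_matrix(bar_seq, hrf, tr_s)
  drop(A %*% bar_drive(masks, grid, x0, y0, sigma)^css_n)
}

#' Estimate a CSS spatial pRF from retinotopy data
#'
#' Two-stage optimization: stage 1 evaluates an exhaustive coarse grid
#' (pRF centres on a 1-deg lattice within the aperture, sigma in
#' {0.5, 1, ..., 8}, exponent in {0.05, 0.25, 0.5, 0.75, 1}) using a
#' separable Gaussian blur of the rasterized bar frames; stage 2 refines
#' the coarse optimum with Nelder-Mead on the continuous forward model.
#' The exponent is clipped to [0.01, 1].
#'
#' @param bar_seq a [generate_retinotopy_run()] sequence.
#' @param voxel_series observed TR-resolution series.
#' @param hrf HRF kernel.
#' @param tr_s TR (s).
#' @param sigma_grid,n_grid coarse grids.
#' @param px_coarse,px_fine raster resolutions for the two stages (deg).
#' @return list with `x0`, `y0`, `sigma`, `css_n`, `r2` (percent) and the
#'   stage-1 optimum `coarse`.
#' @export
fit_css_retinotopy <- function(bar_seq, voxel_series, hrf, tr_s = 1,
                               sigma_grid = seq(0.5, 8, by = 0.5),
                               n_grid = c(0.05, 0.25, 0.5, 0.75, 1),
                               px_coarse = 0.5, px_fine = 0.25) {
  if (!all(is.finite(voxel_series))) stop("non-finite voxel series")
  A <- bar_response_matrix(bar_seq, hrf, tr_s)
  stopifnot(length(voxel_series) == nrow(A))
  y_c <- voxel_series - mean(voxel_series)
  ss_y <- sum(y_c^2)
  grid_c <- grid_spec(bar_seq$fov_deg, px_coarse)
  masks_c <- bar_frame_masks(bar_seq, grid_c)
  ny <- length(grid_c$y)
  nx <- length(grid_c$x)
  n_frames <- ncol(masks_c)
  # 1-deg lattice = every other coarse pixel centre, inside the aperture
  lat_i <- seq(1, ny, by = round(1 / px_coarse))
  lat <- expand.grid(iy = lat_i, ix = lat_i)
  lat$x <- grid_c$x[lat$ix]
  lat$y <- grid_c$y[lat$iy]
  lat <- lat[lat$x^2 + lat$y^2 <= (bar_seq$fov_deg / 2)^2, ]
  lat_px <- (lat$ix - 1L) * ny + lat$iy
  best <- list(score = -Inf)
  for (sig in sigma_grid) {
    kx <- stats::dnorm(grid_c$x, mean = 0, sd = sig)
    K <- outer(grid_c$x, grid_c$x,
               function(a, b) stats::dnorm(a - b, sd = sig)) * px_coarse
    # blur every frame: drive of a pRF centred at pixel (i,j) equals the
    # Gaussian-smoothed frame sampled at that pixel (separable kernel)
    D <- matrix(0, length(lat_px), n_frames)
    for (f in seq_len(n_frames)) {
      Fm <- matrix(masks_c[, f], ny, nx)
      B <- K %*% Fm %*% t(K)
      D[, f] <- B[lat_px]
    }
    for (nn in n_grid) {
      P <- tcrossprod(D^nn, A)  # centres x TRs
      P_c <- P - rowMeans(P)
      num <- drop(P_c %*% y_c)
      den <- sqrt(rowSums(P_c^2) * ss_y)
      score <- ifelse(den > 0, (num / den)^2, -Inf)
      k <- which.max(score)
      if (score[k] > best$score) {
        best <- list(score = score[k], x0 = lat$x[k], y0 = lat$y[k],
                     sigma = sig, css_n = nn)
      }
    }
  }
  # stage 2: continuous refinement from the coarse optimum
  grid_f <- grid_spec(bar_seq$fov_deg, px_fine)
  masks_f <- bar_frame_masks(bar_seq, grid_f)
  objective <- function(par) {
    sigma <- exp(par[3])
    nn <- min(max(par[4], 0.01), 1)
    if (sigma < 0.05 || sigma > 24) return(1e6)
    d <- bar_drive(masks_f, grid_f, par[1], par[2], sigma)^nn
    p <- drop(A %*% d)
    p_c <- p - mean(p)
    den <- sum(p_c^2) * ss_y
    if (den <= 0) return(1)
    1 - sum(p_c * y_c)^2 / den
  }
  opt <- stats::optim(
    c(best$x0, best$y0, log(best$sigma), best$css_n), objective,
    method = "Nelder-Mead",
    control = list(maxit = 1000, reltol = 1e-10)
  )
  out <- list(x0 = opt$par[1], y0 = opt$par[2], sigma = exp(opt$par[3]),
              css_n = min(max(opt$par[4], 0.01), 1),
              r2 = 100 * (1 - opt$value), coarse = best)
  out
}
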