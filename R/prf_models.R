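# pRF encoding models: LSS, CSS, CST, DoG, DN-ST.
#
# All models share the same spatial stage: a circular 2D Gaussian with
# unit volume, whose dot product with the binary stimulus is evaluated in
# closed form per rectangle (product of 1-D Gaussian integrals), so the
# millisecond drive is exact and piecewise constant between events.

#' Circular 2D Gaussian pRF
#'
#' @param x0,y0 centre (deg).
#' @param sigma standard deviation (deg), > 0.
#' @return object of class `spatial_prf`.
#' @export
spatial_prf <- function(x0, y0, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(x0 = x0, y0 = y0, sigma = sigma), class = "spatial_prf")
}

#' Gaussian-rectangle overlap fraction
#'
#' Closed-form integral of a unit-volume circular Gaussian over an
#' axis-aligned rectangle: the separable product of two 1-D Gaussian
#' integrals. Always in [0, 1].
#'
#' @param prf a [spatial_prf()].
#' @param rect numeric with named elements or data.frame row containing
#'   `x_min`, `x_max`, `y_min`, `y_max` (deg).
#' @return overlap fraction in [0, 1].
#' @export
rect_overlap <- function(prf, rect) {
  stopifnot(inherits(prf, "spatial_prf"))
  rect <- as.list(rect)
  if (rect$x_max <= rect$x_min || rect$y_max <= rect$y_min) {
    warning("degenerate rectangle (zero area); overlap is 0")
    return(0)
  }
  px <- stats::pnorm(rect$x_max, prf$x0, prf$sigma) -
    stats::pnorm(rect$x_min, prf$x0, prf$sigma)
  py <- stats::pnorm(rect$y_max, prf$y0, prf$sigma) -
    stats::pnorm(rect$y_min, prf$y0, prf$sigma)
  px * py
}

#' Millisecond spatial drive of a pRF
#'
#' At each millisecond, the dot product between the Gaussian pRF and the
#' binary stimulus: the sum of [rect_overlap()] over the rectangles active
#' at that time. This is the linear-spatial-summation (LSS) neural
#' prediction; the other models transform it.
#'
#' @param prf a [spatial_prf()].
#' @param sequence a `stim_sequence`.
#' @return numeric vector, one value per ms (length `duration_ms`).
#' @export
spatial_drive <- function(prf, sequence) {
  stopifnot(inherits(prf, "spatial_prf"), inherits(sequence, "stim_sequence"))
  ev <- sequence$events
  d <- numeric(sequence$duration_ms)
  if (nrow(ev) == 0L) return(d)
  key <- paste(ev$x_min, ev$x_max, ev$y_min, ev$y_max)
  ukey <- !duplicated(key)
  ov_unique <- vapply(which(ukey), function(i) {
    rect_overlap(prf, ev[i, c("x_min", "x_max", "y_min", "y_max")])
  }, numeric(1))
  ov <- ov_unique[match(key, key[ukey])]
  for (i in seq_len(nrow(ev))) {
    if (ov[i] < 1e-12) next
    idx <- (ev$on_ms[i] + 1L):ev$off_ms[i]
    d[idx] <- d[idx] + ov[i]
  }
  d
}

#' Linear spatial summation (LSS) prediction
#'
#' Identical to [spatial_drive()]: linear summation over space and time.
#'
#' @inheritParams spatial_drive
#' @return numeric millisecond neural response.
#' @export
predict_lss <- function(prf, sequence) spatial_drive(prf, sequence)

#' Compressive spatial summation (CSS) prediction
#'
#' The spatial drive raised pointwise to a power-law exponent in
#' [0.01, 1]; exponents < 1 make summation across space subadditive (for
#' four equal overlaps o, `(4 o)^n < 4 o^n`), the source of CSS-predicted
#' simultaneous suppression.
#'
#' @param prf a [spatial_prf()].
#' @param css_n power-law exponent in [0.01, 1].
#' @param sequence a `stim_sequence`.
#' @return numeric millisecond neural response.
#' @export
predict_css <- function(prf, css_n, sequence) {
  if (css_n < 0.01 || css_n > 1) stop("css_n must be in [0.01, 1]")
  spatial_drive(prf, sequence)^css_n
}

# gamma IRF of the spatiotemporal channels, sampled at dt_ms
gamma_irf <- function(t_ms, tau_ms, kappa, n) {
  kt <- kappa * tau_ms
  (t_ms / kt)^(n - 1) * exp(-t_ms / kt) / (kt * factorial(n - 1))
}

#' Temporal impulse responses of the CST channels
#'
#' The sustained IRF is a monophasic gamma (default kappa = 1, n = 9, time
#' constant chosen so the peak `(n - 1) kappa tau` falls at ~39 ms,
#' within the 40--50 ms response window the channel is meant to model).
#' The on-transient IRF is the difference between the sustained gamma and
#' a second gamma (tau = 4.93 ms, kappa = 1.33, n = 10), a biphasic kernel
#' responding at stimulus onset; the off-transient IRF is its negation.
#' Discrete areas are enforced exactly: sustained sums to 1; each
#' transient kernel's positive and negative lobes are balanced so it sums
#' to 0.
#'
#' @param dt_ms sampling step (ms), <= 1.
#' @param tau_s,kappa_s,n_s sustained gamma parameters.
#' @param tau_t,kappa_t,n_t second (transient-forming) gamma parameters.
#' @param tail_mass kernels are truncated where the analytic gamma tail
#'   falls below this mass.
#' @return list with numeric kernels `sustained`, `on_transient`,
#'   `off_transient` and the step `dt_ms`.
#' @export
make_temporal_irfs <- function(dt_ms = 1, tau_s = 4.93, kappa_s = 1,
                               n_s = 9, tau_t = 4.93, kappa_t = 1.33,
                               n_t = 10, tail_mass = 1e-8) {
  if (dt_ms > 1) stop("dt_ms must be <= 1 ms")
  t_max <- max(
    stats::qgamma(1 - tail_mass, shape = n_s, scale = kappa_s * tau_s),
    stats::qgamma(1 - tail_mass, shape = n_t, scale = kappa_t * tau_t)
  )
  t_ms <- seq(0, ceiling(t_max), by = dt_ms)
  g1 <- gamma_irf(t_ms, tau_s, kappa_s, n_s)
  g2 <- gamma_irf(t_ms, tau_t, kappa_t, n_t)
  g1[1] <- 0
  g2[1] <- 0
  sustained <- g1 / sum(g1)
  on_tr <- g1 / sum(g1) - g2 / sum(g2)
  pos <- sum(on_tr[on_tr > 0])
  neg <- -sum(on_tr[on_tr < 0])
  if (neg > 0) on_tr[on_tr < 0] <- on_tr[on_tr < 0] * pos / neg
  structure(
    list(sustained = sustained, on_transient = on_tr,
         off_transient = -on_tr, dt_ms = dt_ms),
    class = "temporal_irfs"
  )
}

#' Compressive spatiotemporal summation (CST) prediction
#'
#' Each of three channels convolves the spatial drive with its IRF
#' (sustained, on-transient, off-transient), half-wave rectifies, and
#' applies a shared compressive power law with exponent `cst_n` in
#' [0.1, 1]. On- and off-transient channels are summed after the
#' nonlinearity; channel weighting (`beta_s`, `beta_t`) is left to the
#' fitting stage.
#'
#' @param prf a [spatial_prf()] (use the effective size
#'   `sigma / sqrt(css_n)` when reconstructing from compressive retinotopy
#'   estimates; see [effective_prf_size()]).
#' @param cst_n exponent in [0.1, 1].
#' @param sequence a `stim_sequence`.
#' @param irfs a [make_temporal_irfs()] kernel set.
#' @param drive optional precomputed spatial drive (ms vector).
#' @return list of numeric millisecond series `sustained` and `transient`.
#' @export
predict_cst <- function(prf, cst_n, sequence, irfs = make_temporal_irfs(),
                        drive = NULL) {
  if (cst_n < 0.1 || cst_n > 1) stop("cst_n must be in [0.1, 1]")
  if (is.null(drive)) drive <- spatial_drive(prf, sequence)
  ch <- cst_channels(drive, irfs)
  list(sustained = ch$sustained^cst_n,
       transient = ch$on^cst_n + ch$off^cst_n)
}

# rectified channel responses before the static nonlinearity; split out so
# the exponent grid-fit can reuse the convolutions
cst_channels <- function(drive, irfs) {
  s <- pmax(conv_causal(drive, irfs$sustained), 0)
  on <- conv_causal(drive, irfs$on_transient)
  list(sustained = s, on = pmax(on, 0), off = pmax(-on, 0))
}

#' Difference-of-Gaussians (DoG) prediction
#'
#' Centre Gaussian minus a concentric surround Gaussian
#' `surround_scale` times larger (per-area scale factors: V1 7.4, V2 6.8,
#' V3 7.3, hV4 5.8). Both Gaussians have unit volume (fully balanced
#' surround), so a stimulus covering the whole field drives the pRF to ~0.
#' Temporal behaviour is linear, like LSS; the drive may be negative.
#'
#' @param prf centre [spatial_prf()].
#' @param surround_scale surround-to-centre size ratio, > 1.
#' @param sequence a `stim_sequence`.
#' @return numeric millisecond neural response (may be negative).
#' @export
predict_dog <- function(prf, surround_scale, sequence) {
  if (surround_scale <= 1) stop("surround_scale must be > 1")
  surround <- spatial_prf(prf$x0, prf$y0, prf$sigma * surround_scale)
  spatial_drive(prf, sequence) - spatial_drive(surround, sequence)
}

#' Per-area DoG surround scale factors
#'
#' @param area one of "V1", "V2", "V3", "hV4".
#' @return surround-to-centre size ratio.
#' @export
dog_surround_scale <- function(area) {
  scales <- c(V1 = 7.4, V2 = 6.8, V3 = 7.3, hV4 = 5.8)
  if (!area %in% names(scales)) {
    stop("no surround scale tabulated for area ", area)
  }
  unname(scales[area])
}

#' Delayed-normalization spatiotemporal (DN-ST) prediction
#'
#' The linear response `r(t)` convolves the spatial drive with a gamma
#' kernel `t exp(-t / tau1)`; the output divides `|r|^n` by
#' `sigma_dn^n + (|r| * exp(-t / tau2))^n`, an exponential-decay low-pass
#' in the denominator that delays normalization. Both kernels are
#' normalized to unit sum so `sigma_dn` is comparable across time
#' constants. 0/0 is defined as 0.
#'
#' @param prf a [spatial_prf()].
#' @param tau1_ms,tau2_ms time constants (ms), positive; voxels with
#'   time constants above 1000 ms are excluded upstream.
#' @param sigma_dn semi-saturation constant, >= 0.
#' @param n_dn exponent, > 0.
#' @param sequence a `stim_sequence`.
#' @param tail_mass kernel truncation threshold.
#' @return numeric millisecond neural response, finite and non-negative.
#' @export
predict_dnst <- function(prf, tau1_ms, tau2_ms, sigma_dn, n_dn, sequence,
                         tail_mass = 1e-8) {
  if (tau1_ms <= 0 || tau2_ms <= 0 || n_dn <= 0 || sigma_dn < 0) {
    stop("DN-ST parameters must be positive (sigma_dn >= 0)")
  }
  drive <- spatial_drive(prf, sequence)
  t1 <- seq(0, ceiling(stats::qgamma(1 - tail_mass, shape = 2,
                                     scale = tau1_ms)))
  irf1 <- t1 * exp(-t1 / tau1_ms)
  irf1 <- irf1 / sum(irf1)
  t2 <- seq(0, ceiling(-tau2_ms * log(tail_mass)))
  irf2 <- exp(-t2 / tau2_ms)
  irf2 <- irf2 / sum(irf2)
  r <- abs(conv_causal(drive, irf1))
  den <- sigma_dn^n_dn + conv_causal(r, irf2)^n_dn
  out <- ifelse(den == 0, 0, r^n_dn / den)
  pmax(out, 0)
}

#' Effective pRF size of a compressive spatial fit
#'
#' `sigma / sqrt(css_n)` approximates the standard deviation a linear
#' (non-compressive) Gaussian model would estimate; LSS, CST, DoG-centre
#' and DN-ST pRFs reconstructed from compressive retinotopy estimates use
#' this size, while the CSS model uses `(sigma, css_n)` as estimated.
#'
#' @param sigma fitted standard deviation (deg).
#' @param css_n fitted compressive exponent.
#' @return effective size (deg).
#' @export
effective_prf_size <- function(sigma, css_n) sigma / sqrt(css_n)
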