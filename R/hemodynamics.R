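# Neural-to-BOLD stage: canonical double-gamma HRF and TR downsampling.

#' Canonical double-gamma HRF kernel
#'
#' SPM-default parameterization: gamma peak at ~5 s (delay 6 s,
#' dispersion 1 s), undershoot delay 16 s, peak:undershoot ratio 6,
#' 32-s support, sampled at `dt_ms` and normalized to unit integral.
#' The kernel is 0 at t = 0, rises to a single positive peak and has a
#' single negative undershoot.
#'
#' @param dt_ms sampling step (ms).
#' @param peak_delay_s,under_delay_s gamma shape parameters (s).
#' @param peak_disp_s,under_disp_s gamma dispersions (s).
#' @param ratio undershoot amplitude relative to the peak (1/6).
#' @param dur_s kernel support (s), >= 32.
#' @return numeric kernel with attribute `dt_ms`.
#' @export
double_gamma_hrf <- function(dt_ms = 1, peak_delay_s = 6, under_delay_s = 16,
                             peak_disp_s = 1, under_disp_s = 1,
                             ratio = 1 / 6, dur_s = 32) {
  if (peak_delay_s <= 0 || under_delay_s <= 0) stop("delays must be > 0")
  if (dur_s < 32) stop("kernel support must be >= 32 s")
  t_s <- seq(0, dur_s, by = dt_ms / 1000)
  h <- stats::dgamma(t_s, shape = peak_delay_s / peak_disp_s,
                     rate = 1 / peak_disp_s) -
    ratio * stats::dgamma(t_s, shape = under_delay_s / under_disp_s,
                          rate = 1 / under_disp_s)
  h <- h / (sum(h) * dt_ms / 1000)
  attr(h, "dt_ms") <- dt_ms
  h
}

#' Convolve a neural time series with the HRF and downsample to TRs
#'
#' Causal convolution at the neural sampling resolution (zero-padded
#' start; runs begin with a blank so the bias is negligible), then box-car
#' averaging within each TR bin (mean-conserving downsampling). Optional
#' max-normalization to 1 matches the scaling applied to predictions
#' before regression.
#'
#' The convolution itself is carried out at `conv_dt_ms` resolution: the
#' neural series is box-integrated into `conv_dt_ms` bins (exact for the
#' piecewise-constant drives produced here) and the kernel is bin-summed,
#' which is a midpoint quadrature of the exact millisecond convolution.
#' The HRF varies on a seconds timescale, so the default 10-ms step keeps
#' the quadrature error below 1e-4 relative; pass `conv_dt_ms = dt_ms`
#' for the exact millisecond path.
#'
#' @param neural numeric neural series (one sample per `dt_ms`).
#' @param hrf kernel from [double_gamma_hrf()] with matching `dt_ms`.
#' @param tr_s TR (s).
#' @param normalize logical; divide by the series maximum.
#' @param dt_ms sampling step of `neural` (ms).
#' @param conv_dt_ms internal convolution step (ms); must divide
#'   `tr_s * 1000` and be a multiple of `dt_ms`.
#' @return numeric vector, one value per TR.
#' @export
neural_to_bold <- function(neural, hrf, tr_s = 1, normalize = FALSE,
                           dt_ms = attr(hrf, "dt_ms"), conv_dt_ms = 10) {
  q <- round(conv_dt_ms / dt_ms)
  if (q < 1L || abs(q * dt_ms - conv_dt_ms) > 1e-9) {
    stop("conv_dt_ms must be a multiple of dt_ms")
  }
  samples_per_tr <- round(tr_s * 1000 / conv_dt_ms)
  if (samples_per_tr < 1L ||
      abs(samples_per_tr * conv_dt_ms - tr_s * 1000) > 1e-9) {
    stop("conv_dt_ms must divide the TR")
  }
  h <- as.numeric(hrf)
  if (q > 1L) {
    pad <- function(x) c(x, numeric((q - length(x) %% q) %% q))
    neural <- colMeans(matrix(pad(neural), nrow = q))
    h <- colSums(matrix(pad(h), nrow = q))
  }
  n_tr <- floor(length(neural) / samples_per_tr)
  if (n_tr < 1L) stop("run shorter than one TR")
  conv <- conv_causal(neural, h)
  conv <- conv[seq_len(n_tr * samples_per_tr)]
  bold <- colMeans(matrix(conv, nrow = samples_per_tr))
  if (normalize) {
    m <- max(abs(bold))
    if (m > 0) bold <- bold / m
  }
  bold
}
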