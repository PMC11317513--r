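# Forward prediction: pRF model -> millisecond neural response ->
# HRF convolution -> TR-resolution regressors, per run, concatenated.

#' Predict TR-resolution BOLD regressors for one voxel
#'
#' Runs the full forward chain for the chosen encoding model over a list
#' of stimulus runs and concatenates the per-run BOLD predictions. The
#' CST model returns two regressor columns (sustained, combined
#' transient); all other models return one.
#'
#' @param model one of `"lss"`, `"css"`, `"cst"`, `"dog"`, `"dnst"`.
#' @param params named list of voxel parameters: `x0`, `y0`, `sigma`,
#'   plus `css_n` (css), `cst_n` (cst), `surround_scale` (dog), and
#'   `tau1_ms`, `tau2_ms`, `sigma_dn`, `n_dn` (dnst). For all models
#'   except CSS, `sigma` should already be the effective size.
#' @param sequences list of `stim_sequence` runs.
#' @param hrf kernel from [double_gamma_hrf()].
#' @param tr_s TR (s).
#' @param irfs CST temporal kernels, defaults to [make_temporal_irfs()].
#' @return numeric matrix (total TRs x regressors), column names
#'   `"pred"` or `c("sustained", "transient")`.
#' @export
predict_model_regressors <- function(model, params, sequences, hrf,
                                     tr_s = 1, irfs = NULL) {
  model <- match.arg(model, c("lss", "css", "cst", "dog", "dnst"))
  prf <- spatial_prf(params$x0, params$y0, params$sigma)
  if (model == "cst" && is.null(irfs)) irfs <- make_temporal_irfs()
  per_run <- lapply(sequences, function(seqn) {
    neural <- switch(
      model,
      lss = predict_lss(prf, seqn),
      css = predict_css(prf, params$css_n, seqn),
      dog = predict_dog(prf, params$surround_scale, seqn),
      dnst = predict_dnst(prf, params$tau1_ms, params$tau2_ms,
                          params$sigma_dn, params$n_dn, seqn),
      cst = predict_cst(prf, params$cst_n, seqn, irfs)
    )
    if (model == "cst") {
      cbind(sustained = neural_to_bold(neural$sustained, hrf, tr_s),
            transient = neural_to_bold(neural$transient, hrf, tr_s))
    } else {
      cbind(pred = neural_to_bold(neural, hrf, tr_s))
    }
  })
  do.call(rbind, per_run)
}

#' Max-normalize prediction regressors
#'
#' Scales each regressor column of a concatenated prediction so its
#' maximum height is 1 (the scaling applied before regression; the fitted
#' beta weights absorb it).
#'
#' @param x numeric matrix or vector.
#' @return same shape, each column divided by its maximum absolute value.
#' @export
normalize_max <- function(x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    m <- max(abs(x[, j]))
    if (m > 0) x[, j] <- x[, j] / m
  }
  x
}
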