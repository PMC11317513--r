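# Synthetic voxel populations: ground-truth parameter sampling and
# forward simulation of noisy percent-signal-change datasets with a
# target split-half reliability.

#' Area profile for synthetic voxel populations
#'
#' Describes the parameter distributions of a simulated visual-area
#' population: pRF centres uniform within (a sub-box of) the quadrant
#' stimulus box, effective sizes and exponents uniform within ranges.
#' Typical profiles range from a V1-like area (effective size ~1 deg,
#' near-linear exponents) to a TO-like area (~7.8 deg, strong
#' compression).
#'
#' @param area label.
#' @param n_voxels voxels to draw.
#' @param model generating encoding model: `"lss"`, `"css"`, `"cst"`,
#'   `"dog"`, or `"dnst"`.
#' @param sigma_range effective pRF size range (deg).
#' @param exponent_range compressive exponent range (css_n or cst_n).
#' @param beta_s_range,beta_t_range CST channel weight ranges.
#' @param amp_range response amplitude range (percent signal change of
#'   the peak prediction).
#' @param center_box `c(x_min, x_max, y_min, y_max)` sampling box for pRF
#'   centres in the upper-right frame (deg); mirrored for lower_left.
#' @param quadrant `"upper_right"` or `"lower_left"`.
#' @param target_reliability expected split-half reliability of the
#'   simulated data, in (0, 1]; 1 means noiseless.
#' @param surround_scale DoG surround ratio (dog model only).
#' @param dnst DN-ST parameter list (`tau1_ms`, `tau2_ms`, `sigma_dn`,
#'   `n_dn`) (dnst model only).
#' @return object of class `area_profile`.
#' @export
area_profile <- function(area = "V1like", n_voxels = 50, model = "lss",
                         sigma_range = c(0.5, 1),
                         exponent_range = c(1, 1),
                         beta_s_range = c(0.8, 1.2),
                         beta_t_range = c(0.8, 1.2),
                         amp_range = c(1, 2),
                         center_box = c(0.59, 9.41, 0.59, 9.41),
                         quadrant = "upper_right",
                         target_reliability = 0.8,
                         surround_scale = 7.4,
                         dnst = list(tau1_ms = 70, tau2_ms = 100,
                                     sigma_dn = 0.05, n_dn = 2)) {
  model <- match.arg(model, c("lss", "css", "cst", "dog", "dnst"))
  if (target_reliability <= 0 || target_reliability > 1) {
    stop("target_reliability must be in (0, 1]")
  }
  if (center_box[2] < center_box[1] || center_box[4] < center_box[3]) {
    stop("empty centre box")
  }
  structure(
    list(area = area, n_voxels = as.integer(n_voxels), model = model,
         sigma_range = sigma_range, exponent_range = exponent_range,
         beta_s_range = beta_s_range, beta_t_range = beta_t_range,
         amp_range = amp_range, center_box = center_box,
         quadrant = quadrant, target_reliability = target_reliability,
         surround_scale = surround_scale, dnst = dnst),
    class = "area_profile"
  )
}

#' Sample a ground-truth voxel population
#'
#' Draws `n_voxels` parameter records from an [area_profile()];
#' reproducible given the seed, and every sampled centre passes the
#' geometric voxel-selection filter by construction.
#'
#' @param profile an [area_profile()].
#' @param seed integer seed.
#' @return data.frame of ground-truth records (one row per voxel) with
#'   attribute `profile`.
#' @export
sample_population <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "area_profile"))
  sgn <- if (profile$quadrant == "lower_left") -1 else 1
  rec <- with_seed(derive_seed(seed, 404L), {
    n <- profile$n_voxels
    runif2 <- function(r) stats::runif(n, r[1], r[2])
    data.frame(
      voxel = seq_len(n), area = profile$area, model = profile$model,
      x0 = sgn * runif2(profile$center_box[1:2]),
      y0 = sgn * runif2(profile$center_box[3:4]),
      sigma = runif2(profile$sigma_range),
      exponent = runif2(profile$exponent_range),
      beta_s = runif2(profile$beta_s_range),
      beta_t = runif2(profile$beta_t_range),
      amp = runif2(profile$amp_range)
    )
  })
  attr(rec, "profile") <- profile
  rec
}

# noiseless signal (TR resolution, concatenated runs) for one record
record_signal <- function(record, sequences, hrf, tr_s = 1, irfs = NULL) {
  params <- list(x0 = record$x0, y0 = record$y0, sigma = record$sigma,
                 css_n = record$exponent, cst_n = record$exponent,
                 surround_scale = record$surround_scale %||%
                   attr(record, "surround_scale") %||% 7.4)
  profile <- attr(record, "profile")
  if (record$model == "dog" && !is.null(profile)) {
    params$surround_scale <- profile$surround_scale
  }
  if (record$model == "dnst") {
    dn <- if (is.null(profile)) {
      list(tau1_ms = 70, tau2_ms = 100, sigma_dn = 0.05, n_dn = 2)
    } else {
      profile$dnst
    }
    params <- c(params, dn)
  }
  reg <- predict_model_regressors(record$model, params, sequences, hrf,
                                  tr_s, irfs)
  reg <- normalize_max(reg)
  if (record$model == "cst") {
    record$amp * drop(reg %*% c(record$beta_s, record$beta_t)) /
      (record$beta_s + record$beta_t)
  } else {
    record$amp * drop(reg)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a noisy voxel dataset from ground-truth records
#'
#' For each voxel: the noiseless BOLD prediction of its generating model
#' over the concatenated unique runs (percent-signal-change scale), which
#' is repeated `n_repeats` times with independent Gaussian noise per TR.
#' The noise SD is calibrated in closed form so the expected split-half
#' reliability (squared correlation between half means, each half
#' averaging `n_repeats / 2` repeats) matches the profile's target: the
#' expected between-half correlation is `S / (S + sigma2 / r)` with `S`
#' the signal variance and `r` repeats per half, so
#' `sigma2 = r S (1 - sqrt(rho)) / sqrt(rho)`.
#'
#' @param records data.frame from [sample_population()].
#' @param sequences list of `stim_sequence` runs (the unique run pair).
#' @param hrf HRF kernel.
#' @param n_repeats repeats of the concatenated pair (even, >= 2).
#' @param seed integer seed for the noise.
#' @param tr_s TR (s).
#' @param irfs CST kernels (built once when needed).
#' @return object of class `voxel_dataset`: list with `data` (array TRs x
#'   repeats x voxels), `signal` (TRs x voxels), `records`, `noise_sd`
#'   (per voxel), `n_repeats`, `tr_s`, `seed`.
#' @export
simulate_dataset <- function(records, sequences, hrf, n_repeats = 2L,
                             seed = 1L, tr_s = 1, irfs = NULL) {
  stopifnot(n_repeats >= 2L, n_repeats %% 2L == 0L)
  profile <- attr(records, "profile")
  rho <- if (is.null(profile)) 1 else profile$target_reliability
  if (is.null(irfs) && any(records$model == "cst")) {
    irfs <- make_temporal_irfs()
  }
  sig <- vapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    attr(rec, "profile") <- profile
    record_signal(rec, sequences, hrf, tr_s, irfs)
  }, numeric(sum(vapply(sequences, function(s) s$duration_ms, numeric(1)) /
                   (tr_s * 1000))))
  n_tr <- nrow(sig)
  r_half <- n_repeats / 2
  noise_sd <- vapply(seq_len(ncol(sig)), function(i) {
    s_var <- stats::var(sig[, i])
    if (rho >= 1) 0 else {
      sqrt(r_half * s_var * (1 - sqrt(rho)) / sqrt(rho))
    }
  }, numeric(1))
  data <- with_seed(derive_seed(seed, 505L), {
    arr <- array(0, dim = c(n_tr, n_repeats, ncol(sig)))
    for (v in seq_len(ncol(sig))) {
      for (r in seq_len(n_repeats)) {
        arr[, r, v] <- sig[, v] + stats::rnorm(n_tr, 0, noise_sd[v])
      }
    }
    arr
  })
  structure(
    list(data = data, signal = sig, records = records,
         noise_sd = noise_sd, n_repeats = n_repeats, tr_s = tr_s,
         seed = seed),
    class = "voxel_dataset"
  )
}

#' Simulate a multi-participant dataset
#'
#' Draws an independent population per participant from a shared profile,
#' with a participant-level perturbation of the compressive exponent
#' (truncated normal around each voxel's draw) so that the suppression
#' LMM's random slopes are exercised.
#'
#' @param profile an [area_profile()].
#' @param n_participants number of participants.
#' @param sequences list of `stim_sequence` runs.
#' @param hrf HRF kernel.
#' @param seed integer seed.
#' @param exponent_participant_sd SD of the participant-level exponent
#'   shift.
#' @param ... passed to [simulate_dataset()].
#' @return named list of `voxel_dataset`s, one per participant
#'   (`"S1"`, `"S2"`, ...).
#' @export
simulate_participants <- function(profile, n_participants, sequences, hrf,
                                  seed = 1L, exponent_participant_sd = 0,
                                  ...) {
  stats::setNames(lapply(seq_len(n_participants), function(p) {
    rec <- sample_population(profile, seed = derive_seed(seed, p))
    if (exponent_participant_sd > 0) {
      shift <- with_seed(derive_seed(seed, 606L, p),
                         stats::rnorm(1, 0, exponent_participant_sd))
      lo <- max(min(profile$exponent_range), 0.1)
      rec$exponent <- pmin(pmax(rec$exponent + shift, lo), 1)
      attr(rec, "profile") <- profile
    }
    simulate_dataset(rec, sequences, hrf, seed = derive_seed(seed, 707L, p),
                     ...)
  }), paste0("S", seq_len(n_participants)))
}
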