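# End-to-end orchestration and file formats. The canonical interchange
# formats are long-format TSV tables plus JSON manifests; every stage
# communicates only through documented structures.

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic run:
#' stimulus design, population profile, participants, models to fit, and
#' seeds. All randomness derives from `seed`.
#'
#' @param seed master integer seed.
#' @param profile an [area_profile()].
#' @param n_participants participants to simulate.
#' @param n_repeats repeats of the unique run pair per participant (even).
#' @param fit_models character subset of
#'   `c("lss", "css", "cst", "dog", "dnst")` to fit per voxel (may be
#'   empty: the suppression analysis runs on the simulated data alone).
#' @param onset_matched passed to [seqsim_design()].
#' @param exponent_participant_sd participant-level exponent SD.
#' @param apply_filters logical; apply [select_voxels()] before the
#'   suppression stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, profile = area_profile(),
                            n_participants = 3L, n_repeats = 2L,
                            fit_models = character(0),
                            onset_matched = FALSE,
                            exponent_participant_sd = 0,
                            apply_filters = TRUE) {
  stopifnot(inherits(profile, "area_profile"),
            n_participants >= 1L, n_repeats %% 2L == 0L)
  if (length(fit_models)) {
    fit_models <- match.arg(fit_models,
                            c("lss", "css", "cst", "dog", "dnst"),
                            several.ok = TRUE)
  }
  structure(
    list(seed = as.integer(seed), profile = profile,
         n_participants = as.integer(n_participants),
         n_repeats = as.integer(n_repeats),
         fit_models = if (length(fit_models)) fit_models else character(0),
         onset_matched = isTRUE(onset_matched),
         exponent_participant_sd = exponent_participant_sd,
         apply_filters = isTRUE(apply_filters)),
    class = "pipeline_config"
  )
}

# split a repeats array into averaged odd/even halves
split_halves <- function(mat) {
  list(odd = rowMeans(mat[, seq(1, ncol(mat), by = 2), drop = FALSE]),
       even = rowMeans(mat[, seq(2, ncol(mat), by = 2), drop = FALSE]))
}

#' Run the full synthetic pipeline
#'
#' Stimulus generation, population simulation, optional per-voxel model
#' fitting (split-half cross-validated), voxel selection, block-window
#' segmentation, condition amplitudes, and the suppression LMM. All eight
#' conditions are predicted jointly per voxel from the concatenated
#' two-run stimulus.
#'
#' @param config a [pipeline_config()].
#' @return object of class `results_bundle`: list with `schedules`,
#'   `datasets`, `fits` (long data.frame, one row per voxel x model),
#'   `voxels` (per-voxel metadata incl. selection flags),
#'   `amplitudes`, `window_start`, `suppression_table`, `lmm`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- seqsim_design(seed = config$seed,
                          onset_matched = config$onset_matched)
  runs <- lapply(1:2, function(r) generate_seqsim_run(design, r))
  sequences <- lapply(runs, `[[`, "sequence")
  schedules <- lapply(runs, `[[`, "schedule")
  hrf <- double_gamma_hrf()
  run_len_tr <- sequences[[1]]$duration_ms / 1000 / design$tr_s
  datasets <- simulate_participants(
    config$profile, config$n_participants, sequences, hrf,
    seed = config$seed,
    exponent_participant_sd = config$exponent_participant_sd,
    n_repeats = config$n_repeats
  )
  irfs <- if ("cst" %in% c(config$fit_models, config$profile$model)) {
    make_temporal_irfs()
  }
  voxels <- NULL
  fits <- NULL
  tables <- NULL
  amplitudes <- list()
  window_start <- list()
  for (p in names(datasets)) {
    ds <- datasets[[p]]
    rec <- ds$records
    n_vox <- dim(ds$data)[3]
    rel <- vapply(seq_len(n_vox), function(v) {
      if (ds$n_repeats < 2L) 100 else split_half_reliability(ds$data[, , v])
    }, numeric(1))
    vmeta <- data.frame(participant = p, rec,
                        reliability = rel,
                        ret_r2 = 100)  # synthetic truth: known parameters
    if (config$apply_filters) {
      vmeta <- select_voxels(vmeta)
    } else {
      vmeta$keep <- TRUE
      vmeta$exclusion_reason <- ""
    }
    voxels <- rbind(voxels, vmeta)
    keep_idx <- which(vmeta$keep)
    for (m in config$fit_models) {
      for (v in keep_idx) {
        halves <- split_halves(ds$data[, , v])
        fit <- if (m == "cst") {
          g <- gridfit_cst_exponent(
            list(x0 = rec$x0[v], y0 = rec$y0[v], sigma = rec$sigma[v]),
            sequences, list(halves$odd, halves$even), hrf,
            tr_s = design$tr_s, irfs = irfs
          )
          c(g$fit, list(best_cst_n = g$best_cst_n))
        } else {
          params <- list(x0 = rec$x0[v], y0 = rec$y0[v],
                         sigma = rec$sigma[v], css_n = rec$exponent[v],
                         surround_scale = config$profile$surround_scale)
          params <- c(params, config$profile$dnst)
          reg <- normalize_max(predict_model_regressors(
            m, params, sequences, hrf, design$tr_s, irfs))
          crossval_fit(reg, list(halves$odd, halves$even))
        }
        fits <- rbind(fits, data.frame(
          participant = p, voxel = rec$voxel[v], model = m,
          cv_r2 = fit$cv_r2, adj_cv_r2 = fit$adj_cv_r2,
          noise_ceiling = rel[v],
          best_cst_n = if (m == "cst") fit$best_cst_n else NA_real_
        ))
      }
    }
    if (length(keep_idx) == 0L) {
      message("participant ", p, ": no voxels pass filters; skipped")
      next
    }
    wins <- lapply(keep_idx, function(v) {
      avg <- rowMeans(ds$data[, , v])
      seg <- segment_blocks(avg, schedules, run_len_tr, tr_s = design$tr_s)
      average_condition_windows(seg)$mean
    })
    ca <- condition_amplitudes(wins)
    amplitudes[[p]] <- ca$amplitudes
    window_start[[p]] <- ca$window_start
    tables <- rbind(tables,
                    build_suppression_table(ca$amplitudes, participant = p,
                                            area = config$profile$area))
  }
  lmm <- if (!is.null(tables) &&
             length(unique(tables$participant)) >= 2L) {
    fit_suppression_lmm(tables)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("seqsimprf")),
    seed = config$seed,
    n_participants = config$n_participants,
    n_repeats = config$n_repeats,
    profile = unclass(config$profile),
    fit_models = config$fit_models,
    onset_matched = config$onset_matched
  )
  structure(
    list(schedules = schedules, datasets = datasets, fits = fits,
         voxels = voxels, amplitudes = amplitudes,
         window_start = window_start, suppression_table = tables,
         lmm = lmm, manifest = manifest),
    class = "results_bundle"
  )
}

#' Write a voxel dataset as long-format TSV
#'
#' Columns: participant, voxel, repeat, tr, value. Values round-trip at
#' full double precision.
#'
#' @param dataset a `voxel_dataset`.
#' @param path output file.
#' @param participant participant id recorded in the table.
#' @return invisibly, `path`.
#' @export
write_voxel_table <- function(dataset, path, participant = "S1") {
  d <- dataset$data
  long <- expand.grid(tr = seq_len(dim(d)[1]), rep = seq_len(dim(d)[2]),
                      voxel = seq_len(dim(d)[3]))
  long$value <- as.vector(d)
  out <- data.frame(participant = participant, voxel = long$voxel,
                    rep = long$rep, tr = long$tr,
                    value = sprintf("%.17g", long$value))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format voxel table
#'
#' @param path TSV with columns participant, voxel, rep, tr, value.
#' @return list per participant of arrays (TRs x repeats x voxels).
#' @export
read_voxel_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("participant", "voxel", "rep", "tr", "value")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("voxel table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tab$value))) {
    stop("non-finite values at line(s) ",
         paste(utils::head(which(!is.finite(tab$value)) + 1L, 5),
               collapse = ", "))
  }
  lapply(split(tab, tab$participant), function(g) {
    n_tr <- max(g$tr)
    n_rep <- max(g$rep)
    n_vox <- max(g$voxel)
    arr <- array(NA_real_, dim = c(n_tr, n_rep, n_vox))
    arr[cbind(g$tr, g$rep, g$voxel)] <- g$value
    arr
  })
}

#' Write a results bundle to disk
#'
#' Exports the fit table, voxel metadata, suppression table, LMM summary
#' (TSV + JSON) and a JSON manifest with MD5 checksums of every written
#' file, sufficient to verify reproduction.
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$fits)) wt(bundle$fits, "fits.tsv")
  if (!is.null(bundle$voxels)) wt(bundle$voxels, "voxels.tsv")
  if (!is.null(bundle$suppression_table)) {
    wt(bundle$suppression_table, "suppression_table.tsv")
  }
  if (!is.null(bundle$lmm)) {
    lm_tab <- data.frame(
      condition = names(bundle$lmm$slopes),
      slope = bundle$lmm$slopes, se = bundle$lmm$slope_se,
      ci_lower = bundle$lmm$slope_ci95["lower", ],
      ci_upper = bundle$lmm$slope_ci95["upper", ],
      intercept = bundle$lmm$intercepts
    )
    wt(lm_tab, "lmm_slopes.tsv")
    jsonlite::write_json(
      list(slopes = as.list(bundle$lmm$slopes),
           r2 = bundle$lmm$r2, loglik = bundle$lmm$loglik,
           aic = bundle$lmm$aic, bic = bundle$lmm$bic,
           df = bundle$lmm$df, random = bundle$lmm$random),
      file.path(dir, "lmm.json"), auto_unbox = TRUE, digits = NA
    )
    paths <- c(paths, file.path(dir, "lmm.json"))
  }
  manifest <- c(bundle$manifest,
                list(files = as.list(stats::setNames(
                  unname(tools::md5sum(paths)), basename(paths)))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}
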