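# Suppression quantification: block-window segmentation, condition
# amplitudes with the 10%-cumulative-sum start rule, the SIM-on-SEQ
# linear mixed model, LMM variant comparison, and bootstrap summaries.

#' Segment a run series into per-block 23-TR windows
#'
#' Each window spans -4 s to +18 s around its block onset (4 s pre-onset
#' baseline, 8-s stimulus block, 11 s post-block) sampled at TR = 1 s,
#' i.e. 23 samples; sample w corresponds to t = w - 5 seconds relative to
#' onset.
#'
#' @param series numeric TR-resolution series of one concatenated
#'   presentation (e.g. the average across split halves of the two-run
#'   concatenation).
#' @param schedules list of block schedules, one per run in `series`
#'   order (from [generate_seqsim_run()]).
#' @param run_len_tr TRs per run.
#' @param pre_s,post_s window extent before block onset and after block
#'   offset (s).
#' @param tr_s TR (s).
#' @return list with `windows` (23 x blocks matrix) and `blocks`
#'   (data.frame with cond_id and label per window column).
#' @export
segment_blocks <- function(series, schedules, run_len_tr,
                           pre_s = 4, post_s = 11, tr_s = 1) {
  stopifnot(tr_s == 1)
  n_win <- pre_s + 8 + post_s
  all_blocks <- do.call(rbind, lapply(seq_along(schedules), function(r) {
    sc <- schedules[[r]]
    sc$onset_tr <- sc$onset_s + (r - 1L) * run_len_tr
    sc
  }))
  win <- matrix(NA_real_, n_win, nrow(all_blocks))
  for (b in seq_len(nrow(all_blocks))) {
    idx <- (all_blocks$onset_tr[b] - pre_s + 1):(all_blocks$onset_tr[b] +
                                                   8 + post_s)
    if (any(idx < 1) || any(idx > length(series))) {
      stop("block window exceeds the run bounds")
    }
    win[, b] <- series[idx]
  }
  list(windows = win, blocks = all_blocks)
}

#' Average block windows by condition
#'
#' @param seg result of [segment_blocks()].
#' @return list with `mean` (23 x conditions matrix, columns named by
#'   condition label) and `sem` (same shape) across the repeats of each
#'   condition.
#' @export
average_condition_windows <- function(seg) {
  labs <- sort(unique(seg$blocks$label))
  m <- sapply(labs, function(l) {
    rowMeans(seg$windows[, seg$blocks$label == l, drop = FALSE])
  })
  s <- sapply(labs, function(l) {
    w <- seg$windows[, seg$blocks$label == l, drop = FALSE]
    apply(w, 1, stats::sd) / sqrt(ncol(w))
  })
  list(mean = m, sem = s)
}

#' Peak-window start from the 10%-cumulative-sum rule
#'
#' Given a grand-mean 23-TR window (averaged across voxels of an area for
#' one condition), re-baselines to the mean of the 4 pre-onset TRs, clips
#' at zero, and finds the first TR after block onset at which the
#' cumulative sum exceeds 10 percent of its total; the start is mapped to
#' the nearer of 4 s or 5 s. Degenerate (non-positive) grand means
#' default to 4 s with a warning.
#'
#' @param grand_mean numeric length-23 window.
#' @return 4 or 5 (seconds after block onset).
#' @export
peak_window_start <- function(grand_mean) {
  stopifnot(length(grand_mean) == 23L)
  base <- mean(grand_mean[1:4])
  post <- pmax(grand_mean[6:23] - base, 0)  # t = 1..18 s
  tot <- sum(post)
  if (tot <= 0) {
    warning("non-positive grand mean; defaulting to a 4-s start")
    return(4)
  }
  t_cross <- which(cumsum(post) > 0.1 * tot)[1]
  if (t_cross <= 4) 4 else 5
}

#' Summarize windows into per-condition amplitudes
#'
#' For each condition, the area-level grand-mean window determines the
#' 9-TR averaging window (4--12 s or 5--13 s after block onset via
#' [peak_window_start()]); each voxel's amplitude is the mean of its own
#' averaged window over those 9 TRs. One value per voxel and condition.
#'
#' @param windows_by_voxel list (one element per voxel) of 23 x 8
#'   condition-mean window matrices with condition-label column names, as
#'   produced by [average_condition_windows()].
#' @return list with `amplitudes` (voxels x conditions matrix) and
#'   `window_start` (named vector of 4/5 per condition).
#' @export
condition_amplitudes <- function(windows_by_voxel) {
  labs <- colnames(windows_by_voxel[[1]])
  grand <- Reduce(`+`, windows_by_voxel) / length(windows_by_voxel)
  starts <- vapply(labs, function(l) peak_window_start(grand[, l]),
                   numeric(1))
  amp <- t(vapply(windows_by_voxel, function(w) {
    vapply(labs, function(l) {
      idx <- (starts[l] + 5):(starts[l] + 13)  # 9 samples, t = start..start+8
      mean(w[idx, l])
    }, numeric(1))
  }, numeric(length(labs))))
  colnames(amp) <- labs
  list(amplitudes = amp, window_start = starts)
}

#' Assemble the SEQ/SIM suppression table
#'
#' Pairs the sequential and simultaneous amplitude of each voxel within
#' each size-by-timing condition pair.
#'
#' @param amplitudes voxels x 8 matrix with `seq_*`/`sim_*` condition
#'   labels as column names.
#' @param participant participant id (recycled).
#' @param area visual-area label (recycled).
#' @return data.frame with columns participant, area, voxel, condition,
#'   seq_ampl, sim_ampl.
#' @export
build_suppression_table <- function(amplitudes, participant = "S1",
                                    area = "synthetic") {
  labs <- colnames(amplitudes)
  pair_labs <- sort(unique(sub("^(seq|sim)_", "", labs)))
  out <- do.call(rbind, lapply(pair_labs, function(p) {
    data.frame(
      participant = participant, area = area,
      voxel = seq_len(nrow(amplitudes)), condition = p,
      seq_ampl = amplitudes[, paste0("seq_", p)],
      sim_ampl = amplitudes[, paste0("sim_", p)]
    )
  }))
  rownames(out) <- NULL
  out
}

# cell-means design columns: per-condition intercept and slope dummies
lmm_design <- function(table) {
  table$condition <- factor(table$condition)
  table$participant <- factor(table$participant)
  conds <- levels(table$condition)
  for (j in seq_along(conds)) {
    table[[paste0("c", j)]] <- as.numeric(table$condition == conds[j])
    table[[paste0("s", j)]] <- table[[paste0("c", j)]] * table$seq_ampl
  }
  attr(table, "conds") <- conds
  table
}

#' Fit the simultaneous-suppression linear mixed model
#'
#' Models each voxel's simultaneous amplitude as a linear function of its
#' sequential amplitude with a fixed intercept and slope per condition
#' and a random intercept and slope per condition within participant
#' (maximum likelihood). The fixed slope per condition is the suppression
#' level: 1 means no suppression, smaller means stronger suppression.
#' Uses cell-means coding so per-condition slopes are reported directly.
#' Singular or failed full-covariance fits are refitted with a diagonal
#' random-effects covariance and flagged.
#'
#' @param table data.frame from [build_suppression_table()] (columns
#'   participant, condition, seq_ampl, sim_ampl).
#' @param random `"full"` (default, 8x8 random-effect covariance),
#'   `"diagonal"`, or `"none"` (plain fixed-effects OLS, for degenerate
#'   inputs).
#' @return object of class `suppression_lmm`: list with `slopes`,
#'   `intercepts`, `slope_se`, `slope_ci95` (2 x conditions), per-
#'   participant `participant_slopes` (fixed + random effect),
#'   `r2`, `loglik`, `aic`, `bic`, `df`, `singular`, `random`, `model`.
#' @export
fit_suppression_lmm <- function(table, random = c("full", "diagonal",
                                                  "none")) {
  random <- match.arg(random)
  if (length(unique(table$participant)) < 2L && random != "none") {
    stop("need >= 2 participants for random effects")
  }
  d <- lmm_design(table)
  conds <- attr(d, "conds")
  k <- length(conds)
  cn <- paste0("c", seq_len(k))
  sn <- paste0("s", seq_len(k))
  fixed <- paste(c(cn, sn), collapse = " + ")
  re_full <- sprintf("(0 + %s | participant)", fixed)
  re_diag <- paste(sprintf("(0 + %s | participant)", c(cn, sn)),
                   collapse = " + ")
  fit_one <- function(re) {
    f <- stats::as.formula(paste("sim_ampl ~ 0 +", fixed, "+", re))
    lme4::lmer(f, data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  }
  singular <- FALSE
  if (random == "none") {
    mod <- stats::lm(stats::as.formula(paste("sim_ampl ~ 0 +", fixed)),
                     data = d)
  } else if (random == "diagonal") {
    mod <- fit_one(re_diag)
  } else {
    mod <- tryCatch(fit_one(re_full), error = function(e) NULL)
    if (is.null(mod) || lme4::isSingular(mod, tol = 1e-4)) {
      singular <- TRUE
      mod2 <- tryCatch(fit_one(re_diag), error = function(e) NULL)
      if (!is.null(mod2)) {
        random <- "diagonal"
        mod <- mod2
      }
    }
    if (is.null(mod)) stop("LMM failed to fit")
  }
  fe <- if (inherits(mod, "merMod")) lme4::fixef(mod) else stats::coef(mod)
  vc <- as.matrix(stats::vcov(mod))
  se <- sqrt(diag(vc))
  slopes <- stats::setNames(fe[sn], conds)
  slope_se <- stats::setNames(se[sn], conds)
  # t-based CI95: with a handful of participants the Wald z interval is
  # anti-conservative; the slope's effective df is participants - 1
  ci_df <- if (inherits(mod, "merMod")) {
    max(length(unique(d$participant)) - 1L, 1L)
  } else {
    stats::df.residual(mod)
  }
  tcrit <- stats::qt(0.975, ci_df)
  ci <- rbind(lower = slopes - tcrit * slope_se,
              upper = slopes + tcrit * slope_se)
  part_slopes <- NULL
  if (inherits(mod, "merMod")) {
    # a diagonal fit has one ranef block per term, all grouped by
    # participant; bind them back into one matrix
    re <- do.call(cbind, unname(lme4::ranef(mod)))
    got <- intersect(sn, colnames(re))
    if (length(got)) {
      part_slopes <- sweep(as.matrix(re[, got, drop = FALSE]), 2, -fe[got])
      colnames(part_slopes) <- conds[match(got, sn)]
    }
  }
  ll <- stats::logLik(mod)
  structure(
    list(slopes = slopes, intercepts = stats::setNames(fe[cn], conds),
         slope_se = slope_se, slope_ci95 = ci,
         participant_slopes = part_slopes,
         r2 = 100 * stats::cor(stats::fitted(mod), d$sim_ampl)^2,
         loglik = as.numeric(ll), aic = stats::AIC(mod),
         bic = stats::BIC(mod), df = attr(ll, "df"),
         singular = singular, random = random, model = mod),
    class = "suppression_lmm"
  )
}

#' @export
print.suppression_lmm <- function(x, ...) {
  cat("Simultaneous-suppression LMM (", x$random, " random effects)\n",
      sep = "")
  tab <- data.frame(slope = x$slopes, se = x$slope_se,
                    ci_lo = x$slope_ci95["lower", ],
                    ci_hi = x$slope_ci95["upper", ])
  print(round(tab, 3))
  cat(sprintf("R2 = %.1f%%  logLik = %.1f  AIC = %.1f  BIC = %.1f  df = %d\n",
              x$r2, x$loglik, x$aic, x$bic, x$df))
  invisible(x)
}

#' Compare the main LMM against its three simpler variants
#'
#' Variants: (main) fixed and random per-condition intercepts and slopes;
#' (i) a single fixed slope with one random intercept per participant;
#' (ii) fixed per-condition effects with a single random intercept per
#' participant; (iii) fixed per-condition effects with a random
#' per-condition intercept per participant. Degrees of freedom in this
#' parameterization are 45, 4, 10, and 19.
#'
#' @param table data.frame from [build_suppression_table()].
#' @return data.frame with model, df, logLik, AIC, BIC, converged.
#' @export
compare_lmm_variants <- function(table) {
  d <- lmm_design(table)
  conds <- attr(d, "conds")
  k <- length(conds)
  cn <- paste0("c", seq_len(k))
  sn <- paste0("s", seq_len(k))
  fixed <- paste(c(cn, sn), collapse = " + ")
  forms <- list(
    main = paste("sim_ampl ~ 0 +", fixed,
                 sprintf("+ (0 + %s | participant)", fixed)),
    no_interaction = "sim_ampl ~ 1 + seq_ampl + (1 | participant)",
    single_intercept = paste("sim_ampl ~ 0 +", fixed, "+ (1 | participant)"),
    cond_intercepts = paste("sim_ampl ~ 0 +", fixed,
                            sprintf("+ (0 + %s | participant)",
                                    paste(cn, collapse = " + ")))
  )
  rows <- lapply(names(forms), function(nm) {
    mod <- tryCatch(
      lme4::lmer(stats::as.formula(forms[[nm]]), data = d, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL
    )
    if (is.null(mod)) {
      return(data.frame(model = nm, df = NA, loglik = NA, aic = NA,
                        bic = NA, converged = FALSE))
    }
    ll <- stats::logLik(mod)
    data.frame(model = nm, df = attr(ll, "df"), loglik = as.numeric(ll),
               aic = stats::AIC(mod), bic = stats::BIC(mod),
               converged = TRUE)
  })
  do.call(rbind, rows)
}

#' Bootstrap summary of pRF parameters within participant and area
#'
#' Resamples values with replacement `n_boot` times within each
#' participant-area cell, takes the chosen statistic of each resample
#' (median for sizes, exponents, and time constants; mean for channel
#' beta weights), and reports the per-cell mean resampled statistic plus
#' the across-participant group mean and SEM per area.
#'
#' @param values data.frame with columns participant, area, value.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param statistic `"median"` or `"mean"`.
#' @param seed integer seed.
#' @return list with `per_participant` and `group` data.frames.
#' @export
bootstrap_param_summary <- function(values, n_boot = 1000,
                                    statistic = c("median", "mean"),
                                    seed = 1L) {
  statistic <- match.arg(statistic)
  stat_fun <- match.fun(statistic)
  cells <- unique(values[, c("participant", "area")])
  if (nrow(cells) == 0L) stop("empty group")
  per <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- values$value[values$participant == cells$participant[i] &
                        values$area == cells$area[i]]
    boots <- with_seed(derive_seed(seed, 303L, i), {
      vapply(seq_len(n_boot),
             function(b) stat_fun(sample(v, length(v), replace = TRUE)),
             numeric(1))
    })
    data.frame(participant = cells$participant[i], area = cells$area[i],
               estimate = mean(boots), boot_sd = stats::sd(boots))
  }))
  grp <- do.call(rbind, lapply(split(per, per$area), function(g) {
    data.frame(area = g$area[1], mean = mean(g$estimate),
               sem = stats::sd(g$estimate) / sqrt(nrow(g)),
               n_participants = nrow(g))
  }))
  rownames(grp) <- NULL
  list(per_participant = per, group = grp)
}
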