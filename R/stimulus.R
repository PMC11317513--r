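# SEQ-SIM and retinotopy stimulus generation.
#
# The canonical stimulus representation is an event list: one row per
# rectangle presentation with on/off times in ms and the rectangle's
# corners in degrees of visual angle (fixation at the origin, x rightward,
# y upward). Rasterization to a pixel grid exists only for oracles and for
# models that need an image-domain stimulus (retinotopy bars).

#' Build the 2-by-2 square layout of one quadrant
#'
#' Four congruent axis-aligned squares separated by `gap_deg` in x and y,
#' centred on `center`. With size 2 and gap 0.82 the group spans
#' 2.59--7.41 degrees; with size 4 it spans 0.59--9.41 degrees (group
#' centre (5, 5), eccentricity ~7.1 degrees). The lower-left layout is the
#' point reflection of the upper-right layout through fixation, obtained by
#' passing a negated centre.
#'
#' @param size_deg side length of each square (deg), > 0.
#' @param gap_deg gap between squares (deg), >= 0. Default 0.82.
#' @param center numeric length-2, centre of the 2x2 group (deg). Must lie
#'   strictly inside one quadrant (neither coordinate zero).
#' @return an object of class `square_layout` with elements `rects`
#'   (data.frame: square, x_min, x_max, y_min, y_max), `size_deg`,
#'   `gap_deg`, `center`, `quadrant`.
#' @export
#' @examples
#' lay <- build_square_layout(2, 0.82, c(5, 5))
#' range(unlist(lay$rects[, c("x_min", "x_max")]))  # 2.59 7.41
build_square_layout <- function(size_deg, gap_deg = 0.82, center = c(5, 5)) {
  if (!is.numeric(size_deg) || length(size_deg) != 1L || size_deg <= 0) {
    stop("size_deg must be a single positive number")
  }
  if (!is.numeric(gap_deg) || length(gap_deg) != 1L || gap_deg < 0) {
    stop("gap_deg must be a single non-negative number")
  }
  if (length(center) != 2L || any(center == 0)) {
    stop("center must lie strictly inside one quadrant (no zero coordinate)")
  }
  half_gap <- gap_deg / 2
  # per-axis low/high square intervals; formula is sign-symmetric
  lo <- function(c) c(c - size_deg - half_gap, c - half_gap)
  hi <- function(c) c(c + half_gap, c + size_deg + half_gap)
  xs <- rbind(lo(center[1]), hi(center[1]))
  ys <- rbind(lo(center[2]), hi(center[2]))
  # square order: 1 = (low-x, low-y), 2 = (high-x, low-y),
  #               3 = (low-x, high-y), 4 = (high-x, high-y)
  idx <- cbind(x = c(1, 2, 1, 2), y = c(1, 1, 2, 2))
  rects <- data.frame(
    square = 1:4,
    x_min = xs[idx[, "x"], 1], x_max = xs[idx[, "x"], 2],
    y_min = ys[idx[, "y"], 1], y_max = ys[idx[, "y"], 2]
  )
  quadrant <- if (center[1] > 0 && center[2] > 0) {
    "upper_right"
  } else if (center[1] < 0 && center[2] < 0) {
    "lower_left"
  } else if (center[1] > 0) "lower_right" else "upper_left"
  structure(
    list(rects = rects, size_deg = size_deg, gap_deg = gap_deg,
         center = center, quadrant = quadrant),
    class = "square_layout"
  )
}

#' SEQ-SIM run design
#'
#' Holds the block/trial timing of the SEQ-SIM protocol: 8 conditions
#' ({SEQ, SIM} x {0.2 s, 1 s} x {2 deg, 4 deg}), each shown twice per run
#' in a seeded pseudo-random order (16 blocks of ~8 s separated by 12-s
#' blanks), for two unique runs. Short blocks contain 8 trials, long
#' blocks 2 trials; sequential squares are separated by a 33-ms ISI.
#'
#' @param seed integer; seeds block order, sequential square order, and
#'   simultaneous-short onset jitter.
#' @param block_dur_s stimulus block duration (s).
#' @param blank_dur_s blank between blocks (s).
#' @param start_blank_s blank before the first block in the analyzed
#'   (countdown-trimmed) timeline.
#' @param isi_ms inter-square interval in sequential trials (ms).
#' @param sim_long_second_onset_s onset of the second simultaneous long
#'   trial relative to block onset (s).
#' @param sizes square side lengths (deg) of the two size conditions.
#' @param durations_s per-square presentation durations of the two timing
#'   conditions (s).
#' @param gap_deg gap between squares (deg).
#' @param centers list of quadrant group centres.
#' @param tr_s fMRI sampling interval (s).
#' @param onset_matched logical; if TRUE, sequential trials are locked to
#'   regular trial slots with identity square order and simultaneous-short
#'   jitter is disabled, so that a pRF covering a single square sees
#'   identical SEQ and SIM drive (the linear no-suppression null).
#' @return object of class `seqsim_design`.
#' @export
seqsim_design <- function(seed = 1L, block_dur_s = 8, blank_dur_s = 12,
                          start_blank_s = 12, isi_ms = 33,
                          sim_long_second_onset_s = 4,
                          sizes = c(2, 4), durations_s = c(0.2, 1),
                          gap_deg = 0.82,
                          centers = list(upper_right = c(5, 5),
                                         lower_left = c(-5, -5)),
                          tr_s = 1, onset_matched = FALSE) {
  conditions <- expand.grid(
    presentation = c("seq", "sim"),
    duration_s = durations_s,
    size_deg = sizes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  conditions$trials_per_block <- ifelse(conditions$duration_s < 0.5, 8L, 2L)
  conditions$label <- sprintf(
    "%s_%s_%s", conditions$presentation,
    ifelse(conditions$duration_s < 0.5, "short", "long"),
    ifelse(conditions$size_deg == min(sizes), "small", "big")
  )
  conditions$cond_id <- seq_len(nrow(conditions))
  layouts <- lapply(centers, function(ctr) {
    lapply(stats::setNames(sizes, paste0("size", sizes)),
           function(s) build_square_layout(s, gap_deg, ctr))
  })
  structure(
    list(seed = as.integer(seed), block_dur_s = block_dur_s,
         blank_dur_s = blank_dur_s, start_blank_s = start_blank_s,
         isi_ms = isi_ms, sim_long_second_onset_s = sim_long_second_onset_s,
         sizes = sizes, durations_s = durations_s, gap_deg = gap_deg,
         centers = centers, layouts = layouts, conditions = conditions,
         n_blocks = 2L * nrow(conditions), tr_s = tr_s,
         onset_matched = isTRUE(onset_matched)),
    class = "seqsim_design"
  )
}

# square on/off times (ms, relative to block onset) for one quadrant/block
block_square_times <- function(design, presentation, duration_s,
                               trials_per_block) {
  dur <- round(duration_s * 1000)
  isi <- design$isi_ms
  if (presentation == "seq") {
    trial_len <- 4L * dur + 3L * isi
    if (trials_per_block == 2L) {
      # long: back-to-back trials (ISI across the trial boundary) unless
      # onset-matched, where trials are locked to 0/4-s slots
      trial_onsets <- if (design$onset_matched) {
        c(0, design$sim_long_second_onset_s * 1000)
      } else {
        c(0, trial_len + isi)
      }
    } else {
      trial_onsets <- (seq_len(trials_per_block) - 1L) * 1000
    }
    ev <- lapply(seq_along(trial_onsets), function(tr) {
      ord <- if (design$onset_matched) 1:4 else sample.int(4L)
      on <- trial_onsets[tr] + (seq_len(4L) - 1L) * (dur + isi)
      data.frame(trial = tr, square = ord, on_ms = on, off_ms = on + dur)
    })
  } else {
    slot <- 1000
    if (trials_per_block == 2L) {
      trial_onsets <- c(0, design$sim_long_second_onset_s * 1000)
    } else {
      jit <- c(0, if (design$onset_matched) rep(0, trials_per_block - 1L)
               else round(stats::runif(trials_per_block - 1L, 0,
                                       slot - dur)))
      trial_onsets <- (seq_len(trials_per_block) - 1L) * slot + jit
    }
    ev <- lapply(seq_along(trial_onsets), function(tr) {
      data.frame(trial = tr, square = 1:4,
                 on_ms = trial_onsets[tr], off_ms = trial_onsets[tr] + dur)
    })
  }
  do.call(rbind, ev)
}

#' Generate one SEQ-SIM run
#'
#' Produces the millisecond-resolution binary stimulus sequence (as an
#' event list) and the block schedule of one run: 16 pseudo-randomly
#' ordered condition blocks (each condition twice) separated by 12-s
#' blanks, on the countdown-trimmed 332-s analyzed timeline. Block onsets
#' and conditions are identical across quadrants; square order and
#' simultaneous-short onset jitter are drawn independently per quadrant.
#' Fully deterministic given `(design$seed, run)`.
#'
#' @param design a [seqsim_design()].
#' @param run run index (1 or 2); the two unique runs differ in block order
#'   and within-block randomization.
#' @return list with `sequence` (class `stim_sequence`: data.frame
#'   `events` with columns block, cond_id, label, quadrant, square, trial,
#'   on_ms, off_ms, x_min, x_max, y_min, y_max; `duration_ms`;
#'   `fov_deg`; `dt_ms`) and `schedule` (data.frame: block, cond_id,
#'   label, presentation, duration_s, size_deg, onset_s, offset_s).
#' @export
generate_seqsim_run <- function(design, run = 1L) {
  stopifnot(inherits(design, "seqsim_design"))
  conds <- design$conditions
  order_seed <- derive_seed(design$seed, 101L, run)
  block_conds <- with_seed(order_seed, {
    bc <- sample(rep(conds$cond_id, 2L))
    if (run > 1L) {
      prev <- with_seed(derive_seed(design$seed, 101L, 1L),
                        sample(rep(conds$cond_id, 2L)))
      k <- 0L
      while (identical(bc, prev) && k < 100L) {
        bc <- sample(rep(conds$cond_id, 2L))
        k <- k + 1L
      }
    }
    bc
  })
  cycle <- design$block_dur_s + design$blank_dur_s
  onsets_s <- design$start_blank_s + (seq_along(block_conds) - 1L) * cycle
  schedule <- data.frame(
    block = seq_along(block_conds),
    cond_id = block_conds,
    label = conds$label[block_conds],
    presentation = conds$presentation[block_conds],
    duration_s = conds$duration_s[block_conds],
    size_deg = conds$size_deg[block_conds],
    onset_s = onsets_s,
    offset_s = onsets_s + design$block_dur_s
  )
  quadrants <- names(design$centers)
  events <- with_seed(derive_seed(design$seed, 202L, run), {
    out <- vector("list", nrow(schedule) * length(quadrants))
    i <- 0L
    for (b in seq_len(nrow(schedule))) {
      cond <- conds[schedule$cond_id[b], ]
      for (q in quadrants) {
        i <- i + 1L
        tt <- block_square_times(design, cond$presentation, cond$duration_s,
                                 cond$trials_per_block)
        lay <- design$layouts[[q]][[paste0("size", cond$size_deg)]]
        tt <- cbind(
          data.frame(block = b, cond_id = cond$cond_id, label = cond$label,
                     quadrant = q),
          tt
        )
        tt$on_ms <- tt$on_ms + schedule$onset_s[b] * 1000
        tt$off_ms <- tt$off_ms + schedule$onset_s[b] * 1000
        geo <- lay$rects[match(tt$square, lay$rects$square), -1]
        out[[i]] <- cbind(tt, geo)
      }
    }
    do.call(rbind, out)
  })
  rownames(events) <- NULL
  duration_ms <- (max(schedule$offset_s) + design$blank_dur_s) * 1000
  if (any(events$off_ms > duration_ms)) {
    stop("square interval exceeds the run duration")
  }
  max_spill <- design$blank_dur_s * 1000 / 2
  if (any(events$off_ms - schedule$onset_s[events$block] * 1000 >
          design$block_dur_s * 1000 + max_spill)) {
    stop("square interval exceeds its block")
  }
  sequence <- structure(
    list(events = events, duration_ms = duration_ms,
         fov_deg = 24, dt_ms = 1),
    class = "stim_sequence"
  )
  list(sequence = sequence, schedule = schedule)
}

#' Count pooled-drive transients in one block
#'
#' Counts the time points at which the union of the footprint rectangles
#' switches on or off within a block (onsets plus offsets of the pooled
#' drive). A pRF overlapping all four squares of a quadrant sees 16
#' transients in a sequential long block and 64 in a sequential short
#' block; a single-square footprint sees equal counts for the SEQ and SIM
#' members of a condition pair.
#'
#' @param sequence a `stim_sequence`.
#' @param block block number.
#' @param squares square indices in the footprint (subset of 1:4).
#' @param quadrant quadrant name, default `"upper_right"`.
#' @return integer transient count.
#' @export
count_transients <- function(sequence, block, squares = 1:4,
                             quadrant = "upper_right") {
  stopifnot(inherits(sequence, "stim_sequence"))
  if (length(squares) == 0L) stop("footprint must be non-empty")
  ev <- sequence$events
  ev <- ev[ev$block == block & ev$quadrant == quadrant &
             ev$square %in% squares, ]
  if (nrow(ev) == 0L) stop("no events for this block/footprint")
  m <- merge_intervals(ev$on_ms, ev$off_ms)
  2L * nrow(m)
}

#' Generate the retinotopy bar-sweep protocol
#'
#' A bar aperture sweeps a circular field of view in discrete steps:
#' 4 orientations x 2 directions x `n_steps` positions, each shown for
#' `step_dur_s`. Image content inside the bar is ignored (binary
#' apertures).
#'
#' @param fov_deg aperture diameter (deg).
#' @param bar_width_deg bar width (deg); must not exceed the aperture.
#' @param n_steps discrete bar positions per sweep.
#' @param step_dur_s seconds per bar position.
#' @param orientations sweep-axis angles (deg); the bar is orthogonal to
#'   its sweep axis.
#' @return object of class `bar_sequence`: data.frame `frames` (sweep,
#'   orientation, direction, step, position, on_ms, off_ms), plus
#'   `fov_deg`, `bar_width_deg`, `duration_ms`, `dt_ms`.
#' @export
generate_retinotopy_run <- function(fov_deg = 24, bar_width_deg = 3,
                                    n_steps = 12, step_dur_s = 2,
                                    orientations = c(0, 45, 90, 135)) {
  if (bar_width_deg > fov_deg) stop("bar wider than aperture")
  step <- fov_deg / n_steps
  positions <- -fov_deg / 2 + step * (seq_len(n_steps) - 0.5)
  frames <- list()
  sweep <- 0L
  t_ms <- 0
  for (ori in orientations) {
    for (dir in c(1, -1)) {
      sweep <- sweep + 1L
      pos <- if (dir > 0) positions else rev(positions)
      on <- t_ms + (seq_len(n_steps) - 1L) * step_dur_s * 1000
      frames[[sweep]] <- data.frame(
        sweep = sweep, orientation = ori, direction = dir,
        step = seq_len(n_steps), position = pos,
        on_ms = on, off_ms = on + step_dur_s * 1000
      )
      t_ms <- t_ms + n_steps * step_dur_s * 1000
    }
  }
  structure(
    list(frames = do.call(rbind, frames), fov_deg = fov_deg,
         bar_width_deg = bar_width_deg, duration_ms = t_ms, dt_ms = 1),
    class = "bar_sequence"
  )
}

#' Pixel-grid specification
#'
#' @param fov_deg square field-of-view side (deg), centred on fixation.
#' @param px_deg pixel size (deg); pixel centres decide membership.
#' @return list with pixel-centre coordinate vectors `x` (ascending) and
#'   `y` (ascending), and `px_deg`.
#' @export
grid_spec <- function(fov_deg = 24, px_deg = 0.5) {
  if (px_deg <= 0) stop("grid resolution must be > 0")
  n <- round(fov_deg / px_deg)
  ctr <- -fov_deg / 2 + px_deg * (seq_len(n) - 0.5)
  list(x = ctr, y = ctr, px_deg = px_deg)
}

#' Rasterize a stimulus sequence at given times
#'
#' Binary array (y, x, t); a pixel is 1 iff its centre lies in an active
#' rectangle (square sequences) or inside the bar-and-aperture mask (bar
#' sequences). Used as the numeric oracle for the closed-form drive and as
#' the image-domain stimulus for the retinotopy fitter.
#'
#' @param sequence `stim_sequence` or `bar_sequence`.
#' @param grid a [grid_spec()].
#' @param times_ms time points (ms) to rasterize.
#' @return binary array `length(grid$y)` x `length(grid$x)` x
#'   `length(times_ms)`.
#' @export
rasterize <- function(sequence, grid, times_ms) {
  if (any(times_ms < 0 | times_ms > sequence$duration_ms)) {
    stop("time slice outside the sequence duration")
  }
  nx <- length(grid$x)
  ny <- length(grid$y)
  out <- array(0L, dim = c(ny, nx, length(times_ms)))
  if (inherits(sequence, "stim_sequence")) {
    ev <- sequence$events
    for (k in seq_along(times_ms)) {
      t <- times_ms[k]
      act <- ev[ev$on_ms <= t & t < ev$off_ms, ]
      if (nrow(act) == 0L) next
      frame <- matrix(0L, ny, nx)
      for (i in seq_len(nrow(act))) {
        xi <- grid$x >= act$x_min[i] & grid$x <= act$x_max[i]
        yi <- grid$y >= act$y_min[i] & grid$y <= act$y_max[i]
        frame[yi, xi] <- 1L
      }
      out[, , k] <- frame
    }
  } else if (inherits(sequence, "bar_sequence")) {
    xx <- matrix(grid$x, ny, nx, byrow = TRUE)
    yy <- matrix(grid$y, ny, nx)
    apert <- xx^2 + yy^2 <= (sequence$fov_deg / 2)^2
    fr <- sequence$frames
    for (k in seq_along(times_ms)) {
      t <- times_ms[k]
      act <- fr[fr$on_ms <= t & t < fr$off_ms, ]
      if (nrow(act) == 0L) next
      a <- act$orientation[1] * pi / 180
      u <- cos(a) * xx + sin(a) * yy
      out[, , k] <- (abs(u - act$position[1]) <=
                       sequence$bar_width_deg / 2 & apert) + 0L
    }
  } else {
    stop("unsupported sequence type")
  }
  out
}

#' Export a block schedule and event list as TSV
#'
#' @param run a list as returned by [generate_seqsim_run()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_schedule <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sched <- file.path(dir, "schedule.tsv")
  evts <- file.path(dir, "events.tsv")
  utils::write.table(run$schedule, sched, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(run$sequence$events, evts, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(sched, evts))
}
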