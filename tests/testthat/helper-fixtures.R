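# Shared fixtures, built lazily once per session. Everything is generated
# in code; no files are read.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_design <- function() fixture("design", function() seqsim_design(seed = 7L))

fx_runs <- function() {
  fixture("runs", function() {
    lapply(1:2, function(r) generate_seqsim_run(fx_design(), r))
  })
}

fx_sequences <- function() lapply(fx_runs(), `[[`, "sequence")
fx_schedules <- function() lapply(fx_runs(), `[[`, "schedule")

fx_hrf <- function() fixture("hrf", function() double_gamma_hrf())
fx_irfs <- function() fixture("irfs", function() make_temporal_irfs())

# a short single-rectangle step stimulus for temporal-model oracles
step_sequence <- function(on_ms = 500, off_ms = 3500, duration_ms = 6000,
                          rect = c(3, 5, 3, 5)) {
  ev <- data.frame(
    block = 1L, cond_id = 1L, label = "step", quadrant = "upper_right",
    square = 1L, trial = 1L, on_ms = on_ms, off_ms = off_ms,
    x_min = rect[1], x_max = rect[2], y_min = rect[3], y_max = rect[4]
  )
  structure(list(events = ev, duration_ms = duration_ms, fov_deg = 24,
                 dt_ms = 1), class = "stim_sequence")
}

# generative sampler for the suppression LMM recovery tests
simulate_lmm_table <- function(seed, truth, n_participants = 8,
                               n_voxels = 20, slope_sd = 0.1,
                               intercept_sd = 0.05, resid_sd = 0.1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_participants), function(p) {
    sl <- truth + stats::rnorm(length(truth), 0, slope_sd)
    ic <- stats::rnorm(length(truth), 0, intercept_sd)
    do.call(rbind, lapply(seq_along(truth), function(j) {
      seq_a <- stats::runif(n_voxels, 0.5, 2.5)
      data.frame(
        participant = paste0("S", p), area = "sim", voxel = seq_len(n_voxels),
        condition = names(truth)[j], seq_ampl = seq_a,
        sim_ampl = ic[j] + sl[j] * seq_a + stats::rnorm(n_voxels, 0, resid_sd)
      )
    }))
  }))
}
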