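#' @keywords internal
"_PACKAGE"

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a bounded child seed from a parent seed
#'
#' Keeps derived seeds within 32-bit integer range so they remain valid
#' arguments to [set.seed()].
#'
#' @param seed parent seed.
#' @param ... integer offsets identifying the child stream.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p)) %% 2147483647
  as.integer(s)
}

#' Causal linear convolution via FFT
#'
#' Full linear convolution of a signal with a kernel, truncated to the
#' length of the signal (causal filtering; kernel index 1 maps to lag 0).
#'
#' @param x numeric signal.
#' @param k numeric kernel.
#' @return numeric vector, `length(x)`.
#' @keywords internal
conv_causal <- function(x, k) {
  nx <- length(x)
  nk <- length(k)
  n <- stats::nextn(nx + nk - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(n - nx))) *
                       stats::fft(c(k, numeric(n - nk))), inverse = TRUE)) / n
  y[seq_len(nx)]
}

#' Merge possibly-overlapping closed intervals
#'
#' Intervals that overlap or abut are fused; used for pooled-drive
#' transient counting.
#'
#' @param on,off numeric vectors of interval endpoints (ms).
#' @return two-column matrix of merged `(on, off)` intervals.
#' @keywords internal
merge_intervals <- function(on, off) {
  stopifnot(length(on) == length(off), all(off >= on))
  o <- order(on)
  on <- on[o]
  off <- off[o]
  m_on <- on[1]
  m_off <- off[1]
  res <- NULL
  for (i in seq_along(on)[-1]) {
    if (on[i] <= m_off) {
      m_off <- max(m_off, off[i])
    } else {
      res <- rbind(res, c(m_on, m_off))
      m_on <- on[i]
      m_off <- off[i]
    }
  }
  rbind(res, c(m_on, m_off))
}

#' Coefficient of determination (percent)
#'
#' `1 - SS_res / SS_tot` with `SS_tot` centred on the mean of `obs`,
#' expressed in percent. Returns `NA` for zero-variance observations.
#'
#' @param obs observed values.
#' @param pred predicted values.
#' @keywords internal
r2_percent <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) return(NA_real_)
  100 * (1 - sum((obs - pred)^2) / ss_tot)
}
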