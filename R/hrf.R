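#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking around 5 s minus a
#' scaled gamma density modelling the post-stimulus undershoot. With the
#' default parameters (response delay 6, undershoot delay 16, unit
#' dispersions, undershoot ratio 1/6) the response is zero at `t = 0`, peaks
#' near 5 s and has decayed essentially to zero by 32 s. The returned series
#' is scaled to a unit peak so that regressor amplitudes are interpretable as
#' response peak heights.
#'
#' @param t numeric vector of times in seconds; all must be `>= 0`.
#' @param peak_delay,peak_disp gamma shape parameters of the positive lobe
#'   (delay = shape * dispersion, in seconds).
#' @param under_delay,under_disp gamma parameters of the undershoot lobe.
#' @param under_ratio relative amplitude of the undershoot (default 1/6).
#' @return numeric vector of response amplitudes, unit peak.
#' @examples
#' tt <- seq(0, 32, by = 0.1)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)]  # ~5 s
#' @export
canonical_hrf <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, under_ratio = 1 / 6) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time grid must be finite and nonnegative", call. = FALSE)
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    under_ratio * dgamma(t, shape = under_delay / under_disp, scale = under_disp)
  # unit peak on a fine reference grid so scaling does not depend on `t`
  ref <- seq(0, 32, by = 0.01)
  peak <- max(dgamma(ref, shape = peak_delay / peak_disp, scale = peak_disp) -
                under_ratio * dgamma(ref, shape = under_delay / under_disp,
                                     scale = under_disp))
  h / peak
}

# Convolve per-event boxcars with the canonical HRF on a microtime grid and
# sample at volume acquisition times. `onsets`/`durations` in seconds.
# Returns a length-n_volumes regressor. Results are memoised (the same event
# timing recurs for every run, participant and pair).
hrf_regressor <- function(onsets, durations, tr_s, n_volumes, dt = 0.1,
                          hrf_params = list()) {
  key <- paste(c(signif(onsets, 10), "|", signif(durations, 10), tr_s,
                 n_volumes, dt, unlist(hrf_params)), collapse = ",")
  hit <- .hrf_cache[[key]]
  if (!is.null(hit)) return(hit)
  run_len <- n_volumes * tr_s
  nt <- ceiling(run_len / dt)
  box <- numeric(nt)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1
    i1 <- min(nt, ceiling((onsets[k] + durations[k]) / dt))
    if (i0 > nt) stop("event beyond run end", call. = FALSE)
    box[i0:i1] <- 1
  }
  kern <- do.call(canonical_hrf, c(list(t = seq(0, 32, by = dt)), hrf_params))
  conv <- convolve(box, rev(kern), type = "open")[seq_len(nt)] * dt
  idx <- pmin(nt, floor(((seq_len(n_volumes) - 1) * tr_s) / dt) + 1)
  out <- conv[idx]
  if (length(.hrf_cache) > 512) rm(list = ls(.hrf_cache), envir = .hrf_cache)
  assign(key, out, envir = .hrf_cache)
  out
}

.hrf_cache <- new.env(parent = emptyenv())
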