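#' Discrete cosine high-pass basis
#'
#' Unit-norm DCT columns spanning fluctuations slower than `cutoff_s`
#' seconds: the constant plus cosines with periods `2 * n * tr / k >= cutoff`
#' for `k = 1, 2, ...`. Regressing data on the orthogonal complement of this
#' basis implements the high-pass filter; the column count is
#' `floor(2 * n * tr / cutoff) + 1`.
#'
#' @param n_volumes number of time points.
#' @param tr_s repetition time in seconds.
#' @param cutoff_s cutoff period in seconds (default 128; must exceed
#'   `2 * tr_s`).
#' @return an `n_volumes` x k matrix with orthonormal columns.
#' @export
dct_highpass_basis <- function(n_volumes, tr_s, cutoff_s = 128) {
  if (cutoff_s <= 2 * tr_s)
    stop("cutoff_s must exceed 2 * tr_s", call. = FALSE)
  n <- as.integer(n_volumes)
  kmax <- floor(2 * n * tr_s / cutoff_s)
  t0 <- seq_len(n) - 1L
  basis <- matrix(0, n, kmax + 1L)
  basis[, 1] <- 1 / sqrt(n)
  for (k in seq_len(kmax))
    basis[, k + 1L] <- sqrt(2 / n) * cos(pi * (2 * t0 + 1) * k / (2 * n))
  basis
}

# Residualise the columns (time dimension) of a (voxels x time) matrix, or
# the rows of a (time x p) design, against the DCT basis, per run block.
hp_filter_time <- function(m, basis_list, blocks, time_in_cols = TRUE) {
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    k <- basis_list[[b]]
    if (time_in_cols) {
      m[, idx] <- m[, idx, drop = FALSE] -
        (m[, idx, drop = FALSE] %*% k) %*% t(k)
    } else {
      m[idx, ] <- m[idx, , drop = FALSE] -
        k %*% (t(k) %*% m[idx, , drop = FALSE])
    }
  }
  m
}

#' Build a first-level design matrix
#'
#' Interest events are 5 s boxcars starting at the role-assignment phase
#' (covering role + cue-response), convolved with the canonical HRF; the
#' 2.5 s verify phase is modelled as a single covariate of no interest.
#' Two modes:
#' \describe{
#'   \item{`condition`}{the whole six-run session, concatenated: one
#'     regressor per condition (fIJA, fRJA, sIJA, sRJA, fCTRL, sCTRL; six
#'     regressors of interest), a verify regressor, and one intercept per
#'     run.}
#'   \item{`trialwise`}{a single run: one regressor per trial (32 regressors
#'     of interest), a verify regressor ("response and verify" covariate of
#'     no interest) and an intercept — 33 task-related columns, matching the
#'     33 beta images (32 + 1 of no interest) the beta-series analysis
#'     consumes per run.}
#' }
#'
#' @param design a [generate_design()] object.
#' @param participant `"a"` or `"b"`: whose condition labels / roles to use.
#' @param mode `"condition"` or `"trialwise"`.
#' @param run_index run to model (trialwise mode only).
#' @param cutoff_s high-pass cutoff period recorded with the design.
#' @param dt microtime resolution for HRF convolution, seconds.
#' @return an object of class `dyad_design_matrix` with elements `X`,
#'   `names`, `frame_times`, `blocks` (row indices per run), `interest_idx`,
#'   `nuisance_idx`, `intercept_idx`, `tr_s`, `cutoff_s`, `mode`.
#' @export
build_design <- function(design, participant = c("a", "b"),
                         mode = c("condition", "trialwise"), run_index = NULL,
                         cutoff_s = 128, dt = 0.1) {
  participant <- match.arg(participant)
  mode <- match.arg(mode)
  ev <- design_events(design, participant)
  tr_s <- design$tr_s
  nv <- design$n_volumes
  run_len <- nv * tr_s
  if (any(ev$onset + ev$duration > run_len))
    stop("events extend beyond run end", call. = FALSE)
  role_on <- ev$onset + JA_PHASES[["fixation1"]]
  verify_on <- ev$onset + TRIAL_DUR_S - JA_PHASES[["verify"]]

  if (mode == "condition") {
    runs <- sort(unique(ev$run_index))
    nrun <- length(runs)
    nt <- nv * nrun
    blocks <- lapply(seq_len(nrun), function(b) (b - 1L) * nv + seq_len(nv))
    xint <- matrix(0, nt, 6L)
    xver <- numeric(nt)
    for (b in seq_len(nrun)) {
      sel <- ev$run_index == runs[b]
      rows <- blocks[[b]]
      for (ci in seq_along(JA_CONDITIONS)) {
        cc <- JA_CONDITIONS[ci]
        csel <- sel & ev$condition == cc
        if (any(csel))
          xint[rows, ci] <- xint[rows, ci] +
            hrf_regressor(role_on[csel], rep(5, sum(csel)), tr_s, nv, dt)
      }
      xver[rows] <- hrf_regressor(verify_on[sel],
                                  rep(JA_PHASES[["verify"]], sum(sel)),
                                  tr_s, nv, dt)
    }
    if (any(colSums(abs(xint)) == 0))
      stop("all-zero condition regressor: ",
           paste(JA_CONDITIONS[colSums(abs(xint)) == 0], collapse = ", "),
           call. = FALSE)
    xrun <- matrix(0, nt, nrun)
    for (b in seq_len(nrun)) xrun[blocks[[b]], b] <- 1
    X <- cbind(xint, verify = xver, xrun)
    nm <- c(JA_CONDITIONS, "verify", paste0("run", runs, "_intercept"))
    interest <- seq_len(6L)
    nuisance <- 7L
    intercept <- 7L + seq_len(nrun)
  } else {
    if (is.null(run_index)) stop("run_index required in trialwise mode",
                                 call. = FALSE)
    sel <- which(ev$run_index == run_index)
    if (length(sel) != TRIALS_PER_RUN)
      stop("run must contain ", TRIALS_PER_RUN, " trials", call. = FALSE)
    blocks <- list(seq_len(nv))
    xtr <- vapply(sel, function(i)
      hrf_regressor(role_on[i], 5, tr_s, nv, dt), numeric(nv))
    xver <- hrf_regressor(verify_on[sel],
                          rep(JA_PHASES[["verify"]], length(sel)), tr_s, nv, dt)
    X <- cbind(xtr, verify = xver, intercept = 1)
    nm <- c(sprintf("trial%02d", ev$trial_index[sel]), "verify", "intercept")
    interest <- seq_len(TRIALS_PER_RUN)
    nuisance <- TRIALS_PER_RUN + 1L
    intercept <- TRIALS_PER_RUN + 2L
    nt <- nv
  }
  colnames(X) <- nm
  structure(list(X = X, names = nm,
                 frame_times = (seq_len(nt) - 1L) * tr_s,
                 blocks = blocks, interest_idx = interest,
                 nuisance_idx = nuisance, intercept_idx = intercept,
                 tr_s = tr_s, cutoff_s = cutoff_s, mode = mode,
                 n_volumes = nv),
            class = "dyad_design_matrix")
}

#' @export
print.dyad_design_matrix <- function(x, ...) {
  cat("First-level design (", x$mode, "): ", nrow(x$X), " x ", ncol(x$X),
      ", ", length(x$blocks), " run block(s), high-pass ", x$cutoff_s,
      " s\n", sep = "")
  invisible(x)
}
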