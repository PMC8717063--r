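#' Ground-truth specification for the synthetic dyadic cohort
#'
#' Defines the voxel grid and the known inter-brain coupling structure that
#' [simulate_pair()] injects: a `task_sync_mask` whose voxels share a fraction
#' `coupling_task` of their trial-to-trial response-amplitude variance within
#' a real pair (joint-attention runs only), and a disjoint
#' `residual_sync_mask` whose voxels receive a shared slow background signal
#' carrying a fraction `coupling_residual` of the noise variance. Control
#' runs never receive shared components, so any synchrony detected there is a
#' false positive by construction.
#'
#' @param grid_shape integer length-3 voxel dimensions (default `c(24,24,24)`,
#'   3 mm isotropic, a desk-scale stand-in for a whole-brain grid resliced to
#'   3 mm).
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param task_sync_mask,residual_sync_mask logical arrays matching
#'   `grid_shape` (default: two disjoint compact ~50-voxel blobs).
#' @param coupling_task,coupling_residual shared-variance fractions in
#'   `[0, 1]`.
#' @param ar1_phi lag-1 autocorrelation of the voxel noise, in `(-1, 1)`.
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param drift_amp per-component standard deviation of the slow cosine
#'   drift (periods > 128 s).
#' @param amp_mean,amp_sd mean and SD of per-trial response amplitudes.
#' @param verify_amp fixed response amplitude of the verify phase.
#' @return an object of class `sync_truth`.
#' @export
sync_ground_truth <- function(grid_shape = c(24L, 24L, 24L), voxel_mm = 3,
                              task_sync_mask = NULL, residual_sync_mask = NULL,
                              coupling_task = 0.6, coupling_residual = 0.5,
                              ar1_phi = 0.3, noise_sd = 1, drift_amp = 1,
                              amp_mean = 1, amp_sd = 0.5, verify_amp = 0.5) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  grid_shape <- as.integer(grid_shape)
  assert_prob(coupling_task, "coupling_task")
  assert_prob(coupling_residual, "coupling_residual")
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)", call. = FALSE)
  ctr <- grid_shape / 2
  if (is.null(task_sync_mask))
    task_sync_mask <- make_blob_mask(grid_shape, ctr * c(0.5, 0.5, 0.5), 50L)
  if (is.null(residual_sync_mask))
    residual_sync_mask <- make_blob_mask(grid_shape, ctr * c(1.5, 1.5, 1.5), 50L)
  check_mask <- function(m, name) {
    if (!is.logical(m) || !identical(as.integer(dim(m)), grid_shape))
      stop(sprintf("'%s' must be a logical array of dim %s", name,
                   paste(grid_shape, collapse = "x")), call. = FALSE)
  }
  check_mask(task_sync_mask, "task_sync_mask")
  check_mask(residual_sync_mask, "residual_sync_mask")
  if (any(task_sync_mask & residual_sync_mask))
    stop("task and residual masks must be disjoint", call. = FALSE)
  out <- list(grid_shape = grid_shape, voxel_mm = voxel_mm,
              task_sync_mask = task_sync_mask,
              residual_sync_mask = residual_sync_mask,
              coupling_task = coupling_task,
              coupling_residual = coupling_residual,
              ar1_phi = ar1_phi, noise_sd = noise_sd, drift_amp = drift_amp,
              amp_mean = amp_mean, amp_sd = amp_sd, verify_amp = verify_amp)
  class(out) <- "sync_truth"
  out
}

#' Compact connected voxel blob
#'
#' The `n_voxels` grid voxels nearest to `center` (Euclidean, ties broken by
#' linear index), giving a connected roughly spherical region — used for
#' ground-truth coupling masks.
#'
#' @param grid_shape integer length-3 dimensions.
#' @param center numeric length-3 voxel coordinates.
#' @param n_voxels blob size.
#' @return logical array of dimension `grid_shape`.
#' @export
make_blob_mask <- function(grid_shape, center, n_voxels) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  ord <- order(d2, seq_along(d2))
  m <- logical(nrow(g))
  m[ord[seq_len(n_voxels)]] <- TRUE
  array(m, dim = grid_shape)
}

mni_like_affine <- function(grid_shape, voxel_mm) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * grid_shape / 2
  aff
}

new_bold_run <- function(data, truth, tr_s, participant_id, pair_id,
                         run_index, task_type) {
  structure(list(data = data, dim = truth$grid_shape,
                 voxel_mm = truth$voxel_mm,
                 affine = mni_like_affine(truth$grid_shape, truth$voxel_mm),
                 tr_s = tr_s, n_volumes = ncol(data),
                 participant_id = participant_id, pair_id = pair_id,
                 run_index = run_index, task_type = task_type),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("BOLD run ", x$participant_id, " run ", x$run_index, " (", x$task_type,
      "): ", paste(x$dim, collapse = "x"), " voxels x ", x$n_volumes,
      " volumes, TR ", x$tr_s, " s\n", sep = "")
  invisible(x)
}

#' 4D array view of a BOLD run
#' @param run a `bold_run`.
#' @return numeric 4D array (x, y, z, time).
#' @export
bold_array <- function(run) {
  array(run$data, dim = c(run$dim, run$n_volumes))
}

# Low-pass-filtered unit-variance Gaussian series (FFT brick wall at
# `cutoff_hz`), emulating resting-state-like slow shared fluctuations.
lowpass_noise <- function(n, tr_s, cutoff_hz = 0.1) {
  x <- rnorm(n)
  f <- fft(x)
  freq <- seq_len(n) - 1
  freq <- pmin(freq, n - freq) / (n * tr_s)
  f[freq > cutoff_hz] <- 0
  s <- Re(fft(f, inverse = TRUE)) / n
  s / sd(s)
}

# Convolved trial (32 cols) and verify regressors for one run of a design —
# identical across runs because trial timing is fixed.
run_trial_regressors <- function(design) {
  ev <- design$trials[design$trials$run_index == 1L, ]
  role_on <- ev$onset_s + JA_PHASES[["fixation1"]]
  C <- vapply(seq_len(nrow(ev)), function(i)
    hrf_regressor(role_on[i], 5, design$tr_s, design$n_volumes),
    numeric(design$n_volumes))
  verify_on <- ev$onset_s + TRIAL_DUR_S - JA_PHASES[["verify"]]
  v <- hrf_regressor(verify_on, rep(JA_PHASES[["verify"]], nrow(ev)),
                     design$tr_s, design$n_volumes)
  list(trials = C, verify = v)
}

drift_series <- function(n_volumes, tr_s, amp, cutoff_s = 128) {
  basis <- dct_highpass_basis(n_volumes, tr_s, cutoff_s)
  k <- ncol(basis) - 1L
  if (k < 1L || amp == 0) return(numeric(n_volumes))
  sqrt(n_volumes) * as.vector(basis[, -1, drop = FALSE] %*% rnorm(k, 0, amp))
}

#' Simulate one run of a pair
#'
#' Forward model for a single participant-pair run: per-voxel signal is the
#' sum of HRF-convolved 5 s trial events scaled by per-trial amplitudes, an
#' HRF-convolved verify-phase response, a slow cosine drift (periods > 128 s),
#' and stationary AR(1) Gaussian noise. In JA runs, trial amplitudes of the
#' two participants share a latent component (variance fraction
#' `coupling_task`) inside `task_sync_mask`, and a shared low-frequency
#' (< 0.1 Hz) background series (variance fraction `coupling_residual`) is
#' added inside `residual_sync_mask`. Control runs receive no shared
#' components. Fully deterministic given `(design, truth, seed)`.
#'
#' @param design a [generate_design()] object.
#' @param truth a [sync_ground_truth()] object.
#' @param seed pair-level master seed.
#' @param run_index which of the six runs to simulate.
#' @return list with elements `a` and `b` (class `bold_run`) and `latents`
#'   (the generating per-trial amplitude series and shared background series,
#'   kept as ground truth for validation).
#' @export
simulate_run <- function(design, truth, seed, run_index) {
  stopifnot(inherits(design, "ja_design"), inherits(truth, "sync_truth"))
  run_index <- as.integer(run_index)
  task <- design$run_order[run_index]
  is_ja <- task != "control"
  nvox <- prod(truth$grid_shape)
  nt <- design$n_volumes
  reg <- run_trial_regressors(design)
  task_idx <- which(truth$task_sync_mask)
  res_idx <- which(truth$residual_sync_mask)

  set.seed(split_seed(seed, run_index, 1))
  g <- rnorm(TRIALS_PER_RUN)                       # shared amplitude latent
  set.seed(split_seed(seed, run_index, 2))
  shared_bg <- lowpass_noise(nt, design$tr_s)      # shared background latent
  ct <- truth$coupling_task
  cr <- truth$coupling_residual
  sd_bg <- if (cr > 0 && cr < 1) truth$noise_sd * sqrt(cr / (1 - cr)) else
    if (cr == 1) truth$noise_sd * 1e6 else 0

  sim_participant <- function(p) {
    set.seed(split_seed(seed, run_index, 3, p))
    e <- rnorm(TRIALS_PER_RUN)                     # idiosyncratic amp latent
    set.seed(split_seed(seed, run_index, 4, p))
    u <- rnorm(TRIALS_PER_RUN)                     # background amp latent
    amp_bg <- truth$amp_mean + truth$amp_sd * u
    amp_mask <- if (is_ja)
      truth$amp_mean + truth$amp_sd * (sqrt(ct) * g + sqrt(1 - ct) * e)
    else amp_bg
    sig_bg <- as.vector(reg$trials %*% amp_bg) + truth$verify_amp * reg$verify
    sig_mask <- as.vector(reg$trials %*% amp_mask) + truth$verify_amp * reg$verify

    set.seed(split_seed(seed, run_index, 5, p))
    drift <- drift_series(nt, design$tr_s, truth$drift_amp)

    set.seed(split_seed(seed, run_index, 6, p))
    innov <- matrix(rnorm(nvox * nt, sd = truth$noise_sd *
                            sqrt(1 - truth$ar1_phi^2)), nvox, nt)
    y <- ar1_filter_cpp(innov, truth$ar1_phi)
    base <- sig_bg + drift
    y <- y + matrix(base, nvox, nt, byrow = TRUE)
    if (length(task_idx))
      y[task_idx, ] <- y[task_idx, ] +
        matrix(sig_mask - sig_bg, length(task_idx), nt, byrow = TRUE)
    if (is_ja && length(res_idx) && sd_bg > 0)
      y[res_idx, ] <- y[res_idx, ] +
        matrix(sd_bg * shared_bg, length(res_idx), nt, byrow = TRUE)
    list(run = new_bold_run(y, truth, design$tr_s,
                            paste0(design$pair_id, toupper(letters[p])),
                            design$pair_id, run_index, task),
         amp_mask = amp_mask, amp_bg = amp_bg)
  }

  pa <- sim_participant(1L)
  pb <- sim_participant(2L)
  list(a = pa$run, b = pb$run,
       latents = list(task = task, shared_amp = g, shared_bg = shared_bg,
                      amp_mask_a = pa$amp_mask, amp_mask_b = pb$amp_mask,
                      amp_bg_a = pa$amp_bg, amp_bg_b = pb$amp_bg))
}

#' Simulate all six runs of a pair
#'
#' @inheritParams simulate_run
#' @return list with `a` and `b` (each a list of six `bold_run`s in
#'   acquisition order) and `latents` (per-run generating latents).
#' @export
simulate_pair <- function(design, truth, seed) {
  runs <- lapply(seq_len(6L), function(r) simulate_run(design, truth, seed, r))
  list(a = lapply(runs, `[[`, "a"), b = lapply(runs, `[[`, "b"),
       latents = lapply(runs, `[[`, "latents"))
}

#' Spatial Gaussian smoothing of a BOLD run
#'
#' Separable 3D Gaussian smoothing of every volume with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, expressed in voxel units from
#' the run's affine (per-axis voxel sizes, so anisotropic grids are handled).
#' Kernels are renormalised at the boundary, so constant images are exact
#' eigenfunctions. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param run a `bold_run`.
#' @param fwhm_mm full width at half maximum in millimetres (>= 0).
#' @return the smoothed `bold_run`.
#' @export
smooth_gaussian <- function(run, fwhm_mm) {
  stopifnot(inherits(run, "bold_run"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(run)
  vox <- abs(diag(run$affine)[1:3])
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  y <- run$data
  d <- run$dim
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(4 * s))
    kern <- exp(-((-h:h)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    y <- smooth_axis_mat(y, d, axis, kern)
  }
  run$data <- y
  run
}

# Convolve a (voxels x time) matrix along one spatial axis with kernel
# renormalisation at the edges.
smooth_axis_mat <- function(y, d, axis, kern) {
  nt <- ncol(y)
  a <- array(y, dim = c(d, nt))
  perm <- c(axis, setdiff(1:3, axis), 4L)
  a <- aperm(a, perm)
  dd <- dim(a)
  m <- matrix(a, nrow = dd[1])
  n <- dd[1]
  h <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (off in -h:h) {
    w <- kern[off + h + 1L]
    src <- max(1L, 1L - off):min(n, n - off)
    dst <- src + off
    out[dst, ] <- out[dst, ] + w * m[src, ]
    wsum[dst] <- wsum[dst] + w
  }
  out <- out / wsum
  a <- array(out, dd)
  a <- aperm(a, order(perm))
  matrix(a, nrow = prod(d), ncol = nt)
}
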