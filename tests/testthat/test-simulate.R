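test_that("simulation is bit-deterministic and metadata is coherent", {
  d <- short_design()
  truth <- tiny_truth()
  s1 <- simulate_run(d, truth, 9, 1)
  s2 <- simulate_run(d, truth, 9, 1)
  expect_identical(s1, s2)
  s3 <- simulate_run(d, truth, 10, 1)
  expect_false(identical(s1$a$data, s3$a$data))
  expect_equal(s1$a$n_volumes, d$n_volumes)
  expect_false(anyNA(s1$a$data))
  expect_equal(dim(bold_array(s1$a)), c(tiny_grid, d$n_volumes))
})

test_that("trial-amplitude coupling reaches its degenerate limits", {
  d <- short_design()
  ja_run <- which(d$run_order == "fJA")[1]
  # coupling 1: amplitude series identical between members in the task mask
  t1 <- tiny_truth(coupling_task = 1)
  s <- simulate_run(d, t1, 4, ja_run)
  expect_equal(s$latents$amp_mask_a, s$latents$amp_mask_b)
  # coupling 0: independent amplitude series
  t0 <- tiny_truth(coupling_task = 0, coupling_residual = 0)
  rs <- vapply(1:40, function(seed) {
    s <- simulate_run(d, t0, seed, ja_run)
    cor(s$latents$amp_mask_a, s$latents$amp_mask_b)
  }, 1)
  expect_lt(abs(mean(rs)), 3 / sqrt(40 * 32))
})

test_that("amplitude coupling matches the requested shared-variance fraction", {
  # oracle: direct correlation of the generating latents across 4 JA runs
  # of many seeds (128 trials per seed)
  d <- short_design()
  ja_runs <- which(d$run_order != "control")
  t8 <- tiny_truth(coupling_task = 0.8)
  rs <- vapply(1:30, function(seed) {
    a <- unlist(lapply(ja_runs, function(r)
      simulate_run(d, t8, seed, r)$latents$amp_mask_a))
    b <- unlist(lapply(ja_runs, function(r)
      simulate_run(d, t8, seed, r)$latents$amp_mask_b))
    cor(a, b)
  }, 1)
  expect_equal(mean(rs), 0.8, tolerance = 0.05)
})

test_that("expected amplitude correlation is monotone in coupling", {
  d <- short_design()
  r1 <- which(d$run_order == "fJA")[1]
  mean_r <- vapply(c(0, 0.3, 0.6, 0.9), function(ct) {
    t <- tiny_truth(coupling_task = ct)
    mean(vapply(1:25, function(seed) {
      s <- simulate_run(d, t, seed, r1)
      cor(s$latents$amp_mask_a, s$latents$amp_mask_b)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_r) > 0))
})

test_that("control runs carry no shared components", {
  d <- short_design()
  ctrl <- which(d$run_order == "control")[1]
  t <- tiny_truth(coupling_task = 0.9, coupling_residual = 0.9)
  s <- simulate_run(d, t, 2, ctrl)
  expect_identical(s$latents$amp_mask_a, s$latents$amp_bg_a)
  # turning the couplings off changes nothing in a control run
  t0 <- tiny_truth(coupling_task = 0, coupling_residual = 0)
  s0 <- simulate_run(d, t0, 2, ctrl)
  expect_identical(s$a$data, s0$a$data)
  expect_identical(s$b$data, s0$b$data)
})

test_that("mask geometry is validated", {
  expect_error(sync_ground_truth(grid_shape = c(8, 8, 8),
                                 task_sync_mask = array(TRUE, c(4, 4, 4))),
               "logical array")
  m <- make_blob_mask(c(8, 8, 8), c(4, 4, 4), 10)
  expect_error(sync_ground_truth(grid_shape = c(8, 8, 8),
                                 task_sync_mask = m, residual_sync_mask = m),
               "disjoint")
  expect_error(tiny_truth(coupling_task = 1.2), "coupling_task")
})

test_that("blob masks are connected and have the requested size", {
  m <- make_blob_mask(c(12, 12, 12), c(6, 6, 6), 50)
  expect_equal(sum(m), 50)
  lab <- dyadsync:::label_clusters_cpp(as.logical(m), c(12L, 12L, 12L), 26L)
  expect_equal(max(lab), 1L)
})

test_that("gaussian smoothing: identity, constant field, impulse oracle", {
  d <- short_design()
  truth <- tiny_truth()
  s <- simulate_run(d, truth, 1, 1)$a
  expect_identical(smooth_gaussian(s, 0), s)

  const <- s
  const$data <- matrix(7, nrow(s$data), ncol(s$data))
  sm <- smooth_gaussian(const, 8)
  expect_equal(sm$data, const$data, tolerance = 1e-12)

  # impulse response against a dense explicit-kernel convolution oracle
  imp <- s
  imp$data <- matrix(0, nrow(s$data), 2)
  imp$n_volumes <- 2L
  centre <- c(4, 4, 4)
  imp$data[centre[1] + 8 * (centre[2] - 1) + 64 * (centre[3] - 1), 1] <- 1
  sm <- smooth_gaussian(imp, 8)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3   # voxels, 3 mm grid
  h <- ceiling(4 * sigma)
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  # oracle: explicit 1D convolution matrix with the same edge
  # renormalisation (row weights sum to 1), applied separably
  w1 <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    if (abs(j - i) <= h) w1[i, j] <- k1[j - i + h + 1]
  w1 <- w1 / rowSums(w1)
  oracle <- outer(outer(w1[, centre[1]], w1[, centre[2]]), w1[, centre[3]])
  got <- array(sm$data[, 1], c(8, 8, 8))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(got[4, 4, 4], w1[4, 4]^3, tolerance = 1e-10)
})

test_that("BOLD runs round-trip through NIfTI at float32 precision", {
  d <- short_design()
  s <- simulate_run(d, tiny_truth(), 3, 2)$a
  f <- withr::local_tempfile(fileext = ".nii")
  write_bold_nifti(s, f)
  r <- read_bold_nifti(f, tr_s = s$tr_s)
  expect_equal(r$dim, s$dim)
  expect_equal(r$n_volumes, s$n_volumes)
  expect_equal(r$data, s$data, tolerance = 1e-5)   # float32 storage
  expect_equal(r$affine, s$affine, tolerance = 1e-6)
  # the study-scale grid shape is preserved too
  arr <- bold_array(s)
  expect_equal(length(dim(arr)), 4L)
})

test_that("maps and masks write as NIfTI with the grid geometry", {
  m <- make_blob_mask(c(8, 8, 8), c(4, 4, 4), 12)
  f <- withr::local_tempfile(fileext = ".nii")
  write_map_nifti(m, f, voxel_mm = 3)
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), c(8, 8, 8))
  expect_equal(sum(img), 12)
})
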