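test_that("fisher transform matches its closed form and symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(1, eps = 1e-4), atanh(1 - 1e-4))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("pseudo-pair enumeration is exhaustive, disjoint and exact", {
  # P = 2, enumerable by hand
  p2 <- enumerate_pseudo_pairs(c("p1", "p2"))
  expect_equal(nrow(p2), 2L)
  expect_setequal(paste(p2$member_a, p2$member_b),
                  c("p1 p2", "p2 p1"))
  # P in 2..22 against brute-force enumeration with set difference
  for (p in c(2, 5, 13, 22)) {
    ids <- sprintf("p%02d", seq_len(p))
    got <- enumerate_pseudo_pairs(ids)
    brute <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
    brute <- brute[brute$a != brute$b, ]
    expect_equal(nrow(got), p * (p - 1))
    expect_setequal(paste(got$member_a, got$member_b),
                    paste(brute$a, brute$b))
    # no pseudo pair coincides with a real pair (a-member with own b-member)
    expect_false(any(got$member_a == got$member_b))
  }
  expect_equal(nrow(enumerate_pseudo_pairs(1:22)), 462L)
  expect_error(enumerate_pseudo_pairs(c("a", "a")), "duplicate")
  expect_error(enumerate_pseudo_pairs("a"), "at least 2")
})

make_series <- function(values, id = "x") {
  structure(list(values = values, runs = 1:4, participant_id = id,
                 dim = NULL), class = "beta_series")
}

test_that("pair correlation: self-correlation, null distribution, symmetry", {
  set.seed(5)
  v <- matrix(rnorm(200 * 128), 200, 128)
  x <- make_series(v)
  self <- pair_correlation(x, x)
  expect_equal(self$r, rep(1, 200))
  expect_equal(self$z, rep(atanh(1 - 1e-7), 200))

  # independent series: null sampling distribution of r over voxels
  y <- make_series(matrix(rnorm(200 * 128), 200, 128), "y")
  pc <- pair_correlation(x, y)
  expect_lt(abs(mean(pc$r)), 3 / sqrt(127 * 200))
  expect_equal(sd(pc$r), 1 / sqrt(127), tolerance = 0.2)
  # symmetric in its arguments
  pc2 <- pair_correlation(y, x)
  expect_equal(pc2$r, pc$r)
  expect_identical(pc$analysis, "beta_series")
})

test_that("zero-variance series are flagged, mismatches rejected", {
  x <- make_series(rbind(rep(1, 128), rnorm(128)))
  y <- make_series(rbind(rnorm(128), rnorm(128)), "y")
  pc <- pair_correlation(x, y)
  expect_true(is.na(pc$z[1]))
  expect_equal(pc$flagged, 1L)
  bad <- make_series(matrix(rnorm(2 * 64), 2, 64), "y")
  expect_error(pair_correlation(x, bad), "mismatch")
})

test_that("beta series assembly reorders JA runs canonically", {
  d <- short_design()
  truth <- tiny_truth()
  ja_runs <- c(which(d$run_order == "fJA"), which(d$run_order == "sJA"))
  dm1 <- build_design(d, "a", "trialwise", run_index = 1)
  fits <- lapply(seq_len(6), function(r) {
    y <- simulate_run(d, truth, 2, r)$a$data[1:20, ]
    f <- fit_glm(y, dm1, whiten = "none")
    attr(f, "run_index") <- r
    f
  })
  bs <- assemble_beta_series(fits, d, participant_id = "a")
  expect_equal(ncol(bs$values), 128L)
  expect_equal(bs$runs, ja_runs)
  # scrambled input order yields the identical series
  bs2 <- assemble_beta_series(rev(fits), d, participant_id = "a")
  expect_equal(bs2$values, bs$values)
  # 33 per-run betas reduce to 32 of interest
  expect_equal(length(fits[[1]]$interest_cols), 32L)
  expect_equal(ncol(fits[[1]]$betas), 33L)
  # missing JA run refused
  expect_error(assemble_beta_series(fits[-ja_runs[1]], d), "missing")
})

test_that("residual series collect the right runs and reject whitened fits", {
  d <- short_design()
  truth <- tiny_truth()
  dm1 <- build_design(d, "a", "trialwise", run_index = 1)
  fits <- lapply(seq_len(6), function(r) {
    y <- simulate_run(d, truth, 2, r)$a$data[1:10, ]
    f <- fit_glm(y, dm1, whiten = "none")
    attr(f, "run_index") <- r
    f
  })
  rs <- residual_series(fits, d, "JA")
  expect_equal(length(rs$values), 4L)
  expect_equal(max(abs(rowMeans(rs$values[[1]]))), 0, tolerance = 1e-10)
  rsc <- residual_series(fits, d, "control")
  expect_equal(rsc$runs, which(d$run_order == "control"))
  fw <- fit_glm(simulate_run(d, truth, 2, 1)$a$data[1:10, ], dm1,
                whiten = "ar1")
  attr(fw, "run_index") <- 1L
  fits[[1]] <- fw
  if (1L %in% rs$runs) {
    expect_error(residual_series(fits, d, "JA"), "whiten")
  }
})

test_that("residual correlation averages Fisher z across runs", {
  set.seed(9)
  mk <- function(id) {
    structure(list(values = lapply(1:4, function(i)
      matrix(rnorm(50 * 100), 50, 100)),
      runs = 1:4, condition_type = "JA", participant_id = id, dim = NULL),
      class = "residual_series")
  }
  x <- mk("a"); y <- mk("b")
  pc <- pair_correlation(x, y)
  z_oracle <- rowMeans(vapply(1:4, function(i)
    atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7,
      dyadsync::row_correlation(x$values[[i]], y$values[[i]])))),
    numeric(50)))
  expect_equal(pc$z, z_oracle, tolerance = 1e-12)
  expect_identical(pc$analysis, "residual_JA")
})

test_that("real and pseudo z distributions are exchangeable without coupling", {
  # type-I premise: with coupling 0, a pseudo pair is statistically
  # indistinguishable from a real pair (KS test on beta-series z over seeds)
  set.seed(31)
  d <- short_design()
  truth <- tiny_truth(coupling_task = 0, coupling_residual = 0)
  ja <- which(d$run_order != "control")
  zr <- c(); zp <- c()
  amp <- function(seed, run, member)
    simulate_run(d, truth, seed, run)$latents[[paste0("amp_mask_", member)]]
  for (seed in 1:12) {
    a1 <- unlist(lapply(ja, amp, seed = seed, member = "a"))
    b1 <- unlist(lapply(ja, amp, seed = seed, member = "b"))
    b2 <- unlist(lapply(ja, amp, seed = seed + 100, member = "b"))
    zr <- c(zr, atanh(cor(a1, b1)))
    zp <- c(zp, atanh(cor(a1, b2)))
  }
  expect_gt(suppressWarnings(ks.test(zr, zp)$p.value), 0.01)
})
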