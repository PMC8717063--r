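test_that("one-sample t matches the direct t-test oracle", {
  set.seed(2)
  m <- matrix(rnorm(30 * 12, mean = 0.4), 30, 12)
  tm <- one_sample_t(m)
  expect_equal(tm$df, 11)
  oracle <- apply(m, 1, function(x) t.test(x)$statistic)
  expect_equal(tm$t, unname(oracle), tolerance = 1e-10)
  # permuting participant order leaves the map unchanged
  tm2 <- one_sample_t(m[, sample(12)])
  expect_equal(tm2$t, tm$t)
  # constant images are masked
  mc <- rbind(m, 3)
  expect_true(is.na(one_sample_t(mc)$t[31]))
})

test_that("welch t matches the hand formula and t.test oracle", {
  # frozen 4+4 toy table, hand-computed Welch statistic
  x <- matrix(c(1.1, 2.3, 0.7, 1.9), 1)
  y <- matrix(c(3.0, 2.5, 3.8, 2.9), 1)
  tm <- welch_two_sample_t(rbind(x, x), rbind(y, y))
  expect_equal(tm$t[1], -3.402692059680, tolerance = 1e-10)
  expect_equal(tm$df[1], 5.548849974643, tolerance = 1e-10)
  # random instances against stats::t.test(var.equal = FALSE)
  set.seed(8)
  a <- matrix(rnorm(20 * 8), 20); b <- matrix(rnorm(20 * 11, 0.3), 20, 11)
  tm <- welch_two_sample_t(a, b)
  for (i in c(1, 7, 20)) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(tm$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tm$df[i], unname(tt$parameter), tolerance = 1e-10)
  }
  # identical groups give t = 0
  same <- matrix(rnorm(5 * 6), 5)
  expect_equal(welch_two_sample_t(same, same)$t, rep(0, 5))
})

test_that("welch reduces to student t for equal variances and sizes", {
  set.seed(13)
  a <- matrix(rnorm(50 * 10), 50)
  b <- matrix(rnorm(50 * 10), 50)
  tm <- welch_two_sample_t(a, b)
  student <- vapply(seq_len(50), function(i)
    unname(t.test(a[i, ], b[i, ], var.equal = TRUE)$statistic), 1)
  expect_equal(tm$t, student, tolerance = 1e-10)
})

test_that("conjunction is intersection of thresholded maps", {
  mk <- function(t) structure(list(t = t, df = 20, dim = NULL),
                              class = "group_tmap")
  thr <- qt(0.999, 20)
  t1 <- c(5, 5, 0, 5); t2 <- c(5, 0, 5, 5)
  expect_equal(as.vector(conjunction(list(mk(t1), mk(t2)))),
               c(TRUE, FALSE, FALSE, TRUE))
  # single map = thresholding that map
  expect_equal(as.vector(conjunction(list(mk(t1)))), t1 > thr)
  # disjoint suprathreshold sets -> empty conjunction
  expect_false(any(conjunction(list(mk(c(5, 0)), mk(c(0, 5))))))
  expect_error(conjunction(list()), "empty")
})

test_that("conjunction recovers a jointly active injected region", {
  set.seed(4)
  dims <- c(8, 8, 8)
  region <- as.vector(make_blob_mask(dims, c(4, 4, 4), 20))
  n <- 16
  maps <- lapply(1:4, function(k) {
    m <- matrix(rnorm(prod(dims) * n), ncol = n)
    m[region, ] <- m[region, ] + 2.5
    tm <- one_sample_t(m, dim = dims)
    tm
  })
  conj <- conjunction(maps, height_p = 0.001)
  expect_gt(mean(conj[region]), 0.9)        # region recovered
  expect_lt(mean(conj[!region]), 0.01)      # little else
})

test_that("cluster labelling agrees with the flood-fill oracle", {
  set.seed(77)
  for (i in 1:6) {
    mask <- array(runif(8^3) < 0.25, c(8, 8, 8))
    for (conn in c(6L, 26L)) {
      lab_cpp <- array(dyadsync:::label_clusters_cpp(as.logical(mask),
                                                     c(8L, 8L, 8L), conn),
                       c(8, 8, 8))
      lab_ora <- label_clusters_oracle(mask, conn)
      expect_equal(max(lab_cpp), max(lab_ora))
      # same partition (labels may be permuted): compare co-membership via
      # sorted cluster sizes and a label-matching check
      expect_equal(sort(tabulate(lab_cpp[lab_cpp > 0])),
                   sort(tabulate(lab_ora[lab_ora > 0])))
      relab <- lab_ora[lab_cpp > 0]
      expect_equal(length(unique(paste(lab_cpp[lab_cpp > 0], relab))),
                   max(lab_cpp))
    }
  }
})

test_that("permutation p-values respect the 1/n_perm floor", {
  set.seed(6)
  dims <- c(6, 6, 6)
  n <- 14
  m <- matrix(rnorm(prod(dims) * n), ncol = n)
  blob <- as.vector(make_blob_mask(dims, c(3, 3, 3), 15))
  m[blob, ] <- m[blob, ] + 3
  tm <- one_sample_t(m, dim = dims)
  ct <- cluster_fwe(tm, m, type = "one_sample", n_perm = 50L, seed = 2)
  expect_gte(min(ct$p_fwe), 1 / 50)
  expect_true(any(ct$significant))
  # the injected cluster is the largest and covers the blob
  expect_gte(ct$n_voxels[1], 10)
})

test_that("too few exchangeable units are refused", {
  dims <- c(4, 4, 4)
  m <- matrix(rnorm(prod(dims) * 3), ncol = 3)
  tm <- one_sample_t(m, dim = dims)
  expect_error(cluster_fwe(tm, m, type = "one_sample", n_perm = 20),
               "too few units")
})

test_that("two-sample cluster FWE detects a real>pseudo effect", {
  set.seed(15)
  dims <- c(8, 8, 8)
  blob <- as.vector(make_blob_mask(dims, c(4, 4, 4), 12))
  zr <- matrix(rnorm(prod(dims) * 10, 0, 0.1), ncol = 10)
  zp <- matrix(rnorm(prod(dims) * 40, 0, 0.1), ncol = 40)
  zr[blob, ] <- zr[blob, ] + 0.5
  tm <- welch_two_sample_t(zr, zp, dim = dims)
  ct <- cluster_fwe(tm, list(real = zr, pseudo = zp), type = "two_sample",
                    n_perm = 100L, seed = 3)
  expect_true(any(ct$significant))
  top <- ct[1, ]
  vox <- which(attr(ct, "labels") == top$cluster_id)
  expect_gt(mean(vox %in% which(blob)), 0.5)
})

test_that("permutation FWE p-values are valid under the null", {
  # under exchangeability P(p <= alpha) <= alpha + 1/n_perm
  set.seed(44)
  dims <- c(6, 6, 6)
  n_rep <- 60
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    m <- matrix(rnorm(prod(dims) * 12), ncol = 12)
    tm <- one_sample_t(m, dim = dims)
    ct <- cluster_fwe(tm, m, type = "one_sample", n_perm = 60L, seed = r)
    rej[r] <- nrow(ct) > 0 && any(ct$p_fwe <= 0.05)
  }
  rate <- mean(rej)
  expect_lte(rate, 0.05 + 1 / 60 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
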