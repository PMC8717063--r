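#' Voxelwise one-sample t map
#'
#' Tests the mean of per-participant images against zero, `df = n - 1`.
#' Zero-variance voxels are masked (`NA`).
#'
#' @param images voxels x participants matrix (each column one contrast or
#'   z image), or a list of equal-length vectors / `contrast_image`s.
#' @param dim optional grid dimensions carried with the map.
#' @return object of class `group_tmap`: `t`, `df` (scalar), `n`, `dim`.
#' @export
one_sample_t <- function(images, dim = NULL) {
  m <- as_image_matrix(images)
  dim <- dim %||% attr(m, "grid_dim")
  n <- ncol(m)
  if (n < 2) stop("need at least 2 images", call. = FALSE)
  mu <- rowMeans(m)
  s2 <- rowSums((m - mu)^2) / (n - 1)
  tval <- mu / sqrt(s2 / n)
  tval[s2 <= 0] <- NA_real_
  structure(list(t = tval, df = n - 1, n = n, dim = dim,
                 analysis = "one_sample"),
            class = "group_tmap")
}

#' Voxelwise Welch two-sample t map (real vs pseudo pairs)
#'
#' Welch's unequal-variance t with Satterthwaite degrees of freedom,
#' positive where the first group (real pairs) exceeds the second (pseudo
#' pairs). The measurements are treated as independent between groups, as in
#' the real-versus-pseudo synchronization comparison. Voxels with zero
#' variance in both groups are masked.
#'
#' @param real,pseudo voxels x n matrices of Fisher-z maps (or lists of
#'   vectors / `pair_cor_map`s, in which case their `z` maps are stacked).
#' @param dim optional grid dimensions.
#' @return object of class `group_tmap` with per-voxel `df`.
#' @export
welch_two_sample_t <- function(real, pseudo, dim = NULL) {
  x <- as_image_matrix(real)
  y <- as_image_matrix(pseudo)
  dim <- dim %||% attr(x, "grid_dim") %||% attr(y, "grid_dim")
  if (nrow(x) != nrow(y)) stop("grid mismatch", call. = FALSE)
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 images per group", call. = FALSE)
  res <- welch_stats(x, y)
  structure(list(t = res$t, df = res$df, n = c(n1, n2), dim = dim,
                 analysis = "welch_two_sample"),
            class = "group_tmap")
}

welch_stats <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tval <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  bad <- se2 <= 0
  tval[bad] <- NA_real_
  df[bad] <- NA_real_
  list(t = tval, df = df)
}

as_image_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (inherits(images, "pair_cor_map")) images <- list(images)
  if (is.list(images)) {
    grid_dim <- NULL
    cols <- lapply(images, function(im) {
      if (inherits(im, "pair_cor_map")) { grid_dim <<- im$dim; im$z }
      else if (inherits(im, "contrast_image")) { grid_dim <<- im$dim; im$values }
      else as.numeric(im)
    })
    m <- do.call(cbind, cols)
    attr(m, "grid_dim") <- grid_dim
    return(m)
  }
  stop("cannot interpret images", call. = FALSE)
}

#' Minimum-statistic conjunction of thresholded t maps
#'
#' A voxel passes the conjunction iff every component map exceeds its own
#' height threshold (`t > qt(1 - height_p, df)`) — the conjunction-null
#' minimum-statistic rule, equal to the intersection of the individually
#' thresholded maps.
#'
#' @param maps non-empty list of `group_tmap`s on a common grid.
#' @param height_p cluster-forming / voxel threshold p (default 0.001).
#' @return logical voxel vector with the grid `dim` attribute.
#' @export
conjunction <- function(maps, height_p = 0.001) {
  if (length(maps) == 0) stop("empty map list", call. = FALSE)
  masks <- lapply(maps, function(m) {
    stopifnot(inherits(m, "group_tmap"))
    thr <- qt(1 - height_p, m$df)
    pass <- !is.na(m$t) & m$t > thr
    pass
  })
  out <- Reduce(`&`, masks)
  attr(out, "dim3") <- maps[[1]]$dim
  out
}

#' Cluster-level family-wise-error-corrected inference
#'
#' Thresholds the t map at height `p < height_p` (one-sided, positive),
#' labels maximal connected suprathreshold components (26-neighbourhood by
#' default) and assigns each cluster a family-wise-error-corrected p-value:
#' the proportion of permutations — the observed labelling included — whose
#' maximum cluster size is at least the cluster's size. Sign flipping of
#' participant images is used for one-sample maps and group-label
#' permutation for two-sample (real vs pseudo) maps. The smallest attainable
#' p is therefore `1 / n_perm`.
#'
#' @param tmap a `group_tmap` (used for the observed statistic and df).
#' @param data the exchangeable unit-level data: for `type = "one_sample"` a
#'   voxels x n matrix (or list) of participant images; for
#'   `type = "two_sample"` a list `list(real = , pseudo = )` of voxels x n
#'   matrices.
#' @param type `"one_sample"` or `"two_sample"`.
#' @param height_p cluster-forming threshold (default 0.001).
#' @param alpha cluster-level FWE threshold reported in the table (default
#'   0.05).
#' @param n_perm number of permutations including the identity (>= 100
#'   recommended; at least 10 distinct permutations must exist).
#' @param seed RNG seed for the permutation draw.
#' @param connectivity 6 or 26 (default 26).
#' @param method `"permutation"` (default). A random-field-theory
#'   approximation is not provided; the permutation route is exact under
#'   exchangeability and is the supported method.
#' @return object of class `cluster_table`: a data.frame (cluster_id,
#'   n_voxels, peak_t, peak_index, x, y, z, p_fwe, significant) ordered by
#'   size (ties broken by peak t), with attributes `threshold`, `perm_max`
#'   (the permutation null of maximum cluster size) and `dim`. Also carries
#'   a `labels` attribute with the observed cluster labelling.
#' @export
cluster_fwe <- function(tmap, data, type = c("one_sample", "two_sample"),
                        height_p = 0.001, alpha = 0.05, n_perm = 1000L,
                        seed = 1L, connectivity = 26L,
                        method = "permutation") {
  type <- match.arg(type)
  stopifnot(inherits(tmap, "group_tmap"))
  if (!identical(method, "permutation"))
    stop("only the permutation method is implemented", call. = FALSE)
  dim3 <- tmap$dim
  if (is.null(dim3)) stop("tmap carries no grid dimensions", call. = FALSE)

  if (type == "one_sample") {
    m <- as_image_matrix(data)
    n <- ncol(m)
    if (2^n < 10) stop("too few units to permute (< 10 distinct sign flips)",
                       call. = FALSE)
  } else {
    stopifnot(is.list(data), all(c("real", "pseudo") %in% names(data)))
    x <- as_image_matrix(data$real)
    y <- as_image_matrix(data$pseudo)
    n1 <- ncol(x)
    ntot <- n1 + ncol(y)
    if (lchoose(ntot, n1) < log(10))
      stop("too few units to permute (< 10 distinct label shuffles)",
           call. = FALSE)
    z_all <- cbind(x, y)
  }

  # Height thresholding with per-voxel df: qt is monotone in df, so only
  # voxels whose t lies between the loosest and tightest possible threshold
  # need an exact quantile — orders of magnitude fewer qt calls per
  # permutation than evaluating every voxel.
  thr_mask <- function(tval, df) {
    ok <- !is.na(tval)
    if (length(df) == 1L) return(ok & tval > qt(1 - height_p, df))
    dfr <- range(df[ok])
    hi <- qt(1 - height_p, dfr[1])   # smallest df -> largest threshold
    lo <- qt(1 - height_p, dfr[2])
    out <- ok & tval > hi
    band <- which(ok & tval > lo & tval <= hi)
    if (length(band))
      out[band] <- tval[band] > qt(1 - height_p, df[band])
    out
  }

  obs_mask <- thr_mask(tmap$t, tmap$df)
  labels <- label_clusters_cpp(obs_mask, as.integer(dim3),
                               as.integer(connectivity))
  k <- max(labels)
  sizes <- if (k > 0) tabulate(labels[labels > 0], nbins = k) else integer(0)

  set.seed(seed)
  perm_max <- integer(n_perm)
  perm_max[1] <- max_cluster_size_cpp(obs_mask, as.integer(dim3),
                                      as.integer(connectivity))
  # remaining permutations, vectorised with one GEMM per chunk
  chunk <- 64L
  if (type == "one_sample") {
    ssq <- rowSums(m^2)
    i <- 2L
    while (i <= n_perm) {
      j <- min(n_perm, i + chunk - 1L)
      s_mat <- matrix(sample(c(-1, 1), n * (j - i + 1L), replace = TRUE),
                      n, j - i + 1L)
      mu <- (m %*% s_mat) / n
      v <- (ssq - n * mu^2) / (n - 1)
      tt <- mu / sqrt(v / n)
      tt[v <= 0] <- NA_real_
      for (c in seq_len(ncol(tt)))
        perm_max[i + c - 1L] <- max_cluster_size_cpp(
          thr_mask(tt[, c], n - 1), as.integer(dim3),
          as.integer(connectivity))
      i <- j + 1L
    }
  } else {
    z2 <- z_all^2
    s_tot <- rowSums(z_all)
    q_tot <- rowSums(z2)
    n2 <- ntot - n1
    i <- 2L
    while (i <= n_perm) {
      j <- min(n_perm, i + chunk - 1L)
      nc <- j - i + 1L
      pm <- matrix(0, ntot, nc)
      for (c in seq_len(nc)) pm[sample(ntot, n1), c] <- 1
      s1 <- z_all %*% pm
      q1 <- z2 %*% pm
      m1 <- s1 / n1
      m2 <- (s_tot - s1) / n2
      v1 <- (q1 - n1 * m1^2) / (n1 - 1)
      v2 <- ((q_tot - q1) - n2 * m2^2) / (n2 - 1)
      se2 <- v1 / n1 + v2 / n2
      tt <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      tt[se2 <= 0] <- NA_real_
      for (c in seq_len(nc))
        perm_max[i + c - 1L] <- max_cluster_size_cpp(
          thr_mask(tt[, c], df[, c]), as.integer(dim3),
          as.integer(connectivity))
      i <- j + 1L
    }
  }

  if (k > 0) {
    peak_t <- vapply(seq_len(k), function(c)
      max(tmap$t[labels == c], na.rm = TRUE), 1)
    peak_index <- vapply(seq_len(k), function(c) {
      w <- which(labels == c)
      w[which.max(tmap$t[w])]
    }, 1L)
    p_fwe <- vapply(sizes, function(s) mean(perm_max >= s), 1)
    coords <- arrayInd(peak_index, dim3)
    tab <- data.frame(cluster_id = seq_len(k), n_voxels = sizes,
                      peak_t = peak_t, peak_index = peak_index,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      p_fwe = p_fwe, significant = p_fwe < alpha)
    tab <- tab[order(-tab$n_voxels, -tab$peak_t), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      peak_t = numeric(0), peak_index = integer(0),
                      x = integer(0), y = integer(0), z = integer(0),
                      p_fwe = numeric(0), significant = logical(0))
  }
  structure(tab, class = c("cluster_table", "data.frame"),
            threshold = qt(1 - height_p, if (length(tmap$df) == 1) tmap$df
                           else stats::median(tmap$df, na.rm = TRUE)),
            height_p = height_p, alpha = alpha, n_perm = n_perm,
            perm_max = perm_max, labels = labels, grid_dim = dim3)
}
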