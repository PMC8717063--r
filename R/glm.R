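#' First-level GLM with DCT high-pass filtering and AR(1) ReML prewhitening
#'
#' Fits `Y = X b + e` per voxel after projecting both data and design onto
#' the orthogonal complement of the discrete cosine high-pass basis (per run
#' block). With `whiten = "ar1"`, a single AR(1) coefficient is estimated by
#' restricted maximum likelihood from a pooled voxel set (voxels exceeding a
#' first-pass omnibus F threshold), both sides are premultiplied by the
#' exact AR(1) inverse-covariance Cholesky factor, and the model is refit by
#' ordinary least squares — so the whitened-OLS estimates equal generalised
#' least squares under the fitted AR(1) covariance. `whiten = "none"` skips
#' prewhitening, preserving the autocorrelation structure of the residuals
#' (the setting used to extract residual time series for inter-brain
#' correlation). No global scaling is applied.
#'
#' Intercept columns lie inside the span of the DCT basis (which contains
#' the constant) and are annihilated by the filter; they are dropped from
#' the filtered regression, their effect being absorbed by the filter
#' projector. Zero-variance voxels get zero betas and are flagged.
#'
#' @param y a `bold_run`, or a voxels x time numeric matrix. For a
#'   condition-mode (concatenated-session) design, pass a list of six
#'   `bold_run`s or a matrix spanning all runs.
#' @param dm a [build_design()] object.
#' @param whiten `"ar1"` or `"none"`.
#' @param pool_p first-pass omnibus F p-value defining the ReML pooling set
#'   (default 0.001).
#' @param pool_max cap on pooled voxels (a deterministic thinning keeps the
#'   ReML cost bounded).
#' @return an object of class `dyad_glm_fit`: `betas` (voxels x kept
#'   regressors), `residuals` (voxels x time, in the filtered and — if
#'   requested — whitened space), `ar1_phi`, `sigma2`, `df_resid`,
#'   `design`, `whitened`, `kept` (retained design columns), `flagged`
#'   (zero-variance voxels), and `dim` (grid dims when known).
#' @export
fit_glm <- function(y, dm, whiten = c("ar1", "none"), pool_p = 0.001,
                    pool_max = 1000L) {
  whiten <- match.arg(whiten)
  stopifnot(inherits(dm, "dyad_design_matrix"))
  grid_dim <- NULL
  if (inherits(y, "bold_run")) {
    grid_dim <- y$dim
    y <- y$data
  } else if (is.list(y)) {
    grid_dim <- y[[1]]$dim
    y <- do.call(cbind, lapply(y, function(r) r$data))
  }
  stopifnot(is.matrix(y))
  if (anyNA(y)) stop("NaN/NA values in input data", call. = FALSE)
  X <- dm$X
  if (nrow(X) != ncol(y))
    stop("time dimension of data and design disagree", call. = FALSE)

  basis_list <- lapply(dm$blocks, function(b)
    dct_highpass_basis(length(b), dm$tr_s, dm$cutoff_s))
  n_filter <- sum(vapply(basis_list, ncol, 1L))
  yf <- hp_filter_time(y, basis_list, dm$blocks, time_in_cols = TRUE)
  xf <- hp_filter_time(X, basis_list, dm$blocks, time_in_cols = FALSE)

  kept <- which(sqrt(colSums(xf^2)) > 1e-8 * sqrt(nrow(xf)))
  xf <- xf[, kept, drop = FALSE]
  if (qr(xf)$rank < ncol(xf))
    stop("design matrix is rank deficient after filtering", call. = FALSE)
  p <- ncol(xf)
  df_resid <- nrow(xf) - n_filter - p
  if (df_resid < 1) stop("no residual degrees of freedom", call. = FALSE)

  flagged <- row_var_zero(y)
  ols <- function(xw, yw) {
    qx <- qr(xw)
    betas <- t(qr.coef(qx, t(yw)))
    betas[flagged, ] <- 0
    res <- yw - betas %*% t(xw)
    list(betas = betas, res = res)
  }

  fit0 <- ols(xf, yf)
  phi <- 0
  if (whiten == "ar1") {
    pool <- reml_pool(yf, xf, fit0, dm, kept, df_resid, pool_p, flagged)
    if (length(pool) > pool_max)
      pool <- pool[round(seq(1, length(pool), length.out = pool_max))]
    phi <- estimate_ar1_reml(yf[pool, , drop = FALSE], xf, blocks = dm$blocks)
    yw <- ar1_whiten(yf, phi, dm$blocks, time_in_cols = TRUE)
    xw <- ar1_whiten(xf, phi, dm$blocks, time_in_cols = FALSE)
    fit1 <- ols(xw, yw)
  } else {
    fit1 <- fit0
  }
  sigma2 <- rowSums(fit1$res^2) / df_resid
  structure(list(betas = fit1$betas, residuals = fit1$res, ar1_phi = phi,
                 sigma2 = sigma2, df_resid = df_resid, design = dm,
                 whitened = whiten == "ar1", kept = kept, flagged = flagged,
                 dim = grid_dim,
                 interest_cols = match(dm$interest_idx, kept)),
            class = "dyad_glm_fit")
}

row_var_zero <- function(y) {
  mu <- rowMeans(y)
  rowSums((y - mu)^2) < 1e-12
}

# Pooling set for ReML: voxels whose omnibus F over the interest regressors
# exceeds the `pool_p` threshold in the first-pass OLS fit. Falls back to all
# non-degenerate voxels when nothing passes (tiny simulations).
reml_pool <- function(yf, xf, fit0, dm, kept, df_resid, pool_p, flagged) {
  int_cols <- match(dm$interest_idx, kept)
  int_cols <- int_cols[!is.na(int_cols)]
  rss1 <- rowSums(fit0$res^2)
  x0 <- xf[, -int_cols, drop = FALSE]
  if (ncol(x0) > 0) {
    q0 <- qr(x0)
    b0 <- t(qr.coef(q0, t(yf)))
    rss0 <- rowSums((yf - b0 %*% t(x0))^2)
  } else {
    rss0 <- rowSums(yf^2)
  }
  q <- length(int_cols)
  fstat <- ((rss0 - rss1) / q) / (rss1 / df_resid)
  thr <- qf(1 - pool_p, q, df_resid)
  pool <- which(fstat > thr & !flagged)
  if (length(pool) < 2L) pool <- which(!flagged)
  pool
}

# Exact AR(1) whitening transform: y*_1 = sqrt(1-phi^2) y_1,
# y*_t = y_t - phi y_{t-1}, applied per run block. W'W is proportional to the
# inverse AR(1) correlation matrix, so OLS on transformed quantities is GLS.
ar1_whiten <- function(m, phi, blocks, time_in_cols = TRUE) {
  s0 <- sqrt(1 - phi^2)
  for (b in blocks) {
    if (time_in_cols) {
      seg <- m[, b, drop = FALSE]
      n <- ncol(seg)
      out <- seg
      out[, 1] <- s0 * seg[, 1]
      if (n > 1) out[, 2:n] <- seg[, 2:n, drop = FALSE] -
          phi * seg[, 1:(n - 1), drop = FALSE]
      m[, b] <- out
    } else {
      seg <- m[b, , drop = FALSE]
      n <- nrow(seg)
      out <- seg
      out[1, ] <- s0 * seg[1, ]
      if (n > 1) out[2:n, ] <- seg[2:n, , drop = FALSE] -
          phi * seg[1:(n - 1), , drop = FALSE]
      m[b, ] <- out
    }
  }
  m
}

#' Pooled AR(1) coefficient by restricted maximum likelihood
#'
#' Maximises the restricted likelihood of the model `y = X b + e`,
#' `e ~ AR(1)(phi) x sigma^2_v`, summed over the pooled voxels with each
#' voxel's variance profiled out, over a single global `phi`. Uses the
#' closed-form AR(1) determinant and the exact bidiagonal whitening factor,
#' so each evaluation costs one OLS pass.
#'
#' @param residuals_pooled voxels x time matrix of pooled data (or
#'   residual-like series), time in columns.
#' @param design a [build_design()] object, or a plain time x p design
#'   matrix.
#' @param blocks list of run-block index vectors (defaults to one block).
#' @param interval search interval for `phi`.
#' @param tol convergence tolerance of the scalar optimiser (phi units).
#' @return the scalar ReML estimate of `phi`.
#' @export
estimate_ar1_reml <- function(residuals_pooled, design,
                              blocks = NULL,
                              interval = c(-0.95, 0.95), tol = 1e-3) {
  y <- residuals_pooled
  stopifnot(is.matrix(y), ncol(y) >= 2)
  if (inherits(design, "dyad_design_matrix")) {
    x <- design$X
    blocks <- blocks %||% design$blocks
  } else {
    x <- as.matrix(design)
  }
  blocks <- blocks %||% list(seq_len(ncol(y)))
  if (any(row_var_zero(y)))
    stop("degenerate (constant) series in pooling set", call. = FALSE)
  nt <- ncol(y)
  p <- ncol(x)
  nvox <- nrow(y)
  nblk <- length(blocks)

  neg2_rll <- function(phi) {
    yw <- ar1_whiten(y, phi, blocks, time_in_cols = TRUE)
    xw <- ar1_whiten(x, phi, blocks, time_in_cols = FALSE)
    qx <- qr(xw)
    res <- yw - t(qr.coef(qx, t(yw))) %*% t(xw)
    rss_gls <- rowSums(res^2) / (1 - phi^2)
    logdet_r <- (nt - nblk) * log(1 - phi^2)
    logdet_xvx <- 2 * sum(log(abs(diag(qr.R(qx))))) - p * log(1 - phi^2)
    sum((nt - p) * log(rss_gls)) + nvox * (logdet_r + logdet_xvx)
  }
  optimize(neg2_rll, interval = interval, tol = tol)$minimum
}

#' Linear contrast of condition betas
#'
#' @param fit a condition-mode [fit_glm()] result.
#' @param weights numeric length-6 weights over the interest regressors
#'   (fIJA, fRJA, sIJA, sRJA, fCTRL, sCTRL).
#' @return object of class `contrast_image`: voxel values plus the weights.
#' @export
compute_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "dyad_glm_fit"))
  ic <- fit$interest_cols
  if (anyNA(ic)) stop("fit is missing interest regressors", call. = FALSE)
  if (length(weights) != length(ic))
    stop("weights length must equal the number of interest regressors (",
         length(ic), ")", call. = FALSE)
  vals <- as.vector(fit$betas[, ic, drop = FALSE] %*% weights)
  structure(list(values = vals, weights = weights, dim = fit$dim),
            class = "contrast_image")
}

#' Predefined second-level contrast vectors
#'
#' The ten session contrasts over (fIJA, fRJA, sIJA, sRJA, fCTRL, sCTRL):
#' each JA condition against its matching solo control, the between-category
#' differences, the initiator-vs-responder gradient and the main effect of
#' JA (JA conditions vs controls, weights summing to zero), plus the two
#' minimum-statistic conjunction recipes (spatial-specific = sIJA & sRJA &
#' (sIJA>fIJA) & (sRJA>fRJA); feature-specific analogously).
#'
#' @return named list with `contrasts` (named list of length-6 weight
#'   vectors, in condition order fIJA, fRJA, sIJA, sRJA, fCTRL, sCTRL) and
#'   `conjunctions` (named list of contrast-name vectors).
#' @export
ja_contrast_table <- function() {
  ord <- JA_CONDITIONS  # fIJA fRJA sIJA sRJA fCTRL sCTRL
  w <- function(...) {
    v <- c(...)
    names(v) <- ord
    v
  }
  contrasts <- list(
    sIJA            = w(0, 0, 1, 0, 0, -1),
    sRJA            = w(0, 0, 0, 1, 0, -1),
    fIJA            = w(1, 0, 0, 0, -1, 0),
    fRJA            = w(0, 1, 0, 0, -1, 0),
    `sIJA>fIJA`     = w(-1, 0, 1, 0, 1, -1),
    `sRJA>fRJA`     = w(0, -1, 0, 1, 1, -1),
    `sIJA<fIJA`     = w(1, 0, -1, 0, -1, 1),
    `sRJA<fRJA`     = w(0, 1, 0, -1, -1, 1),
    `IJA>RJA`       = w(1, -1, 1, -1, 0, 0),
    main_effect_JA  = w(1, 1, 1, 1, -2, -2))
  conjunctions <- list(
    spatial_specific = c("sIJA", "sRJA", "sIJA>fIJA", "sRJA>fRJA"),
    feature_specific = c("fIJA", "fRJA", "sIJA<fIJA", "sRJA<fRJA"))
  list(contrasts = contrasts, conjunctions = conjunctions)
}
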