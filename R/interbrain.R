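#' Fisher variance-stabilising transform
#'
#' `z = atanh(r)`, with `|r| >= 1 - eps` clipped to `atanh(1 - eps)` so that
#' perfect correlations map to a finite configurable maximum.
#'
#' @param r correlations in `[-1, 1]` (values outside are rejected; `NA`
#'   passes through).
#' @param eps clipping margin (default `1e-7`).
#' @return z-scores of the same shape.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("|r| > 1 is not a correlation", call. = FALSE)
  r <- pmax(pmin(r, 1 - eps), -1 + eps)
  atanh(r)
}

#' Assemble a trial-wise beta series across the four JA runs
#'
#' Reorders the session's trial-wise fits canonically — first fJA run,
#' second fJA run, first sJA run, second sJA run (acquisition order within
#' task type) — drops control runs and the no-interest (verify) beta, and
#' concatenates the 32 interest betas per run into an ordered series of
#' 4 x 32 = 128 per-trial amplitudes per voxel. The canonical reorder makes
#' series comparable across participants regardless of each pair's
#' counterbalanced run order, which is what makes pseudo-pair comparison
#' possible.
#'
#' @param fits named or unnamed list of trial-wise [fit_glm()] results, one
#'   per run (any order; control-run fits may be present and are ignored).
#' @param design the session [generate_design()] object (supplies each run's
#'   task type).
#' @param participant_id identifier carried in the result.
#' @return object of class `beta_series`: `values` (voxels x 128), `runs`
#'   (the canonical run indices), `participant_id`, `dim`.
#' @export
assemble_beta_series <- function(fits, design, participant_id = NA) {
  stopifnot(inherits(design, "ja_design"))
  run_of <- vapply(fits, function(f) {
    ri <- attr(f, "run_index")
    if (is.null(ri)) stop("each fit needs a 'run_index' attribute",
                          call. = FALSE)
    as.integer(ri)
  }, 1L)
  canonical <- c(which(design$run_order == "fJA"),
                 which(design$run_order == "sJA"))
  if (!all(canonical %in% run_of))
    stop("missing trial-wise fit for run(s) ",
         paste(setdiff(canonical, run_of), collapse = ", "), call. = FALSE)
  mats <- lapply(canonical, function(r) {
    f <- fits[[which(run_of == r)[1]]]
    if (f$design$mode != "trialwise")
      stop("fits must be trial-wise", call. = FALSE)
    ic <- f$interest_cols
    if (length(ic) != TRIALS_PER_RUN || anyNA(ic))
      stop("expected ", TRIALS_PER_RUN, " interest betas per run",
           call. = FALSE)
    f$betas[, ic, drop = FALSE]
  })
  values <- do.call(cbind, mats)
  structure(list(values = values, runs = canonical,
                 participant_id = participant_id,
                 dim = fits[[1]]$dim),
            class = "beta_series")
}

#' Residual time series for inter-brain correlation
#'
#' Collects per-run residuals from unwhitened (`whiten = "none"`) trial-wise
#' fits — each event modelled individually and removed, serial-correlation
#' modelling off so the autocorrelation structure of the residuals is
#' preserved — for either the four JA runs (canonical order) or the two
#' control runs. Residuals are demeaned per run.
#'
#' @param fits list of trial-wise `whiten = "none"` [fit_glm()] results with
#'   `run_index` attributes.
#' @param design the session design.
#' @param condition_type `"JA"` or `"control"`.
#' @param participant_id identifier carried in the result.
#' @return object of class `residual_series`: `values` (list of voxels x
#'   time matrices, one per run), `runs`, `condition_type`, `dim`.
#' @export
residual_series <- function(fits, design, condition_type = c("JA", "control"),
                            participant_id = NA) {
  condition_type <- match.arg(condition_type)
  stopifnot(inherits(design, "ja_design"))
  run_of <- vapply(fits, function(f) as.integer(attr(f, "run_index")), 1L)
  wanted <- if (condition_type == "JA")
    c(which(design$run_order == "fJA"), which(design$run_order == "sJA"))
  else which(design$run_order == "control")
  if (!all(wanted %in% run_of))
    stop("missing fit for run(s) ", paste(setdiff(wanted, run_of),
                                          collapse = ", "), call. = FALSE)
  vals <- lapply(wanted, function(r) {
    f <- fits[[which(run_of == r)[1]]]
    if (f$whitened)
      stop("residual series must come from whiten = 'none' fits",
           call. = FALSE)
    res <- f$residuals
    res - rowMeans(res)
  })
  structure(list(values = vals, runs = wanted,
                 condition_type = condition_type,
                 participant_id = participant_id, dim = fits[[1]]$dim),
            class = "residual_series")
}

#' Enumerate pseudo pairs from a cohort of real pairs
#'
#' Every ordered combination of an A-role-sequence member of one pair with
#' the B-role-sequence member of a *different* pair: `P * (P - 1)` pseudo
#' pairs for `P` real pairs (462 for 22), disjoint from the real pairs by
#' construction. Because A and B members carry complementary role sequences
#' and all series are reordered to canonical task order, pseudo-pair series
#' are aligned trial-for-trial with real-pair series.
#'
#' @param pair_ids vector of real-pair identifiers (length >= 2, no
#'   duplicates).
#' @return data.frame with columns `member_a` (pair id contributing its A
#'   member), `member_b`, and `pair_type = "pseudo"`, in deterministic
#'   row-major order.
#' @export
enumerate_pseudo_pairs <- function(pair_ids) {
  if (anyDuplicated(pair_ids)) stop("duplicate pair ids", call. = FALSE)
  p <- length(pair_ids)
  if (p < 2) stop("need at least 2 real pairs", call. = FALSE)
  g <- expand.grid(member_b = pair_ids, member_a = pair_ids,
                   stringsAsFactors = FALSE)[, c("member_a", "member_b")]
  g <- g[g$member_a != g$member_b, , drop = FALSE]
  rownames(g) <- NULL
  g$pair_type <- "pseudo"
  g
}

#' Voxelwise inter-brain correlation map
#'
#' Pearson correlation between two participants' series at identical voxel
#' coordinates, Fisher z-transformed. For `beta_series`, the two 128-trial
#' series are correlated directly. For `residual_series`, the correlation is
#' computed per run and the Fisher z values are averaged across the runs of
#' the condition type (avoiding spurious correlation from concatenating
#' across run boundaries). Zero-variance voxels yield `NA` and are flagged.
#'
#' @param x,y two objects of the same class (`beta_series` or
#'   `residual_series`) on the same grid.
#' @param pair_type `"real"` or `"pseudo"` (bookkeeping).
#' @param fisher apply the Fisher transform (default `TRUE`; when `FALSE`,
#'   `z` is the plain (averaged) correlation).
#' @return object of class `pair_cor_map`: `r` (voxel vector; for residual
#'   series the back-transformed average), `z`, `analysis`, `pair_type`,
#'   `member_ids`, `dim`.
#' @export
pair_correlation <- function(x, y, pair_type = c("real", "pseudo"),
                             fisher = TRUE) {
  pair_type <- match.arg(pair_type)
  if (!identical(class(x), class(y)))
    stop("series must be of the same analysis type", call. = FALSE)
  if (inherits(x, "beta_series")) {
    if (!identical(dim(x$values), dim(y$values)))
      stop("series length / grid mismatch", call. = FALSE)
    r <- row_correlation(x$values, y$values)
    z <- if (fisher) fisher_z(r) else r
    analysis <- "beta_series"
    rr <- r
  } else if (inherits(x, "residual_series")) {
    if (x$condition_type != y$condition_type)
      stop("residual series must share a condition type", call. = FALSE)
    if (length(x$values) != length(y$values))
      stop("run count mismatch", call. = FALSE)
    zs <- lapply(seq_along(x$values), function(i) {
      if (!identical(dim(x$values[[i]]), dim(y$values[[i]])))
        stop("series length / grid mismatch", call. = FALSE)
      r <- row_correlation(x$values[[i]], y$values[[i]])
      if (fisher) fisher_z(r) else r
    })
    z <- Reduce(`+`, zs) / length(zs)
    rr <- if (fisher) tanh(z) else z
    analysis <- paste0("residual_", x$condition_type)
  } else {
    stop("unsupported series type", call. = FALSE)
  }
  structure(list(r = rr, z = z, analysis = analysis, pair_type = pair_type,
                 member_ids = c(x$participant_id, y$participant_id),
                 flagged = which(is.na(z)), dim = x$dim),
            class = "pair_cor_map")
}
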