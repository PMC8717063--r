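#' Default pipeline configuration
#'
#' Every tunable of the end-to-end synthetic-cohort pipeline with its
#' default. Defaults reproduce the study conditions the generator emulates:
#' 22 pairs, six runs of 175 volumes at TR 2.5 s (two fJA, two sJA, two
#' control; 32 trials each, 192 per session), a 24x24x24 grid of 3 mm
#' voxels, 50-voxel coupling masks with shared-variance fractions 0.6
#' (trial amplitudes) and 0.5 (background), 128 s high-pass cutoff, AR(1)
#' prewhitening for beta estimation, no prewhitening for residual
#' extraction, and permutation cluster-FWE inference at height p < 0.001,
#' cluster alpha 0.05.
#'
#' @return nested named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    pairs = 22L,
    grid = c(24L, 24L, 24L),
    voxel_mm = 3,
    tr_s = 2.5,
    n_volumes = 175L,
    lead_in_s = 20,
    control_block = 4L,
    coupling_task = 0.6,
    coupling_residual = 0.5,
    task_mask_voxels = 50L,
    residual_mask_voxels = 50L,
    ar1_phi = 0.3,
    noise_sd = 1,
    drift_amp = 1,
    amp_mean = 1,
    amp_sd = 0.5,
    verify_amp = 0.5,
    smooth_fwhm_mm = 0,
    glm = list(cutoff_s = 128, whiten_beta = "ar1",
               whiten_residual = "none", pool_max = 500L),
    sync = list(analyses = c("beta", "residual"), fisher = TRUE),
    group = list(height_p = 0.001, alpha = 0.05, n_perm = 200L,
                 connectivity = 26L, method = "permutation"),
    include_task_contrasts = FALSE,
    contrast_n_perm = 100L,
    seed = NULL,
    out_dir = NULL)
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a named list, or a path to a YAML or JSON file. Missing keys are
#' filled from [default_config()]; unknown keys (top level or within `glm`,
#' `sync`, `group`) are rejected to catch typos. A seed is mandatory: every
#' stochastic stage draws from it.
#'
#' @param config list or file path.
#' @return the completed configuration (class `dyad_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  def <- default_config()
  check_keys <- function(x, ref, where) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad))
      stop("unknown config key(s) ", where, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(config, def, "")
  for (k in c("glm", "sync", "group"))
    if (!is.null(config[[k]])) check_keys(config[[k]], def[[k]],
                                          paste0("in '", k, "'"))
  cfg <- modifyList(def, config)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  cfg$pairs <- as.integer(cfg$pairs)
  if (cfg$pairs < 2) stop("need at least 2 pairs", call. = FALSE)
  assert_prob(cfg$coupling_task, "coupling_task")
  assert_prob(cfg$coupling_residual, "coupling_residual")
  stopifnot(length(cfg$grid) == 3, cfg$n_volumes >= 2,
            cfg$group$n_perm >= 2, cfg$group$height_p > 0,
            cfg$group$height_p < 1)
  if (!is.null(cfg$out_dir) && !dir.exists(dirname(cfg$out_dir)) &&
      !dir.exists(cfg$out_dir))
    stop("parent of out_dir does not exist: ", cfg$out_dir, call. = FALSE)
  class(cfg) <- c("dyad_config", "list")
  cfg
}

truth_from_config <- function(cfg) {
  ctr <- cfg$grid / 2
  sync_ground_truth(
    grid_shape = cfg$grid, voxel_mm = cfg$voxel_mm,
    task_sync_mask = make_blob_mask(cfg$grid, ctr * 0.5,
                                    cfg$task_mask_voxels),
    residual_sync_mask = make_blob_mask(cfg$grid, ctr * 1.5,
                                        cfg$residual_mask_voxels),
    coupling_task = cfg$coupling_task,
    coupling_residual = cfg$coupling_residual,
    ar1_phi = cfg$ar1_phi, noise_sd = cfg$noise_sd,
    drift_amp = cfg$drift_amp, amp_mean = cfg$amp_mean,
    amp_sd = cfg$amp_sd, verify_amp = cfg$verify_amp)
}

# ---------------------------------------------------------------------------
# Fast fused trial-wise fit used by the pipeline's streaming sync stage.
# Produces exactly what fit_glm() produces (tested for agreement) but shares
# the high-pass filtering between the whitened (betas) and unwhitened
# (residuals) fits, caches the filtered design across calls, and skips
# whitened residual assembly.

trialwise_cache <- function(dm) {
  basis <- dct_highpass_basis(dm$n_volumes, dm$tr_s, dm$cutoff_s)
  xf <- hp_filter_time(dm$X, list(basis), dm$blocks, time_in_cols = FALSE)
  kept <- which(sqrt(colSums(xf^2)) > 1e-8 * sqrt(nrow(xf)))
  xf <- xf[, kept, drop = FALSE]
  qx <- qr(xf)
  int_cols <- match(dm$interest_idx, kept)
  nuis_cols <- setdiff(seq_len(ncol(xf)), int_cols)
  x0 <- xf[, nuis_cols, drop = FALSE]
  q0 <- if (ncol(x0) > 0) qr(x0) else NULL
  df_resid <- nrow(xf) - ncol(basis) - ncol(xf)
  list(dm = dm, basis = basis, xf = xf, qx = qx, kept = kept,
       int_cols = int_cols, x0 = x0, q0 = q0, df_resid = df_resid,
       fthr_q = length(int_cols))
}

fit_trialwise_fast <- function(y, cache, whiten_beta = TRUE, pool_p = 0.001,
                               pool_max = 500L) {
  yf <- y - (y %*% cache$basis) %*% t(cache$basis)
  betas0 <- t(qr.coef(cache$qx, t(yf)))
  res0 <- yf - betas0 %*% t(cache$xf)
  res0 <- res0 - rowMeans(res0)
  if (!whiten_beta)
    return(list(betas = betas0, residuals = res0, phi = 0,
                int_cols = cache$int_cols))
  rss1 <- rowSums(res0^2)
  rss0 <- if (!is.null(cache$q0)) {
    b0 <- t(qr.coef(cache$q0, t(yf)))
    rowSums((yf - b0 %*% t(cache$x0))^2)
  } else rowSums(yf^2)
  q <- cache$fthr_q
  fstat <- ((rss0 - rss1) / q) / (rss1 / cache$df_resid)
  pool <- which(fstat > qf(0.999, q, cache$df_resid) & rss1 > 1e-12)
  if (length(pool) < 2L) pool <- which(rss1 > 1e-12)
  if (length(pool) > pool_max)
    pool <- pool[round(seq(1, length(pool), length.out = pool_max))]
  phi <- estimate_ar1_reml(yf[pool, , drop = FALSE], cache$xf,
                           blocks = list(seq_len(ncol(yf))))
  blocks <- list(seq_len(ncol(yf)))
  yw <- ar1_whiten(yf, phi, blocks, time_in_cols = TRUE)
  xw <- ar1_whiten(cache$xf, phi, blocks, time_in_cols = FALSE)
  betas1 <- t(qr.coef(qr(xw), t(yw)))
  list(betas = betas1, residuals = res0, phi = phi,
       int_cols = cache$int_cols)
}

# Standardise rows to zero mean / unit sum of squares so that a row dot
# product is a Pearson correlation. Zero-variance rows become NaN.
row_standardize <- function(m) {
  mu <- rowMeans(m)
  m <- m - mu
  ss <- sqrt(rowSums(m^2))
  m / ss
}

#' Run the full synthetic hyperscanning pipeline
#'
#' Executes synthesis, first-level fitting, inter-brain correlation and
#' group inference for a whole cohort: per pair, a counterbalanced session
#' design and paired BOLD runs with the configured coupling ground truth;
#' per participant-run, trial-wise GLMs (AR(1)-prewhitened for beta
#' estimation, unwhitened for residual extraction); beta series over the
#' canonically reordered JA runs and per-run residual series; voxelwise
#' Fisher-z correlation maps for all real and all `P(P-1)` pseudo pairs;
#' and, per analysis type (beta series, JA residual, control residual), a
#' Welch real-vs-pseudo t map with permutation cluster-FWE correction.
#' Optionally also fits the condition-wise GLM and computes the predefined
#' session contrasts, their one-sample group maps and the two conjunction
#' maps.
#'
#' Runs are simulated deterministically from the master seed and re-derived
#' on demand rather than held in memory, so the memory footprint stays at a
#' few participant-runs regardless of cohort size.
#'
#' @param config a [validate_config()]-acceptable configuration.
#' @return a manifest (class `dyad_manifest`): configuration snapshot,
#'   stage timings, per-analysis group results (`group_tmap`s and
#'   `cluster_table`s), summary statistics, ground truth, and — when
#'   `out_dir` is set — a table of written artifacts with MD5 hashes.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  t_start <- Sys.time()
  timings <- c()
  tick <- function(label, t0) {
    timings[[label]] <<- round(as.numeric(Sys.time()) - as.numeric(t0), 3)
  }

  t0 <- Sys.time()
  truth <- truth_from_config(cfg)
  p_n <- cfg$pairs
  designs <- lapply(seq_len(p_n), function(p)
    generate_design(split_seed(cfg$seed, 7, p),
                    pair_id = sprintf("pair%02d", p), tr_s = cfg$tr_s,
                    n_volumes = cfg$n_volumes, lead_in_s = cfg$lead_in_s,
                    control_block = cfg$control_block))
  pair_seeds <- vapply(seq_len(p_n), function(p) split_seed(cfg$seed, 8, p), 1L)
  tick("design", t0)

  # pair bookkeeping: rows = real pairs then exhaustively enumerated pseudo
  real_tab <- data.frame(member_a = seq_len(p_n), member_b = seq_len(p_n),
                         pair_type = "real")
  pseudo_tab <- enumerate_pseudo_pairs(seq_len(p_n))
  all_tab <- rbind(real_tab, pseudo_tab)
  n_all <- nrow(all_tab)

  dm_trial <- build_design(designs[[1]], "a", "trialwise", run_index = 1L,
                           cutoff_s = cfg$glm$cutoff_s)
  cache <- trialwise_cache(dm_trial)
  nvox <- prod(cfg$grid)

  # canonical slot order: fJA1 fJA2 sJA1 sJA2 control1 control2
  canonical_runs <- function(d) c(which(d$run_order == "fJA"),
                                  which(d$run_order == "sJA"),
                                  which(d$run_order == "control"))

  t0 <- Sys.time()
  do_beta <- "beta" %in% cfg$sync$analyses
  do_resid <- "residual" %in% cfg$sync$analyses
  betas_a <- if (do_beta) vector("list", p_n)
  betas_b <- if (do_beta) vector("list", p_n)
  z_beta <- if (do_beta) matrix(NA_real_, nvox, n_all)
  z_res_ja <- if (do_resid) matrix(0, nvox, n_all)
  z_res_ctrl <- if (do_resid) matrix(0, nvox, n_all)
  phis <- c()

  for (slot in seq_len(6L)) {
    is_ja_slot <- slot <= 4L
    res_a <- vector("list", p_n)
    res_b <- vector("list", p_n)
    for (p in seq_len(p_n)) {
      run_idx <- canonical_runs(designs[[p]])[slot]
      sim <- simulate_run(designs[[p]], truth, pair_seeds[p], run_idx)
      for (member in c("a", "b")) {
        y <- sim[[member]]$data
        if (cfg$smooth_fwhm_mm > 0)
          y <- smooth_gaussian(sim[[member]], cfg$smooth_fwhm_mm)$data
        fit <- fit_trialwise_fast(
          y, cache,
          whiten_beta = is_ja_slot && do_beta &&
            cfg$glm$whiten_beta == "ar1",
          pool_max = cfg$glm$pool_max)
        if (is_ja_slot && do_beta) {
          phis <- c(phis, fit$phi)
          bm <- fit$betas[, fit$int_cols, drop = FALSE]
          if (member == "a") {
            if (is.null(betas_a[[p]])) betas_a[[p]] <-
                matrix(NA_real_, nvox, 4L * TRIALS_PER_RUN)
            betas_a[[p]][, (slot - 1L) * TRIALS_PER_RUN + seq_len(TRIALS_PER_RUN)] <- bm
          } else {
            if (is.null(betas_b[[p]])) betas_b[[p]] <-
                matrix(NA_real_, nvox, 4L * TRIALS_PER_RUN)
            betas_b[[p]][, (slot - 1L) * TRIALS_PER_RUN + seq_len(TRIALS_PER_RUN)] <- bm
          }
        }
        if (do_resid) {
          sr <- row_standardize(fit$residuals)
          if (member == "a") res_a[[p]] <- sr else res_b[[p]] <- sr
        }
      }
    }
    if (do_resid) {
      for (i in seq_len(n_all)) {
        r <- row_dot_cpp(res_a[[all_tab$member_a[i]]],
                         res_b[[all_tab$member_b[i]]])
        r[!is.finite(r)] <- NA_real_
        z <- if (cfg$sync$fisher) fisher_z(r) else r
        if (is_ja_slot) z_res_ja[, i] <- z_res_ja[, i] + z / 4
        else z_res_ctrl[, i] <- z_res_ctrl[, i] + z / 2
      }
    }
  }
  if (do_beta) {
    sa <- lapply(betas_a, row_standardize)
    sb <- lapply(betas_b, row_standardize)
    for (i in seq_len(n_all)) {
      r <- row_dot_cpp(sa[[all_tab$member_a[i]]], sb[[all_tab$member_b[i]]])
      r[!is.finite(r)] <- NA_real_
      z_beta[, i] <- if (cfg$sync$fisher) fisher_z(r) else r
    }
  }
  tick("first_level_and_sync", t0)

  t0 <- Sys.time()
  real_idx <- which(all_tab$pair_type == "real")
  pseudo_idx <- which(all_tab$pair_type == "pseudo")
  analyses <- list()
  zmaps <- list()
  if (do_beta) zmaps$beta_series <- z_beta
  if (do_resid) {
    zmaps$residual_ja <- z_res_ja
    zmaps$residual_control <- z_res_ctrl
  }
  for (k in seq_along(zmaps)) {
    nm <- names(zmaps)[k]
    zr <- zmaps[[k]][, real_idx, drop = FALSE]
    zp <- zmaps[[k]][, pseudo_idx, drop = FALSE]
    tmap <- welch_two_sample_t(zr, zp, dim = cfg$grid)
    tmap$analysis <- nm
    ct <- cluster_fwe(tmap, list(real = zr, pseudo = zp),
                      type = "two_sample", height_p = cfg$group$height_p,
                      alpha = cfg$group$alpha, n_perm = cfg$group$n_perm,
                      seed = split_seed(cfg$seed, 9, k),
                      connectivity = cfg$group$connectivity,
                      method = cfg$group$method)
    analyses[[nm]] <- list(tmap = tmap, clusters = ct,
                           mean_real_z = rowMeans(zr, na.rm = TRUE),
                           mean_pseudo_z = rowMeans(zp, na.rm = TRUE))
  }
  tick("group_sync", t0)

  contrasts_out <- NULL
  if (isTRUE(cfg$include_task_contrasts)) {
    t0 <- Sys.time()
    contrasts_out <- pipeline_task_contrasts(cfg, designs, truth, pair_seeds)
    tick("group_contrasts", t0)
  }

  summary <- list(
    n_pairs = p_n,
    n_pseudo_pairs = nrow(pseudo_tab),
    n_trials_per_session = nrow(designs[[1]]$trials),
    ar1_phi_mean = if (length(phis)) mean(phis) else NA_real_,
    analyses = lapply(analyses, function(a)
      list(n_clusters = nrow(a$clusters),
           n_significant = sum(a$clusters$significant),
           min_p_fwe = if (nrow(a$clusters)) min(a$clusters$p_fwe) else NA_real_,
           max_t = max(a$tmap$t, na.rm = TRUE))))

  manifest <- structure(list(
    config = cfg, truth = truth,
    package_version = as.character(packageVersion("dyadsync")),
    r_version = R.version.string,
    created = format(t_start, "%Y-%m-%d %H:%M:%S"),
    timings_s = timings,
    analyses = analyses,
    contrasts = contrasts_out,
    summary = summary,
    outputs = NULL), class = "dyad_manifest")

  if (!is.null(cfg$out_dir)) manifest <- write_artifacts(manifest, cfg)
  manifest
}

# Condition-wise GLM, predefined contrasts, one-sample group maps,
# conjunctions, and a permutation cluster table for the main effect of JA.
pipeline_task_contrasts <- function(cfg, designs, truth, pair_seeds) {
  tab <- ja_contrast_table()
  nvox <- prod(cfg$grid)
  cmats <- lapply(tab$contrasts, function(w)
    matrix(NA_real_, nvox, 2L * cfg$pairs))
  col <- 0L
  for (p in seq_len(cfg$pairs)) {
    sim <- simulate_pair(designs[[p]], truth, pair_seeds[p])
    for (member in c("a", "b")) {
      col <- col + 1L
      dm <- build_design(designs[[p]], member, "condition",
                         cutoff_s = cfg$glm$cutoff_s)
      fit <- fit_glm(sim[[member]], dm, whiten = cfg$glm$whiten_beta,
                     pool_max = cfg$glm$pool_max)
      fit$dim <- cfg$grid
      for (cn in names(tab$contrasts))
        cmats[[cn]][, col] <- compute_contrast(fit, tab$contrasts[[cn]])$values
    }
  }
  tmaps <- lapply(cmats, one_sample_t, dim = cfg$grid)
  for (nm in names(tmaps)) tmaps[[nm]]$analysis <- nm
  conj <- lapply(ja_contrast_table()$conjunctions, function(members)
    conjunction(tmaps[members], height_p = cfg$group$height_p))
  main_ct <- cluster_fwe(tmaps$main_effect_JA, cmats$main_effect_JA,
                         type = "one_sample", height_p = cfg$group$height_p,
                         alpha = cfg$group$alpha,
                         n_perm = cfg$contrast_n_perm,
                         seed = split_seed(cfg$seed, 11),
                         connectivity = cfg$group$connectivity)
  list(tmaps = tmaps, conjunctions = conj, main_effect_clusters = main_ct)
}

write_artifacts <- function(manifest, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  aff <- mni_like_affine(cfg$grid, cfg$voxel_mm)
  save_map <- function(v, name) {
    f <- file.path(cfg$out_dir, name)
    write_map_nifti(v, f, dim = cfg$grid, affine = aff)
    paths <<- c(paths, f)
  }
  save_map(manifest$truth$task_sync_mask, "task_sync_mask.nii")
  save_map(manifest$truth$residual_sync_mask, "residual_sync_mask.nii")
  for (nm in names(manifest$analyses)) {
    a <- manifest$analyses[[nm]]
    tv <- a$tmap$t
    tv[is.na(tv)] <- 0
    save_map(tv, paste0("tmap_", nm, ".nii"))
    f <- file.path(cfg$out_dir, paste0("clusters_", nm, ".csv"))
    write.table(as.data.frame(a$clusters), f, sep = ",", row.names = FALSE,
                quote = FALSE)
    paths <- c(paths, f)
  }
  mf <- file.path(cfg$out_dir, "manifest.json")
  slim <- manifest[c("package_version", "r_version", "created", "timings_s",
                     "summary")]
  slim$config <- manifest$config[setdiff(names(manifest$config), "out_dir")]
  jsonlite::write_json(slim, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, mf)
  manifest$outputs <- data.frame(path = paths,
                                 md5 = unname(tools::md5sum(paths)),
                                 stringsAsFactors = FALSE)
  manifest
}

#' Summarise a pipeline run as a key-value report
#'
#' Flat report of design counts, pair counts (real and pseudo), pooled
#' AR(1) estimates and per-analysis cluster results; optionally written as
#' CSV.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @param path optional CSV output path.
#' @return data.frame with columns `key` and `value` (invisibly when
#'   written to `path`).
#' @export
write_report <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "dyad_manifest"))
  s <- manifest$summary
  rows <- list(
    c("pairs", s$n_pairs),
    c("pseudo_pairs", s$n_pseudo_pairs),
    c("trials_per_session", s$n_trials_per_session),
    c("ar1_phi_mean", signif(s$ar1_phi_mean, 4)))
  for (nm in names(s$analyses)) {
    a <- s$analyses[[nm]]
    rows <- c(rows, list(
      c(paste0(nm, "_clusters"), a$n_clusters),
      c(paste0(nm, "_significant_clusters"), a$n_significant),
      c(paste0(nm, "_min_p_fwe"), signif(a$min_p_fwe, 4))))
  }
  df <- data.frame(key = vapply(rows, `[`, "", 1),
                   value = vapply(rows, `[`, "", 2),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.dyad_manifest <- function(x, ...) {
  s <- x$summary
  cat("dyadsync pipeline run (", x$created, ")\n", sep = "")
  cat("  pairs:", s$n_pairs, " pseudo pairs:", s$n_pseudo_pairs, "\n")
  cat("  mean AR(1) phi:", round(s$ar1_phi_mean, 3), "\n")
  for (nm in names(s$analyses)) {
    a <- s$analyses[[nm]]
    cat(sprintf("  %-18s clusters: %d significant: %d min p_FWE: %s\n",
                nm, a$n_clusters, a$n_significant,
                format(a$min_p_fwe, digits = 3)))
  }
  invisible(x)
}
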