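#' Conditions, phase timing and trial arithmetic of the dyadic JA experiment
#'
#' A session has six runs — two feature-based joint-attention (fJA) runs, two
#' spatial joint-attention (sJA) runs and two solo control runs — in a seeded
#' counterbalanced order. Every run holds 32 contiguous 12.5 s trials
#' (fixation 2.5 s, role assignment 2.5 s, cue-response 2.5 s, fixation 2.5 s,
#' verify 2.5 s; no inter-trial jitter), 192 trials per session. Within each
#' JA run the two partners swap initiator/responder roles pseudo-randomly but
#' evenly (16 trials in each role); control runs alternate feature (fCTRL)
#' and spatial (sCTRL) solo trials in blocks, 16 of each.
#'
#' @name ja_design
NULL

JA_PHASES <- c(fixation1 = 2.5, role = 2.5, cue = 2.5, fixation2 = 2.5, verify = 2.5)
TRIAL_DUR_S <- sum(JA_PHASES)            # 12.5 s
TRIALS_PER_RUN <- 32L
JA_CONDITIONS <- c("fIJA", "fRJA", "sIJA", "sRJA", "fCTRL", "sCTRL")

#' Generate a dyadic joint-attention session design
#'
#' @param seed integer seed controlling run order and role sequences.
#' @param pair_id identifier for the pair (default `"pair01"`).
#' @param tr_s repetition time in seconds (default 2.5).
#' @param n_volumes volumes acquired per run (default 175).
#' @param lead_in_s rest before the first trial, seconds (default 20; the
#'   32 x 12.5 s = 400 s of trials plus lead-in must fit in the run).
#' @param control_block trials per alternating control block (default 4,
#'   i.e. eight alternating blocks, fCTRL first).
#' @return an object of class `ja_design`: run order plus a per-trial table
#'   with onsets, the role of participant A, and both participants'
#'   condition labels (complementary within a JA trial: fIJA pairs with
#'   fRJA, sIJA with sRJA; control trials are identical for both).
#' @export
generate_design <- function(seed, pair_id = "pair01", tr_s = 2.5,
                            n_volumes = 175L, lead_in_s = 20,
                            control_block = 4L) {
  stopifnot(TRIALS_PER_RUN %% (2L * control_block) == 0)
  run_len <- n_volumes * tr_s
  if (lead_in_s + TRIALS_PER_RUN * TRIAL_DUR_S > run_len)
    stop("trials do not fit in the run: reduce lead_in_s", call. = FALSE)

  set.seed(split_seed(seed, 1))
  run_order <- sample(c("fJA", "fJA", "sJA", "sJA", "control", "control"))

  trials <- vector("list", 6L)
  for (r in seq_len(6L)) {
    task <- run_order[r]
    ti <- seq_len(TRIALS_PER_RUN) - 1L
    onset <- lead_in_s + ti * TRIAL_DUR_S
    if (task == "control") {
      kind <- rep(rep(c("fCTRL", "sCTRL"), each = control_block),
                  length.out = TRIALS_PER_RUN)
      df <- data.frame(run_index = r, trial_index = ti, onset_s = onset,
                       task = task, role_a = "solo",
                       condition_a = kind, condition_b = kind,
                       stringsAsFactors = FALSE)
    } else {
      set.seed(split_seed(seed, 2, r))
      role_a <- sample(rep(c("initiator", "responder"), each = TRIALS_PER_RUN / 2L))
      pref <- if (task == "fJA") "f" else "s"
      cond_a <- ifelse(role_a == "initiator", paste0(pref, "IJA"), paste0(pref, "RJA"))
      cond_b <- ifelse(role_a == "initiator", paste0(pref, "RJA"), paste0(pref, "IJA"))
      df <- data.frame(run_index = r, trial_index = ti, onset_s = onset,
                       task = task, role_a = role_a,
                       condition_a = cond_a, condition_b = cond_b,
                       stringsAsFactors = FALSE)
    }
    trials[[r]] <- df
  }
  out <- list(pair_id = pair_id, seed = seed, tr_s = tr_s,
              n_volumes = as.integer(n_volumes), lead_in_s = lead_in_s,
              run_order = run_order, trials = do.call(rbind, trials))
  class(out) <- "ja_design"
  out
}

#' @export
print.ja_design <- function(x, ...) {
  cat("Dyadic JA session design (", x$pair_id, ")\n", sep = "")
  cat("  runs:", paste(x$run_order, collapse = " "), "\n")
  cat("  trials:", nrow(x$trials), " TR:", x$tr_s, "s  volumes/run:",
      x$n_volumes, "\n")
  invisible(x)
}

# Per-participant view of the trial table ("a" or "b").
design_events <- function(design, participant = c("a", "b")) {
  participant <- match.arg(participant)
  tr <- design$trials
  cond <- if (participant == "a") tr$condition_a else tr$condition_b
  role <- if (participant == "a") tr$role_a else
    ifelse(tr$role_a == "solo", "solo",
           ifelse(tr$role_a == "initiator", "responder", "initiator"))
  data.frame(onset = tr$onset_s, duration = TRIAL_DUR_S, condition = cond,
             role = role, trial_index = tr$trial_index,
             run_index = tr$run_index, stringsAsFactors = FALSE)
}

#' Write / read a per-participant events table
#'
#' Tab-separated, one row per trial across the whole session, with header
#' `onset duration condition role trial_index run_index` (seconds; 0-based
#' trial index; 1-based run index). A write/read round trip reproduces the
#' table exactly.
#'
#' @param design a [generate_design()] object.
#' @param path file path.
#' @param participant `"a"` or `"b"`: whose condition labels to write.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the events `data.frame`.
#' @export
write_events_tsv <- function(design, path, participant = c("a", "b")) {
  ev <- design_events(design, match.arg(participant))
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "condition", "role", "trial_index", "run_index")
  if (!all(need %in% names(ev)))
    stop("malformed events file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!ev$condition %in% JA_CONDITIONS))
    stop("malformed events file: unknown condition label", call. = FALSE)
  ev[, need]
}
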