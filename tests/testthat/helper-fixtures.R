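# Shared fixture builders: all synthetic, generated in code at test time.

tiny_grid <- c(8L, 8L, 8L)

tiny_truth <- function(...) {
  sync_ground_truth(
    grid_shape = tiny_grid, voxel_mm = 3,
    task_sync_mask = make_blob_mask(tiny_grid, c(3, 3, 3), 10L),
    residual_sync_mask = make_blob_mask(tiny_grid, c(6, 6, 6), 10L),
    ...)
}

# A short-run design for fast GLM tests (fewer volumes than the study run;
# trials still fit: 32 x 12.5 s + lead-in 10 s = 410 s <= 168 x 2.5 s).
short_design <- function(seed = 1, n_volumes = 168L, lead_in_s = 10) {
  generate_design(seed, n_volumes = n_volumes, lead_in_s = lead_in_s)
}

# Flood-fill connected-components oracle in plain R (BFS over an explicit
# neighbour table) — independent of the C++ labelling implementation.
label_clusters_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  if (connectivity == 6) nbr <- nbr[rowSums(abs(nbr)) == 1, , drop = FALSE]
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (j in seq_len(nrow(nbr))) {
        w <- cur + nbr[j, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  lab
}
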