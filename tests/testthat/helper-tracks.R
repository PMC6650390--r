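# Build a track data.frame from a position matrix.
make_track <- function(pos, dt = 2, cell_id = 1L, cell_type = "NK",
                       t0 = 0) {
  pos <- as.matrix(pos)
  data.frame(cell_id = cell_id, cell_type = cell_type,
             frame = seq_len(nrow(pos)),
             t_min = t0 + (seq_len(nrow(pos)) - 1) * dt,
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
             stringsAsFactors = FALSE)
}

# Pure 3D Brownian track (no boundaries), per-axis step variance 2*M*dt.
brownian_track <- function(n, M, dt = 2, cell_id = 1L, start = c(0, 0, 0)) {
  steps <- matrix(rnorm(3 * (n - 1), sd = sqrt(2 * M * dt)), ncol = 3)
  pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, -start))
  make_track(pos, dt = dt, cell_id = cell_id)
}

# Naive double-loop MSD used as an independent oracle.
msd_naive <- function(p, max_lag) {
  p <- as.matrix(p)
  N <- nrow(p)
  out <- numeric(max_lag)
  for (n in seq_len(max_lag)) {
    acc <- 0
    for (i in seq_len(N - n)) {
      acc <- acc + sum((p[i + n, ] - p[i, ])^2)
    }
    out[n] <- acc / (N - n)
  }
  out
}

# Brute-force contact episodes: all pairs, all frames, strict radius,
# no gap merging.
contacts_brute <- function(nk_tracks, target_tracks, radius, dt) {
  out <- list()
  for (ni in unique(nk_tracks$cell_id)) for (ti in unique(target_tracks$cell_id)) {
    nk <- nk_tracks[nk_tracks$cell_id == ni, ]
    tg <- target_tracks[target_tracks$cell_id == ti, ]
    common <- sort(intersect(nk$frame, tg$frame))
    inc <- logical(0)
    for (f in common) {
      a <- as.numeric(nk[nk$frame == f, c("x_um", "y_um", "z_um")])
      b <- as.numeric(tg[tg$frame == f, c("x_um", "y_um", "z_um")])
      inc <- c(inc, sqrt(sum((a - b)^2)) < radius)
    }
    if (!any(inc)) next
    r <- rle(inc)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      out[[length(out) + 1L]] <- data.frame(
        nk_id = ni, target_id = ti,
        start_frame = common[starts[k]], end_frame = common[ends[k]])
    }
  }
  if (length(out) == 0L)
    return(data.frame(nk_id = integer(), target_id = integer(),
                      start_frame = integer(), end_frame = integer()))
  res <- do.call(rbind, out)
  res[order(res$nk_id, res$target_id, res$start_frame), ]
}
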