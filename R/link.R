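#' Linking configuration
#'
#' Parameters of the frame-to-frame probabilistic linker. A candidate link
#' between a track end and a detection in the next frame is scored by the
#' log-density of an anisotropic Gaussian motion model (the cell's next
#' position is Gaussian around its previous one, with standard deviation
#' `sigma_xy` voxels laterally and `sigma_z` voxels axially), plus the log
#' odds of the detection holding exactly one cell. Unlinked detections and
#' track ends pay `log(p_appear)` / `log(p_disappear)`. The per-frame-pair
#' assignment maximising the summed log-score is found exactly.
#'
#' @param sigma_xy,sigma_z motion-model standard deviations in voxels.
#' @param p_count_0,p_count_1,p_count_2plus prior probabilities that a
#'   segmented object holds 0, 1, or 2+ cells (must sum to 1).
#' @param p_appear,p_disappear probabilities of random appearance and
#'   disappearance of a cell between frames.
#' @param p_death,p_division track death and division probabilities (kept
#'   at 0: no gap closing, no mitosis).
#' @return An object of class `linking_config`.
#' @export
linking_config <- function(sigma_xy = 6, sigma_z = 0.5,
                           p_count_0 = 0.2, p_count_1 = 0.7,
                           p_count_2plus = 0.1,
                           p_appear = 0.001, p_disappear = 0.001,
                           p_death = 0, p_division = 0) {
  cfg <- list(sigma_xy = sigma_xy, sigma_z = sigma_z,
              p_count_0 = p_count_0, p_count_1 = p_count_1,
              p_count_2plus = p_count_2plus,
              p_appear = p_appear, p_disappear = p_disappear,
              p_death = p_death, p_division = p_division)
  pr <- unlist(cfg[3:9])
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]",
                                 call. = FALSE)
  if (abs(cfg$p_count_0 + cfg$p_count_1 + cfg$p_count_2plus - 1) > 1e-9)
    stop("count probabilities must sum to 1", call. = FALSE)
  if (cfg$sigma_xy <= 0 || cfg$sigma_z <= 0)
    stop("motion sigmas must be > 0", call. = FALSE)
  class(cfg) <- "linking_config"
  cfg
}

# Exact solver for the rectangular assignment problem (minimise total
# cost) by the Jonker-Volgenant shortest-augmenting-path method. `cost`
# may contain Inf for forbidden pairings as long as a finite-cost perfect
# matching exists. Returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)          # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  BIG <- 1e9 + max(0, max(cost[is.finite(cost)]))
  cost[!is.finite(cost)] <- BIG
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking of detections from one channel under the
#' anisotropic Gaussian motion model. For each consecutive frame pair the
#' bipartite assignment maximising the summed link log-scores is solved
#' exactly; a link may also be rejected in favour of terminating the track
#' (`log p_disappear`) and starting a new one (`log p_appear`). There is
#' no gap closing: a missed detection ends the track and a new track
#' starts when the cell reappears.
#'
#' @param detections data.frame with columns `frame`, `x_um`, `y_um`,
#'   `z_um` (one channel; filter by channel first), optionally `t_min`.
#' @param cfg a [linking_config()].
#' @param voxel_size um per voxel `c(x, y, z)`, used to express the motion
#'   model (whose sigmas are in voxels) in micrometres.
#' @param dt frame interval in minutes (for the output `t_min` column when
#'   absent from the input).
#' @return data.frame of tracked positions: `cell_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`, `z_um`.
#' @export
link_tracks <- function(detections, cfg = linking_config(),
                        voxel_size = c(1.1, 1.1, 8), dt = 2) {
  stopifnot(inherits(cfg, "linking_config"))
  if (nrow(detections) == 0L) stop("empty detection list", call. = FALSE)
  if (is.null(detections$t_min))
    detections$t_min <- (detections$frame - 1) * dt
  frames <- sort(unique(detections$frame))
  sig_um <- c(cfg$sigma_xy * voxel_size[1], cfg$sigma_xy * voxel_size[2],
              cfg$sigma_z * voxel_size[3])
  # score of accepting a detection as one real cell vs noise
  one_cell_bonus <- log(cfg$p_count_1) -
    log(max(cfg$p_count_0, .Machine$double.eps))
  log_appear <- log(max(cfg$p_appear, .Machine$double.eps))
  log_disappear <- log(max(cfg$p_disappear, .Machine$double.eps))

  det_by_frame <- split(seq_len(nrow(detections)), detections$frame)
  next_id <- 0L
  track_id <- rep(NA_integer_, nrow(detections))
  first <- det_by_frame[[as.character(frames[1])]]
  track_id[first] <- next_id + seq_along(first)
  next_id <- next_id + length(first)
  active <- first  # row indices of current track ends

  for (fi in seq_along(frames)[-1]) {
    cur <- det_by_frame[[as.character(frames[fi])]]
    if (is.null(cur)) {
      active <- integer()
      next
    }
    gap <- frames[fi] - frames[fi - 1L]
    if (length(active) == 0L || gap != 1L) {
      track_id[cur] <- next_id + seq_along(cur)
      next_id <- next_id + length(cur)
      active <- cur
      next
    }
    na <- length(active)
    nb <- length(cur)
    A <- as.matrix(detections[active, c("x_um", "y_um", "z_um")])
    B <- as.matrix(detections[cur, c("x_um", "y_um", "z_um")])
    link_score <- matrix(0, na, nb)
    for (ax in 1:3) {
      dlt <- outer(A[, ax], B[, ax], "-")
      link_score <- link_score +
        stats::dnorm(dlt, sd = sig_um[ax], log = TRUE)
    }
    link_score <- link_score + one_cell_bonus
    # maximisation as min-cost assignment on an (na+nb) square matrix:
    # dummy columns = disappearance, dummy rows = appearance
    n <- na + nb
    costm <- matrix(-(log_appear + log_disappear), n, n)
    costm[seq_len(na), seq_len(nb)] <- -link_score
    costm[seq_len(na), nb + seq_len(na)] <- Inf
    for (i in seq_len(na)) costm[i, nb + i] <- -log_disappear
    costm[na + seq_len(nb), seq_len(nb)] <- Inf
    costm[na + seq_len(nb), nb + seq_len(na)] <- 0
    for (j in seq_len(nb)) costm[na + j, j] <- -log_appear
    sol <- solve_assignment(costm)
    for (i in seq_len(na)) {
      j <- sol[i]
      if (j <= nb) track_id[cur[j]] <- track_id[active[i]]
    }
    new_rows <- cur[is.na(track_id[cur])]
    if (length(new_rows)) {
      track_id[new_rows] <- next_id + seq_along(new_rows)
      next_id <- next_id + length(new_rows)
    }
    active <- cur
  }
  out <- data.frame(cell_id = track_id[!is.na(track_id)],
                    frame = detections$frame[!is.na(track_id)],
                    t_min = detections$t_min[!is.na(track_id)],
                    x_um = detections$x_um[!is.na(track_id)],
                    y_um = detections$y_um[!is.na(track_id)],
                    z_um = detections$z_um[!is.na(track_id)])
  out <- out[order(out$cell_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Fraction of matched track points within a distance tolerance
#'
#' Pairs every track of `a` (the estimated set) with the track of `b`
#' (the reference set) sharing the greatest number of frames, ties broken
#' by the smallest mean centre distance, and reports the fraction of
#' paired time points whose centre-to-centre distance is at most `tol`
#' micrometres. Several fragments of `a` may map to one reference track
#' (broken tracks are scored on the frames they cover); time points
#' without a counterpart are excluded from the denominator. Used to score
#' tracking accuracy against ground truth or manual tracks.
#'
#' @param a estimated track table (`cell_id`, `frame`, `x_um`, `y_um`,
#'   `z_um`).
#' @param b reference track table with the same columns and time base.
#' @param tol distance tolerance in um (default 2, about a quarter of a
#'   cell diameter).
#' @return Fraction in `[0, 1]`.
#' @export
compare_track_sets <- function(a, b, tol = 2) {
  ta <- split(a, a$cell_id)
  tb <- split(b, b$cell_id)
  if (length(ta) == 0L || length(tb) == 0L)
    stop("no temporal overlap between track sets", call. = FALSE)
  ov <- matrix(0L, length(ta), length(tb))
  md <- matrix(Inf, length(ta), length(tb))
  for (i in seq_along(ta)) for (j in seq_along(tb)) {
    common <- intersect(ta[[i]]$frame, tb[[j]]$frame)
    ov[i, j] <- length(common)
    if (length(common) > 0L) {
      pa <- ta[[i]][match(common, ta[[i]]$frame), c("x_um", "y_um", "z_um")]
      pb <- tb[[j]][match(common, tb[[j]]$frame), c("x_um", "y_um", "z_um")]
      md[i, j] <- mean(sqrt(rowSums((pa - pb)^2)))
    }
  }
  if (all(ov == 0L)) stop("no temporal overlap between track sets",
                          call. = FALSE)
  # each estimated track maps to the reference track of greatest temporal
  # overlap; ties broken by the smallest mean centre distance
  n_ok <- 0L
  n_tot <- 0L
  for (i in seq_along(ta)) {
    if (all(ov[i, ] == 0L)) next
    best <- which(ov[i, ] == max(ov[i, ]))
    j <- best[which.min(md[i, best])]
    fa <- ta[[i]]
    fb <- tb[[j]]
    common <- intersect(fa$frame, fb$frame)
    pa <- fa[match(common, fa$frame), c("x_um", "y_um", "z_um")]
    pb <- fb[match(common, fb$frame), c("x_um", "y_um", "z_um")]
    d <- sqrt(rowSums((pa - pb)^2))
    n_ok <- n_ok + sum(d <= tol)
    n_tot <- n_tot + length(common)
  }
  if (n_tot == 0L) stop("no temporal overlap between paired tracks",
                        call. = FALSE)
  n_ok / n_tot
}
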