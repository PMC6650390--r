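#' Contact analysis configuration
#'
#' @param contact_radius centre-to-centre distance (um) strictly below
#'   which an NK and a target cell are in contact (default 20).
#' @param gap_tolerance number of consecutive non-contact frames bridged
#'   when merging contact runs (default 0: no merging).
#' @param death_attribution_window minutes after the end of a contact
#'   episode during which a target death is still attributed to it.
#' @param death_intensity_fraction fraction of the running baseline below
#'   which a target's fluorescence counts as lost.
#' @param death_min_frames consecutive low-intensity frames required to
#'   call death.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(contact_radius = 20, gap_tolerance = 0L,
                           death_attribution_window = 30,
                           death_intensity_fraction = 0.5,
                           death_min_frames = 3L) {
  cfg <- list(contact_radius = contact_radius,
              gap_tolerance = as.integer(gap_tolerance),
              death_attribution_window = death_attribution_window,
              death_intensity_fraction = death_intensity_fraction,
              death_min_frames = as.integer(death_min_frames))
  if (cfg$contact_radius <= 0) stop("'contact_radius' must be > 0",
                                    call. = FALSE)
  if (cfg$gap_tolerance < 0L || cfg$death_attribution_window < 0)
    stop("tolerances must be >= 0", call. = FALSE)
  f <- cfg$death_intensity_fraction
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop("'death_intensity_fraction' must lie in (0, 1)", call. = FALSE)
  if (cfg$death_min_frames < 1L) stop("'death_min_frames' must be >= 1",
                                      call. = FALSE)
  class(cfg) <- "contact_config"
  cfg
}

#' Detect NK-target contact episodes
#'
#' For every NK-target pair, finds maximal runs of frames in which the two
#' centres lie strictly closer than `contact_radius`; runs separated by at
#' most `gap_tolerance` frames (missing or beyond-radius) are merged.
#' Episode times are half-open: `end_min = t(last frame) + dt`, so a
#' single-frame episode has duration `dt`.
#'
#' @param nk_tracks,target_tracks track tables sharing the frame/time
#'   base.
#' @param cfg a [contact_config()].
#' @return data.frame of episodes: `nk_id`, `target_id`, `start_frame`,
#'   `end_frame`, `start_min`, `end_min`, `duration_min`.
#' @export
detect_contacts <- function(nk_tracks, target_tracks,
                            cfg = contact_config()) {
  stopifnot(inherits(cfg, "contact_config"))
  empty <- data.frame(nk_id = integer(), target_id = integer(),
                      start_frame = integer(), end_frame = integer(),
                      start_min = numeric(), end_min = numeric(),
                      duration_min = numeric())
  if (nrow(nk_tracks) == 0L || nrow(target_tracks) == 0L) return(empty)
  tt <- sort(unique(c(nk_tracks$t_min, target_tracks$t_min)))
  dt <- if (length(tt) > 1) min(diff(tt)) else 1
  out <- list()
  for (nk in split(nk_tracks, nk_tracks$cell_id)) {
    for (tg in split(target_tracks, target_tracks$cell_id)) {
      common <- intersect(nk$frame, tg$frame)
      if (length(common) == 0L) next
      common <- sort(common)
      pa <- nk[match(common, nk$frame), c("x_um", "y_um", "z_um")]
      pb <- tg[match(common, tg$frame), c("x_um", "y_um", "z_um")]
      close <- sqrt(rowSums((pa - pb)^2)) < cfg$contact_radius
      # map to the full frame axis so frame gaps count as non-contact
      frames_in <- common[close]
      if (length(frames_in) == 0L) next
      runs <- split_runs(frames_in, cfg$gap_tolerance)
      tmin_nk <- nk$t_min[match(common, nk$frame)]
      t_of_frame <- function(f) tmin_nk[match(f, common)]
      for (rn in runs) {
        s <- rn[1]
        e <- rn[length(rn)]
        out[[length(out) + 1L]] <- data.frame(
          nk_id = nk$cell_id[1], target_id = tg$cell_id[1],
          start_frame = s, end_frame = e,
          start_min = t_of_frame(s),
          end_min = t_of_frame(e) + dt,
          duration_min = t_of_frame(e) + dt - t_of_frame(s))
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Split a sorted integer vector into runs, merging gaps of at most
# `gap` missing values.
split_runs <- function(frames, gap = 0L) {
  brk <- which(diff(frames) > gap + 1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(frames))
  lapply(seq_along(starts), function(i) frames[starts[i]:ends[i]])
}

#' Call target death from a fluorescence intensity trace
#'
#' Death is called at the first frame where the intensity falls strictly
#' below `death_intensity_fraction` times its running pre-drop baseline
#' (the mean intensity over all frames before that point that were not
#' themselves below threshold) and stays below for at least
#' `death_min_frames` consecutive frames. Calcein leaks out of dying
#' cells, so a sustained loss of fluorescence marks death.
#'
#' @param trace data.frame with `frame`, `t_min`, `intensity` for one
#'   target.
#' @param cfg a [contact_config()].
#' @return data.frame with `death_frame`, `death_min` (one row) or `NULL`
#'   when no death is detected.
#' @export
detect_target_death <- function(trace, cfg = contact_config()) {
  stopifnot(inherits(cfg, "contact_config"))
  trace <- trace[order(trace$frame), ]
  n <- nrow(trace)
  if (n < cfg$death_min_frames)
    stop("trace shorter than 'death_min_frames'", call. = FALSE)
  inten <- trace$intensity
  baseline <- inten[1]
  n_base <- 1L
  k <- 2L
  while (k <= n) {
    if (inten[k] < cfg$death_intensity_fraction * baseline) {
      run_end <- k
      while (run_end < n &&
             inten[run_end + 1L] < cfg$death_intensity_fraction * baseline)
        run_end <- run_end + 1L
      if (run_end - k + 1L >= cfg$death_min_frames) {
        return(data.frame(death_frame = trace$frame[k],
                          death_min = trace$t_min[k]))
      }
      k <- run_end + 1L
    } else {
      baseline <- (baseline * n_base + inten[k]) / (n_base + 1L)
      n_base <- n_base + 1L
      k <- k + 1L
    }
  }
  NULL
}

#' Assign cytolytic outcomes to contact episodes
#'
#' An episode is cytolytic when its target's death time falls within
#' `[start, end + death_attribution_window]`. When several episodes of
#' one target qualify, the episode overlapping the death wins; otherwise
#' the one whose end most closely precedes the death. All other episodes
#' are non-cytolytic. Deaths attributable to no episode are reported
#' separately.
#'
#' @param episodes output of [detect_contacts()].
#' @param deaths data.frame with `target_id`, `death_min` (one row per
#'   dead target).
#' @param cfg a [contact_config()].
#' @return List with `episodes` (input plus `outcome`), `nk_tally`
#'   (`nk_id`, `contacts`, `kills`), `unattributed_deaths`.
#' @export
assign_outcomes <- function(episodes, deaths, cfg = contact_config()) {
  stopifnot(inherits(cfg, "contact_config"))
  episodes$outcome <- rep("non-cytolytic", nrow(episodes))
  unattributed <- integer()
  if (!is.null(deaths) && nrow(deaths) > 0) {
    for (r in seq_len(nrow(deaths))) {
      tgt <- deaths$target_id[r]
      tdeath <- deaths$death_min[r]
      cand <- which(episodes$target_id == tgt &
                    episodes$start_min <= tdeath &
                    tdeath <= episodes$end_min + cfg$death_attribution_window)
      if (length(cand) == 0L) {
        unattributed <- c(unattributed, tgt)
        next
      }
      overlapping <- cand[episodes$start_min[cand] <= tdeath &
                          tdeath <= episodes$end_min[cand]]
      winner <- if (length(overlapping) > 0) {
        # several conjugates at the moment of death: credit the longest
        # exposure (earliest onset), since kills are triggered at contact
        # onset and take effect after a delay
        overlapping[which.min(episodes$start_min[overlapping])]
      } else {
        prior <- cand[episodes$end_min[cand] <= tdeath]
        if (length(prior) > 0) prior[which.max(episodes$end_min[prior])]
        else cand[which.min(episodes$start_min[cand])]
      }
      episodes$outcome[winner] <- "cytolytic"
    }
  }
  tally <- if (nrow(episodes) > 0) {
    agg <- stats::aggregate(cbind(contacts = rep(1L, nrow(episodes)),
                                  kills = episodes$outcome == "cytolytic")
                            ~ nk_id, data = episodes, FUN = sum)
    agg$kills <- as.integer(agg$kills)
    agg
  } else data.frame(nk_id = integer(), contacts = integer(),
                    kills = integer())
  list(episodes = episodes, nk_tally = tally,
       unattributed_deaths = unique(unattributed))
}

#' Interaction summary statistics
#'
#' Contact and kill count distributions, episode-duration mean and sample
#' standard deviation, the cytolytic fraction, and a two-sided
#' Mann-Whitney U test comparing cytolytic versus non-cytolytic episode
#' durations (skipped with a notice when either group is empty).
#'
#' @param episodes episodes with an `outcome` column
#'   (see [assign_outcomes()]).
#' @param n_nk total number of tracked NK cells, for the fraction that
#'   ever contacted a target (`NA` if unknown).
#' @return List with `n_episodes`, `mean_duration_min`, `sd_duration_min`,
#'   `cytolytic_fraction`, `contacts_per_nk`, `kills_per_nk`,
#'   `frac_nk_with_contact`, `mw_p_value` (`NA` when skipped), `notes`.
#' @export
interaction_stats <- function(episodes, n_nk = NA_integer_) {
  if (nrow(episodes) == 0L) stop("no contact episodes", call. = FALSE)
  dur <- episodes$duration_min
  cyt <- episodes$outcome == "cytolytic"
  notes <- character()
  p <- NA_real_
  if (any(cyt) && any(!cyt)) {
    p <- suppressWarnings(
      stats::wilcox.test(dur[cyt], dur[!cyt], exact = TRUE)$p.value)
  } else {
    notes <- "one outcome group empty; Mann-Whitney comparison skipped"
  }
  per_nk <- table(episodes$nk_id)
  kills_nk <- tapply(cyt, episodes$nk_id, sum)
  list(n_episodes = nrow(episodes),
       mean_duration_min = mean(dur),
       sd_duration_min = stats::sd(dur),
       cytolytic_fraction = mean(cyt),
       contacts_per_nk = as.integer(per_nk),
       kills_per_nk = as.integer(kills_nk),
       frac_nk_with_contact = if (is.na(n_nk)) NA_real_ else
         length(per_nk) / n_nk,
       mw_p_value = p,
       notes = notes)
}

#' Initial distance from each NK cell to its nearest target
#'
#' Euclidean distance at the NK track's first frame to the nearest target
#' position at that same frame (or the target's first available frame).
#'
#' @param nk_tracks,target_tracks track tables on a shared time base.
#' @return data.frame with `nk_id`, `nearest_target_id`, `distance_um`.
#' @export
nearest_target_distance <- function(nk_tracks, target_tracks) {
  if (nrow(target_tracks) == 0L) stop("no targets", call. = FALSE)
  out <- lapply(split(nk_tracks, nk_tracks$cell_id), function(nk) {
    nk <- nk[order(nk$frame), ]
    f0 <- nk$frame[1]
    p0 <- as.numeric(nk[1, c("x_um", "y_um", "z_um")])
    best <- c(id = NA_real_, d = Inf)
    for (tg in split(target_tracks, target_tracks$cell_id)) {
      row <- tg[tg$frame == f0, ]
      if (nrow(row) == 0L) row <- tg[which.min(tg$frame), ]
      d <- sqrt(sum((as.numeric(row[1, c("x_um", "y_um", "z_um")]) - p0)^2))
      if (d < best["d"]) best <- c(id = row$cell_id[1], d = d)
    }
    data.frame(nk_id = nk$cell_id[1], nearest_target_id = best[["id"]],
               distance_um = best[["d"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full interaction analysis of a track table
#'
#' Splits tracks by `cell_type`, detects contacts, derives deaths (from
#' the `alive` column when present, else from `intensity_traces`),
#' assigns outcomes and computes summary statistics.
#'
#' @param tracks combined track table with a `cell_type` column.
#' @param cfg a [contact_config()].
#' @param intensity_traces optional data.frame (`target_id`, `frame`,
#'   `t_min`, `intensity`) for fluorescence-based death calling.
#' @return List with `episodes`, `nk_tally`, `deaths`, `stats`,
#'   `nearest_target`.
#' @export
analyze_interactions <- function(tracks, cfg = contact_config(),
                                 intensity_traces = NULL) {
  nk <- tracks[tracks$cell_type == "NK", ]
  tg <- tracks[tracks$cell_type == "target", ]
  # conjugation requires a live target: frames after death (fluorescence
  # lost) are not scored as contact
  tg_live <- if (!is.null(tg$alive)) tg[is.na(tg$alive) | tg$alive, ] else tg
  episodes <- detect_contacts(nk, tg_live, cfg)
  deaths <- data.frame(target_id = integer(), death_min = numeric(),
                       source = character())
  if (!is.null(intensity_traces) && nrow(intensity_traces) > 0) {
    for (tr in split(intensity_traces, intensity_traces$target_id)) {
      dv <- detect_target_death(tr, cfg)
      if (!is.null(dv))
        deaths <- rbind(deaths,
                        data.frame(target_id = tr$target_id[1],
                                   death_min = dv$death_min,
                                   source = "intensity-called"))
    }
  } else if (!is.null(tg$alive) && nrow(tg) > 0) {
    for (tr in split(tg, tg$cell_id)) {
      tr <- tr[order(tr$frame), ]
      dead <- which(!tr$alive)
      if (length(dead) > 0)
        deaths <- rbind(deaths,
                        data.frame(target_id = tr$cell_id[1],
                                   death_min = tr$t_min[dead[1]],
                                   source = "ground-truth"))
    }
  }
  res <- assign_outcomes(episodes, deaths, cfg)
  st <- if (nrow(episodes) > 0)
    interaction_stats(res$episodes, n_nk = length(unique(nk$cell_id)))
    else NULL
  nt <- if (nrow(tg) > 0 && nrow(nk) > 0)
    nearest_target_distance(nk, tg) else NULL
  list(episodes = res$episodes, nk_tally = res$nk_tally, deaths = deaths,
       stats = st, nearest_target = nt,
       unattributed_deaths = res$unattributed_deaths)
}
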