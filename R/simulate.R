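#' Simulation configuration for the collagen-microwell assay
#'
#' Parameters of the stochastic cell-motility simulator. NK cells switch
#' among three modes of migration -- transient migration arrest (`"TMAP"`,
#' slow confined diffusion), random Brownian movement, and directed
#' (persistent) migration -- by a continuous-time Markov process with
#' exponentially distributed dwell times. Target cells diffuse slowly and
#' can be killed on NK contact.
#'
#' Defaults mirror the assay geometry (a 450 x 450 um well, 300 um deep,
#' imaged every 2 min for 9 h) and the observed mean mode dwell time of
#' 106 min. `M_tmap` is deliberately below the Brownian arrest threshold
#' (see [brownian_threshold()]) and `M_random` well above it, so the three
#' regimes are separable by the windowed MSD analysis.
#'
#' @param n_nk,n_target number of NK and target cells.
#' @param well_size well extent in um, `c(x, y, z)`.
#' @param dt frame interval in minutes.
#' @param duration total simulated time in minutes.
#' @param mode_set subset of `c("TMAP", "random", "directed")` the NK cells
#'   may occupy; a single mode disables switching.
#' @param M_tmap,M_random motility coefficients (um^2/min) of the arrested
#'   and random modes; isotropic Gaussian steps with per-axis variance
#'   `2 * M * dt`.
#' @param v_directed speed (um/min) of directed migration; the heading is
#'   drawn uniformly on the sphere at each entry into the mode and held
#'   fixed for the dwell episode.
#' @param dwell_mean mean mode dwell time in minutes.
#' @param target_M motility coefficient (um^2/min) of live target cells.
#' @param contact_radius centre-to-centre contact distance in um.
#' @param min_separation minimum initial centre-to-centre distance (um)
#'   between any two cells (rejection-sampled placement; 0 disables).
#'   Cells are solid bodies dispersed in the gel, so seeding them apart
#'   emulates the excluded volume of real suspensions.
#' @param p_kill_per_contact probability that a new NK-target contact
#'   episode leads to target death.
#' @param kill_delay_mean mean delay (min, exponential) from contact onset
#'   to target death.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_tracks()]
#' @export
simulation_config <- function(n_nk = 50, n_target = 10,
                              well_size = c(450, 450, 300),
                              dt = 2, duration = 540,
                              mode_set = c("TMAP", "random", "directed"),
                              M_tmap = 1.0, M_random = 15, v_directed = 6,
                              dwell_mean = 106, target_M = 0.3,
                              contact_radius = 20,
                              min_separation = 0,
                              p_kill_per_contact = 0.57,
                              kill_delay_mean = 20,
                              seed = 1L) {
  cfg <- list(n_nk = n_nk, n_target = n_target, well_size = well_size,
              dt = dt, duration = duration, mode_set = mode_set,
              M_tmap = M_tmap, M_random = M_random, v_directed = v_directed,
              dwell_mean = dwell_mean, target_M = target_M,
              contact_radius = contact_radius,
              min_separation = min_separation,
              p_kill_per_contact = p_kill_per_contact,
              kill_delay_mean = kill_delay_mean, seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  num <- c("dt", "duration", "M_tmap", "M_random", "v_directed",
           "dwell_mean", "target_M", "contact_radius", "kill_delay_mean")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", f, "' must be a finite non-negative number", call. = FALSE)
  }
  if (cfg$dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (cfg$duration < cfg$dt) stop("'duration' must be >= dt", call. = FALSE)
  if (cfg$n_nk < 0 || cfg$n_target < 0)
    stop("cell counts must be non-negative", call. = FALSE)
  if (length(cfg$well_size) != 3L || !all(is.finite(cfg$well_size)) ||
      any(cfg$well_size <= 0))
    stop("'well_size' must be three strictly positive lengths", call. = FALSE)
  p <- cfg$p_kill_per_contact
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p_kill_per_contact' must lie in [0, 1]", call. = FALSE)
  if (cfg$min_separation < 0 || !is.finite(cfg$min_separation))
    stop("'min_separation' must be a finite non-negative length",
         call. = FALSE)
  if (!all(cfg$mode_set %in% c("TMAP", "random", "directed")) ||
      length(cfg$mode_set) < 1L)
    stop("'mode_set' must be a non-empty subset of TMAP/random/directed",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate mode-switching 3D cell trajectories with ground truth
#'
#' Generates NK and target trajectories inside a reflecting-boundary well.
#' NK cells follow a three-state continuous-time Markov chain over the
#' migration modes in `cfg$mode_set` (exponential dwell with mean
#' `dwell_mean`, uniform transitions to the other modes). TMAP and random
#' modes take isotropic Gaussian steps with per-axis variance `2 * M * dt`;
#' directed mode advances `v_directed * dt` along a heading fixed for the
#' episode. Targets diffuse with `target_M` until killed; a kill is drawn
#' with probability `p_kill_per_contact` at the onset of each NK-target
#' contact (centre distance below `contact_radius`) and takes effect after
#' an exponential delay. Dead targets stop moving.
#'
#' @param cfg a [simulation_config()].
#' @return A list with components
#'   \describe{
#'     \item{tracks}{data.frame with columns `cell_id`, `cell_type`
#'       (`"NK"`/`"target"`), `frame` (1-based), `t_min`, `x_um`, `y_um`,
#'       `z_um`, `true_mode`, `alive`.}
#'     \item{truth}{list with `mode_episodes` (per-NK mode intervals),
#'       `contacts` (nk_id, target_id, start_frame, end_frame),
#'       `kills` (target_id, death_frame, killer_id), `n_frames`, `dt`.}
#'   }
#' @export
simulate_tracks <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  n_frames <- floor(cfg$duration / cfg$dt) + 1L
  t_min <- (seq_len(n_frames) - 1L) * cfg$dt

  empty_tracks <- data.frame(cell_id = integer(), cell_type = character(),
                             frame = integer(), t_min = numeric(),
                             x_um = numeric(), y_um = numeric(),
                             z_um = numeric(), true_mode = character(),
                             alive = logical(), stringsAsFactors = FALSE)
  truth <- list(mode_episodes = data.frame(cell_id = integer(),
                                           mode = character(),
                                           start_frame = integer(),
                                           end_frame = integer(),
                                           stringsAsFactors = FALSE),
                contacts = data.frame(nk_id = integer(), target_id = integer(),
                                      start_frame = integer(),
                                      end_frame = integer()),
                kills = data.frame(target_id = integer(),
                                   death_frame = integer(),
                                   killer_id = integer()),
                n_frames = n_frames, dt = cfg$dt)
  if (cfg$n_nk == 0 && cfg$n_target == 0)
    return(list(tracks = empty_tracks, truth = truth))

  nk_ids <- seq_len(cfg$n_nk)
  tg_ids <- if (cfg$n_target > 0) cfg$n_nk + seq_len(cfg$n_target) else integer()
  starts <- draw_initial_positions(cfg$n_nk + cfg$n_target, cfg$well_size,
                                   cfg$min_separation)

  # NK cells: draw the mode schedule, then integrate steps
  nk_pos <- vector("list", cfg$n_nk)
  nk_mode <- vector("list", cfg$n_nk)
  episodes <- list()
  for (i in seq_len(cfg$n_nk)) {
    sched <- draw_mode_schedule(cfg$mode_set, cfg$dwell_mean, cfg$duration)
    mode_per_frame <- sched$mode[findInterval(t_min, sched$start)]
    pos <- matrix(NA_real_, n_frames, 3)
    pos[1, ] <- starts[i, ]
    heading <- random_unit_vector()
    cur_ep <- 1L
    for (k in seq_len(n_frames - 1L)) {
      m <- mode_per_frame[k]
      # re-draw heading on entry into a directed episode
      ep <- findInterval(t_min[k], sched$start)
      if (ep != cur_ep) {
        cur_ep <- ep
        if (m == "directed") heading <- random_unit_vector()
      }
      step <- switch(m,
        TMAP = stats::rnorm(3, sd = sqrt(2 * cfg$M_tmap * cfg$dt)),
        random = stats::rnorm(3, sd = sqrt(2 * cfg$M_random * cfg$dt)),
        directed = heading * cfg$v_directed * cfg$dt)
      refl <- reflect_with_flips(pos[k, ] + step, cfg$well_size)
      pos[k + 1L, ] <- refl$p
      if (m == "directed") heading <- heading * refl$sign
    }
    nk_pos[[i]] <- pos
    nk_mode[[i]] <- mode_per_frame
    ep_frames <- frames_of_episodes(sched, t_min)
    if (nrow(ep_frames) > 0) {
      ep_frames$cell_id <- nk_ids[i]
      episodes[[length(episodes) + 1L]] <- ep_frames
    }
  }

  # Target cells: slow Brownian motion, frozen after death
  tg_pos <- vector("list", cfg$n_target)
  for (j in seq_len(cfg$n_target)) {
    pos <- matrix(NA_real_, n_frames, 3)
    pos[1, ] <- starts[cfg$n_nk + j, ]
    steps <- matrix(stats::rnorm(3 * (n_frames - 1L),
                                 sd = sqrt(2 * cfg$target_M * cfg$dt)),
                    ncol = 3)
    for (k in seq_len(n_frames - 1L))
      pos[k + 1L, ] <- reflect_into_well(pos[k, ] + steps[k, ], cfg$well_size)
    tg_pos[[j]] <- pos
  }

  # Contacts and kills: sweep frames; kill decided at contact onset,
  # death after an exponential delay; dead targets freeze.
  death_frame <- rep(NA_integer_, cfg$n_target)
  killer <- rep(NA_integer_, cfg$n_target)
  pending <- list()  # target j -> c(frame_due, killer)
  contact_open <- matrix(FALSE, max(cfg$n_nk, 1L), max(cfg$n_target, 1L))
  contact_start <- matrix(NA_integer_, max(cfg$n_nk, 1L), max(cfg$n_target, 1L))
  contacts <- list()
  if (cfg$n_nk > 0 && cfg$n_target > 0) {
    for (k in seq_len(n_frames)) {
      for (j in seq_len(cfg$n_target)) {
        if (!is.na(death_frame[j]) && k > death_frame[j]) {
          tg_pos[[j]][k, ] <- tg_pos[[j]][death_frame[j], ]
        }
      }
      nkm <- do.call(rbind, lapply(nk_pos, function(p) p[k, ]))
      tgm <- do.call(rbind, lapply(tg_pos, function(p) p[k, ]))
      d <- sqrt(outer(rowSums(nkm^2), rep(1, nrow(tgm))) +
                outer(rep(1, nrow(nkm)), rowSums(tgm^2)) -
                2 * nkm %*% t(tgm))
      inc <- d < cfg$contact_radius
      for (i in seq_len(cfg$n_nk)) for (j in seq_len(cfg$n_target)) {
        if (inc[i, j] && !contact_open[i, j]) {
          contact_open[i, j] <- TRUE
          contact_start[i, j] <- k
          if (is.na(death_frame[j]) &&
              stats::runif(1) < cfg$p_kill_per_contact) {
            delay <- stats::rexp(1, rate = 1 / max(cfg$kill_delay_mean, 1e-9))
            due <- k + max(1L, as.integer(round(delay / cfg$dt)))
            if (due <= n_frames &&
                (is.na(death_frame[j]) || due < death_frame[j])) {
              death_frame[j] <- due
              killer[j] <- nk_ids[i]
            }
          }
        } else if (!inc[i, j] && contact_open[i, j]) {
          contact_open[i, j] <- FALSE
          contacts[[length(contacts) + 1L]] <-
            data.frame(nk_id = nk_ids[i], target_id = tg_ids[j],
                       start_frame = contact_start[i, j], end_frame = k - 1L)
        }
      }
    }
    for (i in seq_len(cfg$n_nk)) for (j in seq_len(cfg$n_target)) {
      if (contact_open[i, j])
        contacts[[length(contacts) + 1L]] <-
          data.frame(nk_id = nk_ids[i], target_id = tg_ids[j],
                     start_frame = contact_start[i, j], end_frame = n_frames)
    }
  }

  rows <- list()
  for (i in seq_len(cfg$n_nk)) {
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = nk_ids[i], cell_type = "NK", frame = seq_len(n_frames),
      t_min = t_min, x_um = nk_pos[[i]][, 1], y_um = nk_pos[[i]][, 2],
      z_um = nk_pos[[i]][, 3], true_mode = nk_mode[[i]], alive = TRUE,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_target)) {
    alive <- if (is.na(death_frame[j])) rep(TRUE, n_frames) else
      seq_len(n_frames) < death_frame[j]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = tg_ids[j], cell_type = "target", frame = seq_len(n_frames),
      t_min = t_min, x_um = tg_pos[[j]][, 1], y_um = tg_pos[[j]][, 2],
      z_um = tg_pos[[j]][, 3], true_mode = NA_character_, alive = alive,
      stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, rows)

  truth$mode_episodes <- if (length(episodes))
    do.call(rbind, episodes)[, c("cell_id", "mode", "start_frame", "end_frame")]
    else truth$mode_episodes
  truth$contacts <- if (length(contacts)) do.call(rbind, contacts)
    else truth$contacts
  killed <- which(!is.na(death_frame))
  truth$kills <- data.frame(target_id = tg_ids[killed],
                            death_frame = death_frame[killed],
                            killer_id = killer[killed])
  list(tracks = tracks, truth = truth)
}

# Exponential dwell schedule over [0, duration]; uniform switch to one of
# the other modes. Returns data.frame(mode, start) with start[1] = 0.
draw_mode_schedule <- function(mode_set, dwell_mean, duration) {
  modes <- character()
  starts <- numeric()
  t <- 0
  cur <- sample(mode_set, 1L)
  repeat {
    modes <- c(modes, cur)
    starts <- c(starts, t)
    if (length(mode_set) == 1L || dwell_mean <= 0) {
      t <- duration
    } else {
      t <- t + stats::rexp(1, rate = 1 / dwell_mean)
    }
    if (t >= duration) break
    cur <- sample(setdiff(mode_set, cur), 1L)
  }
  data.frame(mode = modes, start = starts, stringsAsFactors = FALSE)
}

frames_of_episodes <- function(sched, t_min) {
  n <- length(t_min)
  ep <- findInterval(t_min, sched$start)
  r <- rle(ep)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(mode = sched$mode[r$values], start_frame = starts,
             end_frame = ends, stringsAsFactors = FALSE)
}

# Uniform placement in the well with a minimum pairwise distance
# (sequential rejection sampling).
draw_initial_positions <- function(n, well, min_sep) {
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in seq_len(10000L)) {
      p <- stats::runif(3) * well
      if (i == 1L || min_sep <= 0) break
      d <- sqrt(rowSums((out[seq_len(i - 1L), , drop = FALSE] -
                           matrix(p, i - 1L, 3, byrow = TRUE))^2))
      if (all(d >= min_sep)) break
      if (try == 10000L)
        stop("cannot place cells with the requested 'min_separation'",
             call. = FALSE)
    }
    out[i, ] <- p
  }
  out
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Fold a coordinate back into [0, L] on each axis (specular reflection,
# handles multiple bounces).
reflect_into_well <- function(p, well) {
  reflect_with_flips(p, well)$p
}

# As reflect_into_well, but also report the per-axis direction sign after
# the bounce(s), so persistent headings reflect off the walls instead of
# pressing into them.
reflect_with_flips <- function(p, well) {
  sgn <- c(1, 1, 1)
  for (a in 1:3) {
    L <- well[a]
    x <- p[a] %% (2 * L)
    if (x > L) {
      x <- 2 * L - x
      sgn[a] <- -1
    }
    p[a] <- x
  }
  list(p = p, sign = sgn)
}
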