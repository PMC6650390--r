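#' Track filter configuration
#'
#' @param min_duration minimum track duration in minutes (default 60:
#'   tracks shorter than one hour are excluded).
#' @param max_z_jump maximum allowed z displacement (um) between
#'   consecutive positions; a strictly larger jump excludes the track.
#' @return An object of class `track_filter_config`.
#' @export
track_filter_config <- function(min_duration = 60, max_z_jump = 40) {
  if (min_duration <= 0 || max_z_jump <= 0)
    stop("filter parameters must be > 0", call. = FALSE)
  structure(list(min_duration = min_duration, max_z_jump = max_z_jump),
            class = "track_filter_config")
}

#' Rolling-window MSD analysis configuration
#'
#' @param window sliding-window length in points (default 25) over which
#'   the local MSD curve is computed.
#' @param fit_points number of initial MSD lags used in the linear fits
#'   for the motility coefficient M and the anomalous exponent alpha
#'   (default 6).
#' @param smooth_window length (points) of the centred rolling average
#'   applied to the M and alpha profiles before classification.
#' @param M_threshold motility coefficient (um^2/min) below which a point
#'   is classed as transient migration arrest; the default 4.9 is the
#'   Brownian value for an 8-um particle in aqueous medium at 37 C
#'   (see [brownian_threshold()]).
#' @param alpha_threshold anomalous exponent above which movement counts
#'   as directed (default 1.5).
#' @param directed_min_run minimum consecutive points above
#'   `alpha_threshold` required to call directed migration (default 10).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window = 25L, fit_points = 6L, smooth_window = 5L,
                          M_threshold = 4.9, alpha_threshold = 1.5,
                          directed_min_run = 10L) {
  cfg <- list(window = as.integer(window), fit_points = as.integer(fit_points),
              smooth_window = as.integer(smooth_window),
              M_threshold = M_threshold, alpha_threshold = alpha_threshold,
              directed_min_run = as.integer(directed_min_run))
  if (!(cfg$window > cfg$fit_points && cfg$fit_points >= 3L))
    stop("need window > fit_points >= 3", call. = FALSE)
  if (cfg$M_threshold <= 0 || cfg$alpha_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (cfg$directed_min_run < 1L) stop("'directed_min_run' must be >= 1",
                                      call. = FALSE)
  class(cfg) <- "window_config"
  cfg
}

#' Filter tracks by duration and z-jump artefacts
#'
#' Retains tracks whose total duration is at least `min_duration` minutes
#' and whose consecutive z displacements never exceed `max_z_jump`
#' micrometres (strictly larger jumps, typical of identity swaps across
#' optical sections, exclude the whole track). Idempotent; order
#' preserved.
#'
#' @param tracks track table (`cell_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`, `z_um`, ...).
#' @param cfg a [track_filter_config()].
#' @return The retained rows of `tracks`.
#' @export
filter_tracks <- function(tracks, cfg = track_filter_config()) {
  stopifnot(inherits(cfg, "track_filter_config"))
  if (nrow(tracks) == 0L) return(tracks)
  keep_ids <- vapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    dur <- max(tr$t_min) - min(tr$t_min)
    if (dur < cfg$min_duration) return(FALSE)
    if (nrow(tr) >= 2 && any(abs(diff(tr$z_um)) > cfg$max_z_jump))
      return(FALSE)
    TRUE
  }, logical(1))
  out <- tracks[tracks$cell_id %in% names(keep_ids)[keep_ids], ]
  rownames(out) <- NULL
  out
}

track_positions <- function(track) {
  track <- track[order(track$frame), ]
  as.matrix(track[, c("x_um", "y_um", "z_um")])
}

track_dt <- function(track) {
  tt <- sort(track$t_min)
  if (length(tt) < 2) stop("track needs >= 2 points", call. = FALSE)
  diff(tt)[1]
}

#' Mean migration speed of a track
#'
#' Mean over consecutive position pairs of the step length divided by the
#' frame interval.
#'
#' @param track one cell's rows of a track table.
#' @return Speed in um/min.
#' @export
mean_speed <- function(track) {
  p <- track_positions(track)
  if (nrow(p) < 2) stop("track needs >= 2 points", call. = FALSE)
  dt <- track_dt(track)
  steps <- sqrt(rowSums(diff(p)^2))
  mean(steps / dt)
}

#' Duration-corrected displacement (confinement index)
#'
#' Ratio of net displacement to total path length, multiplied by the
#' square root of the track duration: `||r_end - r_1|| / d_tot *
#' sqrt(t_tot)`. A straight path gives `sqrt(t_tot)`; a closed loop gives
#' 0. Units are sqrt(min).
#'
#' @param track one cell's rows of a track table.
#' @return Corrected displacement in sqrt(min).
#' @export
corrected_displacement <- function(track) {
  p <- track_positions(track)
  if (nrow(p) < 2) stop("track needs >= 2 points", call. = FALSE)
  d_tot <- sum(sqrt(rowSums(diff(p)^2)))
  if (d_tot <= 0) stop("zero total path length: ratio undefined",
                       call. = FALSE)
  t_tot <- max(track$t_min) - min(track$t_min)
  net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  net / d_tot * sqrt(t_tot)
}

#' Mean squared displacement of a position segment
#'
#' Time-averaged 3D MSD over a window of consecutive positions:
#' `MSD(t_n) = 1/(N-n) * sum_i |r_{i+n} - r_i|^2` with `t_n = n * dt`.
#'
#' @param p numeric matrix of positions (rows = time points, columns =
#'   x, y, z in um).
#' @param max_lag largest lag `n` evaluated; must be `< nrow(p)`.
#' @return Numeric vector of length `max_lag`, `MSD(t_1) .. MSD(t_max_lag)`
#'   in um^2.
#' @export
msd <- function(p, max_lag) {
  p <- as.matrix(p)
  N <- nrow(p)
  if (max_lag >= N) stop("'max_lag' must be smaller than the segment length",
                         call. = FALSE)
  vapply(seq_len(max_lag), function(n) {
    d <- p[(n + 1):N, , drop = FALSE] - p[1:(N - n), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Fit motility coefficient and anomalous exponent to an MSD curve
#'
#' `M` is the slope of an unconstrained least-squares line through the
#' first `fit_points` MSD values versus lag time, divided by 6 (the 3D
#' random-walk relation `MSD = 6 M t`); negative slopes clip `M` to 0
#' (arrest). `alpha` is the slope of `log MSD` versus `log t` over the
#' same lags; it is `NA` when any of those MSD values is zero.
#'
#' @param msd_values MSD at lags `1..k` (um^2), `k >= fit_points`.
#' @param dt lag-time unit in minutes.
#' @param fit_points number of initial lags used.
#' @return List with `M` (um^2/min) and `alpha`.
#' @export
fit_msd_window <- function(msd_values, dt, fit_points = 6L) {
  if (length(msd_values) < fit_points)
    stop("need at least 'fit_points' MSD values", call. = FALSE)
  tn <- seq_len(fit_points) * dt
  y <- msd_values[seq_len(fit_points)]
  slope <- stats::cov(tn, y) / stats::var(tn)
  M <- max(slope / 6, 0)
  alpha <- if (any(y <= 0)) NA_real_ else
    stats::cov(log(tn), log(y)) / stats::var(log(tn))
  list(M = M, alpha = alpha)
}

rolling_mean <- function(x, w) {
  # centred rolling average; shrinks symmetrically at the ends; NAs in x
  # are ignored within each window
  n <- length(x)
  half <- (w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    v <- x[lo:hi]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Rolling-window motility profiles of a track
#'
#' Slides a centred window of `cfg$window` points through the track. At
#' each time point with a full window, the window's MSD curve is computed
#' and [fit_msd_window()] yields the local motility coefficient M and
#' anomalous exponent alpha; both profiles are then smoothed by a centred
#' rolling average of `cfg$smooth_window` points. Points closer than half
#' a window to either track end carry `NA`.
#'
#' @param track one cell's rows of a track table (length >= `cfg$window`).
#' @param cfg a [window_config()].
#' @return data.frame (one row per track point): `frame`, `t_min`, `M`,
#'   `alpha`, `M_smooth`, `alpha_smooth`.
#' @export
windowed_profiles <- function(track, cfg = window_config()) {
  stopifnot(inherits(cfg, "window_config"))
  track <- track[order(track$frame), ]
  p <- track_positions(track)
  N <- nrow(p)
  if (N < cfg$window)
    stop("track shorter than the analysis window", call. = FALSE)
  dt <- track_dt(track)
  half <- (cfg$window - 1L) %/% 2L
  M <- rep(NA_real_, N)
  alpha <- rep(NA_real_, N)
  for (i in (half + 1L):(N - half)) {
    seg <- p[(i - half):(i + half), , drop = FALSE]
    fit <- fit_msd_window(msd(seg, cfg$fit_points), dt, cfg$fit_points)
    M[i] <- fit$M
    alpha[i] <- fit$alpha
  }
  core <- (half + 1L):(N - half)
  M_s <- rep(NA_real_, N)
  a_s <- rep(NA_real_, N)
  M_s[core] <- rolling_mean(M[core], cfg$smooth_window)
  a_s[core] <- rolling_mean(alpha[core], cfg$smooth_window)
  data.frame(frame = track$frame, t_min = track$t_min, M = M, alpha = alpha,
             M_smooth = M_s, alpha_smooth = a_s)
}

#' Classify migration modes from smoothed motility profiles
#'
#' A point is `"TMAP"` (transient migration arrest) when its smoothed M
#' lies strictly below `M_threshold`. Among the remaining points, runs of
#' at least `directed_min_run` consecutive points with smoothed alpha
#' strictly above `alpha_threshold` are `"directed"`; arrest takes
#' precedence where both criteria fire. Everything else is `"random"`.
#' Points without a profile (window or smoothing margin) stay `NA`;
#' points with undefined alpha are classified by M alone.
#'
#' @param profile output of [windowed_profiles()].
#' @param cfg a [window_config()].
#' @return Character vector of per-point labels (`"TMAP"`, `"random"`,
#'   `"directed"`, or `NA`).
#' @export
classify_modes <- function(profile, cfg = window_config()) {
  stopifnot(inherits(cfg, "window_config"))
  n <- nrow(profile)
  lab <- rep(NA_character_, n)
  has <- !is.na(profile$M_smooth)
  hi_alpha <- !is.na(profile$alpha_smooth) &
    profile$alpha_smooth > cfg$alpha_threshold
  directed <- rep(FALSE, n)
  r <- rle(hi_alpha)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= cfg$directed_min_run)
      directed[starts[k]:ends[k]] <- TRUE
  }
  lab[has] <- "random"
  lab[has & directed] <- "directed"
  lab[has & profile$M_smooth < cfg$M_threshold] <- "TMAP"
  lab
}

#' Brownian motility threshold of a spherical particle
#'
#' Stokes-Einstein diffusion coefficient `D = kB T / (6 pi eta r)` of a
#' sphere, converted to um^2/min. With an 8-um (cell-sized) particle in
#' water at body temperature this gives the 4.9 um^2/min arrest
#' threshold: a cell whose local motility coefficient falls below the
#' passive Brownian value is not actively migrating.
#'
#' @param diameter particle diameter in um (default 8, an NK cell).
#' @param temperature absolute temperature in K (default 310.15, 37 C).
#' @param viscosity dynamic viscosity in Pa s (default 6.9e-4, water at
#'   37 C).
#' @return Diffusion coefficient in um^2/min.
#' @export
brownian_threshold <- function(diameter = 8, temperature = 310.15,
                               viscosity = 6.9e-4) {
  if (diameter <= 0 || temperature <= 0 || viscosity <= 0)
    stop("all inputs must be > 0", call. = FALSE)
  kB <- 1.380649e-23                       # J/K
  r <- diameter / 2 * 1e-6                 # m
  D <- kB * temperature / (6 * pi * viscosity * r)  # m^2/s
  D * 1e12 * 60                            # um^2/min
}

#' Per-track migration summary
#'
#' Mode fractions over the labelled points, transitions between modes per
#' hour of labelled time, and the arrest group: `"low"` (< 10% of time in
#' TMAP), `"medium"` (10-90%), `"high"` (> 90%).
#'
#' @param track one cell's rows of a track table.
#' @param labels per-point mode labels from [classify_modes()] (`NA`
#'   allowed at the ends).
#' @return List with `cell_id`, `mean_speed`, `corrected_displacement`,
#'   `frac_tmap`, `frac_random`, `frac_directed`, `transitions_per_h`,
#'   `tmap_group`, `labeled_min`.
#' @export
summarize_track <- function(track, labels) {
  track <- track[order(track$frame), ]
  ok <- !is.na(labels)
  if (!any(ok)) stop("no labelled points", call. = FALSE)
  lab <- labels[ok]
  dt <- track_dt(track)
  fr <- c(frac_tmap = mean(lab == "TMAP"),
          frac_random = mean(lab == "random"),
          frac_directed = mean(lab == "directed"))
  switches <- sum(lab[-1] != lab[-length(lab)])
  labeled_min <- length(lab) * dt
  group <- if (fr["frac_tmap"] < 0.10) "low" else
    if (fr["frac_tmap"] > 0.90) "high" else "medium"
  list(cell_id = track$cell_id[1],
       mean_speed = mean_speed(track),
       corrected_displacement = corrected_displacement(track),
       frac_tmap = unname(fr[1]), frac_random = unname(fr[2]),
       frac_directed = unname(fr[3]),
       transitions_per_h = switches / (labeled_min / 60),
       tmap_group = group, labeled_min = labeled_min)
}

#' Pool per-track summaries into population statistics
#'
#' Mode fractions are pooled weighted by each track's labelled duration.
#' The mean mode dwell time is estimated as total labelled time divided by
#' the number of observed mode switches (the exponential-dwell maximum
#' likelihood estimate, robust to episodes censored at track ends).
#'
#' @param summaries list of [summarize_track()] results.
#' @return List with `n_tracks`, `frac_tmap`, `frac_random`,
#'   `frac_directed`, `mean_speed`, `sd_speed`, `speeds`,
#'   `corrected_displacements`, `transitions_per_h`, `dwell_mean_min`
#'   (`NA` when no switch was observed), `tmap_groups` (table).
#' @export
population_summary <- function(summaries) {
  if (length(summaries) == 0L) stop("no track summaries", call. = FALSE)
  w <- vapply(summaries, `[[`, numeric(1), "labeled_min")
  g <- function(f) vapply(summaries, `[[`, numeric(1), f)
  total_switches <- sum(g("transitions_per_h") * w / 60)
  list(n_tracks = length(summaries),
       frac_tmap = sum(g("frac_tmap") * w) / sum(w),
       frac_random = sum(g("frac_random") * w) / sum(w),
       frac_directed = sum(g("frac_directed") * w) / sum(w),
       mean_speed = mean(g("mean_speed")),
       sd_speed = stats::sd(g("mean_speed")),
       speeds = g("mean_speed"),
       corrected_displacements = g("corrected_displacement"),
       transitions_per_h = g("transitions_per_h"),
       dwell_mean_min = if (total_switches > 0) sum(w) / total_switches
         else NA_real_,
       tmap_groups = table(vapply(summaries, `[[`, character(1),
                                  "tmap_group")))
}

#' Full migration analysis of a track table
#'
#' Filters tracks, computes rolling-window profiles, classifies modes and
#' returns per-track and population summaries. Tracks shorter than the
#' analysis window after filtering are skipped.
#'
#' @param tracks track table (NK tracks; filter by `cell_type` first if
#'   mixed).
#' @param filter_cfg a [track_filter_config()].
#' @param window_cfg a [window_config()].
#' @return List with `profiles` (data.frame incl. `cell_id` and `mode`),
#'   `summaries`, `population`.
#' @export
analyze_migration <- function(tracks, filter_cfg = track_filter_config(),
                              window_cfg = window_config()) {
  kept <- filter_tracks(tracks, filter_cfg)
  if (nrow(kept) == 0L) stop("no tracks pass the filters", call. = FALSE)
  profs <- list()
  sums <- list()
  for (tr in split(kept, kept$cell_id)) {
    if (nrow(tr) < window_cfg$window) next
    prof <- windowed_profiles(tr, window_cfg)
    prof$mode <- classify_modes(prof, window_cfg)
    prof$cell_id <- tr$cell_id[1]
    profs[[length(profs) + 1L]] <- prof
    sums[[length(sums) + 1L]] <- summarize_track(tr, prof$mode)
  }
  if (length(sums) == 0L)
    stop("no track is long enough for the analysis window", call. = FALSE)
  list(profiles = do.call(rbind, profs), summaries = sums,
       population = population_summary(sums))
}
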