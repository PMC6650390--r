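#' Rendering configuration for synthetic two-channel volumes
#'
#' Describes how simulated cells are rasterised into 8-bit anisotropic
#' voxel stacks emulating confocal z-stacks of the microwell (by default
#' 512 x 512 pixel sections, 38 optical sections, voxel size
#' 1.1 x 1.1 x 8 um). Each live cell becomes an anisotropic Gaussian
#' intensity blob in its type's channel (NK -> channel 1, target ->
#' channel 2); a killed target keeps a dim residue
#' (`post_kill_intensity_fraction` of its amplitude), emulating calcein
#' leakage on death. Poisson shot noise and Gaussian read noise are
#' applied last.
#'
#' @param frame_shape voxels per frame as `c(z, y, x)`.
#' @param voxel_size um per voxel as `c(x, y, z)`.
#' @param origin_um physical position (um, `c(x, y, z)`) of the low corner
#'   of the imaged field. A negative origin places the well interior away
#'   from the field borders, as in the assay where the 450-um well sits
#'   inside the wider imaging field.
#' @param psf_sigma Gaussian blob standard deviation in um, `c(x, y, z)`;
#'   the default approximates an 8-um cell body blurred axially.
#' @param amplitude peak blob intensity (8-bit counts) above background.
#' @param background_level constant background intensity (counts).
#' @param noise_gain Poisson gain; `0` disables shot noise.
#' @param read_sigma Gaussian read-noise standard deviation (counts);
#'   `0` disables.
#' @param post_kill_intensity_fraction residual amplitude fraction of a
#'   target after its death frame, in `[0, 1]`.
#' @return An object of class `render_config`.
#' @export
render_config <- function(frame_shape = c(38, 512, 512),
                          voxel_size = c(1.1, 1.1, 8),
                          origin_um = c(0, 0, 0),
                          psf_sigma = c(3, 3, 6),
                          amplitude = 200,
                          background_level = 10,
                          noise_gain = 1,
                          read_sigma = 2,
                          post_kill_intensity_fraction = 0.1) {
  rc <- list(frame_shape = as.integer(frame_shape), voxel_size = voxel_size,
             origin_um = origin_um,
             psf_sigma = psf_sigma, amplitude = amplitude,
             background_level = background_level, noise_gain = noise_gain,
             read_sigma = read_sigma,
             post_kill_intensity_fraction = post_kill_intensity_fraction)
  if (length(rc$frame_shape) != 3L || any(rc$frame_shape < 2L))
    stop("'frame_shape' must be c(z, y, x) with every dimension >= 2",
         call. = FALSE)
  if (length(rc$voxel_size) != 3L || any(rc$voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (x, y, z)",
         call. = FALSE)
  if (length(rc$origin_um) != 3L || any(!is.finite(rc$origin_um)))
    stop("'origin_um' must be three finite coordinates", call. = FALSE)
  if (any(rc$psf_sigma <= 0)) stop("'psf_sigma' must be positive", call. = FALSE)
  if (rc$background_level < 0 || rc$amplitude <= 0)
    stop("intensities must be non-negative", call. = FALSE)
  f <- rc$post_kill_intensity_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop("'post_kill_intensity_fraction' must lie in [0, 1]", call. = FALSE)
  class(rc) <- "render_config"
  rc
}

#' Render simulated tracks into a two-channel voxel time series
#'
#' Rasterises every cell position into an 8-bit two-channel volume series.
#' Channel 1 holds NK cells, channel 2 target cells. After a target's
#' death frame its blob amplitude is multiplied by
#' `post_kill_intensity_fraction`. Noise (Poisson shot + Gaussian read) is
#' applied after blob placement; output is clamped to 0..255.
#'
#' @param tracks track table as produced by [simulate_tracks()].
#' @param truth matching ground truth (used for death frames); may be
#'   `NULL` when `tracks` carries an `alive` column or contains no targets.
#' @param rc a [render_config()].
#' @param seed integer seed for the noise draws.
#' @return A `volume_series`: list with `data` (array `[t, c, z, y, x]`,
#'   values 0..255), `voxel_size` (um, x/y/z), `dt` (min).
#' @export
render_volumes <- function(tracks, truth = NULL, rc = render_config(),
                           seed = 1L) {
  stopifnot(inherits(rc, "render_config"))
  extent <- rev(rc$frame_shape) * rc$voxel_size  # physical (x, y, z)
  if (nrow(tracks) > 0) {
    pos <- sweep(as.matrix(tracks[, c("x_um", "y_um", "z_um")]), 2,
                 rc$origin_um)
    if (any(pos < 0) || any(pos > matrix(extent, nrow(pos), 3, byrow = TRUE)))
      stop("track positions fall outside the rendered physical extent; ",
           "adjust frame_shape/voxel_size", call. = FALSE)
  }
  n_frames <- if (nrow(tracks) > 0) max(tracks$frame) else 1L
  dt <- if (nrow(tracks) > 1) {
    tt <- sort(unique(tracks$t_min))
    if (length(tt) > 1) tt[2] - tt[1] else 1
  } else 1
  dims <- c(n_frames, 2L, rc$frame_shape)
  vol <- array(rc$background_level, dim = dims)

  death <- integer(0)
  if (!is.null(truth) && nrow(truth$kills) > 0) {
    death <- truth$kills$death_frame
    names(death) <- as.character(truth$kills$target_id)
  }

  sig_vox <- rc$psf_sigma / rc$voxel_size           # (x, y, z) in voxels
  half <- pmax(1L, ceiling(4 * sig_vox))
  if (nrow(tracks) > 0) {
    for (r in seq_len(nrow(tracks))) {
      ch <- if (tracks$cell_type[r] == "NK") 1L else 2L
      fr <- tracks$frame[r]
      amp <- rc$amplitude
      if (ch == 2L) {
        dfr <- death[as.character(tracks$cell_id[r])]
        if (length(dfr) == 1 && !is.na(dfr) && fr > dfr)
          amp <- amp * rc$post_kill_intensity_fraction
      }
      # voxel-centre coordinates: centre of voxel i is (i - 0.5) * size
      cx <- (tracks$x_um[r] - rc$origin_um[1]) / rc$voxel_size[1] + 0.5
      cy <- (tracks$y_um[r] - rc$origin_um[2]) / rc$voxel_size[2] + 0.5
      cz <- (tracks$z_um[r] - rc$origin_um[3]) / rc$voxel_size[3] + 0.5
      ix <- max(1L, floor(cx - half[1])):min(rc$frame_shape[3], ceiling(cx + half[1]))
      iy <- max(1L, floor(cy - half[2])):min(rc$frame_shape[2], ceiling(cy + half[2]))
      iz <- max(1L, floor(cz - half[3])):min(rc$frame_shape[1], ceiling(cz + half[3]))
      gx <- exp(-(ix - cx)^2 / (2 * sig_vox[1]^2))
      gy <- exp(-(iy - cy)^2 / (2 * sig_vox[2]^2))
      gz <- exp(-(iz - cz)^2 / (2 * sig_vox[3]^2))
      blob <- amp * outer(gz, outer(gy, gx))       # dim (z, y, x)
      vol[fr, ch, iz, iy, ix] <-
        vol[fr, ch, iz, iy, ix] + array(blob, dim(blob))
    }
  }

  set.seed(as.integer(seed))
  if (rc$noise_gain > 0)
    vol[] <- stats::rpois(length(vol), lambda = rc$noise_gain * vol) /
      rc$noise_gain
  if (rc$read_sigma > 0)
    vol[] <- vol + stats::rnorm(length(vol), sd = rc$read_sigma)
  vol[] <- pmin(pmax(round(vol), 0), 255)

  volume_series(vol, voxel_size = rc$voxel_size, dt = dt,
                origin_um = rc$origin_um)
}

#' Construct a volume series container
#'
#' @param data numeric array `[time, channel, z, y, x]` with finite,
#'   non-negative intensities.
#' @param voxel_size um per voxel, `c(x, y, z)`.
#' @param dt frame interval in minutes.
#' @param origin_um physical coordinate (um) of the field's low corner.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size, dt, origin_um = c(0, 0, 0)) {
  if (length(dim(data)) != 5L)
    stop("'data' must be a 5-D array [t, c, z, y, x]", call. = FALSE)
  if (dim(data)[2] < 1L) stop("need at least one channel", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, dt = dt,
                 origin_um = origin_um),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "volume_series: %d frame(s), %d channel(s), %d x %d x %d voxels (z,y,x)\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel size %.2f x %.2f x %.2f um (x,y,z), dt = %g min\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$dt))
  invisible(x)
}

#' Write a volume series as multi-page TIFF plus a YAML sidecar
#'
#' Pages are ordered time-major, then channel, then z. The sidecar records
#' dimensions, axis order, voxel size and frame interval so the series can
#' be read back losslessly with [read_volume_series()].
#'
#' @param v a `volume_series`.
#' @param path output TIFF path; the sidecar is written at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(v, path) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- v$data[t, ch, z, , ] / 255
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(axes = "TCZYX",
                        shape = as.integer(d),
                        voxel_size_um = as.numeric(v$voxel_size),
                        origin_um = as.numeric(v$origin_um),
                        dt_min = v$dt), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume series written by [write_volume_series()]
#'
#' @param path TIFF path with an accompanying `<path>.yaml` sidecar.
#' @return A `volume_series`.
#' @export
read_volume_series <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  vol <- array(0, dim = d)
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    vol[t, ch, z, , ] <- round(pages[[i]] * 255)
  }
  volume_series(vol, voxel_size = meta$voxel_size_um, dt = meta$dt_min,
                origin_um = if (is.null(meta$origin_um)) c(0, 0, 0)
                  else meta$origin_um)
}
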