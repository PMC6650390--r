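#' Segmentation configuration
#'
#' Parameters of the difference-of-Gaussians (DoG) bandpass segmentation
#' with watershed cluster splitting. The DoG subtracts a wide Gaussian
#' blur (`sigma_neg`) from a narrow one (`sigma_pos`), enhancing
#' cell-sized blobs; both sigmas are divided by `z_sigma_divisor` in z to
#' account for the coarse axial sampling. The bandpassed image is
#' thresholded, clusters are split by a watershed on the (negated)
#' bandpassed image after h-minima suppression of shallow minima, holes
#' are filled, and regions smaller than `min_voxels` are discarded.
#'
#' @param sigma_pos,sigma_neg standard deviations (xy pixels) of the
#'   positive and negative DoG kernels; `sigma_neg > sigma_pos > 0`.
#' @param z_sigma_divisor factor dividing both sigmas in z.
#' @param threshold intensity threshold applied to the bandpassed image
#'   (input normalised to `[0, 1]`).
#' @param h_min depth parameter of the h-minima transform before the
#'   watershed; larger values split less.
#' @param min_voxels minimum region size kept (strictly smaller regions
#'   are removed).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(sigma_pos = 1, sigma_neg = 3,
                                z_sigma_divisor = 8, threshold = 0.02,
                                h_min = 0.15, min_voxels = 5L) {
  cfg <- list(sigma_pos = sigma_pos, sigma_neg = sigma_neg,
              z_sigma_divisor = z_sigma_divisor, threshold = threshold,
              h_min = h_min, min_voxels = as.integer(min_voxels))
  if (!(cfg$sigma_neg > cfg$sigma_pos && cfg$sigma_pos > 0))
    stop("need sigma_neg > sigma_pos > 0", call. = FALSE)
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  if (cfg$min_voxels < 1L) stop("'min_voxels' must be >= 1", call. = FALSE)
  if (cfg$z_sigma_divisor <= 0) stop("'z_sigma_divisor' must be > 0",
                                     call. = FALSE)
  class(cfg) <- "segmentation_config"
  cfg
}

#' Temporal-minimum background subtraction
#'
#' Estimates a static background as the per-voxel minimum intensity over
#' time and subtracts it from every frame; negative residuals are clipped
#' to zero. A single-frame series therefore becomes all zeros.
#'
#' @param v a [volume_series()].
#' @return A `volume_series` of identical shape.
#' @export
subtract_background <- function(v) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  if (d[1] < 1L) stop("empty series", call. = FALSE)
  out <- v$data
  for (ch in seq_len(d[2])) {
    stack <- v$data[, ch, , , , drop = FALSE]
    bg <- apply(stack, c(3, 4, 5), min)
    for (t in seq_len(d[1]))
      out[t, ch, , , ] <- pmax(v$data[t, ch, , , ] - bg, 0)
  }
  volume_series(out, v$voxel_size, v$dt, v$origin_um)
}

# --- low-level 3-D image operations -----------------------------------------

# Separable Gaussian smoothing of a (z, y, x) array; sigma per axis in
# voxels, order (z, y, x). Nearest-neighbour (replicate) boundary.
gaussian_smooth_3d <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- exp(-(-half:half)^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    out <- matrix(0, nrow = dm[1], ncol = ncol(m))
    idx <- seq_len(dm[1])
    for (o in -half:half) {
      rows <- pmin(pmax(idx + o, 1L), dm[1])
      out <- out + k[o + half + 1L] * m[rows, , drop = FALSE]
    }
    a <- aperm(array(out, dm), order(perm))
  }
  a
}

# Difference-of-Gaussians bandpass of a (z, y, x) stack. Sigmas are in xy
# pixels; both are divided by z_div along z.
dog_bandpass <- function(stack, sigma_pos, sigma_neg, z_div) {
  pos <- gaussian_smooth_3d(stack, c(sigma_pos / z_div, sigma_pos, sigma_pos))
  neg <- gaussian_smooth_3d(stack, c(sigma_neg / z_div, sigma_neg, sigma_neg))
  pos - neg
}

# 6-connected neighbour offsets of linear indices in a (z, y, x) array.
neighbor_offsets_6 <- function(d) {
  c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
}

# Linear indices of the 6-neighbours of `idx`, NA where the step leaves
# the array.
neighbors_6 <- function(idx, d) {
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  nb <- cbind(ifelse(z > 1L, idx - 1L, NA_integer_),
              ifelse(z < d[1], idx + 1L, NA_integer_),
              ifelse(y > 1L, idx - d[1], NA_integer_),
              ifelse(y < d[2], idx + d[1], NA_integer_),
              ifelse(x > 1L, idx - d[1] * d[2], NA_integer_),
              ifelse(x < d[3], idx + d[1] * d[2], NA_integer_))
  nb
}

# h-minima transform by morphological reconstruction-by-erosion of
# (img + h) above img, 6-connectivity; suppresses minima shallower than h.
hminima_3d <- function(img, h) {
  d <- dim(img)
  rec <- img + h
  repeat {
    er <- rec
    # erosion = min over self and 6-neighbours, via shifted copies
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(rec, perm)
      dm <- dim(m)
      mm <- matrix(m, nrow = dm[1])
      up <- mm[c(1L, seq_len(dm[1] - 1L)), , drop = FALSE]
      dn <- mm[c(seq_len(dm[1] - 1L) + 1L, dm[1]), , drop = FALSE]
      shifted <- aperm(array(pmin(up, dn), dm), order(perm))
      er <- pmin(er, shifted)
    }
    newrec <- pmax(er, img)
    if (max(abs(newrec - rec)) == 0) break
    rec <- newrec
  }
  rec
}

# Label 6-connected components of a logical (z, y, x) mask by iterative
# minimum-label propagation.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0L) return(lab)
  repeat {
    new <- lab
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(new, perm)
      dm <- dim(m)
      mm <- matrix(m, nrow = dm[1])
      mm[mm == 0L] <- .Machine$integer.max
      up <- mm[c(1L, seq_len(dm[1] - 1L)), , drop = FALSE]
      dn <- mm[c(seq_len(dm[1] - 1L) + 1L, dm[1]), , drop = FALSE]
      cand <- pmin(mm, up, dn)
      cand[cand == .Machine$integer.max] <- 0L
      cand <- aperm(array(cand, dm), order(perm))
      new <- ifelse(mask, pmin(ifelse(new == 0L, .Machine$integer.max, new),
                               ifelse(cand == 0L, .Machine$integer.max, cand)),
                    0L)
      new[new == .Machine$integer.max] <- 0L
      new <- array(as.integer(new), d)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# Marker-based watershed restricted to `mask`: voxels are flooded in
# increasing order of `relief`; seeds are the connected regional minima of
# the h-minima-suppressed relief. Ties/contested voxels join the first
# claiming basin (no watershed lines kept).
watershed_3d <- function(relief, mask, h) {
  d <- dim(relief)
  sup <- hminima_3d(relief, h)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))

  # regional minima of `sup` within mask: plateau components none of whose
  # in-mask neighbours is lower
  nb <- neighbors_6(idx, d)
  val <- sup[idx]
  is_min <- rep(TRUE, length(idx))
  has_escape <- rep(FALSE, length(idx))  # equal-valued neighbour that is lower
  for (j in 1:6) {
    ok <- !is.na(nb[, j]) & mask[nb[, j]]
    lower <- ok & sup[nb[, j]] < val
    is_min <- is_min & !lower
  }
  cand <- array(FALSE, d)
  cand[idx[is_min]] <- TRUE
  # a plateau (equal-valued, connected) is a regional minimum only if none
  # of its voxels touches lower ground: invalidate components containing a
  # voxel whose equal-valued in-mask neighbour failed the test above
  for (j in 1:6) {
    ok <- !is.na(nb[, j]) & mask[nb[, j]]
    has_escape <- has_escape |
      (ok & is_min & sup[nb[, j]] == val & !cand[ifelse(is.na(nb[, j]), 1L, nb[, j])])
  }
  seed_mask <- cand
  plateau <- label_components_3d(seed_mask)
  if (any(has_escape)) {
    bad <- unique(plateau[idx[has_escape & is_min]])
    bad <- bad[bad > 0L]
    if (length(bad) && length(bad) < max(plateau)) {
      seed_mask[plateau %in% bad & seed_mask] <- FALSE
      plateau <- label_components_3d(seed_mask)
    }
  }

  lab <- array(0L, d)
  lab[seed_mask] <- plateau[seed_mask]
  ord <- idx[order(sup[idx])]
  off <- neighbor_offsets_6(d)
  nvox <- prod(d)
  # iterate flooding until every masked voxel is claimed (plateaus can
  # need several passes)
  repeat {
    changed <- FALSE
    for (v in ord) {
      if (lab[v] != 0L) next
      z <- (v - 1L) %% d[1] + 1L
      y <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      x <- (v - 1L) %/% (d[1] * d[2]) + 1L
      best <- 0L
      bestval <- Inf
      for (j in 1:6) {
        w <- v + off[j]
        if (j <= 2L && ((j == 1L && z == 1L) || (j == 2L && z == d[1]))) next
        if (j > 2L && j <= 4L && ((j == 3L && y == 1L) || (j == 4L && y == d[2]))) next
        if (j > 4L && ((j == 5L && x == 1L) || (j == 6L && x == d[3]))) next
        if (w < 1L || w > nvox) next
        if (lab[w] > 0L && sup[w] < bestval) {
          bestval <- sup[w]
          best <- lab[w]
        }
      }
      if (best > 0L) {
        lab[v] <- best
        changed <- TRUE
      }
    }
    if (!changed || all(lab[idx] != 0L)) break
  }
  # isolated masked voxels with no seed path: give each component a label
  left <- idx[lab[idx] == 0L]
  if (length(left)) {
    extra_mask <- array(FALSE, d)
    extra_mask[left] <- TRUE
    extra <- label_components_3d(extra_mask)
    mx <- max(lab)
    lab[left] <- extra[left] + mx
  }
  lab
}

# Grow existing labels into the unlabelled part of `mask` (6-connected
# dilation until stable); used to give filled cavities the label of the
# region that encloses them.
propagate_labels <- function(lab, mask) {
  repeat {
    new <- lab
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(new, perm)
      dm <- dim(m)
      mm <- matrix(m, nrow = dm[1])
      up <- mm[c(1L, seq_len(dm[1] - 1L)), , drop = FALSE]
      dn <- mm[c(seq_len(dm[1] - 1L) + 1L, dm[1]), , drop = FALSE]
      cand <- aperm(array(pmax(up, dn), dm), order(perm))
      grow <- mask & new == 0L & cand > 0L
      new[grow] <- cand[grow]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Fill holes: first per z-slice in 2D (EBImage::fillHull), then fill
# cavities fully enclosed in 3D (background not reachable from the volume
# border under 6-connectivity).
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  filled <- mask
  for (z in seq_len(d[1])) {
    sl <- EBImage::fillHull(matrix(as.numeric(mask[z, , ]), d[2], d[3]))
    filled[z, , ] <- sl > 0
  }
  # 3-D fill: propagate "outside" from the border through background
  bg <- !filled
  outside <- array(FALSE, d)
  border <- array(FALSE, d)
  border[1, , ] <- TRUE; border[d[1], , ] <- TRUE
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  border[, , 1] <- TRUE; border[, , d[3]] <- TRUE
  outside[border & bg] <- TRUE
  repeat {
    grown <- outside
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(grown, perm)
      dm <- dim(m)
      mm <- matrix(m, nrow = dm[1])
      up <- mm[c(1L, seq_len(dm[1] - 1L)), , drop = FALSE]
      dn <- mm[c(seq_len(dm[1] - 1L) + 1L, dm[1]), , drop = FALSE]
      grown <- grown | aperm(array(up | dn, dm), order(perm))
    }
    grown <- grown & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  filled | (bg & !outside)
}

#' Segment one channel's z-stack into labelled cell regions
#'
#' Applies the DoG bandpass (anisotropic sigmas), thresholds the filtered
#' image, splits touching cells by a marker-based watershed on the negated
#' bandpassed image after h-minima suppression, fills holes, and removes
#' regions smaller than `min_voxels`. Centroids are intensity-weighted
#' (weights from the raw stack) and reported in micrometres.
#'
#' @param stack numeric array `(z, y, x)`, intensities normalised to
#'   `[0, 1]`.
#' @param cfg a [segmentation_config()].
#' @param voxel_size um per voxel, `c(x, y, z)`.
#' @return data.frame with one row per region: `region_id`, `voxels`,
#'   `x_um`, `y_um`, `z_um`, `intensity` (summed raw intensity), plus the
#'   label array as attribute `"labels"`.
#' @export
segment_frame <- function(stack, cfg = segmentation_config(),
                          voxel_size = c(1.1, 1.1, 8)) {
  stopifnot(inherits(cfg, "segmentation_config"))
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[1] < 2L)
    stop("'stack' must be a (z, y, x) array with >= 2 z-planes",
         call. = FALSE)
  if (max(stack) > 1 + 1e-9 || min(stack) < 0)
    stop("'stack' must be normalised to [0, 1]", call. = FALSE)

  bp <- dog_bandpass(stack, cfg$sigma_pos, cfg$sigma_neg, cfg$z_sigma_divisor)
  mask <- bp > cfg$threshold
  empty <- data.frame(region_id = integer(), voxels = integer(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      intensity = numeric())
  if (!any(mask)) {
    attr(empty, "labels") <- array(0L, d)
    return(empty)
  }
  # restrict the watershed to the mask bounding box (plus margin) -- the
  # transforms are local to the thresholded foreground
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 2L, 1L)
  hi <- pmin(apply(w, 2, max) + 2L, d)
  sub <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  bp_c <- bp[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  mask_c <- mask[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  lab_c <- watershed_3d(-bp_c, mask_c, cfg$h_min)
  filled_c <- fill_holes_3d(lab_c > 0L)
  # newly filled cavities inherit the label of their enclosing region
  if (any(filled_c & lab_c == 0L)) {
    lab_c <- propagate_labels(lab_c, filled_c)
  }
  lab <- array(0L, d)
  lab[sub[[1]], sub[[2]], sub[[3]]] <- lab_c
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= cfg$min_voxels)
  if (length(keep) == 0L) {
    attr(empty, "labels") <- array(0L, d)
    return(empty)
  }
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], keep)

  idx <- which(lab > 0L)
  li <- lab[idx]
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  # centroid weights from the bandpassed response: positive on the blob
  # and free of background and uncorrelated noise
  w <- pmax(bp[idx], 0)
  wsum <- tapply(w, li, sum)
  wsum[wsum == 0] <- 1e-12
  regions <- data.frame(
    region_id = as.integer(names(wsum)),
    voxels = as.integer(tabulate(li)[as.integer(names(wsum))]),
    x_um = as.numeric(tapply(w * (x - 0.5), li, sum) / wsum) * voxel_size[1],
    y_um = as.numeric(tapply(w * (y - 0.5), li, sum) / wsum) * voxel_size[2],
    z_um = as.numeric(tapply(w * (z - 0.5), li, sum) / wsum) * voxel_size[3],
    intensity = as.numeric(tapply(stack[idx], li, sum)))
  rownames(regions) <- NULL
  attr(regions, "labels") <- lab
  regions
}

#' Segment every frame and channel of a volume series
#'
#' Convenience wrapper around [segment_frame()]: normalises 8-bit
#' intensities to `[0, 1]`, runs background subtraction (optional) and
#' segmentation per frame and channel.
#'
#' @param v a [volume_series()] with 8-bit intensities (0..255).
#' @param cfg a [segmentation_config()].
#' @param background_subtract subtract the temporal-minimum background
#'   first (default `TRUE`).
#' @return data.frame of detections: `frame`, `t_min`, `channel`,
#'   `region_id`, `voxels`, `x_um`, `y_um`, `z_um`, `intensity`.
#' @export
segment_volumes <- function(v, cfg = segmentation_config(),
                            background_subtract = TRUE) {
  stopifnot(inherits(v, "volume_series"))
  if (background_subtract && dim(v$data)[1] > 1L) v <- subtract_background(v)
  d <- dim(v$data)
  out <- list()
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    stack <- v$data[t, ch, , , ] / 255
    reg <- segment_frame(array(stack, d[3:5]), cfg, v$voxel_size)
    if (nrow(reg) > 0) {
      reg$x_um <- reg$x_um + v$origin_um[1]
      reg$y_um <- reg$y_um + v$origin_um[2]
      reg$z_um <- reg$z_um + v$origin_um[3]
      reg$frame <- t
      reg$t_min <- (t - 1) * v$dt
      reg$channel <- ch
      out[[length(out) + 1L]] <-
        reg[, c("frame", "t_min", "channel", "region_id", "voxels",
                "x_um", "y_um", "z_um", "intensity")]
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), t_min = numeric(),
                      channel = integer(), region_id = integer(),
                      voxels = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), intensity = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative depth profile of fluorescence
#'
#' Sums intensity per optical section and returns the running fraction of
#' total intensity versus depth. Evenly distributed cells give a diagonal
#' (linear) profile; the curve is non-decreasing and ends at 1.
#'
#' @param v a [volume_series()].
#' @param channel channel index (1-based).
#' @param frame frame index (default 1).
#' @return data.frame with `z_slice`, `z_um`, `cumulative_fraction`.
#' @export
depth_intensity_profile <- function(v, channel = 1L, frame = 1L) {
  stopifnot(inherits(v, "volume_series"))
  d <- dim(v$data)
  if (channel > d[2] || frame > d[1]) stop("channel/frame out of range",
                                           call. = FALSE)
  slice_sum <- apply(v$data[frame, channel, , , , drop = FALSE], 3, sum)
  tot <- sum(slice_sum)
  if (tot <= 0) stop("channel has zero total intensity; profile undefined",
                     call. = FALSE)
  data.frame(z_slice = seq_len(d[3]),
             z_um = v$origin_um[3] + (seq_len(d[3]) - 0.5) * v$voxel_size[3],
             cumulative_fraction = cumsum(slice_sum) / tot)
}
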