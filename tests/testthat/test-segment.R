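# Render a stack of Gaussian blobs directly (no simulation), normalised
# to [0, 1].
blob_stack <- function(centers_um, dims_zyx = c(10, 48, 48),
                       voxel = c(1.1, 1.1, 8), amp = 0.8,
                       sigma_um = c(3, 3, 6)) {
  a <- array(0, dims_zyx)
  for (k in seq_len(nrow(centers_um))) {
    cx <- centers_um[k, 1] / voxel[1] + 0.5
    cy <- centers_um[k, 2] / voxel[2] + 0.5
    cz <- centers_um[k, 3] / voxel[3] + 0.5
    sv <- sigma_um / voxel
    gx <- exp(-(seq_len(dims_zyx[3]) - cx)^2 / (2 * sv[1]^2))
    gy <- exp(-(seq_len(dims_zyx[2]) - cy)^2 / (2 * sv[2]^2))
    gz <- exp(-(seq_len(dims_zyx[1]) - cz)^2 / (2 * sv[3]^2))
    a <- a + amp * outer(gz, outer(gy, gx))
  }
  pmin(a, 1)
}

test_that("temporal-minimum background subtraction removes static content", {
  arr <- array(5, dim = c(4, 2, 3, 6, 6))
  v <- volume_series(arr, c(1.1, 1.1, 8), 2)
  out <- subtract_background(v)
  expect_true(all(out$data == 0))

  # single frame: the minimum is the frame itself
  v1 <- volume_series(arr[1, , , , , drop = FALSE], c(1.1, 1.1, 8), 2)
  expect_true(all(subtract_background(v1)$data == 0))
})

test_that("background subtraction isolates a transient blob", {
  arr <- array(3, dim = c(3, 1, 4, 8, 8))
  blob <- array(0, dim = c(4, 8, 8))
  blob[2, 4, 5] <- 10
  arr[2, 1, , , ] <- arr[2, 1, , , ] + blob
  v <- volume_series(arr, c(1, 1, 1), 1)
  out <- subtract_background(v)$data
  # oracle: per-voxel min is 3 everywhere, so frames 1 and 3 vanish and
  # frame 2 keeps exactly the blob
  expect_true(all(out[1, 1, , , ] == 0))
  expect_true(all(out[3, 1, , , ] == 0))
  expect_equal(array(out[2, 1, , , ], dim(blob)), blob)
})

test_that("a blank stack yields zero regions", {
  reg <- segment_frame(array(0, c(6, 20, 20)), segmentation_config(),
                       c(1.1, 1.1, 8))
  expect_equal(nrow(reg), 0L)
})

test_that("the minimum-size rule drops 4-voxel and keeps 5-voxel regions", {
  # construct sources whose thresholded bandpass response covers exactly
  # 4 or 5 voxels: scale an asymmetric point pair so that the k-th largest
  # response value straddles the fixed 0.02 threshold
  base <- array(0, c(6, 24, 24))
  base[3, 12, 12] <- 1
  base[3, 12, 13] <- 0.55
  base[3, 11, 12] <- 0.3
  bp <- nkwell3d:::dog_bandpass(base, 1, 3, 8)
  v <- sort(bp[bp > 0], decreasing = TRUE)
  mk <- function(n_vox) {
    scale <- 0.02 / ((v[n_vox] + v[n_vox + 1]) / 2)
    segment_frame(base * scale, segmentation_config(), c(1.1, 1.1, 8))
  }
  stopifnot(v[4] > v[5], v[5] > v[6])
  expect_equal(nrow(mk(4L)), 0L)
  r5 <- mk(5L)
  expect_equal(nrow(r5), 1L)
  expect_equal(r5$voxels[1], 5L)
})

test_that("two well-separated blobs give two regions at accurate centroids", {
  centers <- rbind(c(12, 15, 40), c(42, 15, 40))  # 30 um apart in x
  st <- blob_stack(centers)
  reg <- segment_frame(st, segmentation_config(), c(1.1, 1.1, 8))
  expect_equal(nrow(reg), 2L)
  reg <- reg[order(reg$x_um), ]
  expect_lt(abs(reg$x_um[1] - 12), 1.1)
  expect_lt(abs(reg$x_um[2] - 42), 1.1)
  expect_lt(abs(reg$y_um[1] - 15), 1.1)
})

test_that("watershed splits touching blobs when the saddle is deep enough", {
  # 9 um apart: one connected thresholded component with two DoG maxima
  centers <- rbind(c(20, 24, 40), c(29, 24, 40))
  st <- blob_stack(centers)
  bp <- nkwell3d:::dog_bandpass(st, 1, 3, 8)
  expect_equal(max(nkwell3d:::label_components_3d(bp > 0.02)), 1L)
  reg <- segment_frame(st, segmentation_config(h_min = 0.01),
                       c(1.1, 1.1, 8))
  expect_equal(nrow(reg), 2L)
  # an h-value exceeding the basin depth suppresses the split
  reg2 <- segment_frame(st, segmentation_config(h_min = 0.4),
                        c(1.1, 1.1, 8))
  expect_equal(nrow(reg2), 1L)
})

test_that("segmentation rejects non-normalised input", {
  expect_error(segment_frame(array(2, c(4, 8, 8)), segmentation_config(),
                             c(1.1, 1.1, 8)), "normalised")
  expect_error(segment_frame(matrix(0, 4, 4), segmentation_config(),
                             c(1.1, 1.1, 8)), "z-planes")
})

test_that("region count is contrast-invariant above threshold", {
  centers <- rbind(c(12, 15, 40), c(42, 30, 24))
  r1 <- segment_frame(blob_stack(centers, amp = 0.45),
                      segmentation_config(), c(1.1, 1.1, 8))
  r2 <- segment_frame(blob_stack(centers, amp = 0.9),
                      segmentation_config(), c(1.1, 1.1, 8))
  expect_equal(nrow(r1), nrow(r2))
})

test_that("depth profile matches the running-sum oracle and its limits", {
  set.seed(4)
  arr <- array(runif(2 * 1 * 6 * 5 * 5), dim = c(2, 1, 6, 5, 5))
  v <- volume_series(arr, c(1, 1, 8), 2)
  prof <- depth_intensity_profile(v, channel = 1, frame = 1)
  slice_sums <- apply(arr[1, 1, , , ], 1, sum)
  expect_equal(prof$cumulative_fraction,
               cumsum(slice_sums) / sum(slice_sums), tolerance = 1e-9)
  expect_true(all(diff(prof$cumulative_fraction) >= 0))
  expect_equal(prof$cumulative_fraction[6], 1.0)

  # uniform slices -> linear (diagonal) profile
  u <- volume_series(array(1, dim = c(1, 1, 8, 4, 4)), c(1, 1, 8), 2)
  pu <- depth_intensity_profile(u, 1, 1)
  expect_equal(pu$cumulative_fraction, (1:8) / 8, tolerance = 1e-12)

  # all intensity in slice 1 -> immediate step to 1
  s0 <- array(0, dim = c(1, 1, 4, 4, 4))
  s0[1, 1, 1, , ] <- 3
  ps <- depth_intensity_profile(volume_series(s0, c(1, 1, 8), 2), 1, 1)
  expect_equal(ps$cumulative_fraction, rep(1, 4))

  z <- volume_series(array(0, dim = c(1, 1, 4, 4, 4)), c(1, 1, 8), 2)
  expect_error(depth_intensity_profile(z, 1, 1), "zero")
})
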