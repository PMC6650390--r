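test_that("track filters apply the duration and z-jump rules strictly", {
  cfg <- track_filter_config()
  # 59-min track (duration below one hour) is excluded
  short <- make_track(matrix(0, 60, 3), dt = 1)
  expect_equal(nrow(filter_tracks(short, cfg)), 0L)
  # 60-min track retained
  ok <- make_track(matrix(0, 61, 3), dt = 1)
  expect_equal(nrow(filter_tracks(ok, cfg)), 61L)
  # one z step of 41 um excludes; exactly 40 um is retained
  p <- matrix(0, 61, 3)
  p[31, 3] <- 41
  expect_equal(nrow(filter_tracks(make_track(p, dt = 1), cfg)), 0L)
  p[31, 3] <- 40
  expect_equal(nrow(filter_tracks(make_track(p, dt = 1), cfg)), 61L)
})

test_that("filtering a constructed cohort keeps exactly the valid tracks", {
  set.seed(1)
  mk <- function(id, n, zjump = 0) {
    p <- matrix(rnorm(n * 3), n, 3)
    if (zjump > 0) p[floor(n / 2), 3] <- p[floor(n / 2) - 1, 3] + zjump
    make_track(p, dt = 2, cell_id = id)
  }
  cohort <- rbind(mk(1, 40), mk(2, 40), mk(3, 40), mk(4, 40),
                  mk(5, 40, zjump = 50), mk(6, 40, zjump = 45),
                  mk(7, 20),            # 38 min, too short
                  mk(8, 40), mk(9, 40), mk(10, 40))
  kept <- filter_tracks(cohort, track_filter_config())
  expect_setequal(unique(kept$cell_id), c(1, 2, 3, 4, 8, 9, 10))
  # idempotence
  expect_identical(filter_tracks(kept, track_filter_config()), kept)
})

test_that("mean speed matches hand-computed values", {
  still <- make_track(matrix(1, 10, 3), dt = 2)
  expect_equal(mean_speed(still), 0)
  # straight 6.4-um steps every 2 min -> 3.2 um/min
  p <- cbind(seq(0, by = 6.4, length.out = 20), 0, 0)
  expect_equal(mean_speed(make_track(p, dt = 2)), 3.2)
  # (0,0,0) -> (3,4,0) -> (3,4,12): steps 5 and 12 um over 2 min each
  p2 <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  expect_equal(mean_speed(make_track(p2, dt = 2)), (5 / 2 + 12 / 2) / 2)
})

test_that("corrected displacement matches closed forms", {
  # straight line over 4 min: ratio 1, result sqrt(4) = 2
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(corrected_displacement(make_track(p, dt = 2)), 2.0)
  # closed loop -> 0
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(corrected_displacement(make_track(loop, dt = 2)), 0)
  # (0,0,0) -> (3,4,0) -> (3,4,12): net 13, path 17, t_tot 4
  p2 <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  expect_equal(corrected_displacement(make_track(p2, dt = 2)),
               13 / 17 * 2, tolerance = 1e-12)
  expect_error(corrected_displacement(make_track(matrix(0, 5, 3))),
               "zero total path")
})

test_that("corrected displacement never exceeds sqrt of track duration", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    tr <- brownian_track(n, M = runif(1, 0.5, 20), dt = 2)
    cd <- corrected_displacement(tr)
    expect_gte(cd, 0)
    expect_lte(cd, sqrt((n - 1) * 2) + 1e-12)
  }
})

test_that("msd agrees with the naive double-loop oracle", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    p <- matrix(rnorm(n * 3, sd = 5), n, 3)
    lag <- sample(3:(n - 1), 1)
    expect_equal(msd(p, lag), msd_naive(p, lag), tolerance = 1e-12)
  }
})

test_that("msd closed forms: stationary, ballistic, staircase", {
  expect_equal(msd(matrix(2, 10, 3), 4), rep(0, 4))
  # constant step d along a line: MSD(t_n) = (n d)^2
  d <- 3.5
  p <- cbind(seq(0, by = d, length.out = 12), 0, 0)
  expect_equal(msd(p, 5), (seq_len(5) * d)^2, tolerance = 1e-12)
  # unit staircase: MSD = 1, 2, 3 at lags 1..3
  stair <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(msd(stair, 3), c(1, 2, 3))
})

test_that("MSD fits recover exact exponents in the closed-form limits", {
  # ballistic: MSD = (v t)^2 -> alpha = 2 exactly
  v <- 6
  dt <- 2
  fit <- fit_msd_window((seq_len(6) * dt * v)^2, dt, 6)
  expect_equal(fit$alpha, 2, tolerance = 1e-9)
  # diffusive reference curve MSD(t_n) = n um^2 at dt = 1: alpha = 1 and
  # M = slope/6 = 1/6 exactly
  fit2 <- fit_msd_window(as.numeric(1:6), 1, 6)
  expect_equal(fit2$alpha, 1, tolerance = 1e-12)
  expect_equal(fit2$M, 1 / 6, tolerance = 1e-12)
  # negative slope clips M at zero
  fit3 <- fit_msd_window(seq(6, 1), 1, 6)
  expect_equal(fit3$M, 0)
  # zero MSD values leave alpha undefined
  expect_true(is.na(fit_msd_window(c(0, 1, 2, 3, 4, 5), 1, 6)$alpha))
})

test_that("windowed profiles are exact on noise-free ballistic tracks", {
  p <- cbind(seq(0, by = 12, length.out = 60), 0, 0)  # 6 um/min at dt 2
  prof <- windowed_profiles(make_track(p, dt = 2), window_config())
  core <- !is.na(prof$alpha)
  expect_true(any(core))
  expect_true(all(abs(prof$alpha[core] - 2) < 1e-9))
  expect_true(all(prof$M[core] > 4.9))  # reported, far above arrest
})

test_that("median windowed M and alpha recover Brownian ground truth", {
  set.seed(11)
  M_true <- 3
  Ms <- c()
  As <- c()
  for (i in 1:25) {
    tr <- brownian_track(60, M = M_true, dt = 2)
    prof <- windowed_profiles(tr, window_config())
    Ms <- c(Ms, prof$M[!is.na(prof$M)])
    As <- c(As, prof$alpha[!is.na(prof$alpha)])
  }
  expect_gt(length(Ms), 500)
  expect_equal(median(Ms), M_true, tolerance = 0.2)
  expect_true(median(As) > 0.8 && median(As) < 1.2)
})

test_that("mode classification applies thresholds and the run-length rule", {
  mk_prof <- function(M, alpha) {
    data.frame(frame = seq_along(M), t_min = 2 * seq_along(M),
               M = M, alpha = alpha, M_smooth = M, alpha_smooth = alpha)
  }
  cfg <- window_config()
  # M below threshold everywhere -> all TMAP
  expect_true(all(classify_modes(mk_prof(rep(1, 30), rep(1, 30)), cfg)
                  == "TMAP"))
  # motile and diffusive -> all random
  expect_true(all(classify_modes(mk_prof(rep(10, 30), rep(1, 30)), cfg)
                  == "random"))
  # alpha > 1.5 for 9 points only -> stays random; 10 points -> directed
  a9 <- c(rep(1, 10), rep(1.6, 9), rep(1, 11))
  expect_true(all(classify_modes(mk_prof(rep(10, 30), a9), cfg) == "random"))
  a10 <- c(rep(1, 10), rep(1.6, 10), rep(1, 10))
  lab <- classify_modes(mk_prof(rep(10, 30), a10), cfg)
  expect_equal(sum(lab == "directed"), 10L)
  # arrest takes precedence over a directed run
  lab2 <- classify_modes(mk_prof(c(rep(1, 15), rep(10, 15)), a10), cfg)
  expect_equal(unname(lab2[11:15]), rep("TMAP", 5))
  expect_equal(unname(lab2[16:20]), rep("directed", 5))
})

test_that("Stokes-Einstein threshold reproduces reference values", {
  # cell-sized particle in water at 37 C: the 4.9 um^2/min arrest threshold
  expect_equal(signif(brownian_threshold(8, 310.15, 6.9e-4), 2), 4.9)
  # D scales inversely with diameter
  expect_equal(brownian_threshold(16, 310.15, 6.9e-4),
               brownian_threshold(8, 310.15, 6.9e-4) / 2)
  # 2-um particle in water at 20 C: 0.215 um^2/s
  expect_equal(brownian_threshold(2, 293, 1e-3), 12.9, tolerance = 0.01)
  expect_error(brownian_threshold(-1), "> 0")
})

test_that("track summaries count fractions, groups and transitions", {
  tr <- make_track(matrix(cumsum(rep(1, 61)), 61, 3), dt = 2)
  all_tmap <- rep("TMAP", 61)
  s <- summarize_track(tr, all_tmap)
  expect_equal(s$frac_tmap, 1)
  expect_equal(s$tmap_group, "high")
  expect_equal(s$transitions_per_h, 0)
  # one label change over a 2-h labelled span -> 0.5 transitions/h
  lab <- c(rep("random", 30), rep("TMAP", 30), NA)
  s2 <- summarize_track(tr, lab)
  expect_equal(s2$transitions_per_h, 1 / 2)
  # brute-force check on a constructed label sequence
  runs <- c(rep("TMAP", 10), rep("random", 20), rep("directed", 15),
            rep("random", 16))
  s3 <- summarize_track(tr, runs)
  expect_equal(s3$frac_tmap, 10 / 61)
  expect_equal(s3$frac_random, 36 / 61)
  expect_equal(s3$frac_directed, 15 / 61)
  expect_equal(s3$frac_tmap + s3$frac_random + s3$frac_directed, 1,
               tolerance = 1e-9)
  expect_equal(s3$transitions_per_h, 3 / (61 * 2 / 60))
  expect_equal(s3$tmap_group, "medium")
})

test_that("population summary pools fractions by labelled time", {
  tr1 <- make_track(matrix(cumsum(rep(1, 61)), 61, 3), dt = 2, cell_id = 1)
  tr2 <- make_track(matrix(cumsum(rep(2, 61)), 61, 3), dt = 2, cell_id = 2)
  s1 <- summarize_track(tr1, rep("random", 61))
  pop1 <- population_summary(list(s1))
  expect_equal(c(pop1$frac_tmap, pop1$frac_random, pop1$frac_directed),
               c(0, 1, 0))
  s2 <- summarize_track(tr2, rep("directed", 61))
  s3 <- summarize_track(tr1, rep("TMAP", 61))
  pop <- population_summary(list(s3, s2))
  expect_equal(c(pop$frac_tmap, pop$frac_random, pop$frac_directed),
               c(0.5, 0, 0.5))
})
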