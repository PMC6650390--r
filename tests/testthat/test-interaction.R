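test_that("the 20-um contact boundary is strict", {
  nk <- make_track(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
                   dt = 2, cell_id = 1L)
  tg_in <- make_track(matrix(rep(c(19.9, 0, 0), 5), ncol = 3, byrow = TRUE),
                      dt = 2, cell_id = 2L, cell_type = "target")
  ep <- detect_contacts(nk, tg_in, contact_config())
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_frame, 1L)
  expect_equal(ep$duration_min, 5 * 2)  # half-open episode times
  tg_out <- tg_in
  tg_out$x_um <- 20.0
  expect_equal(nrow(detect_contacts(nk, tg_out, contact_config())), 0L)
})

test_that("contact episodes equal the brute-force all-pairs scan", {
  cfgc <- contact_config()
  set.seed(9)
  for (rep in 1:50) {
    n_nk <- sample(2:5, 1)
    n_tg <- sample(1:4, 1)
    n_fr <- sample(10:25, 1)
    nk <- do.call(rbind, lapply(seq_len(n_nk), function(i)
      make_track(matrix(runif(n_fr * 3, 0, 60), n_fr, 3), dt = 2,
                 cell_id = i)))
    tg <- do.call(rbind, lapply(seq_len(n_tg), function(j)
      make_track(matrix(runif(n_fr * 3, 0, 60), n_fr, 3), dt = 2,
                 cell_id = 100L + j, cell_type = "target")))
    got <- detect_contacts(nk, tg, cfgc)
    got <- got[order(got$nk_id, got$target_id, got$start_frame),
               c("nk_id", "target_id", "start_frame", "end_frame")]
    rownames(got) <- NULL
    want <- contacts_brute(nk, tg, cfgc$contact_radius, dt = 2)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("episodes per pair never overlap and durations are positive", {
  set.seed(13)
  nk <- do.call(rbind, lapply(1:4, function(i)
    make_track(matrix(runif(90, 0, 50), 30, 3), dt = 2, cell_id = i)))
  tg <- do.call(rbind, lapply(1:3, function(j)
    make_track(matrix(runif(90, 0, 50), 30, 3), dt = 2, cell_id = 10L + j,
               cell_type = "target")))
  ep <- detect_contacts(nk, tg, contact_config())
  expect_true(all(ep$duration_min > 0))
  for (g in split(ep, paste(ep$nk_id, ep$target_id))) {
    g <- g[order(g$start_frame), ]
    if (nrow(g) > 1)
      expect_true(all(g$start_frame[-1] > g$end_frame[-nrow(g)]))
  }
})

test_that("gap tolerance merges runs split by single dropouts", {
  nk <- make_track(matrix(0, 9, 3), dt = 2, cell_id = 1L)
  pos <- matrix(rep(c(5, 0, 0), 9), ncol = 3, byrow = TRUE)
  pos[5, 1] <- 30  # one frame out of range
  tg <- make_track(pos, dt = 2, cell_id = 2L, cell_type = "target")
  ep0 <- detect_contacts(nk, tg, contact_config(gap_tolerance = 0))
  expect_equal(nrow(ep0), 2L)
  ep1 <- detect_contacts(nk, tg, contact_config(gap_tolerance = 1))
  expect_equal(nrow(ep1), 1L)
  expect_equal(ep1$start_frame, 1L)
  expect_equal(ep1$end_frame, 9L)
})

test_that("death calling needs a sustained drop below half baseline", {
  cfgc <- contact_config()
  flat <- data.frame(frame = 1:20, t_min = 2 * (0:19), intensity = 100)
  expect_null(detect_target_death(flat, cfgc))
  # sustained step to 10% of baseline: called at the step frame
  step <- flat
  step$intensity[8:20] <- 10
  d <- detect_target_death(step, cfgc)
  expect_equal(d$death_frame, 8L)
  # transient one-frame dip does not trigger
  dip <- flat
  dip$intensity[8] <- 10
  expect_null(detect_target_death(dip, cfgc))
  expect_error(detect_target_death(flat[1:2, ], cfgc), "death_min_frames")
})

test_that("outcome assignment follows the attribution window rules", {
  cfgc <- contact_config(death_attribution_window = 30)
  ep <- data.frame(nk_id = c(1L, 2L), target_id = 7L,
                   start_frame = c(1L, 20L), end_frame = c(10L, 30L),
                   start_min = c(0, 40), end_min = c(22, 62),
                   duration_min = c(22, 22))
  # death mid-first-episode -> first episode cytolytic
  r1 <- assign_outcomes(ep, data.frame(target_id = 7L, death_min = 10), cfgc)
  expect_equal(r1$episodes$outcome, c("cytolytic", "non-cytolytic"))
  expect_equal(r1$nk_tally$kills, c(1L, 0L))
  expect_equal(r1$nk_tally$contacts, c(1L, 1L))
  # death 10 min after the second episode ends -> second wins
  r2 <- assign_outcomes(ep, data.frame(target_id = 7L, death_min = 72), cfgc)
  expect_equal(r2$episodes$outcome, c("non-cytolytic", "cytolytic"))
  # no death -> all non-cytolytic
  r3 <- assign_outcomes(ep, NULL, cfgc)
  expect_true(all(r3$episodes$outcome == "non-cytolytic"))
  # death far beyond the window -> unattributed
  r4 <- assign_outcomes(ep, data.frame(target_id = 7L, death_min = 500), cfgc)
  expect_equal(r4$unattributed_deaths, 7L)
  expect_true(all(r4$episodes$outcome == "non-cytolytic"))
})

test_that("interaction statistics match hand arithmetic and exact U test", {
  ep <- data.frame(nk_id = c(1L, 1L, 2L), target_id = c(5L, 6L, 5L),
                   start_min = 0, end_min = c(10, 20, 30),
                   duration_min = c(10, 20, 30),
                   outcome = c("cytolytic", "non-cytolytic", "cytolytic"))
  st <- interaction_stats(ep, n_nk = 4L)
  expect_equal(st$mean_duration_min, 20)
  expect_equal(st$sd_duration_min, 10)  # sample SD
  expect_equal(st$cytolytic_fraction, 2 / 3)
  expect_equal(st$frac_nk_with_contact, 2 / 4)
  # exact Mann-Whitney: {1,2,3} vs {4,5,6} -> U = 0, two-sided p = 0.1
  ep2 <- data.frame(nk_id = 1L, target_id = 1L, start_min = 0,
                    end_min = 1, duration_min = c(1, 2, 3, 4, 5, 6),
                    outcome = rep(c("cytolytic", "non-cytolytic"),
                                  each = 3))
  expect_equal(interaction_stats(ep2)$mw_p_value, 0.1, tolerance = 1e-9)
  # identical groups -> p = 1
  ep3 <- ep2
  ep3$duration_min <- rep(c(4, 8, 15), 2)
  expect_equal(interaction_stats(ep3)$mw_p_value, 1, tolerance = 1e-9)
})

test_that("nearest-target distances equal the exhaustive minimum", {
  nk <- make_track(matrix(0, 5, 3), cell_id = 1L)
  tg <- make_track(matrix(rep(c(30, 0, 0), 5), ncol = 3, byrow = TRUE),
                   cell_id = 9L, cell_type = "target")
  nt <- nearest_target_distance(nk, tg)
  expect_equal(nt$distance_um, 30)
  # coincident -> 0
  tg0 <- make_track(matrix(0, 5, 3), cell_id = 9L, cell_type = "target")
  expect_equal(nearest_target_distance(nk, tg0)$distance_um, 0)
  # random scene vs brute force
  set.seed(21)
  nk_m <- do.call(rbind, lapply(1:4, function(i)
    make_track(matrix(runif(30, 0, 100), 10, 3), cell_id = i)))
  tg_m <- do.call(rbind, lapply(1:5, function(j)
    make_track(matrix(runif(30, 0, 100), 10, 3), cell_id = 10L + j,
               cell_type = "target")))
  nt2 <- nearest_target_distance(nk_m, tg_m)
  for (i in 1:4) {
    p0 <- as.numeric(nk_m[nk_m$cell_id == i & nk_m$frame == 1,
                          c("x_um", "y_um", "z_um")])
    dmin <- min(sapply(10 + 1:5, function(j) {
      q <- as.numeric(tg_m[tg_m$cell_id == j & tg_m$frame == 1,
                           c("x_um", "y_um", "z_um")])
      sqrt(sum((p0 - q)^2))
    }))
    expect_equal(nt2$distance_um[nt2$nk_id == i], dmin)
  }
  expect_error(nearest_target_distance(nk, tg[0, ]), "no targets")
})

test_that("cytolytic assignment recovers simulated killer-target pairs", {
  # kill delays well inside the attribution window, assay-like cell
  # density (~1e-6 NK/um^3) so simultaneous conjugates at the moment of
  # death -- inherently ambiguous -- stay rare
  truth_pairs <- character()
  got_pairs <- character()
  for (sd in c(30, 44)) {
    cfg <- simulation_config(n_nk = 30, n_target = 12, duration = 540,
                             well_size = c(350, 350, 250),
                             p_kill_per_contact = 0.8, kill_delay_mean = 5,
                             seed = sd)
    s <- simulate_tracks(cfg)
    res <- analyze_interactions(s$tracks, contact_config())
    cy <- res$episodes[res$episodes$outcome == "cytolytic", ]
    truth_pairs <- c(truth_pairs,
                     paste(s$truth$kills$killer_id, s$truth$kills$target_id))
    got_pairs <- c(got_pairs, paste(cy$nk_id, cy$target_id))
    # kill count never exceeds contact count
    expect_true(all(res$nk_tally$kills <= res$nk_tally$contacts))
  }
  expect_gt(length(truth_pairs), 10)
  expect_gte(mean(truth_pairs %in% got_pairs), 0.95)
})
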