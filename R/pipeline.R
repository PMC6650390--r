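#' Read and write track tables as CSV
#'
#' The on-disk track format has columns `cell_id`, `cell_type`, `frame`,
#' `t_min`, `x_um`, `y_um`, `z_um`, `true_mode`, `alive`; the last two
#' are optional (simulation ground truth only).
#'
#' @param tracks track table.
#' @param path CSV path.
#' @return `path` (write) or the track data.frame (read).
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the stage toggles and the per-stage configurations. A single
#' global seed governs every stochastic stage; each stage derives its own
#' seed by a fixed offset, so disabling the imaging stage does not change
#' the simulated tracks.
#'
#' @param seed global integer seed.
#' @param use_imaging render volumes and recover tracks by
#'   segmentation + linking (`TRUE`) or analyse the simulated tracks
#'   directly (`FALSE`).
#' @param sim a [simulation_config()]; its `seed` is overridden by
#'   `seed`.
#' @param render a [render_config()].
#' @param segmentation a [segmentation_config()].
#' @param linking a [linking_config()].
#' @param track_filter a [track_filter_config()].
#' @param window a [window_config()].
#' @param contact a [contact_config()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, use_imaging = FALSE,
                       sim = simulation_config(),
                       render = render_config(),
                       segmentation = segmentation_config(),
                       linking = linking_config(),
                       track_filter = track_filter_config(),
                       window = window_config(),
                       contact = contact_config()) {
  structure(list(seed = as.integer(seed), use_imaging = use_imaging,
                 sim = sim, render = render, segmentation = segmentation,
                 linking = linking, track_filter = track_filter,
                 window = window, contact = contact),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Every top-level key maps to the matching `*_config()` constructor;
#' unknown fields are rejected by the constructors. A `seed` key is
#' mandatory.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must provide a seed", call. = FALSE)
  build <- function(ctor, key) {
    if (is.null(y[[key]])) ctor() else do.call(ctor, y[[key]])
  }
  run_config(seed = y$seed,
             use_imaging = isTRUE(y$use_imaging),
             sim = build(simulation_config, "simulation"),
             render = build(render_config, "render"),
             segmentation = build(segmentation_config, "segmentation"),
             linking = build(linking_config, "linking"),
             track_filter = build(track_filter_config, "track_filter"),
             window = build(window_config, "window"),
             contact = build(contact_config, "contact"))
}

#' Run the simulate -> (image) -> analyse pipeline
#'
#' Executes the enabled stages in order and writes every intermediate
#' artifact plus a JSON manifest (configuration, package version, MD5
#' checksums of the CSV/JSON outputs) into `out_dir`. With
#' `use_imaging = TRUE` the simulated scene is rendered to voxel stacks,
#' segmented and re-linked, and the recovered NK tracks feed the
#' migration analysis; otherwise the simulated tracks are analysed
#' directly. Identical configuration and seed give identical manifest
#' checksums.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`tracks`,
#'   `truth`, `migration`, `interactions`, and `linked`/`detections` when
#'   imaging is enabled) and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  put <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (grepl("[.]json$", name)) {
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    } else {
      utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
    }
    artifacts <<- c(artifacts, p)
    p
  }

  sim_cfg <- cfg$sim
  sim_cfg$seed <- cfg$seed
  sim <- simulate_tracks(sim_cfg)
  put(sim$tracks, "tracks_true.csv")
  put(sim$truth$contacts, "truth_contacts.csv")
  put(sim$truth$kills, "truth_kills.csv")

  analysis_tracks <- sim$tracks
  linked <- NULL
  detections <- NULL
  if (cfg$use_imaging) {
    v <- render_volumes(sim$tracks, sim$truth, cfg$render,
                        seed = cfg$seed + 1009L)
    detections <- segment_volumes(v, cfg$segmentation)
    put(detections, "detections.csv")
    nk_det <- detections[detections$channel == 1L, ]
    if (nrow(nk_det) == 0L)
      stop("pipeline stage 'segment' produced no NK detections",
           call. = FALSE)
    linked <- link_tracks(nk_det, cfg$linking, voxel_size = v$voxel_size,
                          dt = v$dt)
    linked$cell_type <- "NK"
    put(linked, "tracks_linked.csv")
    tg <- sim$tracks[sim$tracks$cell_type == "target", ]
    analysis_tracks <- rbind(linked[, c("cell_id", "cell_type", "frame",
                                        "t_min", "x_um", "y_um", "z_um")],
                             tg[, c("cell_id", "cell_type", "frame",
                                    "t_min", "x_um", "y_um", "z_um")])
  }

  nk <- analysis_tracks[analysis_tracks$cell_type == "NK", ]
  mig <- analyze_migration(nk, cfg$track_filter, cfg$window)
  put(mig$profiles, "mode_profiles.csv")
  put(do.call(rbind, lapply(mig$summaries, as.data.frame)),
      "track_summaries.csv")
  pop <- mig$population
  pop$tmap_groups <- as.list(pop$tmap_groups)
  put(pop[!vapply(pop, is.null, logical(1))], "population_summary.json")

  inter <- analyze_interactions(analysis_tracks, cfg$contact)
  put(inter$episodes, "contact_episodes.csv")
  put(inter$nk_tally, "nk_tally.csv")
  if (!is.null(inter$stats)) put(inter$stats, "interaction_summary.json")

  manifest <- list(
    package = "nkwell3d",
    version = as.character(utils::packageVersion("nkwell3d")),
    seed = cfg$seed,
    use_imaging = cfg$use_imaging,
    config = lapply(unclass(cfg)[-(1:2)], unclass),
    checksums = as.list(tools::md5sum(sort(artifacts))))
  names(manifest$checksums) <- basename(sort(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tracks = sim$tracks, truth = sim$truth,
                 migration = mig, interactions = inter,
                 linked = linked, detections = detections,
                 out_dir = out_dir))
}

#' Generate report figures and a summary table from a run directory
#'
#' Reads the artifacts written by [run_pipeline()] and produces PNG
#' figures (origin-centred track plot, migration-mode pie, speed and
#' confinement histograms, transitions histogram, contact-duration
#' histogram and per-NK contact/kill counts) plus
#' `report_summary.csv` collecting the population statistics. When no
#' contact episodes exist, the interaction panels are replaced by a
#' "no contacts" placeholder.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return Invisibly, the summary data.frame.
#' @export
report <- function(run_dir) {
  need <- file.path(run_dir, c("tracks_true.csv", "population_summary.json"))
  if (!all(file.exists(need)))
    stop("missing upstream outputs in ", run_dir, call. = FALSE)
  tracks <- read_tracks_csv(file.path(run_dir, "tracks_true.csv"))
  pop <- jsonlite::read_json(file.path(run_dir, "population_summary.json"),
                             simplifyVector = TRUE)
  fig <- function(name, expr) {
    grDevices::png(file.path(run_dir, name), width = 720, height = 620)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
  }
  nk <- tracks[tracks$cell_type == "NK", ]
  fig("fig_tracks.png", {
    plot(NA, xlim = c(-200, 200), ylim = c(-200, 200), asp = 1,
         xlab = "x (um)", ylab = "y (um)",
         main = "NK trajectories (origin-centred)")
    for (tr in split(nk, nk$cell_id)) {
      tr <- tr[order(tr$frame), ]
      graphics::lines(tr$x_um - tr$x_um[1], tr$y_um - tr$y_um[1],
                      col = grDevices::rgb(0, 0, 0, 0.35))
    }
  })
  fig("fig_mode_pie.png", {
    graphics::pie(c(TMAP = pop$frac_tmap, random = pop$frac_random,
                    directed = pop$frac_directed),
                  main = "Time in each migration mode")
  })
  fig("fig_speed_hist.png", {
    graphics::hist(unlist(pop$speeds), breaks = 20,
                   xlab = "mean speed (um/min)", main = "Track mean speeds")
  })
  fig("fig_confinement_hist.png", {
    graphics::hist(unlist(pop$corrected_displacements), breaks = 20,
                   xlab = "corrected displacement (sqrt(min))",
                   main = "Confinement")
  })
  fig("fig_transitions_hist.png", {
    graphics::hist(unlist(pop$transitions_per_h), breaks = 20,
                   xlab = "mode transitions per hour", main = "Stop-and-go")
  })
  ep_path <- file.path(run_dir, "contact_episodes.csv")
  episodes <- if (file.exists(ep_path)) utils::read.csv(ep_path)
    else data.frame()
  if (nrow(episodes) > 0) {
    fig("fig_contact_durations.png", {
      graphics::hist(episodes$duration_min, breaks = 20,
                     xlab = "contact duration (min)",
                     main = "NK-target conjugation periods")
    })
    tally <- utils::read.csv(file.path(run_dir, "nk_tally.csv"))
    fig("fig_contacts_kills.png", {
      graphics::barplot(t(as.matrix(tally[, c("contacts", "kills")])),
                        beside = TRUE, names.arg = tally$nk_id,
                        legend.text = c("contacts", "kills"),
                        xlab = "NK cell", ylab = "count",
                        main = "Contacts and kills per NK cell")
    })
  } else {
    fig("fig_contact_durations.png", {
      plot.new()
      graphics::text(0.5, 0.5, "no contacts")
    })
  }
  ist_path <- file.path(run_dir, "interaction_summary.json")
  ist <- if (file.exists(ist_path))
    jsonlite::read_json(ist_path, simplifyVector = TRUE) else NULL
  summary_df <- data.frame(
    statistic = c("n_tracks", "mean_speed_um_min", "sd_speed_um_min",
                  "frac_tmap", "frac_random", "frac_directed",
                  "dwell_mean_min", "n_contact_episodes",
                  "mean_contact_duration_min", "cytolytic_fraction"),
    value = c(pop$n_tracks, pop$mean_speed, pop$sd_speed, pop$frac_tmap,
              pop$frac_random, pop$frac_directed,
              ifelse(is.null(pop$dwell_mean_min) ||
                       is.na(pop$dwell_mean_min), NA, pop$dwell_mean_min),
              if (is.null(ist)) c(0, NA, NA) else
                c(ist$n_episodes, ist$mean_duration_min,
                  ist$cytolytic_fraction)))
  utils::write.csv(summary_df, file.path(run_dir, "report_summary.csv"),
                   row.names = FALSE)
  invisible(summary_df)
}
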