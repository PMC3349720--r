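# Orchestration: generate -> discretize -> analyze, driven by a single
# YAML/JSON configuration, with per-stage CSV/JSON artifacts and a run
# manifest.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    cohort = list(n_individuals = 5),
    generator = list(duration = 1800),
    discretize = list(move_threshold = 0.3, margin = 3),
    turning = list(),
    distfit = list(exclusion_cap = 1000,
                   spwmc = FALSE),
    correlations = list(max_lag = 10),
    modes = list(epsilon = 300, grid_step = 60))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML or JSON with optional sections `seed`, `cohort`, `generator`
#' (fields of [generator_config()]), `discretize`, `turning`, `distfit`,
#' `correlations`, `modes`; missing entries fall back to the defaults
#' (which are the standard study parameters: 0.3 cm threshold, 0.2 s
#' frames, 3 cm margin, epsilon 300 s, 1000 s pause cap).
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .merge_config(.pipeline_defaults(), user)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order and writes per-stage artifacts
#' into `out_dir`: `trajectories.csv`, `ledgers.json`, `bouts.csv`,
#' `turn_curve.csv`, `turn_influence.csv`, `fits.json`, `pacf.csv`,
#' `crosscorr.csv`, `segments.csv`, `mode_curve.csv` and `manifest.json`
#' (seed, package version, full configuration, stage counts). Stages
#' after `generate` read the bouts table from `out_dir` if it is not
#' being recomputed, so subsets like `c("distfit")` run against
#' precomputed artifacts. Reruns with the same seed are numerically
#' identical.
#'
#' @param config Path to a config file or a configuration list.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector from `c("generate", "discretize",
#'   "turning", "distfit", "correlations", "modes")` or `"all"`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = "all") {
  all_stages <- c("generate", "discretize", "turning", "distfit",
                  "correlations", "modes")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- .merge_config(.pipeline_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log <- list()

  gen_cfg <- do.call(generator_config,
                     c(config$generator, list(seed = config$seed)))

  if ("generate" %in% stages) {
    cohort <- generate_cohort(gen_cfg, config$cohort$n_individuals)
    write_trajectory_csv(cohort, file.path(out_dir, "trajectories.csv"))
    res$cohort <- cohort
    log$generate <- list(n_individuals = length(cohort),
                         n_frames = sum(vapply(cohort, nrow, numeric(1))))
  }

  needs_bouts <- any(c("turning", "distfit", "correlations", "modes")
                     %in% stages)
  if ("discretize" %in% stages || needs_bouts) {
    if (is.null(res$cohort) && !("discretize" %in% stages)) {
      bp <- file.path(out_dir, "bouts.csv")
      if (!file.exists(bp)) {
        stop("stage requires precomputed bouts but '", bp,
             "' is missing; run the discretize stage first")
      }
      res$seqs <- .read_bouts_csv(bp)
    } else {
      if (is.null(res$cohort)) {
        tp <- file.path(out_dir, "trajectories.csv")
        if (!file.exists(tp)) {
          stop("discretize requires trajectories but '", tp,
               "' is missing; run the generate stage first")
        }
        res$cohort <- read_trajectory_csv(
          tp, frame_dt = gen_cfg$frame_dt,
          arena_outer_radius = gen_cfg$arena_outer_radius,
          dome_radius = gen_cfg$dome_radius)
      }
      res$seqs <- lapply(res$cohort, discretize_trajectory,
                         move_threshold = config$discretize$move_threshold,
                         margin = config$discretize$margin)
      .write_bouts_csv(res$seqs, file.path(out_dir, "bouts.csv"))
      log$discretize <- list(
        n_bouts = sum(vapply(res$seqs, function(s) nrow(s$bouts),
                             numeric(1))),
        n_censored_edge = sum(vapply(res$seqs, function(s)
          sum(s$bouts$censored_edge), numeric(1))))
    }
  }

  if ("turning" %in% stages) {
    pairs <- do.call(rbind, lapply(res$seqs, turn_after_pause))
    curve <- turn_probability_curve(pairs)
    infl <- turn_influence(curve)
    .write_curve_csv(curve, file.path(out_dir, "turn_curve.csv"))
    utils::write.csv(infl, file.path(out_dir, "turn_influence.csv"),
                     row.names = FALSE)
    res$turn_curve <- curve; res$turn_influence <- infl
    log$turning <- list(n_pauses = nrow(pairs))
  }

  if ("distfit" %in% stages) {
    mv <- unlist(lapply(res$seqs, bout_durations, state = "move"))
    pa <- unlist(lapply(res$seqs, bout_durations, state = "pause"))
    fits <- list(
      moves = .fit_to_record(pooled_fit(mv, exclusion_cap = Inf,
                                        frame_dt = gen_cfg$frame_dt)),
      pauses = .fit_to_record(pooled_fit(
        pa, exclusion_cap = config$distfit$exclusion_cap,
        frame_dt = gen_cfg$frame_dt)))
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    res$fits <- fits
    log$distfit <- list(n_moves = length(mv), n_pauses = length(pa))
    if (isTRUE(config$distfit$spwmc)) {
      prof <- spwmc(pa, frame_dt = gen_cfg$frame_dt)
      utils::write.csv(
        data.frame(truncation = prof$truncation, n = prof$n, prof$waic,
                   check.names = FALSE),
        file.path(out_dir, "spwmc.csv"), row.names = FALSE)
      res$spwmc <- prof
    }
  }

  if ("correlations" %in% stages) {
    ml <- config$correlations$max_lag
    pacf_rows <- list(); cc_rows <- list()
    for (id in names(res$seqs)) {
      s <- res$seqs[[id]]
      mvs <- bout_durations(s, "move", include_censored = TRUE)
      pas <- bout_durations(s, "pause", include_censored = TRUE)
      prs <- move_pause_pairs(s)
      if (length(mvs) > ml + 10) {
        pacf_rows[[id]] <- cbind(individual_id = id, series = "move",
                                 partial_autocorrelation(mvs, ml))
      }
      if (length(pas) > ml + 10) {
        pacf_rows[[paste0(id, "p")]] <-
          cbind(individual_id = id, series = "pause",
                partial_autocorrelation(pas, ml))
      }
      if (nrow(prs) > ml + 10) {
        cc_rows[[id]] <- cbind(individual_id = id,
                               cross_correlation(prs$move, prs$pause, ml))
      }
    }
    if (length(pacf_rows)) {
      utils::write.csv(do.call(rbind, pacf_rows),
                       file.path(out_dir, "pacf.csv"), row.names = FALSE)
    }
    if (length(cc_rows)) {
      utils::write.csv(do.call(rbind, cc_rows),
                       file.path(out_dir, "crosscorr.csv"),
                       row.names = FALSE)
    }
    res$pacf <- pacf_rows; res$crosscorr <- cc_rows
    log$correlations <- list(n_individuals_pacf = length(pacf_rows))
  }

  if ("modes" %in% stages) {
    segs <- lapply(res$seqs, function(s)
      partial_sums_segment(signed_series(s),
                           epsilon = config$modes$epsilon))
    seg_df <- do.call(rbind, lapply(names(segs), function(id)
      cbind(individual_id = id, segs[[id]]$segments)))
    utils::write.csv(seg_df, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    grid <- seq(0, gen_cfg$duration, by = config$modes$grid_step)
    curve <- mode_probability_curve(segs, grid)
    utils::write.csv(curve, file.path(out_dir, "mode_curve.csv"),
                     row.names = FALSE)
    res$segmentations <- segs; res$mode_curve <- curve
    log$modes <- list(n_segments = nrow(seg_df))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("intermove")),
    seed = config$seed, stages = stages, config = config, counts = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(res, list(manifest = manifest)))
}

.fit_to_record <- function(fit) {
  list(model = fit$model$family,
       n = fit$n,
       max = fit$model$support[2],
       params = as.list(fit$params),
       neg_loglik = -fit$loglik,
       aic = fit$aic)
}

.write_bouts_csv <- function(seqs, path) {
  df <- do.call(rbind, lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    n_turns <- vapply(s$directions, function(d)
      if (length(d) < 2) 0L else sum(d[-1] != d[-length(d)]), integer(1))
    data.frame(individual_id = id, state = s$bouts$state,
               start_s = (s$bouts$start_frame - 1) * s$frame_dt,
               duration_s = s$bouts$duration, block = s$bouts$block,
               censored_edge = s$bouts$censored_edge, n_turns = n_turns)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.read_bouts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$individual_id), function(d) {
    dt <- 0.2
    structure(list(
      bouts = data.frame(state = d$state,
                         start_frame = as.integer(round(d$start_s / dt)) + 1L,
                         n_frames = as.integer(round(d$duration_s / dt)),
                         duration = d$duration_s, block = d$block,
                         censored_edge = d$censored_edge),
      directions = rep(list(integer(0)), nrow(d)),
      censored_gaps = data.frame(start_frame = integer(0),
                                 end_frame = integer(0)),
      frame_dt = dt, individual_id = d$individual_id[1]),
      class = "bout_seq")
  })
}

.write_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(bin_left_s = curve$bin_left, bin_right_s = curve$bin_right,
               value = curve$p, ci_lo = curve$lo, ci_hi = curve$hi,
               n = curve$n),
    path, row.names = FALSE)
  invisible(path)
}
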