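# Synthetic trajectory generator.
#
# Emulates 8 h recordings of a single juvenile locust circling an annular
# arena at 5 Hz: alternating move/pause bouts with heavy-tailed (power law
# x stretched-exponential tail) durations, pause-length-dependent
# reorientation, within-pause fidgeting, and a slowly drifting two-mode
# (local search / relocation) regime. The generator emits a ground-truth
# bout ledger so every downstream stage can be tested by exact recovery.

#' Generator configuration
#'
#' Builds and validates the configuration for the synthetic trajectory
#' generator. Defaults reproduce the study conditions: 0.2 s frames, 8 h
#' records, an annular arena of outer radius 40 cm with a 17.5 cm central
#' dome, move/pause duration laws with the reference stretched-tail
#' power-law parameters (moves: mu 1.49, beta 0.55, theta 8 s; pauses: mu
#' 1.67, beta 0.23, theta 15.27 s), a turn-after-pause curve rising to a
#' 0.25 plateau between 6 and 100 s and increasing again beyond 100 s,
#' and a relocation-mode occupancy drifting from 0.2 to 0.6 over the
#' record.
#'
#' @param frame_dt Frame interval (s).
#' @param duration Record length (s).
#' @param arena_outer_radius,dome_radius Arena geometry (cm).
#' @param move_dist_params,pause_dist_params Lists with `mu` (in (1, 3]),
#'   `beta` (in (0, 1]), `theta` (s; may be `Inf` for a pure power law)
#'   and `xmin` (s) of the bout-length laws.
#' @param turn_after_pause_curve List with `x` (pause lengths, s) and `p`
#'   (probabilities); the probability of reversing travel direction after
#'   a pause is interpolated linearly in log10 pause length and held
#'   constant beyond the end knots.
#' @param within_pause_switch_rate Per-frame-transition probability that
#'   the fidgeting rotation direction flips during a pause.
#' @param mode_schedule List with `t` (s) and `p`: probability that a new
#'   behavioural mode segment is "relocation", interpolated linearly in
#'   time.
#' @param mode_dwell Mean behavioural-mode segment duration (s); dwell
#'   times are gamma distributed (shape 4) so very short segments are
#'   rare.
#' @param move_pause_coupling Gaussian-copula correlation between each
#'   move and its adjacent pause, in `[-1, 1]`. Negative values couple
#'   long moves with short pauses (and vice versa) while preserving both
#'   marginal bout-length laws exactly.
#' @param relocation_pause_cap In relocation mode pauses are resting
#'   pauses: drawn from the pause law conditioned on `<= cap` (s).
#' @param local_search_move_cap In local-search mode moves are short:
#'   drawn from the move law conditioned on `<= cap` (s).
#' @param move_speed Tangential speed during moves (cm/s); must exceed
#'   the move classification threshold per frame by a safe margin.
#' @param jitter_radius Confinement radius of within-pause positional
#'   jitter (cm); keeps every pause displacement below the 0.3 cm
#'   classification threshold.
#' @param seed Master seed; all sub-streams derive from it.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(frame_dt = 0.2,
                             duration = 28800,
                             arena_outer_radius = 40,
                             dome_radius = 17.5,
                             move_dist_params = list(mu = 1.49, beta = 0.55,
                                                     theta = 8, xmin = 0.2),
                             pause_dist_params = list(mu = 1.67, beta = 0.23,
                                                      theta = 15.27,
                                                      xmin = 0.2),
                             turn_after_pause_curve = list(
                               x = c(0.2, 6, 100, 1000),
                               p = c(0.05, 0.25, 0.25, 0.5)),
                             within_pause_switch_rate = 0.55,
                             mode_schedule = list(t = c(0, 28800),
                                                  p = c(0.2, 0.6)),
                             mode_dwell = 1440,
                             move_pause_coupling = -0.6,
                             relocation_pause_cap = 6,
                             local_search_move_cap = 6,
                             move_speed = 3,
                             jitter_radius = 0.15,
                             seed = 1L) {
  cfg <- structure(list(
    frame_dt = frame_dt, duration = duration,
    arena_outer_radius = arena_outer_radius, dome_radius = dome_radius,
    move_dist_params = move_dist_params,
    pause_dist_params = pause_dist_params,
    turn_after_pause_curve = turn_after_pause_curve,
    within_pause_switch_rate = within_pause_switch_rate,
    mode_schedule = mode_schedule, mode_dwell = mode_dwell,
    move_pause_coupling = move_pause_coupling,
    relocation_pause_cap = relocation_pause_cap,
    local_search_move_cap = local_search_move_cap,
    move_speed = move_speed, jitter_radius = jitter_radius,
    seed = as.integer(seed)), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config Object to validate.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with(config, {
    if (!(frame_dt > 0)) stop("frame_dt must be positive")
    if (!(duration >= frame_dt)) stop("duration must cover >= 1 frame")
    if (!(arena_outer_radius > 0 && dome_radius > 0 &&
          dome_radius < arena_outer_radius))
      stop("radii must be positive with dome_radius < arena_outer_radius")
    for (p in list(move_dist_params, pause_dist_params)) {
      if (!(p$mu > 1 && p$mu <= 3)) stop("mu must lie in (1, 3]")
      if (!(p$beta > 0 && p$beta <= 1)) stop("beta must lie in (0, 1]")
      if (!(p$theta > 0)) stop("theta must be positive")
      if (!(p$xmin >= frame_dt)) stop("xmin must be >= frame_dt")
    }
    if (any(turn_after_pause_curve$p < 0 | turn_after_pause_curve$p > 1))
      stop("turn probabilities must lie in [0, 1]")
    if (is.unsorted(turn_after_pause_curve$x, strictly = TRUE))
      stop("turn curve knots must be strictly increasing")
    if (!(within_pause_switch_rate >= 0 && within_pause_switch_rate <= 1))
      stop("within_pause_switch_rate must lie in [0, 1]")
    if (!(move_pause_coupling >= -1 && move_pause_coupling <= 1))
      stop("move_pause_coupling must lie in [-1, 1]")
    if (any(mode_schedule$p < 0 | mode_schedule$p > 1))
      stop("mode schedule probabilities must lie in [0, 1]")
    if (move_speed * frame_dt <= 0.3)
      stop("move_speed * frame_dt must exceed 0.3 cm, otherwise moves ",
           "would classify as pauses")
    if (move_speed * frame_dt <= 0.3 + jitter_radius)
      stop("move_speed * frame_dt must exceed 0.3 cm + jitter_radius so ",
           "move steps stay unambiguous")
    if (!(jitter_radius > 0 && jitter_radius <= 0.15))
      stop("jitter_radius must lie in (0, 0.15] cm")
  })
  invisible(config)
}

# interpolate the turn-after-pause curve (linear in log10 pause length,
# constant beyond the end knots)
eval_turn_curve <- function(curve, pause_len) {
  stats::approx(x = log10(curve$x), y = curve$p, xout = log10(pause_len),
                rule = 2, ties = "ordered")$y
}

eval_mode_schedule <- function(schedule, t) {
  stats::approx(x = schedule$t, y = schedule$p, xout = t, rule = 2,
                ties = "ordered")$y
}

#' Sample bout durations from the stretched-tail power law
#'
#' Draws durations from `f(x) proportional to x^(-mu) exp(-(x/theta)^beta)`
#' on `[xmin, Inf)` and snaps them to the frame grid (see
#' [model_sample()] for the bin convention). `theta = Inf` reduces to the
#' pure power law. Uses the current R random number stream.
#'
#' @param params List with `mu` in (1, 3], `beta` in (0, 1], `theta` > 0
#'   and `xmin` (a grid multiple).
#' @param n Number of durations (>= 1).
#' @param frame_dt Grid step (s).
#' @return `n` grid durations `>= xmin`.
#' @export
sample_bout_lengths <- function(params, n, frame_dt = 0.2) {
  if (!(n >= 1)) stop("n must be >= 1")
  if (!(params$mu > 1 && params$mu <= 3)) stop("mu must lie in (1, 3]")
  if (!(params$beta > 0 && params$beta <= 1)) stop("beta must lie in (0, 1]")
  if (!(params$theta > 0)) stop("theta must be positive")
  if (!(params$xmin >= frame_dt)) stop("xmin must be >= frame_dt")
  model <- candidate_model("pl_stretched_tail",
                           support = c(params$xmin, Inf))
  model_sample(model, n, params[c("mu", "beta", "theta")],
               frame_dt = frame_dt)
}

# draw bout durations conditioned on <= cap by rejection (vectorized)
.sample_capped <- function(params, n, frame_dt, cap) {
  out <- numeric(0)
  while (length(out) < n) {
    batch <- sample_bout_lengths(params, max(2L * (n - length(out)), 64L),
                                 frame_dt)
    out <- c(out, batch[batch <= cap])
  }
  out[seq_len(n)]
}

.dist_model <- function(params) {
  candidate_model("pl_stretched_tail", support = c(params$xmin, Inf))
}

#' Simulate the ground-truth bout ledger
#'
#' Runs the bout-level process (mode segments, alternating move/pause
#' durations, turn decisions, within-pause fidget directions) without
#' rendering frame positions. This ledger is the generator's ground
#' truth: downstream recovery tests compare against it directly.
#' Consumes the current R random number stream (callers usually go
#' through [simulate_trajectory()], which seeds it from the config).
#'
#' @param config A [generator_config()].
#' @return Object of class `bout_ledger`: list with `bouts` (data.frame:
#'   `state`, `start_frame` (first owned frame transition, 1-based),
#'   `n_frames` (owned transitions), `duration`, `mode`, `turn_after`
#'   (pauses: was the post-pause travel direction reversed), `truncated`),
#'   `dirs` (+1 = anti-clockwise / -1 = clockwise, one per frame
#'   transition), `modes` (realized mode intervals) and `n_transitions`.
#' @export
simulate_bout_ledger <- function(config) {
  validate_generator_config(config)
  dt <- config$frame_dt
  n_target <- round(config$duration / dt)

  # behavioural mode segments
  seg_t <- 0; seg_start <- numeric(0); seg_mode <- character(0)
  while (seg_t < config$duration) {
    seg_start <- c(seg_start, seg_t)
    p_rel <- eval_mode_schedule(config$mode_schedule, seg_t)
    seg_mode <- c(seg_mode,
                  if (stats::runif(1) < p_rel) "relocation" else "local_search")
    seg_t <- seg_t + stats::rgamma(1, shape = 4,
                                   rate = 4 / config$mode_dwell)
  }
  seg_end <- c(seg_start[-1], Inf)

  # alternating bouts; the mode of a bout is the mode of the segment
  # containing the bout's start time
  state0 <- if (stats::runif(1) < 0.5) "move" else "pause"
  m_move <- .dist_model(config$move_dist_params)
  m_pause <- .dist_model(config$pause_dist_params)
  p_move <- config$move_dist_params[c("mu", "beta", "theta")]
  p_pause <- config$pause_dist_params[c("mu", "beta", "theta")]
  f_move_cap <- .grid_cdf_at(m_move, config$local_search_move_cap,
                             p_move, dt)
  f_pause_cap <- .grid_cdf_at(m_pause, config$relocation_pause_cap,
                              p_pause, dt)
  rho <- config$move_pause_coupling
  # draw k (move, pause) cycles: a Gaussian copula couples each move
  # with its adjacent pause (negative rho: long moves go with short
  # pauses) while both marginal laws are preserved exactly; mode
  # conditioning truncates via u-rescaling
  draw_cycles <- function(mode, k) {
    z1 <- stats::rnorm(k)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(k)
    um <- stats::pnorm(z1)
    up <- stats::pnorm(z2)
    if (mode == "local_search") um <- um * f_move_cap
    if (mode == "relocation") up <- up * f_pause_cap
    list(mv = model_quantile_grid(m_move, um, p_move, dt),
         pa = model_quantile_grid(m_pause, up, p_pause, dt))
  }
  # alternating bouts, drawn in chunks per mode segment; a bout straddling
  # a segment boundary keeps the mode of the segment its start falls in
  states_l <- list(); durs_l <- list(); modes_l <- list(); li <- 0L
  t <- 0; s <- state0
  for (si in seq_along(seg_start)) {
    seg_hi <- min(seg_end[si], config$duration)
    mode <- seg_mode[si]
    while (t < seg_hi) {
      k <- 32L
      cyc <- draw_cycles(mode, k)
      mv <- cyc$mv; pa <- cyc$pa
      vec <- numeric(2L * k)
      if (s == "move") {
        vec[seq(1, 2 * k, 2)] <- mv; vec[seq(2, 2 * k, 2)] <- pa
        st <- rep(c("move", "pause"), k)
      } else {
        vec[seq(1, 2 * k, 2)] <- pa; vec[seq(2, 2 * k, 2)] <- mv
        st <- rep(c("pause", "move"), k)
      }
      cum <- t + cumsum(vec)
      stop_i <- which(cum >= seg_hi)[1]
      take <- if (is.na(stop_i)) 2L * k else stop_i
      li <- li + 1L
      states_l[[li]] <- st[seq_len(take)]
      durs_l[[li]] <- vec[seq_len(take)]
      modes_l[[li]] <- rep(mode, take)
      t <- cum[take]
      s <- if (st[take] == "move") "pause" else "move"
    }
  }
  states <- unlist(states_l); durs <- unlist(durs_l)
  modes <- unlist(modes_l)

  n_tr <- as.integer(round(durs / dt))
  cum <- cumsum(n_tr)
  keep <- which(cum < n_target + 1e-9)
  truncated <- logical(length(durs))
  if (length(keep) < length(durs)) {
    cut_at <- length(keep) + 1L
    extra <- as.integer(n_target - if (length(keep)) cum[length(keep)] else 0L)
    if (extra > 0) {
      n_tr[cut_at] <- extra
      durs[cut_at] <- extra * dt
      truncated[cut_at] <- TRUE
      keep <- c(keep, cut_at)
    }
  }
  states <- states[keep]; durs <- durs[keep]; modes <- modes[keep]
  n_tr <- n_tr[keep]; truncated <- truncated[keep]
  start <- as.integer(cumsum(c(1L, n_tr[-length(n_tr)])))

  # travel direction per move bout: flip after a pause with probability
  # given by the turn curve evaluated at the pause length
  is_move <- states == "move"
  is_pause <- !is_move
  dir0 <- if (stats::runif(1) < 0.5) 1L else -1L
  move_dir <- integer(length(states))
  turn_after <- rep(NA, length(states))
  cur <- dir0
  for (i in seq_along(states)) {
    if (is_move[i]) {
      move_dir[i] <- cur
    } else {
      flip <- stats::runif(1) <
        eval_turn_curve(config$turn_after_pause_curve, durs[i])
      turn_after[i] <- flip
      if (flip) cur <- -cur
    }
  }
  # a turn decision is only observable for interior pauses; keep the
  # decision everywhere, analysts drop edge pauses themselves

  # per-transition directions
  dirs <- integer(sum(n_tr))
  prev_move <- dir0
  r <- config$within_pause_switch_rate
  for (i in seq_along(states)) {
    span <- start[i]:(start[i] + n_tr[i] - 1L)
    if (is_move[i]) {
      dirs[span] <- move_dir[i]
      prev_move <- move_dir[i]
    } else {
      k <- n_tr[i]
      flips <- if (k > 1) stats::runif(k - 1) < r else logical(0)
      dirs[span] <- as.integer(prev_move *
                                 cumprod(c(1L, ifelse(flips, -1L, 1L))))
    }
  }

  structure(list(
    bouts = data.frame(state = states, start_frame = start,
                       n_frames = n_tr, duration = durs, mode = modes,
                       turn_after = turn_after, truncated = truncated,
                       stringsAsFactors = FALSE),
    dirs = dirs,
    modes = data.frame(t_start = seg_start,
                       t_end = pmin(seg_end, config$duration),
                       mode = seg_mode, stringsAsFactors = FALSE),
    n_transitions = sum(n_tr), frame_dt = dt),
    class = "bout_ledger")
}

#' Simulate a trajectory in the annular arena
#'
#' Renders frame-level positions from a ground-truth bout ledger. Motion
#' is reduced to one dimension along the annulus mid-radius circle: moves
#' advance at constant tangential speed in the current travel direction;
#' pauses jitter tangentially within `jitter_radius` of the pause anchor
#' with per-frame angular steps whose signs realize the ledger's fidget
#' directions, so re-discretization recovers the ledger exactly.
#'
#' @param config A [generator_config()].
#' @param individual_id Label stored on the trajectory.
#' @return Object of class `trajectory`: data.frame with `t_s`, `x_cm`,
#'   `y_cm` and attributes `individual_id`, `frame_dt`,
#'   `arena_outer_radius`, `dome_radius` and `ground_truth` (the
#'   [simulate_bout_ledger()] result).
#' @export
simulate_trajectory <- function(config, individual_id = "ind01") {
  validate_generator_config(config)
  set.seed(config$seed)
  ledger <- simulate_bout_ledger(config)
  dt <- config$frame_dt
  r0 <- (config$arena_outer_radius + config$dome_radius) / 2
  omega <- config$move_speed / r0            # rad/s
  n <- ledger$n_transitions
  b <- ledger$bouts

  dphi <- numeric(n)
  is_move_tr <- rep(b$state == "move", b$n_frames)
  dphi[is_move_tr] <- ledger$dirs[is_move_tr] * omega * dt

  pause_tr <- which(!is_move_tr)
  if (length(pause_tr)) {
    reset <- rep(FALSE, length(pause_tr))
    # first owned transition of each pause bout starts a fresh anchor
    pause_starts <- b$start_frame[b$state == "pause"]
    reset[match(pause_starts, pause_tr)] <- TRUE
    off <- pause_offsets_cpp(ledger$dirs[pause_tr],
                             stats::runif(length(pause_tr)), reset,
                             config$jitter_radius / r0)
    prev <- c(0, off[-length(off)])
    prev[reset] <- 0
    dphi[pause_tr] <- off - prev
  }

  phi <- stats::runif(1, 0, 2 * pi) + cumsum(c(0, dphi))
  out <- data.frame(t_s = (0:n) * dt,
                    x_cm = r0 * cos(phi), y_cm = r0 * sin(phi))
  structure(out, individual_id = individual_id, frame_dt = dt,
            arena_outer_radius = config$arena_outer_radius,
            dome_radius = config$dome_radius, ground_truth = ledger,
            class = c("trajectory", "data.frame"))
}

#' Generate a cohort of independent trajectories
#'
#' Each individual gets a seed derived deterministically from the master
#' seed, so the cohort is bitwise reproducible.
#'
#' @param config A [generator_config()]; its `seed` is the master seed.
#' @param n_individuals Number of trajectories (>= 1).
#' @return List of `trajectory` objects named `ind01`, `ind02`, ...
#' @export
generate_cohort <- function(config, n_individuals) {
  stopifnot(n_individuals >= 1)
  seeds <- .with_private_seed(config$seed,
                              sample.int(2147483646L, n_individuals))
  out <- lapply(seq_len(n_individuals), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    simulate_trajectory(cfg, individual_id = sprintf("ind%02d", i))
  })
  names(out) <- vapply(out, attr, character(1), "individual_id")
  out
}

#' Write/read trajectories as CSV
#'
#' The interchange format has columns `individual_id`, `t_s`, `x_cm`,
#' `y_cm`; several individuals may share one file.
#'
#' @param trajectories A `trajectory` or list of them.
#' @param path Output file.
#' @export
write_trajectory_csv <- function(trajectories, path) {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- list(trajectories)
  }
  dfs <- lapply(trajectories, function(tr) {
    data.frame(individual_id = attr(tr, "individual_id"),
               t_s = tr$t_s, x_cm = tr$x_cm, y_cm = tr$y_cm)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param frame_dt,arena_outer_radius,dome_radius Metadata to attach
#'   (CSV carries positions only).
#' @export
read_trajectory_csv <- function(path, frame_dt = 0.2,
                                arena_outer_radius = 40,
                                dome_radius = 17.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$t_s), ]
    structure(data.frame(t_s = d$t_s, x_cm = d$x_cm, y_cm = d$y_cm),
              individual_id = d$individual_id[1], frame_dt = frame_dt,
              arena_outer_radius = arena_outer_radius,
              dome_radius = dome_radius,
              class = c("trajectory", "data.frame"))
  })
}

#' Write a ground-truth ledger as JSON
#'
#' @param ledger A `bout_ledger`.
#' @param path Output file.
#' @export
write_ledger_json <- function(ledger, path) {
  stopifnot(inherits(ledger, "bout_ledger"))
  jsonlite::write_json(
    list(bouts = ledger$bouts[c("state", "start_frame", "n_frames",
                                "duration", "mode")],
         modes = ledger$modes,
         n_transitions = ledger$n_transitions,
         frame_dt = ledger$frame_dt),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
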