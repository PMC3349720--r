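# Programmatic fixtures shared across test files.

# trajectory on the annulus mid-radius circle from a vector of polar
# angles (radians)
make_traj <- function(phi, r = 28.75, dt = 0.2, id = "t1",
                      outer = 40, dome = 17.5) {
  structure(data.frame(t_s = (seq_along(phi) - 1) * dt,
                       x_cm = r * cos(phi), y_cm = r * sin(phi)),
            individual_id = id, frame_dt = dt,
            arena_outer_radius = outer, dome_radius = dome,
            class = c("trajectory", "data.frame"))
}

# bout sequence assembled directly from per-bout states and direction
# vectors (one direction label per owned transition)
make_bout_seq <- function(states, dirs_list, dt = 0.2,
                          censored_edge = NULL) {
  n_tr <- vapply(dirs_list, length, integer(1))
  start <- as.integer(cumsum(c(1L, n_tr[-length(n_tr)])))
  if (is.null(censored_edge)) censored_edge <- rep(FALSE, length(states))
  structure(list(
    bouts = data.frame(state = states, start_frame = start,
                       n_frames = as.integer(n_tr),
                       duration = n_tr * dt, block = 1L,
                       censored_edge = censored_edge,
                       stringsAsFactors = FALSE),
    directions = lapply(dirs_list, as.integer),
    censored_gaps = data.frame(start_frame = integer(0),
                               end_frame = integer(0)),
    frame_dt = dt, individual_id = "fix"), class = "bout_seq")
}

# signed series built directly from value/time vectors
make_signed_series <- function(values) {
  tend <- cumsum(abs(values))
  structure(data.frame(value = values,
                       t_start = c(0, tend[-length(tend)]),
                       t_end = tend, block = 1L),
            class = c("signed_series", "data.frame"))
}

# small fast generator configuration
quick_cfg <- function(duration = 600, seed = 1, ...) {
  generator_config(duration = duration, seed = seed, ...)
}

move_params <- list(mu = 1.49, beta = 0.55, theta = 8, xmin = 0.2)
pause_params <- list(mu = 1.67, beta = 0.23, theta = 15.27, xmin = 0.2)
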