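# Discretization of frame-level trajectories into move/pause bouts with
# per-frame rotational (CW/ACW) direction, with edge exclusion.
#
# Conventions: state and direction attach to frame *transitions* (pairs of
# successive frames); a bout of n_frames owns the n_frames transitions
# starting at its start_frame; all bin edges are left-closed/right-open;
# the arena center is the origin and time zero is the first frame.

.traj_attr <- function(traj, what, default = NULL) {
  v <- attr(traj, what)
  if (is.null(v)) default else v
}

#' Classify frame transitions as move or pause
#'
#' A transition is a move iff the Euclidean displacement between the two
#' successive frames exceeds `move_threshold` (default 0.3 cm at 0.2 s
#' frames); displacements equal to the threshold are pauses.
#'
#' @param traj A `trajectory` (data.frame with `t_s`, `x_cm`, `y_cm`).
#' @param move_threshold Displacement threshold in cm (> 0).
#' @return Character vector (`"move"`/`"pause"`), one per transition.
#' @export
classify_frames <- function(traj, move_threshold = 0.3) {
  stopifnot(nrow(traj) >= 2, move_threshold > 0)
  dts <- diff(traj$t_s)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1])) {
    stop("trajectory frames are not uniformly spaced")
  }
  disp <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  ifelse(disp > move_threshold, "move", "pause")
}

#' Rotational direction of frame transitions
#'
#' Direction of motion around the arena center from the sign of the
#' z-component of the cross product of successive position vectors:
#' positive is anti-clockwise (+1), negative clockwise (-1). Transitions
#' with zero cross product (no angular displacement) carry the previous
#' direction forward; leading zeros take the first nonzero direction.
#'
#' @param traj A `trajectory`.
#' @return Integer vector of +1 (ACW) / -1 (CW), one per transition.
#' @export
rotational_direction <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  x <- traj$x_cm; y <- traj$y_cm
  n <- length(x) - 1
  cr <- x[1:n] * y[2:(n + 1)] - y[1:n] * x[2:(n + 1)]
  s <- sign(cr)
  if (all(s == 0)) {
    warning("no angular motion in trajectory; directions undefined")
    return(rep(NA_integer_, n))
  }
  # carry forward previous nonzero direction; backfill leading zeros
  nz <- s != 0
  idx <- cummax(ifelse(nz, seq_len(n), 0L))
  first_nz <- which(nz)[1]
  idx[idx == 0L] <- first_nz
  as.integer(s[idx])
}

#' Encode labelled transitions into a bout sequence
#'
#' Maximal runs of identical state labels become bouts; each bout owns
#' its transitions' direction labels and has duration
#' `n_frames * frame_dt`, so total duration is conserved.
#'
#' @param labels Character vector of `"move"`/`"pause"` per transition.
#' @param dir_labels Integer vector (+1/-1) per transition, same length.
#' @param frame_dt Frame interval (s).
#' @param individual_id Label stored on the result.
#' @return Object of class `bout_seq`: list with `bouts` (data.frame:
#'   `state`, `start_frame`, `n_frames`, `duration`, `block`,
#'   `censored_edge`), `directions` (list of per-bout integer vectors),
#'   `censored_gaps` (data.frame), `frame_dt`, `individual_id`.
#' @export
encode_bouts <- function(labels, dir_labels, frame_dt,
                         individual_id = "unknown") {
  if (!length(labels)) stop("empty label input")
  stopifnot(length(labels) == length(dir_labels), frame_dt > 0)
  r <- rle(labels)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  bouts <- data.frame(state = r$values, start_frame = start,
                      n_frames = r$lengths,
                      duration = r$lengths * frame_dt,
                      block = 1L, censored_edge = FALSE,
                      stringsAsFactors = FALSE)
  dirs <- lapply(seq_len(nrow(bouts)), function(i) {
    dir_labels[start[i]:(start[i] + r$lengths[i] - 1L)]
  })
  structure(list(bouts = bouts, directions = dirs,
                 censored_gaps = data.frame(start_frame = integer(0),
                                            end_frame = integer(0)),
                 frame_dt = frame_dt, individual_id = individual_id),
            class = "bout_seq")
}

#' @export
print.bout_seq <- function(x, ...) {
  cat("Bout sequence for", x$individual_id, "\n")
  tb <- table(x$bouts$state)
  cat(" ", nrow(x$bouts), "bouts (",
      paste(names(tb), tb, collapse = ", "), ")\n")
  cat("  frame_dt:", x$frame_dt, "s; blocks:",
      length(unique(x$bouts$block)), "; censored gaps:",
      nrow(x$censored_gaps), "\n")
  invisible(x)
}

#' Flag frames near the arena walls for exclusion
#'
#' Frames within `margin` of the outer wall or the central dome are
#' censored (default 3 cm: radius above 37 cm or below 20.5 cm in the
#' standard arena), removing edge effects. The trajectory then splits
#' into contiguous uncensored blocks.
#'
#' @param traj A `trajectory` with arena radii attributes (or supply
#'   them).
#' @param margin Exclusion margin in cm (>= 0).
#' @param arena_outer_radius,dome_radius Arena geometry (cm); defaults
#'   taken from the trajectory attributes.
#' @return The trajectory with a logical attribute `censored` (per
#'   frame).
#' @export
apply_edge_exclusion <- function(traj, margin = 3,
                                 arena_outer_radius =
                                   .traj_attr(traj, "arena_outer_radius", 40),
                                 dome_radius =
                                   .traj_attr(traj, "dome_radius", 17.5)) {
  stopifnot(margin >= 0)
  hi <- arena_outer_radius - margin
  lo <- dome_radius + margin
  if (lo >= hi) stop("margin leaves no admissible annulus")
  r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  attr(traj, "censored") <- r > hi | r < lo
  traj
}

#' Discretize a trajectory into move/pause bouts
#'
#' Full pipeline: classify transitions against the displacement
#' threshold, assign rotational directions, censor frames near the walls,
#' and encode bouts within each contiguous uncensored block. Bouts
#' abutting a censored gap or the record ends are flagged
#' `censored_edge` (their true length is unknown) and are excluded from
#' duration statistics by [bout_durations()].
#'
#' @param traj A `trajectory`.
#' @param move_threshold Displacement threshold (cm).
#' @param margin Edge-exclusion margin (cm).
#' @return A `bout_seq` (see [encode_bouts()]); `bouts$block` numbers the
#'   uncensored blocks and `censored_gaps` lists removed frame intervals.
#' @export
discretize_trajectory <- function(traj, move_threshold = 0.3, margin = 3) {
  labels <- classify_frames(traj, move_threshold)
  dirs <- rotational_direction(traj)
  traj <- apply_edge_exclusion(traj, margin)
  cens_frame <- attr(traj, "censored")
  n <- length(labels)
  # a transition is usable iff both endpoint frames are uncensored
  ok <- !(cens_frame[1:n] | cens_frame[2:(n + 1)])
  if (!any(ok)) stop("no uncensored transitions remain")
  rb <- rle(ok)
  ends <- cumsum(rb$lengths)
  starts <- ends - rb$lengths + 1L
  blocks <- which(rb$values)
  gaps <- which(!rb$values)
  seqs <- lapply(seq_along(blocks), function(bi) {
    i <- blocks[bi]
    span <- starts[i]:ends[i]
    bs <- encode_bouts(labels[span], dirs[span], .traj_attr(traj, "frame_dt",
                                                            diff(traj$t_s[1:2])),
                       individual_id = .traj_attr(traj, "individual_id",
                                                  "unknown"))
    bs$bouts$start_frame <- bs$bouts$start_frame + starts[i] - 1L
    bs$bouts$block <- bi
    bs
  })
  bouts <- do.call(rbind, lapply(seqs, `[[`, "bouts"))
  dirs_l <- do.call(c, lapply(seqs, `[[`, "directions"))
  # first and last bout of each block touch a gap or a record end
  for (bi in unique(bouts$block)) {
    w <- which(bouts$block == bi)
    bouts$censored_edge[w[c(1, length(w))]] <- TRUE
  }
  structure(list(
    bouts = bouts, directions = dirs_l,
    censored_gaps = data.frame(start_frame = starts[gaps],
                               end_frame = ends[gaps]),
    frame_dt = .traj_attr(traj, "frame_dt", diff(traj$t_s[1:2])),
    individual_id = .traj_attr(traj, "individual_id", "unknown")),
    class = "bout_seq")
}

#' Extract bout durations from a sequence
#'
#' @param seq A `bout_seq`.
#' @param state `"move"` or `"pause"`.
#' @param include_censored Include bouts flagged `censored_edge`
#'   (default FALSE: edge bouts are right/left-censored and excluded
#'   from duration distributions).
#' @return Numeric vector of durations (s).
#' @export
bout_durations <- function(seq, state = c("move", "pause"),
                           include_censored = FALSE) {
  state <- match.arg(state)
  b <- seq$bouts
  sel <- b$state == state
  if (!include_censored) sel <- sel & !b$censored_edge
  b$duration[sel]
}

#' Convert a generator ground-truth ledger to a bout sequence
#'
#' Gives the ledger the same container as [discretize_trajectory()]
#' output so downstream analyses can run on generator truth directly.
#' The first and last bouts (and any truncated bout) are flagged as edge
#' bouts.
#'
#' @param ledger A `bout_ledger` from [simulate_bout_ledger()].
#' @param individual_id Label.
#' @return A `bout_seq`.
#' @export
as_bout_seq <- function(ledger, individual_id = "ind01") {
  stopifnot(inherits(ledger, "bout_ledger"))
  b <- ledger$bouts
  bouts <- data.frame(state = b$state, start_frame = b$start_frame,
                      n_frames = b$n_frames, duration = b$duration,
                      block = 1L, censored_edge = FALSE,
                      stringsAsFactors = FALSE)
  bouts$censored_edge[c(1, nrow(bouts))] <- TRUE
  bouts$censored_edge[b$truncated] <- TRUE
  dirs <- lapply(seq_len(nrow(bouts)), function(i) {
    ledger$dirs[b$start_frame[i]:(b$start_frame[i] + b$n_frames[i] - 1L)]
  })
  structure(list(bouts = bouts, directions = dirs,
                 censored_gaps = data.frame(start_frame = integer(0),
                                            end_frame = integer(0)),
                 frame_dt = ledger$frame_dt, individual_id = individual_id),
            class = "bout_seq")
}

#' Angular speed of moves versus move length
#'
#' For each move bout, the angular speed is the absolute net unwrapped
#' polar-angle change over the bout divided by its duration (degrees per
#' second). Bin means with 95% confidence intervals are reported over
#' log-spaced move-length bins together with a nonlinear least-squares
#' fit of the saturating form `omega(t) = c t / (a + t)`.
#'
#' @param seq A `bout_seq` from [discretize_trajectory()].
#' @param traj The matching `trajectory`.
#' @param base Growth factor of the move-length bins.
#' @return List with `profile` (data.frame `left`, `right`, `mean_omega`,
#'   `lo`, `hi`, `n`), `fit` (named vector `a`, `c`, or NULL if the fit
#'   failed) and `omega` (per-move values with durations).
#' @export
angular_speed_profile <- function(seq, traj, base = 2) {
  b <- seq$bouts
  mv <- b[b$state == "move", , drop = FALSE]
  if (!nrow(mv)) stop("no move bouts")
  phi <- .unwrap(atan2(traj$y_cm, traj$x_cm))
  # bout owns transitions start..start+n-1, i.e. frames start..start+n
  omega <- abs(phi[mv$start_frame + mv$n_frames] - phi[mv$start_frame]) /
    mv$duration * 180 / pi
  edges <- log_bin_edges(max(mv$duration), base = base,
                         anchor = seq$frame_dt)
  idx <- findInterval(mv$duration, edges, rightmost.closed = FALSE)
  prof <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(i) {
    o <- omega[idx == i]
    if (!length(o)) return(NULL)
    m <- mean(o)
    se <- if (length(o) > 1) stats::sd(o) / sqrt(length(o)) else NA_real_
    data.frame(left = edges[i], right = edges[i + 1], mean_omega = m,
               lo = m - 1.96 * se, hi = m + 1.96 * se, n = length(o))
  }))
  fit <- tryCatch({
    cf <- stats::coef(stats::nls(omega ~ cc * t / (aa + t),
                                 data = data.frame(omega = omega,
                                                   t = mv$duration),
                                 start = list(aa = stats::median(mv$duration),
                                              cc = max(stats::quantile(
                                                omega, 0.9), 1e-3))))
    c(a = unname(cf["aa"]), c = unname(cf["cc"]))
  }, error = function(e) NULL)
  list(profile = prof, fit = fit,
       omega = data.frame(duration = mv$duration, omega = omega))
}

.unwrap <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + cumsum(c(0, d))
}
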