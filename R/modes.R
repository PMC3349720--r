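# Behavioural mode segmentation: a CUSUM-style partial-sums (PS)
# algorithm on the signed move/pause series separates local-search
# stretches (net pausing) from relocation stretches (net moving).

#' Signed bout-duration series
#'
#' Moves become positive values, pauses negative, in bout order, with
#' the cumulative experiment time at each bout end.
#'
#' @param seq A `bout_seq`.
#' @return Object of class `signed_series`: data.frame with `value`
#'   (signed duration, s), `t_start`, `t_end` (s) and `block`.
#' @export
signed_series <- function(seq) {
  b <- seq$bouts
  if (!nrow(b)) stop("empty bout sequence")
  dt <- seq$frame_dt
  t_start <- (b$start_frame - 1) * dt
  out <- data.frame(value = ifelse(b$state == "move", 1, -1) * b$duration,
                    t_start = t_start, t_end = t_start + b$duration,
                    block = b$block)
  class(out) <- c("signed_series", "data.frame")
  out
}

#' Partial-sums (CUSUM) segmentation into behavioural modes
#'
#' Computes the cumulative sum `C_j = sum_(i<=j) (value_i - T)` of the
#' signed series and allocates breakpoints at pronounced local extrema of
#' `C`: a bout is a candidate if `C` attains a strict maximum or minimum
#' over the window of neighbouring bouts spanning at least `epsilon/2` of
#' wall-clock time on each side, and candidates closer than `epsilon` to
#' the previously accepted breakpoint are rejected (the more extreme
#' deviation wins). Each resulting segment is labelled `"relocation"` if
#' its net signed sum is positive, `"local_search"` if negative
#' (zero-sum segments merge with the preceding segment); adjacent
#' same-label segments are merged, so every reported mode lasts at least
#' `epsilon`.
#'
#' @param series A `signed_series`. Blocks are segmented independently;
#'   blocks shorter than `epsilon` are reported unlabelled and skipped.
#' @param epsilon Minimum mode duration in seconds (default 300 s =
#'   5 min).
#' @param T_ref Reference value subtracted from each signed value
#'   (default 0, separating the move and pause contributions
#'   unambiguously).
#' @return Object of class `mode_segmentation`: list with `segments`
#'   (data.frame `block`, `start_bout`, `end_bout`, `t_start`, `t_end`,
#'   `net`, `label`), `breakpoints` (bout indices), `epsilon`,
#'   `skipped_blocks`.
#' @export
partial_sums_segment <- function(series, epsilon = 300, T_ref = 0) {
  if (epsilon <= 0) stop("epsilon must be positive")
  stopifnot(inherits(series, "signed_series"))
  segs <- list(); bps <- integer(0); skipped <- integer(0)
  for (bl in unique(series$block)) {
    w <- which(series$block == bl)
    sb <- series[w, , drop = FALSE]
    span <- sb$t_end[nrow(sb)] - sb$t_start[1]
    if (span < epsilon) {
      skipped <- c(skipped, bl)
      next
    }
    res <- .ps_segment_block(sb$value, sb$t_end, epsilon, T_ref)
    if (length(res$breakpoints)) bps <- c(bps, w[res$breakpoints])
    sg <- res$segments
    sg$block <- bl
    sg$start_bout <- w[sg$start_bout]
    sg$end_bout <- w[sg$end_bout]
    sg$t_start <- sb$t_start[match(sg$start_bout, w)]
    sg$t_end <- sb$t_end[match(sg$end_bout, w)]
    segs[[length(segs) + 1]] <- sg
  }
  if (!length(segs)) stop("no block long enough to segment")
  segments <- do.call(rbind, segs)
  segments <- segments[c("block", "start_bout", "end_bout", "t_start",
                         "t_end", "net", "label")]
  structure(list(segments = segments, breakpoints = bps,
                 epsilon = epsilon, skipped_blocks = skipped),
            class = "mode_segmentation")
}

.ps_segment_block <- function(values, t_end, epsilon, T_ref) {
  n <- length(values)
  C <- cumsum(values - T_ref)
  # candidate extrema: strict max or min of C over the +/- epsilon/2
  # wall-clock window, with at least epsilon of record on both sides
  half <- epsilon / 2
  cand <- integer(0); cand_val <- numeric(0)
  lo_ptr <- 1L; hi_ptr <- 1L
  t_first <- t_end[1]; t_last <- t_end[n]
  for (j in seq_len(n)) {
    if (t_end[j] - t_first < half || t_last - t_end[j] < half) next
    while (t_end[lo_ptr] < t_end[j] - half) lo_ptr <- lo_ptr + 1L
    while (hi_ptr < n && t_end[hi_ptr + 1] <= t_end[j] + half)
      hi_ptr <- hi_ptr + 1L
    win <- C[lo_ptr:hi_ptr]
    cj <- C[j]
    others <- win[-(j - lo_ptr + 1L)]
    if (!length(others)) next
    # non-strict extremum: grid durations make exact ties in C common;
    # the epsilon-separation pruning below dedupes tied neighbours
    if (cj >= max(others) || cj <= min(others)) {
      cand <- c(cand, j); cand_val <- c(cand_val, cj)
    }
  }
  # enforce epsilon separation; on conflict keep the larger |C| deviation
  acc <- integer(0)
  for (k in seq_along(cand)) {
    j <- cand[k]
    if (!length(acc)) {
      acc <- j
    } else if (t_end[j] - t_end[acc[length(acc)]] >= epsilon) {
      acc <- c(acc, j)
    } else if (abs(C[j]) > abs(C[acc[length(acc)]])) {
      acc[length(acc)] <- j
    }
  }
  bounds <- c(0L, acc, n)
  seg <- data.frame(start_bout = bounds[-length(bounds)] + 1L,
                    end_bout = bounds[-1])
  seg$net <- vapply(seq_len(nrow(seg)), function(i) {
    sum(values[seg$start_bout[i]:seg$end_bout[i]])
  }, numeric(1))
  # labels: sign of the net sum; zero-sum merges with the predecessor
  lab <- ifelse(seg$net > 0, "relocation",
                ifelse(seg$net < 0, "local_search", NA))
  if (all(is.na(lab))) {
    # fully balanced record: fall back to which state holds more time
    lab[] <- if (sum(abs(values[values < 0])) >= sum(values[values > 0]))
      "local_search" else "relocation"
  }
  if (is.na(lab[1])) lab[1] <- lab[which(!is.na(lab))[1]]
  for (i in seq_along(lab)) if (is.na(lab[i])) lab[i] <- lab[i - 1]
  seg$label <- lab
  # merge adjacent same-label segments
  rl <- rle(lab)
  last <- cumsum(rl$lengths)
  first <- last - rl$lengths + 1L
  merged <- data.frame(
    start_bout = seg$start_bout[first],
    end_bout = seg$end_bout[last],
    net = vapply(seq_along(first), function(i)
      sum(seg$net[first[i]:last[i]]), numeric(1)),
    label = rl$values)
  bp_kept <- merged$end_bout[-nrow(merged)]
  list(segments = merged, breakpoints = bp_kept)
}

#' @export
print.mode_segmentation <- function(x, ...) {
  cat("Partial-sums segmentation (epsilon =", x$epsilon, "s):",
      nrow(x$segments), "segment(s)\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Population mode-probability curves
#'
#' At each grid time, the fraction of individuals whose containing
#' segment is labelled relocation (resp. local search). The two
#' probabilities sum to 1 wherever every individual is covered.
#'
#' @param cohort_segs List of `mode_segmentation` objects (one per
#'   individual).
#' @param time_grid Numeric vector of times (s).
#' @return data.frame with `t`, `p_relocation`, `p_local_search`,
#'   `n_covered`; grid points covered by no individual get `NA`.
#' @export
mode_probability_curve <- function(cohort_segs, time_grid) {
  stopifnot(length(cohort_segs) >= 1)
  counts <- vapply(time_grid, function(t) {
    lab <- vapply(cohort_segs, function(sg) {
      s <- sg$segments
      i <- which(s$t_start <= t & t < s$t_end)
      if (length(i)) s$label[i[1]] else NA_character_
    }, character(1))
    c(rel = sum(lab == "relocation", na.rm = TRUE),
      loc = sum(lab == "local_search", na.rm = TRUE),
      cov = sum(!is.na(lab)))
  }, numeric(3))
  cov <- counts["cov", ]
  data.frame(t = time_grid,
             p_relocation = ifelse(cov > 0, counts["rel", ] / cov, NA),
             p_local_search = ifelse(cov > 0, counts["loc", ] / cov, NA),
             n_covered = cov)
}

#' Sensitivity of the segmentation to the time threshold
#'
#' Re-segments the same series at several epsilon values; larger
#' thresholds prune breakpoints, never add them.
#'
#' @param series A `signed_series`.
#' @param epsilons Numeric vector of thresholds (s).
#' @return List with `segmentations` (one per epsilon) and `summary`
#'   (data.frame `epsilon`, `n_breakpoints`, `n_segments`).
#' @export
epsilon_sensitivity <- function(series, epsilons) {
  stopifnot(length(epsilons) >= 1, all(epsilons > 0))
  segs <- lapply(epsilons, function(e)
    partial_sums_segment(series, epsilon = e))
  list(segmentations = segs,
       summary = data.frame(
         epsilon = epsilons,
         n_breakpoints = vapply(segs, function(s)
           length(s$breakpoints), numeric(1)),
         n_segments = vapply(segs, function(s)
           nrow(s$segments), numeric(1))))
}
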