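# Reorientation analysis: direction changes after pauses as a function of
# pause length, fidgeting (CW/ACW switching) within bouts, and the
# influence of each pause scale on overall turning.

#' Turn-after-pause outcomes
#'
#' For every pause with a move on both sides in the same uncensored
#' block, records whether the travel direction reversed across the
#' pause: the direction of the last transition of the preceding move is
#' compared with the first transition of the following move. Pauses at
#' block boundaries are excluded (not an error).
#'
#' @param seq A `bout_seq`.
#' @return data.frame with `duration` (pause length, s) and `turned`
#'   (logical).
#' @export
turn_after_pause <- function(seq) {
  b <- seq$bouts
  n <- nrow(b)
  out_d <- numeric(0); out_t <- logical(0)
  if (n < 3) return(data.frame(duration = out_d, turned = out_t))
  first_dir <- vapply(seq$directions, function(d) d[1], integer(1))
  last_dir <- vapply(seq$directions, function(d) d[length(d)], integer(1))
  i <- which(b$state == "pause")
  i <- i[i > 1 & i < n]
  i <- i[b$state[i - 1] == "move" & b$state[i + 1] == "move" &
           b$block[i - 1] == b$block[i] & b$block[i + 1] == b$block[i] &
           !b$censored_edge[i]]
  data.frame(duration = b$duration[i],
             turned = last_dir[i - 1] != first_dir[i + 1])
}

#' Within-bout turning
#'
#' CW/ACW switching between consecutive owned transitions of each bout:
#' `any_turn` is whether at least one switch occurred, `proportion` the
#' fraction of consecutive transition pairs with a switch (the fidgeting
#' intensity). Bouts owning a single transition have no pairs and return
#' `NA`.
#'
#' @param seq A `bout_seq`, or a single integer direction vector.
#' @return For a `bout_seq`: data.frame with `state`, `duration`,
#'   `any_turn`, `proportion` per bout. For a direction vector: list with
#'   `any_turn` and `proportion`.
#' @export
turns_within_bout <- function(seq) {
  if (is.numeric(seq) || is.integer(seq)) {
    return(.turns_within_vec(as.integer(seq)))
  }
  stopifnot(inherits(seq, "bout_seq"))
  res <- lapply(seq$directions, .turns_within_vec)
  data.frame(state = seq$bouts$state, duration = seq$bouts$duration,
             any_turn = vapply(res, `[[`, logical(1), "any_turn"),
             proportion = vapply(res, `[[`, numeric(1), "proportion"))
}

.turns_within_vec <- function(d) {
  if (length(d) < 2) {
    return(list(any_turn = NA, proportion = NA_real_))
  }
  sw <- d[-1] != d[-length(d)]
  list(any_turn = any(sw), proportion = mean(sw))
}

#' Log-binned turn-probability curve
#'
#' Bins pause lengths into log-spaced classes (base-2 by default,
#' anchored at the frame interval) and estimates the mean probability of
#' turning per bin with 95% confidence intervals (normal approximation;
#' Wilson interval for bins with fewer than 30 observations). Empty bins
#' are omitted.
#'
#' @param pairs data.frame from [turn_after_pause()] (`duration`,
#'   `turned`), or any data.frame with those columns.
#' @param bins Numeric vector of increasing bin edges; default base-2
#'   log bins anchored at 0.2 s covering the data.
#' @param anchor Anchor of the default bins (s).
#' @param base Growth factor of the default bins.
#' @return Object of class `turn_curve`: data.frame with `bin_left`,
#'   `bin_right`, `p`, `lo`, `hi`, `n`.
#' @export
turn_probability_curve <- function(pairs, bins = NULL, anchor = 0.2,
                                   base = 2) {
  stopifnot(nrow(pairs) >= 1)
  if (is.null(bins)) {
    bins <- log_bin_edges(max(pairs$duration), base = base, anchor = anchor)
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  idx <- findInterval(pairs$duration, bins, rightmost.closed = FALSE)
  rows <- lapply(seq_len(length(bins) - 1), function(i) {
    tt <- pairs$turned[idx == i]
    n <- length(tt)
    if (!n) return(NULL)
    p <- mean(tt)
    if (n >= 30) {
      se <- sqrt(p * (1 - p) / n)
      lo <- max(0, p - 1.96 * se); hi <- min(1, p + 1.96 * se)
    } else {
      ci <- .wilson_ci(sum(tt), n)
      lo <- ci[1]; hi <- ci[2]
    }
    data.frame(bin_left = bins[i], bin_right = bins[i + 1],
               p = p, lo = lo, hi = hi, n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("turn_curve", "data.frame")
  out
}

.wilson_ci <- function(x, n, z = 1.96) {
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' @export
plot.turn_curve <- function(x, ...) {
  mid <- sqrt(x$bin_left * x$bin_right)
  graphics::plot(mid, x$p, log = "x", ylim = c(0, 1), pch = 19,
                 xlab = "pause length (s)",
                 ylab = "P(direction change after pause)", ...)
  graphics::arrows(mid, x$lo, mid, x$hi, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

#' Influence of each pause-length class on turning
#'
#' Multiplies the mean turn probability of each bin by the proportion of
#' pauses in that bin: abundant short pauses can dominate overall
#' reorientation even at low per-pause turn probability.
#'
#' @param curve A `turn_curve`.
#' @param pause_counts Optional per-bin counts (defaults to `curve$n`);
#'   must match the curve's binning.
#' @return data.frame with `bin_left`, `bin_right`, `proportion`,
#'   `influence`; `sum(influence) <= 1`.
#' @export
turn_influence <- function(curve, pause_counts = curve$n) {
  if (length(pause_counts) != nrow(curve)) {
    stop("pause_counts must have one entry per curve bin")
  }
  prop <- pause_counts / sum(pause_counts)
  data.frame(bin_left = curve$bin_left, bin_right = curve$bin_right,
             proportion = prop, influence = curve$p * prop)
}

#' Compare within-pause turn proportions of two pause-length classes
#'
#' Standard two-sample Student t-test (pooled variance), as used to
#' contrast fidgeting intensity between long (>= 100 s) and intermediate
#' (6-100 s) pauses.
#'
#' @param groupA,groupB Numeric vectors of within-pause turn proportions.
#' @return An object of class `htest` (from [stats::t.test()] with
#'   `var.equal = TRUE`); its `parameter` is `nA + nB - 2`.
#' @export
compare_turn_proportions <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    stop("zero variance in both groups")
  }
  stats::t.test(groupA, groupB, var.equal = TRUE)
}
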