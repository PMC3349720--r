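# Sequence structure of moves and pauses: partial autocorrelation of bout
# duration series, move-pause cross-correlation with a shuffle null, and
# adjacent move/pause pairing.
#
# Durations are log-transformed before correlation by default: the bout
# laws are heavy-tailed, and product-moment correlation on the raw scale
# is dominated by single extreme bouts.

#' Partial autocorrelation of a bout-duration series
#'
#' PACF computed by the Durbin-Levinson recursion on the sample
#' autocorrelations: the lag-k coefficient equals the last coefficient of
#' the order-k autoregression (Yule-Walker solution). The 95% white-noise
#' band is `+/- 1.96 / sqrt(n)`.
#'
#' @param series Numeric vector of bout durations in sequence order.
#' @param max_lag Maximum lag; the series must be longer than
#'   `max_lag + 10`.
#' @param log Log-transform the series first (default TRUE).
#' @return data.frame with `lag`, `pacf`, plus attribute `band`.
#' @export
partial_autocorrelation <- function(series, max_lag, log = TRUE) {
  stopifnot(max_lag >= 1, length(series) > max_lag + 10)
  x <- if (log) base::log(series) else series
  if (stats::sd(x) == 0) stop("constant series: PACF undefined")
  n <- length(x)
  x <- x - mean(x)
  r <- vapply(0:max_lag, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / sum(x^2)
  }, numeric(1))
  # Durbin-Levinson
  pac <- numeric(max_lag)
  phi <- numeric(0)
  for (k in 1:max_lag) {
    if (k == 1) {
      a <- r[2]
    } else {
      num <- r[k + 1] - sum(phi * r[k:2])
      den <- 1 - sum(phi * r[2:k])
      a <- num / den
    }
    phi <- c(phi - a * rev(phi), a)
    pac[k] <- a
  }
  out <- data.frame(lag = 1:max_lag, pacf = pac)
  attr(out, "band") <- 1.96 / sqrt(n)
  out
}

#' Cross-correlation of paired move and pause durations
#'
#' Moves are paired with the pause that immediately follows them;
#' `cross_correlation` reports the Pearson correlation of
#' `(move_i, pause_(i+lag))` for lags in `[-max_lag, max_lag]`. Pairs
#' never straddle censored gaps when built with [move_pause_pairs()].
#'
#' @param moves,pauses Equal-length numeric vectors, aligned by pair
#'   index (move i precedes pause i).
#' @param max_lag Maximum |lag|; series must be longer than
#'   `max_lag + 10`.
#' @param log Log-transform both series first (default TRUE).
#' @return data.frame with `lag`, `r`, `n`, plus attribute `band`
#'   (`1.96/sqrt(n)` white-noise guide at lag 0 length).
#' @export
cross_correlation <- function(moves, pauses, max_lag, log = TRUE) {
  stopifnot(length(moves) == length(pauses),
            length(moves) > max_lag + 10)
  if (log) {
    moves <- base::log(moves); pauses <- base::log(pauses)
  }
  if (stats::sd(moves) == 0 || stats::sd(pauses) == 0) {
    stop("zero variance series")
  }
  n <- length(moves)
  lags <- -max_lag:max_lag
  rr <- vapply(lags, function(l) {
    if (l >= 0) {
      mi <- 1:(n - l); pi_ <- (1 + l):n
    } else {
      mi <- (1 - l):n; pi_ <- 1:(n + l)
    }
    stats::cor(moves[mi], pauses[pi_])
  }, numeric(1))
  out <- data.frame(lag = lags, r = rr,
                    n = n - abs(lags))
  attr(out, "band") <- 1.96 / sqrt(n)
  out
}

#' Extract aligned move/pause pairs from a bout sequence
#'
#' Pairs each move with the pause immediately following it, within
#' uncensored blocks only.
#'
#' @param seq A `bout_seq`.
#' @return data.frame with `move`, `pause` (durations, s) and `block`.
#' @export
move_pause_pairs <- function(seq) {
  b <- seq$bouts
  n <- nrow(b)
  if (n < 2) return(data.frame(move = numeric(0), pause = numeric(0),
                               block = integer(0)))
  i <- which(b$state == "move" & seq_len(n) < n)
  i <- i[b$state[i + 1] == "pause" & b$block[i + 1] == b$block[i]]
  data.frame(move = b$duration[i], pause = b$duration[i + 1],
             block = b$block[i])
}

#' Shuffle null band for the move-pause cross-correlation
#'
#' Destroys sequence structure by independently permuting both series,
#' recomputes the cross-correlation, and reports the 2.5/97.5 percentile
#' band per lag. Uses the current R random number stream.
#'
#' @inheritParams cross_correlation
#' @param n_shuffles Number of permutations (>= 100 recommended).
#' @return data.frame with `lag`, `lo`, `hi`, `center` (median).
#' @export
shuffle_null <- function(moves, pauses, max_lag, n_shuffles = 200,
                         log = TRUE) {
  stopifnot(n_shuffles >= 1)
  sims <- replicate(n_shuffles, {
    cross_correlation(sample(moves), sample(pauses), max_lag,
                      log = log)$r
  })
  qs <- apply(sims, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(lag = -max_lag:max_lag, lo = qs[1, ], center = qs[2, ],
             hi = qs[3, ])
}

#' Pause-centred adjacent move triples
#'
#' One triple per interior pause: the pause duration together with the
#' immediately preceding and following move durations (within a block),
#' plus first-order (log-scale) correlations of the pause length with
#' each neighbour. Zero-variance cases are flagged by `NA` correlations
#' with a warning.
#'
#' @param seq A `bout_seq`.
#' @param log Log-transform durations before correlating (default TRUE).
#' @return List with `triples` (data.frame `pause`, `move_before`,
#'   `move_after`), `cor_before`, `cor_after`.
#' @export
adjacent_pairs <- function(seq, log = TRUE) {
  b <- seq$bouts
  n <- nrow(b)
  i <- which(b$state == "pause")
  i <- i[i > 1 & i < n]
  i <- i[b$state[i - 1] == "move" & b$state[i + 1] == "move" &
           b$block[i - 1] == b$block[i] & b$block[i + 1] == b$block[i]]
  tri <- data.frame(pause = b$duration[i], move_before = b$duration[i - 1],
                    move_after = b$duration[i + 1])
  tr <- if (log) base::log else identity
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  out <- list(triples = tri,
              cor_before = safe_cor(tr(tri$pause), tr(tri$move_before)),
              cor_after = safe_cor(tr(tri$pause), tr(tri$move_after)))
  if (is.na(out$cor_before) || is.na(out$cor_after)) {
    warning("zero variance or too few triples: correlation undefined")
  }
  out
}
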