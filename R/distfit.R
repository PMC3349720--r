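# Fitting and comparing bout-length distributions.
#
# Durations are pre-binned on the frame grid (0.2 s), so all likelihoods
# are binned: the contribution of an observation labelled d is the model
# probability of the bin [d, d + frame_dt).

#' Empirical complementary cumulative distribution function
#'
#' `P(X >= x)` evaluated at every distinct observed duration.
#'
#' @param durations Numeric vector of durations (seconds).
#' @return A data.frame with columns `x` (sorted distinct values) and
#'   `ccdf`.
#' @examples
#' empirical_ccdf(c(0.2, 0.4, 0.4, 0.8))
#' @export
empirical_ccdf <- function(durations) {
  stopifnot(length(durations) >= 1, all(is.finite(durations)))
  x <- sort(unique(durations))
  n <- length(durations)
  # P(X >= x): count of observations >= x
  cc <- 1 - (cumsum(tabulate(match(durations, x), length(x))) -
               tabulate(match(durations, x), length(x))) / n
  data.frame(x = x, ccdf = cc)
}

# base-`base` log bin edges anchored at `anchor`, covering data up to xmax
log_bin_edges <- function(xmax, base = 2, anchor = 0.2) {
  stopifnot(base > 1, anchor > 0, xmax >= anchor)
  k <- ceiling(log(xmax * (1 + 1e-12) / anchor, base))
  anchor * base^(0:max(k, 1))
}

#' Log-binned empirical probability density function
#'
#' Density per logarithmically growing bin (anchored at the grid floor),
#' the standard display for heavy-tailed duration data.
#'
#' @param durations Numeric vector of durations (seconds).
#' @param base Bin growth factor (> 1), default 2.
#' @param anchor Left edge of the first bin (default 0.2 s).
#' @return A data.frame with `left`, `right`, `count`, `density`
#'   (`count / (n * width)`); `sum(density * width)` is 1.
#' @export
log_binned_pdf <- function(durations, base = 2, anchor = 0.2) {
  stopifnot(length(durations) >= 1, base > 1)
  edges <- log_bin_edges(max(durations), base = base, anchor = anchor)
  idx <- findInterval(durations, edges, rightmost.closed = FALSE)
  cnt <- tabulate(idx, length(edges) - 1)
  w <- diff(edges)
  data.frame(left = edges[-length(edges)], right = edges[-1],
             count = cnt, density = cnt / (length(durations) * w))
}

#' Binned log-likelihood of grid durations under a candidate model
#'
#' The log-likelihood treats each duration `d` as the bin
#' `[d, d + frame_dt)` and sums `n_k * log P(bin k)` with bin
#' probabilities from the normalized family density (closed form where
#' available, adaptive Gauss-Legendre quadrature otherwise).
#'
#' @param durations Numeric vector of durations on the `frame_dt` grid.
#' @param model A [candidate_model()].
#' @param params Named parameters for the family.
#' @param frame_dt Grid step in seconds (default 0.2).
#' @return Log-likelihood in nats; `-Inf` if any observed bin has zero
#'   probability under the model.
#' @export
binned_loglik <- function(durations, model, params, frame_dt = 0.2) {
  stopifnot(length(durations) >= 1)
  tab <- table(durations)
  d <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  lp <- model_bin_logprob(model, d, frame_dt, params)
  if (any(!is.finite(lp) & cnt > 0)) return(-Inf)
  sum(cnt * lp)
}

#' Akaike weights
#'
#' Normalized relative likelihoods `exp(-delta_m / 2)` with
#' `delta_m = AIC_m - min(AIC)`.
#'
#' @param aics Numeric vector of AIC values (at least 2 finite).
#' @return Weights summing to 1 (models with infinite AIC get weight 0).
#' @examples
#' akaike_weights(c(100, 102))  # c(0.7311, 0.2689)
#' @export
akaike_weights <- function(aics) {
  if (sum(is.finite(aics)) < 1) stop("no finite AIC values")
  d <- aics - min(aics[is.finite(aics)])
  w <- exp(-d / 2)
  w[!is.finite(aics)] <- 0
  w / sum(w)
}

# random multi-start generation in the transformed (box) space with a
# fixed, private sub-seed stream; the user's RNG state is untouched
.with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Maximum-likelihood fit of a candidate model to binned durations
#'
#' Maximizes the binned log-likelihood by bounded quasi-Newton
#' optimization with multiple starting points (one moment-guided start
#' plus random restarts drawn from a fixed sub-seed stream, so fits are
#' reproducible). Scale-like parameters are optimized on the log scale.
#'
#' @param durations Numeric vector of durations on the grid (n >= 10).
#' @param model A [candidate_model()]. For the bounded families the upper
#'   support bound should normally be `max(durations) + frame_dt`; see
#'   [fit_family()] for a convenience wrapper that sets supports from the
#'   data.
#' @param frame_dt Grid step (seconds).
#' @param n_starts Number of optimization starts (default 8).
#' @param seed Integer seed for the private multi-start stream.
#' @return An object of class `fit_result`: list with `model`, `params`
#'   (named vector), `loglik`, `aic`, `n`, `convergence` (0 = at least
#'   one start converged), `n_starts_converged`.
#' @export
fit_mle <- function(durations, model, frame_dt = 0.2, n_starts = 8,
                    seed = 1L) {
  stopifnot(length(durations) >= 10)
  info <- model_param_info(model)
  k <- length(info$names)
  lower <- info$lower; upper <- info$upper
  lsc <- rep_len(info$log_scale, k)

  if (model$family == "exp_head_pl_stretched_tail") {
    # keep the head/tail boundary inside the bulk of the data
    qs <- stats::quantile(durations, c(0.05, 0.95), names = FALSE)
    lower[4] <- max(lower[4], min(durations) + frame_dt / 2)
    upper[4] <- max(lower[4] * 1.5, qs[2])
    upper[5] <- max(upper[5], max(durations) * 10)
  }

  tab <- table(durations)
  d <- as.numeric(names(tab))
  cnt <- as.numeric(tab)

  tr <- function(x) ifelse(lsc, log(x), x)
  itr <- function(y) ifelse(lsc, exp(y), y)
  nll <- function(y) {
    p <- itr(y)
    names(p) <- info$names
    if (model$family == "exp_head_pl_stretched_tail" &&
        p["x3"] <= p["x2"]) return(1e10)
    lp <- model_bin_logprob(model, d, frame_dt, as.list(p))
    if (any(!is.finite(lp) & cnt > 0)) return(1e10)
    v <- -sum(cnt * lp)
    if (!is.finite(v)) 1e10 else v
  }

  # moment-guided start
  m <- mean(durations)
  start0 <- switch(model$family,
    bounded_exponential = c(lambda = 1 / max(m - model$support[1], frame_dt)),
    pure_power_law = c(mu = min(max(1 + 1 / max(log(m / model$support[1]),
                                                0.1), 1.05), 3.4)),
    bounded_power_law = c(mu = 1.5),
    pl_stretched_tail = c(mu = 1.5, beta = 0.5,
                          theta = stats::quantile(durations, 0.9,
                                                  names = FALSE)),
    exp_head_pl_stretched_tail = c(
      lambda = 1 / max(m, frame_dt), mu = 1.5, beta = 0.5,
      x2 = stats::quantile(durations, 0.25, names = FALSE) + frame_dt,
      x3 = stats::quantile(durations, 0.9, names = FALSE)))
  start0 <- pmin(pmax(start0, lower * 1.0000001), upper * 0.9999999)

  starts <- list(tr(start0))
  if (n_starts > 1) {
    rand <- .with_private_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        lo <- tr(lower); hi <- tr(upper)
        lo + stats::runif(k) * (hi - lo)
      })
    })
    starts <- c(starts, rand)
  }

  best <- NULL; n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, nll, lower = tr(lower), upper = tr(upper),
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || best$objective >= 1e10) {
    return(structure(list(model = model, params = NULL, loglik = -Inf,
                          aic = Inf, n = length(durations),
                          convergence = 1L, n_starts_converged = n_conv,
                          frame_dt = frame_dt),
                     class = "fit_result"))
  }
  params <- itr(best$par)
  names(params) <- info$names
  ll <- -best$objective
  structure(list(model = model, params = params, loglik = ll,
                 aic = 2 * k - 2 * ll, n = length(durations),
                 convergence = if (n_conv > 0) 0L else best$convergence,
                 n_starts_converged = n_conv, frame_dt = frame_dt),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Binned MLE fit:", x$model$family, "\n")
  cat("  n =", x$n, " support = [", x$model$support[1], ",",
      x$model$support[2], ")\n")
  if (is.null(x$params)) {
    cat("  FIT FAILED\n")
  } else {
    cat("  params:", paste(names(x$params),
                           signif(x$params, 5), sep = " = ",
                           collapse = ", "), "\n")
    cat("  loglik =", format(x$loglik, digits = 8),
        " AIC =", format(x$aic, digits = 8), "\n")
  }
  invisible(x)
}

#' Fit a family with data-driven support
#'
#' Convenience wrapper around [fit_mle()] that builds the
#' [candidate_model()] with support `[min(durations), max(durations) +
#' frame_dt)` for bounded families and `[min(durations), Inf)` otherwise.
#'
#' @inheritParams fit_mle
#' @param family Family name as in [candidate_model()].
#' @export
fit_family <- function(durations, family, frame_dt = 0.2, n_starts = 8,
                       seed = 1L) {
  a <- min(durations)
  b <- if (family %in% c("bounded_exponential", "bounded_power_law"))
    max(durations) + frame_dt else Inf
  fit_mle(durations, candidate_model(family, support = c(a, b)),
          frame_dt = frame_dt, n_starts = n_starts, seed = seed)
}

#' Sequential pointwise model comparison (SPWMC)
#'
#' Refits a set of candidate families to the durations above a sliding
#' truncation point and tracks Akaike weights, revealing which family
#' dominates which regime of the distribution (e.g. bounded power law in
#' the tail).
#'
#' @param durations Numeric vector of grid durations.
#' @param families Character vector of families to compare; default the
#'   three classical dispersal models (bounded exponential, pure power
#'   law, bounded power law).
#' @param grid Numeric vector of truncation points; default 15 log-spaced
#'   points from the grid floor to the 90th percentile. Points leaving
#'   fewer than `min_n` observations (or above the maximum) are dropped
#'   with a warning.
#' @param frame_dt Grid step (seconds).
#' @param min_n Minimum retained sample size per truncation point.
#' @param seed Seed passed to [fit_mle()].
#' @return Object of class `spwmc_profile`: list with `truncation`, `n`
#'   (retained sample sizes), `waic` (matrix point x family), `fits`
#'   (list of lists of `fit_result`).
#' @export
spwmc <- function(durations,
                  families = c("bounded_exponential", "pure_power_law",
                               "bounded_power_law"),
                  grid = NULL, frame_dt = 0.2, min_n = 50, seed = 1L) {
  stopifnot(length(durations) >= min_n)
  if (is.null(grid)) {
    hi <- stats::quantile(durations, 0.9, names = FALSE)
    lo <- min(durations)
    grid <- if (hi <= lo) lo else exp(seq(log(lo), log(hi), length.out = 15))
  }
  keep <- vapply(grid, function(g) sum(durations >= g) >= min_n &&
                   g <= max(durations), logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " truncation point(s) dropped (fewer than ",
            min_n, " observations or above the maximum)")
  }
  grid <- grid[keep]
  fits <- lapply(grid, function(g) {
    dsub <- durations[durations >= g]
    lapply(families, function(fam)
      fit_family(dsub, fam, frame_dt = frame_dt, n_starts = 4, seed = seed))
  })
  waic <- t(vapply(fits, function(fl)
    akaike_weights(vapply(fl, function(f) f$aic, numeric(1))),
    numeric(length(families))))
  colnames(waic) <- families
  structure(list(truncation = grid,
                 n = vapply(grid, function(g) sum(durations >= g),
                            numeric(1)),
                 waic = waic, fits = fits, families = families),
            class = "spwmc_profile")
}

#' @export
print.spwmc_profile <- function(x, ...) {
  cat("SPWMC profile over", length(x$truncation), "truncation points\n")
  df <- data.frame(truncation = signif(x$truncation, 4), n = x$n,
                   signif(x$waic, 3), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Poisson-band model criticism
#'
#' Compares observed log-binned counts with the expectation under a fitted
#' model, assuming Poisson deviations per bin: the band is
#' `E_b +/- 2 sqrt(E_b)`.
#'
#' @param durations Numeric vector of grid durations used in the fit.
#' @param fit A `fit_result`.
#' @param base Log-bin growth factor (default 2).
#' @return data.frame with `left`, `right`, `observed`, `expected`, `lo`,
#'   `hi`, `outside` (logical flag).
#' @export
model_criticism <- function(durations, fit, base = 2) {
  stopifnot(inherits(fit, "fit_result"), !is.null(fit$params))
  n <- length(durations)
  edges <- log_bin_edges(max(durations), base = base,
                         anchor = fit$model$support[1])
  obs <- tabulate(findInterval(durations, edges, rightmost.closed = FALSE),
                  length(edges) - 1)
  pr <- .bin_prob_range(fit, edges)
  expd <- n * pr
  lo <- expd - 2 * sqrt(expd)
  hi <- expd + 2 * sqrt(expd)
  data.frame(left = edges[-length(edges)], right = edges[-1],
             observed = obs, expected = expd, lo = lo, hi = hi,
             outside = obs < lo | obs > hi)
}

# model probability of arbitrary [edges] intervals, respecting the grid
# convention: interval [l, r) gets the mass of all grid bins with left
# edge in [l, r)
.bin_prob_range <- function(fit, edges) {
  model <- fit$model; params <- fit$params; dt <- fit$frame_dt
  a <- model$support[1]; b <- model$support[2]
  top <- if (is.finite(b)) b else edges[length(edges)]
  lefts <- seq(a, top - dt / 2, by = dt)
  lp <- model_bin_logprob(model, lefts, dt, params)
  p <- exp(lp)
  idx <- findInterval(lefts, edges, rightmost.closed = FALSE)
  out <- vapply(seq_len(length(edges) - 1),
                function(i) sum(p[idx == i]), numeric(1))
  # any model mass beyond the last edge belongs to no display bin
  out
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' G statistic on log-binned counts versus the fitted-model expectation
#' (bins with expected count < 5 merged from the right), with a
#' parametric bootstrap null: each replicate is drawn from the fitted
#' model, refitted, and its G statistic recomputed. Large p-values
#' (> 0.1) indicate a good fit.
#'
#' @param durations Numeric vector of grid durations used in the fit.
#' @param fit A `fit_result`.
#' @param n_boot Number of bootstrap replicates (>= 200 recommended).
#' @param base Log-bin growth factor.
#' @param n_starts Optimization starts for the bootstrap refits.
#' @param seed Seed for the bootstrap stream.
#' @return List with `statistic`, `p_value`, `n_boot_used`,
#'   `n_boot_failed`.
#' @export
gof_test <- function(durations, fit, n_boot = 200, base = 2, n_starts = 4,
                     seed = 1L) {
  stopifnot(inherits(fit, "fit_result"), !is.null(fit$params),
            n_boot >= 1)
  g_obs <- .g_statistic(durations, fit, base = base)
  fam <- fit$model$family
  dt <- fit$frame_dt
  g_boot <- .with_private_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      sim <- model_sample(fit$model, fit$n, fit$params, frame_dt = dt)
      rf <- tryCatch(fit_family(sim, fam, frame_dt = dt,
                                n_starts = n_starts, seed = seed + b),
                     error = function(e) NULL)
      if (is.null(rf) || is.null(rf$params)) return(NA_real_)
      .g_statistic(sim, rf, base = base)
    }, numeric(1))
  })
  ok <- is.finite(g_boot)
  list(statistic = g_obs,
       p_value = mean(g_boot[ok] >= g_obs),
       n_boot_used = sum(ok), n_boot_failed = sum(!ok))
}

.g_statistic <- function(durations, fit, base = 2) {
  n <- length(durations)
  edges <- log_bin_edges(max(durations), base = base,
                         anchor = fit$model$support[1])
  obs <- tabulate(findInterval(durations, edges, rightmost.closed = FALSE),
                  length(edges) - 1)
  expd <- n * .bin_prob_range(fit, edges)
  # merge bins with small expectation from the right
  o <- obs; e <- expd
  i <- length(e)
  while (i > 1) {
    if (e[i] < 5) {
      e[i - 1] <- e[i - 1] + e[i]; o[i - 1] <- o[i - 1] + o[i]
      e <- e[-i]; o <- o[-i]
    }
    i <- i - 1
  }
  keep <- e > 0
  o <- o[keep]; e <- e[keep]
  # rescale expectation to the observed total over kept bins
  e <- e * sum(o) / sum(e)
  pos <- o > 0
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Pooled cohort fit of the stretched-tail power law
#'
#' Pools bout durations across individuals (the "average animal"),
#' removes durations above an exclusion cap (atypical behaviour;
#' 1000 s for pauses in the source protocol), and fits the power law with
#' stretched-exponential tail by binned MLE.
#'
#' @param durations Numeric vector or list of numeric vectors (one per
#'   individual) of grid durations.
#' @param exclusion_cap Durations strictly greater than this are dropped
#'   (default 1000 s; `Inf` disables the filter).
#' @param frame_dt Grid step (seconds).
#' @param ... Passed to [fit_mle()].
#' @return A `fit_result`.
#' @export
pooled_fit <- function(durations, exclusion_cap = 1000, frame_dt = 0.2,
                       ...) {
  stopifnot(exclusion_cap > frame_dt)
  d <- unlist(durations, use.names = FALSE)
  d <- d[d <= exclusion_cap]
  if (!length(d)) stop("no durations remain after applying the cap")
  fit_mle(d, candidate_model("pl_stretched_tail",
                             support = c(min(d), Inf)),
          frame_dt = frame_dt, ...)
}
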