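# Independent oracles used to freeze expected values.

# Brute-force fine-grid Riemann-sum binned log-likelihood: midpoint rule
# on each observed data bin plus a log-spaced midpoint rule for the
# normalization constant. Independent of the package's quadrature path.
riemann_loglik <- function(durations, model, params, frame_dt = 0.2,
                           n_sub = 4000, n_norm = 400000) {
  a <- model$support[1]; b <- model$support[2]
  dens <- function(x) exp(intermove:::model_logdensity(model, x, params))
  # normalization over the support (truncate infinite supports far out)
  upper <- if (is.finite(b)) b else {
    p <- as.list(params)
    tth <- switch(model$family, pl_stretched_tail = p$theta,
                  exp_head_pl_stretched_tail = p$x3, Inf)
    if (!is.finite(tth)) 1e9 else {
      U <- max(4 * a, tth)
      ref <- log(dens(a) * a)
      repeat {
        lb <- -(U / tth)^p$beta + (1 - p$mu) * log(U)
        if (lb < ref - 45 || U > 1e15) break
        U <- U * 2
      }
      U
    }
  }
  lx <- seq(log(a), log(upper), length.out = n_norm)
  mid <- exp((lx[-1] + lx[-n_norm]) / 2)
  Z <- sum(dens(mid) * diff(exp(lx)))
  tab <- table(durations)
  d <- as.numeric(names(tab)); cnt <- as.numeric(tab)
  lp <- vapply(d, function(l) {
    r <- min(l + frame_dt, b)
    xs <- seq(l, r, length.out = n_sub + 1)
    m <- (xs[-1] + xs[-length(xs)]) / 2
    log(sum(dens(m)) * (r - l) / n_sub) - log(Z)
  }, numeric(1))
  sum(cnt * lp)
}

# PACF oracle: lag-k coefficient as the last coefficient of the order-k
# Yule-Walker autoregression, solved by direct Toeplitz inversion.
pacf_toeplitz_oracle <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  r <- vapply(0:max_lag, function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / sum(x^2), numeric(1))
  vapply(1:max_lag, function(k) {
    R <- stats::toeplitz(r[1:k])
    solve(R, r[2:(k + 1)])[k]
  }, numeric(1))
}

# rotational direction oracle via the finite difference of the unwrapped
# polar angle
polar_dir_oracle <- function(traj) {
  phi <- atan2(traj$y_cm, traj$x_cm)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  s <- sign(d)
  # carry-forward rule for zero steps, matching the package contract
  n <- length(s)
  nz <- s != 0
  if (!any(nz)) return(rep(NA_integer_, n))
  idx <- cummax(ifelse(nz, seq_len(n), 0L))
  idx[idx == 0L] <- which(nz)[1]
  as.integer(s[idx])
}

# discrete-law mean oracle: sum over grid bins of d * P(bin d), bin
# probabilities by midpoint Riemann sums (independent of the package
# quadrature)
discrete_mean_oracle <- function(params, frame_dt = 0.2, xmax = 20000,
                                 n_sub = 50) {
  dens <- function(x) x^(-params$mu) * exp(-(x / params$theta)^params$beta)
  lefts <- seq(params$xmin, xmax, by = frame_dt)
  offs <- (seq_len(n_sub) - 0.5) * frame_dt / n_sub
  mids <- rep(lefts, each = n_sub) + offs
  v <- dens(mids) * frame_dt / n_sub
  binp <- colSums(matrix(v, nrow = n_sub))
  sum(lefts * binp) / sum(binp)
}
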