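# Binned likelihood, MLE, model comparison and goodness of fit.

test_that("empirical CCDF counts observations at and above each value", {
  cc <- empirical_ccdf(c(0.2))
  expect_equal(cc$ccdf, 1)
  cc <- empirical_ccdf(c(0.2, 0.4, 0.4, 0.8))
  expect_equal(cc$ccdf[cc$x == 0.4], 0.75)
  expect_equal(cc$ccdf[1], 1)
  expect_true(all(diff(cc$ccdf) <= 0))
})

test_that("log-binned PDF is a proper density", {
  set.seed(501)
  x <- sample_bout_lengths(move_params, 5000)
  pdf <- log_binned_pdf(x)
  expect_equal(sum(pdf$density * (pdf$right - pdf$left)), 1)
  expect_equal(sum(pdf$count), 5000)
  # degenerate: all durations in the first bin
  pdf1 <- log_binned_pdf(rep(0.2, 10))
  expect_equal(pdf1$density[1], 1 / (pdf1$right[1] - pdf1$left[1]))
})

test_that("log-log PDF slope of pure power-law data is about -mu", {
  set.seed(502)
  m <- candidate_model("pure_power_law", c(0.2, Inf))
  x <- model_sample(m, 1e5, c(mu = 2))
  pdf <- log_binned_pdf(x)
  pdf <- pdf[pdf$count >= 30, ]
  mid <- sqrt(pdf$left * pdf$right)
  slope <- stats::coef(stats::lm(log(pdf$density) ~ log(mid)))[2]
  expect_equal(unname(slope), -2, tolerance = 0.1)
})

test_that("binned log-likelihood matches the fine-grid Riemann oracle", {
  set.seed(503)
  toy <- sample(seq(0.2, 6, by = 0.2), 20, replace = TRUE,
                prob = (seq(0.2, 6, by = 0.2))^-1.5)
  cases <- list(
    list(m = candidate_model("bounded_exponential", c(0.2, 6.2)),
         p = c(lambda = 0.6)),
    list(m = candidate_model("pure_power_law", c(0.2, Inf)),
         p = c(mu = 1.9)),
    list(m = candidate_model("bounded_power_law", c(0.2, 6.2)),
         p = c(mu = 1.4)),
    list(m = candidate_model("pl_stretched_tail", c(0.2, Inf)),
         p = c(mu = 1.49, beta = 0.55, theta = 8)),
    list(m = candidate_model("exp_head_pl_stretched_tail", c(0.2, Inf)),
         p = c(lambda = 1.5, mu = 1.6, beta = 0.4, x2 = 1.1, x3 = 12)))
  for (cs in cases) {
    ll <- binned_loglik(toy, cs$m, cs$p)
    oracle <- riemann_loglik(toy, cs$m, cs$p)
    expect_equal(ll, oracle, tolerance = 1e-6)
  }
})

test_that("binned log-likelihood closed-form corner cases", {
  # all mass in one bin under a model whose support is that bin
  m1 <- candidate_model("bounded_exponential", c(0.2, 0.4))
  expect_equal(binned_loglik(rep(0.2, 7), m1, c(lambda = 1)), 0)
  # two near-equal-probability bins, counts (5, 5): loglik 10 log(1/2)
  m2 <- candidate_model("bounded_exponential", c(0.2, 0.6))
  ll <- binned_loglik(c(rep(0.2, 5), rep(0.4, 5)), m2, c(lambda = 1e-4))
  expect_equal(ll, 10 * log(0.5), tolerance = 1e-6)
  # observation off the support flags -Inf
  expect_identical(binned_loglik(c(0.2, 0.8), m1, c(lambda = 1)), -Inf)
})

test_that("optimizer beats a dense parameter-grid search", {
  set.seed(504)
  d <- sample_bout_lengths(move_params, 150)
  m <- candidate_model("pl_stretched_tail", c(0.2, Inf))
  fit <- fit_mle(d, m, n_starts = 6)
  grid <- expand.grid(mu = seq(1.05, 2.9, length.out = 22),
                      beta = seq(0.08, 1, length.out = 22),
                      theta = exp(seq(log(0.3), log(300), length.out = 22)))
  best_grid <- max(vapply(seq_len(nrow(grid)), function(i)
    binned_loglik(d, m, unlist(grid[i, ])), numeric(1)))
  expect_gte(fit$loglik, best_grid - 1e-4)
})

test_that("known-parameter recovery for the simple families", {
  set.seed(505)
  m <- candidate_model("pure_power_law", c(0.2, Inf))
  x <- model_sample(m, 1e5, c(mu = 2))
  f <- fit_mle(x, m)
  expect_equal(unname(f$params["mu"]), 2, tolerance = 0.02)
  expect_equal(f$aic, 2 - 2 * f$loglik)

  b <- candidate_model("bounded_exponential", c(0.2, 30))
  y <- model_sample(b, 2e4, c(lambda = 1))
  g <- fit_family(y, "bounded_exponential")
  # 95% CI for lambda-hat is roughly lambda +/- 2 lambda / sqrt(n)
  expect_lt(abs(g$params["lambda"] - 1), 2 / sqrt(2e4) * 1.5)
})

test_that("stretched-tail MLE is consistent (moderate-n sanity)", {
  set.seed(506)
  d <- sample_bout_lengths(move_params, 2e4)
  f <- fit_mle(d, candidate_model("pl_stretched_tail", c(0.2, Inf)),
               n_starts = 6)
  llt <- binned_loglik(d, f$model,
                       c(mu = 1.49, beta = 0.55, theta = 8))
  expect_gte(f$loglik, llt)          # the MLE dominates the truth
  expect_equal(unname(f$params["mu"]), 1.49, tolerance = 0.12)
})

test_that("median recovered mu is unbiased over replicates", {
  # recovery-bias invariant, scaled to test runtime: 10 replicates at
  # n = 10000 (the flat theta ridge does not bias mu)
  mus <- vapply(1:10, function(i) {
    set.seed(600 + i)
    d <- sample_bout_lengths(move_params, 1e4)
    f <- fit_mle(d, candidate_model("pl_stretched_tail", c(0.2, Inf)),
                 n_starts = 4)
    unname(f$params["mu"])
  }, numeric(1))
  expect_lt(abs(stats::median(mus) - 1.49), 0.05)
})

test_that("SPWMC gives the true family dominant weight", {
  set.seed(507)
  bexp <- candidate_model("bounded_exponential", c(0.2, 60))
  d1 <- model_sample(bexp, 2000, c(lambda = 0.5))
  pr1 <- spwmc(d1)
  expect_equal(rowSums(pr1$waic), rep(1, nrow(pr1$waic)))
  expect_true(all(pr1$waic[pr1$n >= 500, "bounded_exponential"] > 0.9))

  bpl <- candidate_model("bounded_power_law", c(0.2, 500))
  d2 <- model_sample(bpl, 2000, c(mu = 1.8))
  pr2 <- spwmc(d2)
  # the bounded power law dominates in the tail region
  tail_pts <- pr2$truncation >= stats::quantile(d2, 0.5)
  expect_true(all(pr2$waic[tail_pts, "bounded_power_law"] > 0.5))
  expect_warning(spwmc(d1, grid = c(0.2, 1e5)), "dropped")
})

test_that("Poisson-band criticism flags misspecification, not truth", {
  set.seed(508)
  bexp <- candidate_model("bounded_exponential", c(0.2, 60))
  d <- model_sample(bexp, 2e4, c(lambda = 0.4))
  f <- fit_family(d, "bounded_exponential")
  mc <- model_criticism(d, f)
  expect_equal(mc$hi - mc$expected, 2 * sqrt(mc$expected))
  used <- mc$expected >= 5
  expect_gte(mean(!mc$outside[used]), 0.8)
  # exponential data criticized under a power-law fit: tail run outside
  fpl <- fit_family(d, "pure_power_law")
  mc2 <- model_criticism(d, fpl)
  expect_gte(sum(mc2$outside), 3)
})

test_that("parametric-bootstrap GOF separates good and bad fits", {
  set.seed(509)
  bexp <- candidate_model("bounded_exponential", c(0.2, 60))
  d <- model_sample(bexp, 400, c(lambda = 0.5))
  f <- fit_family(d, "bounded_exponential")
  g <- gof_test(d, f, n_boot = 200, seed = 7)
  expect_gt(g$p_value, 0)   # observed-like replicates are counted
  expect_gt(g$p_value, 0.01)
  # grossly misspecified: heavy-tailed data under an exponential fit
  set.seed(510)
  hv <- sample_bout_lengths(list(mu = 1.6, beta = 0.4, theta = 30,
                                 xmin = 0.2), 2000)
  fb <- fit_family(hv, "bounded_exponential")
  g2 <- gof_test(hv, fb, n_boot = 200, seed = 8)
  expect_lt(g2$p_value, 0.01)
})

test_that("pooled fit applies the exclusion cap", {
  set.seed(511)
  cohort <- list(sample_bout_lengths(pause_params, 3000),
                 c(sample_bout_lengths(pause_params, 3000), 1200, 2000))
  d <- unlist(cohort)
  f <- pooled_fit(cohort, exclusion_cap = 1000, n_starts = 2)
  expect_equal(f$n, sum(d <= 1000))
  f2 <- pooled_fit(cohort, exclusion_cap = Inf, n_starts = 2)
  expect_equal(f2$n, length(d))
  expect_error(pooled_fit(list(numeric(0))), "remain|>= 10")
})
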