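# Synthetic generator: reproducibility, ground-truth round trips and
# distributional fidelity.

test_that("configuration invariants are enforced", {
  expect_error(generator_config(frame_dt = 0), "frame_dt")
  expect_error(generator_config(dome_radius = 45), "radii")
  expect_error(generator_config(
    move_dist_params = list(mu = 3.5, beta = 0.5, theta = 8, xmin = 0.2)),
    "mu")
  expect_error(generator_config(within_pause_switch_rate = 1.3), "rate")
  expect_error(generator_config(move_speed = 1), "0.3 cm")
  expect_silent(validate_generator_config(generator_config()))
})

test_that("same master seed gives a bitwise-identical cohort", {
  cfg <- quick_cfg(duration = 120, seed = 21)
  c1 <- generate_cohort(cfg, 3)
  c2 <- generate_cohort(cfg, 3)
  expect_identical(c1, c2)
  cfg2 <- quick_cfg(duration = 120, seed = 22)
  c3 <- generate_cohort(cfg2, 3)
  expect_false(isTRUE(all.equal(c1[[1]]$x_cm, c3[[1]]$x_cm)))
  # per-individual trajectories differ from each other
  expect_false(isTRUE(all.equal(c1[[1]]$x_cm, c1[[2]]$x_cm)))
})

test_that("discretization recovers the ground-truth ledger exactly", {
  cfg <- quick_cfg(duration = 900, seed = 23)
  tr <- simulate_trajectory(cfg)
  led <- attr(tr, "ground_truth")
  sq <- discretize_trajectory(tr)
  expect_equal(sq$bouts$state, led$bouts$state)
  expect_equal(sq$bouts$start_frame, led$bouts$start_frame)
  expect_equal(sq$bouts$n_frames, led$bouts$n_frames)
  expect_identical(unlist(sq$directions), led$dirs)
  # no censoring on the mid-radius circle
  expect_equal(nrow(sq$censored_gaps), 0)
  # frame spacing and radii invariants
  expect_equal(diff(tr$t_s), rep(cfg$frame_dt, nrow(tr) - 1))
  r <- sqrt(tr$x_cm^2 + tr$y_cm^2)
  expect_true(all(r > 0 & r <= cfg$arena_outer_radius))
})

test_that("turn-curve extremes produce the expected direction sequences", {
  # turn probability 1 everywhere: every interior pause is a turn
  cfg1 <- quick_cfg(duration = 400, seed = 24,
                    turn_after_pause_curve = list(x = c(0.2, 10),
                                                  p = c(1, 1)))
  tr1 <- simulate_trajectory(cfg1)
  tap1 <- turn_after_pause(discretize_trajectory(tr1))
  expect_true(all(tap1$turned))
  # turn probability 0 and no fidget switching: no switches at all
  cfg0 <- quick_cfg(duration = 400, seed = 25,
                    turn_after_pause_curve = list(x = c(0.2, 10),
                                                  p = c(0, 0)),
                    within_pause_switch_rate = 0)
  tr0 <- simulate_trajectory(cfg0)
  sq0 <- discretize_trajectory(tr0)
  expect_equal(length(unique(unlist(sq0$directions))), 1)
  expect_false(any(turn_after_pause(sq0)$turned))
})

test_that("ledger bookkeeping is consistent", {
  cfg <- quick_cfg(duration = 600, seed = 26)
  set.seed(cfg$seed)
  led <- simulate_bout_ledger(cfg)
  b <- led$bouts
  expect_equal(sum(b$n_frames), led$n_transitions)
  expect_equal(led$n_transitions, round(cfg$duration / cfg$frame_dt))
  expect_equal(b$duration, b$n_frames * cfg$frame_dt)
  # states strictly alternate
  expect_true(all(b$state[-1] != b$state[-nrow(b)]))
  # start frames tile the record
  expect_equal(b$start_frame,
               as.integer(cumsum(c(1, b$n_frames[-nrow(b)]))))
  expect_length(led$dirs, led$n_transitions)
  expect_true(all(led$dirs %in% c(-1L, 1L)))
})

test_that("sampled bout laws reproduce their target CCDF (DKW band)", {
  set.seed(27)
  n <- 1e5
  x <- sample_bout_lengths(move_params, n)
  m <- candidate_model("pl_stretched_tail", c(0.2, Inf))
  lefts <- seq(0.2, max(x), by = 0.2)
  pr <- exp(model_bin_logprob(m, lefts, 0.2, unlist(move_params[1:3])))
  th <- 1 - c(0, cumsum(pr)[-length(pr)])
  cc <- empirical_ccdf(x)
  th_at <- th[match(round(cc$x / 0.2), round(lefts / 0.2))]
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  expect_true(all(abs(cc$ccdf - th_at) < eps))
})

test_that("configured turn curve is recovered within binomial CIs", {
  # plateau-free rising curve, estimated from the ledgers of a small
  # cohort and compared per log bin
  cfg <- generator_config(duration = 7200, seed = 28)
  pairs <- list()
  for (i in 1:6) {
    ci <- cfg; ci$seed <- 3000 + i
    set.seed(ci$seed)
    led <- simulate_bout_ledger(ci)
    pairs[[i]] <- turn_after_pause(as_bout_seq(led))
  }
  pairs <- do.call(rbind, pairs)
  curve <- turn_probability_curve(pairs)
  truth <- intermove:::eval_turn_curve(cfg$turn_after_pause_curve,
                                       sqrt(curve$bin_left * curve$bin_right))
  used <- curve$n >= 50
  # binomial 95% CI contains the configured probability (allowing the
  # within-bin curvature of the log-interpolated curve)
  cover <- truth[used] >= curve$lo[used] - 0.03 &
    truth[used] <= curve$hi[used] + 0.03
  expect_gte(mean(cover), 0.9)
})

test_that("trajectory CSV and ledger JSON round-trip", {
  cfg <- quick_cfg(duration = 120, seed = 29)
  co <- generate_cohort(cfg, 2)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(co, tmp)
  back <- read_trajectory_csv(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[["ind01"]]$x_cm, co[["ind01"]]$x_cm)
  ltmp <- tempfile(fileext = ".json")
  write_ledger_json(attr(co[[1]], "ground_truth"), ltmp)
  j <- jsonlite::read_json(ltmp, simplifyVector = TRUE)
  expect_equal(j$n_transitions,
               attr(co[[1]], "ground_truth")$n_transitions)
})
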