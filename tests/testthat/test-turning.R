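# Reorientation: turns after pauses, fidgeting within bouts, influence
# and the long-vs-intermediate pause contrast.

test_that("turn after pause compares the flanking move directions", {
  # CW move, pause, ACW move -> turn
  sq <- make_bout_seq(c("move", "pause", "move"),
                      list(c(-1, -1), c(-1, 1, -1), c(1, 1)))
  tap <- turn_after_pause(sq)
  expect_equal(nrow(tap), 1)
  expect_true(tap$turned)
  expect_equal(tap$duration, 0.6)
  # CW move, pause, CW move -> no turn (whatever happens inside)
  sq2 <- make_bout_seq(c("move", "pause", "move"),
                       list(c(-1, -1), c(1, -1, 1), c(-1, -1)))
  expect_false(turn_after_pause(sq2)$turned)
  # pause at a block boundary is excluded
  sq3 <- make_bout_seq(c("move", "pause", "move"),
                       list(c(-1, -1), c(1), c(-1)),
                       censored_edge = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(turn_after_pause(sq3)), 0)
})

test_that("within-bout turning counts sign changes between transitions", {
  r <- turns_within_bout(c(-1L, -1L, 1L, -1L))
  expect_true(r$any_turn)
  expect_equal(r$proportion, 2 / 3)
  r2 <- turns_within_bout(c(-1L, -1L, -1L))
  expect_false(r2$any_turn)
  expect_equal(r2$proportion, 0)
  r3 <- turns_within_bout(c(1L))
  expect_true(is.na(r3$any_turn))
  expect_true(is.na(r3$proportion))
  # bout_seq interface returns one row per bout
  sq <- make_bout_seq(c("move", "pause"), list(c(1, 1), c(1, -1, 1)))
  tw <- turns_within_bout(sq)
  expect_equal(tw$proportion, c(0, 1))
})

test_that("within-pause switch rate is recovered from long pauses", {
  cfg <- quick_cfg(duration = 3600, seed = 31,
                   within_pause_switch_rate = 0.55)
  set.seed(cfg$seed)
  led <- simulate_bout_ledger(cfg)
  tw <- turns_within_bout(as_bout_seq(led))
  long_pauses <- tw$state == "pause" & tw$duration >= 2
  props <- tw$proportion[long_pauses]
  n_pairs <- sum(tw$duration[long_pauses] / 0.2 - 1)
  se <- sqrt(0.55 * 0.45 / n_pairs)
  expect_lt(abs(stats::weighted.mean(props,
                                     tw$duration[long_pauses] / 0.2 - 1) -
                  0.55), 3 * se)
})

test_that("turn probability curve bins, CIs and error handling", {
  pairs <- data.frame(duration = c(0.2, 0.3, 1, 5, 5, 200),
                      turned = rep(TRUE, 6))
  cur <- turn_probability_curve(pairs)
  expect_true(all(cur$p == 1))
  expect_true(all(cur$lo >= 0 & cur$hi <= 1))
  expect_equal(sum(cur$n), 6)
  expect_error(turn_probability_curve(pairs, bins = c(1, 0.5)),
               "increasing")
})

test_that("turn influence weights probability by abundance", {
  cur <- structure(data.frame(bin_left = c(0.2, 0.4, 0.8),
                              bin_right = c(0.4, 0.8, 1.6),
                              p = c(0.5, 0.5, 0.5),
                              lo = 0, hi = 1, n = c(10, 10, 10)),
                   class = c("turn_curve", "data.frame"))
  infl <- turn_influence(cur)
  expect_equal(infl$influence, rep(0.5 / 3, 3))
  cur$p <- c(1, 0, 0); cur$n <- c(30, 0, 0)
  infl2 <- turn_influence(cur)
  expect_equal(infl2$influence, c(1, 0, 0))
  expect_lte(sum(infl2$influence), 1)
  expect_error(turn_influence(cur, pause_counts = 1:2), "per curve bin")
})

test_that("abundant short pauses dominate influence despite low p", {
  set.seed(32)
  durs <- sample_bout_lengths(pause_params, 2e4)
  cfg <- generator_config()
  p <- intermove:::eval_turn_curve(cfg$turn_after_pause_curve, durs)
  pairs <- data.frame(duration = durs,
                      turned = stats::runif(2e4) < p)
  cur <- turn_probability_curve(pairs)
  infl <- turn_influence(cur)
  short <- infl$bin_right <= 6.5
  expect_gt(sum(infl$influence[short]), sum(infl$influence[!short]))
  # even though per-pause probability is lowest in the short bins
  # (restrict to bins with enough observations to estimate p)
  well_obs <- cur$bin_left >= 6 & cur$n >= 20
  expect_lt(cur$p[1], min(cur$p[well_obs], na.rm = TRUE))
})

test_that("pooled t-test contrasts fidget proportions between classes", {
  expect_error(compare_turn_proportions(rep(0.5, 4), rep(0.5, 4)),
               "zero variance")
  a <- c(0.5, 0.6, 0.7); b <- a + 0.1
  ht <- compare_turn_proportions(a, b)
  expect_equal(unname(ht$parameter), 4)        # nA + nB - 2
  ht0 <- compare_turn_proportions(a, a)
  expect_equal(unname(ht0$statistic), 0)
  # group moments matching the reference contrast: intermediate pauses
  # (mean 0.5771, sd 0.1049) vs long pauses (mean 0.6505, sd 0.0191)
  set.seed(33)
  gA <- stats::rnorm(4600, 0.5771, 0.1049)
  gB <- stats::rnorm(232, 0.6505, 0.0191)
  ht2 <- compare_turn_proportions(gA, gB)
  expect_lt(unname(ht2$statistic), 0)
  expect_gt(abs(unname(ht2$statistic)), 5)
  expect_equal(unname(ht2$parameter), 4830)
  expect_lt(ht2$p.value, 1e-4)
})

test_that("pauses dominate turning relative to moves", {
  cfg <- quick_cfg(duration = 3600, seed = 34)
  set.seed(cfg$seed)
  led <- simulate_bout_ledger(cfg)
  tw <- turns_within_bout(as_bout_seq(led))
  turning <- tw$any_turn %in% TRUE
  # of all bouts containing a direction change, most are pauses
  expect_gt(sum(turning & tw$state == "pause"),
            sum(turning & tw$state == "move"))
})
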