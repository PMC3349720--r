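# Frame classification, rotational direction, bout encoding, edge
# exclusion and the angular-speed profile.

test_that("displacement threshold classifies transitions correctly", {
  dt <- 0.2
  # straight-line steps of chosen lengths (arena geometry irrelevant here)
  steps <- c(0.35, 0.30, 0.29, 0.31)
  x <- cumsum(c(25, steps))
  traj <- structure(data.frame(t_s = (0:4) * dt, x_cm = x, y_cm = 0 * x),
                    frame_dt = dt, class = c("trajectory", "data.frame"))
  expect_equal(classify_frames(traj),
               c("move", "pause", "pause", "move"))
  # 51 identical positions -> 50 pause labels
  traj2 <- make_traj(rep(0.5, 51))
  expect_equal(classify_frames(traj2), rep("pause", 50))
  # non-uniform spacing is an input error
  traj3 <- traj
  traj3$t_s[3] <- traj3$t_s[3] + 0.05
  expect_error(classify_frames(traj3), "uniform")
})

test_that("rotational direction follows the cross-product sign", {
  deg <- pi / 180
  tr <- make_traj(c(0, 1, 2) * deg)
  expect_equal(rotational_direction(tr), c(1L, 1L))
  tr2 <- make_traj(c(0, 1, 0) * deg)
  expect_equal(rotational_direction(tr2), c(1L, -1L))
  # zero cross product carries the previous label forward, and leading
  # zeros take the first nonzero label
  tr3 <- make_traj(c(0, 0, 1, 1, 0.5) * deg)
  expect_equal(rotational_direction(tr3), c(1L, 1L, 1L, -1L))
  expect_warning(rotational_direction(make_traj(rep(0.3, 5))), "undefined")
})

test_that("direction labels equal the unwrapped-polar-angle oracle", {
  set.seed(601)
  for (i in 1:200) {
    phi <- cumsum(stats::rnorm(100, 0, 0.02))
    tr <- make_traj(phi)
    expect_identical(rotational_direction(tr), polar_dir_oracle(tr))
  }
})

test_that("bout encoding conserves duration and merges runs", {
  lab <- c("move", "move", "pause", "pause", "pause", "move")
  dir <- c(1L, 1L, 1L, -1L, 1L, -1L)
  bs <- encode_bouts(lab, dir, 0.2)
  expect_equal(bs$bouts$state, c("move", "pause", "move"))
  expect_equal(bs$bouts$duration, c(0.4, 0.6, 0.2))
  expect_equal(bs$directions[[2]], c(1L, -1L, 1L))
  expect_equal(sum(bs$bouts$duration), length(lab) * 0.2)
  # all-move input: a single bout
  bs2 <- encode_bouts(rep("move", 40), rep(1L, 40), 0.2)
  expect_equal(nrow(bs2$bouts), 1)
  expect_equal(bs2$bouts$duration, 8)
  expect_error(encode_bouts(character(0), integer(0), 0.2), "empty")
})

test_that("edge exclusion censors the 3 cm wall and dome margins", {
  dt <- 0.2
  mk <- function(r) make_traj(seq(0, 0.1, length.out = 6), r = r)
  expect_false(any(attr(apply_edge_exclusion(mk(30)), "censored")))
  expect_true(all(attr(apply_edge_exclusion(mk(38)), "censored")))
  expect_true(all(attr(apply_edge_exclusion(mk(20.4)), "censored")))
  expect_false(any(attr(apply_edge_exclusion(mk(20.6)), "censored")))
  expect_error(apply_edge_exclusion(mk(30), margin = 15), "annulus")
})

test_that("discretization splits at censored gaps and flags edge bouts", {
  dt <- 0.2
  # radius profile: inside, outside (censored), inside
  r <- c(rep(30, 30), rep(38.5, 10), rep(30, 30))
  phi <- cumsum(rep(0.03, 70))     # constant angular motion (moves)
  traj <- structure(data.frame(t_s = (0:69) * dt,
                               x_cm = r * cos(phi), y_cm = r * sin(phi)),
                    individual_id = "e1", frame_dt = dt,
                    arena_outer_radius = 40, dome_radius = 17.5,
                    class = c("trajectory", "data.frame"))
  sq <- discretize_trajectory(traj)
  expect_equal(length(unique(sq$bouts$block)), 2)
  expect_equal(nrow(sq$censored_gaps), 1)
  expect_true(all(sq$bouts$censored_edge))  # one bout per block, both edges
  # conservation within blocks: sum of durations = transitions * dt
  n_tr <- sum(sq$bouts$n_frames)
  expect_equal(sum(sq$bouts$duration), n_tr * dt)
})

test_that("raising the move threshold never increases total move time", {
  set.seed(602)
  cfg <- quick_cfg(duration = 300, seed = 11)
  tr <- simulate_trajectory(cfg)
  mt_prev <- Inf
  for (thr in c(0.1, 0.3, 0.5, 0.8)) {
    lab <- classify_frames(tr, move_threshold = thr)
    mt <- sum(lab == "move")
    expect_lte(mt, mt_prev)
    mt_prev <- mt
  }
})

test_that("angular speed profile recovers constant and saturating laws", {
  dt <- 0.2
  # constant 10 deg/s for 10 s
  phi <- seq(0, by = 10 * pi / 180 * dt, length.out = 51)
  tr <- make_traj(phi)
  sq <- discretize_trajectory(tr)
  sq$bouts$censored_edge <- FALSE
  prof <- angular_speed_profile(sq, tr)
  expect_equal(prof$omega$omega, 10, tolerance = 1e-9)

  # saturating law omega(t) = 18 t / (3 + t): the printed constants give
  # omega(15) = 15 deg/s
  expect_equal(18 * 15 / (3 + 15), 15)
  # self-recovery from noisy synthetic moves
  set.seed(603)
  durs <- round(stats::runif(400, 1, 40) / dt) * dt
  om <- 18 * durs / (3 + durs) + stats::rnorm(400, 0, 0.5)
  states <- rep(c("move", "pause"), 400)[1:800]
  dirs <- vector("list", 800)
  phi_all <- list(0)
  cur <- 0
  k <- 1
  traj_phi <- c(0)
  for (i in seq_len(800)) {
    if (states[i] == "move") {
      d <- durs[(i + 1) / 2]
      n <- round(d / dt)
      step <- om[(i + 1) / 2] * pi / 180 * dt
      traj_phi <- c(traj_phi, traj_phi[length(traj_phi)] +
                      cumsum(rep(step, n)))
      dirs[[i]] <- rep(1L, n)
    } else {
      # single-frame pause with negligible angular step
      traj_phi <- c(traj_phi, traj_phi[length(traj_phi)] + 1e-5)
      dirs[[i]] <- 1L
    }
  }
  n_tr_per <- vapply(dirs, length, integer(1))
  sq2 <- make_bout_seq(states, dirs)
  tr2 <- make_traj(traj_phi)
  prof2 <- angular_speed_profile(sq2, tr2)
  expect_false(is.null(prof2$fit))
  expect_equal(unname(prof2$fit["a"]), 3, tolerance = 0.5)
  expect_equal(unname(prof2$fit["c"]), 18, tolerance = 1)
})
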