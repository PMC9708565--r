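test_that("arena geometry matches the task layout", {
  ar <- arena_spec()
  expect_equal(ar$width, 75)
  expect_equal(ar$height, 75)
  t1 <- ar$target_rects[["1"]]; t2 <- ar$target_rects[["2"]]
  expect_equal(mean(t1[c("ymin", "ymax")]), 34)   # near-target center distance
  expect_equal(mean(t2[c("ymin", "ymax")]), 52)   # far-target center distance
  expect_equal(unname(t1["xmax"] - t1["xmin"]), 18)
  expect_equal(unname(t1["ymax"] - t1["ymin"]), 14)
  expect_false(foragerl:::rects_overlap(t1, ar$collection_rect))
  expect_error(arena_spec(target_rects = list("1" = rect(30, 50, 60, 80))),
               class = "invalid_input")          # outside the arena
})

test_that("STF evaluation rewards target-rect entry and tracks the return", {
  ar <- arena_spec()
  # straight out through (0, 34) and back to the port
  y <- c(seq(0, 34, by = 0.5), seq(34, 0, by = -0.5))
  traj <- data.frame(t = seq_along(y) * 0.01, x = 0 * y, y = y)
  out <- evaluate_stf_trajectory(traj, ar, "1")
  expect_true(out$rewarded)
  expect_true(out$returned_home)
  expect_equal(out$intercept_time, traj$t[which(y >= 27)[1]])
  # same path misses the far target
  expect_false(evaluate_stf_trajectory(traj, ar, "2")$rewarded)

  # never leaves the collection area
  stay <- data.frame(t = 1:20 * 0.01, x = rep(0, 20), y = rep(5, 20))
  out2 <- evaluate_stf_trajectory(stay, ar, "1")
  expect_false(out2$rewarded)
  expect_true(out2$returned_home)

  # max radial extent 20 cm cannot reach either default target
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- data.frame(t = seq_along(th) * 0.01,
                     x = 20 * cos(th), y = abs(20 * sin(th)))
  expect_false(evaluate_stf_trajectory(circ, ar, "1")$rewarded)
  expect_false(evaluate_stf_trajectory(circ, ar, "2")$rewarded)

  expect_error(evaluate_stf_trajectory(traj[0, ], ar, "1"),
               class = "invalid_input")
  expect_error(evaluate_stf_trajectory(traj, ar, "9"), class = "key_error")
})

test_that("STF reward is monotone under dilation of the intersecting segment", {
  ar <- arena_spec()
  y <- seq(0, 30, by = 0.5)
  traj <- data.frame(t = seq_along(y) * 0.01, x = 0 * y, y = y)
  expect_true(evaluate_stf_trajectory(traj, ar, "1")$rewarded)
  # dilating the path (scaling up, still crossing the rect) keeps the reward
  for (f in c(1.1, 1.3, 1.36)) {
    tr2 <- traj; tr2$y <- tr2$y * f
    expect_true(evaluate_stf_trajectory(tr2, ar, "1")$rewarded)
  }
})

test_that("NTF evaluation enforces contiguous band occupancy and 1-s delay", {
  js <- joystick_spec()
  dt <- 0.01
  mk <- function(r) data.frame(t = seq_along(r) * dt - dt, x = r, y = 0 * r)
  # hold mid-band for 200 ms
  r <- c(seq(0, 5, by = 0.25), rep(5, 20), seq(5, 0, by = -0.25))
  out <- evaluate_ntf_trajectory(mk(r), js, "1")
  expect_true(out$rewarded)
  expect_equal(out$reward_time - out$intercept_time, 1.0)
  # a single 10-ms sample inside the band does not qualify
  r2 <- c(1, 2, 3, 5, 7, 8, 8, 8, 7, 3, 1, rep(0.5, 10))
  expect_false(evaluate_ntf_trajectory(mk(r2), js, "1")$rewarded)
  # never reaching the band
  r3 <- rep(2, 50)
  expect_false(evaluate_ntf_trajectory(mk(r3), js, "1")$rewarded)
  # occupancy below the sample interval is a configuration error
  js2 <- joystick_spec(occupancy_required = 0.001)
  expect_error(evaluate_ntf_trajectory(mk(r), js2, "1"),
               class = "configuration_error")
})

test_that("evaluation is deterministic and block schedules expose the switch", {
  ar <- arena_spec()
  y <- seq(0, 34, by = 0.5)
  traj <- data.frame(t = seq_along(y) * 0.01, x = 0 * y, y = y)
  o1 <- evaluate_stf_trajectory(traj, ar, "1")
  o2 <- evaluate_stf_trajectory(traj, ar, "1")
  expect_identical(o1, o2)
  sched <- block_schedule()
  expect_equal(attr(sched, "switch_index"), 81L)
  expect_equal(foragerl:::block_of_trial(sched, c(1, 80, 81, 160)),
               c(1L, 1L, 2L, 2L))
  expect_error(block_schedule("1", 0), class = "invalid_input")
})
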