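test_that("preprocessing reproduces cubics, removes spikes, keeps constants", {
  t <- seq(0, 5, by = 0.05)
  # cubic trajectory passes through untouched away from the edges
  x <- 2 + 0.5 * t - 0.3 * t^2 + 0.05 * t^3
  y <- 1 - 0.2 * t + 0.1 * t^2
  tr <- data.frame(t = t, x = x, y = y)
  out <- preprocess_trace(tr, jump_threshold = 10)
  core <- 6:(length(t) - 5)
  expect_equal(out$x[core], x[core], tolerance = 1e-10)
  expect_equal(out$y[core], y[core], tolerance = 1e-10)

  # one 50-cm single-frame spike is removed
  x2 <- x; x2[50] <- x[50] + 50
  out2 <- preprocess_trace(data.frame(t = t, x = x2, y = y),
                           jump_threshold = 10)
  expect_lt(abs(out2$x[50] - x[50]), 1)

  # constant trace is unchanged
  cst <- data.frame(t = t, x = rep(2, length(t)), y = rep(-1, length(t)))
  expect_equal(preprocess_trace(cst, 10), cst)

  expect_error(preprocess_trace(tr[1:5, ], 10), class = "invalid_input")
  many_bad <- tr
  many_bad$x[seq(2, 90, by = 3)] <- 1e4
  expect_error(preprocess_trace(many_bad, 10), class = "quality_error")
})

make_excursion_trace <- function(peaks, dt = 0.05, dur = 1.5, gap = 3) {
  # radial excursions along +y with rest at the port between them
  t <- c(); y <- c(); rew <- c()
  tcur <- 0
  for (p in peaks) {
    n_mv <- round(dur / dt); n_rest <- round(gap / dt)
    prof <- p * sin(seq(0, pi, length.out = n_mv))
    y <- c(y, prof, rep(0, n_rest))
    rew <- c(rew, rep(0, n_mv + n_rest))
    t <- c(t, tcur + seq_len(n_mv + n_rest) * dt)
    tcur <- tcur + (n_mv + n_rest) * dt
  }
  data.frame(t = t, x = 0 * y, y = y, reward_flag = rew, laser_flag = 0,
             block_id = 1)
}

test_that("attempt extraction applies amplitude and duration thresholds", {
  # stationary trace: no attempts
  still <- data.frame(t = 1:100 * 0.05, x = rnorm(100, 0, 0.1),
                      y = rnorm(100, 0, 0.1))
  expect_equal(nrow(extract_attempts(still)), 0)

  # two 12-cm, 1.5-s excursions separated by 3 s of rest: exactly 2
  tr <- make_excursion_trace(c(12, 12))
  at <- extract_attempts(tr)
  expect_equal(nrow(at), 2)
  expect_equal(at$max_amplitude, c(12, 12), tolerance = 0.2)

  # a 12-cm excursion lasting only 0.5 s is rejected
  short <- make_excursion_trace(12, dur = 0.5)
  expect_equal(nrow(extract_attempts(short)), 0)

  # a 9-cm excursion stays below the amplitude threshold
  low <- make_excursion_trace(9)
  expect_equal(nrow(extract_attempts(low)), 0)
})

test_that("attempt segmentation is idempotent on extracted segments", {
  tr <- make_excursion_trace(c(15, 20, 12))
  at <- extract_attempts(tr)
  for (k in seq_len(nrow(at))) {
    sub <- tr[at$start_idx[k]:at$stop_idx[k], ]
    at2 <- extract_attempts(sub)
    expect_equal(nrow(at2), 1)
    expect_equal(at2$stop_idx - at2$start_idx,
                 at$stop_idx[k] - at$start_idx[k])
  }
})

test_that("rewards map to attempts and performance is the rewarded fraction", {
  tr <- make_excursion_trace(c(15, 20, 12, 18))
  # put rewards inside attempts 1 and 3
  at0 <- extract_attempts(tr)
  tr$reward_flag[at0$start_idx[c(1, 3)] + 5] <- 1
  at <- extract_attempts(tr)
  expect_equal(at$rewarded, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(performance(at), 0.5)
  expect_error(performance(at[0, ]), class = "invalid_input")
})

test_that("conditional deltas recover hand-built means and degrade gracefully", {
  # amplitudes: +1 after unrewarded, 0 after rewarded, by construction
  amp <- c(10, 11, 11, 12, 12, 13, 13)
  rew <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  s <- data.frame(max_amplitude = amp, initial_heading = 0,
                  rewarded = rew, laser = FALSE)
  dt <- suppressWarnings(conditional_deltas(list(s)))
  expect_equal(unname(dt$condition_means_signed[["unrewarded"]]), 1)
  expect_equal(unname(dt$condition_means_signed[["rewarded"]]), 0)
  # all-identical amplitudes: all deltas zero, KW far from significant
  s2 <- data.frame(max_amplitude = rep(5, 30), initial_heading = 0,
                   rewarded = rep(c(TRUE, FALSE), 15),
                   laser = rep(c(FALSE, FALSE, TRUE), 10))
  sessions <- replicate(6, s2, simplify = FALSE)
  dt2 <- conditional_deltas(sessions)
  expect_true(all(unlist(dt2$condition_means) == 0))
  expect_gt(dt2$kruskal$p.value, 0.9)
})

test_that("default-policy reversion shows up in the conditional deltas", {
  ar <- arena_spec(); sh <- stf_shape()
  pol <- default_stf_policy()
  set.seed(21)
  sessions <- lapply(1:10, function(s) {
    mask <- which(runif(160) < 0.3)
    sim <- run_session(ar, block_schedule("1", 160), pol, sh,
                       pert = perturbation_spec("default_policy",
                                                trial_mask = mask),
                       seed = 600 + s)
    sim_attempts(sim)
  })
  dt <- conditional_deltas(sessions, statistic = "scaling")
  cm <- dt$condition_means
  # reversion: the policy moves more after rewarded+laser than after
  # plain rewarded trials
  expect_gt(cm[["rewarded_laser"]], cm[["rewarded"]])
  expect_lt(dt$kruskal$p.value, 0.05)
})

test_that("PETH bootstrap finds a deleted-movement window and not noise", {
  set.seed(41)
  # homogeneous movement process; catch trials have movements deleted in
  # a 1-3 s window after the event
  n_ev <- 40
  events <- seq(20, by = 20, length.out = n_ev)
  catch <- rep(FALSE, n_ev); catch[sample(n_ev, 12)] <- TRUE
  mt <- sort(runif(3000, 0, max(events) + 15))
  del <- logical(length(mt))
  for (e in events[catch]) del <- del | (mt > e + 1 & mt < e + 3)
  res <- peth_bootstrap(mt[!del], events, catch, n_boot = 300)
  expect_gt(nrow(res$significant_spans), 0)
  overlaps <- res$significant_spans[, "t_on"] < 3 &
    res$significant_spans[, "t_off"] > 1
  expect_true(any(overlaps))

  # identical labels on identical data: no spans
  res0 <- peth_bootstrap(mt, events, catch, n_boot = 300)
  expect_equal(nrow(res0$significant_spans), 0)
  expect_error(peth_bootstrap(mt, events, catch, n_boot = 50),
               class = "configuration_error")
  expect_error(peth_bootstrap(mt, events, rep(FALSE, n_ev)),
               class = "invalid_input")
})
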