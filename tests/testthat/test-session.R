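test_that("sessions are deterministic given the seed", {
  ar <- arena_spec(); sh <- stf_shape()
  pol <- default_stf_policy()
  s1 <- run_session(ar, block_schedule(c("1"), 20), pol, sh, seed = 77)
  s2 <- run_session(ar, block_schedule(c("1"), 20), pol, sh, seed = 77)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$policy_history, s2$policy_history)
  expect_error(run_session(ar, block_schedule(c("1"), 20)[0, ], pol, sh),
               class = "invalid_input")
})

test_that("with no learning the policy history is constant", {
  ar <- arena_spec(); sh <- stf_shape()
  pol <- default_stf_policy()
  sim <- run_session(ar, block_schedule(c("1"), 30), pol, sh,
                     mesh = mesh_params(alpha = 0, beta = 0), seed = 5)
  expect_true(all(sim$policy_history$A == pol$A))
  expect_true(all(sim$policy_history$Omega == pol$Omega))
  expect_equal(nrow(sim$policy_history), 31)
})

test_that("MeSH expectation properties: drift-free null, reward-driven growth", {
  # outcome-independent reward: E[A' - A] = 0 with beta = 0
  set.seed(31)
  mp <- mesh_params(alpha = 0.4, beta = 0, lambda = 0.3)
  drifts <- replicate(300, {
    p <- policy_state(A = 10, Omega = 0, A0 = 10, Omega0 = 0,
                      sigma_a = 2, sigma_omega = 0.1)
    for (i in 1:20) {
      p <- mesh_update(p, max(0, rnorm(1, p$A, 2)), 0, 0.7, mp)
    }
    p$A - 10
  })
  expect_gt(stats::t.test(drifts)$p.value, 0.01)

  # reward contingent on a_i above threshold: E[A] increases (sign test)
  set.seed(32)
  ups <- 0
  grew <- replicate(200, {
    p <- policy_state(A = 10, Omega = 0, A0 = 10, Omega0 = 0,
                      sigma_a = 2, sigma_omega = 0.1)
    u <- 0
    for (i in 1:40) {
      a <- max(0, rnorm(1, p$A, 2))
      u <- update_reward_rate(u, a > 11, 0.3)
      p <- mesh_update(p, a, 0, u, mp)
    }
    p$A > 10
  })
  expect_lt(stats::binom.test(sum(grew), 200,
                              alternative = "greater")$p.value, 1e-6)
})

test_that("switch to the far target drives amplitude up late in block 2", {
  ar <- arena_spec(); sh <- stf_shape()
  pol <- default_stf_policy()
  late_gain <- vapply(1:6, function(s) {
    sim <- run_session(ar, block_schedule(), pol, sh, seed = 400 + s)
    amp <- sim$trials$max_amplitude
    mean(amp[150:160]) - mean(amp[70:80])
  }, numeric(1))
  expect_lt(stats::t.test(late_gain, alternative = "greater")$p.value, 0.05)
})

test_that("NTF sessions freeze heading and respect the band rule", {
  js <- joystick_spec(); sh <- ntf_shape()
  pol <- default_ntf_policy(sh, js)
  sim <- run_session(js, block_schedule(c("1"), 30), pol, sh, seed = 6,
                     init_spec = initiation_spec(), init_window = 12)
  expect_true(all(sim$policy_history$Omega == pol$Omega))
  expect_gt(mean(sim$trials$rewarded), 0.3)
  expect_true(any(is.finite(sim$trials$initiation_latency)))
  # amplitudes concentrate around the band-1 center
  expect_equal(mean(sim$trials$max_amplitude), 5, tolerance = 0.25)
})

test_that("sim_attempts carries the per-trial policy scaling", {
  ar <- arena_spec(); sh <- stf_shape()
  sim <- run_session(ar, block_schedule(c("1"), 10), default_stf_policy(),
                     sh, seed = 3)
  at <- sim_attempts(sim)
  expect_equal(nrow(at), 10)
  expect_equal(at$scaling, sim$policy_history$A[1:10])
})

test_that("session outcomes agree with the standalone trajectory evaluators", {
  ar <- arena_spec(); sh <- stf_shape()
  sim <- run_session(ar, block_schedule(c("1", "2"), c(10, 10)),
                     default_stf_policy(), sh, seed = 42,
                     store_trajectories = TRUE)
  for (i in seq_len(20)) {
    out <- evaluate_stf_trajectory(sim$trajectories[[i]], ar,
                                   sim$trials$target[i])
    expect_identical(out$rewarded, sim$trials$rewarded[i])
    if (!is.na(out$intercept_time)) {
      expect_equal(out$intercept_time, sim$trials$intercept_time[i])
    }
  }
  js <- joystick_spec(); shn <- ntf_shape()
  simn <- run_session(js, block_schedule(c("1"), 15),
                      default_ntf_policy(shn, js), shn, seed = 9,
                      store_trajectories = TRUE)
  for (i in seq_len(15)) {
    out <- evaluate_ntf_trajectory(simn$trajectories[[i]], js,
                                   simn$trials$target[i])
    expect_identical(out$rewarded, simn$trials$rewarded[i])
  }
})
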