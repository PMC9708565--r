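test_that("switch-aligned summaries compute per-offset means and sems", {
  mk <- function(amp) data.frame(max_amplitude = rep(amp, 30))
  # single constant session: flat curve, sem 0
  c1 <- switch_aligned_summary(list(mk(10)), switch_index = 16,
                               window = c(5, 10))
  expect_true(all(c1$mean_amplitude == 10))
  expect_true(all(c1$sem == 0))
  # two sessions at 8 and 12: mean 10, sem = sd/sqrt(2) = 2
  c2 <- switch_aligned_summary(list(mk(8), mk(12)), 16, c(5, 10))
  expect_true(all(c2$mean_amplitude == 10))
  expect_true(all(abs(c2$sem - 2) < 1e-12))
  # window exceeding a session truncates with a warning
  expect_warning(switch_aligned_summary(list(mk(10)), 16, c(5, 20)),
                 regexp = "truncat")
})

test_that("simulated far-switch sessions yield a rising aligned curve", {
  ar <- arena_spec(); sh <- stf_shape()
  sessions <- lapply(1:8, function(s) {
    sim_attempts(run_session(ar, block_schedule(), default_stf_policy(), sh,
                             seed = 900 + s))
  })
  cur <- switch_aligned_summary(sessions, 81, c(10, 40))
  post <- cur[cur$trial_offset >= 0, ]
  ct <- stats::cor.test(post$trial_offset, post$mean_amplitude,
                        method = "spearman", exact = FALSE,
                        alternative = "greater")
  expect_lt(ct$p.value, 0.05)
})

test_that("a one-pair grid returns that pair; self-fit prefers the truth", {
  ar <- arena_spec(); sh <- stf_shape()
  sched <- block_schedule(c("1", "2"), c(40, 45))
  obs_sessions <- lapply(1:6, function(s) {
    sim_attempts(run_session(ar, sched, default_stf_policy(sh), sh,
                             mesh = mesh_params(alpha = 0.2),
                             seed = 50 + s))
  })
  observed <- switch_aligned_summary(obs_sessions, 41, c(10, 40))

  g1 <- fit_grid(alpha = 0.2, sigma_frac = 0.25)
  fit1 <- grid_search_fit(observed, ar, sched, shape = sh, grid = g1,
                          n_sims = 2, seed = 3)
  expect_equal(fit1$best$alpha, 0.2)
  expect_equal(nrow(fit1$grid), 1)

  # generating pair against a distant pair: truth scores better
  g2 <- fit_grid(alpha = c(0.05, 0.2), sigma_frac = c(0.05, 0.25))
  fit2 <- grid_search_fit(observed, ar, sched, shape = sh, grid = g2,
                          n_sims = 4, seed = 3)
  best <- fit2$best
  expect_true(best$alpha >= 0.2 || best$sigma_frac >= 0.25)
  expect_true(all(fit2$grid$loss >= 0))
})

test_that("loss is zero iff the curves are identical", {
  obs <- data.frame(trial_offset = -5:10,
                    mean_amplitude = rnorm(16, 30),
                    sem = 1, n_sessions = 5)
  class(obs) <- c("fl_switch_curve", "data.frame")
  err <- obs$mean_amplitude - obs$mean_amplitude
  expect_equal(mean(err^2), 0)
  expect_error(grid_search_fit(obs, arena_spec(), block_schedule(),
                               grid = fit_grid()[0, ]),
               class = "invalid_input")
})

test_that("recovered learning rate is unbiased to within one grid step", {
  ar <- arena_spec(); sh <- stf_shape()
  pol <- default_stf_policy(sh)
  sched <- block_schedule(c("1", "2"), c(40, 45))
  gen <- list(alpha = 0.4, sigma_frac = 0.2)
  best_alpha <- vapply(1:10, function(f) {
    obs <- lapply(1:10, function(s) {
      p <- pol; p$sigma_a <- gen$sigma_frac * p$A0
      sim_attempts(run_session(ar, sched, p, sh,
                               mesh = mesh_params(alpha = gen$alpha),
                               seed = f * 10000 + s))
    })
    observed <- switch_aligned_summary(obs, 41, c(10, 40))
    grid_search_fit(observed, ar, sched, shape = sh, grid = fit_grid(),
                    n_sims = 20, seed = f * 777)$best$alpha
  }, numeric(1))
  # one grid step up from 0.4 is 0.8: the mean recovered alpha must sit
  # closer to the truth than that
  expect_lt(abs(mean(best_alpha) - gen$alpha), 0.4)
})
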