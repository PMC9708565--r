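test_that("reward-rate smoothing follows the exponential recursion", {
  expect_equal(update_reward_rate(0.2, TRUE, 1), 1.0)
  expect_equal(update_reward_rate(0.5, FALSE, 0.3), 0.35)
  # constant reward stream converges geometrically at rate (1 - lambda)
  u <- 0
  gaps <- numeric(20)
  for (i in 1:20) { u <- update_reward_rate(u, TRUE, 0.3); gaps[i] <- 1 - u }
  expect_equal(gaps, 0.7^(1:20))
  expect_error(update_reward_rate(0.5, TRUE, 0), class = "invalid_input")
  expect_error(update_reward_rate(0.5, TRUE, 1.5), class = "invalid_input")
})

test_that("mesh_update substitution table holds exactly", {
  mk <- function(A, A0 = A) policy_state(A = A, Omega = 0, A0 = A0,
                                         Omega0 = 0, sigma_a = 1,
                                         sigma_omega = 0.1)
  # executed == policy == default: fixed point for any rates
  p <- mk(1.5)
  for (al in c(0, 0.3, 1)) for (be in c(0, 0.5)) {
    out <- mesh_update(p, 1.5, 0, 0.7, mesh_params(al, be))
    expect_identical(out$A, 1.5)
    expect_identical(out$Omega, 0)
  }
  # A=1, a=2, upsilon=1, alpha=0.5, beta=0 -> 1.5
  out <- mesh_update(mk(1), 2, 0, 1, mesh_params(0.5, 0))
  expect_identical(out$A, 1 + 0.5 * (2 - 1) * 1)
  # A=2, a=2, A0=1, upsilon=0, beta=0.1 -> 1.9 (pure homeostatic relaxation)
  out <- mesh_update(mk(2, A0 = 1), 2, 0, 0, mesh_params(0.5, 0.1))
  expect_identical(out$A, 2 - 0.1 * (2 - 1))
})

test_that("homeostasis relaxes expectations to A0 with factor (1 - beta)", {
  p <- policy_state(A = 5, Omega = 0, A0 = 2, Omega0 = 0,
                    sigma_a = 1, sigma_omega = 0.1)
  mp <- mesh_params(alpha = 0.4, beta = 0.1)
  # on expectations, a_i = A: the gap to A0 shrinks by exactly (1 - beta)
  gap <- numeric(100)
  for (i in 1:100) {
    p <- mesh_update(p, p$A, 0, 0, mp)
    gap[i] <- p$A - 2
  }
  expect_lt(max(abs(gap / (3 * 0.9^(1:100)) - 1)), 1e-9)
})

test_that("heading updates are circular across the +/-pi seam", {
  p <- policy_state(A = 1, Omega = pi, A0 = 1, Omega0 = pi,
                    sigma_a = 0.1, sigma_omega = 0.1)
  # executed heading just past the seam: a small signed step, no 2*pi jump
  out <- mesh_update(p, 1, -pi + 0.1, 1, mesh_params(0.5, 0))
  expect_equal(abs(circ_diff(out$Omega, pi)), 0.05, tolerance = 1e-12)
})

test_that("perturbation variants implement the update-table rows", {
  before <- policy_state(A = 2, Omega = 0.5, A0 = 1, Omega0 = 0,
                         sigma_a = 0.2, sigma_omega = 0.1)
  after <- before; after$A <- 2.05; after$Omega <- 0.52
  ctx <- list(a_i = 2.2, omega_i = 0.6, upsilon_prev = 0.5,
              mesh = mesh_params(0.5, 0.1, 0.3))

  # none and unmasked trials pass through
  expect_identical(
    apply_perturbation(before, after, perturbation_spec("none"), 3), after)
  sp <- perturbation_spec("default_policy", trial_mask = 5L)
  expect_identical(apply_perturbation(before, after, sp, 4), after)
  # default policy: parameters revert to the defaults
  out <- apply_perturbation(before, after, sp, 5)
  expect_identical(out$A, before$A0)
  expect_identical(out$Omega, before$Omega0)
  # learning bias: mu + 10 * dmu
  lb <- perturbation_spec("learning_bias", trial_mask = 5L)
  out <- apply_perturbation(before, after, lb, 5)
  expect_equal(out$A, 2 + 10 * 0.05)
  # reduced learning: mu + g * dmu, g in [0, 0.1]
  rl <- perturbation_spec("reduced_learning", trial_mask = 5L)
  out <- apply_perturbation(before, after, rl, 5)
  expect_equal(out$A, 2 + 0.05 * 0.05)
  expect_error(perturbation_spec("reduced_learning", gain = 0.5),
               class = "configuration_error")
  # reward not detected: recompute with the reward forced absent
  rnd <- perturbation_spec("reward_not_detected", trial_mask = 5L)
  out <- apply_perturbation(before, after, rnd, 5, context = ctx)
  manual <- mesh_update(before, ctx$a_i, ctx$omega_i,
                        update_reward_rate(0.5, FALSE, 0.3), ctx$mesh)
  expect_identical(out, manual)
  expect_error(perturbation_spec("no_such_variant"),
               class = "configuration_error")
})
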