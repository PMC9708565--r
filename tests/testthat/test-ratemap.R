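test_that("uniform occupancy and firing give a flat normalized map", {
  set.seed(3)
  tr <- synth_open_field_trace(900, 0.1, seed = 3)
  spk_frames <- seq_len(nrow(tr))               # one transient every frame
  rm <- compute_rate_map(spk_frames, tr)
  vals <- rm$rate[!is.na(rm$rate)]
  expect_gt(length(vals), 50)
  # count/occupancy is the frame rate everywhere, so the normalized map is 1
  expect_true(all(abs(vals - 1) < 1e-9))
})

test_that("a Gaussian place field is recovered near its true center", {
  tr <- synth_open_field_trace(600, 0.1, seed = 5)
  set.seed(6)
  ctr <- c(-12, 55)
  rate <- 8 * exp(-((tr$x - ctr[1])^2 + (tr$y - ctr[2])^2) / (2 * 36))
  spk <- which(rpois(nrow(tr), rate * 0.1) > 0)
  rm <- compute_rate_map(spk, tr)
  expect_lt(sqrt(sum((rm$peak_xy - ctr)^2)), 4 * sqrt(2))
})

test_that("visit and movement filters apply", {
  # a bin visited fewer than 5 times is masked
  tr <- synth_open_field_trace(300, 0.1, seed = 8)
  rm <- compute_rate_map(integer(0), tr, min_visits = 5)
  low <- rm$visits < 5
  expect_true(all(is.na(rm$rate[low])))
  # no movement periods at all is an error
  still <- data.frame(t = 1:100 * 0.1, x = rep(1, 100), y = rep(1, 100))
  expect_error(compute_rate_map(integer(0), still), class = "invalid_input")
})

test_that("reliability is 1 for identical trials and ~0 for noise", {
  seqs <- synth_trial_sequence(n_roi = 20, n_trials = 8, noise_sd = 0,
                               seed = 2)
  rel <- suppressWarnings(
    response_reliability(seqs$activity, seqs$trial_starts, seqs$trial_len,
                         frame_rate = 10))
  expect_true(all(abs(rel[!is.na(rel)] - 1) < 1e-10))

  set.seed(4)
  noise <- matrix(rnorm(20 * 1400), 20, 1400)
  rel0 <- response_reliability(noise, seqs$trial_starts, seqs$trial_len,
                               frame_rate = 10)
  expect_lt(abs(mean(rel0, na.rm = TRUE)), 0.1)
  expect_error(response_reliability(noise, seqs$trial_starts[1:3],
                                    seqs$trial_len, 10),
               class = "invalid_input")
})

test_that("movement-locked activity is more reliable than inter-trial noise", {
  set.seed(5)
  seqs <- synth_trial_sequence(n_roi = 30, n_trials = 10, trial_len = 40,
                               gap_len = 40, noise_sd = 0.3, seed = 5)
  # windows centered on the sequence vs windows in the silent gap
  rel_mv <- response_reliability(seqs$activity, seqs$trial_starts, 40, 10)
  rel_gap <- response_reliability(seqs$activity, seqs$trial_starts + 40, 40, 10)
  expect_lt(stats::t.test(rel_mv, rel_gap, alternative = "greater")$p.value,
            1e-6)
})

test_that("cross-validated sorting recovers the latency order", {
  seqs <- synth_trial_sequence(n_roi = 50, n_trials = 20, noise_sd = 0.1,
                               seed = 7)
  out <- pmth_sort(seqs$activity, seqs$trial_starts, seqs$trial_len,
                   mode = "crossval", seed = 1)
  rho <- stats::cor(seq_along(out$order), out$heldout_peak_latency,
                    method = "spearman")
  expect_gt(rho, 0.9)
  expect_identical(pmth_sort(seqs$activity[1, , drop = FALSE],
                             seqs$trial_starts, seqs$trial_len)$order, 1L)
})

test_that("hierarchical sorting falls back to latency order on ties", {
  seqs <- synth_trial_sequence(n_roi = 12, n_trials = 6, noise_sd = 0,
                               width = 1.5,
                               latencies = round(seq(16, 34, length.out = 12)),
                               seed = 9)
  out <- pmth_sort(seqs$activity, seqs$trial_starts, seqs$trial_len,
                   mode = "hierarchical")
  # tuning curves all have equal mean activity -> pure latency sort
  expect_equal(out$order, order(seqs$latencies))
})
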