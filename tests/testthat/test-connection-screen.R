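test_that("stimulus trains are equally spaced from zero", {
  tr <- build_stim_train()
  expect_equal(tr$spike_times_ms, c(0, 50, 100, 150, 200))
  expect_equal(build_stim_train(1, 35)$spike_times_ms, 0)
  expect_equal(build_stim_train(3, 10)$spike_times_ms, c(0, 100, 200))
  expect_error(build_stim_train(0, 20), "integer")
  expect_error(build_stim_train(5, 0), "positive")
})

test_that("synthesized sweeps hit the requested PSC amplitude exactly", {
  tr <- build_stim_train()
  # no connection, no noise: identically zero
  z <- synthesize_sweep(tr, connected = FALSE, noise_sd_pa = 0)
  expect_true(all(z$current_pa == 0))
  # connected, noiseless: first-spike trough is exactly -amplitude
  sw <- synthesize_sweep(tr, connected = TRUE, psc_amplitude_pa = 50,
                         noise_sd_pa = 0)
  w1 <- sw$current_pa[sw$time_ms >= 50 & sw$time_ms < 90]
  expect_equal(min(w1), -50)
  # determinism under seed
  a <- synthesize_sweep(tr, TRUE, noise_sd_pa = 5, seed = 11)
  b <- synthesize_sweep(tr, TRUE, noise_sd_pa = 5, seed = 11)
  expect_identical(a, b)
})

test_that("sweep averaging is a pointwise mean that shrinks noise like 1/sqrt(k)", {
  tr <- build_stim_train()
  sw <- synthesize_sweep(tr, TRUE, noise_sd_pa = 0)
  avg <- average_sweeps(list(sw, sw, sw))
  expect_equal(avg$current_pa, sw$current_pa)
  set.seed(202)
  k <- 9
  noise <- lapply(seq_len(k), function(i) {
    synthesize_sweep(tr, FALSE, noise_sd_pa = 5)
  })
  expect_equal(sd(average_sweeps(noise)$current_pa), 5 / sqrt(k),
               tolerance = 0.1)
  short <- synthesize_sweep(tr, FALSE, noise_sd_pa = 0, duration_ms = 400)
  expect_error(average_sweeps(list(sw, short)), "grids")
})

test_that("classification recovers noiseless connections and rejects nulls", {
  tr <- build_stim_train()
  res <- classify_connection(
    synthesize_sweep(tr, TRUE, psc_amplitude_pa = 50, noise_sd_pa = 0), tr
  )
  expect_true(res$connected)
  expect_equal(res$mean_evoked_amplitude_pa, 50, tolerance = 0.01)
  expect_equal(length(res$per_spike_amplitudes_pa), tr$n_spikes)
  expect_equal(res$per_spike_amplitudes_pa[1], 50)
  # amplitude exactly zero is never classified connected
  res0 <- classify_connection(
    synthesize_sweep(tr, TRUE, psc_amplitude_pa = 0, noise_sd_pa = 0), tr
  )
  expect_false(res0$connected)
  # seeded pure-noise sweep stays below the 3-SD threshold
  noise <- average_sweeps(lapply(1:3, function(i) {
    synthesize_sweep(tr, FALSE, noise_sd_pa = 5, seed = 300 + i)
  }))
  expect_false(classify_connection(noise, tr)$connected)
})

test_that("classification is invariant to sweep order", {
  tr <- build_stim_train()
  sweeps <- lapply(1:3, function(i) {
    synthesize_sweep(tr, TRUE, noise_sd_pa = 5, seed = 40 + i)
  })
  r1 <- classify_connection(average_sweeps(sweeps), tr)
  r2 <- classify_connection(average_sweeps(rev(sweeps)), tr)
  expect_equal(r1$mean_evoked_amplitude_pa, r2$mean_evoked_amplitude_pa)
  expect_identical(r1$connected, r2$connected)
})

test_that("false-positive rate under pure noise is below 5% per direction", {
  tr <- build_stim_train()
  set.seed(77)
  fp <- vapply(1:200, function(i) {
    sweeps <- lapply(1:3, function(j) {
      synthesize_sweep(tr, FALSE, noise_sd_pa = 5)
    })
    classify_connection(average_sweeps(sweeps), tr)$connected
  }, logical(1))
  expect_lt(mean(fp), 0.05)
})

test_that("screen_pair tests both directions independently", {
  one_way <- screen_pair(1, 2, connected_ab = TRUE, connected_ba = FALSE,
                         noise_sd_pa = 0)
  expect_equal(one_way$connected, c(TRUE, FALSE))
  expect_equal(one_way$pre, c(1, 2))
  neither <- screen_pair(3, 4, FALSE, FALSE, noise_sd_pa = 0)
  expect_equal(neither$connected, c(FALSE, FALSE))
  # a direction interrupted by QC failure is untested, not classified
  qc <- screen_pair(5, 6, TRUE, TRUE, untested_ba = TRUE, noise_sd_pa = 0)
  expect_true(qc$tested[1] && !qc$tested[2])
  expect_true(is.na(qc$connected[2]))
})

test_that("end-to-end classification matches ground truth at moderate noise", {
  set.seed(99)
  truth_ab <- runif(25) < 0.3
  truth_ba <- runif(25) < 0.3
  for (i in seq_len(25)) {
    res <- screen_pair(1, 2, truth_ab[i], truth_ba[i],
                       noise_sd_pa = 5, seed = 500 + i)
    expect_equal(res$connected, c(truth_ab[i], truth_ba[i]))
  }
})
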