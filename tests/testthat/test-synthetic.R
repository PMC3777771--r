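test_that("oscillator specs are validated against the analysis bands", {
  expect_error(oscillator_spec(band = c(9, 11)), "inside one of the six")
  expect_error(oscillator_spec(coupling = 1.2), "coupling")
  expect_error(oscillator_spec(noise_sd = -1), "noise_sd")
  expect_silent(oscillator_spec(band = c(14, 25)))
})

test_that("full coupling without noise gives exact phase locking", {
  spec <- oscillator_spec(band = c(8, 10), lag = pi / 2, coupling = 1,
                          noise_sd = 0)
  ts <- generate_coupled_pair(spec, 4096, 312.5, seed = 2)
  pa <- instantaneous_phase(ts$data[1, ])
  pb <- instantaneous_phase(ts$data[2, ])
  d <- pa - pb
  d <- atan2(sin(d), cos(d))
  expect_equal(max(abs(d - pi / 2)), 0, tolerance = 1e-6)
  expect_equal(pli_pair(pa, pb), 1)
  expect_error(generate_coupled_pair(spec, 4096, rate = 18), "too low")
  expect_error(generate_coupled_pair(spec, 0, 312.5), "positive")
})

test_that("uncoupled pairs sit at the finite-sample null floor", {
  # frozen Monte-Carlo oracle (300 reps, same geometry): mean 0.1382,
  # sd 0.0991, 95th percentile 0.3145
  spec <- oscillator_spec(band = c(8, 10), lag = 0, coupling = 0, noise_sd = 1)
  vals <- vapply(1:20, function(s) pipeline_pair_pli(spec, 4096, 312.5, s),
                 numeric(1))
  tol <- 1.96 * 0.0991 * sqrt(1 / 300 + 1 / 20)
  expect_lt(abs(mean(vals) - 0.1382), tol)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("moderate coupling reproduces the Monte-Carlo oracle interval", {
  # frozen oracle for coupling 0.6, lag pi/4, noise 1, n = 4096 @ 312.5 Hz:
  # mean 0.4711, sd 0.1325 over 300 replicates
  spec <- oscillator_spec(band = c(8, 10), lag = pi / 4, coupling = 0.6,
                          noise_sd = 1)
  vals <- vapply(1:25, function(s) pipeline_pair_pli(spec, 4096, 312.5, s),
                 numeric(1))
  tol <- 1.96 * 0.1325 * sqrt(1 / 300 + 1 / 25)
  expect_lt(abs(mean(vals) - 0.4711), tol)
})

test_that("zero-lag mixing: identity is exact, dimensions are checked", {
  spec <- oscillator_spec(band = c(8, 10), lag = pi / 4, coupling = 0.6)
  ts <- generate_coupled_pair(spec, 2048, 312.5, seed = 4)
  expect_identical(apply_mixing(ts, diag(2))$data, ts$data)
  expect_error(apply_mixing(ts, diag(3)), "2 x 2")
})

test_that("mild symmetric mixing leaves a coupled pair's PLI unchanged", {
  # zero-lag mixing scales Im(z_a conj(z_b)) by (1 - eps^2) > 0, so every
  # sign(sin dphi) sample is preserved
  spec <- oscillator_spec(band = c(8, 10), lag = pi / 4, coupling = 0.6,
                          noise_sd = 1)
  M <- matrix(c(1, 0.2, 0.2, 1), 2)
  for (s in 1:5) {
    ts <- generate_coupled_pair(spec, 4096, 312.5, seed = 100 + s)
    mixed <- apply_mixing(ts, M)
    p0 <- pli_matrix(preprocess_recording(ts, c(8, 10), n_epochs = 1,
                                          epoch_length = 4096))$values[1, 2]
    p1 <- pli_matrix(preprocess_recording(mixed, c(8, 10), n_epochs = 1,
                                          epoch_length = 4096))$values[1, 2]
    expect_equal(p1, p0, tolerance = 0.02)
  }
})

test_that("mixing independent sources does not create PLI", {
  # unmixed independent-pair null (frozen oracle): mean 0.1382, sd 0.0991
  spec <- oscillator_spec(band = c(8, 10), lag = 0, coupling = 0, noise_sd = 1)
  M <- matrix(c(1, 0.5, 0.5, 1), 2)
  vals <- vapply(1:20, function(s) {
    ts <- apply_mixing(generate_coupled_pair(spec, 4096, 312.5, seed = 200 + s), M)
    pli_matrix(preprocess_recording(ts, c(8, 10), n_epochs = 1,
                                    epoch_length = 4096))$values[1, 2]
  }, numeric(1))
  tol <- 1.96 * 0.0991 * sqrt(1 / 300 + 1 / 20)
  expect_lt(mean(vals), 0.1382 + tol)
})

test_that("cohorts are seed-deterministic, byte for byte", {
  atlas <- dmn_atlas()
  spec <- cohort_spec(n_subjects = 3, effect_networks = "DMN", seed = 42,
                      n_epochs = 1, epoch_length = 1024)
  a <- generate_cohort(spec, atlas)
  b <- generate_cohort(spec, atlas)
  for (i in seq_len(nrow(a$recordings))) {
    expect_identical(a$recordings$ts[[i]]$data, b$recordings$ts[[i]]$data)
  }
  expect_identical(a$cognition, b$cognition)
  expect_identical(a$truth, b$truth)
})

test_that("cohort structure matches its specification", {
  atlas <- mini_atlas()
  spec <- cohort_spec(n_subjects = 3, effect_networks = "DMN",
                      effect_size = 0.08, seed = 9,
                      n_epochs = 1, epoch_length = 1024)
  coh <- generate_cohort(spec, atlas)
  expect_s3_class(coh, "meg_cohort")
  expect_equal(nrow(coh$recordings), 6)
  expect_equal(dim(coh$recordings$ts[[1]]$data), c(20, 1024))
  expect_setequal(unique(coh$cognition$domain), cognitive_domains())
  # truth: only the affected network carries nonzero injected change
  expect_true(all(coh$truth$delta_true[coh$truth$network != "DMN"] == 0))
  expect_true(all(coh$truth$delta_true[coh$truth$network == "DMN"] > 0))
  # linked domain rides on the true change; cognition deltas consistent
  expect_equal(coh$cognition$z_t2 - coh$cognition$z_t1, coh$cognition$delta)
  expect_error(generate_cohort(cohort_spec(effect_networks = "nope"), atlas),
               "unknown effect network")
})

test_that("a null cohort spec injects nothing", {
  atlas <- dmn_atlas()
  spec <- cohort_spec(n_subjects = 3, effect_size = 0, cognition_link = NULL,
                      seed = 5, n_epochs = 1, epoch_length = 1024)
  coh <- generate_cohort(spec, atlas)
  expect_true(all(coh$truth$delta_true == 0))
})

test_that("voxel expansion is collapsible by representative selection", {
  atlas <- dmn_atlas()
  spec <- cohort_spec(n_subjects = 2, seed = 3, n_epochs = 1,
                      epoch_length = 1024, voxels_per_roi = 3)
  coh <- generate_cohort(spec, atlas)
  ts <- coh$recordings$ts[[1]]
  expect_equal(nrow(ts$data), 18)
  expect_equal(ts$roi[1:3], rep(atlas$registry[1], 3))
  sel <- select_representative_voxel(ts, "lower_alpha")
  expect_equal(length(sel$ts$labels), 6)
  # the scale-1.0 copy (voxel 1) always wins the pseudo-Z ranking
  expect_true(all(sel$selected$voxel == 1))
})

test_that("cohort containers round-trip through delimited text", {
  atlas <- dmn_atlas()
  spec <- cohort_spec(n_subjects = 2, seed = 8, n_epochs = 1,
                      epoch_length = 256)
  coh <- generate_cohort(spec, atlas)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$recordings), 4)
  expect_equal(back$recordings$ts[[2]]$data, coh$recordings$ts[[2]]$data,
               tolerance = 1e-12)
  expect_equal(back$recordings$ts[[2]]$labels, coh$recordings$ts[[2]]$labels)
  expect_equal(back$cognition$delta, coh$cognition$delta, tolerance = 1e-12)
})

test_that("cohort specs load from YAML key-value files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 6", "effect_networks: [DMN]",
               "effect_size: 0.07", "seed: 11",
               "cognition_link:", "  verbal_memory: 20"), path)
  spec <- read_cohort_spec(path)
  expect_equal(spec$n_subjects, 6)
  expect_equal(spec$effect_size, 0.07)
  expect_equal(spec$cognition_link, c(verbal_memory = 20))
  writeLines("banana: 1", path)
  expect_error(read_cohort_spec(path), "unknown cohort spec key")
})

test_that("the calibrated coupling map inverts cleanly", {
  for (m in c(4, 6, 16)) {
    f0 <- network_pli_from_coupling(0, m)
    f1 <- network_pli_from_coupling(1, m)
    expect_lt(f0, 0.2)
    expect_gt(f1, 0.8)
    tgt <- 0.3
    cc <- coupling_for_network_pli(tgt, m)
    expect_equal(network_pli_from_coupling(cc, m), tgt, tolerance = 1e-4)
  }
  expect_equal(coupling_for_network_pli(0.01, 6), 0)  # below the null floor
  expect_equal(coupling_for_network_pli(0.999, 6), 1)
})
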