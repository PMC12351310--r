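test_that("stimulus generation hits its acoustic targets and is reproducible", {
  s1 <- generate_stimulus(stimulus_spec("coo", seed = 3))
  s2 <- generate_stimulus(stimulus_spec("coo", seed = 3))
  expect_identical(s1$wave, s2$wave)
  expect_false(identical(
    s1$wave, generate_stimulus(stimulus_spec("coo", seed = 4))$wave))

  st <- generate_stimulus(stimulus_spec("coo", duration_s = 0.5,
                                        sample_rate = 24000, seed = 1))
  expect_length(st$wave, 12000L)

  f <- extract_features(generate_stimulus(stimulus_spec("coo", duration_s = 1,
                                                        seed = 11)))
  expect_lt(abs(f$f0_mean - 581) / 581, 0.05)
  expect_gt(f$hnr, 0.6)

  expect_error(stimulus_spec("speech"), "valid categories")
})

test_that("category recipes produce the intended contrasts", {
  feats <- lapply(sound_categories(), function(cat)
    extract_features(generate_stimulus(stimulus_spec(cat, duration_s = 1,
                                                     seed = 21))))
  names(feats) <- sound_categories()
  # coos most periodic, screams highest centroid, aggressive/nature noisy
  hnrs <- vapply(feats, `[[`, numeric(1), "hnr")
  expect_equal(names(which.max(hnrs)), "coo")
  cents <- vapply(feats, `[[`, numeric(1), "centroid_khz")
  expect_equal(names(which.max(cents)), "scream")
  expect_lt(feats$aggressive$hnr, feats$coo$hnr)
  expect_lt(feats$nature$hnr, feats$coo$hnr)
})

test_that("run designs count blocks and events correctly", {
  ds <- generate_run_design(2, seed = 5)
  d <- ds[[1]]
  sound <- d$blocks[d$blocks$condition != "silence", ]
  expect_equal(nrow(sound), 20L)
  expect_equal(sum(d$blocks$condition == "silence"), 20L)
  expect_true(all(lengths(d$events) == 42L))
  expect_equal(unname(table(sound$condition)["coo"]), 2L)
  # blocks contiguous and non-overlapping
  expect_equal(d$blocks$onset_s[-1],
               head(d$blocks$onset_s + d$blocks$duration_s, -1))
  # event count formula for other parameterizations
  d2 <- generate_run_design(1, block_s = 10, soa_ms = 300, seed = 1)[[1]]
  expect_true(all(lengths(d2$events) == floor(10 / 0.3)))
})

test_that("Latin-square counterbalancing fills every serial position", {
  ds <- generate_run_design(10, seed = 2)
  for (cond in c("coo", "scrambled_nature")) {
    pos <- unlist(lapply(ds, function(d)
      d$blocks$serial_pos[d$blocks$condition == cond]))
    expect_equal(as.vector(table(factor(pos, levels = 1:10))), rep(2L, 10))
  }
})

test_that("time-series forward model honors its null and noise structure", {
  ds <- generate_run_design(1, seed = 3)[[1]]
  hrf <- mion_hrf(3)
  conds <- ds$condition_labels
  tr0 <- ground_truth(matrix(0, 4, 10, dimnames = list(NULL, conds)),
                      noise_sd = 0)
  sim <- simulate_roi_timeseries(ds, tr0, hrf, seed = 1, drift_amp = 0)
  expect_equal(max(abs(sim$Y - 100)), 0, tolerance = 1e-12)

  expect_error(simulate_roi_timeseries(ds, tr0, rep(0.1, ds$n_vols + 5)),
               "longer than the run")

  # injected shared components recoverable from task-free voxels by PCA
  trS <- ground_truth(matrix(0, 30, 10, dimnames = list(NULL, conds)),
                      noise_sd = 0.05, shared_noise_rank = 3,
                      shared_noise_amp = 2)
  simS <- simulate_roi_timeseries(ds, trS, hrf, seed = 9, drift_amp = 0)
  pcs <- stats::prcomp(simS$Y, center = TRUE)$x[, 1:3]
  r2 <- vapply(seq_len(3), function(j) {
    summary(stats::lm(simS$shared_components[, j] ~ pcs))$r.squared
  }, numeric(1))
  expect_true(all(r2 >= 0.9))

  # MION polarity flips the task component only
  tr1 <- ground_truth(matrix(2, 1, 10, dimnames = list(NULL, conds)),
                      noise_sd = 0)
  sp <- simulate_roi_timeseries(ds, tr1, hrf, seed = 2, drift_amp = 0)
  sn <- simulate_roi_timeseries(ds, tr1, hrf, seed = 2, drift_amp = 0,
                                mion_sign_flip = TRUE)
  expect_equal(sp$Y - 100, -(sn$Y - 100), tolerance = 1e-10)
})

test_that("beta patterns converge to category means and validate input", {
  conds <- sound_categories()
  tr <- make_category_truth(8, conds, "distinct", effect_size = 1,
                            noise_sd = 1, seed = 3)
  pat <- simulate_beta_patterns(8, 200, conds, tr, seed = 4)
  emp <- apply(pat$values, c(1, 2), mean)
  sem <- 1 / sqrt(200)
  expect_true(all(abs(emp - tr$category_means) < 3 * sem + 1e-12))

  expect_error(simulate_beta_patterns(8, 2, conds, tr, seed = 1), "4 runs")
  expect_error(beta_pattern(array(0, c(3, 1, 4)), "a", 1:4), "2 conditions")
  tr2 <- make_category_truth(8, conds, "dissociation", seed = 5)
  expect_equal(tr2$category_means[, "animal"], tr2$category_means[, "nature"])
})

test_that("beta patterns round-trip through the long-format table", {
  pat <- quick_pattern(seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_pattern(pat, path)
  back <- read_beta_pattern(path)
  expect_equal(back$values, pat$values, tolerance = 1e-12)
  expect_equal(back$condition_labels, pat$condition_labels)
})

test_that("waveforms round-trip through WAV in both encodings", {
  w <- sin(2 * pi * 440 * (0:4799) / 24000) * 0.7
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, p16, 24000, bits = 16L)
  r16 <- read_wav(p16)
  expect_equal(r16$sample_rate, 24000)
  expect_equal(r16$wave, w, tolerance = 1e-4)
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, p32, 24000, bits = 32L)
  expect_equal(read_wav(p32)$wave, w, tolerance = 1e-7)
})
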