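test_that("MION kernel is unit-sum, slow, and saturates within a block", {
  h <- mion_hrf(0.5)
  expect_equal(sum(h), 1.0, tolerance = 1e-9)
  peak_t <- (which.max(h) - 1) * 0.5
  expect_gte(peak_t, 3); expect_lte(peak_t, 5)
  expect_lt(h[round(30 / 0.5) + 1], 0.1 * max(h))
  box <- c(rep(1, 42), rep(0, 38))
  cv <- stats::convolve(box, rev(h), type = "open")[1:80]
  expect_gte(cv[42] / max(cv), 0.95)
  expect_error(mion_hrf(3, shape = -1), "positive")
})

test_that("design matrices have the advertised structure", {
  d <- generate_run_design(1, seed = 4)[[1]]
  hrf <- mion_hrf(3)
  nuis <- matrix(rnorm(d$n_vols * 6), ncol = 6)
  dm <- build_design_matrix(d, hrf, drift_order = 2, nuisance = nuis)
  expect_equal(ncol(dm$X), 10 + 3 + 6)
  expect_equal(sum(dm$dummy_mask), d$n_dummies)
  # regressor peak ~ block offset + kernel peak
  blk <- d$blocks[d$blocks$condition == "coo", ][1, ]
  reg <- dm$X[, "coo"]
  reg[d$blocks$onset_s[d$blocks$condition == "coo"][2] / d$tr_s + seq_len(12)] <- 0
  t_peak <- (which.max(reg) - 1) * d$tr_s
  expected <- blk$onset_s + blk$duration_s
  expect_lte(abs(t_peak - expected), d$tr_s + 3) # slow kernel: plateau near offset
})

test_that("OLS fits match the normal-equations oracle and are exact when noiseless", {
  set.seed(12)
  X <- cbind(1, matrix(rnorm(60 * 4), 60, 4))
  colnames(X) <- c("b0", paste0("x", 1:4))
  B <- matrix(rnorm(5 * 7), 5, 7)
  Y <- X %*% B
  fit <- fit_glm(Y, X)
  expect_lt(max(abs(fit$betas - B)), 1e-8)
  Yn <- Y + matrix(rnorm(60 * 7), 60, 7)
  fitn <- fit_glm(Yn, X)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Yn
  expect_lt(max(abs(fitn$betas - oracle)), 1e-10)

  Xr <- cbind(X, X[, 2] + X[, 3])
  colnames(Xr)[6] <- "dup"
  expect_error(fit_glm(Yn, Xr), "collinear.*dup")
  expect_error(fit_glm(Yn[1:4, ], X[1:4, ]), "more regressors")
})

test_that("contrast t-statistics control type-I error under the null", {
  set.seed(77)
  X <- cbind(1, scale(matrix(rnorm(40 * 2), 40, 2)))
  colnames(X) <- c("b0", "a", "b")
  rej <- mean(replicate(200, {
    fit <- fit_glm(matrix(rnorm(40 * 5), 40, 5), X)
    ct <- contrast_t(fit, c(a = 1))
    any_p <- 2 * stats::pt(abs(ct$t), ct$df, lower.tail = FALSE)
    mean(any_p < 0.05)
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("vocalization contrasts average the vocal regressors", {
  w <- vocalization_contrast(sound_categories())
  expect_equal(sum(w), 1)
  expect_setequal(names(w), vocal_categories())
  w2 <- vocalization_contrast(sound_categories(), versus = "nonvocal")
  expect_equal(sum(w2), 0)
})

test_that("percent signal change is zero at baseline and recovers injections", {
  ds <- generate_run_design(6, seed = 8)
  hrf <- mion_hrf(3)
  conds <- ds[[1]]$condition_labels
  tr0 <- ground_truth(matrix(0, 1, 10, dimnames = list(NULL, conds)),
                      noise_sd = 0)
  sims0 <- lapply(ds, function(d)
    simulate_roi_timeseries(d, tr0, hrf, seed = d$run_id, drift_amp = 0))
  psc0 <- percent_signal_change(lapply(sims0, `[[`, "Y"), ds, hrf)
  expect_lt(max(abs(psc0$psc)), 1e-9)
  expect_equal(psc0$psc[psc0$condition == "silence"], 0)

  # raw MION polarity: activation decreases signal; flip restores positives
  tr1 <- ground_truth(matrix(1, 1, 10, dimnames = list(NULL, conds)),
                      noise_sd = 0.3)
  simsM <- lapply(ds, function(d)
    simulate_roi_timeseries(d, tr1, hrf, seed = 50 + d$run_id,
                            mion_sign_flip = TRUE))
  pscM <- percent_signal_change(lapply(simsM, `[[`, "Y"), ds, hrf,
                                mion_sign_flip = TRUE)
  expect_true(all(pscM$psc[pscM$condition != "silence"] > 0.5))
})

test_that("PSC standard errors shrink as one over the square root of runs", {
  hrf <- mion_hrf(3)
  ratios <- sapply(1:6, function(s) {
    ds40 <- generate_run_design(40, seed = 100 + s)
    conds <- ds40[[1]]$condition_labels
    tr <- ground_truth(matrix(1, 1, 10, dimnames = list(NULL, conds)),
                       noise_sd = 2)
    sims <- lapply(ds40, function(d)
      simulate_roi_timeseries(d, tr, hrf, seed = 7000 * s + d$run_id))
    p40 <- percent_signal_change(lapply(sims, `[[`, "Y"), ds40, hrf)
    p10 <- percent_signal_change(lapply(sims[1:10], `[[`, "Y"), ds40[1:10], hrf)
    mean(p10$sem[1:10]) / mean(p40$sem[1:10])
  })
  expect_equal(mean(ratios), 2.0, tolerance = 0.3)
})

test_that("FIR deconvolution recovers the forward response shape", {
  ds <- generate_run_design(4, seed = 21)
  hrf <- mion_hrf(3)
  conds <- ds[[1]]$condition_labels
  tr <- ground_truth(matrix(1, 1, 10, dimnames = list(NULL, conds)),
                     noise_sd = 0.05)
  sims <- lapply(ds, function(d)
    simulate_roi_timeseries(d, tr, hrf, seed = 500 + d$run_id))
  fir <- fir_timecourse(lapply(sims, `[[`, "Y"), ds, smooth = FALSE)
  expect_equal(nrow(fir$timecourse), 12L) # (21 + 15) / 3 lags
  # forward model: block boxcar (7 TRs) convolved with the kernel,
  # referenced like the estimator to the trailing silence lags
  box <- rep(c(1, 0), c(7, 5))
  fwd <- stats::convolve(box, rev(hrf), type = "open")[1:12]
  fwd <- fwd - mean(fwd[10:12])
  for (cc in c("coo", "nature")) {
    expect_gte(cor(fir$timecourse[, cc], fwd), 0.95)
    expect_equal(fir$timecourse[, cc], fwd, tolerance = 0.25)
  }
})

test_that("3-point smoothing averages with zero padding at the edges", {
  expect_equal(vocfmri:::smooth3(c(0, 3, 0)), c(1, 1, 1))
  expect_equal(vocfmri:::smooth3(c(3, 3, 3)), c(2, 3, 2))
})
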