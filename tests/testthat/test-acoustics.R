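test_that("gammatone spectrogram shows tuning, silence, and noise spread", {
  sp <- gammatone_spectrogram(pure_tone(1000)$wave, 16000)
  ch <- which.max(rowMeans(sp$envelope))
  expect_equal(ch, which.min(abs(sp$center_freqs - 1000)))
  expect_true(all(diff(sp$center_freqs) > 0))

  sil <- gammatone_spectrogram(numeric(8000), 16000)
  expect_lt(max(sil$envelope), 1e-10)

  wn <- seeded_noise(seed = 4)
  spn <- gammatone_spectrogram(wn$wave, wn$sample_rate)
  lev <- 20 * log10(rowMeans(spn$envelope) + 1e-20)
  expect_gte(mean(lev > max(lev) - 20), 0.8)

  expect_error(gammatone_spectrogram(rnorm(100), 16000, fmax_hz = 9000),
               "Nyquist")
})

test_that("modulation power spectrum localizes temporal modulations", {
  am <- am_tone(10)
  m <- compute_mps(gammatone_spectrogram(am$wave, am$sample_rate),
                   demean = "channel")
  marg <- 10 * log10(colSums(10^(m$power_db / 10)))
  peaks <- m$rate_hz[order(marg, decreasing = TRUE)[1:2]]
  expect_equal(sort(peaks), c(-10, 10), tolerance = 0.06)
  expect_equal(max(m$power_db), 0)

  wn <- seeded_noise(seed = 6)
  mn <- compute_mps(gammatone_spectrogram(wn$wave, wn$sample_rate))
  margn <- colSums(10^(mn$power_db / 10))
  expect_equal(mn$rate_hz[which.max(margn)], 0)

  # gain invariance
  sp1 <- gammatone_spectrogram(am$wave, am$sample_rate)
  sp2 <- gammatone_spectrogram(am$wave * 0.1, am$sample_rate)
  expect_equal(compute_mps(sp1)$power_db, compute_mps(sp2)$power_db,
               tolerance = 1e-6)

  small <- gammatone_spectrogram(rnorm(600), 16000, n_channels = 8)
  expect_error(compute_mps(small), "at least 16")
})

test_that("MPS averaging is linear in power and idempotent", {
  wn <- seeded_noise(seed = 7)
  m <- compute_mps(gammatone_spectrogram(wn$wave, wn$sample_rate))
  expect_equal(average_mps(list(m))$power_db, m$power_db)
  expect_equal(average_mps(list(m, m))$power_db, m$power_db, tolerance = 1e-9)

  # two maps sharing a 0 dB region, each with its own disjoint peak:
  # averaged, the disjoint peaks sit at -3.01 dB re the shared region
  base <- m
  mk <- function(hot) {
    p <- matrix(-300, nrow(m$power_db), ncol(m$power_db))
    p[1, 1] <- 0 # shared peak region
    p[hot[1], hot[2]] <- 0
    list(power_db = p, rate_hz = m$rate_hz,
         scale_cyc_per_khz = m$scale_cyc_per_khz, reference_peak_db = 0)
  }
  avg <- average_mps(list(mk(c(5, 5)), mk(c(9, 9))))
  expect_equal(avg$power_db[1, 1], 0)
  expect_equal(avg$power_db[5, 5], 10 * log10(0.5), tolerance = 1e-6)
  expect_equal(avg$power_db[9, 9], 10 * log10(0.5), tolerance = 1e-6)

  m2 <- compute_mps(gammatone_spectrogram(wn$wave, wn$sample_rate, hop_ms = 4))
  expect_error(average_mps(list(m, m2)), "axes")
})

test_that("feature extraction matches first-principles expectations", {
  tone <- pure_tone(500)
  f <- extract_features(tone)
  expect_lt(abs(f$f0_mean - 500) / 500, 0.01)
  expect_gte(f$hnr, 0.95)

  f2k <- extract_features(pure_tone(2000))
  expect_equal(f2k$centroid_khz, 2.0, tolerance = 0.05)

  wn <- seeded_noise(seed = 9)
  fn <- extract_features(wn)
  harm <- make_stimulus(rowSums(sapply(1:3, function(h)
    sin(2 * pi * 300 * h * (0:15999) / 16000) / h)) / 3, 16000)
  fh <- extract_features(harm)
  expect_lte(fn$hnr, 0.3)
  expect_lt(fn$pscv, fh$pscv)

  # amplitude scaling moves rms_db by exactly 20 log10(gain), nothing else
  g <- 0.25
  fg <- extract_features(make_stimulus(tone$wave * g, tone$sample_rate))
  expect_equal(fg$rms_db - f$rms_db, 20 * log10(g), tolerance = 1e-8)
  expect_equal(fg$centroid_khz, f$centroid_khz, tolerance = 1e-8)
  expect_equal(fg$f0_mean, f$f0_mean, tolerance = 1e-8)

  expect_error(extract_features(make_stimulus(rnorm(100), 16000)), "50 ms")
})

test_that("category aggregation reproduces the published group means", {
  tab <- load_category_features()
  expect_equal(dim(tab), c(5L, 9L))
  expect_equal(tab$hnr[tab$category == "coo"], 0.83)
  expect_equal(tab$centroid_khz[tab$category == "scream"], 5.01)

  agg <- aggregate_category_features(tab)
  expect_equal(round(agg$group_means["nonvocal", "pssd"], 1), 20.8)
  expect_equal(round(agg$group_means["vocal", "pssd"], 2), 15.56)
  expect_equal(round(agg$group_means["nonvocal", "pscv"], 1), 2.7)

  expect_error(aggregate_category_features(tab, rep("bird", 5)),
               "unknown category")
})

test_that("correlation-distance RDMs agree with a double-loop oracle", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  d <- compute_rdm(m)
  expect_equal(d$matrix["a", "b"], 0)
  expect_equal(d$matrix["a", "c"], 2)

  set.seed(31)
  v <- matrix(rnorm(30), 5, 6, dimnames = list(letters[1:5], NULL))
  d5 <- compute_rdm(v)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) oracle[i, j] <- 1 - cor(v[i, ], v[j, ])
  diag(oracle) <- 0
  expect_lt(max(abs(d5$matrix - oracle)), 1e-12)
  expect_true(all(d5$matrix >= 0 & d5$matrix <= 2))

  vz <- v; vz[2, ] <- 7
  expect_error(compute_rdm(vz), "zero-variance.*b")

  # fixture RDM: nearest pair is animal/nature
  dF <- compute_rdm(fixture_feature_matrix(), standardize = TRUE)
  off <- dF$matrix; diag(off) <- Inf
  nearest <- arrayInd(which.min(off), dim(off))
  expect_setequal(dF$labels[nearest], c("animal", "nature"))
})

test_that("dendrograms are validated by cophenetic correlation", {
  # ultrametric input is represented exactly
  um <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(cluster_dendrogram(dsm(um, letters[1:4]))$cophenetic_r, 1.0)

  # 3-point case: merges in the order of the two smallest distances
  m3 <- matrix(c(0, 1, 5, 1, 0, 3, 5, 3, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- cluster_dendrogram(dsm(m3, c("x", "y", "z")))$tree
  expect_equal(tr$height[1], 1) # x-y merge first
  expect_true(all(tr$merge[1, ] < 0))
  expect_setequal(tr$labels[-tr$merge[1, ]], c("x", "y"))

  dF <- compute_rdm(fixture_feature_matrix(), standardize = TRUE)
  res <- cluster_dendrogram(dF)
  expect_equal(res$cophenetic_r, 0.80, tolerance = 0.05)
  expect_match(res$newick, "animal.*nature|nature.*animal")

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(cluster_dendrogram(bad), "symmetric")
})

test_that("RDM comparison equals a direct rank-correlation oracle", {
  set.seed(17)
  mk <- function() {
    m <- matrix(0, 5, 5)
    m[lower.tri(m)] <- runif(10)
    m + t(m)
  }
  a <- mk(); b <- mk()
  rho <- compare_rdms(dsm(a), dsm(b))
  expect_equal(rho, cor(a[lower.tri(a)], b[lower.tri(b)], method = "spearman"),
               tolerance = 1e-12)
  expect_equal(compare_rdms(dsm(a), dsm(a)), 1.0)
  rev_b <- max(a) + min(a[lower.tri(a)]) - a
  diag(rev_b) <- 0
  expect_equal(compare_rdms(dsm(a), dsm(rev_b)), -1.0)
  expect_error(compare_rdms(dsm(a), dsm(mk()[1:4, 1:4])), "size")
})

test_that("centroid statistics behave under null, shift and a manual oracle", {
  # constant table -> degenerate null
  cm <- matrix(2, 10, 10, dimnames = list(NULL, paste0("c", 1:10)))
  res0 <- suppressWarnings(centroid_stats(cm))
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p, 1)

  # hand-ranked 3x3 table: classic Friedman statistic
  h <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  n <- 3; k <- 3
  Rj <- colSums(t(apply(h, 1, rank)))
  chisq_manual <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  expect_equal(centroid_stats(h)$chisq, chisq_manual)

  # one shifted category detected against all others (power simulation).
  # With the exact signed-rank, 20 matched stimuli per category are needed
  # before a pair can clear the 45-fold Bonferroni bar (at n = 10 the
  # smallest attainable corrected p is 2/2^10 * 45 = 0.088).
  n_sig <- 0
  for (rep in 1:20) {
    vals <- withr::with_seed(rep, {
      x <- matrix(rnorm(200, 2, 0.5), 20, 10)
      x[, 4] <- x[, 4] + 10
      x
    })
    colnames(vals) <- paste0("c", 1:10)
    res <- centroid_stats(vals)
    hits <- res$pairwise[res$pairwise$a == "c4" | res$pairwise$b == "c4", ]
    if (all(hits$significant)) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / 20, 0.8)

  expect_error(centroid_stats(c(1, 2, 3), c("a", "a", "b")), "unbalanced")
})
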