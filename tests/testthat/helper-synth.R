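# shared fixture builders (everything generated in code)

make_stimulus <- function(wave, fs, category = NA) {
  structure(list(wave = wave, sample_rate = fs, category = category,
                 scrambled = FALSE), class = "stimulus")
}

pure_tone <- function(freq_hz, dur_s = 1, fs = 16000, amp = 0.5) {
  make_stimulus(amp * sin(2 * pi * freq_hz * (0:(dur_s * fs - 1)) / fs), fs)
}

am_tone <- function(mod_hz, carrier_hz = 1000, dur_s = 1, fs = 16000, depth = 0.9) {
  t <- (0:(dur_s * fs - 1)) / fs
  make_stimulus((1 + depth * sin(2 * pi * mod_hz * t)) * sin(2 * pi * carrier_hz * t), fs)
}

seeded_noise <- function(dur_s = 1, fs = 16000, seed = 1, amp = 0.1) {
  make_stimulus(withr::with_seed(seed, amp * stats::rnorm(dur_s * fs)), fs)
}

# category feature matrix used for acoustic RDMs (six features, as in the
# published dissimilarity analysis)
fixture_feature_matrix <- function() {
  tab <- load_category_features()
  m <- as.matrix(tab[, c("pssd", "pscv", "rms_db", "f0_mean", "f0_sd", "hnr")])
  rownames(m) <- tab$category
  m
}

# quick separable-or-not beta patterns for MVPA tests
quick_pattern <- function(n_voxels = 12, n_runs = 6, conds = vocal_categories(),
                          structure = "distinct", effect = 1, noise = 1,
                          seed = 1) {
  tr <- make_category_truth(n_voxels, conds, structure, effect_size = effect,
                            noise_sd = noise, seed = seed)
  simulate_beta_patterns(n_voxels, n_runs, conds, tr, seed = seed + 7919)
}
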