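# Synthetic data with known ground truth: stimuli whose acoustics hit the
# category-level targets (tonal high-HNR coos, broadband high-centroid
# screams, pulsed noisy aggressive calls, mixed animal calls, broadband
# nature sounds), counterbalanced block designs, forward-modelled voxel
# time series, and run-wise beta patterns.

default_category_targets <- function() {
  data.frame(
    category   = c("coo", "scream", "aggressive", "animal", "nature"),
    f0_hz      = c(581, 684, 430, 503, 439),
    harmonicity = c(0.83, 0.67, 0.39, 0.64, 0.37),
    centroid_khz = c(2.08, 5.01, 2.69, 2.11, 1.45),
    rms_db     = c(-9.95, -13.06, -14.9, -23.45, -23.57),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic stimulus
#'
#' Acoustic targets default to the category means of the stimulus set
#' (fundamental frequency, periodicity, spectral centroid, RMS level).
#'
#' @param category One of `sound_categories()`.
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz (>= 8000).
#' @param f0_hz Target fundamental frequency (Hz).
#' @param harmonicity Target periodicity in `[0, 1]` (harmonic-to-noise ratio scale).
#' @param centroid_khz Target spectral centroid (kHz).
#' @param rms_db Target RMS level in dB re full scale.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(category, duration_s = 0.5, sample_rate = 24000,
                          f0_hz = NULL, harmonicity = NULL,
                          centroid_khz = NULL, rms_db = NULL, seed = 1L) {
  cats <- sound_categories()
  if (!is.character(category) || length(category) != 1L || !(category %in% cats))
    stop("unsupported category '", category, "'; valid categories: ",
         paste(cats, collapse = ", "))
  stopifnot(duration_s > 0, sample_rate >= 8000)
  tg <- default_category_targets()
  tg <- tg[tg$category == category, ]
  spec <- list(category = category, duration_s = duration_s,
               sample_rate = sample_rate,
               f0_hz = if (is.null(f0_hz)) tg$f0_hz else f0_hz,
               harmonicity = if (is.null(harmonicity)) tg$harmonicity else harmonicity,
               centroid_khz = if (is.null(centroid_khz)) tg$centroid_khz else centroid_khz,
               rms_db = if (is.null(rms_db)) tg$rms_db else rms_db,
               seed = as.integer(seed))
  if (spec$harmonicity < 0 || spec$harmonicity > 1)
    stop("harmonicity must lie in [0, 1]")
  structure(spec, class = "stimulus_spec")
}

# impose an exponentially decaying spectral envelope (amplitude ~ exp(-f/lambda))
# on a waveform; lambda approximately equals the resulting spectral centroid
shape_spectrum <- function(x, sample_rate, lambda_hz, floor_frac = 0.02) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f) # two-sided
  env <- exp(-f / lambda_hz) + floor_frac
  Re(stats::fft(stats::fft(x) * env, inverse = TRUE)) / n
}

#' Generate a synthetic stimulus waveform
#'
#' Category-specific recipes: coos are harmonic stacks with a slowly
#' jittered, stable fundamental; screams add a strong high-frequency noise
#' floor to a high-pitched harmonic stack; aggressive calls are pulsed
#' noise bursts with a weak harmonic residue; animal calls mix a vibrato
#' harmonic stack with noise; nature sounds are shaped broadband noise.
#' Recipes are calibrated to the category targets by construction.
#'
#' @param spec A [stimulus_spec()].
#' @return A `stimulus` object: list with `wave` (numeric, RMS at the target
#'   level), `sample_rate`, `category`, `scrambled = FALSE`.
#' @export
generate_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(spec$duration_s * spec$sample_rate)
  fs <- spec$sample_rate
  lambda <- spec$centroid_khz * 1000
  wave <- with_seed(spec$seed, {
    t <- (seq_len(n) - 1) / fs
    # slow multiplicative F0 jitter: random walk, low-pass by cumulative mean
    jit_sd <- switch(spec$category, coo = 0.002, animal = 0.01, 0.02)
    jitter <- stats::filter(stats::rnorm(n, 0, jit_sd), rep(1 / 400, 400),
                            sides = 1)
    jitter[is.na(jitter)] <- 0
    phase <- 2 * pi * cumsum(spec$f0_hz * (1 + as.numeric(jitter))) / fs
    n_harm <- max(1L, floor(0.45 * fs / spec$f0_hz))
    h <- seq_len(min(n_harm, 30L))
    amps <- exp(-h * spec$f0_hz / lambda)
    harm <- colSums(amps * t(sapply(h, function(k) cos(k * phase))))
    if (spec$category == "animal") { # vibrato
      harm <- harm * (1 + 0.2 * sin(2 * pi * 6 * t))
    }
    noise <- shape_spectrum(stats::rnorm(n), fs, lambda)
    if (spec$category == "aggressive") { # pulsed bursts at ~30 Hz
      pulse <- 0.15 + 0.85 * (0.5 - 0.5 * cos(2 * pi * 30 * t))^2
      noise <- noise * pulse
      harm <- harm * pulse
    }
    unit <- function(x) x / max(stats::sd(x), 1e-12)
    w <- sqrt(spec$harmonicity) * unit(harm) +
      sqrt(1 - spec$harmonicity) * unit(noise)
    # 5 ms raised-cosine onset/offset ramps
    nr <- min(n %/% 2L, round(0.005 * fs))
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 0.5) / nr)
    w[seq_len(nr)] <- w[seq_len(nr)] * ramp
    w[n - nr + seq_len(nr)] <- w[n - nr + seq_len(nr)] * rev(ramp)
    w <- w / max(stats::sd(w), 1e-12) * 10^(spec$rms_db / 20)
    peak <- max(abs(w))
    if (peak > 0.99) w <- w * 0.99 / peak
    w
  })
  structure(list(wave = wave, sample_rate = fs, category = spec$category,
                 scrambled = FALSE), class = "stimulus")
}

#' Generate counterbalanced block-design runs
#'
#' Ten sound conditions (five categories and their scrambled versions) in
#' 21 s blocks of 42 events at 500 ms stimulus-onset asynchrony, each block
#' followed by a 15 s silent block; block order counterbalanced with a
#' Latin square built by cyclic shifts of a seeded random first row, so
#' that across a full cycle of runs every condition occupies every serial
#' position equally often.
#'
#' @param n_runs Number of runs (>= 1).
#' @param n_conditions Number of sound conditions.
#' @param reps Repetitions of each condition per run.
#' @param block_s,silence_s Sound and silence block durations (s).
#' @param soa_ms Stimulus-onset asynchrony within a block (ms).
#' @param tr_s Repetition time (s).
#' @param n_dummies Dummy volumes at the start of each run (excluded from fits).
#' @param condition_labels Optional condition names (length `n_conditions`).
#' @param n_vols Total volumes per run; default covers dummies plus all blocks.
#' @param seed Integer seed for the Latin-square first row.
#' @return List of `run_design` objects. Each has `blocks` (data.frame with
#'   condition, onset_s, duration_s, serial_pos), `events` (per sound block,
#'   vector of stimulus onsets), `tr_s`, `n_dummies`, `n_vols`, `run_id`.
#' @export
generate_run_design <- function(n_runs, n_conditions = 10L, reps = 2L,
                                block_s = 21, silence_s = 15, soa_ms = 500,
                                tr_s = 3, n_dummies = 5L,
                                condition_labels = NULL, n_vols = NULL,
                                seed = 1L) {
  stopifnot(n_runs >= 1, n_conditions >= 2, reps >= 1)
  events_per_block <- floor(block_s / (soa_ms / 1000))
  if (events_per_block < 1) stop("block shorter than one stimulus-onset asynchrony")
  if (is.null(condition_labels)) {
    base <- sound_categories()
    condition_labels <- if (n_conditions == 10L)
      c(base, paste0("scrambled_", base))
    else paste0("cond", seq_len(n_conditions))
  }
  if (length(condition_labels) != n_conditions)
    stop("condition_labels must have length n_conditions")
  first_row <- with_seed(seed, sample.int(n_conditions))
  square <- t(sapply(seq_len(n_conditions) - 1L,
                     function(s) first_row[(seq_len(n_conditions) + s - 1L) %% n_conditions + 1L]))
  n_blocks <- n_conditions * reps
  row_seq <- 0L # rows consumed so far, cycles through the square
  lapply(seq_len(n_runs), function(run_id) {
    order_idx <- integer(0)
    for (r in seq_len(reps)) {
      row <- square[row_seq %% n_conditions + 1L, ]
      row_seq <<- row_seq + 1L
      order_idx <- c(order_idx, row)
    }
    onset <- n_dummies * tr_s
    blocks <- data.frame(condition = character(0), onset_s = numeric(0),
                         duration_s = numeric(0), serial_pos = integer(0),
                         stringsAsFactors = FALSE)
    events <- list()
    for (b in seq_len(n_blocks)) {
      cond <- condition_labels[order_idx[b]]
      blocks <- rbind(blocks, data.frame(
        condition = cond, onset_s = onset, duration_s = block_s,
        serial_pos = (b - 1L) %% n_conditions + 1L, stringsAsFactors = FALSE))
      events[[b]] <- onset + (seq_len(events_per_block) - 1) * soa_ms / 1000
      onset <- onset + block_s
      blocks <- rbind(blocks, data.frame(
        condition = "silence", onset_s = onset, duration_s = silence_s,
        serial_pos = NA_integer_, stringsAsFactors = FALSE))
      onset <- onset + silence_s
    }
    total_s <- onset
    nv <- if (is.null(n_vols)) ceiling(total_s / tr_s) else n_vols
    structure(list(blocks = blocks, events = events, tr_s = tr_s,
                   n_dummies = as.integer(n_dummies), soa_ms = soa_ms,
                   n_vols = as.integer(nv), run_id = run_id,
                   condition_labels = condition_labels),
              class = "run_design")
  })
}

#' Ground truth for forward simulation
#'
#' @param category_means Voxel-by-condition matrix of true activation
#'   amplitudes, in percent of baseline signal.
#' @param noise_sd I.i.d. noise SD in raw signal units.
#' @param shared_noise_rank Number of shared (spatially structured) noise
#'   components injected across voxels.
#' @param shared_noise_amp Amplitude of shared components (percent of baseline).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(category_means, noise_sd = 0,
                         shared_noise_rank = 0L, shared_noise_amp = 1) {
  category_means <- as.matrix(category_means)
  stopifnot(noise_sd >= 0, shared_noise_rank >= 0)
  structure(list(category_means = category_means, noise_sd = noise_sd,
                 shared_noise_rank = as.integer(shared_noise_rank),
                 shared_noise_amp = shared_noise_amp),
            class = "ground_truth")
}

#' Category-mean structures for beta-pattern simulation
#'
#' `"distinct"` draws an independent mean pattern per condition;
#' `"dissociation"` gives the three vocalizations distinct patterns and the
#' two non-vocalizations one shared pattern (vocalization-selective
#' structure); `"null"` gives all conditions the same pattern.
#'
#' @param n_voxels Number of voxels.
#' @param condition_labels Condition names.
#' @param structure One of `"distinct"`, `"dissociation"`, `"null"`.
#' @param effect_size SD of the mean patterns.
#' @param seed Integer seed.
#' @inheritParams ground_truth
#' @return A `ground_truth` object.
#' @export
make_category_truth <- function(n_voxels, condition_labels,
                                structure = c("distinct", "dissociation", "null"),
                                effect_size = 1, noise_sd = 1, seed = 1L,
                                shared_noise_rank = 0L, shared_noise_amp = 1) {
  structure <- match.arg(structure)
  k <- length(condition_labels)
  means <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_voxels * k, 0, effect_size), n_voxels, k)
    colnames(m) <- condition_labels
    if (structure == "null") {
      m[] <- m[, 1]
    } else if (structure == "dissociation") {
      nv <- intersect(condition_labels, nonvocal_categories())
      if (length(nv) >= 2) m[, nv] <- m[, nv[1]]
    }
    m
  })
  ground_truth(means, noise_sd = noise_sd, shared_noise_rank = shared_noise_rank,
               shared_noise_amp = shared_noise_amp)
}

# condition boxcars sampled at the TR over a run (fraction of each TR inside
# a block of that condition), dummies included as frames
condition_boxcars <- function(design) {
  nv <- design$n_vols
  tr <- design$tr_s
  conds <- design$condition_labels
  frame_start <- (seq_len(nv) - 1) * tr
  x <- matrix(0, nrow = nv, ncol = length(conds),
              dimnames = list(NULL, conds))
  sound <- design$blocks[design$blocks$condition != "silence", ]
  for (i in seq_len(nrow(sound))) {
    ov <- pmax(0, pmin(frame_start + tr, sound$onset_s[i] + sound$duration_s[i]) -
                 pmax(frame_start, sound$onset_s[i])) / tr
    x[, sound$condition[i]] <- x[, sound$condition[i]] + ov
  }
  x
}

#' Simulate ROI voxel time series from a run design
#'
#' Forward model: per voxel, signal = baseline x (1 + [task + drift +
#' shared noise] / 100) + i.i.d. noise, where task is the sum over
#' conditions of the true amplitude times the condition boxcar convolved
#' with the hemodynamic kernel. With `mion_sign_flip = TRUE` the raw MION
#' polarity is emitted (activation decreases signal); the default emits
#' activation-positive values, the convention used throughout the pipeline.
#'
#' @param design A `run_design`.
#' @param truth A [ground_truth()] whose `category_means` columns match the
#'   design's sound conditions.
#' @param hrf_kernel Hemodynamic kernel sampled at the TR (see [mion_hrf()]).
#' @param seed Integer seed.
#' @param baseline Baseline signal level.
#' @param drift_amp Peak amplitude of a quadratic drift (percent of baseline).
#' @param dims Optional 3D grid dimensions (`prod(dims)` voxels) for NIfTI
#'   export; defaults to a flat voxel list.
#' @param mion_sign_flip Emit raw MION polarity (activation-negative).
#' @return List with `Y` (frame x voxel matrix), `design`, `frame_table`
#'   (volume, time, dummy flag), `truth`, `dims`, and `shared_components`
#'   (frame x rank matrix of injected shared noise time courses, or NULL).
#' @export
simulate_roi_timeseries <- function(design, truth, hrf_kernel, seed = 1L,
                                    baseline = 100, drift_amp = 0.5,
                                    dims = NULL, mion_sign_flip = FALSE) {
  stopifnot(inherits(design, "run_design"), inherits(truth, "ground_truth"))
  nv <- design$n_vols
  if (length(hrf_kernel) > nv) stop("HRF kernel longer than the run")
  x <- condition_boxcars(design)
  xc <- apply(x, 2, function(col) {
    y <- stats::convolve(col, rev(hrf_kernel), type = "open")[seq_len(nv)]
    y
  })
  amps <- truth$category_means # voxel x condition, percent units
  missing <- setdiff(colnames(x), colnames(amps))
  if (length(missing)) stop("truth lacks conditions: ", paste(missing, collapse = ", "))
  task <- xc[, colnames(amps), drop = FALSE] %*% t(amps) # frame x voxel
  n_vox <- nrow(amps)
  tt <- seq_len(nv) / nv - 0.5
  out <- with_seed(seed, {
    drift <- outer(tt^2 - mean(tt^2), stats::runif(n_vox, -drift_amp, drift_amp))
    shared <- NULL
    shared_field <- 0
    if (truth$shared_noise_rank > 0) {
      shared <- matrix(stats::rnorm(nv * truth$shared_noise_rank), nv)
      # smooth the shared time courses slightly (physiological-like)
      shared <- apply(shared, 2, function(z) as.numeric(stats::filter(z, rep(1 / 3, 3), sides = 2, circular = TRUE)))
      load <- matrix(stats::rnorm(truth$shared_noise_rank * n_vox), ncol = n_vox)
      shared_field <- truth$shared_noise_amp * shared %*% load
    }
    sgn <- if (mion_sign_flip) -1 else 1
    Y <- baseline * (1 + sgn * task / 100 + drift / 100 + shared_field / 100) +
      matrix(stats::rnorm(nv * n_vox, 0, truth$noise_sd), nv)
    list(Y = Y, shared = shared)
  })
  frame_table <- data.frame(volume = seq_len(nv),
                            time_s = (seq_len(nv) - 1) * design$tr_s,
                            dummy = seq_len(nv) <= design$n_dummies)
  list(Y = out$Y, design = design, frame_table = frame_table, truth = truth,
       dims = dims, shared_components = out$shared)
}

#' Write a simulated time series as a NIfTI-1 volume plus design table
#'
#' @param sim Output of [simulate_roi_timeseries()] with non-NULL `dims`.
#' @param nifti_path Output `.nii` path.
#' @param design_path Output tab-delimited design table path.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return Paths, invisibly.
#' @export
write_simulation <- function(sim, nifti_path, design_path, voxel_mm = 3) {
  dims <- sim$dims
  if (is.null(dims)) stop("simulation carries no 3D grid dims")
  stopifnot(prod(dims) == ncol(sim$Y))
  arr <- array(t(sim$Y), dim = c(dims, nrow(sim$Y)))
  img <- RNifti::asNifti(arr, pixdim = c(rep(voxel_mm, 3), sim$design$tr_s))
  RNifti::writeNifti(img, nifti_path)
  blk <- sim$design$blocks
  utils::write.table(blk[, c("condition", "onset_s", "duration_s")],
                     design_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(nifti_path, design_path))
}

#' Construct a beta pattern container
#'
#' @param values Numeric array indexed (voxel, condition, run).
#' @param condition_labels,run_ids Dimension labels.
#' @param roi_label ROI name.
#' @return A `beta_pattern` object.
#' @export
beta_pattern <- function(values, condition_labels, run_ids,
                         roi_label = "roi") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D (voxel, condition, run) array")
  if (dim(values)[2] < 2) stop("a beta pattern needs at least 2 conditions")
  if (dim(values)[3] < 2) stop("a beta pattern needs at least 2 runs")
  if (anyNA(values)) stop("beta pattern contains missing values")
  stopifnot(length(condition_labels) == dim(values)[2],
            length(run_ids) == dim(values)[3])
  dimnames(values) <- list(NULL, condition_labels, NULL)
  structure(list(values = values, condition_labels = condition_labels,
                 run_ids = run_ids, roi_label = roi_label),
            class = "beta_pattern")
}

#' Simulate run-wise beta patterns
#'
#' Each entry is the condition's true voxel mean plus i.i.d. Gaussian noise.
#'
#' @param n_voxels Number of voxels.
#' @param n_runs Number of runs (>= 4, so hold-out schemes are feasible).
#' @param condition_labels Condition names (>= 2).
#' @param truth A [ground_truth()] with matching dimensions.
#' @param seed Integer seed.
#' @param roi_label ROI name for the container.
#' @return A [beta_pattern()].
#' @export
simulate_beta_patterns <- function(n_voxels, n_runs, condition_labels, truth,
                                   seed = 1L, roi_label = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_runs < 4) stop("need at least 4 runs (hold-out feasibility)")
  k <- length(condition_labels)
  if (k < 2) stop("need at least 2 conditions")
  means <- truth$category_means[, condition_labels, drop = FALSE]
  stopifnot(nrow(means) == n_voxels)
  vals <- with_seed(seed, {
    noise <- array(stats::rnorm(n_voxels * k * n_runs, 0, truth$noise_sd),
                   dim = c(n_voxels, k, n_runs))
    array(rep(means, n_runs), dim = c(n_voxels, k, n_runs)) + noise
  })
  beta_pattern(vals, condition_labels, seq_len(n_runs), roi_label)
}

#' Write or read beta patterns as long-format delimited tables
#'
#' Columns: roi, voxel, condition, run, beta.
#'
#' @param pattern A `beta_pattern`.
#' @param path File path.
#' @return `write_beta_pattern` returns `path` invisibly; `read_beta_pattern`
#'   returns a `beta_pattern`.
#' @export
write_beta_pattern <- function(pattern, path) {
  v <- pattern$values
  d <- dim(v)
  tab <- data.frame(
    roi = pattern$roi_label,
    voxel = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(rep(pattern$condition_labels, each = d[1]), times = d[3]),
    run = rep(pattern$run_ids, each = d[1] * d[2]),
    beta = as.vector(v))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beta_pattern
#' @export
read_beta_pattern <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  conds <- unique(tab$condition)
  runs <- sort(unique(tab$run))
  nvox <- max(tab$voxel)
  v <- array(NA_real_, dim = c(nvox, length(conds), length(runs)))
  for (ri in seq_along(runs)) for (ci in seq_along(conds)) {
    sel <- tab$run == runs[ri] & tab$condition == conds[ci]
    v[tab$voxel[sel], ci, ri] <- tab$beta[sel]
  }
  beta_pattern(v, conds, runs, tab$roi[1])
}
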