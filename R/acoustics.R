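# Stimulus-level acoustics: modulation power spectra of auditory
# spectrograms, the category feature set (RMS, F0 statistics, HNR, spectral
# spread/variability, centroid), acoustic dissimilarity matrices, their
# dendrograms, and the spectral-centroid condition statistics.

#' Dissimilarity matrix container
#'
#' @param matrix Symmetric zero-diagonal numeric matrix.
#' @param labels Condition/category names.
#' @param metric Label of the distance used.
#' @return A `dsm` object.
#' @export
dsm <- function(matrix, labels = rownames(matrix), metric = "unknown") {
  matrix <- as.matrix(matrix)
  check_dsm(matrix)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = matrix, labels = labels, metric = metric),
            class = "dsm")
}

#' Modulation power spectrum of an auditory spectrogram
#'
#' The log envelope (mean removed) is autocorrelated in two dimensions
#' (across frequency channels and time frames) and the 2D FFT magnitude of
#' the autocorrelation taken, giving power over temporal modulation rate
#' (Hz, signed) and spectral modulation scale (cycles/kHz). Power is
#' expressed in dB relative to the peak, so the result is invariant to
#' global waveform gain.
#'
#' @param spectrogram An `auditory_spectrogram` with >= 16 channels and
#'   >= 16 frames.
#' @param demean `"global"` removes the grand mean of the log envelope
#'   (keeps the stationary spectral profile as energy near 0 Hz);
#'   `"channel"` removes each channel's temporal mean as well, isolating
#'   genuine temporal modulations.
#' @return A `modulation_power_spectrum`: `power_db` (scale x rate, max
#'   0 dB), `rate_hz`, `scale_cyc_per_khz`, `reference_peak_db`.
#' @export
compute_mps <- function(spectrogram, demean = c("global", "channel")) {
  stopifnot(inherits(spectrogram, "auditory_spectrogram"))
  demean <- match.arg(demean)
  env <- spectrogram$envelope
  if (nrow(env) < 16 || ncol(env) < 16)
    stop("need at least 16 channels and 16 frames for a modulation power spectrum")
  logenv <- log(env + 1e-12)
  logenv <- logenv - mean(logenv)
  if (demean == "channel") logenv <- logenv - rowMeans(logenv)
  # 2D autocorrelation by Wiener-Khinchin with zero padding (linear autocorr)
  nr <- 2L * nrow(logenv); nc <- 2L * ncol(logenv)
  padded <- matrix(0, nr, nc)
  padded[seq_len(nrow(logenv)), seq_len(ncol(logenv))] <- logenv
  F1 <- stats::fft(padded)
  ac <- Re(stats::fft(F1 * Conj(F1), inverse = TRUE)) / (nr * nc)
  P <- Mod(stats::fft(ac)) # FFT magnitude of the autocorrelation
  # axes: spectral modulation in cycles/channel -> cycles/kHz via the mean
  # channel spacing; temporal modulation from the frame hop
  hop_s <- spectrogram$hop_s
  d_khz <- mean(diff(spectrogram$center_freqs)) / 1000
  rate <- (seq_len(nc) - 1) / nc / hop_s
  rate[rate >= 1 / (2 * hop_s)] <- rate[rate >= 1 / (2 * hop_s)] - 1 / hop_s
  scale <- (seq_len(nr) - 1) / nr / d_khz
  scale[scale >= 1 / (2 * d_khz)] <- scale[scale >= 1 / (2 * d_khz)] - 1 / d_khz
  ro <- order(rate); so <- order(scale)
  P <- P[so, ro]
  peak <- max(P)
  structure(list(power_db = 10 * log10(pmax(P, peak * 1e-15) / peak),
                 rate_hz = rate[ro], scale_cyc_per_khz = scale[so],
                 reference_peak_db = 10 * log10(peak)),
            class = "modulation_power_spectrum")
}

#' Average modulation power spectra
#'
#' Element-wise mean in linear power (on the absolute scale), re-expressed
#' in dB relative to the new peak.
#'
#' @param mps_list List of `modulation_power_spectrum` objects on identical axes.
#' @return A `modulation_power_spectrum`.
#' @export
average_mps <- function(mps_list) {
  stopifnot(length(mps_list) >= 1)
  ref <- mps_list[[1]]
  for (m in mps_list) {
    if (!isTRUE(all.equal(m$rate_hz, ref$rate_hz)) ||
        !isTRUE(all.equal(m$scale_cyc_per_khz, ref$scale_cyc_per_khz)))
      stop("modulation power spectra have mismatching axes")
  }
  lin <- lapply(mps_list, function(m) 10^((m$power_db + m$reference_peak_db) / 10))
  avg <- Reduce(`+`, lin) / length(lin)
  peak <- max(avg)
  structure(list(power_db = 10 * log10(pmax(avg, peak * 1e-15) / peak),
                 rate_hz = ref$rate_hz, scale_cyc_per_khz = ref$scale_cyc_per_khz,
                 reference_peak_db = 10 * log10(peak)),
            class = "modulation_power_spectrum")
}

#' Half-maximum contour mask of a modulation power spectrum
#'
#' @param mps A `modulation_power_spectrum`.
#' @return Logical matrix marking bins within 6 dB of the peak (half maximum
#'   in power).
#' @export
mps_halfmax_mask <- function(mps) mps$power_db >= -6.0206

# framewise normalized autocorrelation peak within a lag window; returns
# the refined lag (parabolic interpolation) and peak value
frame_acf_peak <- function(x, lag_min, lag_max) {
  x <- x - mean(x)
  n <- length(x)
  if (stats::sd(x) < 1e-12) return(c(NA, 0))
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(X * Conj(X), inverse = TRUE))[seq_len(lag_max + 2L)] / nfft
  r <- r / r[1]
  lags <- lag_min:min(lag_max, length(r) - 2L)
  if (length(lags) < 1) return(c(NA, 0))
  # peak located on the biased estimate (its lag taper suppresses spurious
  # long-lag subharmonics); the peak value is then corrected for the taper
  # (the zero-padded lag-l sum spans only n - l terms)
  vals <- r[lags + 1L]
  i <- which.max(vals)
  l0 <- lags[i]
  y1 <- r[l0]; y2 <- r[l0 + 1L]; y3 <- r[l0 + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  c(l0 + max(-0.5, min(0.5, delta)), min(1, vals[i] * n / (n - l0)))
}

#' Extract the acoustic feature set from a stimulus
#'
#' Computes the per-stimulus version of the category feature table: RMS
#' level (dB re full scale), F0 mean and SD over voiced frames (framewise
#' normalized autocorrelation, 25 ms frames, 10 ms hop, voicing threshold
#' 0.3), harmonic-to-noise ratio as the mean voiced-frame autocorrelation
#' peak (0-1 scale), power-spectrum SD (power-weighted SD of frequency, Hz),
#' power-spectrum coefficient of variation (SD/mean of spectral magnitude
#' across bins), duration, and amplitude-weighted spectral centroid (kHz).
#'
#' @param stimulus A `stimulus` (or list with `wave` and `sample_rate`).
#' @param f0_range_hz Search range for the fundamental (Hz).
#' @return An `acoustic_features` one-row data frame with columns `rms_db`,
#'   `f0_mean`, `f0_sd`, `hnr`, `pssd`, `pscv`, `duration_s`, `centroid_khz`.
#' @export
extract_features <- function(stimulus, f0_range_hz = c(100, 2000)) {
  wave <- stimulus$wave
  fs <- stimulus$sample_rate
  if (length(wave) < 0.05 * fs) stop("stimulus shorter than 50 ms")
  frame_len <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  lag_min <- max(2L, floor(fs / f0_range_hz[2]))
  lag_max <- ceiling(fs / f0_range_hz[1])
  starts <- seq(1L, length(wave) - frame_len + 1L, by = hop)
  peaks <- t(vapply(starts, function(s)
    frame_acf_peak(wave[s:(s + frame_len - 1L)], lag_min, lag_max),
    numeric(2)))
  voiced <- !is.na(peaks[, 1]) & peaks[, 2] >= 0.3
  if (any(voiced)) {
    f0 <- fs / peaks[voiced, 1]
    f0_mean <- mean(f0)
    f0_sd <- stats::sd(f0)
    hnr <- mean(peaks[voiced, 2])
  } else {
    f0_mean <- NA_real_; f0_sd <- NA_real_; hnr <- 0
  }
  n <- length(wave)
  A <- Mod(stats::fft(wave))[seq_len(floor(n / 2))]
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  P <- A^2
  centroid_hz <- sum(f * A) / sum(A)
  mu_p <- sum(f * P) / sum(P)
  out <- data.frame(
    rms_db = 20 * log10(sqrt(mean(wave^2))),
    f0_mean = f0_mean, f0_sd = f0_sd, hnr = hnr,
    pssd = sqrt(sum(P * (f - mu_p)^2) / sum(P)),
    pscv = stats::sd(A) / mean(A),
    duration_s = n / fs,
    centroid_khz = centroid_hz / 1000)
  class(out) <- c("acoustic_features", class(out))
  out
}

#' Load the packaged category acoustic feature table
#'
#' The mean acoustic parameters of the five sound categories (N = 10
#' stimuli per category): RMS amplitude, F0 mean and SD, HNR, power
#' spectrum SD and CV, duration, spectral centroid.
#'
#' @return Data frame with a `category` column and eight feature columns.
#' @export
load_category_features <- function() {
  path <- system.file("extdata", "category_acoustic_features.tsv",
                      package = "vocfmri")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Aggregate per-stimulus features into category and group means
#'
#' Unweighted mean per feature per category, then group means as the
#' unweighted mean of category means over the three vocalization and the
#' two non-vocalization categories.
#'
#' @param features Data frame of feature rows (numeric columns are aggregated).
#' @param categories Category label per row; defaults to a `category` column.
#' @return List with `category_means` (one row per category) and
#'   `group_means` (rows `vocal` and `nonvocal`).
#' @export
aggregate_category_features <- function(features, categories = features$category) {
  if (is.null(categories)) stop("no category labels supplied")
  known <- sound_categories()
  bad <- setdiff(unique(categories), known)
  if (length(bad)) stop("unknown category label(s): ", paste(bad, collapse = ", "))
  num <- features[vapply(features, is.numeric, logical(1))]
  cat_means <- stats::aggregate(num, by = list(category = categories), FUN = mean)
  rownames(cat_means) <- cat_means$category
  voc <- cat_means[intersect(vocal_categories(), rownames(cat_means)), -1, drop = FALSE]
  nonvoc <- cat_means[intersect(nonvocal_categories(), rownames(cat_means)), -1, drop = FALSE]
  group_means <- rbind(vocal = colMeans(voc), nonvocal = colMeans(nonvoc))
  list(category_means = cat_means, group_means = as.data.frame(group_means))
}

#' Correlation-distance dissimilarity matrix
#'
#' Entry (i, j) is 1 minus the Pearson correlation of the descriptor
#' vectors of items i and j. With `standardize = TRUE` each vector
#' dimension is z-scored across items first (recommended when features are
#' on incommensurate scales, as in the category feature table).
#'
#' @param vectors Item-by-dimension numeric matrix with item rownames.
#' @param standardize Z-score each column across items first.
#' @return A [dsm()] with metric `"correlation"`.
#' @export
compute_rdm <- function(vectors, standardize = FALSE) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 3) stop("need at least 3 items")
  if (ncol(vectors) < 2) stop("need vectors of length >= 2")
  labels <- rownames(vectors)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(vectors)))
  if (standardize) vectors <- scale(vectors)
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds < 1e-14))
    stop("zero-variance vector for label(s): ",
         paste(labels[sds < 1e-14], collapse = ", "))
  d <- 1 - stats::cor(t(vectors))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dsm(d, labels, metric = "correlation")
}

#' Hierarchical clustering of a dissimilarity matrix with cophenetic check
#'
#' Agglomerative clustering (UPGMA by default) plus the cophenetic
#' correlation — the Pearson correlation between the original pairwise
#' distances and those implied by the tree — as a measure of how faithfully
#' the dendrogram represents the dissimilarity structure.
#'
#' @param d A [dsm()] or symmetric matrix.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `tree` (hclust), `cophenetic_r`, and `newick` (string).
#' @export
cluster_dendrogram <- function(d, linkage = "average") {
  m <- if (inherits(d, "dsm")) d$matrix else as.matrix(d)
  check_dsm(m)
  dd <- stats::as.dist(m)
  tree <- stats::hclust(dd, method = linkage)
  coph <- stats::cophenetic(tree)
  list(tree = tree,
       cophenetic_r = stats::cor(dd, coph),
       newick = hclust_newick(tree))
}

# serialize an hclust tree to a Newick string (heights as branch lengths)
hclust_newick <- function(tree) {
  lab <- tree$labels
  if (is.null(lab)) lab <- paste0("item", seq_along(tree$order))
  node <- function(i, h_parent) {
    if (i < 0) return(paste0(lab[-i], ":", format(h_parent, digits = 6)))
    kids <- tree$merge[i, ]
    h <- tree$height[i]
    paste0("(", node(kids[1], h), ",", node(kids[2], h), "):",
           format(h_parent - h, digits = 6))
  }
  root <- nrow(tree$merge)
  kids <- tree$merge[root, ]
  h <- tree$height[root]
  paste0("(", node(kids[1], h), ",", node(kids[2], h), ");")
}

#' Rank correlation between two dissimilarity matrices
#'
#' Spearman correlation of the vectorized strictly-lower triangles.
#'
#' @param dsm_a,dsm_b [dsm()] objects (or matrices) over the same labels.
#' @return Spearman's rho.
#' @export
compare_rdms <- function(dsm_a, dsm_b) {
  a <- if (inherits(dsm_a, "dsm")) dsm_a$matrix else as.matrix(dsm_a)
  b <- if (inherits(dsm_b, "dsm")) dsm_b$matrix else as.matrix(dsm_b)
  if (!all(dim(a) == dim(b))) stop("dissimilarity matrices differ in size")
  stats::cor(lower_tri_vec(a), lower_tri_vec(b), method = "spearman")
}

# Friedman omnibus + pairwise Wilcoxon signed-rank with Bonferroni over all
# pairs; shared by the acoustics and ROI condition statistics
friedman_posthoc <- function(mat, alpha = 0.05) {
  k <- ncol(mat)
  if (anyNA(mat)) stop("unbalanced input: missing cells")
  if (all(apply(mat, 2, stats::sd) < 1e-14) &&
      max(abs(sweep(mat, 1, rowMeans(mat)))) < 1e-14) {
    warning("constant data: Friedman test degenerate")
    fr <- list(statistic = c(`Friedman chi-squared` = 0),
               parameter = c(df = k - 1), p.value = 1)
  } else {
    fr <- stats::friedman.test(as.matrix(mat))
  }
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  ptab <- data.frame(a = colnames(mat)[pairs[1, ]],
                     b = colnames(mat)[pairs[2, ]],
                     p_raw = NA_real_)
  for (i in seq_len(n_pairs)) {
    x <- mat[, pairs[1, i]]; y <- mat[, pairs[2, i]]
    ptab$p_raw[i] <- if (max(abs(x - y)) < 1e-14) 1 else
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  }
  ptab$p_bonf <- pmin(1, ptab$p_raw * n_pairs)
  ptab$significant <- ptab$p_bonf < alpha
  list(chisq = unname(fr$statistic), df = unname(fr$parameter),
       p = fr$p.value, pairwise = ptab)
}

#' Friedman and post-hoc statistics for spectral centroids across categories
#'
#' Tests whether the per-stimulus spectral centroids differ across the
#' sound conditions (balanced design, stimuli matched across conditions by
#' rank position within category), with Bonferroni-corrected pairwise
#' Wilcoxon signed-rank follow-ups.
#'
#' @param centroids Numeric vector of per-stimulus centroids, or a
#'   block-by-condition matrix.
#' @param categories Condition label per centroid (ignored for matrix input).
#' @return List with `chisq`, `df`, `p` and a `pairwise` table
#'   (`p_raw`, `p_bonf`, `significant`).
#' @export
centroid_stats <- function(centroids, categories = NULL) {
  if (is.matrix(centroids)) {
    mat <- centroids
  } else {
    if (is.null(categories)) stop("supply condition labels")
    tab <- table(categories)
    if (length(unique(tab)) != 1)
      stop("unbalanced design: unequal stimulus counts per condition")
    conds <- names(tab)
    mat <- sapply(conds, function(cc) sort(centroids[categories == cc]))
  }
  friedman_posthoc(mat)
}
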