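# Representational similarity analysis: neural dissimilarity matrices from
# beta patterns, the two target models (vocalization/non-vocalization
# dissociation; vocalization distinction), multiple-regression RSA with
# repeated hold-out, and non-metric 2D embedding.

#' Neural dissimilarity matrix from a beta pattern
#'
#' Beta patterns are averaged across the selected runs per condition, the
#' cross-condition mean pattern is subtracted (preventing spuriously high
#' correlations from a shared activation profile), and pairwise Euclidean
#' distances between the centered condition patterns are computed.
#'
#' @param pattern A [beta_pattern()].
#' @param runs Run indices to average over; default all.
#' @return A [dsm()] with metric `"euclidean"`.
#' @export
compute_neural_dsm <- function(pattern, runs = NULL) {
  stopifnot(inherits(pattern, "beta_pattern"))
  if (is.null(runs)) runs <- seq_len(dim(pattern$values)[3])
  if (length(runs) < 1) stop("empty run subset")
  avg <- apply(pattern$values[, , runs, drop = FALSE], c(1, 2), mean)
  avg <- avg - rowMeans(avg) # subtract cross-condition mean pattern
  d <- as.matrix(stats::dist(t(avg)))
  dimnames(d) <- list(pattern$condition_labels, pattern$condition_labels)
  dsm(d, pattern$condition_labels, metric = "euclidean")
}

#' The two target model dissimilarity matrices
#'
#' The dissociation model posits maximum similarity (0) within the three
#' vocalizations and within the two non-vocalizations, and maximum
#' dissimilarity (2) between the groups. The distinction model posits
#' maximum dissimilarity (2) among vocalizations, maximum similarity (0)
#' among non-vocalizations, and intermediate dissimilarity (1) between
#' groups.
#'
#' @return List with elements `dissociation` and `distinction`, each a
#'   [dsm()] over the five categories.
#' @export
model_dsms <- function() {
  cats <- sound_categories()
  voc <- cats %in% vocal_categories()
  dis <- matrix(0, 5, 5, dimnames = list(cats, cats))
  dst <- matrix(0, 5, 5, dimnames = list(cats, cats))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    dis[i, j] <- if (voc[i] != voc[j]) 2 else 0
    dst[i, j] <- if (voc[i] && voc[j]) 2 else if (!voc[i] && !voc[j]) 0 else 1
  }
  list(dissociation = dsm(dis, cats, "model"),
       distinction = dsm(dst, cats, "model"))
}

#' Regress a neural DSM on model DSMs
#'
#' The strictly-lower triangles are vectorized, each vector z-scored, and
#' the neural vector regressed on the model vectors by ordinary least
#' squares without intercept (the z-scored response has zero mean).
#'
#' @param neural A [dsm()].
#' @param models Named list of model [dsm()]s over the same labels.
#' @return Named vector of regression coefficients (z units).
#' @export
regress_models <- function(neural, models) {
  nm <- if (inherits(neural, "dsm")) neural$matrix else as.matrix(neural)
  y <- lower_tri_vec(nm)
  if (stats::sd(y) < 1e-14) stop("zero-variance neural dissimilarity vector")
  Xm <- sapply(models, function(m) {
    mm <- if (inherits(m, "dsm")) m$matrix else as.matrix(m)
    if (!all(dim(mm) == dim(nm))) stop("model and neural DSM sizes differ")
    lower_tri_vec(mm)
  })
  Xz <- scale(Xm)
  if (qr(Xz)$rank < ncol(Xz)) stop("perfectly collinear model DSMs")
  yz <- as.numeric(scale(y))
  b <- solve(crossprod(Xz), crossprod(Xz, yz))
  stats::setNames(as.numeric(b), colnames(Xm))
}

#' Multiple-regression RSA with repeated hold-out
#'
#' Per iteration, a random subset of runs (default 3: the literal reading
#' of holding out all but three runs) is drawn, the neural DSM computed
#' from it and regressed on the model DSMs; the per-model coefficient
#' distribution over iterations gives the mean beta, a percentile
#' confidence interval, and a Wilcoxon signed-rank p-value against zero.
#'
#' @param pattern A [beta_pattern()].
#' @param models Named list of model [dsm()]s; default [model_dsms()].
#' @param n_iter Number of hold-out iterations (>= 100).
#' @param subset_size Runs used per iteration (must be < NRuns).
#' @param seed Integer seed.
#' @param ci_level Confidence level for the percentile interval.
#' @return An `rsa_result` data frame: model, beta (mean over iterations),
#'   ci_lo, ci_hi, p_vs_zero, n_iterations; per-iteration draws in
#'   `attr(, "iterations")`.
#' @export
repeated_holdout_rsa <- function(pattern, models = model_dsms(), n_iter = 1000L,
                                 subset_size = 3L, seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(pattern, "beta_pattern"), n_iter >= 100, subset_size >= 1)
  n_runs <- dim(pattern$values)[3]
  if (subset_size >= n_runs) stop("subset_size must be smaller than the number of runs")
  betas <- with_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      sub <- sample.int(n_runs, subset_size)
      regress_models(compute_neural_dsm(pattern, runs = sub), models)
    }, numeric(length(models))))
  })
  colnames(betas) <- names(models)
  a <- (1 - ci_level) / 2
  out <- data.frame(
    model = names(models),
    beta = colMeans(betas),
    ci_lo = apply(betas, 2, stats::quantile, probs = a),
    ci_hi = apply(betas, 2, stats::quantile, probs = 1 - a),
    p_vs_zero = apply(betas, 2, function(b)
      suppressWarnings(stats::wilcox.test(b, mu = 0)$p.value)),
    n_iterations = n_iter, row.names = NULL)
  attr(out, "iterations") <- betas
  class(out) <- c("rsa_result", class(out))
  out
}

#' Non-metric 2D embedding of a dissimilarity matrix
#'
#' Kruskal non-metric multidimensional scaling (stress-1 minimized), best
#' of several seeded random restarts; used to project the representational
#' geometry of the conditions onto a plane.
#'
#' @param d A [dsm()] or symmetric matrix.
#' @param dims Embedding dimension.
#' @param n_restarts Random initializations (best solution kept).
#' @param seed Integer seed.
#' @return List with `coords` (label-by-dims matrix) and `stress`
#'   (Kruskal stress-1, fraction).
#' @export
mds_embed <- function(d, dims = 2L, n_restarts = 8L, seed = 1L) {
  m <- if (inherits(d, "dsm")) d$matrix else as.matrix(d)
  check_dsm(m)
  labels <- rownames(m)
  n <- nrow(m)
  if (max(m) < 1e-14) {
    warning("all-zero dissimilarities: returning coincident points")
    coords <- matrix(0, n, dims, dimnames = list(labels, NULL))
    return(list(coords = coords, stress = 0))
  }
  dd <- stats::as.dist(m + 1e-9) # isoMDS rejects exact zero off-diagonals
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) stats::cmdscale(dd, k = dims)
      else matrix(stats::rnorm(n * dims), n, dims)
      if (ncol(init) < dims) init <- cbind(init, matrix(0, n, dims - ncol(init)))
      fit <- tryCatch(
        suppressMessages(MASS::isoMDS(dd, y = init, k = dims, trace = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress)) best <- fit
    }
  })
  if (is.null(best)) stop("non-metric scaling failed to converge")
  coords <- best$points
  rownames(coords) <- labels
  list(coords = coords, stress = best$stress / 100) # isoMDS reports percent
}
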