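# Leave-one-run-out multivoxel pattern classification: linear SVM trained
# on beta patterns from all runs but one and tested on the held-out run,
# chance-level tests, and cross-classifier comparisons.

#' Leave-one-run-out SVM classification of beta patterns
#'
#' For each fold, a linear support vector machine (cost 1, one-vs-one for
#' multiclass) is trained on the beta patterns of all runs but one and
#' tested on the held-out run; features are standardized with training-fold
#' statistics only. Accuracy is reported per fold and averaged, with a
#' one-tailed test against chance.
#'
#' @param pattern A [beta_pattern()].
#' @param class_labels Conditions to classify (>= 2, subset of the
#'   pattern's conditions); defaults to all conditions.
#' @param kernel SVM kernel (linear by default).
#' @param cost SVM regularization constant.
#' @return A `classification_result`: `fold_accuracies`, `mean_accuracy`,
#'   `chance` (1/#classes), `n_folds` (= number of runs), `p_vs_chance`,
#'   and `fold_predictions` (per-fold predicted labels, test order).
#' @export
loro_crossval_svm <- function(pattern, class_labels = NULL, kernel = "linear",
                              cost = 1) {
  stopifnot(inherits(pattern, "beta_pattern"))
  if (is.null(class_labels)) class_labels <- pattern$condition_labels
  if (length(class_labels) < 2) stop("need at least 2 classes")
  missing <- setdiff(class_labels, pattern$condition_labels)
  if (length(missing)) stop("class(es) absent from pattern: ",
                            paste(missing, collapse = ", "))
  v <- pattern$values
  n_runs <- dim(v)[3]
  if (n_runs < 4) stop("need at least 4 runs for leave-one-run-out")
  ci <- match(class_labels, pattern$condition_labels)
  # samples: one per condition per run; features = voxels
  feats <- t(sapply(seq_len(n_runs), function(r) as.vector(v[, ci, r])))
  # reshape to (run*class) x voxel
  X <- do.call(rbind, lapply(seq_len(n_runs), function(r) t(v[, ci, r])))
  y <- factor(rep(class_labels, times = n_runs), levels = class_labels)
  run_of <- rep(seq_len(n_runs), each = length(ci))
  folds <- lapply(seq_len(n_runs), function(test_run) {
    tr <- run_of != test_run
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = kernel, cost = cost, scale = FALSE)
    pred <- stats::predict(fit, Xte)
    list(accuracy = mean(pred == y[!tr]), predicted = as.character(pred))
  })
  acc <- vapply(folds, `[[`, numeric(1), "accuracy")
  out <- structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                        chance = 1 / length(class_labels),
                        n_folds = n_runs, class_labels = class_labels,
                        fold_predictions = lapply(folds, `[[`, "predicted")),
                   class = "classification_result")
  out$p_vs_chance <- test_vs_chance(out)
  out
}

#' Pairwise classification of vocalizations versus their scrambled versions
#'
#' One two-class leave-one-run-out classification per matched pair (coo vs
#' scrambled coo, scream vs scrambled scream, aggressive vs scrambled
#' aggressive), chance 1/2.
#'
#' @param pattern A [beta_pattern()] containing the three vocalization
#'   conditions and their `scrambled_*` counterparts.
#' @param pairs Optional list of 2-vectors naming the pairs.
#' @inheritParams loro_crossval_svm
#' @return Named list of `classification_result`s, one per pair.
#' @export
pairwise_voc_vs_scrambled <- function(pattern, pairs = NULL, cost = 1) {
  if (is.null(pairs)) {
    voc <- intersect(vocal_categories(), pattern$condition_labels)
    pairs <- lapply(voc, function(v) c(v, paste0("scrambled_", v)))
    names(pairs) <- voc
  }
  lapply(pairs, function(p) {
    if (!all(p %in% pattern$condition_labels))
      stop("unmatched pair: ", paste(p, collapse = " / "))
    loro_crossval_svm(pattern, class_labels = p, cost = cost)
  })
}

#' One-tailed test of fold accuracies against chance
#'
#' The per-fold accuracies are compared with the chance constant. The
#' default is a Wilcoxon signed-rank test of accuracy minus chance (the
#' one-sample formulation of the problem); `mode = "ranksum"` performs a
#' literal rank-sum test of the accuracies against a constant vector at
#' chance.
#'
#' @param result A `classification_result`.
#' @param mode `"signedrank"` or `"ranksum"`.
#' @return One-tailed p-value (1 with a warning when every fold equals chance).
#' @export
test_vs_chance <- function(result, mode = c("signedrank", "ranksum")) {
  mode <- match.arg(mode)
  acc <- result$fold_accuracies
  if (length(acc) < 2) stop("need at least 2 folds")
  d <- acc - result$chance
  if (all(abs(d) < 1e-12)) {
    warning("all folds at chance: test undefined, returning p = 1")
    return(1)
  }
  if (mode == "signedrank") {
    suppressWarnings(stats::wilcox.test(acc, mu = result$chance,
                                        alternative = "greater")$p.value)
  } else {
    suppressWarnings(stats::wilcox.test(acc, rep(result$chance, length(acc)),
                                        alternative = "greater")$p.value)
  }
}

#' Compare classification accuracies across classifiers
#'
#' Omnibus Kruskal-Wallis test over the per-fold accuracies of two or more
#' classification results, plus pairwise comparisons: paired Wilcoxon
#' signed-rank when fold counts match matched designs (`paired = TRUE`),
#' rank-sum otherwise.
#'
#' @param results List of `classification_result`s.
#' @param paired Use paired tests for the pairwise table.
#' @return List with `kruskal_p`, `kruskal_stat`, and `pairwise` table.
#' @export
compare_classifiers <- function(results, paired = TRUE) {
  if (length(results) < 2) stop("need at least 2 result sets")
  accs <- lapply(results, function(r) r$fold_accuracies)
  if (is.null(names(accs))) names(accs) <- paste0("clf", seq_along(accs))
  if (paired && length(unique(vapply(accs, length, integer(1)))) != 1)
    stop("paired comparison requires equal fold counts")
  kw <- stats::kruskal.test(accs)
  cmb <- utils::combn(length(accs), 2)
  pw <- data.frame(a = names(accs)[cmb[1, ]], b = names(accs)[cmb[2, ]],
                   p = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    x <- accs[[cmb[1, i]]]; y <- accs[[cmb[2, i]]]
    pw$p[i] <- if (paired) {
      if (max(abs(x - y)) < 1e-12) 1 else
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    } else suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  list(kruskal_p = kw$p.value, kruskal_stat = unname(kw$statistic),
       pairwise = pw)
}

#' Permute condition labels independently within each run
#'
#' Null-model helper: returns a beta pattern whose condition labels are
#' randomly permuted per run, destroying any true condition structure while
#' preserving run and voxel statistics.
#'
#' @param pattern A [beta_pattern()].
#' @param seed Integer seed.
#' @return A [beta_pattern()].
#' @export
permute_labels_within_runs <- function(pattern, seed = 1L) {
  v <- pattern$values
  v2 <- with_seed(seed, {
    for (r in seq_len(dim(v)[3])) v[, , r] <- v[, sample.int(dim(v)[2]), r]
    v
  })
  beta_pattern(v2, pattern$condition_labels, pattern$run_ids, pattern$roi_label)
}
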