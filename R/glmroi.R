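# Block-design GLM with a MION hemodynamic kernel, simplified noise-PC
# denoising, contrast t-maps, two-step split-half ROI selection, percent
# signal change, FIR time courses, and nonparametric ROI condition
# statistics.

#' MION hemodynamic response kernel
#'
#' Gamma-variate kernel for the iron-oxide contrast agent: slower and
#' longer-tailed than the BOLD response (default peak near 4 s, under 10%
#' of peak by 30 s), normalized to unit sum. The sign convention (raw MION
#' signal decreases on activation) is handled by the pipeline, so the
#' kernel itself is positive.
#'
#' @param tr_s Sampling interval (TR) in seconds.
#' @param duration_s Kernel support in seconds.
#' @param shape,scale Gamma shape and scale; mode at `(shape - 1) * scale` s.
#' @return Numeric kernel sampled at the TR, summing to 1.
#' @export
mion_hrf <- function(tr_s, duration_s = 40, shape = 2, scale = 4) {
  stopifnot(tr_s > 0)
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  t <- seq(0, duration_s, by = tr_s)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / sum(k)
}

# shifted Legendre polynomial drift basis (order 0 = intercept); orders >= 1
# are centered so the intercept estimates the baseline level
drift_basis <- function(n_frames, drift_order) {
  x <- seq(-1, 1, length.out = n_frames)
  cols <- sapply(0:drift_order, function(p) x^p)
  cols <- as.matrix(cols)
  for (j in seq_len(ncol(cols))[-1]) cols[, j] <- cols[, j] - mean(cols[, j])
  colnames(cols) <- c("baseline", if (drift_order >= 1) paste0("drift", seq_len(drift_order)))
  cols
}

#' Build a design matrix for one run
#'
#' One regressor per sound condition (condition boxcar convolved with the
#' hemodynamic kernel); the silent blocks are left unmodelled and form the
#' implicit baseline. Polynomial drift and optional nuisance columns are
#' appended; the initial dummy volumes are flagged for exclusion from
#' fitting.
#'
#' @param design A `run_design`.
#' @param hrf Hemodynamic kernel sampled at the TR.
#' @param drift_order Highest polynomial drift order (0 = intercept only).
#' @param nuisance Optional frame-by-regressor matrix (e.g. motion parameters).
#' @return A `design_matrix`: list with `X` (frame x column), `condition_cols`,
#'   `dummy_mask` (TRUE = excluded dummy frame), `frame_times`, `tr_s`.
#' @export
build_design_matrix <- function(design, hrf, drift_order = 2L, nuisance = NULL) {
  stopifnot(inherits(design, "run_design"))
  nv <- design$n_vols
  box <- condition_boxcars(design)
  present <- colSums(box) > 0
  if (any(!present))
    stop("condition(s) with no blocks in this run: ",
         paste(colnames(box)[!present], collapse = ", "))
  xc <- apply(box, 2, function(col)
    stats::convolve(col, rev(hrf), type = "open")[seq_len(nv)])
  drift <- drift_basis(nv, drift_order)
  X <- cbind(xc, drift)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nv)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  structure(list(X = X, condition_cols = colnames(box),
                 dummy_mask = seq_len(nv) <= design$n_dummies,
                 frame_times = (seq_len(nv) - 1) * design$tr_s,
                 tr_s = design$tr_s, run_id = design$run_id),
            class = "design_matrix")
}

# stack run-wise designs for a fixed-effects fit: condition columns shared,
# drift/nuisance columns block-diagonal per run
stack_designs <- function(dm_list) {
  conds <- dm_list[[1]]$condition_cols
  for (dm in dm_list) stopifnot(identical(dm$condition_cols, conds))
  Xc <- do.call(rbind, lapply(dm_list, function(dm) dm$X[, conds, drop = FALSE]))
  other <- lapply(dm_list, function(dm)
    dm$X[, setdiff(colnames(dm$X), conds), drop = FALSE])
  p_other <- vapply(other, ncol, integer(1))
  Xo <- matrix(0, nrow = nrow(Xc), ncol = sum(p_other))
  cn <- character(sum(p_other))
  r0 <- 0L; c0 <- 0L
  for (i in seq_along(other)) {
    nr <- nrow(other[[i]])
    Xo[r0 + seq_len(nr), c0 + seq_len(p_other[i])] <- other[[i]]
    cn[c0 + seq_len(p_other[i])] <- paste0("run", i, "_", colnames(other[[i]]))
    r0 <- r0 + nr; c0 <- c0 + p_other[i]
  }
  colnames(Xo) <- cn
  list(X = cbind(Xc, Xo),
       condition_cols = conds,
       dummy_mask = unlist(lapply(dm_list, function(dm) dm$dummy_mask)))
}

#' Fit a voxel-wise ordinary least squares GLM
#'
#' @param Y Frame-by-voxel data matrix.
#' @param X Frame-by-regressor design matrix.
#' @param dummy_mask Optional logical vector of frames to exclude.
#' @return A `glm_fit`: `betas` (regressor x voxel), `sigma2`, `df`,
#'   `XtXinv`, `colnames`.
#' @export
fit_glm <- function(Y, X, dummy_mask = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!is.null(dummy_mask)) {
    Y <- Y[!dummy_mask, , drop = FALSE]
    X <- X[!dummy_mask, , drop = FALSE]
  }
  stopifnot(nrow(Y) == nrow(X))
  if (nrow(X) <= ncol(X)) stop("more regressors than frames")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  structure(list(betas = betas, sigma2 = colSums(res^2) / df, df = df,
                 XtXinv = chol2inv(chol(crossprod(X))),
                 colnames = colnames(X)),
            class = "glm_fit")
}

#' Contrast t-statistics from a GLM fit
#'
#' @param fit A [fit_glm()] result.
#' @param weights Named contrast weights over regressors (missing = 0).
#' @return List with `t` (per voxel), `effect` (c'beta) and `df`.
#' @export
contrast_t <- function(fit, weights) {
  cvec <- numeric(length(fit$colnames))
  names(cvec) <- fit$colnames
  bad <- setdiff(names(weights), fit$colnames)
  if (length(bad)) stop("unknown regressor(s) in contrast: ", paste(bad, collapse = ", "))
  cvec[names(weights)] <- weights
  eff <- drop(t(cvec) %*% fit$betas)
  se <- sqrt(fit$sigma2 * drop(t(cvec) %*% fit$XtXinv %*% cvec))
  list(t = eff / se, effect = eff, df = fit$df)
}

#' Vocalizations-versus-baseline contrast weights
#'
#' Mean of the three vocalization regressors against the implicit silent
#' baseline; `versus = "nonvocal"` subtracts the mean of the two
#' non-vocalization regressors instead.
#'
#' @param condition_cols Condition regressor names.
#' @param versus `"silence"` or `"nonvocal"`.
#' @return Named weight vector.
#' @export
vocalization_contrast <- function(condition_cols, versus = c("silence", "nonvocal")) {
  versus <- match.arg(versus)
  voc <- intersect(vocal_categories(), condition_cols)
  w <- stats::setNames(rep(1 / length(voc), length(voc)), voc)
  if (versus == "nonvocal") {
    nv <- intersect(nonvocal_categories(), condition_cols)
    w <- c(w, stats::setNames(rep(-1 / length(nv), length(nv)), nv))
  }
  w
}

#' Cross-validated noise-PC denoising
#'
#' Simplified task-based denoising: voxels whose task model has negative
#' leave-one-run-out cross-validated R-squared form a noise pool; principal
#' components of the pool's run-wise time series are candidate nuisance
#' regressors, added one at a time; the number of components k is chosen at
#' the maximum mean cross-validated R-squared of the task model (search
#' stops once the improvement falls below 0.1 percentage point). The
#' denoised data are the original data minus their projection onto the
#' selected per-run components.
#'
#' @param Y_list Per-run frame-by-voxel matrices (dummies already excluded).
#' @param X_list Per-run `design_matrix` objects (or matrices with attribute
#'   `condition_cols`).
#' @param k_max Maximum number of noise components to consider.
#' @return List with `Y` (denoised per-run list), `k` (chosen), `noise_pool`
#'   (logical per voxel), `cv_r2_by_k` (mean cross-validated R-squared per k).
#' @export
noise_pc_denoise <- function(Y_list, X_list, k_max = 20L) {
  stopifnot(length(Y_list) >= 2, length(Y_list) == length(X_list))
  n_runs <- length(Y_list)
  getX <- function(i) if (inherits(X_list[[i]], "design_matrix")) X_list[[i]] else
    stop("X_list must contain design_matrix objects")
  conds <- getX(1)$condition_cols
  prep <- lapply(seq_len(n_runs), function(i) {
    dm <- getX(i)
    keep <- !dm$dummy_mask
    X <- dm$X[keep, , drop = FALSE]
    other <- setdiff(colnames(X), conds)
    Xd <- X[, other, drop = FALSE] # drift/nuisance
    Y <- Y_list[[i]]
    if (nrow(Y) == length(keep)) Y <- Y[keep, , drop = FALSE]
    # residualize Y and task regressors against drift once, per run
    Pd <- Xd %*% solve(crossprod(Xd), t(Xd))
    list(Y = Y - Pd %*% Y, Xt = X[, conds, drop = FALSE] - Pd %*% X[, conds, drop = FALSE])
  })
  cv_r2 <- function(pcs) { # pcs: per-run frame x k (or NULL)
    resid_pc <- lapply(seq_len(n_runs), function(i) {
      Y <- prep[[i]]$Y; Xt <- prep[[i]]$Xt
      if (!is.null(pcs) && ncol(pcs[[i]]) > 0) {
        P <- pcs[[i]]
        proj <- P %*% solve(crossprod(P), t(P))
        Y <- Y - proj %*% Y
        Xt <- Xt - proj %*% Xt
      }
      list(Y = Y, Xt = Xt)
    })
    num <- 0; den <- 0
    r2_vox <- 0
    for (test in seq_len(n_runs)) {
      Xtr <- do.call(rbind, lapply(setdiff(seq_len(n_runs), test),
                                   function(i) resid_pc[[i]]$Xt))
      Ytr <- do.call(rbind, lapply(setdiff(seq_len(n_runs), test),
                                   function(i) resid_pc[[i]]$Y))
      b <- solve(crossprod(Xtr), crossprod(Xtr, Ytr))
      pred <- resid_pc[[test]]$Xt %*% b
      err <- resid_pc[[test]]$Y - pred
      num <- num + colSums(err^2)
      den <- den + colSums(resid_pc[[test]]$Y^2)
    }
    1 - num / pmax(den, 1e-12)
  }
  r2_0 <- cv_r2(NULL)
  pool <- r2_0 < 0
  if (!any(pool)) {
    warning("empty noise pool: no voxels with negative cross-validated R^2; k = 0")
    return(list(Y = Y_list, k = 0L, noise_pool = pool,
                cv_r2_by_k = c(`0` = mean(r2_0))))
  }
  pcs_full <- lapply(seq_len(n_runs), function(i) {
    pn <- prep[[i]]$Y[, pool, drop = FALSE]
    k <- min(k_max, nrow(pn) - 1L, ncol(pn))
    stats::prcomp(pn, center = TRUE, scale. = FALSE, rank. = k)$x
  })
  k_cap <- min(k_max, min(vapply(pcs_full, ncol, integer(1))))
  track <- c(`0` = mean(r2_0))
  best_k <- 0L; best_r2 <- mean(r2_0)
  for (k in seq_len(k_cap)) {
    rk <- mean(cv_r2(lapply(pcs_full, function(p) p[, seq_len(k), drop = FALSE])))
    track <- c(track, stats::setNames(rk, as.character(k)))
    if (rk > best_r2 + 1e-12) { best_r2 <- rk; best_k <- k }
    if (rk - track[length(track) - 1L] < 0.001) break
  }
  Y_den <- Y_list
  if (best_k > 0) {
    for (i in seq_len(n_runs)) {
      P <- pcs_full[[i]][, seq_len(best_k), drop = FALSE]
      Yi <- Y_list[[i]]
      offset <- nrow(Yi) - nrow(P) # leading dummy frames, if retained
      gamma <- solve(crossprod(P), crossprod(P, Yi[offset + seq_len(nrow(P)), , drop = FALSE]))
      Yi[offset + seq_len(nrow(P)), ] <- Yi[offset + seq_len(nrow(P)), , drop = FALSE] - P %*% gamma
      Y_den[[i]] <- Yi
    }
  }
  list(Y = Y_den, k = best_k, noise_pool = pool, cv_r2_by_k = track)
}

#' Percent signal change per condition relative to the silent baseline
#'
#' Per run, a GLM with condition regressors and centered drift is fitted;
#' the intercept estimates the silent baseline and the percent signal
#' change of a condition is 100 x beta / baseline. Values are averaged
#' across runs with the SEM reported. With `mion_sign_flip = TRUE` the sign
#' is inverted so activation is positive under the raw MION polarity.
#'
#' @param Y_list Per-run frame-by-voxel matrices (raw signal).
#' @param designs Per-run `run_design` objects.
#' @param hrf Hemodynamic kernel at the TR.
#' @param drift_order Polynomial drift order.
#' @param mion_sign_flip Invert the sign (raw MION polarity input).
#' @return A `psc_result` data frame: condition, mean percent signal change,
#'   SEM across runs, n_runs; the silence row is 0 by construction.
#' @export
percent_signal_change <- function(Y_list, designs, hrf, drift_order = 2L,
                                  mion_sign_flip = FALSE) {
  stopifnot(length(Y_list) == length(designs))
  if (!any(designs[[1]]$blocks$condition == "silence"))
    stop("design contains no silent blocks to serve as baseline")
  conds <- designs[[1]]$condition_labels
  per_run <- sapply(seq_along(Y_list), function(i) {
    dm <- build_design_matrix(designs[[i]], hrf, drift_order = drift_order)
    fit <- fit_glm(rowMeans(as.matrix(Y_list[[i]])), dm$X, dm$dummy_mask)
    base <- fit$betas["baseline", 1]
    if (abs(base) < 1e-9) stop("zero baseline level in run ", i)
    sgn <- if (mion_sign_flip) -1 else 1
    100 * sgn * fit$betas[conds, 1] / base
  })
  per_run <- matrix(per_run, nrow = length(conds),
                    dimnames = list(conds, NULL))
  out <- data.frame(condition = c(conds, "silence"),
                    psc = c(rowMeans(per_run), 0),
                    sem = c(apply(per_run, 1, stats::sd) / sqrt(ncol(per_run)), 0),
                    n_runs = length(Y_list))
  attr(out, "per_run") <- per_run
  class(out) <- c("psc_result", class(out))
  out
}

# zero-padded centered 3-point moving average
smooth3 <- function(x) {
  as.numeric(stats::filter(c(0, x, 0), rep(1 / 3, 3), sides = 2))[1 + seq_along(x)]
}

#' FIR time course per condition
#'
#' Finite-impulse-response deconvolution: one regressor per post-onset TR
#' lag per condition, covering the window from block onset to the end of
#' the following silent block; no hemodynamic shape is assumed. The mean
#' course (percent of baseline) is smoothed with a centered 3-point moving
#' average.
#'
#' @param Y_list Per-run frame-by-voxel matrices.
#' @param designs Per-run `run_design` objects.
#' @param n_lags Window length in TRs; default covers block + silence.
#' @param smooth Apply the 3-point moving average.
#' @param drift_order Polynomial drift order.
#' @return List with `lags_s`, `timecourse` (lag x condition, percent
#'   signal change), `sem` (across runs), `raw` (unsmoothed).
#' @export
fir_timecourse <- function(Y_list, designs, n_lags = NULL, smooth = TRUE,
                           drift_order = 2L) {
  d1 <- designs[[1]]
  if (is.null(n_lags)) {
    sound <- d1$blocks[d1$blocks$condition != "silence", ][1, ]
    sil <- d1$blocks[d1$blocks$condition == "silence", ][1, ]
    n_lags <- round((sound$duration_s + sil$duration_s) / d1$tr_s)
  }
  conds <- d1$condition_labels
  fir_run <- function(Y, design) {
    nv <- design$n_vols
    onsets <- design$blocks[design$blocks$condition != "silence", ]
    Xf <- matrix(0, nv, length(conds) * n_lags)
    colnames(Xf) <- paste0(rep(conds, each = n_lags), "_lag",
                           rep(seq_len(n_lags) - 1L, times = length(conds)))
    for (i in seq_len(nrow(onsets))) {
      v0 <- round(onsets$onset_s[i] / design$tr_s) + 1L
      ci <- match(onsets$condition[i], conds)
      for (l in seq_len(n_lags)) {
        v <- v0 + l - 1L
        if (v <= nv) Xf[v, (ci - 1L) * n_lags + l] <- 1
      }
    }
    # contiguous blocks tile every frame, so the FIR basis spans the
    # intercept: fit without it and reference the estimates to the trimmed
    # end of the silent period (last lags) afterwards
    drift <- drift_basis(nv, max(1L, drift_order))[, -1, drop = FALSE]
    X <- cbind(Xf, drift)
    y <- rowMeans(as.matrix(Y))
    fit <- fit_glm(y, X, seq_len(nv) <= design$n_dummies)
    e <- matrix(fit$betas[seq_len(ncol(Xf)), 1],
                nrow = n_lags, dimnames = list(NULL, conds))
    ref_lags <- max(2L, n_lags - 2L):n_lags
    base_level <- mean(y[!(seq_len(nv) <= design$n_dummies)])
    100 * (e - mean(e[ref_lags, ])) / base_level
  }
  per_run <- lapply(seq_along(Y_list), function(i) fir_run(Y_list[[i]], designs[[i]]))
  arr <- simplify2array(per_run) # lag x cond x run
  mean_tc <- apply(arr, c(1, 2), mean)
  sem_tc <- apply(arr, c(1, 2), stats::sd) / sqrt(length(per_run))
  sm <- if (smooth) apply(mean_tc, 2, smooth3) else mean_tc
  list(lags_s = (seq_len(n_lags) - 1L) * d1$tr_s, timecourse = sm,
       sem = sem_tc, raw = mean_tc)
}

#' ROI selection rule
#'
#' @param combined_voxel_p Voxel-wise familywise threshold for the combined
#'   map (Bonferroni surrogate for FWE).
#' @param cluster_min_vox Minimum cluster extent (voxels, 6-connectivity).
#' @param cluster_fdr_q FDR level for the cluster-mass filter.
#' @param individual_p_unc Uncorrected threshold each split-half map must reach.
#' @return An `roi_selection_rule` list.
#' @export
roi_selection_rule <- function(combined_voxel_p = 0.05, cluster_min_vox = 10L,
                               cluster_fdr_q = 0.05, individual_p_unc = 0.001) {
  stopifnot(combined_voxel_p > 0, combined_voxel_p < 1, cluster_min_vox >= 1,
            individual_p_unc > 0, individual_p_unc < 1)
  structure(list(combined_voxel_p = combined_voxel_p,
                 cluster_min_vox = as.integer(cluster_min_vox),
                 cluster_fdr_q = cluster_fdr_q,
                 individual_p_unc = individual_p_unc),
            class = "roi_selection_rule")
}

# label 6-connected components of a logical 3D array
label_clusters_6 <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(nb))) {
        cc <- co + nb[r, ]
        if (any(cc < 1) || any(cc > dims)) next
        li <- cc[1] + (cc[2] - 1L) * dims[1] + (cc[3] - 1L) * dims[1] * dims[2]
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
  }
  labels
}

#' Two-step split-half ROI selection
#'
#' Step 1: the combined t-map is thresholded voxel-wise at a Bonferroni
#' familywise surrogate; 6-connected clusters of at least
#' `cluster_min_vox` voxels are kept if they pass a Benjamini-Hochberg
#' filter on cluster-mass p-values (exponential-excess approximation).
#' Step 2: a cluster is retained only if every split-half map (per subject
#' and hemisphere, computed from the selection half of the runs) is
#' suprathreshold at the uncorrected individual threshold somewhere inside
#' the cluster.
#'
#' @param combined_tmap List with `t` (3D array) and `df`.
#' @param split_tmaps List of split-half maps, same structure and grid.
#' @param rule An [roi_selection_rule()].
#' @param mask Optional logical 3D in-brain mask.
#' @return List of ROI masks (logical 3D arrays); empty list if none survive.
#' @export
select_rois <- function(combined_tmap, split_tmaps, rule = roi_selection_rule(),
                        mask = NULL) {
  tmap <- combined_tmap$t
  df <- combined_tmap$df
  if (is.null(mask)) mask <- array(TRUE, dim(tmap))
  for (sm in split_tmaps) stopifnot(all(dim(sm$t) == dim(tmap)))
  n_mask <- sum(mask)
  u <- stats::qt(1 - rule$combined_voxel_p / n_mask, df)
  supra <- (tmap > u) & mask
  if (!any(supra)) return(list())
  labels <- label_clusters_6(supra)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  ids <- ids[sizes >= rule$cluster_min_vox]
  if (!length(ids)) return(list())
  # cluster-mass p: under the null, t excesses above u are approximately
  # exponential with rate equal to the t-distribution hazard at u
  rate <- stats::dt(u, df) / stats::pt(u, df, lower.tail = FALSE)
  pmass <- vapply(ids, function(i) {
    vox <- labels == i
    stats::pgamma(sum(tmap[vox] - u), shape = sum(vox), rate = rate,
                  lower.tail = FALSE)
  }, numeric(1))
  keep <- stats::p.adjust(pmass, method = "BH") < rule$cluster_fdr_q
  ids <- ids[keep]
  out <- list()
  for (i in ids) {
    vox <- labels == i
    ok <- all(vapply(split_tmaps, function(sm) {
      ui <- stats::qt(1 - rule$individual_p_unc, sm$df)
      any(sm$t[vox] > ui)
    }, logical(1)))
    if (ok) out[[length(out) + 1L]] <- vox
  }
  out
}

#' Nonparametric ROI condition statistics
#'
#' Friedman omnibus over the run-by-condition percent-signal-change table,
#' Bonferroni-corrected pairwise Wilcoxon signed-rank tests (45 pairs for
#' 10 conditions), and per-condition Wilcoxon signed-rank tests against the
#' silent baseline (zero).
#'
#' @param psc_by_run Run-by-condition matrix of percent signal change.
#' @return List with `chisq`, `df`, `p`, `pairwise` (Bonferroni table) and
#'   `vs_silence` (per-condition signed-rank p-values).
#' @export
roi_condition_stats <- function(psc_by_run) {
  psc_by_run <- as.matrix(psc_by_run)
  if (nrow(psc_by_run) < 6) stop("need at least 6 runs")
  res <- friedman_posthoc(psc_by_run)
  res$vs_silence <- data.frame(
    condition = colnames(psc_by_run),
    p = apply(psc_by_run, 2, function(x)
      if (max(abs(x)) < 1e-14) 1 else
        suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)))
  res
}
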