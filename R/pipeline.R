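# Configuration-driven orchestration of the synthetic pipeline stages, in
# dependency order: synth -> acoustics / scrambling -> glmroi -> mvpa / rsa.
# Each stage writes delimited artifacts; the manifest records content
# hashes so that identical seeds yield identical outputs.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived by [derive_seed()].
#' @param stages Stages to run, in any order (dependencies are checked).
#' @param n_per_category Demo stimuli per category.
#' @param n_runs Runs for the design/GLM/MVPA stages.
#' @param n_voxels Voxels for beta-pattern simulation.
#' @param rsa_iter Hold-out iterations for the RSA stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("synth", "acoustics", "scrambling",
                                       "glmroi", "mvpa", "rsa"),
                            n_per_category = 2L, n_runs = 8L,
                            n_voxels = 40L, rsa_iter = 1000L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_per_category = n_per_category, n_runs = n_runs,
                 n_voxels = n_voxels, rsa_iter = rsa_iter),
            class = "pipeline_config")
}

#' Run the synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on fully synthetic
#' inputs: stimulus synthesis, acoustic characterization (features, RDM,
#' dendrogram, average modulation power spectra), scrambling with QC,
#' block-design GLM with percent signal change, leave-one-run-out
#' classification, and model-regression RSA. Every artifact is listed in
#' the returned manifest with its MD5 content hash; the master seed and
#' stage parameters are logged.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a data frame manifest (artifact class, file, md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  need <- function(stage, dep) {
    if (stage %in% stages && !(dep %in% stages))
      stop("stage '", stage, "' requires stage '", dep, "' to be enabled")
  }
  need("acoustics", "synth"); need("scrambling", "synth")
  need("glmroi", "synth"); need("mvpa", "synth"); need("rsa", "synth")
  message("pipeline seed=", config$seed, " stages=", paste(stages, collapse = ","))
  art <- list()
  put <- function(class, path) art[[length(art) + 1L]] <<- c(class, path)
  tab_out <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(obj, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  stimuli <- NULL
  designs <- NULL
  pat <- NULL
  if ("synth" %in% stages) {
    sseed <- derive_seed(config$seed, "synth")
    stimuli <- list()
    for (cat in sound_categories()) {
      for (i in seq_len(config$n_per_category)) {
        sp <- stimulus_spec(cat, seed = derive_seed(sseed, paste0(cat, i)))
        st <- generate_stimulus(sp)
        p <- file.path(config$out_dir, sprintf("stim_%s_%02d.wav", cat, i))
        write_wav(st$wave, p, st$sample_rate)
        put("stimuli", p)
        stimuli[[paste0(cat, i)]] <- st
      }
    }
    designs <- generate_run_design(config$n_runs, seed = derive_seed(sseed, "design"))
    blk <- do.call(rbind, lapply(designs, function(d)
      cbind(run = d$run_id, d$blocks[, c("condition", "onset_s", "duration_s")])))
    put("designs", tab_out(blk, "run_designs.tsv"))
  }
  if ("acoustics" %in% stages) {
    feats <- do.call(rbind, lapply(names(stimuli), function(nm) {
      f <- extract_features(stimuli[[nm]])
      cbind(stimulus = nm, category = stimuli[[nm]]$category, f)
    }))
    put("features", tab_out(feats, "acoustic_features.tsv"))
    tab <- load_category_features()
    feat_cols <- c("pssd", "pscv", "rms_db", "f0_mean", "f0_sd", "hnr")
    vec <- as.matrix(tab[, feat_cols]); rownames(vec) <- tab$category
    rdm <- compute_rdm(vec, standardize = TRUE)
    put("RDMs", tab_out(cbind(label = rdm$labels, as.data.frame(rdm$matrix)),
                        "feature_rdm.tsv"))
    dend <- cluster_dendrogram(rdm)
    pnw <- file.path(config$out_dir, "feature_dendrogram.nwk")
    writeLines(c(dend$newick, sprintf("# cophenetic_r\t%.6f", dend$cophenetic_r)), pnw)
    put("RDMs", pnw)
    # per-category average MPS marginals
    mps_rows <- lapply(sound_categories(), function(cat) {
      ms <- lapply(grep(cat, names(stimuli), value = TRUE), function(nm) {
        compute_mps(gammatone_spectrogram(stimuli[[nm]]$wave,
                                          stimuli[[nm]]$sample_rate))
      })
      avg <- average_mps(ms)
      marg <- 10 * log10(colSums(10^(avg$power_db / 10)))
      data.frame(category = cat, rate_hz = avg$rate_hz, power_db = marg - max(marg))
    })
    put("MPS", tab_out(do.call(rbind, mps_rows), "mps_rate_marginals.tsv"))
  }
  if ("scrambling" %in% stages) {
    qc_rows <- lapply(names(stimuli), function(nm) {
      pr <- scramble_params(seed = derive_seed(config$seed, paste0("scr", nm)))
      sc <- scramble_waveform(stimuli[[nm]], pr)
      p <- file.path(config$out_dir, sprintf("stim_%s_scrambled.wav", nm))
      write_wav(sc$wave, p, sc$sample_rate)
      put("stimuli", p)
      qc <- scramble_qc(stimuli[[nm]], sc)
      data.frame(stimulus = nm, max_abs_band_diff_db = qc$max_abs_band_diff_db,
                 envelope_r = qc$envelope_r)
    })
    put("scramble_qc", tab_out(do.call(rbind, qc_rows), "scramble_qc.tsv"))
  }
  if (is.null(designs) && any(c("glmroi", "mvpa", "rsa") %in% stages)) {
    designs <- generate_run_design(config$n_runs,
                                   seed = derive_seed(derive_seed(config$seed, "synth"), "design"))
  }
  if ("glmroi" %in% stages) {
    gseed <- derive_seed(config$seed, "glmroi")
    hrf <- mion_hrf(designs[[1]]$tr_s)
    conds <- designs[[1]]$condition_labels
    truth <- make_category_truth(config$n_voxels, conds, "dissociation",
                                 effect_size = 0.5, noise_sd = 0.5, seed = gseed)
    sims <- lapply(designs, function(d)
      simulate_roi_timeseries(d, truth, hrf, seed = derive_seed(gseed, paste0("run", d$run_id))))
    Ys <- lapply(sims, `[[`, "Y")
    psc <- percent_signal_change(Ys, designs, hrf)
    put("psc", tab_out(psc, "roi_psc.tsv"))
    dms <- lapply(designs, function(d) build_design_matrix(d, hrf))
    st <- stack_designs(dms)
    fit <- fit_glm(do.call(rbind, Ys), st$X, st$dummy_mask)
    ct <- contrast_t(fit, vocalization_contrast(st$condition_cols))
    put("tmaps", tab_out(data.frame(voxel = seq_along(ct$t), t = ct$t, df = ct$df),
                         "voc_vs_silence_t.tsv"))
  }
  if ("mvpa" %in% stages || "rsa" %in% stages) {
    mseed <- derive_seed(config$seed, "betas")
    conds10 <- designs[[1]]$condition_labels
    truth10 <- make_category_truth(config$n_voxels, conds10, "distinct",
                                   effect_size = 1, noise_sd = 1, seed = mseed)
    pat <- simulate_beta_patterns(config$n_voxels, config$n_runs, conds10,
                                  truth10, seed = derive_seed(mseed, "pat"))
    put("betas", { p <- file.path(config$out_dir, "beta_patterns.tsv")
      write_beta_pattern(pat, p); p })
  }
  if ("mvpa" %in% stages) {
    res3 <- loro_crossval_svm(pat, vocal_categories())
    pw <- pairwise_voc_vs_scrambled(pat)
    rows <- rbind(
      data.frame(classifier = "3class_voc", mean_accuracy = res3$mean_accuracy,
                 chance = res3$chance, n_folds = res3$n_folds, p = res3$p_vs_chance),
      do.call(rbind, lapply(names(pw), function(nm)
        data.frame(classifier = paste0("pair_", nm),
                   mean_accuracy = pw[[nm]]$mean_accuracy, chance = pw[[nm]]$chance,
                   n_folds = pw[[nm]]$n_folds, p = pw[[nm]]$p_vs_chance))))
    put("accuracies", tab_out(rows, "mvpa_accuracies.tsv"))
  }
  if ("rsa" %in% stages) {
    pat5 <- beta_pattern(pat$values[, sound_categories(), , drop = FALSE],
                         sound_categories(), pat$run_ids, pat$roi_label)
    rsa <- repeated_holdout_rsa(pat5, n_iter = config$rsa_iter,
                                seed = derive_seed(config$seed, "rsa"))
    put("rsa_betas", tab_out(as.data.frame(rsa), "rsa_betas.tsv"))
    emb <- mds_embed(compute_neural_dsm(pat5), seed = derive_seed(config$seed, "mds"))
    put("rsa_betas", tab_out(
      data.frame(label = rownames(emb$coords), x = emb$coords[, 1],
                 y = emb$coords[, 2], stress = emb$stress), "dsm_embedding.tsv"))
  }
  manifest <- do.call(rbind, lapply(art, function(a)
    data.frame(class = a[1], file = a[2], md5 = unname(tools::md5sum(a[2])))))
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write the packaged fixtures and a demo stimulus set
#'
#' Copies the category acoustic feature table (five categories by eight
#' features) and writes one seeded demo stimulus per category as WAV.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the demo stimuli.
#' @return Invisibly, the written paths.
#' @export
write_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  src <- system.file("extdata", "category_acoustic_features.tsv",
                     package = "vocfmri")
  dst <- file.path(out_dir, "category_acoustic_features.tsv")
  file.copy(src, dst, overwrite = TRUE)
  paths <- dst
  for (cat in sound_categories()) {
    st <- generate_stimulus(stimulus_spec(cat, seed = derive_seed(seed, cat)))
    p <- file.path(out_dir, paste0("demo_", cat, ".wav"))
    write_wav(st$wave, p, st$sample_rate)
    paths <- c(paths, p)
  }
  invisible(paths)
}
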