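# FNV-1a hash of a deparsed R object; used to stamp run artifacts.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline from a single configuration
#'
#' Executes the stages in fixed order — QC, preprocessing, unsupervised
#' structure, supervised LOOCV, label permutation, reporting — and writes
#' every artifact to `out_dir`. Exactly one of `input` (path to a wide
#' spectral table) or `simulate` (arguments for [synthetic_truth()]) must
#' be present in the config. Class labels are physically stripped from the
#' objects handed to the QC, preprocessing and unsupervised stages, so no
#' label information can reach any computation before the supervised
#' stage. QC flags are reported but never exclude samples.
#'
#' Config fields: `input` (path) or `simulate` (list, e.g.
#' `list(seed = 1, n_per_class = 12)`); optional `label_column`,
#' `qc` (args for [qc_config()]), `variant` (a [preprocess_variant()]
#' name, default `"sg2_norm"`), `windows` (list of `c(lo, hi)`),
#' `model` (args for [model_config()]), `permutations` (default 10),
#' `tsne` (logical, default TRUE when feasible), and `seed`.
#'
#' @param config A named list, or a path to a YAML file holding one.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulate'")
  }
  seed <- config$seed
  if (is.null(seed) && (has_sim || (config$permutations %||% 10) > 0)) {
    stop("config$seed is required when any stochastic stage is enabled")
  }
  seed <- as.integer(seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat(sprintf("# run %s | seed %d | %s\n", hash, seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = log_path)

  stage <- "load"
  result <- list(config_hash = hash, seed = seed)
  tryCatch({
    if (has_sim) {
      sim_args <- config$simulate
      sim_args$seed <- NULL                # run-level seed governs simulation
      truth <- do.call(synthetic_truth, c(list(seed = seed), sim_args))
      coh <- generate_cohort(truth)
      set <- coh$set
      writeLines(yaml::as.yaml(list(
        truth = list(seed = truth$seed, n_per_class = truth$n_per_class,
                     noise_sd = truth$noise_sd, spike_rate = truth$spike_rate,
                     gain_range = truth$gain_range,
                     bands = truth$bands),
        samples = lapply(coh$sidecar$samples, function(p) {
          list(gain = p$gain, baseline_coeffs = as.numeric(p$baseline_coeffs),
               noise_seed = p$noise_seed, spike_idx = p$spike_idx,
               spike_amp = p$spike_amp)
        }))), file.path(out_dir, "truth_sidecar.yaml"))
      logf("simulate: %d samples on %d-point grid", nrow(set$intensities),
           length(set$wavenumbers))
    } else {
      set <- read_spectra_table(config$input,
                                label_column = config$label_column %||% "label")
      logf("input: %s (%d samples)", config$input, nrow(set$intensities))
    }
    write_spectra_table(set, file.path(out_dir, "spectra_raw.csv"))
    masked <- strip_labels(set)            # label-free view for early stages

    stage <- "qc"
    qcfg <- do.call(qc_config, config$qc %||% list())
    qc <- build_qc_report(masked, qcfg)
    utils::write.csv(as.data.frame(qc), file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    logf("qc: %d/%d samples flagged (report-only; no sample excluded)",
         sum(nzchar(qc$flags)), nrow(qc))

    stage <- "preprocess"
    wins <- if (!is.null(config$windows)) windows(config$windows) else
      windows(c(600, 1900), c(2800, 3400))
    variant <- config$variant %||% "sg2_norm"
    pcfg <- preprocess_variant(variant, wins = wins)
    pre <- apply_preprocess(masked, pcfg)
    write_spectra_table(pre, file.path(out_dir, "spectra_preprocessed.csv"))
    logf("preprocess: %s", pre$meta$preprocess)

    stage <- "unsupervised"
    d <- cosine_distance_matrix(pre)
    utils::write.csv(as.data.frame(as.matrix(d)),
                     file.path(out_dir, "cosine_distance.csv"))
    hc <- agglomerative_cluster(d)
    merges <- data.frame(step = seq_len(nrow(hc$merge)),
                         a = hc$merge[, 1], b = hc$merge[, 2],
                         height = hc$height)
    utils::write.csv(merges, file.path(out_dir, "cluster_merges.csv"),
                     row.names = FALSE)
    mds <- suppressWarnings(classical_mds(d, dims = 2))  # clipping logged below
    utils::write.csv(data.frame(sample_id = rownames(mds), mds),
                     file.path(out_dir, "mds_coordinates.csv"), row.names = FALSE)
    n <- nrow(d)
    do_tsne <- config$tsne %||% (n >= 8)
    if (isTRUE(do_tsne) && n >= 8) {
      perp <- min(5, floor((n - 1) / 3 - 1e-9))
      ts <- tsne_embed(d, perplexity = perp, seed = seed, is_distance = TRUE)
      utils::write.csv(data.frame(sample_id = rownames(ts), ts),
                       file.path(out_dir, "tsne_coordinates.csv"),
                       row.names = FALSE)
      logf("unsupervised: distances, ward-type merges, MDS, t-SNE (perplexity %g)", perp)
    } else {
      logf("unsupervised: distances, ward-type merges, MDS (t-SNE skipped)")
    }

    stage <- "supervised"
    if (is.null(set$labels)) {
      logf("no labels: supervised and permutation stages skipped")
      result <- c(result, list(set = set, qc = qc, preprocessed = pre))
      return(invisible(result))
    }
    mcfg <- do.call(model_config, config$model %||% list())
    labeled_pre <- pre
    labeled_pre$labels <- set$labels
    cv <- nb_loocv(labeled_pre, model = mcfg, seed = seed)
    utils::write.csv(cv$oof, file.path(out_dir, "loocv_oof.csv"), row.names = FALSE)
    met <- cv$metrics
    metrics_df <- data.frame(
      metric = c("auc", "accuracy", "f1", "precision", "recall", "specificity",
                 "f1_macro", "precision_macro", "recall_macro", "resub_auc"),
      value = c(met$auc, met$accuracy, met$f1, met$precision, met$recall,
                met$specificity, met$f1_macro, met$precision_macro,
                met$recall_macro, cv$resub_metrics$auc))
    utils::write.csv(metrics_df, file.path(out_dir, "loocv_metrics.csv"),
                     row.names = FALSE)
    logf("supervised: LOOCV AUC %.3f, accuracy %.3f", met$auc, met$accuracy)

    stage <- "permutation"
    nperm <- config$permutations %||% 10
    perm <- NULL
    if (nperm > 0) {
      perm <- permutation_test(labeled_pre, model = mcfg,
                               n_permutations = nperm, seed = seed)
      utils::write.csv(perm$table, file.path(out_dir, "permutation.csv"),
                       row.names = FALSE)
      logf("permutation: mean permuted LOOCV AUC %.3f (true %.3f)",
           mean(perm$table$loocv_auc), perm$true_loocv_auc)
    }

    stage <- "report"
    bands <- discriminant_band_summary(cv)
    utils::write.csv(as.data.frame(bands), file.path(out_dir, "discriminant_bands.csv"),
                     row.names = FALSE)
    rb <- reliability_and_brier(cv$oof$prob[!is.na(cv$oof$prob)],
                                cv$oof$label[!is.na(cv$oof$prob)])
    utils::write.csv(rb$bins, file.path(out_dir, "reliability_bins.csv"),
                     row.names = FALSE)
    cat(sprintf("brier,%.10g\n", rb$brier),
        file = file.path(out_dir, "brier.csv"))
    logf("report: %d discriminant band(s), Brier %.4f", nrow(bands), rb$brier)
    logf("defaults in effect: variant=%s, selector=%s, n_bins=%d, threshold=%g",
         variant, mcfg$selector, mcfg$n_bins, mcfg$threshold)

    result <- c(result, list(set = set, qc = qc, preprocessed = pre,
                             distance = d, hclust = hc, mds = mds,
                             cv = cv, permutation = perm, bands = bands,
                             reliability = rb))
    invisible(result)
  }, error = function(e) {
    logf("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
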