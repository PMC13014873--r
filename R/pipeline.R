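# End-to-end orchestration: simulate (or read) -> preprocess -> analytics
# -> group statistics -> SOM (+SOMDI, subset refit) -> PLS-DA / k-means /
# random forest -> catabolite band matching -> JSON + Markdown summary.
# Stages write artifacts stamped with the configuration hash and seed and
# are skipped on rerun when the stamped hash matches (resumability).

#' Pipeline configuration
#'
#' @param out_dir output directory for artifacts
#' @param input_path existing dataset (long TSV) or `NULL` with
#'   `simulate = TRUE`
#' @param simulate generate the input with [simulate_dataset()]
#' @param seed master seed; stage seeds derive from it
#' @param n_per_class spectra per class when simulating
#' @param acquisitions_per_map spectra per simulated map (default 10)
#' @param exclude_classes classes dropped before the SOM subset refit
#' @param cosmic_width,baseline_order,noise_tolerance,normalize
#'   preprocessing settings
#' @param som_grid,som_rlen,som_repeats,som_folds SOM settings
#' @param pls_components,pls_folds PLS-DA settings
#' @param kmeans_k clusters for PCA + k-means
#' @param rf_trees,rf_mtry random-forest settings
#' @param regions,ratios analytics settings
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, input_path = NULL, simulate = TRUE,
                            seed = 1, n_per_class = 30,
                            acquisitions_per_map = 10,
                            exclude_classes = "SOL", cosmic_width = 2,
                            baseline_order = 11, noise_tolerance = 1.5,
                            normalize = NULL, som_grid = c(6, 6),
                            som_rlen = 10, som_repeats = 2, som_folds = 0,
                            pls_components = 5, pls_folds = 5,
                            kmeans_k = 4, rf_trees = 100, rf_mtry = 7,
                            regions = default_regions(),
                            ratios = default_ratios()) {
  if (!simulate && (is.null(input_path) || !file.exists(input_path)))
    stop("input_path must exist when simulate = FALSE", call. = FALSE)
  wns <- c(unlist(ratios),
           unlist(lapply(regions, function(r) c(r$lo, r$hi))), normalize)
  if (any(wns < 690 | wns > 1655))
    stop("every referenced wavenumber must lie in [690, 1655] cm^-1",
         call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  # dependency-light content hash (djb2 over the serialised config);
  # out_dir is excluded so the same analysis in two places hashes alike
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

stage_done <- function(out_dir, stage, hash) {
  f <- file.path(out_dir, paste0(".", stage, ".stamp"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1L], hash)
}

stamp_stage <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(".", stage, ".stamp")))
}

pipeline_log <- function(...) message("[ramansen] ", sprintf(...))

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list of summary results; artifacts are written
#'   under `config$out_dir`
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  summary <- list(config_hash = hash, seed = config$seed)
  run_stage <- function(stage, fn) {
    if (stage_done(config$out_dir, stage, hash)) {
      pipeline_log("stage '%s' already complete, skipping", stage)
      return(invisible(NULL))
    }
    pipeline_log("running stage '%s'", stage)
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline halted in stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE))
    stamp_stage(config$out_dir, stage, hash)
  }

  raw_path <- file.path(config$out_dir, "dataset_raw.tsv")
  run_stage("input", function() {
    if (config$simulate) {
      ds <- simulate_dataset(simulation_config(
        n_per_class = config$n_per_class,
        acquisitions_per_map = config$acquisitions_per_map,
        seed = config$seed))
      write_dataset(ds, raw_path)
    } else {
      file.copy(config$input_path, raw_path, overwrite = TRUE)
    }
  })
  ds <- read_dataset(raw_path)

  prep_path <- file.path(config$out_dir, "dataset_prep.tsv")
  run_stage("prep", function() {
    prep <- preprocess_dataset(
      ds, cosmic_width = config$cosmic_width,
      cfg = baseline_config(config$baseline_order,
                            config$noise_tolerance),
      normalize = config$normalize)
    write_dataset(prep, prep_path)
  })
  prep <- read_dataset(prep_path)

  run_stage("analytics", function() {
    tab <- analytics_table(prep, config$regions, config$ratios)
    data.table::fwrite(tab, file.path(config$out_dir, "analytics.tsv"),
                       sep = "\t")
  })
  tab <- as.data.frame(data.table::fread(
    file.path(config$out_dir, "analytics.tsv"), sep = "\t"))

  run_stage("stats", function() {
    vals <- setdiff(names(tab), c("sample_id", "class"))
    rows <- lapply(vals, function(v) {
      kd <- kw_dunn(tab, v)
      cbind(variable = v, kd$dunn,
            kw_p = kd$kruskal$p_value)
    })
    data.table::fwrite(do.call(rbind, rows),
                       file.path(config$out_dir, "stats_kw_dunn.tsv"),
                       sep = "\t")
  })

  som_json <- file.path(config$out_dir, "som_report.json")
  run_stage("som", function() {
    cv <- split_and_cv(prep, train_fraction = 0.8,
                       folds = config$som_folds,
                       repeats = config$som_repeats,
                       seed = config$seed, grid = config$som_grid,
                       rlen = config$som_rlen)
    model <- train_som(prep, grid = config$som_grid,
                       rlen = config$som_rlen, seed = config$seed)
    sd_full <- somdi(model, feature_names = prep$wavenumbers)
    sub <- subset_refit(prep, exclude = config$exclude_classes,
                        feature_names = prep$wavenumbers,
                        grid = config$som_grid, rlen = config$som_rlen,
                        seed = config$seed + 1L)
    top_wn <- function(sp) lapply(sp$top_features, function(i)
      sp$feature_names[i])
    rep <- list(training = round(cv$training, 2),
                testing = round(cv$testing, 2),
                overall = round(cv$overall, 2),
                per_class_testing = round(cv$per_class_testing, 2),
                somdi_top = top_wn(sd_full),
                somdi_top_subset = top_wn(sub$somdi),
                seed = config$seed, config_hash = hash)
    jsonlite::write_json(rep, som_json, auto_unbox = TRUE, digits = NA)
  })

  mva_json <- file.path(config$out_dir, "mva_report.json")
  run_stage("mva", function() {
    feats <- extract_features(prep)
    pls <- plsda_fit(feats, n_components = config$pls_components,
                     cv_folds = config$pls_folds, seed = config$seed)
    km <- pca_kmeans(feats, k = config$kmeans_k, seed = config$seed)
    rf <- rf_fit(feats, n_trees = config$rf_trees, mtry = config$rf_mtry,
                 seed = config$seed)
    data.table::fwrite(
      data.frame(feature = names(pls$vip), vip = pls$vip,
                 rf_importance = rf$importance[names(pls$vip)]),
      file.path(config$out_dir, "feature_importance.tsv"), sep = "\t")
    rep <- list(plsda = list(r2 = pls$r2, q2 = pls$q2,
                             accuracy = round(pls$accuracy, 2)),
                kmeans = list(k = config$kmeans_k,
                              contingency = as.data.frame(km$contingency)),
                rf = list(oob_error = rf$oob_error,
                          accuracy =
                            rf_accuracy_from_oob(100 * rf$oob_error),
                          per_class_error = as.list(rf$per_class_error)),
                seed = config$seed, config_hash = hash)
    jsonlite::write_json(rep, mva_json, auto_unbox = TRUE, digits = NA)
  })

  cat_json <- file.path(config$out_dir, "catabolite_report.json")
  run_stage("catabolite", function() {
    t3 <- load_filtered_peak_table()
    bands <- unique_bands(list(t3))
    # per-class candidate peak lists from the template peak positions
    tables <- lapply(default_templates(), function(t)
      t$peaks$center[t$peaks$multiplier > 0.05])
    report <- match_to_classes(bands[bands$unique, , drop = FALSE],
                               tables)
    data.table::fwrite(report,
                       file.path(config$out_dir,
                                 "catabolite_matches.tsv"), sep = "\t")
    jsonlite::write_json(
      list(stage_counts = as.list(stage_counts(t3)),
           n_unique_bands = sum(bands$unique), config_hash = hash),
      cat_json, auto_unbox = TRUE, digits = NA)
  })

  run_stage("summary", function() {
    summary <- list(
      config_hash = hash, seed = config$seed,
      n_spectra = n_spectra(ds),
      classes = as.list(table(ds$meta$class)),
      som = jsonlite::fromJSON(som_json),
      mva = jsonlite::fromJSON(mva_json),
      catabolite = jsonlite::fromJSON(cat_json))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    md <- c("# Pipeline summary", "",
            sprintf("- config hash: %s, seed: %d", hash, config$seed),
            sprintf("- spectra: %d", n_spectra(ds)),
            sprintf("- SOM overall accuracy: %.2f %%",
                    summary$som$overall),
            sprintf("- PLS-DA: R2 %.3f, Q2 %.3f, accuracy %.2f %%",
                    summary$mva$plsda$r2, summary$mva$plsda$q2,
                    summary$mva$plsda$accuracy),
            sprintf("- RF OOB error: %.2f %%",
                    100 * summary$mva$rf$oob_error))
    writeLines(md, file.path(config$out_dir, "summary.md"))
  })
  invisible(jsonlite::fromJSON(file.path(config$out_dir, "summary.json")))
}
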