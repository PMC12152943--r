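#' Read a pipeline configuration file
#'
#' JSON is read with jsonlite; `.yml`/`.yaml` files require the yaml
#' package. See [run_pipeline()] for the recognised keys.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
}

validate_config <- function(cfg) {
  if (is.null(cfg$output_dir)) stop_config("config needs output_dir")
  cfg$consensus <- cfg$consensus %||% "us4"
  if (!cfg$consensus %in% c("us4", "expanded9"))
    stop_config("consensus must be 'us4' or 'expanded9'")
  cfg$algorithm <- cfg$algorithm %||% "gradient_boosting"
  cfg$n_subsets <- as.integer(cfg$n_subsets %||% 4L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$split_fraction <- cfg$split_fraction %||% 0.8
  cfg$filter_low <- cfg$filter_low %||% 0.35
  cfg$filter_high <- cfg$filter_high %||% 0.65
  if (cfg$filter_low < 0 || cfg$filter_high > 1 ||
      cfg$filter_low >= cfg$filter_high)
    stop_config("filter bounds must satisfy 0 <= low < high <= 1")
  cfg$cv_folds <- as.integer(cfg$cv_folds %||% 10L)
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$inputs) || is.null(cfg$inputs$blocks) ||
        is.null(cfg$inputs$labels))
      stop_config("config needs either 'simulate' or 'inputs' (blocks + labels)")
    paths <- c(unlist(cfg$inputs$blocks), cfg$inputs$labels)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_config("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

assemble_dataset <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    gs <- do.call(generator_spec,
                  c(cfg$simulate[setdiff(names(cfg$simulate), "seed")],
                    list(seed = cfg$simulate$seed %||% cfg$seed)))
    return(make_binary_dataset(gs))
  }
  blocks <- Map(function(path, block) read_binary_matrix(path, block = block),
                cfg$inputs$blocks, names(cfg$inputs$blocks))
  combined <- concat_blocks(unname(blocks))
  lab <- utils::read.csv(cfg$inputs$labels, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!all(c("compound_id", "label") %in% names(lab)))
    stop_schema("labels file needs columns compound_id,label")
  common <- intersect(rownames(combined), lab$compound_id)
  if (length(common) == 0L) stop_schema("no labelled compound matches the matrices")
  combined <- combined[common, ]
  labeled_dataset(as.matrix(combined),
                  lab$label[match(common, lab$compound_id)],
                  provenance = "assembled from input files")
}

write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

metrics_row <- function(name, m) {
  data.frame(model = name,
             accuracy = round(m$accuracy, 2), mcc = round(m$mcc, 2),
             sensitivity = round(m$sensitivity, 2),
             specificity = round(m$specificity, 2),
             precision = round(m$precision, 2),
             balanced_accuracy = round(m$balanced_accuracy, 2),
             stringsAsFactors = FALSE)
}

band_df <- function(t) {
  data.frame(band = colnames(t), negative = unclass(t)["negative", ],
             positive = unclass(t)["positive", ], row.names = NULL)
}

#' Run the end-to-end modelling pipeline
#'
#' Assembles (or simulates) the combined fingerprint dataset, performs the
#' stratified train/test split, runs pooled cross-validation on the
#' training set, fits the configured consensus model (`us4`: 4-submodel
#' undersampling ensemble; `expanded9`: 9-model consensus), predicts the
#' holdout set, applies probability-range filtering, and writes all
#' artifacts (split manifest, prediction sets, metrics, band tables,
#' exclusion summary, feature-importance ranking, JSON provenance) to the
#' output directory. Validation happens before anything is written, and
#' artifacts are staged to a temporary directory and moved in one step.
#' Rerunning an identical configuration reproduces identical artifacts.
#'
#' Recognised config keys: `output_dir`, `seed`, `consensus`
#' (`us4`/`expanded9`), `algorithm`, `n_subsets`, `split_fraction`,
#' `filter_low`, `filter_high`, `cv_folds`, and either `simulate` (a
#' [generator_spec()] argument list) or `inputs` (`blocks`: named list of
#' matrix CSV paths keyed by block label; `labels`: CSV with
#' `compound_id,label`).
#'
#' @param cfg configuration list or path to a JSON/YAML config file.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_config(cfg)
  hash <- config_hash(cfg)
  d <- assemble_dataset(cfg)
  seeds <- derive_seeds(cfg$seed, 4L)
  split <- stratified_split(d, cfg$split_fraction, seed = seeds[1])
  message(sprintf("split: %d train / %d test (balance %s)",
                  nrow(split$train$x), nrow(split$test$x),
                  format_ratio(class_balance(d$y))))
  spec <- learner_spec(cfg$algorithm, cfg$hyperparameters %||% list(),
                       seed = seeds[2])
  cv <- cross_validate(split$train, spec, balancing = "undersample",
                       k = cfg$cv_folds, seed = seeds[3],
                       n_subsets = cfg$n_subsets,
                       boundaries = c(cfg$filter_low, cfg$filter_high))
  if (cfg$consensus == "us4") {
    subsets <- undersample_subsets(split$train, cfg$n_subsets, seed = seeds[4])
    model <- fit_us_ensemble(subsets, spec)
    imp_ens <- model
  } else {
    rf_spec <- learner_spec("random_forest", cfg$hyperparameters %||% list(),
                            seed = seeds[2])
    gb_spec <- learner_spec("gradient_boosting",
                            cfg$hyperparameters %||% list(), seed = seeds[2])
    model <- fit_expanded_consensus(split$train, gb_spec, rf_spec,
                                    seed = seeds[4],
                                    n_subsets = cfg$n_subsets,
                                    cv_k = cfg$cv_folds)
    imp_ens <- model$us_gb
  }
  test_pred <- stats::predict(model, split$test$x)
  filt <- probability_range_filter(test_pred, cfg$filter_low, cfg$filter_high)
  test_band <- band_table(test_pred$mean_probability, split$test$y,
                          c(cfg$filter_low, cfg$filter_high))
  metrics <- rbind(
    metrics_row("cv_pooled", cv$pooled),
    metrics_row("cv_filtered", metrics_from_bands(cv$band)),
    metrics_row("test", compute_metrics(confusion(split$test$y, test_pred))),
    metrics_row("test_filtered", metrics_from_bands(test_band)))
  excl <- rbind(
    data.frame(set = "cv", as.data.frame(excluded_summary(cv$band))),
    data.frame(set = "test", as.data.frame(excluded_summary(test_band))))
  excl$ratio <- round(excl$ratio, 2)
  imp <- mean_scaled_importance(imp_ens)

  stage <- tempfile("cholecon_run_")
  dir.create(stage)
  art <- function(name) file.path(stage, name)
  write_split_manifest(split, art("split_manifest.csv"))
  write_csv_stamped(cv$predictions, art("cv_predictions.csv"), hash)
  write_csv_stamped(as.data.frame(test_pred), art("test_predictions.csv"), hash)
  write_csv_stamped(as.data.frame(filt$retained), art("test_retained.csv"), hash)
  write_csv_stamped(as.data.frame(filt$excluded), art("test_excluded.csv"), hash)
  write_csv_stamped(metrics, art("metrics.csv"), hash)
  write_csv_stamped(band_df(cv$band), art("band_cv.csv"), hash)
  write_csv_stamped(band_df(test_band), art("band_test.csv"), hash)
  write_csv_stamped(excl, art("excluded_summary.csv"), hash)
  write_csv_stamped(as.data.frame(imp), art("importance.csv"), hash)
  jsonlite::write_json(
    list(config = cfg, config_hash = hash,
         seeds = list(master = cfg$seed, split = seeds[1], learner = seeds[2],
                      cv = seeds[3], fit = seeds[4]),
         package_version = as.character(utils::packageVersion("cholecon")),
         r_version = R.version.string,
         n_train = nrow(split$train$x), n_test = nrow(split$test$x)),
    art("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(stage, full.names = TRUE)
  ok <- file.copy(files, cfg$output_dir, overwrite = TRUE)
  unlink(stage, recursive = TRUE)
  if (!all(ok)) stop("failed to write artifacts to ", cfg$output_dir)
  out <- stats::setNames(file.path(cfg$output_dir, basename(files)),
                         basename(files))
  invisible(as.list(out))
}

#' Write synthetic fixture files in the pipeline input formats
#'
#' Generates a dataset with [make_binary_dataset()] and writes one matrix
#' CSV per block plus a `labels.csv`, ready to be referenced from a
#' pipeline config's `inputs` section.
#'
#' @param spec a [generator_spec()].
#' @param dir output directory, created if needed.
#' @return invisibly, the list of written paths keyed by block label (plus
#'   `labels`).
#' @export
simulate_fixtures <- function(spec, dir) {
  d <- make_binary_dataset(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (b in spec$blocks) {
    prefix <- paste0(b$block, ":")
    cols <- startsWith(colnames(d$x), prefix)
    m <- d$x[, cols, drop = FALSE]
    colnames(m) <- sub(prefix, "", colnames(m), fixed = TRUE)
    path <- file.path(dir, paste0(b$block, ".csv"))
    write_binary_matrix(binary_matrix(m, block = b$block), path)
    out[[b$block]] <- path
  }
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(compound_id = rownames(d$x), label = d$y),
                   lab_path, row.names = FALSE, quote = FALSE)
  out$labels <- lab_path
  invisible(out)
}
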