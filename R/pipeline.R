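# End-to-end orchestration: simulate -> preprocess -> extract -> train ->
# evaluate (MPM branch) and simulate-raman -> raman-train -> raman-evaluate
# (Raman branch), from a single validated configuration and root seed.

default_run_config <- function() {
  list(
    seed = 1L,
    out = NULL,
    stages = list(mpm = TRUE, raman = TRUE),
    mpm = list(
      image_size = c(256L, 256L),
      train_planes = list(healthy = 56L, necrotic = 43L, granulated = 43L,
                          fibrotic = 42L),
      test_planes = list(healthy = 94L, necrotic = 95L, granulated = 95L,
                         fibrotic = 94L),
      train_rois = 3L,
      test_rois = 6L,
      bin_factor = 1L,
      normalization = "minmax",
      morph_open_radius_px = 1L,
      use_mask = "or",
      n_levels = 32L,
      d = 9L,
      n_folds = 20L),
    raman = list(
      n_per_class = 40L,
      k = 4L,
      noise_sd = 0.01,
      loo = TRUE))
}

# recursively check that `raw` only uses keys present in the defaults
check_unknown_keys <- function(raw, defaults, path = character(0)) {
  if (!is.list(raw)) return(invisible(TRUE))
  for (nm in names(raw)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      check_unknown_keys(raw[[nm]], defaults[[nm]], c(path, nm))
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Merges a raw configuration (YAML file path or list) over the defaults,
#' rejects unknown keys (naming the offending key path) and checks
#' cross-field invariants such as `d <= 304`.
#'
#' @param raw path to a YAML file, a list, or `NULL` for pure defaults.
#' @return validated configuration list of class `run_config`.
#' @examples
#' cfg <- validate_config(list(raman = list(n_per_class = 10)))
#' cfg$raman$n_per_class
#' @export
validate_config <- function(raw = NULL) {
  defaults <- default_run_config()
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping or a list")
  check_unknown_keys(raw, defaults)
  cfg <- modifyList(defaults, raw)
  if (cfg$mpm$d < 1L || cfg$mpm$d > 304L)
    stop("mpm.d: selected feature count must be in [1, 304]")
  if (cfg$mpm$n_folds < 1L) stop("mpm.n_folds must be >= 1")
  if (!cfg$mpm$use_mask %in% c("or", "shg", "tpef"))
    stop("mpm.use_mask must be one of or/shg/tpef")
  if (cfg$raman$k < 2L) stop("raman.k must be >= 2")
  if (any(unlist(cfg$mpm$train_planes) < 0) ||
      any(unlist(cfg$mpm$test_planes) < 0))
    stop("mpm.train_planes/test_planes must be non-negative")
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full pipeline
#'
#' Executes the enabled branches in order. The MPM branch simulates the
#' training and test cohorts, preprocesses and extracts features, trains
#' the Monte-Carlo committee and evaluates it; the Raman branch simulates
#' the four-class spectrum set, preprocesses it, fits PLS-DA and (by
#' default) evaluates with leave-one-out cross-validation. Fails fast
#' with the stage name on any error. All randomness derives from the
#' root seed, so two runs with identical config produce identical
#' numeric reports.
#'
#' @param config a [validate_config()]ed configuration (or raw input for
#'   it).
#' @param out optional output directory; when given, the report is
#'   written as `report.json` and the metrics as `metrics.json`.
#' @return list of class `run_report` with per-stage provenance (seeds,
#'   counts) and a `metrics` block.
#' @export
run_pipeline <- function(config = NULL, out = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  out <- out %||% cfg$out
  report <- list(seed = cfg$seed, stages = list(), metrics = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (isTRUE(cfg$stages$mpm)) {
    cohorts <- run_stage("simulate-mpm", {
      tr_spec <- mpm_cohort_spec(unlist(cfg$mpm$train_planes),
                                 n_rois = cfg$mpm$train_rois,
                                 shape = cfg$mpm$image_size,
                                 seed = derive_seed(cfg$seed, 10L))
      te_spec <- mpm_cohort_spec(unlist(cfg$mpm$test_planes),
                                 n_rois = cfg$mpm$test_rois,
                                 shape = cfg$mpm$image_size,
                                 seed = derive_seed(cfg$seed, 11L))
      list(train = generate_mpm_cohort(tr_spec),
           test = generate_mpm_cohort(te_spec))
    })
    pp_cfg <- preprocess_config(
      bin_factor = cfg$mpm$bin_factor,
      normalization = cfg$mpm$normalization,
      morph_open_radius_px = cfg$mpm$morph_open_radius_px)
    registry <- default_feature_registry(n_levels = cfg$mpm$n_levels)
    tables <- run_stage("extract", list(
      train = build_feature_table(cohorts$train, pp_cfg, registry,
                                  use_mask = cfg$mpm$use_mask),
      test = build_feature_table(cohorts$test, pp_cfg, registry,
                                 use_mask = cfg$mpm$use_mask)))
    ml <- run_stage("train-evaluate", run_mpm_ml(
      tables$train, tables$test,
      cfg = selection_config(d = cfg$mpm$d, n = nrow(tables$train)),
      n_folds = cfg$mpm$n_folds, seed = derive_seed(cfg$seed, 12L)))
    report$stages$mpm <- list(
      n_train = nrow(tables$train), n_test = nrow(tables$test),
      n_features = length(feature_columns(tables$train)),
      n_folds = cfg$mpm$n_folds, d = cfg$mpm$d)
    report$metrics$mpm <- list(
      pooled = ml$pooled[c("accuracy", "sensitivity", "specificity")],
      test = ml$test_metrics[c("accuracy", "sensitivity", "specificity")],
      mean_rho_by_class = as.list(tapply(
        ml$test_predictions$rho, tables$test$tissue_class, mean)))
    report$mpm_result <- ml
    report$feature_tables <- tables
  }
  if (isTRUE(cfg$stages$raman)) {
    rset <- run_stage("simulate-raman", generate_raman_set(
      cfg$raman$n_per_class,
      band_model = default_band_model(noise_sd = cfg$raman$noise_sd),
      seed = derive_seed(cfg$seed, 20L)))
    proc <- run_stage("raman-preprocess", preprocess_spectra(rset))
    model <- run_stage("raman-train", plsda_fit(proc, k = cfg$raman$k))
    report$stages$raman <- list(n_spectra = nrow(proc$X),
                                n_channels = ncol(proc$X),
                                k = cfg$raman$k)
    report$raman_model <- model
    if (isTRUE(cfg$raman$loo)) {
      cv <- run_stage("raman-evaluate", raman_loo_cv(proc, k = cfg$raman$k))
      report$metrics$raman <- list(
        overall_sensitivity = cv$report$overall_sensitivity,
        overall_specificity = cv$report$overall_specificity,
        sensitivity = as.list(cv$report$sensitivity),
        specificity = as.list(cv$report$specificity))
    }
  }
  class(report) <- c("run_report", "list")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report$metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(seed = report$seed, stages = report$stages),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report  seed =", x$seed, ">\n")
  if (!is.null(x$metrics$mpm)) {
    p <- x$metrics$mpm$pooled
    cat(sprintf("  MPM pooled MC: acc %.3f sens %.3f spec %.3f\n",
                p$accuracy, p$sensitivity, p$specificity))
    t <- x$metrics$mpm$test
    cat(sprintf("  MPM test:      acc %.3f sens %.3f spec %.3f\n",
                t$accuracy, t$sensitivity, t$specificity))
  }
  if (!is.null(x$metrics$raman))
    cat(sprintf("  Raman LOO macro: sens %.3f spec %.3f\n",
                x$metrics$raman$overall_sensitivity,
                x$metrics$raman$overall_specificity))
  invisible(x)
}
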