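# End-to-end study orchestration: generate -> preprocess -> split ->
# component selection -> fit -> validate -> report.

#' Full-run configuration
#'
#' @param study a [study_config()].
#' @param preprocess a [preprocess_config()].
#' @param holdout_frac blinded validation fraction (default 0.25).
#' @param folds cross-validation folds for component selection (default 2).
#' @param max_components largest component count tried (default 15).
#' @param seed master seed; study generation, splitting and fold assignment
#'   derive their seeds from it.
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(study = study_config(), preprocess = preprocess_config(),
                       holdout_frac = 0.25, folds = 2, max_components = 15,
                       seed = 1L, output_dir = NULL) {
  structure(list(study = study, preprocess = preprocess,
                 holdout_frac = holdout_frac, folds = as.integer(folds),
                 max_components = as.integer(max_components),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the complete fixation-metrology study
#'
#' Generates (or takes) the study records, preprocesses them, splits off
#' the stratified blinded holdout, selects the component count by
#' cross-validation, fits the PLS model on the training set, predicts both
#' sets and reports MAEs. With an `output_dir`, writes `model.json`,
#' `features.csv`, `predictions.csv`, `report.json` and coefficient / CDF
#' plot data. Deterministic for a given config.
#'
#' @param config a [run_config()].
#' @param records optional pre-generated list of [tissue_record()]s; by
#'   default the study is simulated from `config$study` with its seed
#'   overridden by `config$seed`.
#' @return Object of class `run_report`: `mae_validation`, `mae_training`,
#'   `n_train`, `n_validation`, `selected_components`, `model`,
#'   `eval_train`, `eval_validation`, `diagnostics`, `paths`.
#' @export
run_study <- function(config = run_config(), records = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) {
    sc <- config$study
    sc$seed <- config$seed
    records <- simulate_study(sc)
  }
  fm <- build_feature_matrix(records, config$preprocess)
  sp <- split_holdout(fm, config$holdout_frac, seed = config$seed + 1L)
  sel <- select_components(sp$train, config$max_components, config$folds,
                           seed = config$seed + 2L)
  model <- fit_plsr(sp$train, sel$n_components)
  pred_tr <- predict(model, sp$train)
  pred_va <- predict(model, sp$validation)
  ev_tr <- evaluate_predictions(pred_tr, sp$train$y)
  ev_va <- evaluate_predictions(pred_va, sp$validation$y)

  paths <- list()
  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    paths$model <- file.path(out, "model.json")
    write_model_json(model, paths$model,
                     provenance = list(seed = config$seed,
                                       n_components = sel$n_components))
    feats <- do.call(rbind, lapply(records, function(r) {
      f <- extract_features(preprocess_tissue(r, config$preprocess))
      data.frame(tissue_id = r$tissue_id, replicate_id = r$replicate_id,
                 fixation_time_h = r$fixation_time,
                 amide1_peak_cm1 = f$amide1_peak_location,
                 amide1_fwhm_cm1 = f$amide1_fwhm,
                 amideA_mag = f$amideA_peak_magnitude)
    }))
    paths$features <- file.path(out, "features.csv")
    utils::write.csv(feats, paths$features, row.names = FALSE)
    preds <- data.frame(
      row_id = c(sp$train$row_ids, sp$validation$row_ids),
      set = rep(c("train", "validation"),
                c(length(pred_tr), length(pred_va))),
      fixation_time_h = c(sp$train$y, sp$validation$y),
      predicted_h = c(pred_tr, pred_va))
    paths$predictions <- file.path(out, "predictions.csv")
    utils::write.csv(preds, paths$predictions, row.names = FALSE)
    paths$coefficients <- file.path(out, "coefficients.csv")
    utils::write.csv(coefficient_spectrum(model), paths$coefficients,
                     row.names = FALSE)
    paths$report <- file.path(out, "report.json")
  }

  report <- structure(
    list(mae_validation = ev_va$mae, mae_training = ev_tr$mae,
         n_train = length(sp$train$y), n_validation = length(sp$validation$y),
         selected_components = sel$n_components, model = model,
         eval_train = ev_tr, eval_validation = ev_va,
         diagnostics = sel$diagnostics, paths = paths),
    class = "run_report")
  if (!is.null(paths$report)) {
    jsonlite::write_json(report_summary(report, print = FALSE)$json,
                         paths$report, auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Summarize a run report
#'
#' @param report a [run_study()] result.
#' @param print print the human-readable text (default TRUE).
#' @return invisible list with `text` (character vector) and `json`
#'   (list mirroring the report fields).
#' @export
report_summary <- function(report, print = TRUE) {
  stopifnot(inherits(report, "run_report"))
  txt <- c(
    sprintf("MAE (validation): %.3f h", report$mae_validation),
    sprintf("MAE (training):   %.3f h", report$mae_training),
    sprintf("Samples: %d training / %d validation",
            report$n_train, report$n_validation),
    sprintf("Selected components: %d", report$selected_components))
  if (length(report$paths) > 0) {
    txt <- c(txt, "Artifacts:",
             paste0("  ", names(report$paths), ": ",
                    unlist(report$paths)))
  }
  js <- list(mae_validation = report$mae_validation,
             mae_training = report$mae_training,
             n_train = report$n_train, n_validation = report$n_validation,
             selected_components = report$selected_components,
             paths = report$paths)
  if (print) cat(paste(txt, collapse = "\n"), "\n")
  invisible(list(text = txt, json = js))
}

#' @export
print.run_report <- function(x, ...) {
  report_summary(x, print = TRUE)
  invisible(x)
}
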