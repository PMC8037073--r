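# End-to-end orchestration ----------------------------------------------------
#
# Part one (training): condition each labelled record, cut 1-minute
# segments, compute the truncated Choi-Williams distribution, extract the
# ST/PR band-power pair, and train the per-lead one-vs-one SVM.
# Part two (operation): run the identical chain on an unknown record and
# classify every minute with the trained model, fusing leads.

#' Pipeline configuration
#'
#' Collects every tunable of the chain, validated up front.
#'
#' @param target_fs common sampling rate after resampling, Hz.
#' @param hp_cutoff baseline high-pass cutoff, Hz.
#' @param passband muscle-noise band-pass edges, Hz.
#' @param sigma Choi-Williams kernel parameter.
#' @param n_freq CWD frequency bins.
#' @param lag_window CWD lag window (odd, samples).
#' @param time_decimation CWD time stride, samples.
#' @param sigma_rbf RBF kernel width.
#' @param gamma_cost SVM soft-margin cost.
#' @param k_folds folds for cross-validation reports.
#' @param seed integer seed for every stochastic step.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(target_fs = 250, hp_cutoff = 0.5,
                            passband = c(2, 35), sigma = 1, n_freq = 256L,
                            lag_window = 127L, time_decimation = 4L,
                            sigma_rbf = 0.1, gamma_cost = 10, k_folds = 10L,
                            seed = 1L) {
  stopifnot(target_fs > 0, hp_cutoff > 0, length(passband) == 2,
            passband[1] > 0, passband[1] < passband[2],
            passband[2] < target_fs / 2,
            sigma > 0, n_freq >= lag_window, lag_window %% 2 == 1,
            time_decimation >= 1, sigma_rbf > 0, gamma_cost > 0, k_folds >= 2)
  structure(list(target_fs = target_fs, hp_cutoff = hp_cutoff,
                 passband = passband, sigma = sigma,
                 n_freq = as.integer(n_freq),
                 lag_window = as.integer(lag_window),
                 time_decimation = as.integer(time_decimation),
                 sigma_rbf = sigma_rbf, gamma_cost = gamma_cost,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

cfg_tfd <- function(config)
  tfd_config(config$sigma, config$n_freq, config$lag_window,
             config$time_decimation)

#' Train the detection model from labelled records
#'
#' Runs the full training chain: conditioning, 1-minute segmentation,
#' truncated CWD, ST/PR feature extraction, and per-lead one-vs-one SVM
#' training; optionally a record-stratified k-fold cross-validation report.
#'
#' @param records list of labelled [ecg_record()] objects.
#' @param config a [pipeline_config()].
#' @param cross_validate if `TRUE`, also run [kfold_cv()].
#' @param progress print per-stage messages.
#' @return list with `model` ([train_model()] result), `features`
#'   (the extracted [feature_table()]), and optionally `cv`.
#' @export
run_training <- function(records, config = pipeline_config(),
                         cross_validate = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(records, "ecg_record")) records <- list(records)
  if (!length(records)) stop("training stage: no input records")
  if (any(vapply(records, function(r) is.null(r$label), logical(1))))
    stop("training stage: every record needs a class label")
  pp <- lapply(records, function(r) {
    if (progress) message("preprocess: ", r$record_id)
    tryCatch(preprocess_record(r, config$target_fs, config$hp_cutoff,
                               config$passband),
             error = function(e) stop("preprocess stage failed on '",
                                      r$record_id, "': ",
                                      conditionMessage(e)))
  })
  features <- tryCatch(
    extract_dataset(pp, cfg_tfd(config), progress = progress),
    error = function(e) stop("feature stage failed: ", conditionMessage(e)))
  model <- tryCatch(
    train_model(features, sigma_rbf = config$sigma_rbf,
                gamma_cost = config$gamma_cost, seed = config$seed),
    error = function(e) stop("training stage failed: ", conditionMessage(e)))
  out <- list(model = model, features = features, config = config)
  if (cross_validate)
    out$cv <- kfold_cv(features, k = config$k_folds, seed = config$seed,
                       sigma_rbf = config$sigma_rbf,
                       gamma_cost = config$gamma_cost)
  out
}

#' Classify every minute of an unknown record
#'
#' Runs the conditioning and feature chain on the record and classifies each
#' 1-minute segment per lead, fusing leads into one label per minute.
#'
#' @param model a trained `ischemia_model`.
#' @param record an [ecg_record()] whose leads the model knows.
#' @param config a [pipeline_config()] (must match the training settings).
#' @return list with per-minute `decisions` (see
#'   [predict.ischemia_model()]) and a `summary` row (fractions of minutes
#'   per class).
#' @export
run_detection <- function(model, record, config = pipeline_config()) {
  stopifnot(inherits(model, "ischemia_model"),
            inherits(record, "ecg_record"),
            inherits(config, "pipeline_config"))
  unknown <- setdiff(record$lead_names, names(model$leads))
  if (length(unknown))
    stop("record lead(s) {", paste(unknown, collapse = ", "),
         "} not in the model; model knows {",
         paste(names(model$leads), collapse = ", "), "}")
  pp <- preprocess_record(record, config$target_fs, config$hp_cutoff,
                          config$passband)
  features <- extract_dataset(pp, cfg_tfd(config))
  decisions <- predict(model, features)
  frac <- table(factor(decisions$label,
                       c("normal", "ischemia", "infarction"))) /
    nrow(decisions)
  list(decisions = decisions,
       summary = data.frame(record_id = record$record_id,
                            n_minutes = nrow(decisions),
                            frac_normal = as.numeric(frac["normal"]),
                            frac_ischemia = as.numeric(frac["ischemia"]),
                            frac_infarction = as.numeric(frac["infarction"])))
}
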