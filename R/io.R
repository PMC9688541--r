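fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "p300prognosis")
  if (p == "") stop_param("packaged fixture ", name, " not found")
  p
}

#' Load and validate the patient table
#'
#' Reads the per-patient demographics/CRS-R table (defaults to the packaged
#' copy of the study cohort). Validation: diagnosis and etiology vocabulary,
#' and each CRS-R total must equal the sum of its six subscores; violations
#' report the offending patient id.
#'
#' @param path CSV path; default the packaged cohort table.
#' @return Data frame of validated patient records.
#' @export
load_patient_table <- function(path = fixture_path("doc_cohort_patients.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  sub <- c("auditory", "visual", "motor", "oromotor", "communication",
           "arousal")
  need <- c("patient_id", "age", "gender", "etiology",
            "time_since_injury_months", "diagnosis_before",
            "diagnosis_after",
            paste0("crsr_before_", c("total", sub)),
            paste0("crsr_after_", c("total", sub)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("patient table lacks column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    rid <- df$patient_id[i]
    if (!df$diagnosis_before[i] %in% diagnosis_levels_before)
      stop_param(rid, ": bad pre-experiment diagnosis '",
                 df$diagnosis_before[i], "'")
    if (!df$diagnosis_after[i] %in% diagnosis_levels_after)
      stop_param(rid, ": bad follow-up diagnosis '", df$diagnosis_after[i], "'")
    if (!df$etiology[i] %in% etiology_levels)
      stop_param(rid, ": bad etiology '", df$etiology[i], "'")
    for (w in c("before", "after")) {
      tot <- df[[paste0("crsr_", w, "_total")]][i]
      s <- sum(vapply(sub, function(k) df[[paste0("crsr_", w, "_", k)]][i],
                      numeric(1)))
      if (tot != s)
        stop_param(rid, ": crsr_", w, "_total (", tot,
                   ") does not equal the subscore sum (", s, ")")
    }
  }
  df
}

#' Load and validate the per-patient epoch-count table
#'
#' @param path CSV path; default the packaged table (columns `patient_id`,
#'   `n_total`, `n_p300`, `n_non_p300`).
#' @return Validated data frame.
#' @export
load_epoch_counts <- function(path = fixture_path("doc_cohort_epoch_counts.csv")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "n_total", "n_p300", "n_non_p300")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("epoch-count table lacks column(s): ",
               paste(miss, collapse = ", "))
  bad <- which(df$n_total != df$n_p300 + df$n_non_p300)
  if (length(bad))
    stop_param("epoch counts do not sum for patient(s): ",
               paste(df$patient_id[bad], collapse = ", "))
  df
}

#' Load a per-patient accuracy/F1 table
#'
#' @param method `"cnn"` or `"bayesian"` to pick a packaged table, ignored
#'   when `path` is given.
#' @param path Optional CSV path (columns `patient_id`, `accuracy_pct`,
#'   `f1`).
#' @return Validated data frame; accuracies in percent.
#' @export
load_accuracy_table <- function(method = c("cnn", "bayesian"), path = NULL) {
  method <- match.arg(method)
  if (is.null(path))
    path <- fixture_path(sprintf("p300_accuracy_%s.csv", method))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "accuracy_pct", "f1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("accuracy table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$accuracy_pct < 0 | df$accuracy_pct > 100))
    stop_param("accuracy_pct must lie in [0, 100]")
  if (any(df$f1 < 0 | df$f1 > 1)) stop_param("f1 must lie in [0, 1]")
  df
}

#' Reproduce the cohort statistics from the packaged tables
#'
#' Runs the full cohort-level statistical layer on the packaged per-patient
#' tables alone -- no EEG simulation involved: outcome labelling, the age
#' summary, the four FDR-adjusted group comparisons per detector, the
#' Gaussian fits, and the accuracy--CRS-R correlations.
#'
#' @return Object of class `p300_reproduction`: `summary`
#'   (a [summarize_cohort()]), `cnn` and `bayesian` (each a `p300_study`).
#' @export
reproduce_printed_statistics <- function() {
  records <- load_patient_table()
  out <- list(summary = summarize_cohort(records))
  for (m in c("cnn", "bayesian")) {
    tab <- load_accuracy_table(m)
    acc <- stats::setNames(tab$accuracy_pct, tab$patient_id)
    f1 <- stats::setNames(tab$f1, tab$patient_id)
    out[[m]] <- run_study_statistics(records, acc, f1, method = m)
  }
  structure(out, class = "p300_reproduction")
}

#' @export
print.p300_reproduction <- function(x, ...) {
  cat("== cohort ==\n"); print(x$summary)
  cat("\n== CNN detector ==\n"); print(x$cnn)
  cat("\n== Bayesian detector ==\n"); print(x$bayesian)
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end synthetic pipeline. Every
#' argument has a default; unknown names passed via `...` are rejected.
#'
#' @param patients List of per-patient settings; each element may set
#'   `n_target`, `n_nontarget`, `p300_amplitude` and any other
#'   [synthetic_config()] field.
#' @param band Detection-path filter band in Hz.
#' @param window_ms Epoch window, ms.
#' @param decim Decimation factor.
#' @param channels Feature channels.
#' @param classifiers Character subset of `c("cnn", "bayesian")`.
#' @param cnn A [cnn_spec()]; its seed is re-derived per patient.
#' @param bayes A [bayes_spec()].
#' @param k Cross-validation folds.
#' @param seed Global pipeline seed.
#' @param ... Must be empty.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(patients = list(list(n_target = 200,
                                                 n_nontarget = 200)),
                            band = c(0.1, 10), window_ms = c(0, 600),
                            decim = 5L, channels = feature_channels(),
                            classifiers = c("cnn", "bayesian"),
                            cnn = cnn_spec(), bayes = bayes_spec(),
                            k = 10L, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop_param("unknown configuration key(s): ",
               paste(names(extra), collapse = ", "))
  stopifnot(all(classifiers %in% c("cnn", "bayesian")))
  structure(list(patients = patients, band = band, window_ms = window_ms,
                 decim = as.integer(decim), channels = channels,
                 classifiers = classifiers, cnn = cnn, bayes = bayes,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cnn <- unclass(x$cnn)
  x$bayes <- unclass(x$bayes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$cnn <- do.call(cnn_spec, x$cnn)
  x$bayes <- do.call(bayes_spec, x$bayes)
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end synthetic pipeline
#'
#' For each configured patient: simulate an oddball recording, band-pass
#' filter it (detection path), extract 0--600 ms epochs, build decimated
#' feature vectors, cross-validate the requested detectors, and compute the
#' pooled metric suite. Results, per-patient metrics and a provenance block
#' (config hash, seed, package and R versions) are written under `out_dir`
#' and returned. Identical config and seed reproduce identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing artifacts.
#' @return Object of class `p300_pipeline_report`: `provenance`, and
#'   `patients` (per patient and classifier: detection accuracy, pooled
#'   metrics).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- names(config$patients)
  if (is.null(ids)) ids <- paste0("S", seq_along(config$patients))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_param("stage '", what, "': ", conditionMessage(e)))
  }
  res <- list()
  for (i in seq_along(config$patients)) {
    p <- config$patients[[i]]
    p$seed <- if (is.null(p$seed)) config$seed + i else p$seed
    cfg <- stage("simulate", do.call(synthetic_config, p))
    rec <- stage("simulate", generate_recording(cfg))
    rec <- stage("preprocess",
                 bandpass_filter(rec, config$band[1], config$band[2]))
    ep <- stage("preprocess", extract_epochs(rec, window_ms = config$window_ms))
    feat <- stage("preprocess",
                  build_feature_vectors(ep, config$channels, config$decim))
    pr <- list(patient_id = ids[i])
    for (cl in config$classifiers) {
      sp <- if (cl == "cnn") config$cnn else config$bayes
      sp$seed <- sp$seed + 100000L * i
      cv <- stage(paste0("classify-", cl),
                  cross_validate(feat, spec = sp, k = config$k,
                                 seed = config$seed + i))
      ev <- stage("evaluate", evaluate_cv(cv))
      pr[[cl]] <- list(detection_accuracy = cv$detection_accuracy,
                       mean_fold_accuracy = cv$mean_fold_accuracy,
                       metrics = ev$pooled)
    }
    res[[ids[i]]] <- pr
  }
  report <- structure(
    list(provenance = list(config_hash = config_hash(config),
                           seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("p300prognosis")),
                           r_version = R.version.string),
         patients = res),
    class = "p300_pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    rows <- do.call(rbind, lapply(res, function(pr) {
      do.call(rbind, lapply(config$classifiers, function(cl)
        cbind(data.frame(patient_id = pr$patient_id, classifier = cl,
                         detection_accuracy = pr[[cl]]$detection_accuracy),
              as.data.frame(pr[[cl]]$metrics))))
    }))
    write.csv(rows, file.path(out_dir, "per_patient_metrics.csv"),
              row.names = FALSE)
    json <- list(provenance = report$provenance,
                 patients = lapply(res, function(pr) {
                   out <- list(patient_id = pr$patient_id)
                   for (cl in config$classifiers)
                     out[[cl]] <- list(
                       detection_accuracy = pr[[cl]]$detection_accuracy,
                       mean_fold_accuracy = pr[[cl]]$mean_fold_accuracy,
                       metrics = as.list(as.data.frame(pr[[cl]]$metrics)))
                   out
                 }))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.p300_pipeline_report <- function(x, ...) {
  cat(sprintf("<p300_pipeline_report> %d patients (config %s, seed %d)\n",
              length(x$patients), substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  for (pr in x$patients) {
    cat(sprintf("  %s:", pr$patient_id))
    for (cl in setdiff(names(pr), "patient_id"))
      cat(sprintf(" %s acc %.3f", cl, pr[[cl]]$detection_accuracy))
    cat("\n")
  }
  invisible(x)
}
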