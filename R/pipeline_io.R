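# Cohort CSV input/output with schema validation, human-readable JSON
# model serialisation, and the end-to-end driver that re-enacts the
# analysis (derive the adjustment on controls, develop the continuous
# model on a training cohort, validate on a held-out cohort) on synthetic
# data.

#' Canonical cohort schema
#'
#' Column names with unit suffixes shared by all modules. `required` lists
#' the columns a cohort file must contain; `numeric` the subset coerced to
#' numbers (rows whose cells fail to parse are flagged and excluded, with
#' a count).
#'
#' @param required Required column names.
#' @param numeric Columns coerced to numeric.
#' @return A list of class `cohort_schema`.
#' @export
cohort_schema <- function(required = c("age", "creatinine_umol_l", "he4"),
                          numeric = intersect(
                            c("age", "creatinine_umol_l", "egfr", "he4",
                              "he4ren", "ca125", "grade"), required)) {
  structure(list(required = required, numeric = numeric),
            class = "cohort_schema")
}

#' Read and validate a cohort CSV
#'
#' Hard failures only on a missing file or missing required columns.
#' Unparseable numeric cells cause the row to be flagged and excluded;
#' the validation report (attribute `validation`) records the excluded
#' row numbers and a count. Unknown columns are preserved untouched.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [cohort_schema()].
#' @return Validated data frame with attribute `validation` (list with
#'   `n_excluded`, `excluded_rows`, `messages`).
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(schema$required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_rows <- integer(0)
  messages <- character(0)
  # canonical numeric columns are coerced whenever present, whether or not
  # the schema requires them
  canonical <- c("age", "creatinine_umol_l", "egfr", "he4", "he4_baseline",
                 "he4ren", "ca125", "grade")
  to_numeric <- union(schema$numeric, intersect(canonical, names(raw)))
  for (col in intersect(to_numeric, names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0) {
      bad_rows <- union(bad_rows, bad)
      messages <- c(messages, paste0(
        "column '", col, "': ", length(bad),
        " unparseable numeric cell(s) at row(s) ",
        paste(bad, collapse = ", ")))
    }
    raw[[col]] <- vals
  }
  out <- if (length(bad_rows) > 0) raw[-bad_rows, , drop = FALSE] else raw
  attr(out, "validation") <- list(n_excluded = length(bad_rows),
                                  excluded_rows = sort(bad_rows),
                                  messages = messages)
  out
}

#' Write a cohort CSV
#'
#' @param cohort Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a fitted model to human-readable JSON
#'
#' Writes the published constants and any fitted coefficients in an
#' inspectable form: the HE4ren adjustment (knot, slope), continuous-model
#' coefficients, categorical cut-offs, simplified weights and threshold,
#' and probability cut-offs.
#'
#' @param model A `fitted_logistic`, `score_model`, `piecewise_fit`, or a
#'   plain named list of constants.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "fitted_logistic")) {
    list(type = "fitted_logistic",
         coefficients = model$coefficients,
         retained = model$retained,
         alpha_stay = model$alpha_stay,
         elimination_trace = model$elimination_trace,
         n = model$n, n_events = model$n_events)
  } else if (inherits(model, "score_model")) {
    list(type = "score_model",
         scores = as.list(model$scores),
         intercept = model$intercept,
         simplified_weights = as.list(model$simplified_weights),
         high_risk_threshold = model$high_risk_threshold)
  } else if (inherits(model, "piecewise_fit")) {
    list(type = "piecewise_fit", knot = model$knot,
         slope_coeff = model$slope_coeff, slope_ci = model$slope_ci,
         intercept = model$intercept, residual_sd = model$residual_sd,
         n = model$n)
  } else {
    model
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return The deserialised list.
#' @export
read_model_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Frozen published constants used throughout the pipeline
#'
#' @return Named list: the HE4ren slope and knot, continuous-model
#'   coefficients, categorical cut-offs, simplified weights and threshold,
#'   and the working probability cut-offs (25%, 33%, 43%).
#' @export
published_constants <- function() {
  list(
    he4ren_slope = HE4REN_SLOPE,
    he4ren_knot = HE4REN_KNOT,
    continuous_coefficients = as.list(DMI_CONTINUOUS_COEF),
    categorical_cutoffs = DMI_CATEGORICAL_CUTOFFS,
    simplified_weights = as.list(DMI_SIMPLIFIED_WEIGHTS),
    simplified_threshold = DMI_SIMPLIFIED_THRESHOLD,
    probability_cutoffs = c(0.25, 0.33, 0.43)
  )
}

#' Run the full analysis on synthetic cohorts
#'
#' End-to-end driver: generates a control cohort and training/validation
#' cancer cohorts, refits the piecewise log-linear HE4--eGFR model on the
#' controls, applies the HE4ren adjustment everywhere, develops the
#' continuous dMI model on the grade 1-or-2 training subset by backward
#' elimination, evaluates it on the held-out validation subset, and
#' applies the simplified categorical classifier. Deterministic given the
#' seed.
#'
#' @param cfg A [generator_config()]; its seed drives every random draw.
#' @param n_training,n_validation Sizes of the two cancer cohorts.
#' @param out_dir Optional directory; when given, cohorts (CSV), models
#'   (JSON) and evaluation tables (CSV) are written there.
#' @return List of class `analysis_bundle`: `controls`, `training`,
#'   `validation` (adjusted cohorts), `piecewise_fit`, `continuous_fit`,
#'   `training_eval`, `validation_eval` (eval_report objects),
#'   `simplified_validation` (classified cohort), `constants`, `log`
#'   (character vector of stage messages).
#' @export
run_full_analysis <- function(cfg = generator_config(),
                              n_training = 120L, n_validation = 240L,
                              out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  note("constants: he4ren slope ", HE4REN_SLOPE, ", knot ", HE4REN_KNOT,
       "; continuous coefficients ",
       paste(names(DMI_CONTINUOUS_COEF), DMI_CONTINUOUS_COEF,
             sep = "=", collapse = ", "),
       "; categorical cutoffs he4ren>=", DMI_CATEGORICAL_CUTOFFS$he4ren,
       ", ca125>=", DMI_CATEGORICAL_CUTOFFS$ca125,
       ", age>=", DMI_CATEGORICAL_CUTOFFS$age,
       "; weights ", paste(DMI_SIMPLIFIED_WEIGHTS, collapse = "/"),
       ", threshold ", DMI_SIMPLIFIED_THRESHOLD,
       "; probability cutoffs 0.25/0.33/0.43")

  controls <- generate_controls(cfg)
  note("generated ", nrow(controls), " controls (seed ", cfg$seed, ")")
  pw <- fit_piecewise_loglinear(controls[, c("egfr", "he4")])
  note(sprintf("piecewise fit: slope_coeff %.4f (95%% CI %.4f-%.4f)",
               pw$slope_coeff, pw$slope_ci[1], pw$slope_ci[2]))

  cfg_train <- cfg; cfg_train$n_patients <- as.integer(n_training)
  cfg_train$seed <- cfg$seed + 1L
  cfg_valid <- cfg; cfg_valid$n_patients <- as.integer(n_validation)
  cfg_valid$seed <- cfg$seed + 2L
  training <- adjust_cohort(
    generate_ec_cohort(cfg_train, cohort_label = "training"))
  validation <- adjust_cohort(
    generate_ec_cohort(cfg_valid, cohort_label = "validation"))
  note("generated training n=", nrow(training),
       ", validation n=", nrow(validation))

  g12_train <- training[!is.na(training$grade) & training$grade != 3, ]
  n_excl <- nrow(training) - nrow(g12_train)
  note("training G1-or-G2 subset n=", nrow(g12_train),
       " (", n_excl, " grade-3/missing-grade rows excluded)")
  g12_train$log_he4ren <- log(g12_train$he4ren)
  g12_train$log_ca125 <- log(g12_train$ca125)
  g12_train$grade_num <- g12_train$grade - 1
  fit <- fit_logistic_backward(
    g12_train, outcome = "dmi",
    candidates = c("age", "log_he4ren", "grade_num", "log_ca125"))
  note("backward elimination retained: ",
       paste(fit$retained, collapse = ", "))

  train_p <- predict_dmi_continuous(g12_train$age, g12_train$he4ren,
                                    g12_train$grade)
  training_eval <- eval_report(train_p, g12_train$dmi)
  g12_valid <- validation[!is.na(validation$grade) & validation$grade != 3, ]
  valid_p <- predict_dmi_continuous(g12_valid$age, g12_valid$he4ren,
                                    g12_valid$grade)
  validation_eval <- eval_report(valid_p, g12_valid$dmi)
  note(sprintf("published continuous model AUC: training %.4f, validation %.4f",
               training_eval$auc, validation_eval$auc))

  simplified_validation <- classify_cohort(validation, model = "simplified")
  note("simplified classifier: ",
       sum(simplified_validation$risk == "high", na.rm = TRUE),
       " of ", nrow(simplified_validation), " validation rows high-risk")

  bundle <- structure(list(
    controls = controls, training = training, validation = validation,
    piecewise_fit = pw, continuous_fit = fit,
    training_eval = training_eval, validation_eval = validation_eval,
    simplified_validation = simplified_validation,
    constants = published_constants(), log = log
  ), class = "analysis_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(controls, file.path(out_dir, "controls.csv"))
    write_cohort(training, file.path(out_dir, "training.csv"))
    write_cohort(validation, file.path(out_dir, "validation.csv"))
    write_model_json(pw, file.path(out_dir, "piecewise_fit.json"))
    write_model_json(fit, file.path(out_dir, "continuous_fit.json"))
    write_model_json(published_constants(),
                     file.path(out_dir, "published_constants.json"))
    utils::write.csv(validation_eval$metrics,
                     file.path(out_dir, "validation_metrics.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "analysis_log.txt"))
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Synthetic end-to-end dMI analysis\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
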