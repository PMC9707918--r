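# The three-model experiment: vFFR computed with a generic microvascular
# resistance (Model A), with CMVR predicted from clinical + angiographic
# features (Model B), and with echocardiographic features added (Model C),
# each compared against measured FFR.

#' Feature panels for the CMVR prediction models
#'
#' `"clinical"` is the routinely available clinical + angiographic panel
#' (Model B); `"clinical_echo"` adds the echo measurements (Model C), so
#' the clinical panel is a strict subset of the echo panel.
#'
#' @param set `"clinical"` or `"clinical_echo"`.
#' @return character vector of cohort column names.
#' @export
cmvr_feature_set <- function(set = c("clinical", "clinical_echo")) {
  set <- match.arg(set)
  clinical <- c("vessel_label", "age", "sex", "hypertension", "diabetes",
                "smoking", "prior_mi", "inlet_diameter", "outlet_diameter",
                "minimum_lumen_diameter", "lesion_length", "mji", "duke_score")
  if (set == "clinical") clinical else c(clinical, "ivs_thickness", "lv_mass")
}

#' Vessel-specific CMVR from measured pressures
#'
#' Applies [invert_cmvr()] to every cohort vessel using its own geometry
#' and measured aortic/distal pressures. Vessels where the inversion
#' fails (e.g. no trans-lesional gradient) are flagged in the result, not
#' dropped.
#'
#' @param cohort a cohort data.frame with `pa_measured`/`pd_measured`
#'   (mmHg) and geometry columns.
#' @param fluid a [fluid_properties()].
#' @return data.frame with `id`, `cmvr_computed` (Pa s/m^3), `q` (m^3/s),
#'   `ok` (logical), `message` (failure reason or `""`).
#' @export
compute_reference_cmvr <- function(cohort, fluid = fluid_properties()) {
  convention <- attr(cohort, "generator")
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    res <- tryCatch(
      invert_cmvr(record_geometry(rec, convention = convention), fluid,
                  pa = mmHg_to_Pa(rec$pa_measured),
                  pd = mmHg_to_Pa(rec$pd_measured)),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(id = rec$id, cmvr_computed = NA_real_, q = NA_real_,
                 ok = FALSE, message = conditionMessage(res))
    else
      data.frame(id = rec$id, cmvr_computed = res$cmvr, q = res$q,
                 ok = TRUE, message = "")
  })
  do.call(rbind, out)
}

#' Fit a CMVR prediction model on a cohort
#'
#' Runs the term-frequency identification protocol
#' ([frequency_select()]) with the computed reference CMVR as the
#' response, modelled on the log scale by default (CMVR is positive and
#' right-skewed). Predictions from the returned model are back-transformed
#' to Pa s/m^3.
#'
#' @param cohort a cohort data.frame.
#' @param cmvr response vector of reference CMVR values (Pa s/m^3),
#'   typically `compute_reference_cmvr(cohort)$cmvr_computed`.
#' @param features feature columns, e.g. [cmvr_feature_set()].
#' @param n_final_terms final model size (16 for the clinical panel and 18
#'   for the clinical + echo panel by default, via `NULL`).
#' @param log_response model `log(cmvr)` (default) or raw CMVR.
#' @param ... further arguments to [frequency_select()] (`n_splits`,
#'   `train_frac`, `max_degree`, `err_threshold`, `seed`).
#' @return a `narmax_model` predicting CMVR.
#' @export
fit_cmvr_model <- function(cohort, cmvr, features = cmvr_feature_set("clinical"),
                           n_final_terms = NULL, log_response = TRUE, ...) {
  keep <- is.finite(cmvr) & cmvr > 0
  if (is.null(n_final_terms))
    n_final_terms <- if ("lv_mass" %in% features) 18L else 16L
  y <- if (log_response) log(cmvr[keep]) else cmvr[keep]
  model <- frequency_select(cohort[keep, , drop = FALSE], y, features,
                            n_final_terms = n_final_terms, ...)
  model$log_response <- log_response
  model
}

# vectorised forward solve over cohort rows for a vector of CMVR values
.solve_cohort <- function(cohort, cmvr, fluid = fluid_properties()) {
  convention <- attr(cohort, "generator")
  vapply(seq_len(nrow(cohort)), function(i) {
    solve_forward(record_geometry(cohort[i, ], convention = convention), fluid,
                  pa = mmHg_to_Pa(cohort$pa_measured[i]), cmvr = cmvr[i])$ffr
  }, 0)
}

#' vFFR under a generic microvascular resistance (Model A)
#'
#' Applies one population-level CMVR value to every vessel.
#'
#' @param cohort a cohort data.frame.
#' @param generic_cmvr the generic CMVR (Pa s/m^3); must be > 0.
#' @param fluid a [fluid_properties()].
#' @return numeric vector of vFFR values, one per row.
#' @export
run_model_a <- function(cohort, generic_cmvr, fluid = fluid_properties()) {
  if (!is.finite(generic_cmvr) || generic_cmvr <= 0)
    stop("generic CMVR must be a positive number")
  .solve_cohort(cohort, rep(generic_cmvr, nrow(cohort)), fluid)
}

#' vFFR under model-predicted microvascular resistance (Models B/C)
#'
#' Predicts each vessel's CMVR from the fitted model and feeds it to the
#' forward solve. Non-positive predictions (possible only for a raw-scale
#' model) are clipped to `cmvr_floor` with a warning.
#'
#' @param cohort a cohort data.frame containing the model's features.
#' @param model a `narmax_model` from [fit_cmvr_model()].
#' @param fluid a [fluid_properties()].
#' @param cmvr_floor lower clip for predicted CMVR (Pa s/m^3).
#' @return numeric vector of vFFR values, one per row.
#' @export
run_model_bc <- function(cohort, model, fluid = fluid_properties(),
                         cmvr_floor = 1e8) {
  miss <- setdiff(model$features, names(cohort))
  if (length(miss))
    stop("cohort lacks model feature column(s): ", paste(miss, collapse = ", "))
  cmvr_hat <- predict(model, cohort, type = "response")
  if (any(cmvr_hat <= 0)) {
    warning(sum(cmvr_hat <= 0), " non-positive CMVR prediction(s) clipped to ",
            cmvr_floor)
    cmvr_hat <- pmax(cmvr_hat, cmvr_floor)
  }
  .solve_cohort(cohort, cmvr_hat, fluid)
}

#' Experiment configuration
#'
#' @param synthetic a [synthetic_config()] describing the cohort, or
#'   `NULL` when a cohort is passed to [compare_models()] directly.
#' @param generic_cmvr Model A's CMVR; `NULL` (default) uses the mean
#'   computed CMVR of the training vessels.
#' @param n_terms_b,n_terms_c final model sizes for the two panels.
#' @param n_splits,train_frac,max_degree,err_threshold identification
#'   protocol settings (see [frequency_select()]).
#' @param eval_reps,leave_out held-out evaluation protocol settings (see
#'   [evaluate_model()]).
#' @param holdout if `TRUE` (default) the comparison metrics are computed
#'   on a held-out partition never used to fit B/C; if `FALSE`, B/C are
#'   fit and evaluated on the full cohort (the in-sample design).
#' @param threshold,loa_factor metric settings.
#' @param seed master seed for the whole experiment.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              generic_cmvr = NULL,
                              n_terms_b = 16L, n_terms_c = 18L,
                              n_splits = 100L, train_frac = 0.75,
                              max_degree = 2L, err_threshold = 0.995,
                              eval_reps = 100L, leave_out = 0.20,
                              holdout = TRUE,
                              threshold = 0.80, loa_factor = 1.96,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$generic_cmvr) && cfg$generic_cmvr <= 0)
    stop("generic_cmvr must be > 0")
  structure(cfg, class = "experiment_config")
}

#' Run the three-model comparison experiment
#'
#' End to end: compute per-vessel reference CMVR from measured pressures,
#' fit the clinical (B) and clinical + echo (C) prediction models on a
#' training partition, compute vFFR for all three model variants on the
#' evaluation vessels, and report agreement and diagnostic accuracy
#' against measured FFR. Model C is fit and evaluated on the vessels with
#' echo measurements available. Fully deterministic given config + seed.
#'
#' @param config an [experiment_config()].
#' @param cohort optional cohort data.frame; generated from
#'   `config$synthetic` when `NULL`.
#' @return object of class `model_comparison`. `$reports` holds the
#'   primary per-model [diagnostic_report()]s, all computed on the same
#'   vessel set (the evaluation vessels with echo available) so the three
#'   models are directly comparable; `$reports_full` repeats A and B on
#'   the full evaluation set. Also included: the per-vessel table, the
#'   fitted models with their held-out [evaluate_model()] reports, and
#'   the id bookkeeping of the train/evaluation partition.
#' @export
compare_models <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    if (is.null(config$synthetic))
      stop("no cohort given and no synthetic config to generate one")
    cohort <- generate_cohort(config$synthetic)
  }
  n <- nrow(cohort)
  seeds <- .spawn_seeds(config$seed, 5L)

  ref <- compute_reference_cmvr(cohort)
  cohort$cmvr_computed <- ref$cmvr_computed
  usable <- ref$ok

  if (config$holdout) {
    set.seed(seeds[1])
    train <- sort(sample.int(n, floor(config$train_frac * n)))
    eval_idx <- setdiff(seq_len(n), train)
  } else {
    train <- seq_len(n)
    eval_idx <- seq_len(n)
  }
  train_fit <- intersect(train, which(usable))

  feats_b <- cmvr_feature_set("clinical")
  feats_c <- cmvr_feature_set("clinical_echo")
  echo <- which(cohort$echo_available %in% TRUE)

  model_b <- fit_cmvr_model(cohort[train_fit, , drop = FALSE],
                            cohort$cmvr_computed[train_fit],
                            features = feats_b,
                            n_final_terms = config$n_terms_b,
                            n_splits = config$n_splits,
                            train_frac = config$train_frac,
                            max_degree = config$max_degree,
                            err_threshold = config$err_threshold,
                            seed = seeds[2])
  train_c <- intersect(train_fit, echo)
  model_c <- fit_cmvr_model(cohort[train_c, , drop = FALSE],
                            cohort$cmvr_computed[train_c],
                            features = feats_c,
                            n_final_terms = config$n_terms_c,
                            n_splits = config$n_splits,
                            train_frac = config$train_frac,
                            max_degree = config$max_degree,
                            err_threshold = config$err_threshold,
                            seed = seeds[3])

  generic <- config$generic_cmvr
  if (is.null(generic)) generic <- mean(cohort$cmvr_computed[train_fit])

  ev <- cohort[eval_idx, , drop = FALSE]
  ev_echo_idx <- intersect(eval_idx, echo)
  ev_c <- cohort[ev_echo_idx, , drop = FALSE]

  vffr_a <- run_model_a(ev, generic)
  vffr_b <- run_model_bc(ev, model_b)
  vffr_c_sub <- run_model_bc(ev_c, model_c)

  per_vessel <- data.frame(
    id = ev$id, ffr_measured = ev$ffr_measured,
    vffr_A = vffr_a, vffr_B = vffr_b,
    vffr_C = NA_real_,
    cmvr_computed = ev$cmvr_computed,
    cmvr_pred_B = predict(model_b, ev, type = "response"),
    cmvr_pred_C = NA_real_, stringsAsFactors = FALSE)
  if ("cmvr_true" %in% names(ev)) per_vessel$cmvr_true <- ev$cmvr_true
  m <- match(ev_c$id, per_vessel$id)
  per_vessel$vffr_C[m] <- vffr_c_sub
  per_vessel$cmvr_pred_C[m] <- predict(model_c, ev_c, type = "response")

  # primary comparison on the common vessel set (echo available), so the
  # three models are scored on identical vessels; A and B additionally
  # reported on the full evaluation set
  common <- match(ev_c$id, ev$id)
  reports <- list(
    A = diagnostic_report(vffr_a[common], ev_c$ffr_measured, config$threshold,
                          config$loa_factor),
    B = diagnostic_report(vffr_b[common], ev_c$ffr_measured, config$threshold,
                          config$loa_factor),
    C = diagnostic_report(vffr_c_sub, ev_c$ffr_measured, config$threshold,
                          config$loa_factor))
  reports_full <- list(
    A = diagnostic_report(vffr_a, ev$ffr_measured, config$threshold,
                          config$loa_factor),
    B = diagnostic_report(vffr_b, ev$ffr_measured, config$threshold,
                          config$loa_factor))

  fit_b_rows <- which(usable)
  fit_c_rows <- intersect(fit_b_rows, echo)
  fit_reports <- list(
    B = evaluate_model(model_b, cohort[fit_b_rows, , drop = FALSE],
                       log(cohort$cmvr_computed[fit_b_rows]),
                       n_reps = config$eval_reps, leave_out = config$leave_out,
                       seed = seeds[4]),
    C = evaluate_model(model_c, cohort[fit_c_rows, , drop = FALSE],
                       log(cohort$cmvr_computed[fit_c_rows]),
                       n_reps = config$eval_reps, leave_out = config$leave_out,
                       seed = seeds[5]))

  structure(list(reports = reports,
                 reports_full = reports_full,
                 per_vessel = per_vessel,
                 models = list(B = model_b, C = model_c),
                 fit_reports = fit_reports,
                 generic_cmvr = generic,
                 cmvr_flags = ref[!ref$ok, , drop = FALSE],
                 train_ids = cohort$id[train],
                 eval_ids = cohort$id[eval_idx],
                 config = config),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Three-model vFFR comparison (generic CMVR",
      sprintf("%.3g Pa s/m3)\n", x$generic_cmvr))
  for (m in names(x$reports)) {
    cat(sprintf("Model %s: ", m)); print(x$reports[[m]])
  }
  cat(sprintf("CMVR model held-out: B r %.2f R2 %.2f | C r %.2f R2 %.2f\n",
              x$fit_reports$B$mean_r, x$fit_reports$B$mean_r_squared,
              x$fit_reports$C$mean_r, x$fit_reports$C$mean_r_squared))
  invisible(x)
}

#' Write the comparison reports to disk
#'
#' Emits three files into `dir`: `comparison.json` (the full metric set
#' and configuration echo), `metrics.csv` (one row per model variant) and
#' `per_vessel.csv`. Output depends only on the comparison object, so
#' identical experiments produce byte-identical files.
#'
#' @param comparison a `model_comparison`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "model_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- do.call(rbind, lapply(comparison$reports, .report_row))
  metrics <- cbind(model = rownames(metrics), metrics)
  rownames(metrics) <- NULL

  paths <- file.path(dir, c("comparison.json", "metrics.csv", "per_vessel.csv"))
  payload <- list(
    generic_cmvr = comparison$generic_cmvr,
    metrics = metrics,
    cmvr_model_fit = list(
      B = list(mean_r = comparison$fit_reports$B$mean_r,
               mean_r_squared = comparison$fit_reports$B$mean_r_squared),
      C = list(mean_r = comparison$fit_reports$C$mean_r,
               mean_r_squared = comparison$fit_reports$C$mean_r_squared)),
    n_train = length(comparison$train_ids),
    n_eval = length(comparison$eval_ids),
    seed = comparison$config$seed)
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  utils::write.csv(format(metrics, digits = 17, trim = TRUE), paths[2],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format(comparison$per_vessel, digits = 17, trim = TRUE),
                   paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
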