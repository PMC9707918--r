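# The repeated-split term-frequency protocol: the model structure is not
# taken from a single FROLS run but from the terms most frequently
# selected across 100 random 75/25 train/test splits, then refit on the
# full data. Evaluation uses a separate 100-replicate 20%-leave-out
# resampling of held-out correlation and R-squared.

# per-replicate seeds derived from one master seed (kept < 2^31)
.spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Term-frequency model building over repeated random splits
#'
#' Runs [frols_select()] on each of `n_splits` seeded random splits
#' (training fraction `train_frac`), tallies how often each candidate term
#' is selected, and builds the final model from the `n_final_terms` most
#' frequently selected terms, refit by ordinary least squares on the full
#' data. Ties at the cutoff frequency are broken by mean ERR across the
#' splits where the term was selected, then by canonical term order.
#'
#' Within every split, the feature standardization constants (and, when
#' the data contain missing values, the median/mode imputation constants)
#' are learned on the training portion only.
#'
#' @param data data.frame of raw features.
#' @param y numeric response (same length as `nrow(data)`).
#' @param features character vector of feature columns.
#' @param n_final_terms number of terms (excluding the intercept) in the
#'   final model.
#' @param max_degree maximum polynomial degree of candidate terms.
#' @param n_splits number of random train/test splits (default 100).
#' @param train_frac training fraction per split (default 0.75).
#' @param err_threshold,max_terms per-split FROLS stopping rule;
#'   `max_terms` defaults to `n_final_terms`.
#' @param seed master seed; all split randomness derives from it.
#' @return object of class `narmax_model`: selected terms with
#'   coefficients and per-term ERR (full-data fit), the full
#'   selection-frequency table, the design dictionary (standardization
#'   constants and categorical encodings), and any imputation constants.
#' @seealso [evaluate_model()], [predict.narmax_model()]
#' @export
frequency_select <- function(data, y, features,
                             n_final_terms = 16L,
                             max_degree = 2L,
                             n_splits = 100L,
                             train_frac = 0.75,
                             err_threshold = 0.995,
                             max_terms = NULL,
                             seed = 1L) {
  n <- nrow(data)
  if (length(y) != n) stop("length(y) must equal nrow(data)")
  if (is.null(max_terms)) max_terms <- n_final_terms
  n_train <- floor(train_frac * n)
  if (n_train <= max_terms + 1L)
    stop("training split (", n_train, " rows) too small for ", max_terms, " terms")
  seeds <- .spawn_seeds(seed, n_splits + 1L)

  # candidate labels are structural: identical across splits
  ref_dict <- design_dictionary(data, features)
  ref_lib <- build_candidate_library(ref_dict, max_degree)
  lab <- labels(ref_lib)
  freq <- stats::setNames(integer(length(lab)), lab)
  err_sum <- stats::setNames(numeric(length(lab)), lab)

  for (s in seq_len(n_splits)) {
    set.seed(seeds[s])
    idx <- sample.int(n, n_train)
    train <- data[idx, , drop = FALSE]
    if (anyNA(train[features])) train <- impute_missing(train, features)
    dict <- design_dictionary(train, features, template = ref_dict)
    # library structure depends only on column names; reuse across splits
    P <- evaluate_terms(ref_lib, encode_design(dict, train))
    fit <- frols_select(P, y[idx], err_threshold = err_threshold,
                        max_terms = max_terms)
    freq[fit$terms] <- freq[fit$terms] + 1L
    err_sum[fit$terms] <- err_sum[fit$terms] + fit$err
  }

  mean_err <- ifelse(freq > 0, err_sum / freq, 0)
  cand <- setdiff(lab, "(Intercept)")
  ord <- order(-freq[cand], -mean_err[cand], seq_along(cand))
  chosen <- cand[ord][seq_len(min(n_final_terms, sum(freq[cand] > 0)))]
  chosen <- lab[lab %in% chosen]  # restore canonical order

  # final refit on the full data (full-data dictionary and imputation)
  full <- data
  impute_constants <- NULL
  if (anyNA(full[features])) {
    full <- impute_missing(full, features)
    impute_constants <- attr(full, "imputation_constants")
  }
  dict <- design_dictionary(full, features)
  libr <- build_candidate_library(dict, max_degree)
  keep <- labels(libr) %in% c("(Intercept)", chosen)
  final_lib <- structure(libr[keep], class = "term_library")
  P <- evaluate_terms(final_lib, encode_design(dict, full))
  final <- frols_select(P, y, err_threshold = 1, max_terms = length(chosen))

  structure(list(terms = final$terms,
                 coefficients = final$coefficients,
                 err = final$err,
                 r_squared = final$r_squared,
                 selection_frequency = freq,
                 mean_err = mean_err,
                 dictionary = dict,
                 library = final_lib,
                 features = features,
                 max_degree = max_degree,
                 n_splits = n_splits,
                 impute_constants = impute_constants,
                 log_response = FALSE,
                 n = n),
            class = "narmax_model")
}

#' @export
print.narmax_model <- function(x, ...) {
  cat(sprintf("Sparse polynomial model: %d terms + intercept (training R2 %.3f, n = %d)\n",
              length(x$terms), x$r_squared, x$n))
  if (isTRUE(x$log_response)) cat("  response fitted on the log scale\n")
  tab <- data.frame(term = x$terms,
                    coefficient = signif(x$coefficients[x$terms], 4),
                    ERR = signif(x$err[x$terms], 3),
                    frequency = x$selection_frequency[x$terms],
                    row.names = NULL)
  print(utils::head(tab[order(-tab$frequency, -tab$ERR), ], 20), row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted sparse polynomial model
#'
#' @param object a `narmax_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param type `"response"` back-transforms to the natural scale when the
#'   model was fitted on a log response; `"link"` returns the linear
#'   predictor as fitted.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.narmax_model <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("newdata lacks model feature column(s): ", paste(miss, collapse = ", "))
  if (anyNA(newdata[object$features])) {
    if (is.null(object$impute_constants))
      newdata <- impute_missing(newdata, object$features)
    else
      newdata <- impute_missing(newdata, object$features,
                                constants = object$impute_constants)
  }
  P <- evaluate_terms(object$library, encode_design(object$dictionary, newdata))
  eta <- drop(P[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
  if (type == "response" && isTRUE(object$log_response)) exp(eta) else eta
}

#' Held-out evaluation of a fixed model structure
#'
#' The replicated leave-out protocol: for each of `n_reps` seeded
#' replicates, a random `leave_out` fraction of rows is held out, the
#' model's coefficients (term structure fixed) are refit on the retained
#' rows, and Pearson correlation and R-squared (1 - SSE/SStot about the
#' held-out mean) are recorded on the held-out rows. Replicates with a
#' degenerate held-out set (constant response or constant prediction) are
#' skipped with a warning and the replicate count adjusted.
#'
#' @param model a `narmax_model`.
#' @param data data.frame with the model's feature columns.
#' @param y numeric response on the scale the model was fitted on (the
#'   linear-predictor scale; for a log-response CMVR model, log CMVR).
#' @param n_reps number of replicates (default 100).
#' @param leave_out held-out fraction per replicate (default 0.20).
#' @param seed master seed.
#' @return object of class `fit_report`: per-replicate `r` and
#'   `r_squared`, their means, and the effective replicate count.
#' @export
evaluate_model <- function(model, data, y, n_reps = 100L, leave_out = 0.20,
                           seed = 1L) {
  stopifnot(inherits(model, "narmax_model"))
  n <- nrow(data)
  if (length(y) != n) stop("length(y) must equal nrow(data)")
  n_out <- max(1L, floor(leave_out * n))
  if (n - n_out <= length(model$terms) + 1L)
    stop("retained fraction too small to refit ", length(model$terms), " terms")
  seeds <- .spawn_seeds(seed, n_reps)
  P_all <- evaluate_terms(model$library,
                          encode_design(model$dictionary,
                                        .impute_like(model, data)))
  cols <- names(model$coefficients)
  r <- r2 <- rep(NA_real_, n_reps)
  for (k in seq_len(n_reps)) {
    set.seed(seeds[k])
    out <- sample.int(n, n_out)
    fit <- stats::lm.fit(P_all[-out, cols, drop = FALSE], y[-out])
    pred <- drop(P_all[out, cols, drop = FALSE] %*%
                   ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    yo <- y[out]
    if (stats::sd(yo) == 0 || stats::sd(pred) == 0) {
      warning("replicate ", k, " skipped: degenerate held-out set")
      next
    }
    r[k] <- stats::cor(pred, yo)
    r2[k] <- 1 - sum((yo - pred)^2) / sum((yo - mean(yo))^2)
  }
  ok <- !is.na(r)
  structure(list(r = r, r_squared = r2,
                 mean_r = mean(r[ok]), mean_r_squared = mean(r2[ok]),
                 n_reps = n_reps, n_effective = sum(ok),
                 leave_out = leave_out),
            class = "fit_report")
}

.impute_like <- function(model, data) {
  if (!anyNA(data[model$features])) return(data)
  if (is.null(model$impute_constants)) impute_missing(data, model$features)
  else impute_missing(data, model$features, constants = model$impute_constants)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Held-out evaluation: %d/%d replicates (%.0f%% leave-out)\n",
              x$n_effective, x$n_reps, 100 * x$leave_out))
  cat(sprintf("  mean r = %.3f, mean R2 = %.3f\n", x$mean_r, x$mean_r_squared))
  invisible(x)
}

#' Median/mode imputation of missing feature values
#'
#' Continuous features are imputed with the median, categorical and
#' logical features with the mode. When `constants` is `NULL` the
#' imputation constants are learned from `data` itself (a training set);
#' passing the constants learned on a training set applies them to new
#' data without leakage.
#'
#' @param data data.frame.
#' @param features columns to impute; defaults to all columns with any
#'   missing value.
#' @param constants named list of imputation values as returned in the
#'   `"imputation_constants"` attribute of a previous call.
#' @return `data` with missing feature values filled in; the constants
#'   used are attached as attribute `"imputation_constants"`.
#' @export
impute_missing <- function(data, features = NULL, constants = NULL) {
  if (is.null(features))
    features <- names(data)[vapply(data, anyNA, TRUE)]
  if (is.null(constants)) {
    constants <- lapply(stats::setNames(features, features), function(f) {
      x <- data[[f]]
      xx <- x[!is.na(x)]
      if (length(xx) == 0L)
        stop("feature '", f, "' is entirely missing; cannot impute")
      if (is.numeric(x)) stats::median(xx)
      else names(sort(table(as.character(xx)), decreasing = TRUE))[1L]
    })
  }
  for (f in features) {
    x <- data[[f]]
    if (!anyNA(x)) next
    v <- constants[[f]]
    if (is.null(v)) stop("no imputation constant for feature '", f, "'")
    if (is.logical(x)) v <- as.logical(v)
    x[is.na(x)] <- v
    data[[f]] <- x
  }
  attr(data, "imputation_constants") <- constants
  data
}
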