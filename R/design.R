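# Feature encoding for polynomial model identification.
#
# Continuous features are standardized (training mean/sd); logicals become
# 0/1; categoricals are one-hot encoded with the first level as baseline.
# The encoding constants live in the dictionary so that a fitted model can
# be applied to new data on exactly the scale it was trained on, and so
# predictions are invariant to affine rescaling of the raw inputs.

#' Build a design dictionary from training data
#'
#' @param data data.frame of raw features.
#' @param features character vector of feature column names to encode.
#' @param template optional `design_dictionary` whose categorical level
#'   sets are reused (level sets are structural: a resampled training set
#'   may lack a rare level, but the indicator columns must stay aligned);
#'   standardization constants are still learned from `data`.
#' @return object of class `design_dictionary` holding, per feature, its
#'   kind (continuous / binary / categorical), standardization constants,
#'   and categorical level maps.
#' @export
design_dictionary <- function(data, features, template = NULL) {
  if (length(features) == 0L) stop("empty feature set")
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols))
    stop("feature column(s) not in data: ", paste(missing_cols, collapse = ", "))
  enc <- list()
  for (f in features) {
    x <- data[[f]]
    if (is.logical(x)) {
      enc[[f]] <- list(kind = "binary")
    } else if (is.character(x) || is.factor(x)) {
      lev <- if (!is.null(template) &&
                 identical(template$encoding[[f]]$kind, "categorical"))
        template$encoding[[f]]$levels
      else if (is.factor(x)) levels(x)
      else sort(unique(x[!is.na(x)]))
      if (length(lev) < 2L)
        stop("categorical feature '", f, "' has fewer than two levels")
      enc[[f]] <- list(kind = "categorical", levels = lev)
    } else {
      m <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      enc[[f]] <- list(kind = "continuous", center = m, scale = s)
    }
  }
  structure(list(features = features, encoding = enc),
            class = "design_dictionary")
}

#' Encode raw data into the base-column matrix
#'
#' Column names are the raw feature name for continuous/binary columns
#' and `"feature=level"` for one-hot indicators (baseline level omitted).
#' Continuous columns are standardized with the dictionary's constants.
#'
#' @param dictionary a [design_dictionary()].
#' @param data data.frame with the dictionary's feature columns.
#' @return numeric matrix with a logical `"binary"` attribute flagging
#'   indicator columns.
#' @export
encode_design <- function(dictionary, data) {
  stopifnot(inherits(dictionary, "design_dictionary"))
  cols <- list()
  binary <- logical()
  for (f in dictionary$features) {
    e <- dictionary$encoding[[f]]
    x <- data[[f]]
    if (is.null(x)) stop("column '", f, "' missing from data")
    if (e$kind == "continuous") {
      cols[[f]] <- (as.numeric(x) - e$center) / e$scale
      binary[f] <- FALSE
    } else if (e$kind == "binary") {
      cols[[f]] <- as.numeric(x)
      binary[f] <- TRUE
    } else {
      x <- as.character(x)
      bad <- setdiff(unique(x[!is.na(x)]), e$levels)
      if (length(bad))
        stop("feature '", f, "' has unseen level(s): ", paste(bad, collapse = ", "))
      for (lv in e$levels[-1L]) {
        nm <- paste0(f, "=", lv)
        cols[[nm]] <- as.numeric(x == lv)
        binary[nm] <- TRUE
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  attr(X, "binary") <- binary
  X
}
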