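# Sparse polynomial identification of CMVR predictors.
#
# The identification engine is forward-regression orthogonal least squares
# (FROLS) with the error-reduction ratio (ERR) as the selection statistic
# -- the standard structure-selection machinery of the NARMAX family. The
# response here is a static per-vessel quantity, so the autoregressive and
# noise lags of the general NARMAX form degenerate and the model is the
# static exogenous polynomial special case: a sparse linear-in-parameters
# model over monomials of the (encoded) features.

#' Candidate polynomial term library
#'
#' Enumerates the intercept plus every monomial of total degree up to
#' `max_degree` over the dictionary's base columns (standardized
#' continuous features and one-hot indicators). Powers of 2 and above on
#' binary/indicator columns are dropped as duplicates (an indicator is
#' idempotent). Terms are ordered by degree, then lexicographically by
#' label, and this canonical order is the deterministic tie-break used
#' throughout selection.
#'
#' With `p` continuous features and `max_degree = 2` the library has
#' `1 + p + p(p+1)/2` terms.
#'
#' @param dictionary a [design_dictionary()].
#' @param max_degree maximum total degree of a term (>= 1; default 2).
#' @return object of class `term_library`: a list of terms, each with a
#'   `label`, base-column names `vars`, and integer `powers`.
#' @export
build_candidate_library <- function(dictionary, max_degree = 2L) {
  stopifnot(inherits(dictionary, "design_dictionary"))
  max_degree <- as.integer(max_degree)
  if (max_degree < 1L) stop("max_degree must be >= 1")
  # probe encode on a minimal synthetic row to learn base-column names
  probe <- .dictionary_probe(dictionary)
  X <- encode_design(dictionary, probe)
  base <- colnames(X)
  binary <- attr(X, "binary")

  terms <- list(list(label = "(Intercept)", vars = character(), powers = integer()))
  combos <- lapply(seq_len(max_degree), function(d) {
    # multisets of size d over base columns, indices non-decreasing
    idx <- .multisets(length(base), d)
    idx
  })
  for (d in seq_len(max_degree)) {
    for (k in seq_len(nrow(combos[[d]]))) {
      ix <- combos[[d]][k, ]
      tab <- table(ix)
      vars <- base[as.integer(names(tab))]
      powers <- as.integer(tab)
      if (any(binary[vars] & powers > 1L)) next  # idempotent indicator
      terms[[length(terms) + 1L]] <- list(label = .term_label(vars, powers),
                                          vars = vars, powers = powers)
    }
  }
  labels <- vapply(terms, `[[`, "", "label")
  keep <- !duplicated(labels)
  terms <- terms[keep]; labels <- labels[keep]
  deg <- vapply(terms, function(t) sum(t$powers), 0L)
  ord <- order(deg, labels)
  structure(terms[ord], class = "term_library")
}

# all multisets of size d from 1..n as a matrix with sorted rows
.multisets <- function(n, d) {
  if (d == 1L) return(matrix(seq_len(n), ncol = 1L))
  prev <- .multisets(n, d - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    rows <- prev[prev[, d - 1L] <= i, , drop = FALSE]
    cbind(rows, i)
  }))
  unname(out)
}

.term_label <- function(vars, powers) {
  if (length(vars) == 0L) return("(Intercept)")
  parts <- ifelse(powers > 1L, paste0(vars, "^", powers), vars)
  paste(parts[order(vars)], collapse = ":")
}

# one synthetic row sufficient to encode: numeric 0, logical FALSE,
# categorical first level
.dictionary_probe <- function(dictionary) {
  row <- lapply(dictionary$encoding, function(e) {
    switch(e$kind,
           continuous = 0,
           binary = FALSE,
           categorical = e$levels[1L])
  })
  as.data.frame(row, col.names = dictionary$features,
                check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf("Candidate term library: %d terms (max degree %d)\n",
              length(x), max(vapply(x, function(t) sum(t$powers), 0L))))
  invisible(x)
}

#' @export
labels.term_library <- function(object, ...) {
  vapply(object, `[[`, "", "label")
}

#' Evaluate a term library on an encoded base matrix
#'
#' @param library a [build_candidate_library()] result.
#' @param X encoded base matrix from [encode_design()].
#' @return n x M matrix of candidate regressor columns (including the
#'   intercept column of ones), labelled by term.
#' @export
evaluate_terms <- function(library, X) {
  stopifnot(inherits(library, "term_library"))
  n <- nrow(X)
  M <- length(library)
  out <- matrix(1, n, M)
  for (j in seq_len(M)) {
    t <- library[[j]]
    for (k in seq_along(t$vars))
      out[, j] <- out[, j] * X[, t$vars[k]]^t$powers[k]
  }
  colnames(out) <- labels(library)
  out
}

#' Forward-regression orthogonal least squares (FROLS) term selection
#'
#' Greedy forward selection over candidate regressor columns: at each
#' step, every remaining candidate is orthogonalized against the already
#' selected basis and the one with the largest error-reduction ratio
#' (ERR) -- its share of the centred response variance -- is selected.
#' Selection stops when the cumulative ERR reaches `err_threshold`, when
#' `max_terms` terms are selected, or when no candidate reduces the error
#' further. Final coefficients come from an ordinary least-squares refit
#' of the response on the selected (un-orthogonalized) terms plus an
#' intercept.
#'
#' ERR is computed on the centred response, so the cumulative ERR of the
#' selected set equals the training R-squared of the refitted model. On an
#' orthogonal design each candidate's ERR is its squared correlation with
#' the response.
#'
#' @param X numeric matrix of candidate regressor columns (an intercept /
#'   constant column, if present, is ignored for selection and always
#'   included in the refit).
#' @param y numeric response vector.
#' @param err_threshold stop once cumulative ERR reaches this value
#'   (default 0.995).
#' @param max_terms maximum number of terms to select (default `Inf`).
#' @return object of class `frols_fit`: list with `terms` (selected column
#'   labels, in selection order), `coefficients` (named, intercept first),
#'   `err` (per-term ERR, selection order), `cum_err`, `r_squared`, `n`.
#' @examples
#' set.seed(1)
#' x1 <- rnorm(100); x2 <- rnorm(100)
#' X <- cbind(x1 = x1, x2 = x2)
#' frols_select(X, 2 * x1)   # picks x1, ERR 1, coefficient 2
#' @export
frols_select <- function(X, y, err_threshold = 0.995, max_terms = Inf) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) stop("response has zero variance; nothing to identify")
  W <- scale(X, center = TRUE, scale = FALSE)  # constant columns vanish
  orig_norm2 <- colSums(W^2)
  available <- orig_norm2 > 1e-12 * max(orig_norm2, 1)
  norm2 <- colSums(W^2)

  selected <- integer(0)
  errs <- numeric(0)
  while (length(selected) < max_terms) {
    ok <- available & norm2 > 1e-10 * pmax(orig_norm2, .Machine$double.eps)
    if (!any(ok)) break
    num <- as.numeric(crossprod(W, yc))^2
    e <- ifelse(ok, num / (norm2 * syy), -Inf)
    j <- which.max(e)                 # ties -> first in canonical order
    if (e[j] <= .Machine$double.eps) break
    selected <- c(selected, j)
    errs <- c(errs, e[j])
    w <- W[, j]
    available[j] <- FALSE
    proj <- as.numeric(crossprod(W, w)) / sum(w^2)
    proj[!available] <- 0
    W <- W - tcrossprod(w, proj)
    norm2 <- colSums(W^2)
    if (sum(errs) >= err_threshold) break
  }
  if (length(selected) == 0L)
    stop("no candidate term explains any response variance")

  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, selected, drop = FALSE]), y)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    drop <- names(coefs)[is.na(coefs)]
    warning("rank-deficient selected set; dropping: ", paste(drop, collapse = ", "))
    keep <- !(colnames(X)[selected] %in% drop)
    selected <- selected[keep]; errs <- errs[keep]
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, selected, drop = FALSE]), y)
    coefs <- fit$coefficients
  }
  r2 <- 1 - sum(fit$residuals^2) / syy
  structure(list(terms = colnames(X)[selected],
                 coefficients = coefs,
                 err = stats::setNames(errs, colnames(X)[selected]),
                 cum_err = sum(errs),
                 r_squared = r2,
                 n = n),
            class = "frols_fit")
}

#' @export
print.frols_fit <- function(x, ...) {
  cat(sprintf("FROLS fit: %d term(s), cumulative ERR %.4f (training R2 %.4f, n = %d)\n",
              length(x$terms), x$cum_err, x$r_squared, x$n))
  tab <- data.frame(term = x$terms, ERR = round(x$err, 4),
                    coefficient = round(x$coefficients[-1L], 4), row.names = NULL)
  print(tab)
  invisible(x)
}
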