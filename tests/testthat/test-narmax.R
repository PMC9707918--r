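# candidate library, FROLS selection, frequency protocol, evaluation,
# imputation

test_that("candidate library has the predicted combinatorial size", {
  d <- data.frame(x1 = rnorm(10), x2 = rnorm(10))
  lib <- build_candidate_library(design_dictionary(d, c("x1", "x2")), 2)
  expect_setequal(labels(lib),
                  c("(Intercept)", "x1", "x2", "x1^2", "x1:x2", "x2^2"))
  # single binary feature: its square collapses
  db <- data.frame(b = c(TRUE, FALSE, TRUE))
  libb <- build_candidate_library(design_dictionary(db, "b"), 2)
  expect_setequal(labels(libb), c("(Intercept)", "b"))
  # p continuous features, degree 2: 1 + p + p(p+1)/2 terms
  for (p in c(3, 5, 8)) {
    dp <- as.data.frame(matrix(rnorm(5 * p), 5, p))
    names(dp) <- paste0("v", seq_len(p))
    libp <- build_candidate_library(design_dictionary(dp, names(dp)), 2)
    expect_length(libp, 1 + p + p * (p + 1) / 2)
  }
  # categorical one-hot indicators are idempotent and cross with continuous
  dc <- data.frame(x = rnorm(10),
                   v = rep(c("LAD", "LCX", "RCA"), length.out = 10))
  libc <- build_candidate_library(design_dictionary(dc, c("x", "v")), 2)
  lab <- labels(libc)
  expect_true(all(c("v=LCX", "v=RCA", "v=LCX:x", "x^2") %in% lab))
  expect_false(any(grepl("v=LCX\\^2", lab)))
})

test_that("a noiseless single-term truth is recovered with ERR 1 and exact coefficient", {
  set.seed(10)
  x1 <- rnorm(100); x2 <- rnorm(100)
  fit <- frols_select(cbind(x1 = x1, x2 = x2), 2 * x1)
  expect_identical(fit$terms, "x1")
  expect_equal(unname(fit$err[["x1"]]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[["x1"]]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0, tolerance = 1e-12)
})

test_that("a planted interaction is found ahead of noise candidates", {
  set.seed(11)
  n <- 200
  d <- data.frame(matrix(rnorm(n * 6), n, 6))
  names(d) <- paste0("x", 1:6)
  y <- d$x1 + d$x1 * d$x2 + rnorm(n, 0, 0.05)
  dict <- design_dictionary(d, names(d))
  P <- evaluate_terms(build_candidate_library(dict, 2), encode_design(dict, d))
  fit <- frols_select(P, y, max_terms = 4)
  expect_true(all(c("x1", "x1:x2") %in% fit$terms))
  # the two true terms carry the two largest ERR values
  expect_setequal(names(sort(fit$err, decreasing = TRUE))[1:2],
                  c("x1", "x1:x2"))
})

test_that("on an orthogonal design ERR equals squared correlation and sums to R2", {
  set.seed(12)
  n <- 64
  # mean-zero orthonormal columns (orthogonal to the constant as well, so
  # centring inside the selector leaves them orthogonal)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, -1]
  colnames(X) <- paste0("q", 1:4)
  beta <- c(2, -1, 0.5, 0)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  fit <- frols_select(X, y, err_threshold = 1, max_terms = 4)
  for (term in fit$terms)
    expect_equal(unname(fit$err[[term]]), cor(X[, term], y)^2,
                 tolerance = 1e-9)
  full <- lm.fit(cbind(1, X), y)
  r2_full <- 1 - sum(full$residuals^2) / sum((y - mean(y))^2)
  expect_equal(fit$cum_err, r2_full, tolerance = 1e-9)
})

test_that("cumulative ERR equals the training R2 of the refitted model", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(50:150, 1)
    p <- sample(4:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("c", seq_len(p))
    beta <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- X %*% beta + rnorm(n)
    fit <- frols_select(X, drop(y), err_threshold = 0.999,
                        max_terms = sample(2:p, 1))
    expect_equal(fit$cum_err, fit$r_squared, tolerance = 1e-9)
  }
})

test_that("FROLS matches exhaustive best-subset R2 on small libraries", {
  set.seed(14)
  worst <- 0
  for (i in 1:60) {
    n <- 80
    M <- sample(6:12, 1)
    X <- matrix(rnorm(n * M), n, M)
    # mildly correlated candidates to make selection non-trivial
    X <- X + rnorm(n) %o% runif(M, 0, 0.5)
    colnames(X) <- paste0("c", seq_len(M))
    k <- sample(1:3, 1)
    beta <- numeric(M); beta[sample.int(M, k)] <- runif(k, 0.5, 2)
    y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
    fit <- frols_select(X, y, err_threshold = 1, max_terms = k)
    oracle <- best_subset_r2(X, y, length(fit$terms))
    worst <- max(worst, oracle - fit$r_squared)
  }
  expect_lt(worst, 0.02)
})

test_that("zero-variance response and empty designs are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(frols_select(X, rep(1, 20)), "zero variance")
  expect_error(design_dictionary(data.frame(x = 1), character()), "empty")
})

test_that("frequency selection is deterministic and finds a noiseless truth always", {
  set.seed(15)
  d <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
  y <- 2 * d$x1
  m1 <- frequency_select(d, y, c("x1", "x2"), n_final_terms = 1, seed = 7)
  m2 <- frequency_select(d, y, c("x1", "x2"), n_final_terms = 1, seed = 7)
  expect_identical(m1$selection_frequency, m2$selection_frequency)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$terms, "x1")
  expect_identical(unname(m1$selection_frequency[["x1"]]), 100L)
  # exact recovery of the noiseless generating function
  expect_equal(predict(m1, d), y, tolerance = 1e-10)
})

test_that("the frequency protocol recovers a planted five-term model", {
  set.seed(16)
  hits <- 0
  for (rep in 1:5) {
    pl <- planted_polynomial(n = 300)
    m <- frequency_select(pl$data, pl$y, names(pl$data),
                          n_final_terms = 8, seed = rep)
    if (all(pl$terms %in% m$terms)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("predictions are invariant to affine rescaling of raw features", {
  set.seed(17)
  pl <- planted_polynomial(n = 250)
  m <- frequency_select(pl$data, pl$y, names(pl$data),
                        n_final_terms = 8, seed = 3)
  new <- head(pl$data, 40)
  p1 <- predict(m, new)
  scaled <- pl$data
  scales <- c(3, 0.2, 10, 7, 0.5, 100)
  shifts <- c(-2, 5, 0.3, -40, 1, 9)
  for (j in 1:6) scaled[[j]] <- scaled[[j]] * scales[j] + shifts[j]
  m_s <- frequency_select(scaled, pl$y, names(scaled),
                          n_final_terms = 8, seed = 3)
  new_s <- head(scaled, 40)
  p2 <- predict(m_s, new_s)
  expect_identical(m$terms, m_s$terms)  # standardization makes terms agree
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("held-out evaluation is exact for a perfect model and null for intercept-only", {
  set.seed(18)
  d <- data.frame(x1 = rnorm(250), x2 = rnorm(250))
  y <- 1 + 2 * d$x1 - d$x2
  m <- frequency_select(d, y, c("x1", "x2"), n_final_terms = 2, seed = 4)
  rep1 <- evaluate_model(m, d, y, n_reps = 50, seed = 5)
  expect_equal(rep1$mean_r, 1, tolerance = 1e-9)
  expect_equal(rep1$mean_r_squared, 1, tolerance = 1e-9)
  expect_identical(rep1$n_effective, 50L)
  # same seed reproduces the report exactly
  rep2 <- evaluate_model(m, d, y, n_reps = 50, seed = 5)
  expect_identical(rep1$r_squared, rep2$r_squared)

  # a model with no explanatory power has held-out R2 <= 0 + noise
  ynoise <- rnorm(250)
  m0 <- frequency_select(d, ynoise, c("x1", "x2"), n_final_terms = 2, seed = 6)
  rep0 <- evaluate_model(m0, d, ynoise, n_reps = 100, seed = 7)
  expect_lt(rep0$mean_r_squared, 0.1)
})

test_that("held-out R2 of the planted model tracks the generative R2", {
  set.seed(19)
  pl <- planted_polynomial(n = 500, noise_to_signal = 3 / 7)  # R2 = 0.7
  m <- frequency_select(pl$data, pl$y, names(pl$data),
                        n_final_terms = 8, seed = 8)
  ev <- evaluate_model(m, pl$data, pl$y, n_reps = 100, seed = 9)
  expect_gt(ev$mean_r_squared, pl$r2_generative - 0.1)
  expect_lt(ev$mean_r_squared, pl$r2_generative + 0.1)
})

test_that("imputation uses medians/modes and learns only from training data", {
  d <- data.frame(num = c(1, 2, 3, NA), cat = c("a", "a", "b", NA),
                  flag = c(TRUE, TRUE, NA, FALSE), stringsAsFactors = FALSE)
  imp <- impute_missing(d)
  expect_identical(imp$num[4], 2)
  expect_identical(imp$cat[4], "a")
  expect_identical(imp$flag[3], TRUE)
  # no missing values: identity
  full <- data.frame(a = 1:3)
  expect_identical(impute_missing(full)$a, full$a)
  # constants learned on one split apply unchanged to another
  train1 <- data.frame(num = c(1, 2, 3))
  train2 <- data.frame(num = c(10, 20, 30))
  c1 <- attr(impute_missing(train1, "num"), "imputation_constants")
  c2 <- attr(impute_missing(train2, "num"), "imputation_constants")
  expect_false(identical(c1$num, c2$num))
  test <- data.frame(num = c(NA, 5))
  expect_identical(impute_missing(test, "num", constants = c1)$num[1], 2)
  expect_identical(impute_missing(test, "num", constants = c2)$num[1], 20)
  # entirely missing feature cannot be imputed
  expect_error(impute_missing(data.frame(z = c(NA_real_, NA_real_)), "z"),
               "entirely missing")
})

test_that("the protocol imputes within each split and still identifies structure", {
  set.seed(20)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  y <- 2 * d$x1 + rnorm(300, 0, 0.2)
  d$x2[sample.int(300, 30)] <- NA
  m <- frequency_select(d, y, c("x1", "x2"), n_final_terms = 1, seed = 11)
  expect_identical(m$terms, "x1")
  pred <- predict(m, data.frame(x1 = c(0, 1), x2 = c(NA, NA)))
  expect_equal(diff(pred), 2, tolerance = 0.05)
})
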