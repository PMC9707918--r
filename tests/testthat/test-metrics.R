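# agreement and diagnostic-accuracy statistics

test_that("classification is closed at the 0.80 threshold", {
  expect_identical(classify_ffr(c(0.80, 0.81, 0.5)), c(TRUE, FALSE, TRUE))
  expect_identical(classify_ffr(numeric()), logical())
  expect_error(classify_ffr(c(0.5, NA)), "non-finite")
})

test_that("2x2 table arithmetic matches hand computation", {
  # construct vectors realising TP=40, FP=5, FN=10, TN=45
  truth_pos <- c(rep(0.7, 40), rep(0.7, 10))   # 50 measured-positive
  truth_neg <- c(rep(0.9, 5), rep(0.9, 45))    # 50 measured-negative
  test_vals <- c(rep(0.7, 40), rep(0.9, 10), rep(0.7, 5), rep(0.9, 45))
  dt <- diagnostic_table(test_vals, c(truth_pos, truth_neg))
  expect_equal(dt$sensitivity, 0.80)
  expect_equal(dt$specificity, 0.90)
  expect_equal(dt$ppv, 8 / 9)
  expect_equal(dt$npv, 45 / 55)
  expect_equal(dt$accuracy, 0.85)

  # perfect agreement
  x <- c(0.6, 0.85, 0.79, 0.95)
  dtp <- diagnostic_table(x, x)
  expect_equal(unlist(dtp[c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))

  # all-negative truth: sensitivity undefined, reported as NA not 0
  dtn <- diagnostic_table(c(0.9, 0.9), c(0.9, 0.95))
  expect_true(is.na(dtn$sensitivity))
  expect_true(is.na(dtn$ppv))   # no test-positives either
  expect_error(diagnostic_table(1:3 / 4, 1:2 / 4), "mismatch")
})

test_that("accuracy decomposes as sens*prev + spec*(1-prev)", {
  set.seed(30)
  for (i in 1:20) {
    n <- 200
    meas <- runif(n, 0.4, 1)
    vffr <- pmin(1, pmax(0.05, meas + rnorm(n, 0, 0.08)))
    dt <- diagnostic_table(vffr, meas)
    prev <- mean(classify_ffr(meas))
    if (is.na(dt$sensitivity) || is.na(dt$specificity)) next
    expect_equal(dt$accuracy,
                 dt$sensitivity * prev + dt$specificity * (1 - prev),
                 tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals brute-force pairwise concordance", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    labels <- rep(c(TRUE, FALSE), length.out = n)[sample.int(n)]
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
  # independent implementation agrees (pROC computes the trapezoidal ROC area)
  set.seed(40)
  sc <- rnorm(80); lb <- runif(80) < 0.4
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::roc(lb, sc, direction = "<",
                                    quiet = TRUE)$auc),
               tolerance = 1e-12)
  # perfect separation and a null classifier
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, rep(FALSE, 3))), 1)
  set.seed(32)
  lab <- rep(c(TRUE, FALSE), 2000)
  expect_equal(roc_auc(rnorm(4000), lab), 0.5, tolerance = 0.03)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Bland-Altman bias and limits match hand computation", {
  x <- c(0.7, 0.9)
  ba <- bland_altman(x + c(-0.1, 0.1), x, loa_factor = 2)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2) * 0.1, tolerance = 1e-12)
  expect_equal(unname(ba$loa), c(-2, 2) * sqrt(2) * 0.1, tolerance = 1e-12)

  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(unname(same$loa), c(0, 0))

  # translation equivariance
  set.seed(33)
  v <- runif(50, 0.4, 1); m <- runif(50, 0.4, 1)
  b0 <- bland_altman(v, m); b1 <- bland_altman(v + 0.05, m)
  expect_equal(b1$bias, b0$bias + 0.05, tolerance = 1e-12)
  expect_equal(b1$sd, b0$sd, tolerance = 1e-12)
  expect_error(bland_altman(0.5, 0.5), "two")
})

test_that("1.96-SD limits cover about 95% of Gaussian differences", {
  set.seed(34)
  cover <- replicate(40, {
    m <- runif(2000, 0.5, 1)
    v <- m + rnorm(2000, 0.02, 0.05)
    ba <- bland_altman(v, m)
    mean(v - m >= ba$loa[1] & v - m <= ba$loa[2])
  })
  expect_equal(mean(cover), 0.95, tolerance = 0.02)
})

test_that("accuracy curve dips near the decision threshold", {
  # single occupied bin reproduces the overall accuracy
  v <- c(0.72, 0.75, 0.78); m <- c(0.7, 0.85, 0.74)
  cur <- accuracy_curve(v, m, breaks = c(0, 0.7, 0.8, 1))
  expect_equal(cur$accuracy[2], mean(classify_ffr(v) == classify_ffr(m)))
  expect_true(is.na(cur$accuracy[1]))  # empty bin is missing, not zero
  expect_identical(cur$n[1], 0L)
  expect_error(accuracy_curve(v, m, breaks = c(0, 0.5, 0.5, 1)), "increasing")

  # under noise, the hardest bin contains the threshold
  set.seed(35)
  m <- runif(4000, 0.4, 1)
  v <- pmin(1, pmax(0.05, m + rnorm(4000, 0, 0.06)))
  cur <- accuracy_curve(v, m, breaks = seq(0.4, 1, by = 0.1))
  expect_identical(which.min(cur$accuracy), which(cur$bin_center == 0.75))
})

test_that("the bundled report is internally consistent", {
  set.seed(36)
  m <- runif(300, 0.4, 1)
  v <- pmin(1, pmax(0.05, m + rnorm(300, 0.01, 0.07)))
  rep <- diagnostic_report(v, m)
  expect_equal(rep$mean_abs_error, mean(abs(v - m)), tolerance = 1e-12)
  expect_true(rep$loa[1] <= rep$bias && rep$bias <= rep$loa[2])
  expect_equal(rep$auc, auc_bruteforce(-v, classify_ffr(m)), tolerance = 1e-12)
  expect_true(all(unlist(rep[c("sensitivity", "specificity", "ppv", "npv",
                               "accuracy")]) >= 0))
  expect_identical(sum(rep$curve$n), 300L)
})
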