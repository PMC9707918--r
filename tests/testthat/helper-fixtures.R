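# shared fixtures: all built in code, no stored data

simple_geometry <- function(r_mm = 1.5, l_mm = 30, stenosis = NULL) {
  vessel_geometry(radius_mm = r_mm, length_mm = l_mm, stenosis = stenosis)
}

stenosed_geometry <- function(mld_mm = 1.2, ref_mm = 2.8, Ke = 1.52) {
  vessel_geometry(radius_mm = c(1.6, mld_mm / 2, 1.4),
                  length_mm = c(25, 12, 40),
                  stenosis = stenosis_spec(mld_mm, ref_mm, Ke = Ke))
}

random_geometry <- function() {
  ref <- runif(1, 2.2, 3.6)
  mld <- ref * runif(1, 0.25, 0.85)
  vessel_geometry(radius_mm = c(ref * runif(1, 1.0, 1.3), mld, ref) / 2,
                  length_mm = c(runif(1, 10, 40), runif(1, 5, 25),
                                runif(1, 20, 60)),
                  stenosis = stenosis_spec(mld, ref))
}

# the five-branch hand tree: scores LAD 3, Dx 1, LCx 2, OM 1, RCA 3
hand_tree <- function(lesion = "LAD") {
  coronary_tree(data.frame(
    id = c("LAD", "Dx", "LCx", "OM", "RCA"),
    parent = c(NA, "LAD", NA, "LCx", NA),
    vessel = c("LAD", "diagonal", "LCx", "obtuse marginal", "RCA"),
    extent = c(0.8, 0.2, 0.5, 0.3, 0.9),
    significant = TRUE,
    stringsAsFactors = FALSE), lesion_branch = lesion)
}

# random rooted forest over n branches with random scores and a lesion
random_tree <- function(n = 8) {
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)[-1])
    if (runif(1) < 0.8) parent[i] <- sprintf("b%d", sample.int(i - 1L, 1))
  br <- data.frame(id = sprintf("b%d", seq_len(n)), parent = parent,
                   vessel = sample(c("LAD", "diagonal", "septal", "LCx",
                                     "OM", "PDA", "ramus"), n, replace = TRUE),
                   extent = runif(n), significant = runif(n) < 0.9,
                   stringsAsFactors = FALSE)
  # ensure the tree carries some score
  br$significant[1] <- TRUE; br$extent[1] <- 0.9
  coronary_tree(br, lesion_branch = sprintf("b%d", sample.int(n, 1)))
}

# brute-force pairwise-concordance AUC (the oracle for roc_auc)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  conc <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(conc)
}

# exhaustive best-subset training R^2 (the oracle for FROLS)
best_subset_r2 <- function(X, y, k) {
  combs <- utils::combn(ncol(X), k)
  best <- -Inf
  for (j in seq_len(ncol(combs))) {
    f <- stats::lm.fit(cbind(1, X[, combs[, j], drop = FALSE]), y)
    r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    if (r2 > best) best <- r2
  }
  best
}

# planted sparse polynomial over p continuous features; returns data,
# response, the planted term labels, and the generative R^2
planted_polynomial <- function(n = 300, p = 6, noise_to_signal = 0.25) {
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- paste0("x", seq_len(p))
  signal <- 1.5 * d$x1 - 1.0 * d$x2 + 0.8 * d$x1 * d$x2 +
    0.7 * d$x3^2 + 0.9 * d$x4
  noise_sd <- sqrt(noise_to_signal * stats::var(signal))
  y <- signal + rnorm(n, 0, noise_sd)
  list(data = d, y = y,
       terms = c("x1", "x2", "x1:x2", "x3^2", "x4"),
       r2_generative = stats::var(signal) / (stats::var(signal) + noise_sd^2))
}
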