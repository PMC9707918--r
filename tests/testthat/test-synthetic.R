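# synthetic cohort generator: determinism, generative structure, masking

test_that("same config and seed give byte-identical cohorts", {
  cfg <- synthetic_config(n_vessels = 120, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(cfg, seed = 100)))
})

test_that("with all noise off, CMVR is an exact function of the covariates", {
  cfg <- synthetic_config(n_vessels = 200, seed = 5, cmvr_noise_sd = 0,
                          ffr_noise_sd = 0, echo_availability = 1)
  co <- generate_cohort(cfg)
  offs <- c(LAD = 0, cfg$vessel_offsets)[co$vessel_label]
  expected <- exp(cfg$cmvr_intercept -
                    cfg$murray_exponent * log(co$outlet_diameter) +
                    cfg$beta_mji * co$mji +
                    cfg$beta_lv_mass * log(co$lv_mass) +
                    cfg$beta_ivs * co$ivs_thickness +
                    cfg$beta_duke * co$duke_score + offs)
  expect_equal(unname(co$cmvr_true), unname(expected), tolerance = 1e-12)
  # identical covariates imply identical CMVR and FFR
  expect_identical(co$ffr_measured, co$ffr_noiseless)
})

test_that("forward solve with the latent CMVR reproduces the pre-noise FFR", {
  co <- generate_cohort(synthetic_config(n_vessels = 80, seed = 21))
  conv <- attr(co, "generator")
  for (i in seq_len(nrow(co))) {
    st <- solve_forward(record_geometry(co[i, ], convention = conv),
                        pa = mmHg_to_Pa(co$pa_measured[i]),
                        cmvr = co$cmvr_true[i])
    expect_equal(st$ffr, co$ffr_noiseless[i], tolerance = 1e-12)
  }
  expect_true(all(co$pd_measured <= co$pa_measured))
  expect_true(all(co$ffr_measured > 0 & co$ffr_measured <= 1))
  expect_true(all(co$minimum_lumen_diameter <= co$outlet_diameter))
  expect_true(all(co$outlet_diameter <= co$inlet_diameter))
  expect_true(all(co$cmvr_true > 0))
})

test_that("regression on a large cohort recovers the generative coefficients", {
  cfg <- synthetic_config(n_vessels = 10000, seed = 2024, echo_availability = 1)
  co <- generate_cohort(cfg)
  fit <- lm(log(cmvr_true) ~ log(outlet_diameter) + mji + log(lv_mass) +
              ivs_thickness + duke_score + vessel_label, data = co)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truth <- c("(Intercept)" = cfg$cmvr_intercept,
             "log(outlet_diameter)" = -cfg$murray_exponent,
             "mji" = cfg$beta_mji,
             "log(lv_mass)" = cfg$beta_lv_mass,
             "ivs_thickness" = cfg$beta_ivs,
             "duke_score" = cfg$beta_duke,
             "vessel_labelLCX" = cfg$vessel_offsets[["LCX"]],
             "vessel_labelRCA" = cfg$vessel_offsets[["RCA"]],
             "vessel_labelbranch" = cfg$vessel_offsets[["branch"]])
  for (nm in names(truth))
    expect_lt(abs(est[[nm]] - truth[[nm]]), 3 * se[[nm]])
  # Murray term: larger outlets have strictly lower latent CMVR
  expect_lt(est[["log(outlet_diameter)"]], 0)
})

test_that("cohort-level calibration lands on the intended population", {
  co <- generate_cohort(synthetic_config(n_vessels = 3000, seed = 1))
  expect_gt(mean(co$cmvr_true), 0.5e10)
  expect_lt(mean(co$cmvr_true), 2.0e10)
  expect_gt(mean(co$ffr_measured), 0.70)
  expect_lt(mean(co$ffr_measured), 0.88)
  expect_equal(mean(co$echo_available), 0.5, tolerance = 0.05)
  expect_equal(mean(co$mji), 0.33, tolerance = 0.03)
})

test_that("apply_missingness masks exactly the requested cell count", {
  co <- generate_cohort(synthetic_config(n_vessels = 100, seed = 3,
                                         echo_availability = 1))
  feats <- c("age", "sex", "hypertension", "diabetes", "smoking", "prior_mi",
             "inlet_diameter", "outlet_diameter", "minimum_lumen_diameter",
             "lesion_length", "mji", "duke_score", "ivs_thickness", "lv_mass")
  na0 <- sum(is.na(co[feats]))
  expect_identical(na0, 0L)
  expect_identical(apply_missingness(co, 0), co)
  m <- apply_missingness(co, 0.1, seed = 4)
  expect_identical(sum(is.na(m[feats])), as.integer(0.1 * 100 * length(feats)))
  # pressures and truth are never masked
  expect_false(anyNA(m[c("pa_measured", "pd_measured", "ffr_measured",
                         "cmvr_true")]))
  # different seeds, different masks, same count
  m2 <- apply_missingness(co, 0.1, seed = 5)
  expect_identical(sum(is.na(m2[feats])), sum(is.na(m[feats])))
  expect_false(identical(is.na(m2[feats]), is.na(m[feats])))
  expect_error(apply_missingness(co, 1), "rate")
})

test_that("cohort CSV and config YAML round trips preserve the experiment", {
  cfg <- synthetic_config(n_vessels = 40, seed = 17)
  co <- generate_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, csv)
  co2 <- read_cohort_csv(csv)
  expect_equal(co2$cmvr_true, co$cmvr_true, tolerance = 1e-14)
  expect_equal(co2$ffr_measured, co$ffr_measured, tolerance = 1e-14)
  expect_identical(co2$vessel_label, co$vessel_label)
  expect_identical(co2$echo_available, co$echo_available)
  expect_equal(attr(co2, "generator"), attr(co, "generator"),
               tolerance = 1e-14)

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, yml)
  cfg2 <- read_synthetic_config(yml)
  expect_identical(generate_cohort(cfg2), co)
})

test_that("invalid configs are rejected", {
  expect_error(synthetic_config(n_vessels = 0), "n_vessels")
  expect_error(synthetic_config(murray_exponent = -1), "murray_exponent")
  expect_error(synthetic_config(cmvr_noise_sd = -0.1), "cmvr_noise_sd")
  expect_error(synthetic_config(vessel_probs = c(LAD = 1, LCX = 1,
                                                 RCA = 0, branch = 0)),
               "sum to 1")
})
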