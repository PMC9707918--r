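# Synthetic per-vessel cohorts with a known generative model.
#
# The generator emulates the structure the analysis assumes: a latent
# hyperaemic microvascular resistance driven log-linearly by outlet
# calibre (a Murray-law diameter term), jeopardized-myocardium indices and
# echocardiographic mass measures, plus lognormal biological noise; and
# "measured" pressures produced by pushing that latent CMVR through the
# forward hemodynamic model of the vessel's own geometry, with additive
# measurement noise on FFR. Every default is a fixed, documented study
# condition, not a tuning knob.

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a stable-coronary-syndrome catheter-lab population:
#' age 64 +/- 10 years, three-quarters male, vessel mix LAD 48% / RCA 22%
#' / LCX 18% / branch 12%, jeopardy index 0.33 +/- 0.13, aortic pressure
#' 90 +/- 10 mmHg truncated to [60, 130]. The latent log-CMVR model is
#'
#' `log CMVR = beta0 - k log(outlet diameter) + beta_mji MJI +
#'   beta_lvm log(LV mass) + beta_ivs IVS + vessel offset +
#'   beta_duke Duke + eps`,  `eps ~ N(0, cmvr_noise_sd^2)`
#'
#' with the Murray exponent `k = 3` so that larger outlets carry
#' proportionally more flow and hence lower resistance. The intercept is
#' set so the cohort mean CMVR is about 1e10 Pa s/m^3; the stenosis
#' severity distribution is set so the cohort mean measured FFR falls
#' near 0.79.
#'
#' @param n_vessels number of vessels to generate.
#' @param seed integer seed; the cohort is a pure function of the config
#'   including this seed.
#' @param murray_exponent Murray scaling exponent `k` (> 0) applied as
#'   coefficient `-k` on log outlet diameter.
#' @param cmvr_intercept intercept `beta0` of the log-CMVR model
#'   (log Pa s/m^3).
#' @param beta_mji,beta_lv_mass,beta_ivs,beta_duke coefficients on MJI
#'   (fraction), log LV mass (log g), IVS thickness (mm) and Duke score.
#' @param vessel_offsets named additive log-CMVR offsets relative to the
#'   LAD for `LCX`, `RCA`, `branch`.
#' @param cmvr_noise_sd SD of the lognormal CMVR noise (log scale, >= 0).
#' @param pa_mean,pa_sd,pa_range aortic pressure distribution (mmHg),
#'   normal truncated to `pa_range`.
#' @param ffr_noise_sd SD of additive FFR measurement noise (dimensionless),
#'   truncated so 0 < FFR <= 1.
#' @param vessel_probs sampling probabilities of `LAD`, `LCX`, `RCA`,
#'   `branch`.
#' @param outlet_diameter_mean named mean outlet diameters (mm) per vessel
#'   type; `diameter_log_sd` is the log-scale SD and
#'   `inlet_outlet_cor` the inlet/outlet log correlation; inlet diameters
#'   are `inlet_taper` times larger on average.
#' @param severity_range,severity_shape diameter-stenosis severity is
#'   `severity_range[1] + diff(severity_range) * Beta(shape1, shape2)`.
#' @param lesion_length_meanlog,lesion_length_sdlog lognormal lesion
#'   length (mm).
#' @param mji_mean named per-vessel-type mean jeopardy index;
#'   `mji_concentration` is the Beta concentration.
#' @param ivs_mean,ivs_sd IVS thickness (mm); `lv_mass_meanlog`,
#'   `lv_mass_sdlog` lognormal LV mass (g); `echo_cor` their correlation.
#' @param echo_availability probability that a vessel's record carries
#'   echo measurements (the latent physiology always exists; availability
#'   masks the measured columns only).
#' @param proximal_length_mm,distal_length_mm modelled vessel lengths
#'   around the lesion; `stenosis_Ke` the expansion loss coefficient.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_vessels = 480L,
                             seed = 20260101L,
                             murray_exponent = 3.0,
                             cmvr_intercept = 37.3,
                             beta_mji = -1.2,
                             beta_lv_mass = -1.8,
                             beta_ivs = -0.17,
                             beta_duke = -0.02,
                             vessel_offsets = c(LCX = 0.15, RCA = 0.10, branch = 0.40),
                             cmvr_noise_sd = 0.32,
                             pa_mean = 90, pa_sd = 10, pa_range = c(60, 130),
                             ffr_noise_sd = 0.01,
                             vessel_probs = c(LAD = 0.48, LCX = 0.18,
                                              RCA = 0.22, branch = 0.12),
                             outlet_diameter_mean = c(LAD = 2.8, LCX = 2.6,
                                                      RCA = 2.9, branch = 2.1),
                             diameter_log_sd = 0.125,
                             inlet_outlet_cor = 0.7,
                             inlet_taper = 1.25,
                             severity_range = c(0.25, 0.80),
                             severity_shape = c(2.6, 2.2),
                             lesion_length_meanlog = log(12),
                             lesion_length_sdlog = 0.35,
                             mji_mean = c(LAD = 0.42, LCX = 0.28,
                                          RCA = 0.30, branch = 0.12),
                             mji_concentration = 12,
                             ivs_mean = 11, ivs_sd = 1.5,
                             lv_mass_meanlog = log(170), lv_mass_sdlog = 0.2,
                             echo_cor = 0.6,
                             echo_availability = 0.5,
                             proximal_length_mm = 25,
                             distal_length_mm = 40,
                             stenosis_Ke = 1.52) {
  cfg <- as.list(environment())
  cfg$n_vessels <- as.integer(cfg$n_vessels)
  if (cfg$n_vessels < 1L) stop("n_vessels must be >= 1")
  if (cfg$murray_exponent <= 0) stop("murray_exponent must be > 0")
  if (cfg$cmvr_noise_sd < 0) stop("cmvr_noise_sd must be >= 0")
  if (cfg$ffr_noise_sd < 0) stop("ffr_noise_sd must be >= 0")
  if (cfg$pa_mean <= 0) stop("pa_mean must be > 0")
  if (any(cfg$outlet_diameter_mean <= 0)) stop("diameter means must be > 0")
  if (!all(c("LCX", "RCA", "branch") %in% names(cfg$vessel_offsets)))
    stop("vessel_offsets must name LCX, RCA and branch")
  if (abs(sum(cfg$vessel_probs) - 1) > 1e-8)
    stop("vessel_probs must sum to 1")
  if (cfg$echo_availability < 0 || cfg$echo_availability > 1)
    stop("echo_availability must lie in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d vessels, seed %d, k = %.1f, echo availability %.0f%%\n",
              x$n_vessels, x$seed, x$murray_exponent, 100 * x$echo_availability))
  invisible(x)
}

# truncated-normal sampler by inverse CDF (exact, vectorised)
.rtnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic per-vessel cohort
#'
#' Deterministic given the config (including its seed): the same config
#' yields a byte-identical cohort. Clinical demographics (age, sex, risk
#' factors) are sampled at realistic prevalences but do not enter the
#' latent CMVR model, so a structure-selection procedure should find them
#' uninformative. Measured pressures are produced by the forward
#' hemodynamic solve of each vessel's own geometry under its latent CMVR;
#' `ffr_noiseless` retains the pre-noise value and `pd_measured` is
#' `ffr_measured * pa_measured`.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of `config$seed`.
#' @return data.frame with one row per vessel (see the column dictionary
#'   in `vignette("cmvr-personalization")`), of class
#'   `c("vffr_cohort", "data.frame")`. Vessel geometry is a deterministic
#'   function of the diameter/length columns; rebuild it with
#'   [record_geometry()].
#' @export
generate_cohort <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n <- cfg$n_vessels
  set.seed(if (is.null(seed)) cfg$seed else seed)

  vessel <- sample(names(cfg$vessel_probs), n, replace = TRUE,
                   prob = cfg$vessel_probs)
  age <- round(.rtnorm(n, 64, 10, 35, 92))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.76, 0.24))
  hypertension <- stats::runif(n) < 0.62
  diabetes <- stats::runif(n) < 0.19
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(0.38, 0.52, 0.10))
  prior_mi <- stats::runif(n) < 0.36

  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  mu_out <- log(cfg$outlet_diameter_mean[vessel])
  outlet <- exp(mu_out + cfg$diameter_log_sd * z1)
  rho <- cfg$inlet_outlet_cor
  inlet <- exp(mu_out + log(cfg$inlet_taper) +
                 cfg$diameter_log_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  inlet <- pmax(inlet, outlet)

  sev <- cfg$severity_range[1] + diff(cfg$severity_range) *
    stats::rbeta(n, cfg$severity_shape[1], cfg$severity_shape[2])
  mld <- outlet * (1 - sev)
  lesion_length <- exp(stats::rnorm(n, cfg$lesion_length_meanlog,
                                    cfg$lesion_length_sdlog))

  m <- cfg$mji_mean[vessel]
  mji <- stats::rbeta(n, m * cfg$mji_concentration,
                      (1 - m) * cfg$mji_concentration)
  duke <- pmin(12L, pmax(0L, as.integer(round(12 * mji + stats::rnorm(n, 0, 1)))))

  z3 <- stats::rnorm(n); z4 <- stats::rnorm(n)
  ivs <- pmax(6, pmin(18, cfg$ivs_mean + cfg$ivs_sd * z3))
  rho_e <- cfg$echo_cor
  lv_mass <- exp(cfg$lv_mass_meanlog +
                   cfg$lv_mass_sdlog * (rho_e * z3 + sqrt(1 - rho_e^2) * z4))
  echo_available <- stats::runif(n) < cfg$echo_availability

  offs <- c(LAD = 0, cfg$vessel_offsets)[vessel]
  eps <- stats::rnorm(n, 0, cfg$cmvr_noise_sd)
  log_cmvr <- cfg$cmvr_intercept -
    cfg$murray_exponent * log(outlet) +
    cfg$beta_mji * mji +
    cfg$beta_lv_mass * log(lv_mass) +
    cfg$beta_ivs * ivs +
    cfg$beta_duke * duke +
    offs + eps
  cmvr_true <- exp(log_cmvr)

  pa_mmHg <- .rtnorm(n, cfg$pa_mean, cfg$pa_sd, cfg$pa_range[1], cfg$pa_range[2])

  cohort <- data.frame(
    id = sprintf("V%04d", seq_len(n)),
    vessel_label = vessel,
    age = age, sex = sex,
    hypertension = hypertension, diabetes = diabetes,
    smoking = smoking, prior_mi = prior_mi,
    inlet_diameter = inlet,
    outlet_diameter = outlet,
    minimum_lumen_diameter = mld,
    lesion_length = lesion_length,
    mji = mji, duke_score = duke,
    echo_available = echo_available,
    ivs_thickness = ifelse(echo_available, ivs, NA_real_),
    lv_mass = ifelse(echo_available, lv_mass, NA_real_),
    cmvr_true = cmvr_true,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(cohort, "generator") <- list(proximal_length_mm = cfg$proximal_length_mm,
                                    distal_length_mm = cfg$distal_length_mm,
                                    stenosis_Ke = cfg$stenosis_Ke)

  convention <- attr(cohort, "generator")
  ffr_noiseless <- vapply(seq_len(n), function(i) {
    solve_forward(record_geometry(cohort[i, ], convention = convention),
                  pa = mmHg_to_Pa(pa_mmHg[i]), cmvr = cmvr_true[i])$ffr
  }, 0)
  noise <- stats::rnorm(n, 0, cfg$ffr_noise_sd)
  ffr_measured <- pmin(1, pmax(1e-6, ffr_noiseless + noise))

  cohort$pa_measured <- pa_mmHg
  cohort$pd_measured <- ffr_measured * pa_mmHg
  cohort$ffr_measured <- ffr_measured
  cohort$ffr_noiseless <- ffr_noiseless
  class(cohort) <- c("vffr_cohort", "data.frame")
  cohort
}

#' Rebuild the modelled geometry of one cohort record
#'
#' The modelled vessel is three near-cylindrical segments -- a proximal
#' segment at the inlet diameter, the lesion throat at the minimum lumen
#' diameter over the lesion length, and a distal segment at the outlet
#' diameter -- plus the stenosis expansion loss referenced to the outlet
#' diameter. Proximal/distal segment lengths and the loss coefficient are
#' the generator's conventions, carried on the cohort as the `"generator"`
#' attribute (defaults 25 mm, 40 mm, Ke 1.52).
#'
#' @param record one row of a cohort data.frame.
#' @param convention optional list overriding `proximal_length_mm`,
#'   `distal_length_mm`, `stenosis_Ke`.
#' @return a [vessel_geometry()].
#' @export
record_geometry <- function(record, convention = NULL) {
  gen <- convention
  if (is.null(gen)) gen <- attr(record, "generator")
  if (is.null(gen)) gen <- list(proximal_length_mm = 25, distal_length_mm = 40,
                                stenosis_Ke = 1.52)
  vessel_geometry(
    radius_mm = c(record$inlet_diameter, record$minimum_lumen_diameter,
                  record$outlet_diameter) / 2,
    length_mm = c(gen$proximal_length_mm, record$lesion_length,
                  gen$distal_length_mm),
    stenosis = stenosis_spec(record$minimum_lumen_diameter,
                             record$outlet_diameter,
                             Ke = gen$stenosis_Ke))
}

# feature cells that apply_missingness may mask (never pressures/FFR/truth)
.maskable_features <- c("age", "sex", "hypertension", "diabetes", "smoking",
                        "prior_mi", "inlet_diameter", "outlet_diameter",
                        "minimum_lumen_diameter", "lesion_length", "mji",
                        "duke_score", "ivs_thickness", "lv_mass")

#' Mask a fixed fraction of feature cells
#'
#' Masks exactly `floor(rate * n_cells)` cells chosen uniformly without
#' replacement among the maskable feature cells (clinical, angiographic
#' and echo columns; measured pressures, FFR and the latent truth are
#' never masked). Seeded and deterministic.
#'
#' @param cohort a cohort data.frame.
#' @param rate fraction of maskable cells to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @return the cohort with masked cells set to `NA`.
#' @export
apply_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  feats <- intersect(.maskable_features, names(cohort))
  n_cells <- nrow(cohort) * length(feats)
  n_mask <- floor(rate * n_cells)
  if (n_mask == 0L) return(cohort)
  set.seed(seed)
  cells <- sample.int(n_cells, n_mask)
  rows <- ((cells - 1L) %% nrow(cohort)) + 1L
  cols <- ((cells - 1L) %/% nrow(cohort)) + 1L
  for (j in unique(cols)) {
    col <- feats[j]
    x <- cohort[[col]]
    x[rows[cols == j]] <- NA
    cohort[[col]] <- x
  }
  cohort
}

#' Read and write cohort tables as CSV
#'
#' Columns are written in a fixed order with full precision so that a
#' write/read round trip reproduces the cohort exactly (up to numeric
#' printing at 17 significant digits). The geometry convention attribute
#' is carried in a `#`-prefixed header comment line.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  gen <- attr(cohort, "generator")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(gen))
    writeLines(sprintf("# geometry_convention proximal_length_mm=%g distal_length_mm=%g stenosis_Ke=%g",
                       gen$proximal_length_mm, gen$distal_length_mm,
                       gen$stenosis_Ke), con)
  utils::write.csv(format(as.data.frame(cohort), digits = 17, trim = TRUE,
                          scientific = NA),
                   con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1L)
  gen <- NULL
  if (startsWith(first, "# geometry_convention")) {
    kv <- regmatches(first, gregexpr("[a-zA-Z_]+=[0-9.eE+-]+", first))[[1]]
    gen <- as.list(as.numeric(sub(".*=", "", kv)))
    names(gen) <- sub("=.*", "", kv)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("hypertension", "diabetes", "prior_mi", "echo_available"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  attr(df, "generator") <- gen
  class(df) <- c("vffr_cohort", "data.frame")
  df
}

#' Read and write the generator config as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `read_synthetic_config()` returns a [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- unclass(config)
  for (f in c("vessel_offsets", "vessel_probs", "outlet_diameter_mean", "mji_mean"))
    out[[f]] <- as.list(out[[f]])  # keep names in the YAML mapping
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("vessel_offsets", "vessel_probs", "outlet_diameter_mean", "mji_mean"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  for (f in c("pa_range", "severity_range", "severity_shape"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.numeric(unlist(raw[[f]]))
  do.call(synthetic_config, raw)
}
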