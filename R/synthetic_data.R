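#' Names of the simulated urinary metabolite panel
#'
#' 54 metabolite names modeled on a targeted urine proton-NMR panel
#' (amino acids, TCA-cycle intermediates, purine degradation products,
#' osmolytes, microbial co-metabolites). Urinary creatinine is carried
#' separately as the normalizer and is not part of the panel.
#'
#' @return Character vector of length 54.
#' @export
panel_metabolites <- function() {
  c(
    "3-hydroxyisobutyrate", "3-hydroxyisovalerate", "alanine", "citrate",
    "glutamine", "glycine", "histidine", "trans-aconitate", "tyrosine",
    "uracil", "xanthosine", "arabinose", "dimethylamine", "4-deoxythreonate",
    "4-hydroxyhippurate", "cis-aconitate", "glucose", "leucine", "valine",
    "isoleucine", "taurine", "creatine", "mannitol", "allantoin",
    "3-aminoisobutyrate", "ethanolamine", "ethanol", "glycolate",
    "hypoxanthine", "propylene-glycol", "proline-betaine",
    "3-methylhistidine", "xylose", "urea", "trimethylamine-N-oxide",
    "2-hydroxyisobutyrate", "3-hydroxyhippurate", "HPHPA",
    "1-methylnicotinamide", "4-deoxyerythronate", "hippurate", "formate",
    "acetate", "lactate", "pyruvate", "succinate", "trigonelline", "betaine",
    "dimethylglycine", "methylamine", "indoxyl-sulfate", "pseudouridine",
    "threonine", "4-hydroxyphenylacetate"
  )
}

#' Default per-metabolite missingness rates
#'
#' Fifteen metabolites exceed the 15% missingness used by the profiling
#' filter; of those, taurine, creatine and mannitol exceed 50% and are
#' dropped by the metabolome-wide screen's filter. All other metabolites
#' have low (0-5%) missingness. Rates are MCAR.
#'
#' @return Named numeric vector over [panel_metabolites()].
#' @export
default_missing_rates <- function() {
  mets <- panel_metabolites()
  rates <- stats::setNames(rep(0.02, length(mets)), mets)
  high <- c(
    "taurine" = 0.62, "creatine" = 0.58, "mannitol" = 0.55,
    "allantoin" = 0.32, "3-aminoisobutyrate" = 0.25, "ethanolamine" = 0.20,
    "ethanol" = 0.35, "glycolate" = 0.22, "histidine" = 0.18,
    "hypoxanthine" = 0.30, "isoleucine" = 0.18, "propylene-glycol" = 0.28,
    "proline-betaine" = 0.40, "3-methylhistidine" = 0.24, "xylose" = 0.20
  )
  rates[names(high)] <- high
  rates
}

default_clinical_missing_rates <- function() {
  c(
    smoking = 0.18, whtr = 0.18, sbp = 0.105, dbp = 0.105, map = 0.105,
    hba1c_pct = 0.05, bmi = 0.11, chol_total = 0.0025, hdl = 0.003,
    log_tg = 0.0025, ldl = 0.003, whr = 0.14, aht = 0.14
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults encode the
#' study conditions the analyses assume: ~2500 participants with type 1
#' diabetes, an 8.4% 10-year incident-CAD rate (209/2501), 54 correlated
#' urinary metabolites driven by latent factors plus eGFR/age coupling,
#' left-censoring at a detection limit, per-metabolite MCAR missingness with
#' three metabolites above 50%, and survival times from a proportional-hazards
#' model with planted per-SD log hazard ratios on two low-missingness
#' metabolites (HR 0.75 and 1.27).
#'
#' @param n_participants Cohort size (default 2501).
#' @param seed Integer seed; the same seed and config give bit-identical
#'   cohorts.
#' @param event_rate_10y Target fraction experiencing an event within the
#'   10-year horizon (default 209/2501).
#' @param planted_log_hr Named numeric vector of per-SD log hazard ratios on
#'   standardized processed metabolites. Ignored (with a message) when
#'   `group_corr_shift` is supplied.
#' @param latent_factors Number of latent factors driving metabolite
#'   correlation (default 6).
#' @param group_corr_shift Optional list of planted case-control correlation
#'   differences, each element `list(pair = c(m1, m2), shift = d, base = b)`:
#'   the target Spearman correlation is `b` in future controls and `b + d` in
#'   future cases. When non-empty the generator pre-assigns future case
#'   status (Bernoulli at `event_rate_10y`) and survival honors it.
#' @param missing_rates Named per-metabolite MCAR missingness fractions.
#' @param zero_fraction Named per-metabolite fraction of concentrations below
#'   the detection limit, stored as exact zeros (default 2%, 10% for three
#'   low-abundance metabolites).
#' @param clinical_moments List of means/SDs/prevalences for clinical
#'   variables; see [default_clinical_moments()].
#' @param censoring_rate Yearly rate of random (death/dropout) censoring;
#'   exposed as a free parameter (default 0.012).
#' @param max_followup Range (years) of administrative end of follow-up per
#'   participant, uniform (default `c(10, 23)` so full-follow-up schemes have
#'   events beyond 10 years).
#' @param baseline_hazard `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape Shape when `baseline_hazard = "weibull"`.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 2501,
                       seed = 1L,
                       event_rate_10y = 209 / 2501,
                       planted_log_hr = c(
                         "3-hydroxyisobutyrate" = log(0.75),
                         "xanthosine" = log(1.27)
                       ),
                       latent_factors = 6L,
                       group_corr_shift = list(),
                       missing_rates = default_missing_rates(),
                       zero_fraction = NULL,
                       clinical_moments = default_clinical_moments(),
                       censoring_rate = 0.012,
                       max_followup = c(10, 23),
                       baseline_hazard = c("exponential", "weibull"),
                       weibull_shape = 1) {
  mets <- panel_metabolites()
  if (n_participants < 10) stop("n_participants must be at least 10")
  if (is.null(zero_fraction)) {
    zero_fraction <- stats::setNames(rep(0.02, length(mets)), mets)
    zero_fraction[c("methylamine", "pyruvate", "ethanol")] <- 0.10
  }
  if (any(zero_fraction < 0 | zero_fraction >= 1)) {
    stop("zero_fraction (detection-limit mass) must be in [0, 1)")
  }
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missing_rates must be in [0, 1)")
  }
  stopifnot(all(names(planted_log_hr) %in% mets))
  sds <- unlist(lapply(clinical_moments, function(m) m[["sd"]]))
  if (any(sds <= 0)) stop("clinical_moments: all SDs must be positive")
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    event_rate_10y = event_rate_10y,
    planted_log_hr = planted_log_hr,
    latent_factors = as.integer(latent_factors),
    group_corr_shift = group_corr_shift,
    missing_rates = missing_rates,
    zero_fraction = zero_fraction,
    clinical_moments = clinical_moments,
    censoring_rate = censoring_rate,
    max_followup = max_followup,
    baseline_hazard = match.arg(baseline_hazard),
    weibull_shape = weibull_shape
  ), class = "sim_config")
}

#' Default clinical moments
#'
#' Means, SDs and prevalences for the simulated baseline clinical table,
#' calibrated to a type 1 diabetes cohort recruited around calendar year
#' 2000: age ~40 (SD ~14.6), diabetes onset age ~15.5, duration ~23.5 years,
#' eGFR ~92 ml/min/1.73m2, HbA1c ~8.3%, SBP ~134 mmHg, BMI ~25.6, ~31%
#' albuminuria, ~45% ever-smokers.
#'
#' @return Named list, each element `list(mean=, sd=)` or `list(p=, sd=1)`.
#' @export
default_clinical_moments <- function() {
  list(
    # dispersion of onset age and duration converted from reported
    # median +/- IQR spreads (sigma ~ IQR / 1.35)
    onset_age = list(mean = 15.5, sd = 10.5),
    duration = list(mean = 23.5, sd = 12.5),
    onset_duration_cor = list(mean = -0.45, sd = 1),
    egfr = list(mean = 94, sd = 26),
    hba1c_pct = list(mean = 8.3, sd = 1.35),
    sbp = list(mean = 131, sd = 15),
    dbp = list(mean = 80, sd = 8.5),
    chol_total = list(mean = 4.95, sd = 0.85),
    hdl = list(mean = 1.39, sd = 0.40),
    log_tg = list(mean = log(0.95), sd = 0.45),
    bmi = list(mean = 25.6, sd = 3.6),
    whr = list(mean = 0.87, sd = 0.06),
    baseline_year = list(mean = 2000, sd = 1),
    p_male = list(p = 0.50, sd = 1),
    p_smoking = list(p = 0.45, sd = 1),
    p_prior_cad = list(p = 0.02, sd = 1),
    creatinine_meanlog = list(mean = log(8), sd = 0.40)
  )
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate the baseline clinical table
#'
#' Draws a clinical table from the configured moments. Diabetes duration and
#' onset age are negatively correlated and age is their sum, so
#' `duration = age - onset_age` holds exactly by construction; the onset
#' calendar year is the fixed baseline year minus duration. eGFR declines
#' with age and duration; albuminuria, antihypertensive treatment and blood
#' pressure are linked to kidney function through logistic/linear couplings.
#' MCAR missingness is inserted per [default_clinical_missing_rates()].
#'
#' @param config A [sim_config()].
#' @return A data.frame, one row per participant (`id` column first). When
#'   `config$group_corr_shift` is non-empty it carries a `future_case`
#'   column used by the downstream generators; it is truth plumbing, never
#'   an analysis input.
#' @export
generate_clinical <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  cm <- config$clinical_moments
  set.seed(config$seed)

  sex_male <- stats::rbinom(n, 1, cm$p_male$p)
  # onset age and duration: right-skewed gamma marginals (both are positive
  # and right-skewed in type 1 diabetes cohorts) matched to the configured
  # mean/SD, coupled negatively through a Gaussian copula; age = sum, so
  # duration = age - onset_age holds exactly
  rho <- cm$onset_duration_cor$mean
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  gamma_q <- function(z, mean, sd) {
    shape <- (mean / sd)^2
    stats::qgamma(stats::pnorm(z), shape = shape, scale = sd^2 / mean)
  }
  onset_age <- pmin(gamma_q(z1, cm$onset_age$mean, cm$onset_age$sd), 39.9)
  duration <- pmax(gamma_q(z2, cm$duration$mean, cm$duration$sd), 0.05)
  age <- onset_age + duration
  baseline_year <- cm$baseline_year$mean
  onset_year <- baseline_year - duration

  egfr <- rtrunc_norm(
    n,
    cm$egfr$mean - 0.45 * (age - 40) - 0.35 * (duration - cm$duration$mean),
    cm$egfr$sd, 5, 170
  )
  albuminuria <- stats::rbinom(n, 1, stats::plogis(
    -0.8 + 0.035 * (duration - cm$duration$mean) - 0.030 * (egfr - cm$egfr$mean)
  ))
  hba1c_pct <- rtrunc_norm(n, cm$hba1c_pct$mean, cm$hba1c_pct$sd, 4.5, 16)
  sbp <- rtrunc_norm(
    n, cm$sbp$mean + 0.35 * (age - 40) + 8 * albuminuria, cm$sbp$sd, 85, 230
  )
  dbp <- rtrunc_norm(n, cm$dbp$mean + 0.08 * (age - 40), cm$dbp$sd, 45, 140)
  map <- dbp + (sbp - dbp) / 3
  chol_total <- rtrunc_norm(
    n, cm$chol_total$mean + 0.012 * (age - 40), cm$chol_total$sd, 2, 10
  )
  hdl <- rtrunc_norm(n, cm$hdl$mean - 0.1 * sex_male, cm$hdl$sd, 0.4, 3.5)
  log_tg <- stats::rnorm(n, cm$log_tg$mean + 0.008 * (age - 40), cm$log_tg$sd)
  ldl <- pmax(chol_total - hdl - exp(log_tg) / 2.2 + stats::rnorm(n, 0, 0.15), 0.5)
  bmi <- rtrunc_norm(n, cm$bmi$mean, cm$bmi$sd, 15, 45)
  whtr <- rtrunc_norm(n, 0.31 + 0.0077 * bmi, 0.045, 0.33, 0.80)
  whr <- rtrunc_norm(
    n, cm$whr$mean + 0.003 * (bmi - cm$bmi$mean) + 0.05 * sex_male,
    cm$whr$sd, 0.60, 1.20
  )
  smoking <- stats::rbinom(n, 1, cm$p_smoking$p)
  aht <- stats::rbinom(n, 1, stats::plogis(
    -0.9 + 0.05 * (age - 40) + 0.03 * (sbp - cm$sbp$mean) + 1.0 * albuminuria
  ))
  prior_cad <- stats::rbinom(n, 1, cm$p_prior_cad$p)

  clin <- data.frame(
    id = seq_len(n), sex_male = sex_male, age = age, onset_age = onset_age,
    duration = duration, onset_year = onset_year, egfr = egfr,
    albuminuria = albuminuria, hba1c_pct = hba1c_pct, sbp = sbp, dbp = dbp,
    map = map, chol_total = chol_total, ldl = ldl, hdl = hdl,
    log_tg = log_tg, bmi = bmi, whtr = whtr, whr = whr, smoking = smoking,
    aht = aht, prior_cad = prior_cad
  )
  if (length(config$group_corr_shift) > 0) {
    clin$future_case <- stats::rbinom(n, 1, config$event_rate_10y)
  }
  # MCAR clinical missingness (covariate imputation is exercised downstream)
  cmr <- default_clinical_missing_rates()
  for (v in names(cmr)) {
    miss <- stats::runif(n) < cmr[[v]]
    clin[[v]][miss] <- NA
  }
  clin
}

# Deterministic latent-factor loadings: metabolite i loads 0.75 on its
# primary factor (cycling over factors) and 0.25 on the next one, with
# idiosyncratic noise bringing each latent log-concentration to unit variance.
factor_loadings <- function(n_metabolites, n_factors) {
  L <- matrix(0, n_metabolites, n_factors)
  for (i in seq_len(n_metabolites)) {
    f1 <- (i - 1) %% n_factors + 1
    f2 <- i %% n_factors + 1
    L[i, f1] <- 0.75
    L[i, f2] <- L[i, f2] + 0.25
  }
  L
}

# Marginal family per metabolite: lognormal for most, squared-normal for a
# few sugars/osmolytes so both branches of the log/sqrt transform rule are
# exercised by default.
metabolite_families <- function() {
  mets <- panel_metabolites()
  fam <- stats::setNames(rep("lognormal", length(mets)), mets)
  fam[c("glucose", "urea", "mannitol", "xylose")] <- "sqnormal"
  fam
}

#' Generate the raw metabolite panel
#'
#' Latent log-concentrations are linear combinations of shared factors,
#' standardized eGFR and age (so metabolites inherit clinical correlations),
#' and idiosyncratic noise; concentrations are the exponential (or square,
#' for a few metabolites, so the sqrt branch of the transform rule is
#' exercised) of the latent value. Concentrations below the per-metabolite
#' detection limit (the configured lower quantile of the marginal) are
#' stored as exact zeros; MCAR missingness is inserted per metabolite.
#' Urinary creatinine is strictly positive and never missing.
#'
#' For pairs named in `config$group_corr_shift` the two metabolites are
#' regenerated as a Gaussian copula pair whose Spearman correlation is
#' `base` in future controls and `base + shift` in future cases (the
#' Pearson correlation on the latent normals is `2*sin(pi*rho_S/6)`).
#'
#' @param clinical Output of [generate_clinical()] (same config).
#' @param config A [sim_config()].
#' @return A [metabolite_panel()] at stage `"raw"`, with a
#'   `detection_limits` attribute recording the planted limits.
#' @export
generate_metabolome <- function(clinical, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(clinical)
  mets <- panel_metabolites()
  p <- length(mets)
  set.seed(config$seed + 1000L)

  L <- factor_loadings(p, config$latent_factors)
  fac <- matrix(stats::rnorm(n * config$latent_factors), n)
  noise_sd <- sqrt(pmax(1 - rowSums(L^2), 0.05))

  egfr <- clinical$egfr
  egfr[is.na(egfr)] <- mean(egfr, na.rm = TRUE)
  egfr_z <- as.numeric(scale(egfr))
  age_z <- as.numeric(scale(clinical$age))
  # clinical coupling: alternating small eGFR/age terms on log-concentration
  g_egfr <- rep(c(0.20, 0.10, 0.00), length.out = p)
  g_age <- rep(c(-0.10, 0.00, 0.10), length.out = p)
  names(g_egfr) <- names(g_age) <- mets
  g_egfr["3-hydroxyisobutyrate"] <- 0.30
  g_age["3-hydroxyisobutyrate"] <- -0.15
  g_egfr["citrate"] <- 0.25
  g_age["xanthosine"] <- 0.12

  latent <- fac %*% t(L) +
    outer(egfr_z, g_egfr) + outer(age_z, g_age) +
    matrix(stats::rnorm(n * p), n) * rep(noise_sd, each = n)

  # planted group-specific correlation pairs replace the factor structure
  shift_mets <- integer(0)
  if (length(config$group_corr_shift) > 0) {
    if (is.null(clinical$future_case)) {
      stop("group_corr_shift set but clinical table lacks future_case; regenerate clinical with the same config")
    }
    for (sh in config$group_corr_shift) {
      i <- match(sh$pair[1], mets)
      j <- match(sh$pair[2], mets)
      if (is.na(i) || is.na(j)) stop("group_corr_shift names an unknown metabolite")
      base <- if (is.null(sh$base)) 0 else sh$base
      rho_s <- ifelse(clinical$future_case == 1, base + sh$shift, base)
      if (any(abs(rho_s) > 0.99)) stop("group_corr_shift target correlation out of range")
      rho_p <- 2 * sin(pi * rho_s / 6) # Spearman target -> latent Pearson
      z1 <- stats::rnorm(n)
      z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * stats::rnorm(n)
      latent[, i] <- z1
      latent[, j] <- z2
      shift_mets <- c(shift_mets, i, j)
    }
  }

  # shared urine-dilution factor: all concentrations scale with it, and
  # urinary creatinine tracks it up to a residual, so dividing by creatinine
  # removes dilution noise (normalization is informative, not cosmetic)
  cmoms <- config$clinical_moments$creatinine_meanlog
  bmi <- clinical$bmi
  bmi[is.na(bmi)] <- mean(bmi, na.rm = TRUE)
  dilution <- exp(stats::rnorm(n, 0, 0.35))
  creatinine <- dilution * exp(stats::rnorm(
    n, cmoms$mean + 0.25 * clinical$sex_male + 0.01 * (bmi - 25.6),
    cmoms$sd
  ))

  mu <- seq(log(0.002), log(2), length.out = p)
  sigma <- seq(0.5, 1.0, length.out = p)
  fam <- metabolite_families()
  conc <- matrix(0, n, p, dimnames = list(NULL, mets))
  for (k in seq_len(p)) {
    if (k %in% shift_mets) {
      # excreted in proportion to creatinine so the metabolite-to-creatinine
      # ratio is a monotone map of the copula latent and the planted Spearman
      # correlation survives normalization exactly
      conc[, k] <- creatinine / exp(cmoms$mean) * exp(mu[k] + sigma[k] * latent[, k])
    } else if (fam[k] == "lognormal") {
      conc[, k] <- dilution * exp(mu[k] + sigma[k] * latent[, k])
    } else {
      # excreted in proportion to creatinine with a squared-normal ratio, so
      # the square root of the ratio is the symmetric scale downstream
      a <- exp(mu[k] / 2) * 4
      conc[, k] <- creatinine / exp(cmoms$mean) * (a + a / 6 * latent[, k])^2
    }
  }

  # detection-limit flooring to exact zero
  limits <- numeric(p)
  names(limits) <- mets
  for (k in seq_len(p)) {
    zf <- config$zero_fraction[[mets[k]]]
    if (zf > 0) {
      limits[k] <- stats::quantile(conc[, k], zf)
      conc[conc[, k] < limits[k], k] <- 0
    }
  }

  # MCAR missingness
  for (k in seq_len(p)) {
    mr <- config$missing_rates[[mets[k]]]
    if (!is.null(mr) && mr > 0) conc[stats::runif(n) < mr, k] <- NA
  }

  panel <- metabolite_panel(conc, creatinine, stage = "raw")
  attr(panel, "detection_limits") <- limits
  panel
}

# Internal: standardized processed values of selected metabolites, using the
# very pipeline the analysis applies, with mean imputation of missing cells.
processed_z <- function(panel, metabolites) {
  z <- impute_mean(preprocess_panel(panel))
  z[, metabolites, drop = FALSE]
}

#' Generate survival outcomes
#'
#' In the proportional-hazards mode (default), event times follow
#' `h0(t) * exp(sum beta_k z_k)` where `z_k` are the standardized processed
#' values of the planted metabolites, obtained by running the package's own
#' preprocessing inside the generator. The baseline hazard `h0` is calibrated
#' by root-finding so the expected 10-year event fraction (accounting for
#' random censoring) equals `event_rate_10y`. Follow-up ends at the first of
#' the event, random censoring, or the participant's administrative end of
#' follow-up (uniform over `config$max_followup`).
#'
#' When `config$group_corr_shift` is non-empty the generator instead honors
#' the pre-assigned `future_case` flag: cases receive an event uniformly
#' within the 10-year horizon and all others are censored (designed
#' case-control mode for correlation-difference studies).
#'
#' @param clinical Output of [generate_clinical()].
#' @param metabolites Output of [generate_metabolome()] (raw panel).
#' @param config A [sim_config()].
#' @return A data.frame with `id`, `event` (0/1) and `time` (years), plus a
#'   `truth` attribute recording the calibrated baseline hazard.
#' @export
generate_survival <- function(clinical, metabolites, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(clinical)
  set.seed(config$seed + 2000L)
  horizon <- 10

  if (length(config$group_corr_shift) > 0) {
    event <- clinical$future_case
    time <- ifelse(event == 1,
      stats::runif(n, 0.25, horizon),
      horizon
    )
    out <- data.frame(id = clinical$id, event = event, time = time)
    attr(out, "truth") <- list(mode = "designed_case_control")
    return(out)
  }

  beta <- config$planted_log_hr
  if (length(beta) > 0) {
    mr <- config$missing_rates[names(beta)]
    if (any(!is.na(mr) & mr > 0.5)) {
      warning("planted effect on a metabolite with >50% missingness; it will be excluded downstream")
    }
    z <- processed_z(metabolites, names(beta))
    lp <- as.numeric(z %*% beta)
  } else {
    lp <- rep(0, n)
  }

  cr <- config$censoring_rate
  # expected event fraction within the horizon under rate h0*exp(lp) and
  # independent exponential censoring at rate cr
  expected_rate <- function(log_h0) {
    r <- exp(log_h0 + lp)
    if (config$baseline_hazard == "exponential") {
      if (cr > 0) {
        mean(r / (r + cr) * (1 - exp(-(r + cr) * horizon)))
      } else {
        mean(1 - exp(-r * horizon))
      }
    } else {
      # Weibull cumulative hazard h0 * t^shape; random censoring ignored in
      # the calibration (it is second-order at the default rates)
      mean(1 - exp(-r * horizon^config$weibull_shape))
    }
  }
  f <- function(lh) expected_rate(lh) - config$event_rate_10y
  log_h0 <- stats::uniroot(f, c(-15, 3), tol = 1e-10)$root
  h0 <- exp(log_h0)

  u <- stats::runif(n)
  rate <- h0 * exp(lp)
  t_event <- if (config$baseline_hazard == "exponential") {
    -log(u) / rate
  } else {
    (-log(u) / rate)^(1 / config$weibull_shape)
  }
  t_cens <- if (cr > 0) stats::rexp(n, cr) else rep(Inf, n)
  t_admin <- stats::runif(n, config$max_followup[1], config$max_followup[2])
  time <- pmin(t_event, t_cens, t_admin)
  event <- as.integer(t_event <= pmin(t_cens, t_admin))
  time <- pmax(time, 1e-4)

  out <- data.frame(id = clinical$id, event = event, time = time)
  attr(out, "truth") <- list(
    mode = "proportional_hazards", baseline_hazard = h0,
    planted_log_hr = beta
  )
  out
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_clinical()], [generate_metabolome()] and
#' [generate_survival()] under one configuration and bundles the result with
#' a `truth` block (planted parameters). The truth block travels alongside
#' the data for testing and is never consumed by the analysis modules.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: a list with `clinical`,
#'   `metabolites` (raw [metabolite_panel()]), `outcomes` and `truth`.
#' @export
generate_cohort <- function(config = sim_config()) {
  clinical <- generate_clinical(config)
  metabolites <- generate_metabolome(clinical, config)
  outcomes <- generate_survival(clinical, metabolites, config)
  truth <- list(
    config_seed = config$seed,
    planted_log_hr = as.list(config$planted_log_hr),
    group_corr_shift = config$group_corr_shift,
    detection_limits = as.list(attr(metabolites, "detection_limits")),
    survival = attr(outcomes, "truth")
  )
  structure(
    list(
      clinical = clinical, metabolites = metabolites,
      outcomes = outcomes, truth = truth
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants, %d metabolites, %d events (%.1f%%)\n",
    nrow(x$clinical), ncol(x$metabolites$values), sum(x$outcomes$event),
    100 * mean(x$outcomes$event)
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `clinical.csv`, `metabolites.csv` (concentrations plus a
#' `creatinine` column), `outcomes.csv` and `truth.json` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- as.data.frame(cohort$metabolites$values, check.names = FALSE)
  met <- cbind(id = cohort$clinical$id, met,
               creatinine = cohort$metabolites$creatinine)
  paths <- c(
    clinical = file.path(dir, "clinical.csv"),
    metabolites = file.path(dir, "metabolites.csv"),
    outcomes = file.path(dir, "outcomes.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$clinical, paths["clinical"], row.names = FALSE)
  utils::write.csv(met, paths["metabolites"], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths["outcomes"], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir Directory holding the four cohort files.
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  met <- utils::read.csv(file.path(dir, "metabolites.csv"),
                         check.names = FALSE)
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"))
  creat <- met$creatinine
  vals <- as.matrix(met[, setdiff(names(met), c("id", "creatinine"))])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(
    list(
      clinical = clinical,
      metabolites = metabolite_panel(vals, creat, stage = "raw"),
      outcomes = outcomes, truth = truth
    ),
    class = "synthetic_cohort"
  )
}
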