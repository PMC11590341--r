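#' Follow-up scheme
#'
#' The screening cohorts are defined by a follow-up horizon and whether the
#' follow-up-dependent control criteria apply. Baseline exclusions (diabetes
#' duration <= 0.5 years, prior CAD, kidney failure: eGFR < 15 or kidney
#' replacement therapy) always apply. The control rule requires event-free
#' participants to reach age >= 35 and diabetes duration >= 15 by the end of
#' their follow-up. The 5-year scheme is derived from the 10-year cohort by
#' truncating follow-up at 5 years without re-applying the control rule.
#'
#' @param name `"10y"`, `"5y"` or `"full"`.
#' @return A list of class `followup_scheme`.
#' @export
followup_scheme <- function(name = c("10y", "5y", "full")) {
  name <- match.arg(name)
  horizon <- switch(name, "10y" = 10, "5y" = 5, "full" = Inf)
  structure(
    list(
      name = name,
      horizon = horizon,
      # rule horizon: the horizon at which the control rule is evaluated
      rule_horizon = if (name == "5y") 10 else horizon,
      control_rule = TRUE
    ),
    class = "followup_scheme"
  )
}

#' Apply a follow-up scheme to a cohort
#'
#' Applies baseline exclusions, recodes events beyond the horizon as censored
#' at the horizon, and (when the rule is active) drops event-free controls
#' that do not satisfy the age/duration criteria at the end of their
#' follow-up. For the 5-year scheme the 10-year cohort is formed first and
#' follow-up is then truncated at 5 years, so the control set is not
#' re-selected.
#'
#' @param cohort A `synthetic_cohort` or a merged data.frame with the
#'   clinical columns plus `event` and `time`.
#' @param scheme A [followup_scheme()].
#' @return A list with `data` (analysis data.frame with recoded `event`,
#'   `time`), `n_cases`, `n_controls`, `n_excluded_baseline`,
#'   `n_excluded_controls` and `n_input`. Counts are conserved:
#'   cases + controls + exclusions = input rows.
#' @export
apply_followup_scheme <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "followup_scheme"))
  if (scheme$horizon <= 0) stop("horizon must be positive")
  df <- cohort_frame(cohort)
  n_input <- nrow(df)

  egfr_filled <- df$egfr
  egfr_filled[is.na(egfr_filled)] <- Inf # missing eGFR does not exclude
  base_excl <- df$duration <= 0.5 | df$prior_cad == 1 | egfr_filled < 15
  df <- df[!base_excl, , drop = FALSE]

  h <- scheme$rule_horizon
  if (is.finite(h)) {
    ev <- df$event == 1 & df$time <= h
    tm <- pmin(df$time, h)
  } else {
    ev <- df$event == 1
    tm <- df$time
  }
  drop_ctrl <- rep(FALSE, nrow(df))
  if (scheme$control_rule) {
    is_ctrl <- !ev
    age_end <- df$age + tm
    dur_end <- df$duration + tm
    drop_ctrl <- is_ctrl & (age_end < 35 | dur_end < 15)
  }
  df <- df[!drop_ctrl, , drop = FALSE]
  ev <- ev[!drop_ctrl]
  tm <- tm[!drop_ctrl]

  if (scheme$name == "5y") {
    ev <- ev & tm <= 5
    tm <- pmin(tm, 5)
  }
  df$event <- as.integer(ev)
  df$time <- tm

  list(
    data = df,
    n_cases = sum(df$event),
    n_controls = sum(df$event == 0),
    n_excluded_baseline = sum(base_excl),
    n_excluded_controls = sum(drop_ctrl),
    n_input = n_input
  )
}

cohort_frame <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) {
    merge(cohort$clinical, cohort$outcomes, by = "id")
  } else {
    as.data.frame(cohort)
  }
}

#' Effective number of tests by principal component analysis
#'
#' The smallest number of principal components whose cumulative explained
#' variance reaches `variance_fraction` of the total, computed on the
#' complete (imputed) standardized metabolite matrix. This is the effective
#' number of independent metabolites used to build the metabolome-wide
#' significance threshold.
#'
#' @param zmat Complete numeric matrix (participants x metabolites).
#' @param variance_fraction Target cumulative fraction, default 0.99.
#' @return Integer count of components.
#' @export
effective_test_count <- function(zmat, variance_fraction = 0.99) {
  if (!(variance_fraction > 0 && variance_fraction <= 1)) {
    stop("variance_fraction must be in (0, 1]")
  }
  if (anyNA(zmat)) stop("matrix must be complete (imputed) for PCA")
  pc <- stats::prcomp(zmat, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  as.integer(which(cum >= variance_fraction - 1e-12)[1])
}

#' Metabolome-wide Bonferroni-style significance threshold
#'
#' `0.05 / (n_components + n_excluded)`: the effective number of tests is the
#' PCA component count plus the metabolites excluded for missingness (they
#' were still looked at, so they still count toward the family).
#'
#' @param n_components Effective test count from [effective_test_count()].
#' @param n_excluded Number of metabolites excluded for missingness.
#' @param alpha Family-wise level, default 0.05.
#' @return A list of class `significance_threshold` with the exact value and
#'   a 3-significant-figure presentation value.
#' @export
bonferroni_threshold <- function(n_components, n_excluded = 0, alpha = 0.05) {
  if (n_components < 0 || n_excluded < 0) stop("counts must be non-negative")
  k <- n_components + n_excluded
  if (k < 1) stop("n_components + n_excluded must be at least 1")
  structure(
    list(
      n_components = n_components, n_excluded = n_excluded, alpha = alpha,
      n_tests = k, threshold = alpha / k, threshold_3sf = signif(alpha / k, 3)
    ),
    class = "significance_threshold"
  )
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat(sprintf(
    "metabolome-wide threshold: %.2g/%d = %s (exact %.6g)\n",
    x$alpha, x$n_tests, format(x$threshold_3sf), x$threshold
  ))
  invisible(x)
}

#' Covariates of the tiered adjustment settings
#'
#' Tier 1: non-modifiable risk factors (age, sex, diabetes onset calendar
#' year). Tier 2: tier 1 plus kidney function (eGFR, albuminuria). Tier 3:
#' tier 2 plus established CAD risk factors (HbA1c %, LDL cholesterol,
#' waist-to-height ratio, systolic blood pressure, smoking). Tiers are
#' strictly nested.
#'
#' @param tier 1, 2 or 3.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier) {
  stopifnot(tier %in% 1:3)
  t1 <- c("age", "sex_male", "onset_year")
  t2 <- c(t1, "egfr", "albuminuria")
  t3 <- c(t2, "hba1c_pct", "ldl", "whtr", "sbp", "smoking")
  switch(tier, t1, t2, t3)
}

# Mean imputation for continuous covariates, mode for dichotomous ones,
# mirroring the metabolite rule.
impute_covariates <- function(df, covariates) {
  for (v in covariates) {
    x <- df[[v]]
    if (anyNA(x)) {
      obs <- x[!is.na(x)]
      if (all(obs %in% c(0, 1))) {
        fill <- as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
      } else {
        fill <- mean(obs)
      }
      x[is.na(x)] <- fill
      df[[v]] <- x
    }
  }
  df
}

#' Stratification bins for covariates violating proportional hazards
#'
#' HbA1c (%): <6, 6-7, ..., 10-11, >11. Age: <30, 30-40, ..., >60 years.
#' Waist-to-height ratio: <0.45, 0.45-0.50, ..., >0.60.
#'
#' @param x Numeric vector.
#' @param variable `"hba1c_pct"`, `"age"` or `"whtr"`.
#' @return Factor of bins.
#' @export
stratification_bins <- function(x, variable = c("hba1c_pct", "age", "whtr")) {
  variable <- match.arg(variable)
  breaks <- switch(variable,
    hba1c_pct = c(-Inf, 6, 7, 8, 9, 10, 11, Inf),
    age = c(-Inf, 30, 40, 50, 60, Inf),
    whtr = c(-Inf, 0.45, 0.50, 0.55, 0.60, Inf)
  )
  cut(x, breaks = breaks, right = FALSE)
}

#' Cox proportional-hazards fit for one metabolite
#'
#' Partial-likelihood fit (Efron tie handling) of the standardized metabolite
#' plus the tier's adjustment covariates, optionally stratified by binned
#' covariates. The hazard ratio is per 1 SD because the metabolite enters
#' standardized. Covariate missingness is mean-imputed (mode for dichotomous
#' covariates) before fitting.
#'
#' @param data Analysis data.frame with `time`, `event` and the clinical
#'   covariates (e.g. `apply_followup_scheme(...)$data`).
#' @param zmat Complete standardized metabolite matrix aligned with `data`
#'   rows.
#' @param metabolite Column name in `zmat`.
#' @param tier Adjustment tier 1-3, or 0 for an unadjusted fit.
#' @param strata Optional named list of stratification factors (one entry per
#'   stratified covariate, aligned with rows).
#' @param extra_metabolites Optional further `zmat` columns entered as
#'   covariates (used e.g. when several planted effects must be fitted
#'   jointly).
#' @return A list of class `cox_screen_result`: hazard ratio per SD, Wald 95%
#'   CI, p-value, PH diagnostics placeholders, convergence flag, and the
#'   underlying `coxph` fit.
#' @export
fit_metabolite_cox <- function(data, zmat, metabolite, tier = 1,
                               strata = NULL, extra_metabolites = NULL) {
  stopifnot(metabolite %in% colnames(zmat))
  stopifnot(nrow(data) == nrow(zmat))
  covs <- if (tier == 0) character(0) else tier_covariates(tier)
  dd <- impute_covariates(data[, c("time", "event", intersect(covs, names(data))),
                               drop = FALSE], covs)
  dd$.z <- zmat[, metabolite]
  rhs <- c(".z", covs)
  for (m in extra_metabolites) {
    nm <- make.names(m)
    dd[[nm]] <- zmat[, m]
    rhs <- c(rhs, nm)
  }
  if (!is.null(strata)) {
    for (s in names(strata)) {
      nm <- paste0(".strat_", s)
      dd[[nm]] <- strata[[s]]
      rhs <- c(rhs, sprintf("strata(%s)", nm))
    }
  }
  fml <- stats::as.formula(
    paste("survival::Surv(time, event) ~", paste(rhs, collapse = " + "))
  )
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dd, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  co <- sm$coefficients[".z", , drop = TRUE]
  se <- co[["se(coef)"]]
  if (!is.finite(se) || se > 50) {
    stop(sprintf("apparent complete separation for metabolite '%s'", metabolite))
  }
  b <- co[["coef"]]
  structure(
    list(
      metabolite = metabolite,
      hr_per_sd = exp(b),
      ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
      p = co[["Pr(>|z|)"]],
      log_hr = b, se = se,
      tier = tier,
      stratified_covariates = names(strata),
      converged = converged,
      n = fit$n, n_events = fit$nevent,
      fit = fit
    ),
    class = "cox_screen_result"
  )
}

#' @export
print.cox_screen_result <- function(x, ...) {
  cat(sprintf(
    "%s: HR = %.2f [%.2f-%.2f] per 1 SD, p = %.2g (tier %d, %d events)\n",
    x$metabolite, x$hr_per_sd, x$ci95[1], x$ci95[2], x$p, x$tier, x$n_events
  ))
  invisible(x)
}

#' Proportional-hazards diagnostics
#'
#' Score test on the scaled Schoenfeld residuals (Kaplan-Meier time
#' transform) for each model term and globally. Terms with p < 0.05 are
#' reported so the caller can stratify the offending covariate (see
#' [stratification_bins()]) or, for metabolites, fall back to the 5-year
#' scheme.
#'
#' @param result A `cox_screen_result` (or a bare `coxph` fit).
#' @param alpha Flagging level, default 0.05.
#' @return A list with `table` (term, chisq, df, p), `global_p`,
#'   `metabolite_p` (the metabolite term, `NA` for a bare fit) and
#'   `failing_terms`.
#' @export
check_proportional_hazards <- function(result, alpha = 0.05) {
  fit <- if (inherits(result, "cox_screen_result")) result$fit else result
  zp <- survival::cox.zph(fit, transform = "km")
  tab <- as.data.frame(zp$table)
  tab$term <- rownames(zp$table)
  rownames(tab) <- NULL
  global_p <- tab$p[tab$term == "GLOBAL"]
  per_term <- tab[tab$term != "GLOBAL", , drop = FALSE]
  list(
    table = tab[, c("term", "chisq", "df", "p")],
    global_p = global_p,
    metabolite_p = if (".z" %in% per_term$term) {
      per_term$p[per_term$term == ".z"]
    } else {
      NA_real_
    },
    failing_terms = per_term$term[per_term$p < alpha]
  )
}

#' Metabolome-wide Cox screen
#'
#' Fits [fit_metabolite_cox()] for every metabolite column at the requested
#' adjustment tier and attaches proportional-hazards diagnostics and the
#' metabolome-wide significance flag.
#'
#' @param data Analysis data.frame (see [fit_metabolite_cox()]).
#' @param zmat Complete standardized metabolite matrix.
#' @param tier Adjustment tier (0-3).
#' @param threshold A [bonferroni_threshold()] (or `NULL` to skip flagging).
#' @param strata Optional stratification list passed to every fit.
#' @param ph_check Run PH diagnostics per metabolite (default TRUE).
#' @return A data.frame, one row per metabolite, with columns
#'   `metabolite, hr, lo, hi, p, ph_p_metabolite, ph_global_p, converged,
#'   significant, nominal`.
#' @export
metabolome_screen <- function(data, zmat, tier = 3, threshold = NULL,
                              strata = NULL, ph_check = TRUE) {
  rows <- lapply(colnames(zmat), function(m) {
    res <- fit_metabolite_cox(data, zmat, m, tier = tier, strata = strata)
    ph <- if (ph_check) check_proportional_hazards(res) else NULL
    data.frame(
      metabolite = m, hr = res$hr_per_sd, lo = res$ci95[1], hi = res$ci95[2],
      p = res$p,
      ph_p_metabolite = if (ph_check) ph$metabolite_p else NA_real_,
      ph_global_p = if (ph_check) ph$global_p else NA_real_,
      converged = res$converged
    )
  })
  out <- do.call(rbind, rows)
  out$nominal <- out$p < 0.05
  out$significant <- if (!is.null(threshold)) out$p < threshold$threshold else NA
  rownames(out) <- NULL
  out
}

#' Albuminuria-stratified screen with interaction tests
#'
#' Fits every metabolite separately in participants with and without
#' albuminuria, adjusted for the full tier-3 covariate set minus albuminuria
#' itself, and tests the metabolite x albuminuria interaction in the pooled
#' fully adjusted model. Strata with fewer than 10 events are flagged as low
#' power.
#'
#' @param data Analysis data.frame containing `albuminuria`.
#' @param zmat Complete standardized metabolite matrix.
#' @return A list with `with_albuminuria` and `without_albuminuria` screen
#'   data.frames (each with a `low_power` attribute), `interaction`
#'   (data.frame metabolite/p), and the stratum case/control counts.
#' @export
albuminuria_stratified_screen <- function(data, zmat) {
  alb <- impute_covariates(data, "albuminuria")$albuminuria
  covs <- setdiff(tier_covariates(3), "albuminuria")

  screen_stratum <- function(keep) {
    dd <- data[keep, , drop = FALSE]
    zz <- zmat[keep, , drop = FALSE]
    res <- lapply(colnames(zz), function(m) {
      r <- fit_stratum_cox(dd, zz, m, covs)
      data.frame(metabolite = m, hr = r$hr, lo = r$lo, hi = r$hi, p = r$p)
    })
    out <- do.call(rbind, res)
    attr(out, "low_power") <- sum(dd$event) < 10
    attr(out, "n_cases") <- sum(dd$event)
    attr(out, "n_controls") <- sum(dd$event == 0)
    out
  }
  with_alb <- screen_stratum(alb == 1)
  without_alb <- screen_stratum(alb == 0)

  dd <- impute_covariates(data, tier_covariates(3))
  inter <- vapply(colnames(zmat), function(m) {
    dd$.z <- zmat[, m]
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ .z * albuminuria +",
      paste(setdiff(tier_covariates(3), "albuminuria"), collapse = " + ")
    ))
    fit <- suppressWarnings(survival::coxph(fml, data = dd, ties = "efron"))
    summary(fit)$coefficients[".z:albuminuria", "Pr(>|z|)"]
  }, numeric(1))

  list(
    with_albuminuria = with_alb,
    without_albuminuria = without_alb,
    interaction = data.frame(metabolite = colnames(zmat), p = unname(inter)),
    counts = list(
      with = c(cases = attr(with_alb, "n_cases"),
               controls = attr(with_alb, "n_controls")),
      without = c(cases = attr(without_alb, "n_cases"),
                  controls = attr(without_alb, "n_controls"))
    )
  )
}

fit_stratum_cox <- function(dd, zz, metabolite, covs) {
  dd <- impute_covariates(dd, covs)
  dd$.z <- zz[, metabolite]
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ .z +", paste(covs, collapse = " + ")
  ))
  fit <- suppressWarnings(survival::coxph(fml, data = dd, ties = "efron"))
  co <- summary(fit)$coefficients[".z", ]
  list(
    hr = exp(co[["coef"]]),
    lo = exp(co[["coef"]] - stats::qnorm(0.975) * co[["se(coef)"]]),
    hi = exp(co[["coef"]] + stats::qnorm(0.975) * co[["se(coef)"]]),
    p = co[["Pr(>|z|)"]]
  )
}

#' Estimated glucose disposal rate
#'
#' HbA1c-adapted linear formula for insulin sensitivity in type 1 diabetes:
#' `24.4 - 12.97 * WHR - 3.39 * AHT - 0.60 * HbA1c(%)`, where WHR is the
#' waist-to-hip ratio and AHT indicates antihypertensive treatment and/or
#' blood pressure >= 140/90 mmHg (1 = yes).
#'
#' @param waist_hip_ratio Numeric.
#' @param aht 0/1 indicator.
#' @param hba1c_percent HbA1c in % units.
#' @return eGDR (mg/kg/min).
#' @export
egdr <- function(waist_hip_ratio, aht, hba1c_percent) {
  if (any(!aht[!is.na(aht)] %in% c(0, 1))) stop("aht must be 0 or 1")
  24.4 - 12.97 * waist_hip_ratio - 3.39 * aht - 0.60 * hba1c_percent
}

#' Linear association of eGDR with a standardized metabolite
#'
#' Ordinary least squares of eGDR on the standardized metabolite, adjusted
#' for the non-modifiable risk factors and kidney function (tier-2 set).
#' The slope is per 1 SD of the metabolite.
#'
#' @param data Analysis data.frame with `whr`, `aht`, `hba1c_pct` and the
#'   adjustment covariates.
#' @param z Standardized metabolite vector aligned with `data`.
#' @param covariates Adjustment covariates, default the tier-2 set.
#' @return A list with `beta`, `se`, `p`, `n` and the `lm` fit.
#' @export
egdr_regression <- function(data, z,
                            covariates = tier_covariates(2)) {
  dd <- impute_covariates(data, unique(c(covariates, "whr", "aht", "hba1c_pct")))
  dd$.egdr <- egdr(dd$whr, dd$aht, dd$hba1c_pct)
  dd$.z <- z
  fml <- stats::as.formula(paste(
    ".egdr ~ .z +", paste(covariates, collapse = " + ")
  ))
  fit <- stats::lm(fml, data = dd)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear covariates in eGDR regression: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  co <- summary(fit)$coefficients[".z", ]
  list(beta = co[["Estimate"]], se = co[["Std. Error"]],
       p = co[["Pr(>|t|)"]], n = nrow(dd), fit = fit)
}
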