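#' Replace zero concentrations by half the minimum detected value
#'
#' Urinary NMR platforms report concentrations below the detection limit as
#' exact zeros. The smallest non-zero, non-missing concentration observed for
#' a metabolite is taken as its detection limit (recorded on the panel), and
#' each zero is replaced by half that value. The minimum is computed over the
#' full cohort handed in, because the detection limit is a property of the
#' assay, not of a follow-up subset.
#'
#' @param panel A `metabolite_panel` at stage `"raw"`.
#' @return The panel at stage `"zero_replaced"`, with `detection_limit` filled.
#' @export
replace_zeros <- function(panel) {
  assert_stage(panel, "raw", "replace_zeros")
  vals <- panel$values
  limits <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    x <- x[!is.na(x) & x > 0]
    if (length(x) == 0L) {
      stop(sprintf(
        "metabolite '%s' has no detected (non-zero) values; cannot set a detection limit",
        colnames(vals)[j]
      ))
    }
    min(x)
  }, numeric(1))
  names(limits) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    zero <- !is.na(vals[, j]) & vals[, j] == 0
    vals[zero, j] <- limits[j] / 2
  }
  panel$detection_limit <- limits
  advance_stage(panel, vals, "zero_replaced")
}

#' Normalize concentrations to metabolite-to-creatinine ratios
#'
#' Divides every metabolite concentration by the participant's urinary
#' creatinine concentration, the standard normalization for urine flow rate.
#' Creatinine itself is not a column of the resulting ratio matrix.
#'
#' @param panel A `metabolite_panel` at stage `"zero_replaced"`.
#' @return The panel at stage `"ratio"`.
#' @export
creatinine_normalize <- function(panel) {
  assert_stage(panel, "zero_replaced", "creatinine_normalize")
  bad <- which(is.na(panel$creatinine) | panel$creatinine <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "creatinine must be positive and non-missing for all participants; offending rows: %s",
      paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  vals <- panel$values / panel$creatinine
  advance_stage(panel, vals, "ratio")
}

#' Sample skewness
#'
#' Third standardized moment `g1 = m3 / m2^(3/2)` with moments about the mean
#' computed over non-missing entries.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return Skewness (numeric scalar).
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations for skewness")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Choose the variance-stabilizing transform for one metabolite
#'
#' Metabolite-to-creatinine ratios are right-skewed; the pipeline applies
#' either a natural logarithm or a square root per metabolite. The transform
#' whose result has the smaller absolute sample skewness is selected; ties go
#' to the logarithm. The decision set is closed: no other transform is ever
#' returned.
#'
#' @param x Numeric vector of positive ratio values (`NA` allowed).
#' @return `"log"` or `"sqrt"`.
#' @export
select_transform <- function(x) {
  obs <- x[!is.na(x)]
  if (any(obs <= 0)) stop("transform selection requires strictly positive values")
  if (length(unique(obs)) < 2L) {
    stop("constant metabolite column: cannot transform/standardize")
  }
  s_log <- abs(sample_skewness(log(obs)))
  s_sqrt <- abs(sample_skewness(sqrt(obs)))
  if (s_log <= s_sqrt) "log" else "sqrt"
}

#' Apply the selected transform to every metabolite
#'
#' Runs [select_transform()] per metabolite on the ratio matrix and applies
#' the winner, recording the choice on the panel.
#'
#' @param panel A `metabolite_panel` at stage `"ratio"`.
#' @return The panel at stage `"transformed"`, with `transform_record` filled.
#' @export
transform_panel <- function(panel) {
  assert_stage(panel, "ratio", "transform_panel")
  vals <- panel$values
  record <- character(ncol(vals))
  names(record) <- colnames(vals)
  for (j in seq_len(ncol(vals))) {
    record[j] <- select_transform(vals[, j])
    vals[, j] <- if (record[j] == "log") log(vals[, j]) else sqrt(vals[, j])
  }
  panel$transform_record <- record
  advance_stage(panel, vals, "transformed")
}

#' Standardize each metabolite to zero mean and unit variance
#'
#' Means and standard deviations (n - 1 denominator) are computed over
#' non-missing entries only; the missing mask is untouched.
#'
#' @param panel A `metabolite_panel` at stage `"transformed"`.
#' @return The panel at stage `"standardized"`.
#' @export
standardize <- function(panel) {
  assert_stage(panel, "transformed", "standardize")
  vals <- panel$values
  for (j in seq_len(ncol(vals))) {
    mu <- mean(vals[, j], na.rm = TRUE)
    sd_j <- stats::sd(vals[, j], na.rm = TRUE)
    if (!is.finite(sd_j) || sd_j == 0) {
      stop(sprintf("metabolite '%s' has zero variance; cannot standardize",
                   colnames(vals)[j]))
    }
    vals[, j] <- (vals[, j] - mu) / sd_j
  }
  advance_stage(panel, vals, "standardized")
}

#' Drop metabolites above a missingness threshold
#'
#' @param panel A `metabolite_panel` at any stage.
#' @param threshold Fraction in (0, 1); metabolites whose missing fraction
#'   exceeds it are removed.
#' @return A list with `panel` (restricted), `excluded` (character vector of
#'   removed metabolite names) and `n_excluded` (their count, used when the
#'   metabolome-wide significance threshold is assembled).
#' @export
filter_missingness <- function(panel, threshold) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  frac <- colMeans(panel$missing_mask)
  drop <- frac > threshold
  excluded <- colnames(panel$values)[drop]
  if (any(drop)) {
    keep <- !drop
    panel$values <- panel$values[, keep, drop = FALSE]
    panel$missing_mask <- panel$missing_mask[, keep, drop = FALSE]
    if (!is.null(panel$transform_record)) {
      panel$transform_record <- panel$transform_record[keep]
    }
    if (!is.null(panel$detection_limit)) {
      panel$detection_limit <- panel$detection_limit[keep]
    }
  }
  list(panel = panel, excluded = excluded, n_excluded = length(excluded))
}

#' Mean-impute missing cells of a standardized panel
#'
#' After standardization the per-metabolite observed mean is zero, so imputed
#' cells are (numerically) zero. Returns a complete numeric matrix ready for
#' PCA and Cox screening.
#'
#' @param panel A `metabolite_panel` at stage `"standardized"`.
#' @return Numeric matrix with no missing values.
#' @export
impute_mean <- function(panel) {
  assert_stage(panel, "standardized", "impute_mean")
  vals <- panel$values
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (all(miss)) {
      stop(sprintf(
        "metabolite '%s' is entirely missing; filter it before imputation",
        colnames(vals)[j]
      ))
    }
    if (any(miss)) vals[miss, j] <- mean(vals[!miss, j])
  }
  vals
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper applying, in order: zero replacement, creatinine
#' normalization, per-metabolite log/sqrt transform, and standardization.
#'
#' @param panel A `metabolite_panel` at stage `"raw"`.
#' @return The panel at stage `"standardized"`.
#' @export
preprocess_panel <- function(panel) {
  standardize(transform_panel(creatinine_normalize(replace_zeros(panel))))
}
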