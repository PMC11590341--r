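#' Metabolite panel container
#'
#' A `metabolite_panel` holds a participants x metabolites concentration
#' matrix together with the per-participant urinary creatinine concentration,
#' a missingness mask, and bookkeeping for the preprocessing pipeline: the
#' current stage, the per-metabolite transform applied, and the detection
#' limit recorded during zero replacement.
#'
#' The stage moves only forward through
#' `raw -> zero_replaced -> ratio -> transformed -> standardized`;
#' each preprocessing operation checks the stage of its input so the pipeline
#' order cannot be violated silently.
#'
#' @param values Numeric matrix (participants x metabolites, mmol/l). Missing
#'   cells are `NA`. Must have column names.
#' @param creatinine Numeric vector of urinary creatinine concentrations
#'   (mmol/l), one per row of `values`.
#' @param stage Character scalar, one of the stages listed above.
#' @param transform_record Named character vector (`"log"` or `"sqrt"` per
#'   metabolite) once the transform stage has run, otherwise `NULL`.
#' @param detection_limit Named numeric vector of per-metabolite detection
#'   limits (half the minimum detected value) once zero replacement has run.
#'
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(values, creatinine, stage = "raw",
                             transform_record = NULL, detection_limit = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("`values` must have metabolite column names")
  }
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (length(creatinine) != nrow(values)) {
    stop("`creatinine` must have one entry per participant row")
  }
  stage <- match.arg(stage, panel_stages())
  structure(
    list(
      values = values,
      creatinine = as.numeric(creatinine),
      missing_mask = is.na(values),
      stage = stage,
      transform_record = transform_record,
      detection_limit = detection_limit
    ),
    class = "metabolite_panel"
  )
}

panel_stages <- function() {
  c("raw", "zero_replaced", "ratio", "transformed", "standardized")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf(
    "<metabolite_panel> %d participants x %d metabolites, stage '%s'\n",
    nrow(x$values), ncol(x$values), x$stage
  ))
  miss <- mean(x$missing_mask)
  cat(sprintf("  overall missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.metabolite_panel <- function(x) dim(x$values)

# Internal: assert the panel is at `stage` before an operation runs, and
# advance to `to` afterwards while preserving the missing mask.
assert_stage <- function(panel, stage, op) {
  if (!inherits(panel, "metabolite_panel")) {
    stop(sprintf("%s() expects a metabolite_panel", op))
  }
  if (panel$stage != stage) {
    stop(sprintf(
      "%s() requires a panel at stage '%s' (got '%s'); stages move only forward",
      op, stage, panel$stage
    ))
  }
  invisible(panel)
}

advance_stage <- function(panel, values, to) {
  stopifnot(identical(dim(values), dim(panel$values)))
  # the mask never changes across stages; values must agree with it
  stopifnot(identical(is.na(values), panel$missing_mask))
  panel$values <- values
  panel$stage <- to
  panel
}
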