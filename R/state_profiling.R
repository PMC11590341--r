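#' Metabolomic state profiling design
#'
#' Fixes the protocol of the bagged-SVM profiling: ten outer bootstraps with
#' a balanced without-replacement training sample (104 cases/104 controls
#' for the 10-year horizon, 49/49 for the 5-year horizon) and all remaining
#' participants as validation; a 7 x 11 grid search over the radial kernel's
#' gamma `[1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001]` and the SVM's C
#' `[1, 5, ..., 50]`, scored by the median phi coefficient over ten inner
#' 50/50 pre-training bootstraps; then bagging of 100 SVMs trained on
#' with-replacement resamples of the full training set, with the fraction of
#' members voting "case" as the ensemble score.
#'
#' @param horizon `"10y"` or `"5y"` (sets the default training case count).
#' @param variable_set One of `"cad_nmr"`, `"nmr"`, `"clinical"`,
#'   `"clinical_plus_cad_nmr"`.
#' @param outer_bootstraps Number of outer train/validation splits.
#' @param train_cases Cases (= controls) per training sample; default 104
#'   (10y) or 49 (5y).
#' @param gamma_grid,c_grid Hyperparameter grids.
#' @param bag_size Number of bagged SVMs.
#' @param inner_bootstraps Pre-training bootstraps for the grid search.
#' @return A list of class `profiling_design`.
#' @export
profiling_design <- function(horizon = c("10y", "5y"),
                             variable_set = c("cad_nmr", "nmr", "clinical",
                                              "clinical_plus_cad_nmr"),
                             outer_bootstraps = 10,
                             train_cases = NULL,
                             gamma_grid = c(1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001),
                             c_grid = c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50),
                             bag_size = 100,
                             inner_bootstraps = 10) {
  horizon <- match.arg(horizon)
  if (is.null(train_cases)) train_cases <- if (horizon == "10y") 104 else 49
  structure(
    list(
      horizon = horizon, variable_set = match.arg(variable_set),
      outer_bootstraps = outer_bootstraps, train_cases = train_cases,
      gamma_grid = gamma_grid, c_grid = c_grid, bag_size = bag_size,
      inner_bootstraps = inner_bootstraps
    ),
    class = "profiling_design"
  )
}

#' Select the feature table for a profiling design
#'
#' Variables with missingness above 15% are excluded; remaining missing cells
#' are imputed to the variable mean. The variable sets are: `cad_nmr` =
#' CAD-associated metabolites (full-adjustment p < 0.05, supplied via
#' `cad_metabolites`, intersected with the low-missingness panel); `nmr` =
#' all metabolites passing the missingness filter; `clinical` = the network
#' module's clinical node list after the same missingness filter (which
#' removes smoking and WHtR under the default generator); combined = union
#' of clinical and cad_nmr.
#'
#' @param panel Standardized (unimputed) `metabolite_panel` aligned with
#'   `data` rows.
#' @param data Clinical data.frame.
#' @param design A [profiling_design()].
#' @param cad_metabolites Character vector of CAD-associated metabolite
#'   names (required for the `cad_nmr` and combined sets; typically the
#'   nominally significant metabolites of the fully adjusted screen).
#' @param missing_threshold Missingness filter, default 0.15.
#' @return A list with `x` (complete numeric feature matrix), `names` and
#'   `kinds`.
#' @export
select_variables <- function(panel, data, design, cad_metabolites = NULL,
                             missing_threshold = 0.15) {
  met_miss <- colMeans(panel$missing_mask)
  met_keep <- names(met_miss)[met_miss <= missing_threshold]
  met_x <- impute_mean(panel)[, met_keep, drop = FALSE]

  clin_all <- c(
    "sex_male", "onset_year", "onset_age", "age", "duration", "bmi", "sbp",
    "dbp", "map", "log_tg", "chol_total", "hdl", "ldl", "hba1c_pct", "egfr",
    "albuminuria", "smoking", "whtr"
  )
  clin_miss <- vapply(clin_all, function(v) mean(is.na(data[[v]])), numeric(1))
  clin_keep <- clin_all[clin_miss <= missing_threshold]
  clin_x <- as.matrix(data[, clin_keep, drop = FALSE])
  for (j in seq_len(ncol(clin_x))) {
    miss <- is.na(clin_x[, j])
    if (any(miss)) clin_x[miss, j] <- mean(clin_x[!miss, j])
  }

  pick_cad <- function() {
    if (is.null(cad_metabolites) || length(cad_metabolites) == 0) {
      stop("empty CAD-associated metabolite set: run the metabolome-wide screen first")
    }
    sel <- intersect(cad_metabolites, met_keep)
    if (length(sel) == 0) {
      stop("no CAD-associated metabolite passes the missingness filter")
    }
    sel
  }
  x <- switch(design$variable_set,
    nmr = met_x,
    cad_nmr = met_x[, pick_cad(), drop = FALSE],
    clinical = clin_x,
    clinical_plus_cad_nmr = cbind(clin_x, met_x[, pick_cad(), drop = FALSE])
  )
  list(x = x, names = colnames(x),
       kinds = ifelse(colnames(x) %in% c("sex_male", "albuminuria", "smoking"),
                      "dichotomous", "continuous"))
}

#' Balanced outer train/validation split
#'
#' Samples `design$train_cases` cases and the same number of controls without
#' replacement into training; every remaining participant goes to validation.
#'
#' @param labels 0/1 outcome vector.
#' @param design A [profiling_design()].
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `validation`
#'   (disjoint, covering all rows).
#' @export
outer_split <- function(labels, design, seed) {
  set.seed(seed)
  cases <- which(labels == 1)
  controls <- which(labels == 0)
  k <- design$train_cases
  if (length(cases) < k + 1 || length(controls) < k + 1) {
    stop("not enough cases/controls for a balanced training sample plus validation")
  }
  train <- c(sample(cases, k), sample(controls, k))
  list(train = sort(train), validation = sort(setdiff(seq_along(labels), train)))
}

#' Phi coefficient of a binary confusion table
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; equal to the
#' Pearson correlation of the two 0/1 codings (and to the Matthews
#' correlation coefficient). A zero margin yields 0 by convention.
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return Value in [-1, 1].
#' @export
phi_coefficient <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# Feature scaling learned on training data only. Strict mode rejects
# constant features; lenient mode (inner pre-training halves, where a rare
# dichotomous feature can be constant by chance) passes them through
# centered with unit scale.
scale_fit <- function(x, strict = TRUE) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  bad <- !is.finite(scale) | scale == 0
  if (any(bad)) {
    if (strict) {
      stop("constant feature(s) in training data: ",
           paste(colnames(x)[bad], collapse = ", "))
    }
    scale[bad] <- 1
  }
  list(center = center, scale = scale)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

svm_fit <- function(x, y, gamma, cost) {
  e1071::svm(
    x = x, y = factor(y, levels = c(0, 1)), type = "C-classification",
    kernel = "radial", gamma = gamma, cost = cost, scale = FALSE
  )
}

svm_predict <- function(model, x) {
  as.integer(as.character(stats::predict(model, x)))
}

#' Grid search over (gamma, C) by median pre-training phi
#'
#' For each of the design's inner bootstraps, half of the training sample is
#' drawn without replacement (per class, so both halves keep both classes)
#' into pre-training; one radial SVM per grid cell is fitted on the scaled
#' pre-training half and scored by the phi coefficient on the held-out half.
#' The cell with the highest median phi across inner bootstraps wins; ties
#' break to the smaller C, then the smaller gamma (the less complex
#' boundary).
#'
#' @param x Training feature matrix.
#' @param y Training 0/1 labels.
#' @param design A [profiling_design()].
#' @param seed Integer seed.
#' @return A list with `gamma`, `cost` and the full `grid` data.frame of
#'   median phi values.
#' @export
grid_search_pretrain <- function(x, y, design, seed) {
  set.seed(seed)
  scale_fit(x) # reject features constant across the whole training set
  grid <- expand.grid(gamma = design$gamma_grid, cost = design$c_grid)
  phis <- matrix(NA_real_, nrow(grid), design$inner_bootstraps)
  for (ib in seq_len(design$inner_bootstraps)) {
    pre <- c(
      sample(which(y == 1), floor(sum(y == 1) / 2)),
      sample(which(y == 0), floor(sum(y == 0) / 2))
    )
    sc <- scale_fit(x[pre, , drop = FALSE], strict = FALSE)
    x_pre <- scale_apply(x[pre, , drop = FALSE], sc)
    x_val <- scale_apply(x[-pre, , drop = FALSE], sc)
    y_pre <- y[pre]
    y_val <- y[-pre]
    for (g in seq_len(nrow(grid))) {
      m <- svm_fit(x_pre, y_pre, grid$gamma[g], grid$cost[g])
      phis[g, ib] <- phi_coefficient(svm_predict(m, x_val), y_val)
    }
  }
  grid$median_phi <- apply(phis, 1, stats::median)
  best <- grid[order(-grid$median_phi, grid$cost, grid$gamma), ][1, ]
  list(gamma = best$gamma, cost = best$cost, grid = grid)
}

#' Train a bagged SVM ensemble
#'
#' Fits `bag_size` radial SVMs at the selected (gamma, C), each on an
#' n-out-of-n with-replacement resample of the training set. Feature scaling
#' is learned once on the full training set and applied unchanged to any
#' prediction data. A resample containing a single class is redrawn (and
#' counted).
#'
#' @param x Training feature matrix.
#' @param y Training 0/1 labels.
#' @param gamma,cost Selected hyperparameters.
#' @param bag_size Ensemble size (default 100).
#' @param seed Integer seed.
#' @param bootstrap Set `FALSE` to train every member on the full training
#'   set (degenerate mode for tests).
#' @return An object of class `svm_ensemble`.
#' @export
train_bagged <- function(x, y, gamma, cost, bag_size = 100, seed,
                         bootstrap = TRUE) {
  set.seed(seed)
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  n <- nrow(xs)
  redraws <- 0L
  members <- vector("list", bag_size)
  for (m in seq_len(bag_size)) {
    if (bootstrap) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        redraws <- redraws + 1L
      }
    } else {
      idx <- seq_len(n)
    }
    members[[m]] <- svm_fit(xs[idx, , drop = FALSE], y[idx], gamma, cost)
  }
  structure(
    list(members = members, scaling = sc, gamma = gamma, cost = cost,
         bag_size = bag_size, redraws = redraws),
    class = "svm_ensemble"
  )
}

#' Ensemble vote score
#'
#' Fraction of ensemble members voting "case" for each row; scores live on
#' the grid 0, 1/bag_size, ..., 1.
#'
#' @param model An `svm_ensemble`.
#' @param x Feature matrix on the original (unscaled) scale.
#' @return Numeric score vector in [0, 1].
#' @export
ensemble_score <- function(model, x) {
  xs <- scale_apply(x, model$scaling)
  votes <- vapply(model$members, function(m) svm_predict(m, xs),
                  integer(nrow(xs)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' Fit the profiling model on a training set
#'
#' Grid search ([grid_search_pretrain()]) followed by bagging
#' ([train_bagged()]). Touches only the rows handed in, so scaling, parameter
#' selection and member training cannot leak validation information.
#'
#' @param x Training feature matrix.
#' @param y Training 0/1 labels.
#' @param design A [profiling_design()].
#' @param seed Integer seed.
#' @return An `svm_ensemble` with the selected parameters attached.
#' @export
fit_profile <- function(x, y, design, seed) {
  gs <- grid_search_pretrain(x, y, design, seed)
  train_bagged(x, y, gs$gamma, gs$cost, design$bag_size, seed + 1L)
}

# AUC of scores against 0/1 labels (rank statistic via pROC).
score_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Evaluate a profiling design over the outer bootstraps
#'
#' Per outer bootstrap: balanced split, grid search, bagging, ensemble
#' scoring of the validation set, and validation AUC. The master seed spawns
#' one child seed per bootstrap (a fixed-length draw from the seeded RNG),
#' so the whole AUC vector is reproducible.
#'
#' @param x Feature matrix (all participants).
#' @param labels 0/1 outcome vector.
#' @param design A [profiling_design()].
#' @param seed Master seed.
#' @return A list of class `profiling_result`: per-bootstrap `auc`, `mean`,
#'   `sd`, and the selected `(gamma, cost)` per bootstrap.
#' @export
evaluate_profiling <- function(x, labels, design, seed) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 2L, design$outer_bootstraps)
  auc <- numeric(design$outer_bootstraps)
  params <- vector("list", design$outer_bootstraps)
  for (b in seq_len(design$outer_bootstraps)) {
    sp <- outer_split(labels, design, child[b])
    if (length(unique(labels[sp$validation])) < 2) {
      stop("validation set contains a single class")
    }
    gs <- grid_search_pretrain(x[sp$train, , drop = FALSE], labels[sp$train],
                               design, child[b] + 1L)
    model <- train_bagged(x[sp$train, , drop = FALSE], labels[sp$train],
                          gs$gamma, gs$cost, design$bag_size, child[b] + 2L)
    scores <- ensemble_score(model, x[sp$validation, , drop = FALSE])
    auc[b] <- score_auc(labels[sp$validation], scores)
    params[[b]] <- c(gamma = gs$gamma, cost = gs$cost)
  }
  structure(
    list(auc = auc, mean = mean(auc), sd = stats::sd(auc),
         params = params, design = design),
    class = "profiling_result"
  )
}

#' @export
print.profiling_result <- function(x, ...) {
  cat(sprintf(
    "<profiling_result '%s' %s> AUC = %.3f +/- %.3f over %d bootstraps\n",
    x$design$variable_set, x$design$horizon, x$mean, x$sd, length(x$auc)
  ))
  invisible(x)
}

#' Compare two profiling results across bootstraps
#'
#' Paired two-sided test on the per-bootstrap AUC differences; a paired
#' t-test by default, Wilcoxon signed-rank by flag.
#'
#' @param a,b `profiling_result`s run on the same bootstrap seeds.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return A list with `p`, `mean_diff` and the underlying htest.
#' @export
compare_profiling <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(a$auc) == length(b$auc))
  ht <- if (method == "t") {
    stats::t.test(a$auc, b$auc, paired = TRUE)
  } else {
    stats::wilcox.test(a$auc, b$auc, paired = TRUE, exact = FALSE)
  }
  list(p = ht$p.value, mean_diff = mean(a$auc - b$auc), test = ht)
}
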