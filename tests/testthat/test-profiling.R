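# reduced design used across these tests: small grids, bag and bootstraps so
# the suite stays fast while every protocol element is exercised
tiny_design <- function(variable_set = "nmr", outer = 3, train_cases = 30,
                        bag = 25) {
  profiling_design(
    horizon = "10y", variable_set = variable_set, outer_bootstraps = outer,
    train_cases = train_cases, gamma_grid = c(0.1, 0.01), c_grid = c(1, 10),
    bag_size = bag, inner_bootstraps = 5
  )
}

separable_features <- function(n = 400, p = 8, shift = 3, seed = 19) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  x[y == 1, 1:4] <- x[y == 1, 1:4] + shift
  list(x = x, y = y)
}

test_that("phi coefficient matches the confusion-table formula", {
  expect_equal(phi_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(phi_coefficient(c(0, 0, 1, 1), c(1, 1, 0, 0)), -1)
  # TP=45, TN=40, FP=10, FN=5
  pred <- c(rep(1, 45), rep(0, 40), rep(1, 10), rep(0, 5))
  truth <- c(rep(1, 45), rep(0, 40), rep(0, 10), rep(1, 5))
  expect_equal(phi_coefficient(pred, truth), 0.7035, tolerance = 1e-4)
  expect_equal(phi_coefficient(rep(1, 10), rbinom(10, 1, 0.5)), 0)
})

test_that("outer splits reproduce the published case/control bookkeeping", {
  labels10 <- rep(c(1, 0), c(209, 2292))
  sp <- outer_split(labels10, profiling_design("10y", "nmr"), seed = 20)
  expect_equal(sum(labels10[sp$train]), 104)
  expect_equal(length(sp$train), 208)
  expect_equal(sum(labels10[sp$validation]), 105)
  expect_equal(sum(labels10[sp$validation] == 0), 2188)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_along(labels10))

  labels5 <- rep(c(1, 0), c(98, 2403))
  sp5 <- outer_split(labels5, profiling_design("5y", "nmr"), seed = 21)
  expect_equal(sum(labels5[sp5$train]), 49)
  expect_equal(sum(labels5[sp5$validation]), 49)
  expect_equal(sum(labels5[sp5$validation] == 0), 2354)

  expect_error(outer_split(rep(c(1, 0), c(50, 500)),
                           profiling_design("10y", "nmr"), seed = 1),
               "not enough")
})

test_that("the default grids span 7 x 11 = 77 cells", {
  d <- profiling_design("10y", "nmr")
  expect_length(d$gamma_grid, 7)
  expect_length(d$c_grid, 11)
  expect_equal(length(d$gamma_grid) * length(d$c_grid), 77)
  expect_equal(d$train_cases, 104)
  expect_equal(profiling_design("5y", "nmr")$train_cases, 49)
})

test_that("variable selection applies the 15% missingness filter and set definitions", {
  co <- default_cohort()
  scheme <- apply_followup_scheme(co, followup_scheme("10y"))
  keep <- match(scheme$data$id, co$clinical$id)
  panel <- preprocess_panel(metabolite_panel(
    co$metabolites$values[keep, ], co$metabolites$creatinine[keep]
  ))
  clin <- scheme$data

  f_clin <- select_variables(panel, clin, tiny_design("clinical"))
  expect_equal(ncol(f_clin$x), 16) # smoking and WHtR fall to the filter
  expect_false(any(c("smoking", "whtr") %in% f_clin$names))
  expect_false(anyNA(f_clin$x))

  f_nmr <- select_variables(panel, clin, tiny_design("nmr"))
  miss <- colMeans(panel$missing_mask)
  expect_setequal(f_nmr$names, names(miss)[miss <= 0.15])
  expect_false("taurine" %in% f_nmr$names) # 62% missing

  cad <- c("3-hydroxyisobutyrate", "xanthosine", "taurine")
  f_cad <- select_variables(panel, clin, tiny_design("cad_nmr"),
                            cad_metabolites = cad)
  expect_setequal(f_cad$names, c("3-hydroxyisobutyrate", "xanthosine"))

  f_comb <- select_variables(panel, clin, tiny_design("clinical_plus_cad_nmr"),
                             cad_metabolites = cad)
  expect_equal(ncol(f_comb$x), 16 + 2)
  expect_false(any(duplicated(f_comb$names)))

  expect_error(select_variables(panel, clin, tiny_design("cad_nmr")),
               "screen")
})

test_that("ensemble scores are vote fractions on the expected grid", {
  sep <- separable_features()
  model <- train_bagged(sep$x, sep$y, gamma = 0.1, cost = 1, bag_size = 25,
                        seed = 22)
  scores <- ensemble_score(model, sep$x)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_true(all(abs(scores * 25 - round(scores * 25)) < 1e-9))
  # clear cases get unanimous votes
  expect_equal(max(scores), 1)

  # bootstrap disabled: every member is the same classifier
  degen <- train_bagged(sep$x, sep$y, gamma = 0.1, cost = 1, bag_size = 10,
                        seed = 23, bootstrap = FALSE)
  s <- ensemble_score(degen, sep$x)
  expect_true(all(s %in% c(0, 1)))

  single <- train_bagged(sep$x, sep$y, gamma = 0.1, cost = 1, bag_size = 1,
                         seed = 24)
  expect_length(single$members, 1)
  expect_true(all(ensemble_score(single, sep$x[1:5, ]) %in% c(0, 1)))
})

test_that("grid search returns a unique cell with the documented tie-break", {
  sep <- separable_features(n = 150, shift = 4)
  d <- tiny_design(train_cases = 20)
  gs <- grid_search_pretrain(sep$x[1:120, ], sep$y[1:120], d, seed = 25)
  expect_true(gs$gamma %in% d$gamma_grid)
  expect_true(gs$cost %in% d$c_grid)
  expect_equal(nrow(gs$grid), 4)
  # separable wide-margin data: the winning cell reaches median phi of 1
  expect_equal(max(gs$grid$median_phi), 1)

  # pure noise: selection still returns one cell, preferring small C and gamma
  set.seed(26)
  noise <- matrix(rnorm(120 * 5), 120, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  ynoise <- rep(c(0, 1), 60)
  gs2 <- grid_search_pretrain(noise, ynoise, d, seed = 27)
  ties <- gs2$grid[gs2$grid$median_phi == max(gs2$grid$median_phi), ]
  expect_equal(gs2$cost, min(ties$cost))
  expect_equal(gs2$gamma, min(ties$gamma[ties$cost == min(ties$cost)]))

  const <- cbind(noise, dead = 1)
  expect_error(grid_search_pretrain(const, ynoise, d, seed = 28), "dead")
})

test_that("profiling is deterministic and separable data yields near-perfect AUC", {
  sep <- separable_features()
  res1 <- evaluate_profiling(sep$x, sep$y, tiny_design(), seed = 29)
  res2 <- evaluate_profiling(sep$x, sep$y, tiny_design(), seed = 29)
  expect_identical(res1$auc, res2$auc)
  expect_gt(res1$mean, 0.95)
  expect_gte(min(res1$auc), 0.9)
  expect_length(res1$auc, 3)
})

test_that("AUC via pROC agrees with the rank-statistic oracle", {
  set.seed(30)
  labels <- rbinom(300, 1, 0.3)
  scores <- runif(300) + 0.3 * labels
  # Mann-Whitney form: (mean rank of cases - (n1+1)/2) / n0
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc_oracle <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(uricad:::score_auc(labels, scores), auc_oracle,
               tolerance = 1e-12)
})

test_that("training never touches validation rows (leakage canary)", {
  sep <- separable_features()
  train_idx <- 1:200
  probe <- sep$x[201:260, ]
  m1 <- fit_profile(sep$x[train_idx, ], sep$y[train_idx], tiny_design(),
                    seed = 31)
  # perturb everything outside the training rows, refit with the same seed
  x2 <- sep$x
  x2[201:400, ] <- x2[201:400, ] + 100
  m2 <- fit_profile(x2[train_idx, ], sep$y[train_idx], tiny_design(),
                    seed = 31)
  expect_identical(ensemble_score(m1, probe), ensemble_score(m2, probe))
  expect_identical(m1$gamma, m2$gamma)
  expect_identical(m1$cost, m2$cost)
})

test_that("paired design comparison computes both tests", {
  a <- structure(list(auc = c(0.7, 0.72, 0.71, 0.69, 0.73)),
                 class = "profiling_result")
  b <- structure(list(auc = c(0.6, 0.63, 0.61, 0.58, 0.64)),
                 class = "profiling_result")
  ct <- compare_profiling(a, b)
  expect_lt(ct$p, 0.01)
  expect_gt(ct$mean_diff, 0)
  cw <- compare_profiling(a, b, method = "wilcoxon")
  expect_lt(cw$p, 0.1)
})
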