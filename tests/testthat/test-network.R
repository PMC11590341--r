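test_that("mixed correlation dispatches on node kinds", {
  x <- 1:6
  mono <- mixed_correlation(x, x^3) # strictly monotone
  expect_equal(mono$r, 1)
  expect_identical(mono$method, "spearman")

  phi <- mixed_correlation(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5),
                           "dichotomous", "dichotomous")
  expect_equal(phi$r, 1) # a = d = 5, b = c = 0
  expect_identical(phi$method, "phi")

  pb <- mixed_correlation(1:6, c(0, 0, 0, 1, 1, 1),
                          "continuous", "dichotomous")
  expect_identical(pb$method, "pointbiserial")
  expect_equal(pb$r, 0.8783, tolerance = 1e-4)

  expect_error(mixed_correlation(c(1, 2, NA, NA, 5), c(NA, 2, 3, 4, NA)),
               "complete pairs")
  expect_error(mixed_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("pairwise deletion gives each pair its own effective n", {
  x <- c(1, 2, 3, 4, 5, NA, 7)
  y <- c(2, 1, 4, 3, NA, 6, 7)
  cc <- mixed_correlation(x, y)
  expect_equal(cc$n, 5)
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(14)
  x <- rnorm(50)
  y <- 0.5 * x + rnorm(50)
  r0 <- mixed_correlation(x, y)$r
  expect_equal(mixed_correlation(exp(x), y)$r, r0)
  expect_equal(mixed_correlation(x, y^3 + 5 * y)$r, r0)
})

test_that("phi equals the Pearson correlation of the 0/1 codings", {
  set.seed(15)
  for (i in 1:10) {
    a <- rbinom(40, 1, 0.5)
    b <- rbinom(40, 1, 0.5)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(mixed_correlation(a, b, "dichotomous", "dichotomous")$r,
                 cor(a, b))
  }
})

test_that("analytic correlation p-values behave at the null, tails and boundary", {
  expect_equal(correlation_pvalue(0, 100, "spearman")$p, 1)
  expect_equal(correlation_pvalue(0, 100, "phi")$p, 1)

  rs <- seq(0.05, 0.9, by = 0.05)
  ps <- vapply(rs, function(r) correlation_pvalue(r, 200, "spearman")$p,
               numeric(1))
  expect_true(all(diff(ps) < 0)) # monotone decreasing in |r|

  b <- correlation_pvalue(1, 50, "spearman")
  expect_true(b$degenerate)
  expect_equal(b$p, .Machine$double.xmin)

  # the borderline r at the link threshold has p close to that threshold
  alpha <- 2e-5
  r_c <- tanh(stats::qnorm(1 - alpha / 2) / sqrt(2501 - 3))
  p_c <- correlation_pvalue(r_c, 2501, "spearman")$p
  expect_lt(abs(log10(p_c) - log10(alpha)), 0.15)
})

test_that("network combinatorics and null sparsity hold", {
  set.seed(16)
  nodes <- as.data.frame(matrix(rnorm(120 * 20), 120))
  colnames(nodes) <- paste0("n", 1:20)
  cm <- correlation_matrix(nodes, rep("continuous", 20))
  net <- build_network(cm, link_alpha = 2e-5)
  expect_equal(net$n_possible, 20 * 19 / 2)
  expect_lte(net$n_links, 1) # independent data: essentially no links

  two <- correlation_matrix(nodes[, 1:2], rep("continuous", 2))
  expect_equal(build_network(two)$n_possible, 1)
})

test_that("centralities match hand-computed small graphs", {
  path <- igraph::make_graph(~ A - B, B - C)
  cp <- centralities(path)
  expect_equal(cp$centrality$betweenness[cp$centrality$node == "B"], 1)
  expect_equal(sum(cp$centrality$betweenness), 1)

  tri <- igraph::make_graph(~ A - B, B - C, C - A)
  expect_equal(centralities(tri)$global_clustering, 1)

  star <- igraph::make_graph(~ H - L1, H - L2, H - L3)
  cs <- centralities(star)
  expect_equal(cs$centrality$degree[cs$centrality$node == "H"], 3)
  expect_true(is.nan(cs$global_clustering) || cs$global_clustering == 0)
})

test_that("permutation difference p-values reach the add-one floor and reproduce", {
  set.seed(17)
  n <- 80
  cases <- data.frame(a = rnorm(n))
  cases$b <- cases$a + rnorm(n, 0, 0.2)
  controls <- data.frame(a = rnorm(n), b = rnorm(n))
  B <- 999
  d <- permutation_difference(cases, controls, rep("continuous", 2),
                              B = B, seed = 3)
  expect_equal(d$p, 1 / (B + 1)) # planted extreme difference hits the floor
  expect_gt(d$delta_r, 0.8)

  d2 <- permutation_difference(cases, controls, rep("continuous", 2),
                               B = B, seed = 3)
  expect_identical(d, d2) # bit-identical at fixed seed

  expect_error(permutation_difference(cases[1:5, ], controls,
                                      rep("continuous", 2), B = 10, seed = 1),
               "at least 10")
})

test_that("difference network applies both inclusion gates", {
  diff <- data.frame(
    node1 = c("a", "a", "b"), node2 = c("b", "c", "c"),
    r_case = c(0.5, 0.5, 0.3), r_control = c(0.1, 0.2, 0.25),
    delta_r = c(0.4, 0.3, 0.05),
    p = c(0.01, 0.2, 0.001)
  )
  p_case <- c(1e-6, 1e-6, 1e-3)
  p_control <- c(0.5, 0.5, 1e-3)
  dn <- difference_network(diff, p_case, p_control)
  expect_identical(dn$include, c(TRUE, FALSE, FALSE))
  expect_equal(dn$n_links, 1)
  expect_equal(dn$edges$node1, "a")
  expect_equal(dn$edges$node2, "b")
})

test_that("Fisher-z power solves and inverts consistently", {
  expect_error(correlation_power(3), "exceed 3")
  pw <- correlation_power(209)
  expect_equal(correlation_power_at(209, pw$r), 0.80, tolerance = 1e-10)
  expect_gt(correlation_power_at(209, 0.5), 0.99)
  expect_lt(correlation_power_at(209, 0.05), 0.01)
})

test_that("node table has 72 nodes with the documented kinds", {
  co <- default_cohort()
  scheme <- apply_followup_scheme(co, followup_scheme("10y"))
  keep <- match(scheme$data$id, co$clinical$id)
  panel <- preprocess_panel(metabolite_panel(
    co$metabolites$values[keep, ], co$metabolites$creatinine[keep]
  ))
  nt <- network_node_table(scheme$data, panel)
  expect_equal(ncol(nt$nodes), 72) # 54 metabolites + 18 clinical variables
  expect_equal(sum(nt$kinds == "dichotomous"), 3)
  expect_equal(72 * 71 / 2, 2556)
})

test_that("network export writes edge list and GraphML", {
  set.seed(18)
  nodes <- data.frame(a = rnorm(30), b = rnorm(30))
  nodes$c <- nodes$a + rnorm(30, 0, 0.1)
  cm <- correlation_matrix(nodes, rep("continuous", 3))
  net <- build_network(cm, link_alpha = 0.01)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "edges.csv")
  gml <- file.path(dir, "net.graphml")
  export_network(net, csv, gml)
  expect_true(file.exists(csv))
  expect_true(file.exists(gml))
  back <- read.csv(csv)
  expect_equal(nrow(back), net$n_links)
})
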