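#' Mixed-type correlation for one pair of variables
#'
#' Dispatches on the node kinds: Spearman's rank correlation for
#' continuous-continuous pairs, point-biserial correlation (Pearson with 0/1
#' coding) for dichotomous-continuous pairs, and the phi coefficient
#' (Pearson of two 0/1 codings) for dichotomous-dichotomous pairs. Missing
#' data are excluded pairwise, so every pair has its own effective n.
#'
#' @param x,y Numeric vectors (dichotomous variables coded 0/1).
#' @param kind_x,kind_y `"continuous"` or `"dichotomous"`.
#' @return A list with `r`, `n` (complete pairs) and `method`.
#' @export
mixed_correlation <- function(x, y, kind_x = "continuous",
                              kind_y = "continuous") {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4) stop("fewer than 4 complete pairs after pairwise deletion")
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant variable: correlation undefined")
  }
  dich <- c(kind_x, kind_y) == "dichotomous"
  method <- if (all(dich)) {
    "phi"
  } else if (any(dich)) {
    "pointbiserial"
  } else {
    "spearman"
  }
  r <- switch(method,
    spearman = stats::cor(x, y, method = "spearman"),
    pointbiserial = stats::cor(x, y, method = "pearson"),
    phi = stats::cor(x, y, method = "pearson")
  )
  list(r = r, n = n, method = method)
}

#' Analytic p-value for a mixed-type correlation
#'
#' Spearman and point-biserial coefficients use the t approximation with
#' n - 2 degrees of freedom; the phi coefficient uses the chi-squared test
#' with 1 degree of freedom on `n * phi^2`. All tests are two-sided. A
#' coefficient of exactly +/-1 is reported at the smallest representable
#' double and flagged via the `degenerate` field.
#'
#' @param r Correlation coefficient.
#' @param n Effective sample size of the pair.
#' @param method `"spearman"`, `"pointbiserial"` or `"phi"`.
#' @return A list with `p` and `degenerate`.
#' @export
correlation_pvalue <- function(r, n,
                               method = c("spearman", "pointbiserial", "phi")) {
  method <- match.arg(method)
  if (n < 4) stop("n must be at least 4")
  if (abs(r) >= 1) {
    return(list(p = .Machine$double.xmin, degenerate = TRUE))
  }
  p <- if (method == "phi") {
    stats::pchisq(n * r^2, df = 1, lower.tail = FALSE)
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(p = p, degenerate = FALSE)
}

#' All pairwise mixed-type correlations of a node table
#'
#' @param nodes Data.frame or matrix of node columns (metabolites on the
#'   processed scale plus clinical variables; dichotomous columns coded 0/1).
#' @param kinds Character vector (`"continuous"`/`"dichotomous"`) per column.
#' @return A list of symmetric matrices `r`, `p`, `n` plus `kinds`.
#' @export
correlation_matrix <- function(nodes, kinds) {
  nodes <- as.data.frame(nodes)
  k <- ncol(nodes)
  stopifnot(length(kinds) == k)
  nm <- colnames(nodes)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cc <- mixed_correlation(nodes[[i]], nodes[[j]], kinds[i], kinds[j])
      pv <- correlation_pvalue(cc$r, cc$n, cc$method)
      r[i, j] <- r[j, i] <- cc$r
      p[i, j] <- p[j, i] <- pv$p
      nmat[i, j] <- nmat[j, i] <- cc$n
    }
  }
  list(r = r, p = p, n = nmat, kinds = stats::setNames(kinds, nm))
}

#' Build a baseline correlation network
#'
#' Includes a link for every pair whose correlation p-value is below
#' `link_alpha` (default 2e-5). The graph is undirected with the correlation
#' coefficient as link weight.
#'
#' @param cm Output of [correlation_matrix()].
#' @param link_alpha Link inclusion threshold.
#' @param group Label carried on the result (`"complete"`, `"cases"`, ...).
#' @return A list of class `correlation_network`: `graph` (igraph),
#'   `n_nodes`, `n_possible` = n(n-1)/2, `n_links`, and the input matrices.
#' @export
build_network <- function(cm, link_alpha = 2e-5, group = "complete") {
  nm <- rownames(cm$r)
  k <- length(nm)
  idx <- which(upper.tri(cm$p) & cm$p < link_alpha, arr.ind = TRUE)
  edges <- data.frame(
    from = nm[idx[, 1]], to = nm[idx[, 2]],
    r = cm$r[idx], p = cm$p[idx], n = cm$n[idx]
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nm, kind = unname(cm$kinds))
  )
  structure(
    list(
      graph = g, group = group, n_nodes = k,
      n_possible = k * (k - 1) / 2, n_links = nrow(edges),
      edges = edges, r = cm$r, p = cm$p
    ),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network '%s'> %d nodes, %d possible links, %d included\n",
    x$group, x$n_nodes, x$n_possible, x$n_links
  ))
  invisible(x)
}

#' Node centralities and global clustering
#'
#' Degree is the link count per node; betweenness is computed on the
#' unweighted graph (each intermediate node credited once per node pair,
#' split equally across equal-length shortest paths); global clustering is
#' the transitivity, 3 x triangles / connected triples.
#'
#' @param network A `correlation_network` (or bare igraph).
#' @return A list with `centrality` (data.frame node/degree/betweenness) and
#'   `global_clustering`.
#' @export
centralities <- function(network) {
  g <- if (inherits(network, "correlation_network")) network$graph else network
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, directed = FALSE)
  list(
    centrality = data.frame(
      node = igraph::V(g)$name, degree = unname(deg),
      betweenness = unname(btw)
    ),
    global_clustering = igraph::transitivity(g, type = "global")
  )
}

# Internal fast correlation for permutations (no error guards, no p-values).
pair_r <- function(x, y, method) {
  ok <- !is.na(x) & !is.na(y)
  if (method == "spearman") {
    stats::cor(rank(x[ok]), rank(y[ok]))
  } else {
    stats::cor(x[ok], y[ok])
  }
}

#' Permutation test for case-control correlation differences
#'
#' For each pair, the observed difference `r_case - r_control` is compared
#' with its permutation null: group labels are shuffled B times preserving
#' the group sizes, the difference is recomputed on each permuted split, and
#' the two-sided p-value is `(1 + #{|d_b| >= |d_obs|}) / (B + 1)` (add-one
#' estimator, so the attainable floor is `1/(B+1)`; with the default
#' B = 20000 that is 5e-5). Permutations are drawn from a seeded RNG so runs
#' reproduce bit-identically.
#'
#' @param case_nodes,control_nodes Data.frames with identical node columns.
#' @param kinds Node kinds as in [correlation_matrix()].
#' @param pairs Optional 2-column matrix of column indices to test (default:
#'   all pairs).
#' @param B Number of permutations (default 20000).
#' @param seed Integer seed (mandatory).
#' @return A data.frame with one row per pair: `node1, node2, r_case,
#'   r_control, delta_r, p`.
#' @export
permutation_difference <- function(case_nodes, control_nodes, kinds,
                                   pairs = NULL, B = 20000, seed) {
  case_nodes <- as.data.frame(case_nodes)
  control_nodes <- as.data.frame(control_nodes)
  stopifnot(identical(colnames(case_nodes), colnames(control_nodes)))
  n1 <- nrow(case_nodes)
  n2 <- nrow(control_nodes)
  if (min(n1, n2) < 10) stop("each group needs at least 10 participants")
  if (missing(seed)) stop("seed is mandatory for the permutation test")
  k <- ncol(case_nodes)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(k, 2))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  method_for <- function(i, j) {
    dich <- c(kinds[i], kinds[j]) == "dichotomous"
    if (all(dich)) "phi" else if (any(dich)) "pointbiserial" else "spearman"
  }
  methods <- vapply(seq_len(nrow(pairs)),
                    function(q) method_for(pairs[q, 1], pairs[q, 2]),
                    character(1))

  pooled <- rbind(case_nodes, control_nodes)
  obs <- numeric(nrow(pairs))
  rc <- rk <- numeric(nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    rc[q] <- pair_r(case_nodes[[i]], case_nodes[[j]], methods[q])
    rk[q] <- pair_r(control_nodes[[i]], control_nodes[[j]], methods[q])
    obs[q] <- rc[q] - rk[q]
  }

  set.seed(seed)
  exceed <- integer(nrow(pairs))
  ntot <- n1 + n2
  pooled_m <- as.matrix(pooled)
  for (b in seq_len(B)) {
    idx <- sample.int(ntot, n1)
    in1 <- logical(ntot)
    in1[idx] <- TRUE
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      d <- pair_r(pooled_m[in1, i], pooled_m[in1, j], methods[q]) -
        pair_r(pooled_m[!in1, i], pooled_m[!in1, j], methods[q])
      if (abs(d) >= abs(obs[q]) - 1e-12) exceed[q] <- exceed[q] + 1L
    }
  }
  nm <- colnames(case_nodes)
  data.frame(
    node1 = nm[pairs[, 1]], node2 = nm[pairs[, 2]],
    r_case = rc, r_control = rk, delta_r = obs,
    p = (1 + exceed) / (B + 1)
  )
}

#' Case-to-control difference network
#'
#' A pair is included when its permutation difference p-value is nominally
#' significant (p < 0.05) and the correlation itself is significant in cases
#' and/or controls (p < 2e-5). The signed difference is the link weight.
#'
#' @param diff Data.frame from [permutation_difference()].
#' @param p_case,p_control Per-pair correlation p-values in each group,
#'   aligned with `diff` rows.
#' @param alpha_diff Nominal gate on the permutation p (default 0.05).
#' @param link_alpha Group-correlation gate (default 2e-5).
#' @param nodes Optional node name vector (default: names seen in `diff`).
#' @return A list of class `difference_network` with `graph`, `edges` (the
#'   included pairs) and the inclusion mask.
#' @export
difference_network <- function(diff, p_case, p_control,
                               alpha_diff = 0.05, link_alpha = 2e-5,
                               nodes = NULL) {
  stopifnot(length(p_case) == nrow(diff), length(p_control) == nrow(diff))
  include <- diff$p < alpha_diff & (p_case < link_alpha | p_control < link_alpha)
  edges <- diff[include, , drop = FALSE]
  if (is.null(nodes)) nodes <- unique(c(diff$node1, diff$node2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$node1, to = edges$node2,
               weight = edges$delta_r, p_diff = edges$p),
    directed = FALSE, vertices = data.frame(name = nodes)
  )
  structure(
    list(graph = g, edges = edges, include = include,
         n_links = sum(include)),
    class = "difference_network"
  )
}

#' @export
print.difference_network <- function(x, ...) {
  cat(sprintf("<difference_network> %d included links\n", x$n_links))
  invisible(x)
}

#' Minimal detectable correlation (Fisher-z power)
#'
#' Solves `atanh(r) * sqrt(n - 3) = z_{1 - alpha/2} + z_{power}` for r: the
#' correlation magnitude detectable with the given power at a two-sided
#' significance level alpha.
#'
#' @param n Sample size (> 3).
#' @param alpha Two-sided significance level (default 2e-5, the network link
#'   threshold).
#' @param power Target power (default 0.80).
#' @return A list with `r` (exact) and `r_2dp` (rounded to 2 decimals, the
#'   reporting convention).
#' @export
correlation_power <- function(n, alpha = 2e-5, power = 0.80) {
  if (n <= 3) stop("n must exceed 3")
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3)
  r <- tanh(z)
  list(r = r, r_2dp = round(r, 2))
}

#' Power to detect a given correlation (Fisher-z)
#'
#' Two-sided power of the correlation test at level `alpha` for a true
#' correlation `r` at sample size `n`, under the Fisher-z normal
#' approximation.
#'
#' @param n Sample size (> 3).
#' @param r True correlation magnitude.
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1].
#' @export
correlation_power_at <- function(n, r, alpha = 2e-5) {
  if (n <= 3) stop("n must exceed 3")
  zc <- stats::qnorm(1 - alpha / 2)
  mu <- atanh(r) * sqrt(n - 3)
  stats::pnorm(mu - zc) + stats::pnorm(-mu - zc)
}

#' Assemble the network node table from a cohort
#'
#' Binds the processed (standardized, unimputed) metabolite columns with the
#' 18 baseline clinical node variables: sex, age, diabetes duration, onset
#' calendar year, onset age, albuminuria, eGFR, HbA1c (%), SBP, DBP, MAP,
#' log-triglyceride, total/LDL/HDL cholesterol, BMI, WHtR and smoking.
#' Clinical nodes enter on their raw scale (rank-based correlation is
#' invariant to monotone rescaling); sex, albuminuria and smoking are
#' dichotomous.
#'
#' @param data Clinical data.frame (analysis cohort rows).
#' @param panel Standardized `metabolite_panel` aligned with `data` rows.
#' @return A list with `nodes` (data.frame) and `kinds`.
#' @export
network_node_table <- function(data, panel) {
  stopifnot(nrow(data) == nrow(panel$values))
  clin_cont <- c(
    "age", "duration", "onset_year", "onset_age", "egfr", "hba1c_pct",
    "sbp", "dbp", "map", "log_tg", "chol_total", "ldl", "hdl", "bmi", "whtr"
  )
  clin_dich <- c("sex_male", "albuminuria", "smoking")
  nodes <- cbind(
    as.data.frame(panel$values, check.names = FALSE),
    data[, c(clin_dich, clin_cont), drop = FALSE]
  )
  kinds <- c(
    rep("continuous", ncol(panel$values)),
    rep("dichotomous", length(clin_dich)),
    rep("continuous", length(clin_cont))
  )
  list(nodes = nodes, kinds = kinds)
}

#' Export a network's edge list (and optionally GraphML)
#'
#' @param network A `correlation_network` or `difference_network`.
#' @param csv_path Path for the edge-list CSV.
#' @param graphml_path Optional path for a GraphML export.
#' @return Invisibly, the edge data.frame.
#' @export
export_network <- function(network, csv_path, graphml_path = NULL) {
  edges <- network$edges
  utils::write.csv(edges, csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(edges)
}
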