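#' Default pipeline configuration
#'
#' Per-stage settings with the analysis defaults: 50% missingness filter for
#' the screen, 2e-5 link threshold, B = 20000 permutations, the printed SVM
#' grids. Every entry can be overridden through the `config` argument of
#' [run_pipeline()] (or a YAML file with the same structure).
#'
#' @return Nested list of stage settings.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = list(n_participants = 2501, event_rate_10y = 209 / 2501),
    preprocess = list(missing_threshold = 0.5),
    screen = list(tier = 3, variance_fraction = 0.99, scheme = "10y"),
    network = list(link_alpha = 2e-5, permutations = 20000,
                   alpha_diff = 0.05, max_diff_pairs = NULL),
    profile = list(horizon = "10y", outer_bootstraps = 10, bag_size = 100,
                   train_cases = NULL,
                   gamma_grid = c(1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001),
                   c_grid = c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50),
                   inner_bootstraps = 10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> screen -> network -> profile on a
#' synthetic cohort, writing per-stage CSV/JSON outputs and a manifest with
#' file checksums under `out_dir`. Stages whose outputs already exist with
#' matching checksums are skipped on re-runs, so a completed run is
#' idempotent; a corrupted intermediate file raises a checksum error.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param config Optional overrides of [default_pipeline_config()]: a nested
#'   list, or a path to a YAML file with the same structure.
#' @param stages Stages to run, in order.
#' @param verbose Emit stage-boundary log lines (default TRUE).
#' @return The manifest (invisibly), also written to `manifest.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         config = list(),
                         stages = c("simulate", "preprocess", "screen",
                                    "network", "profile"),
                         verbose = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(seed = seed, config_hash = config_hash(cfg), stages = list())
  }
  if (!identical(manifest$config_hash, config_hash(cfg)) ||
      !identical(as.integer(manifest$seed), as.integer(seed))) {
    manifest <- list(seed = seed, config_hash = config_hash(cfg),
                     stages = list())
  }

  done <- function(stage, files) {
    stored <- manifest$stages[[stage]]
    if (is.null(stored)) return(FALSE)
    if (!all(file.exists(files))) return(FALSE)
    sums <- unname(tools::md5sum(files))
    stored_sums <- unname(unlist(stored$checksums))
    if (!identical(sums, stored_sums)) {
      stop(sprintf("checksum mismatch for stage '%s': an output file changed on disk", stage))
    }
    TRUE
  }
  record <- function(stage, files, info = list()) {
    manifest$stages[[stage]] <<- c(
      list(files = files,
           checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                               basename(files)))),
      info
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  paths <- list(
    cohort = file.path(out_dir, c("clinical.csv", "metabolites.csv",
                                  "outcomes.csv", "truth.json")),
    processed = file.path(out_dir, c("processed.csv", "transforms.json")),
    screen = file.path(out_dir, c("screen.csv", "threshold.json")),
    network = file.path(out_dir, c("network_complete.csv",
                                   "network_difference.csv")),
    profile = file.path(out_dir, "profiling.csv")
  )

  if ("simulate" %in% stages) {
    if (done("simulate", paths$cohort)) {
      stage_log(verbose, "[simulate] outputs up to date, skipping")
    } else {
      stage_log(verbose, "[simulate] generating cohort (n = %d)",
                cfg$simulate$n_participants)
      cohort <- generate_cohort(sim_config(
        n_participants = cfg$simulate$n_participants,
        event_rate_10y = cfg$simulate$event_rate_10y,
        seed = seed
      ))
      write_cohort(cohort, out_dir)
      record("simulate", paths$cohort,
             list(n = nrow(cohort$clinical),
                  events = sum(cohort$outcomes$event)))
    }
  }

  needs_cohort <- any(c("preprocess", "screen", "network", "profile") %in% stages)
  if (needs_cohort) {
    if (!all(file.exists(paths$cohort[1:3]))) {
      stop("cohort files missing: run the 'simulate' stage first")
    }
    cohort <- read_cohort(out_dir)
    scheme <- followup_scheme(cfg$screen$scheme)
    analysis <- apply_followup_scheme(cohort, scheme)
    keep <- match(analysis$data$id, cohort$clinical$id)
    raw_panel <- metabolite_panel(
      cohort$metabolites$values[keep, , drop = FALSE],
      cohort$metabolites$creatinine[keep]
    )
  }

  if ("preprocess" %in% stages) {
    if (done("preprocess", paths$processed)) {
      stage_log(verbose, "[preprocess] outputs up to date, skipping")
    } else {
      stage_log(verbose, "[preprocess] %d cases / %d controls after scheme '%s'",
                analysis$n_cases, analysis$n_controls, scheme$name)
      proc <- preprocess_panel(raw_panel)
      filt <- filter_missingness(proc, cfg$preprocess$missing_threshold)
      utils::write.csv(
        cbind(id = analysis$data$id,
              as.data.frame(filt$panel$values, check.names = FALSE)),
        paths$processed[1], row.names = FALSE
      )
      jsonlite::write_json(
        list(
          transforms = as.list(proc$transform_record),
          detection_limits = as.list(proc$detection_limit),
          missing_rates = as.list(colMeans(proc$missing_mask)),
          excluded = filt$excluded
        ),
        paths$processed[2], auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      record("preprocess", paths$processed,
             list(excluded = filt$excluded,
                  n_cases = analysis$n_cases,
                  n_controls = analysis$n_controls))
    }
  }

  run_downstream <- any(c("screen", "network", "profile") %in% stages)
  if (run_downstream) {
    if (!all(file.exists(paths$processed))) {
      stop("processed matrix missing: run the 'preprocess' stage first")
    }
    proc_full <- preprocess_panel(raw_panel)
    filt <- filter_missingness(proc_full, cfg$preprocess$missing_threshold)
    zmat <- impute_mean(filt$panel)
  }

  screen_tab <- NULL
  if ("screen" %in% stages) {
    if (done("screen", paths$screen)) {
      stage_log(verbose, "[screen] outputs up to date, skipping")
      screen_tab <- utils::read.csv(paths$screen[1], check.names = FALSE)
    } else {
      k <- effective_test_count(zmat, cfg$screen$variance_fraction)
      thr <- bonferroni_threshold(k, filt$n_excluded)
      stage_log(verbose, "[screen] tier %d, threshold 0.05/%d = %s",
                cfg$screen$tier, thr$n_tests, format(thr$threshold_3sf))
      screen_tab <- metabolome_screen(analysis$data, zmat,
                                      tier = cfg$screen$tier, threshold = thr)
      utils::write.csv(screen_tab, paths$screen[1], row.names = FALSE)
      jsonlite::write_json(
        list(n_components = thr$n_components, n_excluded = thr$n_excluded,
             threshold = thr$threshold, threshold_3sf = thr$threshold_3sf),
        paths$screen[2], auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      record("screen", paths$screen,
             list(n_significant = sum(screen_tab$significant)))
    }
  }

  if ("network" %in% stages) {
    if (done("network", paths$network)) {
      stage_log(verbose, "[network] outputs up to date, skipping")
    } else {
      nt <- network_node_table(analysis$data, filt$panel)
      cm <- correlation_matrix(nt$nodes, nt$kinds)
      net <- build_network(cm, cfg$network$link_alpha)
      stage_log(verbose, "[network] %d nodes, %d/%d links",
                net$n_nodes, net$n_links, net$n_possible)
      export_network(net, paths$network[1])

      is_case <- analysis$data$event == 1
      pairs <- which(upper.tri(cm$p), arr.ind = TRUE)
      # restrict the permutation test to pairs significant in either group
      cm_case <- correlation_matrix(nt$nodes[is_case, , drop = FALSE], nt$kinds)
      cm_ctrl <- correlation_matrix(nt$nodes[!is_case, , drop = FALSE], nt$kinds)
      sig_any <- cm_case$p[pairs] < cfg$network$link_alpha |
        cm_ctrl$p[pairs] < cfg$network$link_alpha
      test_pairs <- pairs[sig_any, , drop = FALSE]
      if (!is.null(cfg$network$max_diff_pairs)) {
        test_pairs <- utils::head(test_pairs, cfg$network$max_diff_pairs)
      }
      if (nrow(test_pairs) > 0) {
        diff <- permutation_difference(
          nt$nodes[is_case, , drop = FALSE], nt$nodes[!is_case, , drop = FALSE],
          nt$kinds, pairs = test_pairs, B = cfg$network$permutations,
          seed = seed + 11L
        )
        dn <- difference_network(diff, cm_case$p[test_pairs],
                                 cm_ctrl$p[test_pairs],
                                 alpha_diff = cfg$network$alpha_diff,
                                 link_alpha = cfg$network$link_alpha,
                                 nodes = colnames(nt$nodes))
        utils::write.csv(diff, paths$network[2], row.names = FALSE)
        n_diff <- dn$n_links
      } else {
        utils::write.csv(
          data.frame(node1 = character(0), node2 = character(0)),
          paths$network[2], row.names = FALSE
        )
        n_diff <- 0L
      }
      record("network", paths$network,
             list(n_links = net$n_links, n_difference_links = n_diff))
    }
  }

  if ("profile" %in% stages) {
    if (done("profile", paths$profile)) {
      stage_log(verbose, "[profile] outputs up to date, skipping")
    } else {
      if (is.null(screen_tab)) {
        if (!file.exists(paths$screen[1])) {
          stop("screen results missing: run the 'screen' stage first")
        }
        screen_tab <- utils::read.csv(paths$screen[1], check.names = FALSE)
      }
      cad <- screen_tab$metabolite[screen_tab$p < 0.05]
      rows <- list()
      for (vs in c("cad_nmr", "nmr", "clinical", "clinical_plus_cad_nmr")) {
        design <- profiling_design(
          horizon = cfg$profile$horizon, variable_set = vs,
          outer_bootstraps = cfg$profile$outer_bootstraps,
          bag_size = cfg$profile$bag_size,
          train_cases = cfg$profile$train_cases,
          gamma_grid = cfg$profile$gamma_grid,
          c_grid = cfg$profile$c_grid,
          inner_bootstraps = cfg$profile$inner_bootstraps
        )
        feats <- select_variables(filt$panel, analysis$data, design,
                                  cad_metabolites = cad)
        res <- evaluate_profiling(feats$x, analysis$data$event, design,
                                  seed + 17L)
        stage_log(verbose, "[profile] %s: AUC %.3f +/- %.3f",
                  vs, res$mean, res$sd)
        rows[[vs]] <- data.frame(
          variable_set = vs, bootstrap = seq_along(res$auc), auc = res$auc
        )
      }
      utils::write.csv(do.call(rbind, rows), paths$profile, row.names = FALSE)
      record("profile", paths$profile)
    }
  }

  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
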