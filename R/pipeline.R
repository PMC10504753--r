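# End-to-end orchestration: simulate (or load) -> screen -> describe ->
# estimate (+ covariate-adjusted comparison) -> centrality -> sex
# comparison -> stability, with consistent sub-seeding and a
# machine-readable manifest.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param input path to an existing cohort CSV, or `NULL` to simulate.
#' @param n cohort size when simulating.
#' @param seed master seed; every stochastic stage receives a fixed
#'   offset of it, recorded in the manifest.
#' @param estimator an [estimator_config()].
#' @param group_var grouping variable for the network comparison test
#'   (`NULL` skips the stage).
#' @param permutations NCT permutations.
#' @param boot_B bootstrap replicates for edge accuracy.
#' @param cs_B subsamples per drop proportion for the CS-coefficient.
#' @param drop_grid case-dropping grid.
#' @param adjust_for covariates for the adjusted re-estimation (empty
#'   vector skips adjustment).
#' @param analysis_only when `TRUE` (default), network stages run on the
#'   screened analysis subsample (index-flagged, comorbid abuse
#'   excluded).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, n = 4000, seed = 1L,
                       estimator = estimator_config(),
                       group_var = "sex", permutations = 1000,
                       boot_B = 1000, cs_B = 100,
                       drop_grid = seq(0.05, 0.75, by = 0.05),
                       adjust_for = c("sex", "family_type", "income_band",
                                      "only_child"),
                       analysis_only = TRUE) {
  structure(list(out_dir = out_dir, input = input, n = n,
                 seed = as.integer(seed), estimator = estimator,
                 group_var = group_var, permutations = permutations,
                 boot_B = boot_B, cs_B = cs_B, drop_grid = drop_grid,
                 adjust_for = adjust_for, analysis_only = analysis_only),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for every scalar and vector field.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` the path, invisibly; `read_run_config` the
#'   configuration.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$estimator <- unclass(x$estimator)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  est <- do.call(estimator_config, x$estimator)
  x$estimator <- NULL
  cfg <- do.call(run_config, x)
  cfg$estimator <- est
  cfg
}

sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing per-stage artifacts (CSV
#' cohort, screening report JSON, Table-1 TSV, network edge lists and
#' JSON, centrality TSV, NCT JSON, stability JSON) plus a manifest with
#' seeds, row counts after every filter, and file hashes. Any stage
#' error aborts with the stage name attached.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), counts = list(),
                   files = list())
  est <- config$estimator
  path_of <- function(f) file.path(config$out_dir, f)
  record <- function(stage, files) {
    manifest$stages[[length(manifest$stages) + 1]] <<- stage
    for (f in files) manifest$files[[basename(f)]] <<-
        unname(tools::md5sum(f))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = stage, message = conditionMessage(e))
      jsonlite::write_json(manifest, path_of("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate / load ------------------------------------------------
  cohort <- run_stage("simulate", {
    if (is.null(config$input)) {
      spec <- synthetic_spec(config$n, seed = sub_seed(config$seed, 11L))
      cohort <- generate_cohort(spec)
      write_cohort(cohort, spec, path_of("cohort.csv"), path_of("truth.json"))
      record("simulate", path_of(c("cohort.csv", "truth.json")))
      cohort
    } else {
      cohort <- read.csv(config$input, stringsAsFactors = FALSE)
      record("load", character(0))
      cohort
    }
  })
  manifest$counts$cohort <- nrow(cohort)

  # -- screen ---------------------------------------------------------
  screened <- run_stage("screen", {
    scr <- screen_cohort(cohort)
    rep <- list(n_total = scr$n_total, n_csa = scr$n_csa,
                n_analysis = scr$n_analysis,
                prevalence_pct = scr$prevalence_pct,
                ci_low_pct = scr$ci_low_pct, ci_high_pct = scr$ci_high_pct)
    jsonlite::write_json(rep, path_of("screen.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    record("screen", path_of("screen.json"))
    if (config$analysis_only) cohort[scr$analysis_flag, , drop = FALSE]
    else cohort
  })
  manifest$counts$analysis <- nrow(screened)

  # -- describe -------------------------------------------------------
  run_stage("describe", {
    t1 <- build_table_one(screened)
    write.table(t1$formatted, path_of("table1.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    record("describe", path_of("table1.tsv"))
  })

  # -- estimate (+ adjusted comparison) -------------------------------
  items <- symptom_items(screened)
  net <- run_stage("estimate", {
    net <- estimate_network(items, config = est)
    el <- edge_difference_table(net, net)[, c("node_i", "node_j", "weight_a")]
    names(el)[3] <- "weight"
    write.table(el, path_of("edges.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    net_json <- list(nodes = net$nodes, weights = net$weights,
                     lambda = net$lambda_selected, gamma = net$gamma,
                     n = net$n, cor_method = net$cor_method)
    jsonlite::write_json(net_json, path_of("network.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("estimate", path_of(c("edges.tsv", "network.json")))
    net
  })
  if (length(config$adjust_for) > 0) {
    run_stage("adjusted", {
      adj <- estimate_network(items, config = est,
                              covariates = screened[, config$adjust_for,
                                                    drop = FALSE])
      cmp <- compare_networks(net, adj)
      jsonlite::write_json(cmp, path_of("adjusted_comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("adjusted", path_of("adjusted_comparison.json"))
    })
  }

  # -- centrality -----------------------------------------------------
  run_stage("centrality", {
    ct <- centrality_table(net, items)
    write.table(ct, path_of("centrality.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    record("centrality", path_of("centrality.tsv"))
  })

  # -- sex comparison -------------------------------------------------
  if (!is.null(config$group_var)) {
    run_stage("compare", {
      g <- screened[[config$group_var]]
      levs <- unique(g)
      if (length(levs) != 2) stop("group variable must have two levels")
      nct <- network_comparison_test(items[g == levs[1], , drop = FALSE],
                                     items[g == levs[2], , drop = FALSE],
                                     permutations = config$permutations,
                                     seed = sub_seed(config$seed, 23L),
                                     config = est)
      out <- list(groups = levs,
                  global_strength = as.list(nct$global_strength),
                  strength_diff = nct$strength_diff_observed,
                  strength_p = nct$strength_p, M = nct$M_observed,
                  M_p = nct$M_p, permutations = nct$permutations,
                  edges = nct$edges)
      jsonlite::write_json(out, path_of("nct.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      record("compare", path_of("nct.json"))
    })
  } else {
    manifest$stages[[length(manifest$stages) + 1]] <- "compare:skipped"
  }

  # -- stability ------------------------------------------------------
  run_stage("stability", {
    eb <- bootstrap_edges(items, B = config$boot_B,
                          seed = sub_seed(config$seed, 31L), config = est)
    cs <- case_drop_cs(items, B = config$cs_B,
                       drop_grid = config$drop_grid,
                       seed = sub_seed(config$seed, 41L), config = est)
    out <- list(edge_ci = eb$edges, B = eb$B,
                cs_coefficient = cs$cs_coefficient, cs_label = cs$label,
                cs_curve = cs$cs_curve)
    jsonlite::write_json(out, path_of("stability.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    record("stability", path_of("stability.json"))
  })

  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
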