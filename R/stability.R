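# Bootstrap accuracy and stability: nonparametric edge-weight CIs,
# bootstrapped edge-difference tests, the case-dropping bootstrap and
# the correlation-stability (CS) coefficient.

#' Nonparametric bootstrap of edge weights
#'
#' Resamples participants with replacement, re-estimates the network per
#' replicate with the full estimator, and reports percentile confidence
#' intervals per edge plus a bootstrapped difference test for every pair
#' of edges (two edges differ significantly when the bootstrap interval
#' of their difference excludes zero).
#'
#' @param items item matrix.
#' @param B number of bootstrap replicates (>= 100 recommended for CIs).
#' @param seed RNG seed.
#' @param config shared [estimator_config()].
#' @param level confidence level for the percentile intervals.
#' @return List of class `edge_bootstrap`: `edges` data frame (sample
#'   estimate, bootstrap mean, CI bounds), `edge_diff_significant`
#'   logical matrix over edge pairs, `boot_weights` (B x edges), counts
#'   of failed replicates, `B`, `seed`.
#' @export
bootstrap_edges <- function(items, B = 1000, seed = 1L,
                            config = estimator_config(), level = 0.95) {
  items <- as.matrix(items)
  stopifnot(B >= 2)
  full <- estimate_network(items, config = config)
  w_full <- upper_tri_vec(full$weights)
  n_edges <- length(w_full)

  boot <- matrix(NA_real_, B, n_edges)
  failed <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(items), replace = TRUE)
      fit <- tryCatch(estimate_network(items[idx, , drop = FALSE],
                                       config = config),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        next
      }
      boot[b, ] <- upper_tri_vec(fit$weights)
    }
  })
  if (failed > 0.05 * B) {
    stop(sprintf("estimator failed in %d of %d bootstrap replicates",
                 failed, B))
  }
  boot <- boot[complete.cases(boot), , drop = FALSE]

  alpha <- (1 - level) / 2
  ci <- t(apply(boot, 2, quantile, probs = c(alpha, 1 - alpha)))
  idx <- which(upper.tri(full$weights), arr.ind = TRUE)
  edges <- data.frame(node_i = full$nodes[idx[, 1]],
                      node_j = full$nodes[idx[, 2]],
                      estimate = w_full, boot_mean = colMeans(boot),
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      stringsAsFactors = FALSE)

  # bootstrapped difference test over all edge pairs
  sig <- matrix(FALSE, n_edges, n_edges)
  for (i in seq_len(n_edges - 1)) {
    d <- boot[, i] - boot[, (i + 1):n_edges, drop = FALSE]
    qs <- apply(d, 2, quantile, probs = c(alpha, 1 - alpha))
    s <- qs[1, ] > 0 | qs[2, ] < 0
    sig[i, (i + 1):n_edges] <- s
    sig[(i + 1):n_edges, i] <- s
  }

  structure(list(edges = edges, edge_diff_significant = sig,
                 boot_weights = boot, network = full,
                 B = B, n_failed = failed, seed = seed, level = level),
            class = "edge_bootstrap")
}

#' Case-dropping bootstrap and CS-coefficient for a centrality index
#'
#' For each drop proportion q on the grid, draws B subsamples retaining
#' `(1-q) * n` participants, re-estimates the network and the chosen
#' centrality index, and records the rank (Spearman) correlation with
#' the full-sample index. The CS-coefficient is the largest q such that
#' at least 95% of subsample correlations stay at or above 0.7; indices
#' should only be interpreted when CS exceeds 0.25, and preferably 0.5.
#'
#' @param items item matrix.
#' @param index `"expected_influence"` or `"bridge_expected_influence"`.
#' @param drop_grid proportions in (0, 0.9); default 0.05 to 0.75 by
#'   0.05.
#' @param B subsamples per grid point (>= 50 recommended).
#' @param seed RNG seed.
#' @param config shared [estimator_config()].
#' @param cor_threshold,coverage the CS rule: require
#'   `P(cor >= cor_threshold) >= coverage`.
#' @return List of class `cs_result`: `cs_coefficient`, `cs_curve` (per
#'   q: mean correlation and coverage), `correlations` matrix, `label`
#'   (the conventional unstable / acceptable / good reading), `B`,
#'   `seed`.
#' @export
case_drop_cs <- function(items,
                         index = c("expected_influence",
                                   "bridge_expected_influence"),
                         drop_grid = seq(0.05, 0.75, by = 0.05),
                         B = 100, seed = 1L, config = estimator_config(),
                         cor_threshold = 0.7, coverage = 0.95) {
  index <- match.arg(index)
  items <- as.matrix(items)
  stopifnot(all(drop_grid > 0), all(drop_grid < 0.9))
  index_fun <- switch(index,
                      expected_influence = expected_influence,
                      bridge_expected_influence = bridge_expected_influence)
  full <- estimate_network(items, config = config)
  ref <- index_fun(full)
  n <- nrow(items)
  p <- ncol(items)

  cors <- matrix(NA_real_, length(drop_grid), B,
                 dimnames = list(paste0("q", drop_grid), NULL))
  withr::with_seed(seed, {
    for (gi in seq_along(drop_grid)) {
      keep_n <- floor((1 - drop_grid[gi]) * n)
      if (keep_n < p + 2) {
        warning(sprintf("drop proportion %.2f leaves too few rows; skipped",
                        drop_grid[gi]))
        next
      }
      for (b in seq_len(B)) {
        idx <- sample.int(n, keep_n)
        fit <- tryCatch(estimate_network(items[idx, , drop = FALSE],
                                         config = config),
                        error = function(e) NULL)
        if (is.null(fit)) next
        sub <- index_fun(fit)
        cors[gi, b] <- suppressWarnings(
          cor(ref, sub, method = "spearman"))
      }
    }
  })

  curve <- data.frame(
    drop = drop_grid,
    mean_cor = rowMeans(cors, na.rm = TRUE),
    coverage = apply(cors, 1, function(x) {
      mean(x >= cor_threshold, na.rm = TRUE)
    }))
  ok <- !is.na(curve$coverage) & curve$coverage >= coverage
  cs <- if (any(ok)) {
    # largest q whose entire prefix satisfies the rule
    run <- which(!ok)
    max_ok <- if (length(run) == 0) length(drop_grid) else min(run) - 1
    if (max_ok >= 1) drop_grid[max_ok] else 0
  } else 0
  label <- if (cs > 0.5) "good" else if (cs > 0.25) "acceptable" else
    "unstable"

  structure(list(cs_coefficient = cs, cs_curve = curve,
                 correlations = cors, index = index, label = label,
                 B = B, seed = seed, cor_threshold = cor_threshold,
                 coverage = coverage),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("CS-coefficient (%s): %.2f [%s]\n", x$index,
              x$cs_coefficient, x$label))
  invisible(x)
}
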