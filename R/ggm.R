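# Regularized partial-correlation network estimation: correlation input
# (Spearman / Pearson / two-step polychoric), graphical lasso, EBIC
# penalty selection, and conversion of the precision matrix to partial
# correlations.

#' Estimator configuration for network fits
#'
#' Bundles the options every network-estimating stage shares, so that the
#' sex-comparison permutations and the bootstrap replicates re-estimate
#' networks with exactly the same estimator as the primary fit.
#'
#' @param cor_method correlation input for the Gaussian graphical model:
#'   `"spearman"` (default; robust for 4-category Likert items),
#'   `"pearson"`, or `"polychoric"` (two-step maximum likelihood, assumes
#'   a latent bivariate normal per item pair).
#' @param gamma EBIC hyperparameter; 0.5 is the conventional default for
#'   EBIC-selected graphical lasso fits. `gamma = 0` reduces to BIC.
#' @param n_lambda number of penalty values on the log-spaced grid from
#'   `lambda_max = max |S_ij|` down to `lambda_min_ratio * lambda_max`.
#' @param lambda_min_ratio smallest grid penalty as a fraction of
#'   `lambda_max`.
#' @param refit when `TRUE`, the EBIC log-likelihood of each candidate is
#'   recomputed from an unpenalized ML fit constrained to the candidate's
#'   sparsity pattern, so that model-size comparison is not biased by
#'   shrinkage; when `FALSE` the penalized estimate's likelihood is used.
#' @param tol convergence tolerance of the glasso solver (average
#'   absolute parameter change, relative to the mean absolute
#'   off-diagonal of `S`).
#' @param maxit outer iteration cap of the solver.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(cor_method = c("spearman", "pearson", "polychoric"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, refit = TRUE,
                             tol = 1e-4, maxit = 1000) {
  cor_method <- match.arg(cor_method)
  stopifnot(gamma >= 0, n_lambda >= 1, lambda_min_ratio > 0,
            lambda_min_ratio <= 1, tol > 0, maxit >= 1)
  structure(list(cor_method = cor_method, gamma = gamma,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 refit = refit, tol = tol, maxit = maxit),
            class = "estimator_config")
}

#' Correlation matrix for ordinal questionnaire items
#'
#' @param items numeric matrix, participants in rows, items in columns.
#' @param method `"spearman"`, `"pearson"`, or `"polychoric"`. The
#'   polychoric estimate is two-step ML: thresholds from the marginal
#'   category proportions via the inverse normal CDF, then the latent
#'   correlation maximizing the bivariate-normal likelihood of the
#'   contingency cells.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(items,
                               method = c("spearman", "pearson", "polychoric")) {
  method <- match.arg(method)
  items <- as.matrix(items)
  if (ncol(items) < 2) stop("need at least 2 item columns")
  const <- apply(items, 2, function(x) length(unique(x)) < 2)
  if (any(const)) {
    nm <- colnames(items)[const]
    if (is.null(nm)) nm <- which(const)
    stop("constant item column(s): ", paste(nm, collapse = ", "))
  }
  if (method %in% c("spearman", "pearson")) {
    R <- cor(items, method = method)
  } else {
    p <- ncol(items)
    R <- diag(p)
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        R[i, j] <- R[j, i] <- polychoric_pair(items[, i], items[, j])
      }
    }
    dimnames(R) <- list(colnames(items), colnames(items))
  }
  R
}

# Bivariate normal CDF P(X <= a, Y <= b) under correlation rho.
bvn_cdf <- function(a, b, rho) {
  if (!is.finite(a) && a > 0) a <- Inf
  if (!is.finite(b) && b > 0) b <- Inf
  if (is.infinite(a) && a < 0) return(0)
  if (is.infinite(b) && b < 0) return(0)
  if (is.infinite(a) && is.infinite(b)) return(1)
  if (is.infinite(a)) return(pnorm(b))
  if (is.infinite(b)) return(pnorm(a))
  sigma <- matrix(c(1, rho, rho, 1), 2)
  as.numeric(mvtnorm::pmvnorm(upper = c(a, b), corr = sigma))
}

# Two-step ML polychoric correlation for one ordinal pair.
polychoric_pair <- function(x, y) {
  tab <- table(factor(x), factor(y))
  tx <- qnorm(cumsum(rowSums(tab)) / sum(tab))
  ty <- qnorm(cumsum(colSums(tab)) / sum(tab))
  ax <- c(-Inf, tx[-length(tx)], Inf)
  ay <- c(-Inf, ty[-length(ty)], Inf)
  K1 <- nrow(tab); K2 <- ncol(tab)
  negll <- function(rho) {
    Fg <- matrix(0, K1 + 1, K2 + 1)
    for (i in seq_len(K1 + 1)) {
      for (j in seq_len(K2 + 1)) {
        Fg[i, j] <- bvn_cdf(ax[i], ay[j], rho)
      }
    }
    P <- Fg[-1, -1, drop = FALSE] - Fg[-(K1 + 1), -1, drop = FALSE] -
      Fg[-1, -(K2 + 1), drop = FALSE] +
      Fg[-(K1 + 1), -(K2 + 1), drop = FALSE]
    P <- pmax(P, 1e-12)
    -sum(tab * log(P))
  }
  optimize(negll, interval = c(-0.999, 0.999))$minimum
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |Theta_ij|` by block coordinate descent on the covariance estimate.
#'
#' @param S symmetric correlation (or covariance) matrix.
#' @param lambda nonnegative L1 penalty applied to the off-diagonal
#'   precision entries (the diagonal is left unpenalized).
#' @param tol,maxit solver controls; see [estimator_config()].
#' @param penalty optional full penalty matrix overriding `lambda`,
#'   allowing per-entry penalties (used internally for pattern refits).
#' @return List with the precision matrix `theta`, the estimated
#'   covariance `w`, the penalized log-likelihood `loglik_pen` (unit
#'   scale, without the Gaussian constant), and convergence details.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-4, maxit = 1000,
                            penalty = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  stopifnot(isSymmetric(unname(S), tol = 1e-8), is.null(penalty) || all(dim(penalty) == p))
  if (is.null(penalty)) {
    stopifnot(lambda >= 0)
    penalty <- matrix(lambda, p, p)
    diag(penalty) <- 0 # only off-diagonal precision entries are shrunk
  }
  fit <- glasso_cpp(unname(S), unname(penalty), tol, maxit)
  if (!fit$converged) {
    res <- max(abs(fit$w - S))
    stop(sprintf("glasso did not converge at lambda=%g (max residual %g)",
                 if (missing(lambda)) NA else lambda, res))
  }
  theta <- fit$theta
  dimnames(theta) <- dimnames(S)
  ld <- determinant(theta, logarithm = TRUE)
  loglik_pen <- as.numeric(ld$modulus) - sum(S * theta) -
    sum(penalty[upper.tri(penalty)] * 2 * abs(theta[upper.tri(theta)]))
  list(theta = theta, w = fit$w, loglik_pen = loglik_pen,
       iters = fit$iters, converged = fit$converged)
}

#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 logL + E log(n) + 4 gamma E log(p)`, the criterion used to
#' pick the graphical-lasso penalty: the extra `log(p)` term penalizes
#' edges more heavily when many candidate edges exist.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param n_edges number of edges (nonzero upper-triangle precision
#'   entries).
#' @param n sample size.
#' @param p number of nodes.
#' @param gamma hyperparameter; 0 gives ordinary BIC.
#' @return The EBIC score (smaller is better).
#' @export
ebic <- function(loglik, n_edges, n, p, gamma = 0.5) {
  stopifnot(n_edges >= 0, n >= 2, p >= 2, gamma >= 0)
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

#' Convert a precision matrix to partial correlations
#'
#' The edge weight between nodes i and j is the partial correlation
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)`: the correlation remaining after
#' conditioning on every other node.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @export
precision_to_partial <- function(theta) {
  theta <- as.matrix(theta)
  d <- diag(theta)
  if (any(d <= 0)) stop("precision matrix has nonpositive diagonal")
  pc <- -theta / sqrt(outer(d, d))
  diag(pc) <- 0
  dimnames(pc) <- dimnames(theta)
  pc
}

default_lambda_grid <- function(S, n_lambda = 100, lambda_min_ratio = 0.01) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- lambda_min_ratio # degenerate: identity input
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit a glasso path and select the network by EBIC
#'
#' Fits the graphical lasso over a decreasing penalty grid (warm starts),
#' scores every fit by [ebic()], and returns the minimizer converted to a
#' partial-correlation network. Ties are broken toward the larger
#' penalty, i.e. the sparser model.
#'
#' @param S correlation matrix of the items.
#' @param n number of participants behind `S`.
#' @param lambda_grid decreasing penalty grid; built from `config` when
#'   `NULL`.
#' @param config an [estimator_config()].
#' @param nodes node labels; taken from `colnames(S)` when `NULL`.
#' @param communities named community vector; inferred from the labels
#'   (GAD = anxiety, PHQ = depression) when `NULL`.
#' @return A `ggm_network` object: partial-correlation `weights`, node
#'   labels and communities, the selected penalty and path diagnostics.
#' @export
select_network <- function(S, n, lambda_grid = NULL,
                           config = estimator_config(), nodes = NULL,
                           communities = NULL) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (is.null(nodes)) nodes <- colnames(S)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(S, config$n_lambda,
                                       config$lambda_min_ratio)
  }
  stopifnot(length(lambda_grid) >= 1, !is.unsorted(rev(lambda_grid)))
  sel <- ebic_glasso_cpp(unname(S), n, lambda_grid, config$gamma,
                         config$refit, config$tol, config$maxit)
  if (!all(as.logical(sel$converged))) {
    bad <- lambda_grid[!as.logical(sel$converged)]
    stop(sprintf("glasso failed to converge at lambda = %s",
                 paste(signif(bad, 4), collapse = ", ")))
  }
  weights <- precision_to_partial(sel$theta)
  dimnames(weights) <- list(nodes, nodes)
  if (is.null(communities)) {
    communities <- tryCatch(symptom_communities(nodes), error = function(e) {
      stats::setNames(rep("all", p), nodes)
    })
  }
  structure(list(weights = weights, nodes = nodes,
                 community = communities,
                 lambda_selected = sel$lambda, gamma = config$gamma, n = n,
                 cor_method = config$cor_method,
                 input_correlation = S,
                 path = list(lambda = lambda_grid,
                             ebic = as.numeric(sel$ebic),
                             edges = as.integer(sel$edges),
                             loglik = as.numeric(sel$loglik)),
                 config = config),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  e <- sum(abs(x$weights[upper.tri(x$weights)]) > 1e-10)
  cat(sprintf(
    "EBIC-glasso network: %d nodes, %d edges (lambda=%.4g, gamma=%.2g, n=%d, %s)\n",
    length(x$nodes), e, x$lambda_selected, x$gamma, x$n, x$cor_method))
  invisible(x)
}

#' Estimate a symptom network from item responses
#'
#' Convenience wrapper: correlation input, optional covariate
#' residualization, glasso path, EBIC selection.
#'
#' @param items numeric matrix of item responses (columns = nodes).
#' @param config an [estimator_config()].
#' @param covariates optional data frame of confounders; when given, each
#'   item is replaced by its least-squares residual on the covariate
#'   design before correlation estimation (see [adjust_for_covariates()]).
#' @return A `ggm_network`.
#' @export
estimate_network <- function(items, config = estimator_config(),
                             covariates = NULL) {
  items <- as.matrix(items)
  if (!is.null(covariates)) items <- adjust_for_covariates(items, covariates)
  S <- correlation_matrix(items, method = config$cor_method)
  select_network(S, n = nrow(items), config = config)
}

#' Residualize items on a covariate design
#'
#' Replaces each item by its residual from a least-squares regression on
#' the covariates (categorical covariates expanded to indicators, with
#' intercept). Used to re-estimate the network controlling for
#' confounders such as sex, family type, income band, and only-child
#' status.
#'
#' @param items numeric matrix of item responses.
#' @param covariates data frame of covariates (factors or numerics).
#' @return Matrix of residualized items, same dimensions as `items`.
#' @export
adjust_for_covariates <- function(items, covariates) {
  items <- as.matrix(items)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(items) == nrow(covariates))
  X <- model.matrix(~., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    warning("dropping aliased covariate column(s): ",
            paste(dropped, collapse = ", "))
  }
  res <- items - qr.fitted(qrX, items)
  dimnames(res) <- dimnames(items)
  res
}

#' Compare two networks edge-wise (original vs adjusted)
#'
#' Spearman rank correlation and a t-test over the 120 upper-triangle
#' edge weights, the comparison used to check whether covariate
#' adjustment altered the network structure.
#'
#' @param a,b `ggm_network` objects on the same node set.
#' @param t_method `"independent"` (two-sample t over the two weight
#'   vectors, the default) or `"paired"`.
#' @return List with `spearman_r`, `spearman_p`, `t`, `t_df`, `t_p`.
#' @export
compare_networks <- function(a, b, t_method = c("independent", "paired")) {
  t_method <- match.arg(t_method)
  stopifnot(inherits(a, "ggm_network"), inherits(b, "ggm_network"))
  if (!identical(a$nodes, b$nodes)) stop("networks have different node sets")
  wa <- upper_tri_vec(a$weights)
  wb <- upper_tri_vec(b$weights)
  ct <- suppressWarnings(stats::cor.test(wa, wb, method = "spearman"))
  if (identical(wa, wb)) {
    tt <- list(statistic = 0, parameter = if (t_method == "paired")
      length(wa) - 1 else 2 * length(wa) - 2, p.value = 1)
  } else {
    tt <- t.test(wa, wb, var.equal = TRUE, paired = t_method == "paired")
  }
  list(spearman_r = as.numeric(ct$estimate), spearman_p = ct$p.value,
       t = as.numeric(tt$statistic), t_df = as.numeric(tt$parameter),
       t_p = tt$p.value)
}
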