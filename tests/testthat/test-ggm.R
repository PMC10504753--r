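test_that("correlation matrix handles duplicates, recodings, and errors", {
  set.seed(51)
  x <- sample(0:3, 400, replace = TRUE)
  y <- sample(0:3, 400, replace = TRUE)
  m <- cbind(a = x, b = x, c = y)
  S <- correlation_matrix(m, "spearman")
  expect_equal(S["a", "b"], 1)

  flipped <- m
  flipped[, "c"] <- 3 - flipped[, "c"] # anti-monotone recode
  S2 <- correlation_matrix(flipped, "spearman")
  expect_equal(S2["a", "c"], -S["a", "c"], tolerance = 1e-12)

  expect_error(correlation_matrix(cbind(k = rep(1, 10), j = 1:10)),
               "constant item column\\(s\\): k")
  expect_error(correlation_matrix(matrix(1:10, ncol = 1)), "at least 2")
})

test_that("polychoric recovers a planted latent correlation", {
  set.seed(53)
  m <- ordinal_pair(50000, rho = 0.5)
  r <- correlation_matrix(m, "polychoric")["x", "y"]
  expect_equal(r, 0.5, tolerance = 0.02)
  # spearman on the same data is attenuated below the latent value
  expect_lt(correlation_matrix(m, "spearman")["x", "y"], r)
})

test_that("glasso solves identity, screening-bound, and exact-inverse cases", {
  expect_equal(graphical_lasso(diag(4), 0.1)$theta, diag(4),
               tolerance = 1e-8)

  S <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.2, 0.3, 0.2, 1), 3)
  # lambda at the largest off-diagonal: all edges screened out
  fit_hi <- graphical_lasso(S, 0.5, tol = 1e-6)
  off <- fit_hi$theta
  diag(off) <- 0
  expect_true(all(off == 0))

  # lambda = 0: matches the brute-force inverse
  fit0 <- graphical_lasso(S, 0, tol = 1e-9)
  expect_equal(fit0$theta, solve(S), tolerance = 1e-6)
})

test_that("glasso stationarity conditions hold at the solution", {
  items <- fixture_items()
  S <- correlation_matrix(items, "spearman")
  lam <- 0.05
  fit <- graphical_lasso(S, lam, tol = 1e-7)
  Winv_resid <- S - fit$w
  inactive <- abs(fit$theta) <= 1e-10
  diag(inactive) <- FALSE
  active <- !inactive
  diag(active) <- FALSE
  # |S_ij - W_ij| <= lambda on zero entries, = lambda (sign-matched) on
  # active entries
  expect_true(all(abs(Winv_resid[inactive]) <= lam + 1e-5))
  expect_true(all(abs(abs(Winv_resid[active]) - lam) <= 1e-4))
})

test_that("EBIC formula reduces to its anchors", {
  expect_equal(ebic(-50, 3, 200, 10, gamma = 0),
               100 + 3 * log(200))
  expect_equal(ebic(-100, 5, 100, 16, gamma = 0.5),
               200 + 5 * log(100) + 10 * log(16))
  expect_equal(ebic(-7.5, 0, 50, 4), 15)
})

test_that("precision-to-partial conversion matches its identities", {
  expect_equal(precision_to_partial(diag(c(2, 3, 4))),
               matrix(0, 3, 3))
  r <- 0.37
  theta2 <- solve(matrix(c(1, r, r, 1), 2))
  expect_equal(precision_to_partial(theta2)[1, 2], r, tolerance = 1e-12)
  expect_error(precision_to_partial(diag(c(1, -1))), "nonpositive")
})

test_that("partial correlations equal the regression-residual oracle", {
  set.seed(59)
  A <- matrix(rnorm(16), 4)
  sigma <- crossprod(A) + diag(4)
  X <- matrix(rnorm(4000 * 4), 4000, 4) %*% chol(sigma)
  S <- cor(X)
  pc <- precision_to_partial(graphical_lasso(S, 0, tol = 1e-9)$theta)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      ri <- resid(lm(X[, i] ~ X[, -c(i, j)]))
      rj <- resid(lm(X[, j] ~ X[, -c(i, j)]))
      expect_equal(pc[i, j], cor(ri, rj), tolerance = 1e-6)
    }
  }
})

test_that("EBIC selection picks single-lambda grids and keeps path monotone", {
  items <- fixture_items()
  S <- correlation_matrix(items, "spearman")
  one <- select_network(S, n = nrow(items), lambda_grid = 0.08)
  expect_equal(one$lambda_selected, 0.08)

  net <- select_network(S, n = nrow(items), config = test_config())
  expect_true(all(diff(net$path$edges) >= 0)) # lambda grid is decreasing
  expect_true(isSymmetric(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_lt(max(abs(net$weights)), 1)
  expect_equal(unname(net$community[c("GAD1", "PHQ9")]),
               c("anxiety", "depression"))
})

test_that("covariate residualization leaves unconfounded networks alone", {
  items <- fixture_items()
  set.seed(61)
  covs <- data.frame(noise1 = rnorm(nrow(items)),
                     noise2 = factor(sample(c("a", "b"), nrow(items),
                                            replace = TRUE)))
  # Pearson input: residuals are continuous, so rank ties do not shift
  cfg <- test_config(cor_method = "pearson")
  net_raw <- estimate_network(items, config = cfg)
  net_adj <- estimate_network(items, config = cfg, covariates = covs)
  expect_lt(max(abs(net_raw$weights - net_adj$weights)), 0.02)

  aliased <- data.frame(x = covs$noise1, y = covs$noise1)
  expect_warning(adjust_for_covariates(items, aliased), "aliased")

  # an item that IS a covariate residualizes to (numerical) zero
  res <- adjust_for_covariates(cbind(items, cov_copy = covs$noise1),
                               covs["noise1"])
  expect_lt(max(abs(res[, "cov_copy"])), 1e-10)
})

test_that("adjustment recovers structure distorted by a group mean shift", {
  truth <- default_planted_network()
  nz <- which(upper.tri(truth) & truth != 0)
  wins <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(2000, female_shift = 0.8, seed = 700 + s)
    coh <- generate_cohort(spec)
    items <- symptom_items(coh)
    raw <- estimate_network(items, config = test_config())
    adj <- estimate_network(items, config = test_config(),
                            covariates = coh["sex"])
    cor_raw <- cor(truth[nz], raw$weights[nz], method = "spearman")
    cor_adj <- cor(truth[nz], adj$weights[nz], method = "spearman")
    wins <- wins + (cor_adj >= cor_raw)
  }
  expect_gte(wins, n_seeds / 2)
})

test_that("network comparison statistics behave on identity and reversal", {
  items <- fixture_items()
  net <- estimate_network(items, config = test_config())
  same <- compare_networks(net, net)
  expect_equal(same$spearman_r, 1)
  expect_equal(same$t, 0)

  # rank reversal on a tie-free network: r = -1 exactly
  set.seed(62)
  w0 <- random_weights(5)
  na_ <- make_net(w0)
  nb_ <- make_net(-w0)
  expect_equal(compare_networks(na_, nb_)$spearman_r, -1)

  noisy <- net
  set.seed(63)
  noisy$weights <- net$weights +
    (function(m) {m[] <- rnorm(length(m), 0, 1e-3); m + t(m)})(net$weights * 0)
  diag(noisy$weights) <- 0
  got <- compare_networks(net, noisy)$spearman_r
  oracle <- cor(rank(net$weights[upper.tri(net$weights)]),
                rank(noisy$weights[upper.tri(noisy$weights)]))
  expect_equal(got, oracle, tolerance = 1e-10)

  other <- net
  other$nodes <- rev(net$nodes)
  expect_error(compare_networks(net, other), "node set")
})
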