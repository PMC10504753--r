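# Shared fixtures, built once per test run.

# fast estimator for tests that re-estimate networks in loops
test_config <- function(n_lambda = 20, ...) {
  estimator_config(n_lambda = n_lambda, ...)
}

# moderately sized cohort from the default planted network
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(synthetic_spec(2000, seed = 424242L))
    }
    cache
  }
})

fixture_items <- function() symptom_items(fixture_cohort())

# hand-built network object for centrality tests
make_net <- function(weights, nodes = colnames(weights),
                     communities = NULL) {
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(weights)))
  dimnames(weights) <- list(nodes, nodes)
  if (is.null(communities)) {
    communities <- tryCatch(symptom_communities(nodes), error = function(e) {
      stats::setNames(rep("all", length(nodes)), nodes)
    })
  }
  structure(list(weights = weights, nodes = nodes,
                 community = communities, lambda_selected = 0,
                 gamma = 0.5, n = NA_integer_, cor_method = "none",
                 input_correlation = NULL, path = NULL, config = NULL),
            class = "ggm_network")
}

# random symmetric zero-diagonal weight matrix (not necessarily PD;
# centrality indices only need the weights)
random_weights <- function(p, scale = 0.3) {
  w <- matrix(0, p, p)
  w[upper.tri(w)] <- runif(p * (p - 1) / 2, -scale, scale)
  w + t(w)
}

# latent bivariate-normal ordinal pair with given correlation
ordinal_pair <- function(n, rho, cuts = qnorm(c(0.5, 0.8, 0.95))) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(x = findInterval(z1, cuts), y = findInterval(z2, cuts))
}

# small cohort carrying exactly the published sex-by-category counts
table1_count_cohort <- function() {
  male <- list(
    residence = c(city = 850, town_county = 849),
    ethnicity = c(han = 1548, other = 151),
    family_type = c(nuclear = 1124, three_generation = 356, other = 219),
    income_band = c(lt930 = 498, i930_2169 = 464, i2170_3565 = 262,
                    gt3565 = 475),
    only_child = c(yes = 965, no = 734))
  female <- list(
    residence = c(city = 938, town_county = 842),
    ethnicity = c(han = 1571, other = 209),
    family_type = c(nuclear = 1148, three_generation = 295, other = 337),
    income_band = c(lt930 = 554, i930_2169 = 583, i2170_3565 = 291,
                    gt3565 = 352),
    only_child = c(yes = 733, no = 1047))
  expand_sex <- function(counts, n) {
    # deterministic per-variable category assignment with the exact
    # marginal counts; variables are filled independently
    out <- data.frame(row = seq_len(n))
    for (v in names(counts)) {
      out[[v]] <- rep(names(counts[[v]]), counts[[v]])
    }
    out$row <- NULL
    out
  }
  m <- expand_sex(male, 1699)
  f <- expand_sex(female, 1780)
  m$sex <- "male"
  f$sex <- "female"
  cohort <- rbind(m, f)
  cohort$age <- rep(c(19, 20), length.out = nrow(cohort))
  for (cl in c(sprintf("GAD%02d", 1:7), sprintf("PHQ%02d", 1:9))) {
    cohort[[cl]] <- rep(c(0L, 1L), length.out = nrow(cohort))
  }
  cohort
}
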