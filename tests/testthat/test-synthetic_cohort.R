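test_that("partial-to-latent mapping handles independence and single edges", {
  expect_equal(partial_to_latent_correlation(matrix(0, 4, 4)), diag(4))

  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.3
  R <- partial_to_latent_correlation(P)
  expect_equal(R[1, 2], 0.3, tolerance = 1e-12)
  expect_equal(R[1, 3], 0)
  expect_equal(R[2, 3], 0)
})

test_that("three-node chain matches brute-force precision inversion", {
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.3
  P[2, 3] <- P[3, 2] <- 0.3
  R <- partial_to_latent_correlation(P)
  expected <- matrix(c(1, 0.3144854510, 0.0989010989,
                       0.3144854510, 1, 0.3144854510,
                       0.0989010989, 0.3144854510, 1), 3, byrow = TRUE)
  expect_equal(unname(R), expected, tolerance = 1e-9)
})

test_that("non-positive-definite constructions are rejected with diagnostics", {
  P <- matrix(0, 2, 2)
  P[1, 2] <- P[2, 1] <- 1.2
  expect_error(partial_to_latent_correlation(P), "in \\(-1, 1\\)")
  P2 <- matrix(0.6, 3, 3)
  diag(P2) <- 0
  expect_error(partial_to_latent_correlation(P2), "eigenvalue")
})

test_that("cohort generation is deterministic under a fixed seed", {
  spec <- synthetic_spec(120, seed = 99L)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_error(synthetic_spec(1), "n >= 2")
})

test_that("generated items respect declared ranges and naming convention", {
  coh <- fixture_cohort()
  expect_true(all(sprintf("CTQ%02d", 1:28) %in% names(coh)))
  expect_true(all(sprintf("GAD%02d", 1:7) %in% names(coh)))
  expect_true(all(sprintf("PHQ%02d", 1:9) %in% names(coh)))
  gp <- as.matrix(coh[, grep("^(GAD|PHQ)", names(coh))])
  ctq <- as.matrix(coh[, grep("^CTQ", names(coh))])
  expect_true(all(gp %in% 0:3))
  expect_true(all(ctq %in% 1:5))
  expect_false(anyNA(coh))
  expect_true(all(coh$sex %in% c("male", "female")))
})

test_that("thresholds control category proportions via the normal CDF", {
  # uniform quartile thresholds on one item
  th <- default_thresholds()
  th$gadphq[["GAD1"]] <- qnorm(c(0.25, 0.5, 0.75))
  spec <- synthetic_spec(50000, true_partial = matrix(0, 16, 16),
                         thresholds = th, female_shift = 0, seed = 7L)
  coh <- generate_cohort(spec)
  props <- as.numeric(table(factor(coh$GAD01, levels = 0:3))) / 50000
  expect_true(all(abs(props - 0.25) < 0.02))
})

test_that("a null network yields independent items", {
  spec <- synthetic_spec(50000, true_partial = matrix(0, 16, 16),
                         female_shift = 0, seed = 11L)
  items <- symptom_items(generate_cohort(spec))
  S <- correlation_matrix(items, method = "spearman")
  expect_lt(max(abs(S[upper.tri(S)])), 0.03)
})

test_that("discretization attenuates a planted latent correlation", {
  nodes <- symptom_nodes()
  P <- matrix(0, 16, 16, dimnames = list(nodes, nodes))
  P["GAD1", "GAD2"] <- P["GAD2", "GAD1"] <- 0.5
  spec <- synthetic_spec(20000, true_partial = P, female_shift = 0,
                         seed = 13L)
  coh <- generate_cohort(spec)
  r <- cor(coh$GAD01, coh$GAD02, method = "spearman")
  expect_gt(r, 0.25)
  expect_lt(r, 0.5)
})

test_that("SA severity raises CSA screening prevalence monotonically", {
  rates <- vapply(c(-1.1, -0.68, -0.3), function(sev) {
    sv <- c(EA = -0.10, PA = -0.45, SA = sev, EN = -0.35, PN = -1.00)
    coh <- generate_cohort(synthetic_spec(20000, ctq_severity = sv,
                                          seed = 17L))
    mean(screen_cohort(coh)$flags$SA)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("sex-specific structure and missingness injection work", {
  P <- default_planted_network()
  Pf <- perturb_edge(P, "GAD1", "GAD4", 0.25)
  spec <- synthetic_spec(6000, sex_effect = Pf, seed = 23L)
  coh <- generate_cohort(spec)
  rm_ <- cor(coh$GAD01[coh$sex == "male"], coh$GAD04[coh$sex == "male"],
             method = "spearman")
  rf <- cor(coh$GAD01[coh$sex == "female"], coh$GAD04[coh$sex == "female"],
            method = "spearman")
  expect_gt(rf, rm_ + 0.05)

  withm <- inject_missing(coh, rate = 0.1, seed = 1L)
  miss_rate <- mean(is.na(withm$GAD01))
  expect_gt(miss_rate, 0.05)
  expect_lt(miss_rate, 0.15)
  expect_false(anyNA(withm$sex))
})
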