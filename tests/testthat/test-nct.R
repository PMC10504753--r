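test_that("Holm adjustment matches the hand-executed step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.5, 1.2)), "p")

  set.seed(81)
  p <- runif(40)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p)) # order preserved
})

test_that("identical groups give null observed statistics and p near 1", {
  items <- fixture_items()[1:150, ]
  res <- network_comparison_test(items, items, permutations = 40,
                                 seed = 3L, config = test_config(10),
                                 min_group_n = 50)
  expect_equal(res$strength_diff_observed, 0)
  expect_equal(res$M_observed, 0)
  expect_true(all(res$edges$diff == 0))
  expect_equal(res$strength_p, 1)
  expect_equal(res$M_p, 1)
})

test_that("the comparison is deterministic under a fixed seed", {
  items <- fixture_items()
  g1 <- items[1:200, ]
  g2 <- items[201:400, ]
  a <- network_comparison_test(g1, g2, permutations = 30, seed = 11L,
                               config = test_config(10))
  b <- network_comparison_test(g1, g2, permutations = 30, seed = 11L,
                               config = test_config(10))
  expect_identical(a$strength_p, b$strength_p)
  expect_identical(a$edges, b$edges)

  # observed statistics are symmetric; per-edge differences antisymmetric
  swapped <- network_comparison_test(g2, g1, permutations = 30, seed = 11L,
                                     config = test_config(10))
  expect_equal(swapped$strength_diff_observed, a$strength_diff_observed)
  expect_equal(swapped$M_observed, a$M_observed)
  expect_equal(swapped$edges$diff, -a$edges$diff)
})

test_that("input contracts are enforced", {
  items <- fixture_items()
  expect_error(network_comparison_test(items[1:100, ], items[101:200, ],
                                       permutations = 10),
               "20 permutations")
  expect_error(network_comparison_test(items[1:30, ], items[31:60, ],
                                       permutations = 50),
               ">= 50 rows")
  renamed <- items
  colnames(renamed) <- rev(colnames(items))
  expect_error(network_comparison_test(items[1:100, ], renamed[1:100, ],
                                       permutations = 50),
               "identical item columns")
})

test_that("edge difference tables subtract and classify by sign", {
  items <- fixture_items()
  net <- estimate_network(items, config = test_config())
  zero <- edge_difference_table(net, net)
  expect_true(all(zero$diff == 0))
  expect_true(all(zero$stronger_in == "equal"))

  bumped <- net
  bumped$weights["GAD1", "GAD2"] <- bumped$weights["GAD1", "GAD2"] - 0.1
  bumped$weights["GAD2", "GAD1"] <- bumped$weights["GAD1", "GAD2"]
  d <- edge_difference_table(net, bumped)
  hit <- d$node_i == "GAD1" & d$node_j == "GAD2"
  expect_equal(d$diff[hit], 0.1, tolerance = 1e-12)
  expect_equal(sum(d$diff != 0), 1)
  expect_equal(d$stronger_in[hit], "first")
  d_swap <- edge_difference_table(bumped, net)
  expect_equal(d_swap$diff, -d$diff)
})

test_that("a planted edge difference is detected with the smallest Holm p", {
  truth <- default_planted_network()
  shifted <- perturb_edge(truth, "GAD1", "GAD4", 0.25)
  g1 <- symptom_items(generate_cohort(
    synthetic_spec(1000, true_partial = truth, female_shift = 0,
                   seed = 901L)))
  g2 <- symptom_items(generate_cohort(
    synthetic_spec(1000, true_partial = shifted, female_shift = 0,
                   seed = 902L)))
  res <- network_comparison_test(g1, g2, permutations = 100, seed = 5L,
                                 config = test_config(10))
  hit <- res$edges$node_i == "GAD1" & res$edges$node_j == "GAD4"
  expect_equal(res$edges$p_holm[hit], min(res$edges$p_holm))
  expect_lt(res$edges$diff[hit], 0) # stronger in group 2
})
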