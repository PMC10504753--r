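make_ctq_rows <- function(n = 1) {
  as.data.frame(matrix(1L, n, 28,
                       dimnames = list(NULL, sprintf("CTQ%02d", 1:28))))
}

set_subscale <- function(row, subscale, values) {
  ids <- sprintf("CTQ%02d", symptomnet:::ctq_subscale_items()[[subscale]])
  row[, ids] <- as.list(values)
  row
}

test_that("subscale scores are item sums and cut-offs flag correctly", {
  tab <- make_ctq_rows(3)
  # row 1: all SA items 1 -> score 5, unflagged
  # row 2: SA (2,2,2,1,1) -> score 8, flagged
  # row 3: SA score 8 and EA score 13 -> both flagged
  tab[2, ] <- set_subscale(tab[2, ], "SA", c(2, 2, 2, 1, 1))
  tab[3, ] <- set_subscale(tab[3, ], "SA", c(2, 2, 2, 1, 1))
  tab[3, ] <- set_subscale(tab[3, ], "EA", c(3, 3, 3, 2, 2))
  scores <- score_subscales(tab, ctq_spec())
  expect_equal(scores$SA, c(5, 8, 8))
  expect_equal(scores$EA[3], 13)
  flags <- flag_subscales(scores, ctq_spec())
  expect_equal(flags$SA, c(FALSE, TRUE, TRUE))
  expect_equal(flags$EA, c(FALSE, FALSE, TRUE))
})

test_that("out-of-range responses are rejected naming row and item", {
  tab <- make_ctq_rows(2)
  tab$CTQ05[2] <- 6L
  expect_error(score_subscales(tab, ctq_spec()), "row 2, item CTQ05")
})

test_that("comorbid-abuse exclusion keeps only pure-SA cases", {
  flags <- data.frame(EA = c(FALSE, FALSE, FALSE, TRUE),
                      PA = c(FALSE, TRUE, FALSE, FALSE),
                      SA = c(TRUE, TRUE, FALSE, TRUE),
                      EN = FALSE, PN = FALSE)
  mask <- apply_exclusions(flags, index = "SA")
  # SA only -> in; SA+PA -> out; no SA -> out; SA+EA -> out
  expect_equal(mask, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("attention filter removes failing rows and handles edge cases", {
  tab <- data.frame(a1 = c(1, 1, 0, 1), a2 = c(1, 0, 0, 1),
                    a3 = c(1, 0, 0, 1), a4 = c(0, 1, 1, 1))
  keep3of4 <- function(t) rowSums(t[, c("a1", "a2", "a3", "a4")]) >= 3
  out <- attention_filter(tab, keep3of4)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 2)
  expect_equal(nrow(attention_filter(tab, function(t) rep(TRUE, nrow(t)))), 4)
  expect_equal(nrow(attention_filter(tab[0, ], keep3of4)), 0)
})

test_that("prevalence interval reproduces the published screening result", {
  # 3479 CSA-positive of 96218 retained participants
  pr <- prevalence_ci(3479, 96218, 0.95)
  expect_equal(round(pr$prevalence_pct, 2), 3.62)
  expect_equal(round(pr$ci_low_pct, 2), 3.50)
  expect_equal(round(pr$ci_high_pct, 2), 3.73)
})

test_that("Wald interval matches closed form and degenerates are clipped", {
  pr <- prevalence_ci(50, 1000, 0.95)
  half <- 100 * qnorm(0.975) * sqrt(0.05 * 0.95 / 1000)
  expect_equal(pr$prevalence_pct, 5)
  expect_equal(pr$ci_low_pct, 5 - half)
  expect_equal(pr$ci_high_pct, 5 + half)

  pr0 <- prevalence_ci(0, 100, 0.95)
  expect_equal(pr0$prevalence_pct, 0)
  expect_equal(pr0$ci_low_pct, 0)
  expect_equal(pr0$ci_high_pct, 0)
  expect_error(prevalence_ci(1, 0), "n_total")

  w <- prevalence_ci(3479, 96218, method = "wilson")
  expect_equal(round(w$ci_low_pct, 2), 3.50)
  expect_equal(round(w$ci_high_pct, 2), 3.74)
})

test_that("screening is invariant to row order and monotone in cut-offs", {
  coh <- fixture_cohort()
  scr <- screen_cohort(coh)
  perm <- sample(nrow(coh))
  scr_p <- screen_cohort(coh[perm, ])
  expect_equal(scr_p$n_csa, scr$n_csa)
  expect_equal(scr_p$prevalence_pct, scr$prevalence_pct)

  scores <- scr$scores
  counts <- vapply(6:12, function(cut) sum(scores$SA >= cut), integer(1))
  expect_true(all(diff(counts) <= 0))
})
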