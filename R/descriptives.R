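# Table-1 style descriptives: Pearson chi-square group comparisons,
# pooled-variance t-tests, and Cronbach's alpha reliabilities.

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction), which
#' is the form that reproduces published sex-by-category comparisons
#' from their printed counts.
#'
#' @param counts integer matrix of counts, at least 2 x 2.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2, all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = as.numeric(ct$statistic),
       df = as.numeric(ct$parameter), p_value = ct$p.value)
}

#' Pooled-variance two-sample t-test
#'
#' Equal-variance (Student) t with `df = n1 + n2 - 2` and a two-sided
#' p-value.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return List: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
pooled_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("degenerate: zero pooled variance with unequal means")
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` with
#' sample variances.
#'
#' @param items numeric matrix, >= 2 columns and >= 2 rows.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  stopifnot(k >= 2, nrow(items) >= 2)
  total_var <- var(rowSums(items))
  if (total_var == 0) stop("total score has zero variance")
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / total_var)
}

#' Build a Table-1 style descriptive comparison by sex
#'
#' Counts (percent) per category with uncorrected chi-square tests for
#' the categorical covariates; mean (SD) with pooled t-tests for age and
#' the GAD-7 / PHQ-9 total scores. Percentages are formatted to one
#' decimal and statistics to two.
#'
#' @param cohort screened cohort data frame (demographics plus item
#'   columns).
#' @param categorical character vector of categorical covariate names.
#' @return List of class `table_one`: `categorical` (per-variable count
#'   table and test), `continuous` (per-variable group means and test),
#'   and `formatted` (character data frame).
#' @export
build_table_one <- function(cohort,
                            categorical = c("residence", "ethnicity",
                                            "family_type", "income_band",
                                            "only_child")) {
  if (nrow(cohort) == 0) stop("empty cohort")
  stopifnot("sex" %in% names(cohort))
  sex <- factor(cohort$sex, levels = c("male", "female"))
  if (any(is.na(sex))) stop("sex must be male/female")

  cat_out <- list()
  rows <- list()
  for (v in categorical) {
    x <- as.character(cohort[[v]])
    tab <- table(sex, x)
    test <- chi_square(tab)
    cat_out[[v]] <- list(counts = tab, statistic = test$statistic,
                         df = test$df, p_value = test$p_value)
    for (lev in colnames(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lev,
        male = sprintf("%d (%.1f)", tab["male", lev],
                       100 * tab["male", lev] / sum(tab["male", ])),
        female = sprintf("%d (%.1f)", tab["female", lev],
                         100 * tab["female", lev] / sum(tab["female", ])),
        statistic = sprintf("%.2f", test$statistic),
        p = format.pval(test$p_value, digits = 3),
        stringsAsFactors = FALSE)
    }
  }

  cont_vars <- list(age = cohort$age,
                    `GAD-7` = score_subscales(cohort, gad7_spec())$total,
                    `PHQ-9` = score_subscales(cohort, phq9_spec())$total)
  cont_out <- list()
  for (v in names(cont_vars)) {
    x <- cont_vars[[v]]
    test <- pooled_t_test(x[sex == "male"], x[sex == "female"])
    cont_out[[v]] <- c(test, list(
      sd_x = sd(x[sex == "male"]), sd_y = sd(x[sex == "female"])))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "mean (SD)",
      male = sprintf("%.2f (%.2f)", test$mean_x, cont_out[[v]]$sd_x),
      female = sprintf("%.2f (%.2f)", test$mean_y, cont_out[[v]]$sd_y),
      statistic = sprintf("%.2f", test$t),
      p = format.pval(test$p_value, digits = 3),
      stringsAsFactors = FALSE)
  }

  structure(list(categorical = cat_out, continuous = cont_out,
                 formatted = do.call(rbind, rows)),
            class = "table_one")
}

#' @export
print.table_one <- function(x, ...) {
  print(x$formatted, row.names = FALSE)
  invisible(x)
}
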