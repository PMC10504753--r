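# Instrument definitions, subscale scoring, clinical cut-offs, the
# comorbid-abuse exclusion, and prevalence with its confidence interval.

#' Define a questionnaire scale
#'
#' @param name scale name.
#' @param item_ids character vector of item column names.
#' @param response_range inclusive integer bounds of valid responses.
#' @param subscales named list mapping subscale name to item columns;
#'   defaults to one subscale holding every item.
#' @param cutoffs named integer vector of flagging thresholds per
#'   subscale (a participant is flagged when score >= cutoff).
#' @return A `scale_spec` object.
#' @export
scale_spec <- function(name, item_ids, response_range,
                       subscales = NULL, cutoffs = NULL) {
  stopifnot(length(response_range) == 2,
            response_range[1] < response_range[2])
  if (is.null(subscales)) subscales <- stats::setNames(list(item_ids), name)
  stopifnot(all(unlist(subscales) %in% item_ids))
  if (!is.null(cutoffs)) {
    stopifnot(all(names(cutoffs) %in% names(subscales)))
    for (s in names(cutoffs)) {
      k <- length(subscales[[s]])
      lo <- k * response_range[1]
      hi <- k * response_range[2]
      if (cutoffs[[s]] < lo || cutoffs[[s]] > hi) {
        stop(sprintf("cutoff %d for %s outside achievable range [%d, %d]",
                     cutoffs[[s]], s, lo, hi))
      }
    }
  }
  structure(list(name = name, item_ids = item_ids,
                 response_range = response_range, subscales = subscales,
                 cutoffs = cutoffs), class = "scale_spec")
}

#' CTQ-SF scale definition with clinical cut-offs
#'
#' 28 items on a 1-5 Likert scale, five clinical subscales with the
#' moderate-severe screening cut-offs: emotional abuse >= 13, physical
#' abuse >= 10, sexual abuse >= 8, emotional neglect >= 15, physical
#' neglect >= 10. Items are assumed already keyed.
#'
#' @return A `scale_spec`.
#' @export
ctq_spec <- function() {
  ids <- sprintf("CTQ%02d", 1:28)
  sub <- lapply(ctq_subscale_items(), function(ix) sprintf("CTQ%02d", ix))
  scale_spec("CTQ-SF", ids, c(1L, 5L), subscales = sub,
             cutoffs = c(EA = 13L, PA = 10L, SA = 8L, EN = 15L, PN = 10L))
}

#' GAD-7 scale definition
#' @return A `scale_spec` (7 items, responses 0-3, total score).
#' @export
gad7_spec <- function() {
  scale_spec("GAD-7", sprintf("GAD%02d", 1:7), c(0L, 3L))
}

#' PHQ-9 scale definition
#' @return A `scale_spec` (9 items, responses 0-3, total score).
#' @export
phq9_spec <- function() {
  scale_spec("PHQ-9", sprintf("PHQ%02d", 1:9), c(0L, 3L))
}

#' Score subscales of one instrument
#'
#' Each subscale score is the plain sum of its item responses; the total
#' over all items is reported as well. Responses outside the declared
#' range are an error naming the offending row and item.
#'
#' @param table data frame holding the item columns.
#' @param spec a [scale_spec()].
#' @return Data frame with one column per subscale plus `total`.
#' @export
score_subscales <- function(table, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  missing <- setdiff(spec$item_ids, names(table))
  if (length(missing) > 0) {
    stop("missing item column(s): ", paste(missing, collapse = ", "))
  }
  items <- as.matrix(table[, spec$item_ids, drop = FALSE])
  lo <- spec$response_range[1]
  hi <- spec$response_range[2]
  bad <- which(is.na(items) | items < lo | items > hi, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("out-of-range response at row %d, item %s",
                 bad[1, 1], spec$item_ids[bad[1, 2]]))
  }
  out <- as.data.frame(lapply(spec$subscales, function(ids) {
    rowSums(items[, ids, drop = FALSE])
  }))
  out$total <- rowSums(items)
  out
}

#' Flag subscales against their cut-offs
#'
#' @param scores output of [score_subscales()].
#' @param spec the same [scale_spec()]; must carry cutoffs.
#' @return Logical data frame, one column per cut-off subscale; `TRUE`
#'   when score >= cutoff.
#' @export
flag_subscales <- function(scores, spec) {
  stopifnot(!is.null(spec$cutoffs))
  as.data.frame(lapply(stats::setNames(names(spec$cutoffs),
                                       names(spec$cutoffs)),
                       function(s) scores[[s]] >= spec$cutoffs[[s]]))
}

#' Comorbid-abuse exclusion predicate
#'
#' A participant enters the analysis sample when flagged on the index
#' subscale and on no other subscale: survivors of more than one form of
#' abuse are excluded so that forms of abuse do not interact.
#'
#' @param flags logical data frame from [flag_subscales()].
#' @param index name of the index subscale (default `"SA"`, sexual
#'   abuse).
#' @return Logical vector: inclusion mask for the analysis cohort.
#' @export
apply_exclusions <- function(flags, index = "SA") {
  stopifnot(index %in% names(flags))
  others <- flags[, setdiff(names(flags), index), drop = FALSE]
  flags[[index]] & rowSums(others) == 0
}

#' Remove participants failing an attention check
#'
#' The attention instrument itself is caller-defined: any predicate over
#' rows (e.g. "at least three of four catch questions answered
#' correctly").
#'
#' @param table data frame.
#' @param predicate function of the table returning a logical keep-mask
#'   (or a precomputed logical vector).
#' @return The filtered table, with attribute `n_removed`.
#' @export
attention_filter <- function(table, predicate) {
  keep <- if (is.function(predicate)) predicate(table) else predicate
  if (nrow(table) == 0) keep <- logical(0)
  stopifnot(is.logical(keep), length(keep) == nrow(table))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Prevalence with a binomial confidence interval
#'
#' Point estimate `100 * k / n` with, by default, the Wald
#' (normal-approximation) interval `100 * (p +/- z * sqrt(p(1-p)/n))`
#' clipped to `[0, 100]`. The Wilson score interval is available via
#' `method = "wilson"`.
#'
#' @param n_pos number of positive screens.
#' @param n_total denominator (>= 1).
#' @param level confidence level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return List: `prevalence_pct`, `ci_low_pct`, `ci_high_pct`, `n_pos`,
#'   `n_total`, `level`, `method`.
#' @export
prevalence_ci <- function(n_pos, n_total, level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n_total < 1) stop("n_total must be >= 1")
  stopifnot(n_pos >= 0, n_pos <= n_total, level > 0, level < 1)
  phat <- n_pos / n_total
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(phat * (1 - phat) / n_total)
    lo <- phat - half
    hi <- phat + half
  } else {
    denom <- 1 + z^2 / n_total
    center <- (phat + z^2 / (2 * n_total)) / denom
    half <- z * sqrt(phat * (1 - phat) / n_total +
                       z^2 / (4 * n_total^2)) / denom
    lo <- center - half
    hi <- center + half
  }
  list(prevalence_pct = 100 * phat,
       ci_low_pct = max(0, 100 * lo), ci_high_pct = min(100, 100 * hi),
       n_pos = n_pos, n_total = n_total, level = level, method = method)
}

#' Screen a cohort for childhood sexual abuse
#'
#' Scores the CTQ-SF, flags all five subscales, computes CSA prevalence
#' over the full cohort (every SA-flagged participant counts toward the
#' numerator), and applies the comorbid-abuse exclusion to define the
#' analysis sample.
#'
#' @param cohort cohort data frame with CTQ item columns.
#' @param spec CTQ [scale_spec()]; defaults to [ctq_spec()].
#' @param level confidence level for the prevalence interval.
#' @return List of class `screen_result`: `scores`, `flags`,
#'   `analysis_flag`, `n_total`, `n_csa`, `n_analysis`, and the
#'   prevalence estimate with interval.
#' @export
screen_cohort <- function(cohort, spec = ctq_spec(), level = 0.95) {
  scores <- score_subscales(cohort, spec)
  flags <- flag_subscales(scores, spec)
  analysis_flag <- apply_exclusions(flags, index = "SA")
  prev <- prevalence_ci(sum(flags$SA), nrow(cohort), level = level)
  structure(list(scores = scores, flags = flags,
                 analysis_flag = analysis_flag,
                 n_total = nrow(cohort), n_csa = sum(flags$SA),
                 n_analysis = sum(analysis_flag),
                 prevalence_pct = prev$prevalence_pct,
                 ci_low_pct = prev$ci_low_pct,
                 ci_high_pct = prev$ci_high_pct),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "CSA screening: %d / %d positive (%.2f%%, 95%% CI %.2f-%.2f%%); %d in analysis sample after comorbid-abuse exclusion\n",
    x$n_csa, x$n_total, x$prevalence_pct, x$ci_low_pct, x$ci_high_pct,
    x$n_analysis))
  invisible(x)
}
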