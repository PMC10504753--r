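# Synthetic cohort generator: latent Gaussian copula over the 16 GAD/PHQ
# symptom items with a planted partial-correlation network, plus CTQ-SF
# trauma items driven by per-subscale severity factors, and demographic
# covariates with sex-specific category probabilities. Ground truth is
# known by construction, so estimator recovery is testable.

#' Map a planted partial-correlation matrix to its latent correlations
#'
#' Given the target matrix of partial correlations (the ground-truth
#' network), builds the standardized precision matrix `I - P` and inverts
#' it, returning the Pearson correlation matrix of the latent Gaussian
#' variables whose partial correlations equal `P`.
#'
#' @param true_partial symmetric matrix of partial correlations with zero
#'   diagonal and entries in (-1, 1).
#' @return Positive-definite correlation matrix with unit diagonal.
#' @export
partial_to_latent_correlation <- function(true_partial) {
  P <- as.matrix(true_partial)
  stopifnot(isSymmetric(unname(P), tol = 1e-10))
  if (any(diag(P) != 0)) stop("true_partial must have a zero diagonal")
  if (any(abs(P) >= 1)) stop("partial correlations must lie in (-1, 1)")
  theta <- diag(nrow(P)) - P
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop(sprintf(
      "implied precision matrix is not positive definite (min eigenvalue %g)",
      min(ev)))
  }
  sigma <- solve(theta)
  R <- stats::cov2cor(sigma)
  dimnames(R) <- dimnames(P)
  R
}

#' Default planted symptom network
#'
#' A 16-node ground truth shaped like the empirical anxiety/depression
#' networks this package targets: a chain backbone along the instrument
#' ordering with heterogeneous weights, plus four strong edges --
#' GAD2--GAD3, PHQ1--PHQ2, PHQ3--PHQ4 within-instrument and GAD5--PHQ8
#' across instruments. Diagonally dominant by construction, hence a valid
#' (positive definite) Gaussian graphical model.
#'
#' @return 16 x 16 partial-correlation matrix with symptom node labels.
#' @export
default_planted_network <- function() {
  nodes <- symptom_nodes()
  p <- length(nodes)
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  chain_w <- seq(0.10, 0.20, length.out = p - 1)
  for (i in seq_len(p - 1)) {
    P[i, i + 1] <- P[i + 1, i] <- chain_w[i]
  }
  strong <- list(c("GAD2", "GAD3", 0.30), c("PHQ1", "PHQ2", 0.28),
                 c("PHQ3", "PHQ4", 0.26), c("GAD5", "PHQ8", 0.25))
  for (e in strong) {
    P[e[1], e[2]] <- P[e[2], e[1]] <- as.numeric(e[3])
  }
  P
}

#' Perturb one edge of a planted network
#'
#' Used to build sex-specific ground truths (e.g. one edge stronger in
#' one stratum) for power studies of the network comparison test.
#'
#' @param P partial-correlation matrix.
#' @param i,j node labels or indices of the edge.
#' @param delta amount added to the edge weight.
#' @return The perturbed matrix (positive definiteness re-checked).
#' @export
perturb_edge <- function(P, i, j, delta) {
  P[i, j] <- P[j, i] <- P[i, j] + delta
  invisible(partial_to_latent_correlation(P)) # validates PD
  P
}

# Printed item-level marginals of the target population: per-item mean
# and SD of the 0-3 GAD-7 and PHQ-9 responses among screened survivors.
# Used only to calibrate realistic discretization thresholds.
gadphq_item_stats <- data.frame(
  node = c(paste0("GAD", 1:7), paste0("PHQ", 1:9)),
  mean = c(0.86, 0.79, 0.89, 0.81, 0.53, 0.76, 0.54,
           0.87, 0.83, 0.89, 1.01, 0.85, 0.77, 0.88, 0.53, 0.29),
  sd = c(0.73, 0.79, 0.82, 0.82, 0.70, 0.77, 0.71,
         0.73, 0.69, 0.86, 0.80, 0.84, 0.79, 0.85, 0.72, 0.57))

# Category probabilities with geometric decay p_k proportional to
# exp(-k/tau), tau solved so the mean over categories 0..(K-1) matches.
geometric_categories <- function(target_mean, K = 4) {
  ks <- seq_len(K) - 1
  mean_at <- function(tau) {
    w <- exp(-ks / tau)
    sum(ks * w) / sum(w)
  }
  stopifnot(target_mean > 0, target_mean < mean(ks) * 2)
  tau <- uniroot(function(t) mean_at(t) - target_mean,
                 interval = c(1e-3, 100))$root
  w <- exp(-ks / tau)
  w / sum(w)
}

#' Default discretization thresholds
#'
#' Latent-normal cut-points per item. GAD/PHQ items (4 categories, 0-3)
#' are calibrated so that, for a standard-normal latent score, category
#' probabilities follow a geometric decay whose mean matches the printed
#' item means of the target population. CTQ items (5 categories, 1-5)
#' use heavily right-skewed base probabilities typical of trauma
#' questionnaires in community samples, with abuse items rarer than
#' neglect items.
#'
#' @return List with `gadphq` (length-16 list of 3 increasing cut-points)
#'   and `ctq` (length-28 list of 4 increasing cut-points).
#' @export
default_thresholds <- function() {
  gp <- lapply(gadphq_item_stats$mean, function(m) {
    qnorm(cumsum(geometric_categories(m, 4))[1:3])
  })
  names(gp) <- gadphq_item_stats$node
  abuse_base <- c(0.86, 0.08, 0.03, 0.02, 0.01)
  neglect_base <- c(0.62, 0.18, 0.10, 0.06, 0.04)
  ctq <- lapply(seq_len(28), function(i) {
    base <- if (i %in% unlist(ctq_subscale_items()[c("EN", "PN")]))
      neglect_base else abuse_base
    qnorm(cumsum(base)[1:4])
  })
  names(ctq) <- sprintf("CTQ%02d", 1:28)
  list(gadphq = gp, ctq = ctq)
}

# Standard CTQ-SF item membership of the five clinical subscales
# (remaining items 10, 16, 22 form the minimization/denial scale, not
# used for screening). Responses are taken as already keyed.
ctq_subscale_items <- function() {
  list(EA = c(3, 8, 14, 18, 25),
       PA = c(9, 11, 12, 15, 17),
       SA = c(20, 21, 23, 24, 27),
       EN = c(5, 7, 13, 19, 28),
       PN = c(1, 2, 4, 6, 26))
}

#' Default per-sex demographic category model
#'
#' Category probabilities for residence, ethnicity, family type, income
#' band and only-child status, separately for male and female
#' participants, matching the group imbalances of the target population
#' (e.g. only-child status strongly sex-dependent).
#'
#' @return Nested list: `$male` / `$female`, each a list of named
#'   probability vectors, plus `$p_male`.
#' @export
default_covariate_model <- function() {
  male <- list(
    residence = c(city = 850, town_county = 849) / 1699,
    ethnicity = c(han = 1548, other = 151) / 1699,
    family_type = c(nuclear = 1124, three_generation = 356, other = 219) / 1699,
    income_band = c(lt930 = 498, i930_2169 = 464,
                    i2170_3565 = 262, gt3565 = 475) / 1699,
    only_child = c(yes = 965, no = 734) / 1699)
  female <- list(
    residence = c(city = 938, town_county = 842) / 1780,
    ethnicity = c(han = 1571, other = 209) / 1780,
    family_type = c(nuclear = 1148, three_generation = 295, other = 337) / 1780,
    income_band = c(lt930 = 554, i930_2169 = 583,
                    i2170_3565 = 291, gt3565 = 352) / 1780,
    only_child = c(yes = 733, no = 1047) / 1780)
  list(male = male, female = female, p_male = 1699 / 3479)
}

#' Specification of a synthetic cohort
#'
#' @param n number of participants (>= 2).
#' @param true_partial ground-truth 16 x 16 partial-correlation matrix
#'   over the GAD/PHQ items.
#' @param thresholds list as returned by [default_thresholds()].
#' @param sex_effect optional second partial matrix used for the female
#'   stratum (males use `true_partial`); `NULL` means both sexes share
#'   the same network.
#' @param ctq_severity named latent mean shifts per CTQ subscale
#'   (EA, PA, SA, EN, PN); larger values raise the rate at which the
#'   subscale cut-off is exceeded. The SA default is calibrated so that
#'   roughly 3.6% of participants screen positive for childhood sexual
#'   abuse.
#' @param covariate_model per-sex category probabilities, see
#'   [default_covariate_model()].
#' @param female_shift latent mean shift added to all GAD/PHQ items for
#'   female participants (females score somewhat higher on both scales in
#'   the target population); affects marginals, not the latent
#'   correlation structure.
#' @param seed integer RNG seed; generation is deterministic given the
#'   spec.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n,
                           true_partial = default_planted_network(),
                           thresholds = default_thresholds(),
                           sex_effect = NULL,
                           ctq_severity = c(EA = -0.10, PA = -0.45,
                                            SA = -0.68, EN = -0.35,
                                            PN = -1.00),
                           covariate_model = default_covariate_model(),
                           female_shift = 0.15,
                           seed = 1L) {
  stopifnot(length(n) == 1, n >= 2)
  invisible(partial_to_latent_correlation(true_partial))
  if (!is.null(sex_effect)) invisible(partial_to_latent_correlation(sex_effect))
  for (th in c(thresholds$gadphq, thresholds$ctq)) {
    if (is.unsorted(th, strictly = TRUE)) {
      stop("thresholds must be strictly increasing per item")
    }
  }
  stopifnot(all(c("EA", "PA", "SA", "EN", "PN") %in% names(ctq_severity)))
  structure(list(n = as.integer(n), true_partial = true_partial,
                 thresholds = thresholds, sex_effect = sex_effect,
                 ctq_severity = ctq_severity,
                 covariate_model = covariate_model,
                 female_shift = female_shift, seed = as.integer(seed)),
            class = "synthetic_spec")
}

discretize <- function(z, cuts, first_level = 0L) {
  as.integer(findInterval(z, cuts)) + first_level
}

rcat <- function(n, probs) {
  names(probs)[1 + findInterval(runif(n), cumsum(probs)[-length(probs)])]
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws latent multivariate-normal symptom scores from the planted
#' network (per sex when a sex effect is specified), discretizes them by
#' the per-item thresholds into Likert categories, generates CTQ-SF items
#' from per-subscale severity factors, and attaches demographic
#' covariates. Deterministic under the spec's seed; no missing values.
#'
#' @param spec a [synthetic_spec()].
#' @return Data frame: `id`, demographics (`sex`, `residence`,
#'   `ethnicity`, `family_type`, `income_band`, `only_child`, `age`), and
#'   item columns `CTQ01..CTQ28` (1-5), `GAD01..GAD07`, `PHQ01..PHQ09`
#'   (0-3).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  cm <- spec$covariate_model
  sex <- ifelse(runif(n) < cm$p_male, "male", "female")
  is_f <- sex == "female"

  # latent symptom scores: one chol per stratum network
  R_m <- partial_to_latent_correlation(spec$true_partial)
  L_m <- chol(R_m)
  Z <- matrix(rnorm(n * 16), n, 16)
  if (!is.null(spec$sex_effect) && any(is_f)) {
    L_f <- chol(partial_to_latent_correlation(spec$sex_effect))
    Zl <- matrix(NA_real_, n, 16)
    Zl[!is_f, ] <- Z[!is_f, , drop = FALSE] %*% L_m
    Zl[is_f, ] <- Z[is_f, , drop = FALSE] %*% L_f
  } else {
    Zl <- Z %*% L_m
  }
  Zl[is_f, ] <- Zl[is_f, , drop = FALSE] + spec$female_shift
  colnames(Zl) <- symptom_nodes()

  gp <- matrix(NA_integer_, n, 16)
  for (j in seq_len(16)) {
    gp[, j] <- discretize(Zl[, j], spec$thresholds$gadphq[[j]], 0L)
  }
  colnames(gp) <- c(sprintf("GAD%02d", 1:7), sprintf("PHQ%02d", 1:9))

  # CTQ items: per-subscale severity + shared subscale factor
  sub <- ctq_subscale_items()
  load <- 0.6
  ctq <- matrix(NA_integer_, n, 28)
  factor_by_sub <- lapply(sub, function(items) rnorm(n))
  denial_factor <- rnorm(n)
  for (i in seq_len(28)) {
    s <- names(sub)[vapply(sub, function(it) i %in% it, logical(1))]
    if (length(s) == 1) {
      lat <- spec$ctq_severity[[s]] + load * factor_by_sub[[s]] +
        sqrt(1 - load^2) * rnorm(n)
    } else { # minimization/denial items
      lat <- -0.8 + load * denial_factor + sqrt(1 - load^2) * rnorm(n)
    }
    ctq[, i] <- discretize(lat, spec$thresholds$ctq[[i]], 1L)
  }
  colnames(ctq) <- sprintf("CTQ%02d", 1:28)

  covs <- data.frame(sex = sex, stringsAsFactors = FALSE)
  for (v in c("residence", "ethnicity", "family_type", "income_band",
              "only_child")) {
    x <- character(n)
    x[!is_f] <- rcat(sum(!is_f), cm$male[[v]])
    x[is_f] <- rcat(sum(is_f), cm$female[[v]])
    covs[[v]] <- x
  }
  covs$age <- round(pmax(16, rnorm(n, mean = 19.6, sd = 1.74)), 1)

  out <- cbind(data.frame(id = sprintf("P%06d", seq_len(n)),
                          stringsAsFactors = FALSE),
               covs, as.data.frame(ctq), as.data.frame(gp))
  rownames(out) <- NULL
  out
}

#' Inject missing values into item columns (off by default in the
#' pipeline; the target analysis reports no missing-data handling)
#'
#' @param cohort cohort data frame.
#' @param rate probability each item cell is set to `NA`.
#' @param seed RNG seed.
#' @return Cohort with `NA`s in item columns.
#' @export
inject_missing <- function(cohort, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  item_cols <- grep("^(CTQ|GAD|PHQ)\\d+$", names(cohort), value = TRUE)
  withr::with_seed(seed, {
    for (cl in item_cols) {
      miss <- runif(nrow(cohort)) < rate
      cohort[[cl]][miss] <- NA
    }
  })
  cohort
}

#' Write a cohort CSV and its ground-truth JSON
#'
#' @param cohort cohort data frame.
#' @param spec the generating [synthetic_spec()].
#' @param csv_path,truth_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, spec, csv_path, truth_path = NULL) {
  write.csv(cohort, csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- list(true_partial = spec$true_partial,
                  sex_effect = spec$sex_effect,
                  thresholds = spec$thresholds,
                  ctq_severity = as.list(spec$ctq_severity),
                  female_shift = spec$female_shift,
                  n = spec$n, seed = spec$seed)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv_path, truth = truth_path))
}
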