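#' Significance tier from a p value
#'
#' The conventional figure-legend coding: `ns` for p >= 0.05, `*` for
#' p < 0.05, `**` for p < 0.01, `***` for p < 0.001.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided unpaired t-test between two groups
#'
#' Classical pooled-variance (Student) two-sample t-test by default — the
#' usual meaning of an "unpaired t-test" in point-and-click statistics
#' software; Welch's unequal-variance form behind `welch = TRUE`. When both
#' groups have zero variance and equal means the statistic is undefined;
#' p = 1 is returned with a flag.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction instead of pooling.
#' @return One-row tibble: `statistic`, `df`, `p`, `mean_a`, `mean_b`,
#'   `method`, `tier`, `degenerate`.
#' @export
t_test_two_sided <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    return(tibble::tibble(statistic = 0, df = NA_real_, p = 1,
                          mean_a = mean(group_a), mean_b = mean(group_b),
                          method = "student_t_degenerate", tier = "ns",
                          degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch,
                       alternative = "two.sided")
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p = fit$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 method = if (welch) "welch_t" else "student_t",
                 tier = significance_tier(fit$p.value),
                 degenerate = FALSE)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits the one-way ANOVA and adjusts each condition-vs-reference contrast
#' for multiplicity with Dunnett's procedure: the joint null distribution
#' of the contrast t statistics is multivariate t with `N - k` degrees of
#' freedom and correlations `rho_ij = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n_ref))` (the product-correlation form,
#' exact for the many-to-one design, balanced or not). Two-sided adjusted
#' p values come from the rectangle probability of that distribution,
#' evaluated by deterministic two-dimensional quadrature over the shared
#' reference-group variate and the pooled scale (the classic factorization
#' of the product-correlated multivariate t); the method string in the
#' output records this. The quadrature is cross-checked against
#' `mvtnorm`/`multcomp` in the test suite.
#'
#' @param cohorts Tibble with `condition` and `rc` columns (any numeric
#'   response; named `rc` after the radius-of-confinement use case), plus
#'   optionally `day` and `cell_id`.
#' @param reference Name of the reference (e.g. wild-type) condition.
#' @return List: `anova` (one-row tibble, F and p) and `comparisons`
#'   (tibble with `contrast`, `n_ref`, `n`, `estimate`, `statistic`,
#'   `p_raw`, `p_adj`, `tier`, `method`).
#' @export
anova_dunnett <- function(cohorts, reference) {
  stopifnot(all(c("condition", "rc") %in% names(cohorts)))
  conds <- unique(cohorts$condition)
  if (!reference %in% conds)
    stop("reference condition not present: ", reference, call. = FALSE)
  if (length(conds) < 2)
    stop("need at least two conditions", call. = FALSE)
  grp <- split(cohorts$rc, cohorts$condition)
  if (any(vapply(grp, length, 1L) < 2))
    stop("every condition needs n >= 2", call. = FALSE)
  others <- setdiff(conds, reference)
  n <- vapply(grp, length, 1L)
  N <- sum(n)
  k <- length(conds)
  df <- N - k
  mse <- sum(vapply(grp, function(g) sum((g - mean(g))^2), 1.0)) / df
  fit <- stats::lm(rc ~ condition, data = cohorts)
  av <- stats::anova(fit)
  t_stat <- vapply(others, function(cn) {
    (mean(grp[[cn]]) - mean(grp[[reference]])) /
      sqrt(mse * (1 / n[[cn]] + 1 / n[[reference]]))
  }, 1.0)
  p_raw <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  lambda <- sqrt(n[others] / (n[others] + n[[reference]]))
  m <- length(others)
  method <- if (m == 1) "students_t" else "dunnett_mvt_quadrature"
  p_adj <- if (m == 1) p_raw else
    vapply(abs(t_stat), function(q)
      1 - dunnett_two_sided_prob(q, lambda, df), 1.0)
  p_adj <- pmin(1, pmax(p_adj, p_raw))  # guard against integration jitter
  list(
    anova = tibble::tibble(f = av$`F value`[1], df1 = av$Df[1],
                           df2 = av$Df[2], p = av$`Pr(>F)`[1]),
    comparisons = tibble::tibble(
      contrast = paste(others, "vs", reference),
      condition = others,
      n_ref = n[[reference]], n = unname(n[others]),
      estimate = vapply(others, function(cn)
        mean(grp[[cn]]) - mean(grp[[reference]]), 1.0),
      statistic = unname(t_stat),
      p_raw = unname(p_raw), p_adj = unname(p_adj),
      tier = significance_tier(unname(p_adj)),
      method = method))
}

# P(max_i |T_i| <= q) for the many-to-one multivariate t with product
# correlations rho_ij = lambda_i * lambda_j and df degrees of freedom.
# Write Z_i = lambda_i * W + sqrt(1 - lambda_i^2) * V_i with W, V_i iid
# standard normal and T_i = Z_i / S, S = sqrt(chisq_df / df); then
#   P = E_S E_W prod_i [ Phi((q S + lambda_i W)/c_i)
#                       - Phi((-q S + lambda_i W)/c_i) ],
# c_i = sqrt(1 - lambda_i^2), evaluated by nested deterministic
# quadrature (Gauss-like adaptive integrate over W inside S).
# c_i = sqrt(1 - lambda_i^2), evaluated on fixed Gauss-Legendre grids: 64
# nodes over W in [-8.5, 8.5] and 48 nodes over S centered on its mode
# (the chi/sqrt(df) density concentrates at 1 with spread ~ 1/sqrt(2 df)).
dunnett_two_sided_prob <- function(q, lambda, df) {
  ci <- sqrt(1 - lambda^2)
  gw <- gauss_legendre(64, -8.5, 8.5)
  half <- min(1, 9 / sqrt(2 * df))
  gs <- gauss_legendre(48, max(1e-8, 1 - half), 1 + half)
  log_norm <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
  dens_s <- exp(log_norm + (df - 1) * log(gs$x) - df * gs$x^2 / 2)
  inner <- vapply(gs$x, function(s) {
    val <- stats::dnorm(gw$x)
    for (i in seq_along(lambda)) {
      val <- val * (stats::pnorm((q * s + lambda[i] * gw$x) / ci[i]) -
                    stats::pnorm((-q * s + lambda[i] * gw$x) / ci[i]))
    }
    sum(gw$w * val)
  }, 1.0)
  min(1, max(0, sum(gs$w * inner * dens_s)))
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenvalue
# method; cached per order.
gauss_legendre <- local({
  cache <- list()
  function(n, a, b) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      k <- seq_len(n - 1)
      beta <- k / sqrt(4 * k^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1)] <- beta
      J[cbind(k + 1, k)] <- beta
      e <- eigen(J, symmetric = TRUE)
      cache[[key]] <<- list(x = e$values,
                            w = 2 * e$vectors[1, ]^2)
    }
    g <- cache[[key]]
    list(x = (b - a) / 2 * g$x + (a + b) / 2, w = (b - a) / 2 * g$w)
  }
})

#' Restrict contrasts to days shared with the reference
#'
#' Day-to-day variation in microscopy makes cross-day comparisons against
#' the reference unreliable, so each condition-vs-reference contrast is
#' restricted to acquisition days on which both the condition and the
#' reference contributed cells.
#'
#' @param cohorts Tibble with `condition`, `day`, and response columns.
#' @param reference Reference condition name.
#' @return Tibble of the retained rows, with a `contrast` column; the
#'   reference rows are duplicated per contrast (restricted to that
#'   contrast's shared days). Errors if some contrast has no shared days.
#' @export
day_paired_filter <- function(cohorts, reference) {
  stopifnot(all(c("condition", "day") %in% names(cohorts)))
  if (!reference %in% cohorts$condition)
    stop("reference condition not present", call. = FALSE)
  ref_days <- unique(cohorts$day[cohorts$condition == reference])
  out <- list()
  for (cn in setdiff(unique(cohorts$condition), reference)) {
    days <- intersect(unique(cohorts$day[cohorts$condition == cn]),
                      ref_days)
    if (!length(days))
      stop(sprintf("no overlapping days between %s and %s", cn, reference),
           call. = FALSE)
    sel <- cohorts[cohorts$condition %in% c(cn, reference) &
                   cohorts$day %in% days, ]
    sel$contrast <- paste(cn, "vs", reference)
    out[[cn]] <- sel
  }
  dplyr::bind_rows(out)
}

#' Clonogenic survival from colony counts
#'
#' Survival is the per-plate ratio of colonies on the selective plate to
#' colonies on the permissive plate, summarized as mean and SEM across
#' plates.
#'
#' @param selective_counts,permissive_counts Integer vectors, one entry per
#'   plate (equal length). All permissive counts must be positive.
#' @return One-row tibble: `survival`, `sem`, `n_plates`.
#' @export
viability <- function(selective_counts, permissive_counts) {
  stopifnot(length(selective_counts) == length(permissive_counts))
  if (any(permissive_counts <= 0))
    stop("permissive colony counts must be positive", call. = FALSE)
  ratios <- selective_counts / permissive_counts
  tibble::tibble(
    survival = mean(ratios),
    sem = if (length(ratios) > 1)
      stats::sd(ratios) / sqrt(length(ratios)) else 0,
    n_plates = length(ratios))
}

#' Normalize a survival fraction to a reference condition
#'
#' E.g. dividing the survival of a treated condition by the survival of
#' wild-type cells given the same treatment (the nocodazole normalization).
#'
#' @param result,reference One-row tibbles from [viability()].
#' @return `result` with an added `normalized` column
#'   (`survival / reference survival`).
#' @export
normalize_to <- function(result, reference) {
  if (reference$survival <= 0)
    stop("reference survival must be positive", call. = FALSE)
  result$normalized <- result$survival / reference$survival
  result
}
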