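# Default Bayes factors computed by numerical integration of the exact
# likelihoods; no closed-form approximations.

# Gauss hypergeometric 2F1(a, b; c; z) for 0 <= z < 1 and c > a + b, by the
# defining series. All terms are positive, so plain summation is stable.
gauss_2f1 <- function(a, b, c, z, tol = 1e-13, max_terms = 20000L) {
  if (z < 0 || z >= 1) stop("gauss_2f1 requires 0 <= z < 1", call. = FALSE)
  term <- 1
  total <- 1
  k <- 0
  while (k < max_terms) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    total <- total + term
    k <- k + 1
    if (term < tol * total) break
  }
  total
}

# Likelihood ratio p(r | rho, n) / p(r | 0, n) for the sample Pearson
# correlation, from the exact hypergeometric sampling density of r.
pearson_r_lik_ratio <- function(rho, r, n) {
  vapply(rho, function(p) {
    z <- (p * r + 1) / 2
    exp(((n - 1) / 2) * log1p(-p^2) - (n - 1.5) * log1p(-p * r)) *
      gauss_2f1(0.5, 0.5, n - 0.5, z) / gauss_2f1(0.5, 0.5, n - 0.5, 0.5)
  }, numeric(1))
}

# Stretched-beta prior density on (-1, 1) with width kappa (JASP default
# kappa = 1 is the uniform distribution).
stretched_beta_density <- function(rho, kappa = 1) {
  a <- 1 / kappa
  0.5 * stats::dbeta((rho + 1) / 2, a, a)
}

#' Default Bayes factor for a Pearson correlation
#'
#' Two-sided Bayes factor for the alternative that the population
#' correlation is nonzero, under a stretched-beta prior of width `kappa`
#' (the default `kappa = 1` is uniform on (-1, 1), the JASP default).
#' Computed by numerical integration of the exact sampling distribution of
#' the observed correlation over the prior.
#'
#' @param x,y Paired observations (n >= 3, finite, nonconstant). Use
#'   [bf10_pearson_stat()] to start from a reported `(r, n)` pair instead.
#' @param kappa Stretched-beta prior width.
#' @return A list of class `bf_result`: `r`, `n`, `bf10`, `capped` (`TRUE`
#'   when `|r| = 1` forced the divergent Bayes factor to a finite cap) and a
#'   prior description.
#' @export
bf10_pearson <- function(x, y, kappa = 1) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stop_if_not(length(x) >= 3, "need at least 3 complete pairs")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance: correlation undefined")
  bf10_pearson_stat(stats::cor(x, y), length(x), kappa = kappa)
}

#' @rdname bf10_pearson
#' @param r Observed Pearson correlation.
#' @param n Number of pairs.
#' @export
bf10_pearson_stat <- function(r, n, kappa = 1) {
  stop_if_not(is.finite(r) && abs(r) <= 1, "r must lie in [-1, 1]")
  stop_if_not(n >= 3, "need n >= 3")
  stop_if_not(kappa > 0, "kappa must be positive")
  capped <- FALSE
  if (abs(r) > 1 - 1e-12) {
    # |r| = 1 has zero sampling probability under any |rho| < 1: divergent BF
    bf <- 1e6
    capped <- TRUE
  } else {
    f <- function(p) pearson_r_lik_ratio(p, r, n) * stretched_beta_density(p, kappa)
    bf <- stats::integrate(f, -1, 1, rel.tol = 1e-9, abs.tol = 0,
                           stop.on.error = TRUE)$value
  }
  out <- list(statistic = r, r = r, n = n, bf10 = bf, capped = capped,
              prior = sprintf("stretched beta on (-1, 1), width %g", kappa),
              evidence = bf_evidence_label(bf))
  class(out) <- "bf_result"
  out
}

#' Default Bayes factor for a two-sample comparison
#'
#' Jeffreys-Zellner-Siow Bayes factor for a difference in means between two
#' independent groups: Cauchy prior with scale `rscale` (default
#' `sqrt(2)/2 = 0.707`, the JASP default) on the standardized effect size,
#' marginalized by numerical integration over the Cauchy's inverse-gamma
#' mixing variable.
#'
#' @param group_a,group_b Numeric observations, each of length >= 2. Use
#'   [bf10_ttest_stat()] to start from a reported `(t, n1, n2)` triple.
#' @param rscale Cauchy prior scale on the effect size.
#' @return A list of class `bf_result` with `t`, `n1`, `n2`, `bf10` and a
#'   prior description.
#' @export
bf10_ttest <- function(group_a, group_b, rscale = sqrt(2) / 2) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  stop_if_not(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs at least 2 observations")
  n1 <- length(group_a); n2 <- length(group_b)
  v_pool <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  stop_if_not(v_pool > 0, "zero pooled variance: t statistic undefined")
  t_stat <- (mean(group_a) - mean(group_b)) /
    sqrt(v_pool * (1 / n1 + 1 / n2))
  bf10_ttest_stat(t_stat, n1, n2, rscale = rscale)
}

#' @rdname bf10_ttest
#' @param t Observed two-sample t statistic.
#' @param n1,n2 Group sizes.
#' @export
bf10_ttest_stat <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  stop_if_not(is.finite(t), "t must be finite")
  stop_if_not(n1 >= 2 && n2 >= 2, "need n1, n2 >= 2")
  stop_if_not(rscale > 0, "rscale must be positive")
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # integrand of BF10 itself (null likelihood folded in, avoids overflow):
  # g is the inverse-gamma(1/2, rscale^2/2) mixing variable of the Cauchy
  f <- function(g) {
    log_num <- -0.5 * log1p(n_eff * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * nu))
    prior <- (rscale^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-rscale^2 / (2 * g))
    exp(log_num - log_den) * prior
  }
  bf <- stats::integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 0,
                         stop.on.error = TRUE)$value
  out <- list(statistic = t, t = t, n1 = n1, n2 = n2, bf10 = bf,
              prior = sprintf("JZS, Cauchy scale %.3f on effect size", rscale),
              evidence = bf_evidence_label(bf))
  class(out) <- "bf_result"
  out
}

#' Verbal evidence category of a Bayes factor
#'
#' The conventional bands: 1-3 anecdotal, 3-10 moderate, 10-30 strong,
#' 30-100 very strong, above 100 extreme evidence for the alternative;
#' values below 1 are reported as the corresponding evidence for the null.
#'
#' @param bf A Bayes factor (> 0).
#' @return A character label.
#' @export
bf_evidence_label <- function(bf) {
  stop_if_not(all(bf > 0), "Bayes factors must be positive")
  vapply(bf, function(b) {
    side <- if (b >= 1) "alternative" else "null"
    m <- max(b, 1 / b)
    band <- if (m <= 3) "anecdotal" else if (m <= 10) "moderate"
    else if (m <= 30) "strong" else if (m <= 100) "very strong" else "extreme"
    if (m == 1) "equivocal" else paste(band, "evidence for the", side)
  }, character(1))
}

#' @export
print.bf_result <- function(x, ...) {
  cat("<bf_result>\n")
  if (!is.null(x$r))
    cat(sprintf("  Pearson r = %.3f (n = %d)\n", x$r, x$n))
  else
    cat(sprintf("  t = %.3f (n1 = %d, n2 = %d)\n", x$t, x$n1, x$n2))
  cat(sprintf("  BF10 = %.4g%s — %s\n", x$bf10,
              if (isTRUE(x$capped)) " (capped)" else "", x$evidence))
  cat(sprintf("  prior: %s\n", x$prior))
  invisible(x)
}

bdi_item_names <- c(
  "Sadness", "Pessimism", "Feelings of failure", "Loss of pleasure",
  "Feelings of guilt", "Feelings of punishment", "Self-dislike",
  "Self-criticism", "Suicidal thoughts", "Crying", "Agitation",
  "Loss of interest", "Indecisiveness", "Worthlessness", "Loss of energy",
  "Changes in sleeping pattern", "Irritability", "Changes in appetite",
  "Concentration difficulty", "Fatigue", "Loss of sexual interest")

#' BDI-II item screen against pupil dilation
#'
#' Correlates the differential pupil dilation score with each of the 21
#' BDI-II items and with the anhedonia score (items 4 + 12 + 21), reporting
#' the default Bayes factor of [bf10_pearson()] for every row and flagging
#' moderate evidence (BF10 > 3). Items with no variance are flagged as not
#' computable instead of erroring.
#'
#' @param features Feature rows from [aggregate_features()].
#' @param clinical Derived clinical records from [derive_clinical()].
#' @param dilation_col Feature column to correlate (default the
#'   reward-minus-control differential score).
#' @param kappa Prior width passed to [bf10_pearson()].
#' @return A 22-row data frame: `item`, `label`, `n`, `r`, `bf10`,
#'   `moderate_evidence`, `computable`.
#' @export
run_item_screen <- function(features, clinical,
                            dilation_col = "diff_reward_minus_control",
                            kappa = 1) {
  stop_if_not(dilation_col %in% names(features),
              "unknown dilation column %s", dilation_col)
  if (!"anhedonia_score" %in% names(clinical))
    clinical <- derive_clinical(clinical)
  merged <- merge(features[, c("participant_id", dilation_col)], clinical,
                  by = "participant_id")
  cols <- c(sprintf("bdi_item_%02d", 1:21), "anhedonia_score")
  labels <- c(bdi_item_names, "BDI anhedonia score (items 4+12+21)")
  rows <- lapply(seq_along(cols), function(j) {
    x <- merged[[dilation_col]]
    y <- merged[[cols[j]]]
    ok <- stats::complete.cases(x, y)
    stop_if_not(sum(ok) >= 3, "fewer than 3 complete pairs for %s", cols[j])
    if (stats::sd(y[ok]) == 0) {
      return(data.frame(item = cols[j], label = labels[j], n = sum(ok),
                        r = NA_real_, bf10 = NA_real_,
                        moderate_evidence = FALSE, computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    bf <- bf10_pearson(x[ok], y[ok], kappa = kappa)
    data.frame(item = cols[j], label = labels[j], n = bf$n, r = bf$r,
               bf10 = bf$bf10, moderate_evidence = bf$bf10 > 3,
               computable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
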