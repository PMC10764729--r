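#' Uniform prior bounds for the latent correlation model
#'
#' All five parameters get independent uniform priors. Defaults are the
#' study's bounds: pupil-dilation mean (-2, 2) and SD (0, 2), symptom mean
#' (0, 20) and SD (0, 10), and the correlation coefficient (-1, 1).
#'
#' @param mu_x,sigma_x,mu_y,sigma_y,rho Length-2 numeric bounds.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mu_x = c(-2, 2), sigma_x = c(0, 2),
                       mu_y = c(0, 20), sigma_y = c(0, 10),
                       rho = c(-1, 1)) {
  p <- list(mu_x = mu_x, sigma_x = sigma_x, mu_y = mu_y, sigma_y = sigma_y,
            rho = rho)
  for (nm in names(p)) {
    stop_if_not(length(p[[nm]]) == 2 && p[[nm]][1] < p[[nm]][2],
                "prior bound %s must satisfy lower < upper", nm)
  }
  stop_if_not(rho[1] >= -1 && rho[2] <= 1, "rho bounds must lie within [-1, 1]")
  class(p) <- "prior_spec"
  p
}

#' Measurement-error SD from a reliability coefficient
#'
#' The uncertainty attached to each observed score is
#' `sd_observed * sqrt(1 - reliability)`: the part of the observed
#' cross-participant SD that test-retest unreliability attributes to noise.
#'
#' @param sd_observed Observed (cross-participant) sample SD, >= 0.
#' @param reliability Test-retest (or split-half) reliability in `[0, 1]`.
#' @return The measurement SD, in the units of `sd_observed`.
#' @export
measurement_se <- function(sd_observed, reliability) {
  stop_if_not(all(sd_observed >= 0), "sd_observed must be >= 0")
  stop_if_not(all(reliability >= 0 & reliability <= 1),
              "reliability must lie in [0, 1]")
  sd_observed * sqrt(1 - reliability)
}

# Log posterior of (mu_x, mu_y, sigma_x, sigma_y, rho) with the latent pairs
# integrated out: marginally (x_i, y_i) is bivariate normal with covariance
# Sigma + diag(se_x_i^2, se_y_i^2). Uniform priors contribute only support.
make_latent_logpost <- function(x, y, se_x, se_y, priors) {
  n <- length(x)
  sex2 <- se_x^2
  sey2 <- se_y^2
  lb <- c(priors$mu_x[1], priors$mu_y[1], priors$sigma_x[1], priors$sigma_y[1],
          priors$rho[1])
  ub <- c(priors$mu_x[2], priors$mu_y[2], priors$sigma_x[2], priors$sigma_y[2],
          priors$rho[2])
  const <- -n * log(2 * pi)
  function(th) {
    sx <- th[3]; sy <- th[4]; rho <- th[5]
    vx <- sx^2 + sex2
    vy <- sy^2 + sey2
    cv <- rho * sx * sy
    dtr <- vx * vy - cv^2
    dx <- x - th[1]
    dy <- y - th[2]
    const - 0.5 * sum(log(dtr) + (vy * dx^2 - 2 * cv * dx * dy + vx * dy^2) / dtr)
  }
}

# Split-chain potential scale reduction factor (R-hat) for one parameter.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(d) {
    m <- length(d) %/% 2
    list(d[seq_len(m)], d[(m + 1):(2 * m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains.
ess_ips <- function(draws_by_chain) {
  sum(vapply(draws_by_chain, function(d) {
    n <- length(d)
    v <- stats::var(d)
    if (v <= 0) return(n)
    lag_max <- min(n - 2L, 1000L)
    ac <- stats::acf(d, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
    s <- 0
    k <- 1
    while (k + 1 <= length(ac)) {
      pair <- ac[k] + ac[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    n / (1 + 2 * s)
  }, numeric(1)))
}

# Adaptive Metropolis chain: component-wise warm-up, then a 50/50 mixture of
# a joint random walk (covariance adapted from the warm-up history) and an
# independence proposal from a multivariate t fitted to the same history.
# On the transformed (unbounded) scale the posterior is near-Gaussian, so
# the independence component delivers close-to-iid draws once warmed up;
# the random-walk component guarantees irreducibility regardless.
run_chain <- function(lp, init, warmup, iter, scales0, t_df = 4,
                      laplace = NULL) {
  p <- length(init)
  th <- init
  lp_cur <- lp(th)
  stopifnot(is.finite(lp_cur))
  hist_mat <- matrix(NA_real_, warmup, p)
  scales <- scales0
  phase1 <- min(250L, warmup %/% 2L)

  for (t in seq_len(phase1)) {
    for (j in seq_len(p)) {
      prop <- th
      prop[j] <- th[j] + stats::rnorm(1, 0, scales[j])
      lp_prop <- lp(prop)
      acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
      if (acc) { th <- prop; lp_cur <- lp_prop }
      scales[j] <- scales[j] * exp(((if (acc) 1 else 0) - 0.44) / (1 + t)^0.6)
    }
    hist_mat[t, ] <- th
  }

  lambda <- 1
  chol_rw <- diag(scales)          # random-walk proposal (scaled 2.38^2/p)
  # Independence proposal: the Laplace approximation when available (slightly
  # overdispersed multivariate t), otherwise the adapted history covariance.
  use_laplace <- !is.null(laplace)
  chol_ind <- if (use_laplace) 1.2 * laplace$chol else diag(scales)
  mu_ind <- if (use_laplace) laplace$mode else th
  refresh <- function(upto) {
    use <- hist_mat[max(1, upto %/% 2):upto, , drop = FALSE]
    cc <- stats::cov(use)
    cc <- cc + diag(1e-10 + 1e-6 * diag(cc), p)
    ok <- tryCatch(chol(cc), error = function(e) NULL)
    if (!is.null(ok)) {
      chol_rw <<- sqrt(2.38^2 / p) * ok
      if (!use_laplace) {
        chol_ind <<- 1.2 * ok
        mu_ind <<- colMeans(use)
      }
    }
  }
  log_q_ind <- function(u) {
    z <- backsolve(chol_ind, u - mu_ind, transpose = TRUE)
    -sum(log(diag(chol_ind))) -
      (t_df + p) / 2 * log1p(sum(z^2) / t_df)
  }
  draw_ind <- function() {
    z <- stats::rnorm(p)
    mu_ind + drop(z %*% chol_ind) * sqrt(t_df / stats::rchisq(1, t_df))
  }

  if (phase1 >= 50) refresh(phase1)
  for (t in (phase1 + 1):warmup) {
    prop <- th + lambda * drop(stats::rnorm(p) %*% chol_rw)
    lp_prop <- lp(prop)
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
    if (acc) { th <- prop; lp_cur <- lp_prop }
    lambda <- lambda * exp(((if (acc) 1 else 0) - 0.234) / (1 + t - phase1)^0.6)
    hist_mat[t, ] <- th
    if (t %% 100 == 0 || t == warmup) refresh(t)
  }

  draws <- matrix(NA_real_, iter, p)
  n_acc <- 0L
  for (t in seq_len(iter)) {
    if (stats::runif(1) < 0.5) {
      prop <- th + lambda * drop(stats::rnorm(p) %*% chol_rw)
      lp_prop <- lp(prop)
      log_ratio <- lp_prop - lp_cur
    } else {
      prop <- draw_ind()
      lp_prop <- lp(prop)
      log_ratio <- lp_prop - lp_cur + log_q_ind(th) - log_q_ind(prop)
    }
    if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
      lp_cur <- lp_prop
      th <- prop
      n_acc <- n_acc + 1L
    }
    draws[t, ] <- th
  }
  list(draws = draws, acc_rate = n_acc / iter)
}

#' Bayesian latent correlation with measurement uncertainty
#'
#' Fits the bivariate Gaussian latent-variable model: each participant's true
#' scores `(xi_i, eta_i)` follow a bivariate normal with means
#' `(mu_x, mu_y)`, SDs `(sigma_x, sigma_y)` and correlation `rho`; the
#' observed scores are `x_i ~ N(xi_i, se_x_i^2)` and `y_i ~ N(eta_i,
#' se_y_i^2)` with known measurement SDs (typically
#' [measurement_se()] of each variable's observed SD). All five parameters
#' carry the uniform priors of [prior_spec()]. The latent pairs are
#' integrated out analytically and the five-parameter posterior is sampled
#' with an adaptive random-walk Metropolis sampler (component-wise warm-up,
#' then joint proposals from the adapted covariance). With all measurement
#' SDs zero the model reduces to the standard Bayesian Pearson correlation
#' under the same priors.
#'
#' The directional Bayes factor for a negative correlation is computed from
#' the posterior draws by [bf_directional()].
#'
#' @param x,y Observed score vectors (equal length >= 3).
#' @param se_x,se_y Measurement SDs, scalar or per observation; `0` means no
#'   measurement error.
#' @param priors A [prior_spec()]. Location bounds are widened with a
#'   warning if data fall outside them.
#' @param chains,iter,warmup MCMC layout: kept draws per chain and warm-up
#'   iterations.
#' @param seed Integer seed (chain c uses `seed + c - 1`).
#' @param rhat_max Convergence bound: the fit errors if any parameter's
#'   split-chain R-hat exceeds it.
#' @return An object of class `latent_corr`: posterior draws, summaries,
#'   R-hat and effective-sample-size diagnostics, and the directional Bayes
#'   factor `bf_minus` with its lower-bound flag.
#' @export
fit_latent_correlation <- function(x, y, se_x = 0, se_y = 0,
                                   priors = prior_spec(),
                                   chains = 4, iter = 5000, warmup = 1000,
                                   seed = 1, rhat_max = 1.01) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(length(x) >= 3, "need at least 3 observations")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)), "x and y must be finite")
  se_x <- rep_len(se_x, length(x))
  se_y <- rep_len(se_y, length(y))
  stop_if_not(all(se_x >= 0) && all(se_y >= 0), "measurement SDs must be >= 0")
  stopifnot(inherits(priors, "prior_spec"))

  widen <- function(b, v, nm) {
    if (min(v) < b[1] || max(v) > b[2]) {
      warning(sprintf("data outside %s prior support; widening bounds", nm),
              call. = FALSE)
      c(min(b[1], min(v) - 3 * stats::sd(v)), max(b[2], max(v) + 3 * stats::sd(v)))
    } else b
  }
  priors$mu_x <- widen(priors$mu_x, x, "mu_x")
  priors$mu_y <- widen(priors$mu_y, y, "mu_y")

  lp_nat <- make_latent_logpost(x, y, se_x, se_y, priors)
  pn <- c("mu_x", "mu_y", "sigma_x", "sigma_y", "rho")
  lb <- c(priors$mu_x[1], priors$mu_y[1], priors$sigma_x[1], priors$sigma_y[1],
          priors$rho[1])
  ub <- c(priors$mu_x[2], priors$mu_y[2], priors$sigma_x[2], priors$sigma_y[2],
          priors$rho[2])
  # Sample on the logit scale of each uniform support: no hard boundaries,
  # near-Gaussian geometry for the adaptive covariance. The Jacobian keeps
  # the implied prior on the natural scale uniform.
  to_nat <- function(u) lb + (ub - lb) * stats::plogis(u)
  lp_u <- function(u) {
    lj <- sum(stats::plogis(u, log.p = TRUE) + stats::plogis(-u, log.p = TRUE))
    lp_nat(to_nat(u)) + lj
  }
  clamp <- function(v, b, eps) min(max(v, b[1] + eps), b[2] - eps)

  # Deterministic Laplace approximation of the transformed posterior, used as
  # the independence-proposal component of every chain.
  th0 <- c(clamp(mean(x), priors$mu_x, 1e-3),
           clamp(mean(y), priors$mu_y, 1e-3),
           clamp(stats::sd(x), priors$sigma_x, 1e-3),
           clamp(stats::sd(y), priors$sigma_y, 1e-3),
           clamp(stats::cor(x, y), priors$rho, 1e-2))
  laplace <- tryCatch({
    opt <- stats::optim(stats::qlogis((th0 - lb) / (ub - lb)), lp_u,
                        method = "BFGS", hessian = TRUE,
                        control = list(fnscale = -1, maxit = 200))
    cv <- solve(-opt$hessian)
    cv <- (cv + t(cv)) / 2
    list(mode = opt$par, chol = chol(cv + diag(1e-8, 5)))
  }, error = function(e) NULL)

  chain_draws <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    res <- with_seed(seed + ch - 1, {
      init <- c(clamp(mean(x), priors$mu_x, 1e-3),
                clamp(mean(y), priors$mu_y, 1e-3),
                clamp(stats::sd(x) * stats::runif(1, 0.7, 1.3), priors$sigma_x, 1e-3),
                clamp(stats::sd(y) * stats::runif(1, 0.7, 1.3), priors$sigma_y, 1e-3),
                clamp(stats::cor(x, y) + stats::rnorm(1, 0, 0.1),
                      priors$rho, 1e-2))
      u0 <- stats::qlogis((init - lb) / (ub - lb))
      run_chain(lp_u, u0, warmup, iter, rep(0.3, 5), laplace = laplace)
    })
    chain_draws[[ch]] <- t(apply(res$draws, 1, to_nat))
    acc[ch] <- res$acc_rate
  }

  rhat <- vapply(seq_along(pn), function(j)
    split_rhat(lapply(chain_draws, function(d) d[, j])), numeric(1))
  names(rhat) <- pn
  ess <- vapply(seq_along(pn), function(j)
    ess_ips(lapply(chain_draws, function(d) d[, j])), numeric(1))
  names(ess) <- pn
  if (max(rhat) > rhat_max) {
    stop(sprintf(
      "MCMC did not converge: max split R-hat %.4f > %.3f (per parameter: %s; ESS: %s)",
      max(rhat), rhat_max,
      paste(sprintf("%s=%.3f", pn, rhat), collapse = ", "),
      paste(sprintf("%s=%.0f", pn, ess), collapse = ", ")), call. = FALSE)
  }

  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- pn
  summ <- t(apply(draws, 2, function(v)
    c(mean = mean(v), median = stats::median(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))))
  bf <- bf_directional(draws[, "rho"], direction = "negative")

  out <- list(draws = draws, summary = summ, rhat = rhat, ess = ess,
              bf_minus = bf$bf, bf_is_lower_bound = bf$is_lower_bound,
              chains = chains, iter = iter, warmup = warmup, seed = seed,
              acc_rate = acc, n = length(x), priors = priors,
              se_x = se_x, se_y = se_y)
  class(out) <- "latent_corr"
  out
}

#' @export
print.latent_corr <- function(x, ...) {
  s <- x$summary["rho", ]
  cat("<latent_corr> bivariate Gaussian correlation with measurement error\n")
  cat(sprintf("  n = %d, %d chains x %d draws (warmup %d)\n",
              x$n, x$chains, x$iter, x$warmup))
  cat(sprintf("  rho: mean %.3f, median %.3f, 95%% CI [%.3f, %.3f]\n",
              s["mean"], s["median"], s["q2.5"], s["q97.5"]))
  cat(sprintf("  BF(-) = %.4g%s\n", x$bf_minus,
              if (x$bf_is_lower_bound) " (lower bound: no draws above zero)" else ""))
  cat(sprintf("  max R-hat %.4f, ESS(rho) %.0f\n", max(x$rhat), x$ess["rho"]))
  invisible(x)
}

#' Directional Bayes factor from posterior draws
#'
#' Under a prior symmetric around zero, the Bayes factor for a one-sided
#' hypothesis about the correlation is the ratio of posterior draws on the
#' favoured side of zero to draws on the other side. When no draw falls on
#' the disfavoured side the ratio is reported as the total draw count and
#' flagged as a lower bound.
#'
#' @param samples Posterior draws of the correlation.
#' @param direction `"negative"` (the default, for a negative correlation)
#'   or `"positive"`.
#' @return A list with `bf`, `is_lower_bound` and the draw counts.
#' @export
bf_directional <- function(samples, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  stop_if_not(length(samples) >= 1, "empty posterior sample set")
  if (length(samples) < 1000)
    warning("fewer than 1000 posterior draws; the counting BF will be coarse",
            call. = FALSE)
  n_neg <- sum(samples < 0)
  n_pos <- sum(samples > 0)
  num <- if (direction == "negative") n_neg else n_pos
  den <- if (direction == "negative") n_pos else n_neg
  if (den == 0) {
    list(bf = length(samples), is_lower_bound = TRUE,
         n_favoured = num, n_other = den)
  } else {
    list(bf = num / den, is_lower_bound = FALSE,
         n_favoured = num, n_other = den)
  }
}
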