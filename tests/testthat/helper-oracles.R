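# Independent oracles used to validate the package's numerics. These share
# only the mathematical definitions with the implementation, never its code
# paths: the grid oracle integrates the marginalized posterior by brute
# force, the Bayes-factor oracles use composite-Simpson quadrature with a
# log-gamma-based hypergeometric series.

# ---- brute-force grid posterior of the latent correlation model ----------
oracle_grid_posterior_rho <- function(x, y, se_x, se_y,
                                      mu_x_b = c(-2, 2), sigma_x_b = c(0, 2),
                                      mu_y_b = c(0, 20), sigma_y_b = c(0, 10),
                                      rho_b = c(-1, 1),
                                      n_coarse = c(15, 15, 15, 15, 41),
                                      n_fine = c(25, 25, 25, 25, 121)) {
  n <- length(x)
  se_x <- rep_len(se_x, n)
  se_y <- rep_len(se_y, n)
  loglik_grid <- function(mx, my, sx, sy, rho) {
    ll <- numeric(length(mx))
    for (i in seq_len(n)) {
      vx <- sx^2 + se_x[i]^2
      vy <- sy^2 + se_y[i]^2
      cv <- rho * sx * sy
      dtr <- vx * vy - cv^2
      dx <- x[i] - mx
      dy <- y[i] - my
      ll <- ll - 0.5 * (log(dtr) +
                          (vy * dx^2 - 2 * cv * dx * dy + vx * dy^2) / dtr)
    }
    ll - n * log(2 * pi)
  }
  mids <- function(b, k) b[1] + (seq_len(k) - 0.5) * diff(b) / k
  run_pass <- function(bx, bsx, bby, bsy, brho, kk) {
    gx <- mids(bx, kk[1]); gy <- mids(bby, kk[2])
    gsx <- mids(bsx, kk[3]); gsy <- mids(bsy, kk[4]); grho <- mids(brho, kk[5])
    g4 <- expand.grid(mx = gx, my = gy, sx = gsx, sy = gsy)
    ll_list <- vector("list", length(grho))
    best <- -Inf
    for (r in seq_along(grho)) {
      ll <- loglik_grid(g4$mx, g4$my, g4$sx, g4$sy, grho[r])
      ll_list[[r]] <- ll
      best <- max(best, max(ll))
    }
    w_rho <- numeric(length(grho))
    keep <- vector("list", length(grho))
    for (r in seq_along(grho)) {
      w <- exp(ll_list[[r]] - best)
      w_rho[r] <- sum(w)
      keep[[r]] <- w
    }
    list(grho = grho, w_rho = w_rho, g4 = g4, keep = keep,
         axes = list(gx = gx, gy = gy, gsx = gsx, gsy = gsy))
  }
  coarse <- run_pass(mu_x_b, sigma_x_b, mu_y_b, sigma_y_b, rho_b, n_coarse)
  shrink <- function(vals, w_marg, b) {
    sel <- which(w_marg > max(w_marg) * 1e-8)
    lo <- vals[max(1, min(sel) - 1)]
    hi <- vals[min(length(vals), max(sel) + 1)]
    pad <- (hi - lo) * 0.25 + diff(b) / 100
    c(max(b[1], lo - pad), min(b[2], hi + pad))
  }
  marg <- function(axis_vals, col) {
    vapply(axis_vals, function(v) {
      s <- 0
      for (r in seq_along(coarse$grho))
        s <- s + sum(coarse$keep[[r]][coarse$g4[[col]] == v])
      s
    }, numeric(1))
  }
  bx <- shrink(coarse$axes$gx, marg(coarse$axes$gx, "mx"), mu_x_b)
  bby <- shrink(coarse$axes$gy, marg(coarse$axes$gy, "my"), mu_y_b)
  bsx <- shrink(coarse$axes$gsx, marg(coarse$axes$gsx, "sx"), sigma_x_b)
  bsy <- shrink(coarse$axes$gsy, marg(coarse$axes$gsy, "sy"), sigma_y_b)
  brho <- shrink(coarse$grho, coarse$w_rho, rho_b)
  fine <- run_pass(bx, bsx, bby, bsy, brho, n_fine)
  p_rho <- fine$w_rho / sum(fine$w_rho)
  cdf <- cumsum(p_rho) - p_rho / 2
  distinct <- c(TRUE, diff(cdf) > 1e-15)   # drop zero-mass bins for approx()
  qfun <- function(q) stats::approx(cdf[distinct], fine$grho[distinct],
                                    xout = q, rule = 2)$y
  list(rho = fine$grho, p = p_rho,
       mean = sum(fine$grho * p_rho),
       q2.5 = qfun(0.025), q50 = qfun(0.5), q97.5 = qfun(0.975),
       sample = function(m, seed) {
         set.seed(seed)
         qfun(stats::runif(m))
       })
}

# ---- hypergeometric series via log-gamma terms ---------------------------
oracle_2f1 <- function(a, b, c, z, terms = 5000L) {
  k <- 0:(terms - 1L)
  lt <- lgamma(a + k) - lgamma(a) + lgamma(b + k) - lgamma(b) -
    (lgamma(c + k) - lgamma(c)) - lgamma(k + 1) + k * log(z)
  sum(exp(lt))
}

# ---- composite Simpson on a uniform grid ---------------------------------
oracle_simpson <- function(f, lo, hi, n_points = 4001L) {
  stopifnot(n_points %% 2L == 1L)
  xs <- seq(lo, hi, length.out = n_points)
  ys <- vapply(xs, f, numeric(1))
  h <- (hi - lo) / (n_points - 1L)
  w <- rep(c(2, 4), length.out = n_points)
  w[1] <- 1
  w[n_points] <- 1
  sum(w * ys) * h / 3
}

# Pearson-correlation BF10 under the stretched-beta (width kappa) prior.
oracle_bf_pearson <- function(r, n, kappa = 1, n_points = 4001L) {
  lik_ratio <- function(rho) {
    z <- (rho * r + 1) / 2
    exp(((n - 1) / 2) * log(1 - rho^2) - (n - 1.5) * log(1 - rho * r)) *
      oracle_2f1(0.5, 0.5, n - 0.5, z) / oracle_2f1(0.5, 0.5, n - 0.5, 0.5)
  }
  a <- 1 / kappa
  f <- function(rho) lik_ratio(rho) * 0.5 * stats::dbeta((rho + 1) / 2, a, a)
  eps <- 1e-9  # integrand is 0 at the endpoints for n > 3
  oracle_simpson(f, -1 + eps, 1 - eps, n_points)
}

# JZS two-sample BF10; the inverse-gamma mixing variable is integrated over
# (0, Inf) through the substitution g = tan(theta)^2.
oracle_bf_ttest <- function(t, n1, n2, rscale = sqrt(2) / 2,
                            n_points = 4001L) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f_theta <- function(theta) {
    g <- tan(theta)^2
    if (!is.finite(g) || g <= 0) return(0)
    log_num <- -0.5 * log1p(n_eff * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * nu))
    prior <- sqrt(rscale^2 / 2) / gamma(0.5) * g^(-1.5) * exp(-rscale^2 / (2 * g))
    jac <- 2 * tan(theta) / cos(theta)^2
    exp(log_num - log_den) * prior * jac
  }
  oracle_simpson(f_theta, 1e-8, pi / 2 - 1e-8, n_points)
}

# Two-sample Kolmogorov-Smirnov distance.
ks_distance <- function(a, b) {
  as.numeric(suppressWarnings(stats::ks.test(a, b)$statistic))
}

# Straight line through two anchor points, evaluated at arbitrary times.
oracle_line <- function(t0, y0, t1, y1, t) y0 + (y1 - y0) * (t - t0) / (t1 - t0)

# Brute-force half-open window lookup (linear scan, unlike the package's
# arithmetic indexing).
window_idx_test <- function(time_s, from, to) {
  which(time_s >= from - 1e-9 & time_s < to - 1e-9)
}
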