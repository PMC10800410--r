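# Kernel-level oracle checks, diagnostics, and reduced-size estimator runs.

test_that("the intercept kernel reproduces the conjugate normal closed form", {
  # one person, no covariates, known residual variance: the Gibbs draw of
  # alpha is N(m_post, v_post) with v_post = 1/(T/s2e + 1/v0) and
  # m_post = v_post * (sum(y)/s2e + m0/v0)
  set.seed(101)
  t_len <- 40L
  s2e <- 0.5
  m0 <- 1
  v0 <- 4
  y <- matrix(rnorm(t_len, 2, sqrt(s2e)), 1, t_len)
  s <- p <- matrix(0, 1, t_len)       # no covariate variation
  w <- diag(c(1 / v0, 1e8, 1e8))      # beta/eta pinned at 0 by the prior
  mu_a <- matrix(c(m0, 0, 0), 1, 3)
  n_rep <- 4000
  draws <- vapply(seq_len(n_rep), function(i) {
    emadsem:::draw_block_ase(y, s, p, ypre = 0, phi = 0, ms = 0, mc = 0,
                             s2e = s2e, w = w, mu_a = mu_a)$draw[1, 1]
  }, numeric(1))
  v_post <- 1 / (t_len / s2e + 1 / v0)
  m_post <- v_post * (sum(y) / s2e + m0 / v0)
  mcse_mean <- sqrt(v_post / n_rep)
  mcse_sd <- sqrt(v_post) / sqrt(2 * n_rep)
  expect_lt(abs(mean(draws) - m_post), 3 * mcse_mean)
  expect_lt(abs(sd(draws) - sqrt(v_post)), 3 * mcse_sd)
})

test_that("with a flat prior the person block centers on per-person least squares", {
  set.seed(102)
  n <- 4L; t_len <- 120L
  phi <- rep(0.3, n)
  s <- matrix(rnorm(n * t_len), n, t_len)
  p <- matrix(rnorm(n * t_len), n, t_len)
  truth <- cbind(a = c(1, -1, 0.5, 2), b = c(0.4, 0, -0.3, 0.2),
                 e = c(0.1, 0.3, 0, -0.2))
  ypre <- rep(0, n)
  y <- matrix(0, n, t_len)
  yprev <- ypre
  for (t in seq_len(t_len)) {
    a_t <- if (t == 1) 1 else 1 - phi
    y[, t] <- truth[, "a"] * a_t + phi * yprev + truth[, "b"] * s[, t] +
      truth[, "e"] * p[, t] + rnorm(n, 0, 0.3)
    yprev <- y[, t]
  }
  w <- diag(1e-8, 3)  # essentially flat prior
  mu_a <- matrix(0, n, 3)
  got <- emadsem:::draw_block_ase(y, s, p, ypre, phi, ms = rep(0, n),
                                  mc = rep(0, n), s2e = 0.09, w = w,
                                  mu_a = mu_a, mean_only = TRUE)$mean
  # independent oracle: per-person OLS on the whitened regression
  for (i in seq_len(n)) {
    amat <- c(1, rep(1 - phi[i], t_len - 1))
    r <- y[i, ] - phi[i] * c(ypre[i], y[i, -t_len])
    ols <- coef(lm(r ~ 0 + amat + s[i, ] + p[i, ]))
    expect_equal(unname(got[i, ]), unname(ols), tolerance = 1e-6)
  }
})

test_that("a phantom cell with no temporal coupling is imputed at the person mean", {
  # phi = 0, beta = eta = 0: the AR conditional for a missing deviation is
  # N(0, s2e), i.e. the raw imputation centers on alpha
  set.seed(103)
  t_len <- 5L
  d <- matrix(c(0.5, 0.2, NA, -0.1, 0.4), 1, t_len)
  miss <- which(is.na(d))
  parity <- ((miss - 1L)) %% 2L  # single row: index = column
  draws <- replicate(3000, {
    di <- d; di[miss] <- 0
    emadsem:::impute_outcome(di, ypre = 0, csp = matrix(0, 1, t_len),
                             phi = 0, s2e = 0.25, miss, parity)[1, miss]
  })
  expect_lt(abs(mean(draws)), 3 * sqrt(0.25 / 3000))
  expect_equal(sd(draws), 0.5, tolerance = 0.05)
})

test_that("imputation respects AR neighbors and never touches observed cells", {
  set.seed(104)
  t_len <- 9L
  phi <- 0.6
  dobs <- matrix(rnorm(t_len), 1, t_len)
  miss <- 5L
  parity <- (miss - 1L) %% 2L
  once <- emadsem:::impute_outcome(dobs, 0, matrix(0, 1, t_len), phi, 0.2,
                                   miss, parity)
  expect_identical(once[1, -miss], dobs[1, -miss])
  draws <- replicate(4000, {
    emadsem:::impute_outcome(dobs, 0, matrix(0, 1, t_len), phi, 0.2,
                             miss, parity)[1, miss]
  })
  m_expect <- phi * (dobs[1, 4] + dobs[1, 6]) / (1 + phi^2)
  v_expect <- 0.2 / (1 + phi^2)
  expect_lt(abs(mean(draws) - m_expect), 3 * sqrt(v_expect / 4000))
})

test_that("the coefficient draw solves the generalized least squares system", {
  set.seed(105)
  n <- 9L
  theta <- matrix(rnorm(n * 6), n, 6)
  res <- rnorm(n); res <- res - mean(res)
  lon <- rnorm(n); lon <- lon - mean(lon)
  tau <- crossprod(matrix(rnorm(36), 6, 6)) / 6 + diag(0.1, 6)
  tau_inv <- solve(tau)
  priors <- dsem_priors()
  got <- emadsem:::draw_gamma(theta, res, lon, tau_inv, priors)

  # independent oracle: assemble the dense 6x16 design per person
  groups <- emadsem:::gamma_groups()
  xt_x <- matrix(0, 16, 16)
  xt_y <- numeric(16)
  for (i in seq_len(n)) {
    x <- matrix(0, 6, 16)
    x[1, groups[[1]]] <- c(1, res[i], lon[i], theta[i, 5], theta[i, 6])
    x[2, groups[[2]]] <- c(1, res[i], lon[i])
    x[3, groups[[3]]] <- c(1, res[i], lon[i])
    x[4, groups[[4]]] <- c(1, res[i], lon[i])
    x[5, groups[[5]]] <- 1
    x[6, groups[[6]]] <- 1
    xt_x <- xt_x + t(x) %*% tau_inv %*% x
    xt_y <- xt_y + t(x) %*% tau_inv %*% theta[i, ]
  }
  gls <- solve(xt_x + diag(1 / priors$gamma_var, 16), xt_y)
  expect_equal(got$mean, as.vector(gls), tolerance = 1e-8)

  # exchangeability: permuting persons leaves the conditional mean unchanged
  perm <- sample(n)
  got_p <- emadsem:::draw_gamma(theta[perm, ], res[perm], lon[perm],
                                tau_inv, priors)
  expect_equal(got_p$mean, got$mean, tolerance = 1e-10)
})

test_that("zero residuals concentrate the covariance draw at the prior scale", {
  set.seed(106)
  u <- matrix(0, 200, 6)
  priors <- dsem_priors()
  draws <- replicate(400, diag(emadsem:::draw_tau(u, priors)))
  # posterior is IW(prior scale, prior df + n): mean scale/(df - p - 1)
  expect_equal(mean(draws[1, ]), 0.1 / (priors$tau_df - 2 + 200 - 4 - 1),
               tolerance = 0.1)
  expect_lt(max(draws), 0.01)
})

test_that("within-variance draws follow the inverse-gamma posterior moments", {
  set.seed(107)
  priors <- dsem_priors()
  ssr <- 40; n_obs <- 200
  draws <- replicate(4000, emadsem:::draw_var_ig(ssr, n_obs, priors))
  shape <- priors$var_shape + n_obs / 2
  rate <- priors$var_rate + ssr / 2
  ig_mean <- rate / (shape - 1)
  ig_sd <- ig_mean / sqrt(shape - 2)
  expect_lt(abs(mean(draws) - ig_mean), 3 * ig_sd / sqrt(4000))

  # vague prior with zero residuals: draws collapse toward zero
  tiny <- replicate(200, emadsem:::draw_var_ig(0, 1000, priors))
  expect_lt(max(tiny), 1e-4)

  # doubling the data with the same mean residual shrinks the spread ~1/sqrt(2)
  d2 <- replicate(4000, emadsem:::draw_var_ig(2 * ssr, 2 * n_obs, priors))
  expect_equal(sd(draws) / sd(d2), sqrt(2), tolerance = 0.15)
})

test_that("potential scale reduction flags separated chains and only those", {
  m <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  same <- psr_diagnostic(list(m, m))
  # identical chains: B = 0, PSR = sqrt((n-1)/n), i.e. 1 to finite-n accuracy
  expect_equal(same$psr, rep(1, 3), tolerance = 0.01)
  expect_true(all(same$psr <= 1))

  offset <- m; offset[, 2] <- offset[, 2] + 5
  shifted <- psr_diagnostic(list(m, offset))
  expect_gt(shifted$psr[2], 1)

  const <- m; const[, 3] <- 1
  const2 <- const; const2[, 3] <- 1
  undef <- psr_diagnostic(list(const, const2))
  expect_true(is.na(undef$psr[3]))

  # well-mixed chains from the same distribution stay under 1.05
  set.seed(108)
  c1 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(psr_diagnostic(list(c1, c2))$psr, 1.05)
})

test_that("posterior summaries use the linear-interpolation percentile convention", {
  draws <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "x"))
  s <- summarize_posterior(list(draws))
  expect_equal(s$median, 2)
  expect_equal(s$lower, 1.05)
  expect_equal(s$upper, 2.95)

  set.seed(109)
  nd <- matrix(rnorm(20000, 0, 2), ncol = 1, dimnames = list(NULL, "x"))
  sn <- summarize_posterior(list(nd))
  expect_equal(sn$upper - sn$lower, 3.92 * 2, tolerance = 0.03)
  expect_lt(abs(sn$median), 0.1)
})

test_that("the sampler nails the truth in the vanishing-noise limit", {
  # residual and random-effect variances near zero, with nonzero covariate
  # couplings so the within dynamics stay identified as the noise vanishes
  g <- setNames(rep(0, 16), emadsem:::gamma_names())
  g["gamma00"] <- 0.8; g["gamma10"] <- 0.4
  g["gamma20"] <- 0.4; g["gamma30"] <- 0.2
  g["gamma40"] <- 0.3; g["gamma50"] <- -0.2
  params <- dsem_params(g, diag(1e-10, 6), sigma2_e = 1e-6,
                        sigma2_str = 1, sigma2_cov = 1)
  cfg <- generator_config(n_persons = 20, missing_rate = 0, params = params,
                          seed = 11)
  sim <- simulate_study(cfg)
  grid <- align_time_grid(sim$panel)
  fit <- suppressWarnings(fit_dsem(
    grid, sim$traits, dsem_spec("na"),
    mcmc_config(n_chains = 2, n_iter = 500, n_burn = 250, seed = 11),
    priors = dsem_priors(tau_scale = diag(1e-8, 6))
  ))
  s <- summarize_posterior(fit)
  expect_lt(abs(s$median[s$term == "gamma00"] - 0.8), 0.01)
  expect_lt(abs(s$median[s$term == "gamma10"] - 0.4), 0.01)
})

test_that("estimation refuses fewer persons than random effects", {
  sim <- small_study(n_persons = 5, seed = 12)
  grid <- align_time_grid(sim$panel)
  expect_error(
    fit_dsem(grid, sim$traits, mcmc = mcmc_config(n_iter = 50, n_burn = 10)),
    class = "emadsem_parameter_error"
  )
})

test_that("doubling the series length contracts gamma10 by about sqrt(2)", {
  g <- setNames(rep(0, 16), emadsem:::gamma_names())
  g["gamma10"] <- 0.32
  params <- dsem_params(g, diag(1e-4, 6), sigma2_e = 0.21,
                        sigma2_str = 1, sigma2_cov = 1)
  post_sd <- function(n_days, seed) {
    sim <- simulate_study(generator_config(
      n_persons = 40, n_days = n_days, missing_rate = 0,
      params = params, seed = seed
    ))
    fit <- suppressWarnings(fit_dsem(
      align_time_grid(sim$panel), sim$traits, dsem_spec("na"),
      mcmc_config(n_chains = 1, n_iter = 1200, n_burn = 400, seed = seed)
    ))
    sd(emadsem:::pooled_draws(fit)[, "gamma10"])
  }
  ratio <- post_sd(21, 13) / post_sd(42, 13)
  expect_gt(ratio, 1.1)
  expect_lt(ratio, 1.9)
})

test_that("observed cells are never modified by the fit", {
  sim <- small_study(n_persons = 12, seed = 14)
  grid <- align_time_grid(sim$panel)
  before <- grid$na[grid$observed]
  fit <- suppressWarnings(fit_dsem(
    grid, sim$traits, dsem_spec("na"),
    mcmc_config(n_chains = 1, n_iter = 120, n_burn = 40, seed = 14)
  ))
  expect_identical(grid$na[grid$observed], before)
  expect_s3_class(tidy(fit), "tbl_df")
  gl <- glance(fit)
  expect_equal(gl$n_persons, 12L)
  expect_true(gl$r2_within >= 0 || is.na(gl$r2_within))
})

test_that("a too-short run warns about non-convergence rather than failing silently", {
  sim <- small_study(n_persons = 12, seed = 15)
  grid <- align_time_grid(sim$panel)
  expect_warning(
    fit_dsem(grid, sim$traits, dsem_spec("na"),
             mcmc_config(n_chains = 2, n_iter = 60, n_burn = 20, seed = 15)),
    class = "emadsem_convergence_warning"
  )
})
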