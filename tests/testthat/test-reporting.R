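# Construct a deterministic fit object with known functionals so the
# standardization and R^2 formulas can be checked against hand arithmetic.
fake_fit <- function(n = 6, phi = 0, beta = 0.5, eta = 0, s2e = 0,
                     s2s = 4, s2c = 1, tau00 = 0.25,
                     alpha = seq(-1, 1, length.out = 6)) {
  theta <- cbind(alpha = alpha, phi = rep(phi, n), beta = rep(beta, n),
                 eta = rep(eta, n), ms = rnorm(n, 0, 0.1),
                 mc = rnorm(n, 0, 0.1))
  dn <- emadsem:::draw_names()
  row <- setNames(numeric(length(dn)), dn)
  row["gamma01"] <- 0.2; row["gamma02"] <- -0.1
  row["tau_00"] <- tau00
  row["sigma2_e"] <- s2e; row["sigma2_str"] <- s2s; row["sigma2_cov"] <- s2c
  draws <- rbind(row, row)
  effects <- array(0, c(2, n, 6), dimnames = list(NULL, NULL,
                                                  emadsem:::effect_names()))
  effects[1, , ] <- theta
  effects[2, , ] <- theta
  structure(
    list(draws = list(draws), effects = list(effects),
         persons = paste0("p", seq_len(n)),
         spec = dsem_spec("na"), mcmc = mcmc_config(n_iter = 10, n_burn = 5),
         data = list(n_persons = n, t_len = 83, n_obs = 83 * n,
                     res = seq(-1, 1, length.out = n),
                     lon = seq(-0.5, 0.5, length.out = n)),
         psr = tibble::tibble(term = dn, psr = NA_real_),
         converged = TRUE, n_jitter = 0),
    class = "dsem_fit"
  )
}

test_that("intercept ranges match the normal-quantile arithmetic", {
  got <- ci_interval_95(0.01, 0.31)
  expect_equal(c(got$lower, got$upper), c(-1.08, 1.10))
  got2 <- ci_interval_95(-0.02, 0.61)
  expect_equal(c(got2$lower, got2$upper), c(-1.55, 1.51))
  expect_equal(unlist(ci_interval_95(0, 0)), c(lower = 0, upper = 0,
                                               lower_raw = 0, upper_raw = 0))
  expect_error(ci_interval_95(0, -1), class = "emadsem_parameter_error")

  # symmetry around the mean and monotone widening in the variance
  for (tau in c(0.1, 0.4, 0.9)) {
    ci <- ci_interval_95(0.3, tau)
    expect_equal(ci$upper_raw - 0.3, 0.3 - ci$lower_raw)
  }
  w <- vapply(c(0.1, 0.4, 0.9),
              function(tau) diff(unlist(ci_interval_95(0.3, tau)[3:4])),
              numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("response-rate arithmetic is exact and scale invariant", {
  expect_equal(as.numeric(response_rate(4978, 88, 63)), 89.8)
  expect_equal(as.numeric(response_rate(5544, 88, 63)), 100)
  expect_equal(as.numeric(response_rate(0, 88, 63)), 0)
  expect_equal(as.numeric(response_rate(4978 * 3, 88 * 3, 63)),
               as.numeric(response_rate(4978, 88, 63)))
  expect_error(response_rate(6000, 88, 63),
               class = "emadsem_integrity_error")
  expect_error(response_rate(10, 0, 63), class = "emadsem_parameter_error")
})

test_that("degenerate within variation yields NA within correlations, not zeros", {
  panel <- ema_panel(tibble::tibble(
    person_id = rep(c("a", "b"), each = 3),
    day = rep(0L, 6), slot = rep(slot_levels(), 2),
    stress = rep(c(2, 4), each = 3),  # constant within person
    na = rep(c(1, 3), each = 3),
    pa = rep(c(5, 2), each = 3)
  ))
  traits <- emadsem:::new_trait_table(c("a", "b"), c(3, 4), c(2, 3))
  d <- descriptives_table(panel, traits)
  expect_true(all(is.na(d$within_cor[upper.tri(d$within_cor)])))
  # between correlations are defined: person means differ
  expect_equal(abs(d$between_cor["NA_", "STR"]), 1)
})

test_that("between correlations match a hand-computed two-person oracle", {
  panel <- ema_panel(tibble::tibble(
    person_id = rep(c("a", "b"), each = 2),
    day = 0L, slot = rep(c("morning", "afternoon"), 2),
    stress = c(1, 3, 4, 4), na = c(2, 2, 3, 5), pa = c(3, 1, 2, 2)
  ))
  traits <- emadsem:::new_trait_table(c("a", "b"), c(3, 4), c(2, 3))
  d <- descriptives_table(panel, traits)
  pm_na <- c(2, 4); pm_str <- c(2, 4)
  expect_equal(d$between_cor["NA_", "STR"], cor(pm_na, pm_str))
  expect_equal(d$between_msd$mean[d$between_msd$variable == "NA_"],
               mean(pm_na))
  expect_equal(d$within_msd$mean[d$within_msd$variable == "STR"],
               mean(c(1, 3, 4, 4)))
})

test_that("within stress-affect correlation tracks the generating coupling", {
  make <- function(beta) {
    g <- setNames(rep(0, 16), emadsem:::gamma_names())
    g["gamma10"] <- 0.2; g["gamma20"] <- beta
    params <- dsem_params(g, diag(1e-6, 6), 0.2, 1, 1)
    sim <- simulate_study(generator_config(
      n_persons = 40, missing_rate = 0, params = params, seed = 16
    ))
    d <- descriptives_table(sim$panel, sim$traits)
    d$within_cor["NA_", "STR"]
  }
  r_small <- make(0.1)
  r_large <- make(0.6)
  expect_gt(r_small, 0)
  expect_gt(r_large, r_small)
})

test_that("with zero between-person coupling between correlations vanish", {
  g <- setNames(rep(0, 16), emadsem:::gamma_names())
  g["gamma10"] <- 0.3; g["gamma20"] <- 0.4
  params <- dsem_params(g, diag(c(1e-6, 1e-6, 1e-6, 1e-6, 0.4, 0.4)),
                        0.2, 1, 1)
  sim <- simulate_study(generator_config(
    n_persons = 300, missing_rate = 0, params = params, seed = 17
  ))
  d <- descriptives_table(sim$panel, sim$traits)
  # within NA-STR tracks beta; between NA-STR has no generating coupling
  expect_gt(d$within_cor["NA_", "STR"], 0.3)
  expect_lt(abs(d$between_cor["NA_", "STR"]), 3 / sqrt(300) * 1.5)
})

test_that("standardization follows coefficient * SD(predictor) / SD(outcome)", {
  # beta = 0.5, SD(strc) = 2, model-implied within SD of the outcome = 1
  fit <- fake_fit(phi = 0, beta = 0.5, eta = 0, s2e = 0, s2s = 4, s2c = 1)
  s <- standardize_estimates(fit)
  expect_equal(s$median[s$term == "gamma20"], 1.0)

  # the lag slope standardizes to itself: std gamma10 = mean(phi_i) = phi
  fit2 <- fake_fit(phi = 0.32, beta = 0, s2e = 0.21)
  s2 <- standardize_estimates(fit2)
  expect_equal(s2$median[s2$term == "gamma10"], 0.32)

  # equal predictor and outcome SDs: standardized equals unstandardized
  fit3 <- fake_fit(phi = 0, beta = 0.5, s2e = 1 - 0.25, s2s = 1)
  s3 <- standardize_estimates(fit3)
  expect_equal(s3$median[s3$term == "gamma20"], 0.5)

  # between slope: gamma01 * sd(res) / sd(alpha_i)
  fit4 <- fake_fit()
  s4 <- standardize_estimates(fit4)
  expect_equal(s4$median[s4$term == "gamma01"],
               0.2 * sd(fit4$data$res) / sd(seq(-1, 1, length.out = 6)))
})

test_that("R-squared reduces to its null and saturated limits", {
  # phi = beta = eta = 0: the model explains nothing within
  null_fit <- fake_fit(phi = 0, beta = 0, eta = 0, s2e = 0.3)
  expect_equal(compute_r2(null_fit)$r2_within, 0)

  # zero residual intercept variance with varying alpha: between R^2 = 1
  sat <- fake_fit(tau00 = 0, s2e = 0.3)
  expect_equal(compute_r2(sat)$r2_between, 1)

  # known decomposition: r2w = 1 - s2e / ((s2e + b^2 s2s)/(1 - phi^2))
  fit <- fake_fit(phi = 0.4, beta = 0.5, eta = 0, s2e = 0.2, s2s = 1)
  vbar <- (0.2 + 0.25) / (1 - 0.16)
  expect_equal(compute_r2(fit)$r2_within, 1 - 0.2 / vbar)
})

test_that("the rendered summary table has the full fixed layout", {
  fit <- fake_fit()
  tab <- render_table2(fit)
  expect_equal(nrow(tab), 25L)
  expect_equal(tab$notation[1], "gamma_00")
  expect_equal(tab$notation[25], "R2_between")

  # round-trip through CSV recovers the machine-precision medians
  path <- tempfile(fileext = ".csv")
  render_table2(fit, path = path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(back$median_raw, tab$median_raw)

  # side-by-side rendering of the mirrored model
  both <- render_table2(fit, pa = fake_fit(phi = 0.34))
  expect_true(all(c("median", "median_pa") %in% names(both)))
  expect_equal(nrow(both), 25L)

  # a missing parameter row is a rendering error naming the row
  s <- summarize_posterior(fit)
  s <- s[s$term != "gamma03", ]
  expect_error(render_table2(s), class = "emadsem_format_error",
               regexp = "gamma03")
})
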