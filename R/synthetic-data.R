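gamma_names <- function() {
  c("gamma00", "gamma01", "gamma02", "gamma03", "gamma04",
    "gamma10", "gamma11", "gamma12",
    "gamma20", "gamma21", "gamma22",
    "gamma30", "gamma31", "gamma32",
    "gamma40", "gamma50")
}

effect_names <- function() c("alpha", "phi", "beta", "eta", "str_b", "cov_b")

#' Parameter set of the two-level AR(1) affect model
#'
#' Collects the full generative parameter set: the 16 between-level regression
#' coefficients, the 6x6 random-effect covariance `tau` (order: intercept u0,
#' autoregression u1, stress slope u2, opposite-affect slope u3, latent mean
#' stress u4, latent mean opposite affect u5), and the within-level variances.
#' The within model for the outcome deviation o_t is
#' `o_t = phi_i * o_{t-1} + beta_i * s_t + eta_i * p_t + e_t`, with the
#' centered stress (s) and opposite-affect (p) deviations white noise.
#'
#' @param gamma Named numeric vector of the 16 coefficients (see
#'   [default_dsem_params()] for the naming).
#' @param tau 6x6 symmetric positive-semidefinite covariance matrix.
#' @param sigma2_e Within residual variance of the outcome.
#' @param sigma2_str,sigma2_cov Within variances of the latent centered stress
#'   and opposite-affect deviations.
#' @param outcome Which affect the model treats as the outcome, `"na"` or
#'   `"pa"`; the other is the within covariate.
#' @param check_stationarity Enforce the generator-mode stationarity margin
#'   `|gamma10| + 2*sqrt(tau11) < 1` (default `TRUE`).
#' @return A `dsem_params` list.
#' @export
dsem_params <- function(gamma, tau, sigma2_e, sigma2_str, sigma2_cov,
                        outcome = c("na", "pa"), check_stationarity = TRUE) {
  outcome <- match.arg(outcome)
  gamma <- gamma[gamma_names()]
  if (anyNA(gamma)) {
    abort_param(sprintf("`gamma` must be named with: %s",
                        paste(gamma_names(), collapse = ", ")))
  }
  tau <- as.matrix(tau)
  if (!all(dim(tau) == c(6, 6)) || !is_psd(tau)) {
    abort_param("`tau` must be a symmetric positive-semidefinite 6x6 matrix.")
  }
  if (sigma2_e < 0 || sigma2_str < 0 || sigma2_cov < 0) {
    abort_param("Within variances must be nonnegative.")
  }
  if (check_stationarity &&
      abs(gamma[["gamma10"]]) + 2 * sqrt(tau[2, 2]) >= 1) {
    abort_param(
      "Nonstationary generator: need |gamma10| + 2*sqrt(tau11) < 1."
    )
  }
  dimnames(tau) <- list(effect_names(), effect_names())
  structure(
    list(gamma = gamma, tau = tau, sigma2_e = sigma2_e,
         sigma2_str = sigma2_str, sigma2_cov = sigma2_cov,
         outcome = outcome),
    class = "dsem_params"
  )
}

#' Default model parameters (reported posterior medians)
#'
#' The negative-affect and positive-affect parameter sets used as generator
#' truth in recovery studies: posterior medians of the two fitted models on
#' the standardized scale, with a diagonal `tau` (off-diagonal random-effect
#' covariances are not reported) and unit within variances for the latent
#' centered stress and opposite-affect deviations (the study scale is
#' standardized; see the methods vignette).
#'
#' @param outcome `"na"` (negative affect as outcome, default) or `"pa"`.
#' @return A [dsem_params()] object.
#' @export
default_dsem_params <- function(outcome = c("na", "pa")) {
  outcome <- match.arg(outcome)
  if (outcome == "na") {
    gamma <- c(
      gamma00 = 0.01, gamma01 = -0.02, gamma02 = 0.17, gamma03 = 0.81,
      gamma04 = 0.13,
      gamma10 = 0.32, gamma11 = -0.04, gamma12 = 0.01,
      gamma20 = 0.02, gamma21 = -0.05, gamma22 = 0.01,
      gamma30 = 0.05, gamma31 = -0.01, gamma32 = 0.04,
      gamma40 = 0.01, gamma50 = -0.02
    )
    tau_diag <- c(0.31, 0.04, 0.02, 0.05, 0.43, 0.65)
    sigma2_e <- 0.21
  } else {
    gamma <- c(
      gamma00 = -0.02, gamma01 = 0.14, gamma02 = -0.15, gamma03 = -0.30,
      gamma04 = -0.30,
      gamma10 = 0.34, gamma11 = -0.02, gamma12 = 0.01,
      gamma20 = -0.01, gamma21 = 0.02, gamma22 = 0.01,
      gamma30 = -0.12, gamma31 = 0.03, gamma32 = 0.03,
      gamma40 = 0.01, gamma50 = 0.01
    )
    tau_diag <- c(0.61, 0.03, 0.02, 0.08, 0.42, 0.62)
    sigma2_e <- 0.28
  }
  dsem_params(gamma, diag(tau_diag), sigma2_e,
              sigma2_str = 1, sigma2_cov = 1, outcome = outcome)
}

#' Configuration of the study simulator
#'
#' Defaults emulate the study design: 88 retained participants, 21 days with 3
#' prompts/day (63 design occasions), 10.2% record-level missingness, and
#' trait distributions matching the reported between-level means/SDs
#' (resilience 3.13 (0.60) on 1-5, loneliness 2.26 (0.55) on 1-4).
#'
#' @param n_persons Number of participants (default 88).
#' @param n_days Study days (default 21).
#' @param slots_per_day Prompts per day (default 3; the time grid assumes 3).
#' @param missing_rate Record-level MCAR deletion probability (default 0.102).
#' @param trait_means,trait_sds Named (`res`, `lon`) normal moments of the
#'   simulated trait composites.
#' @param trait_ranges Named list of instrument ranges used to clip simulated
#'   traits.
#' @param params Generating [dsem_params()].
#' @param seed Optional integer seed for [simulate_study()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_persons = 88L, n_days = 21L,
                             slots_per_day = 3L, missing_rate = 0.102,
                             trait_means = c(res = 3.13, lon = 2.26),
                             trait_sds = c(res = 0.60, lon = 0.55),
                             trait_ranges = list(res = c(1, 5),
                                                 lon = c(1, 4)),
                             params = default_dsem_params(),
                             seed = NULL) {
  if (n_persons < 2) abort_param("`n_persons` must be at least 2.")
  if (missing_rate < 0 || missing_rate > 1) {
    abort_param("`missing_rate` must be in [0, 1].")
  }
  structure(
    list(n_persons = as.integer(n_persons), n_days = as.integer(n_days),
         slots_per_day = as.integer(slots_per_day),
         missing_rate = missing_rate, trait_means = trait_means,
         trait_sds = trait_sds, trait_ranges = trait_ranges,
         params = params, seed = seed),
    class = "generator_config"
  )
}

#' Simulate person-level trait composites
#'
#' Draws resilience and loneliness composites from the configured normal
#' distributions, clips them to the instrument ranges (a message reports how
#' many values were clipped), and grand-mean-centers.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return A `trait_table` tibble.
#' @export
simulate_traits <- function(config, seed = NULL) {
  local_seed(seed, {
    n <- config$n_persons
    ids <- sprintf("p%03d", seq_len(n))
    draw <- function(which) {
      x <- rnorm(n, config$trait_means[[which]], config$trait_sds[[which]])
      r <- config$trait_ranges[[which]]
      n_clip <- sum(x < r[1] | x > r[2])
      if (n_clip > 0) {
        message(sprintf("Clipped %d simulated %s value(s) to [%g, %g].",
                        n_clip, which, r[1], r[2]))
      }
      pmin(pmax(x, r[1]), r[2])
    }
    new_trait_table(ids, draw("res"), draw("lon"))
  })
}

#' Draw person-specific effects from the between-level model
#'
#' Random effects `u ~ MVN(0, tau)` are combined with the between-level
#' regressions: the person intercept responds to centered traits and to the
#' *centered* latent means (`str_b - gamma40`, `cov_b - gamma50`); the
#' autoregression and the two within slopes respond to centered traits; the
#' latent means are intercept-plus-noise.
#'
#' @param params A [dsem_params()].
#' @param traits A `trait_table` with centered trait columns.
#' @param seed Optional seed.
#' @return Tibble with `person_id`, `alpha`, `phi`, `beta`, `eta`, `str_b`,
#'   `cov_b`.
#' @export
draw_person_effects <- function(params, traits, seed = NULL) {
  local_seed(seed, {
    g <- params$gamma
    n <- nrow(traits)
    res <- traits$res_c
    lon <- traits$lon_c
    u <- matrix(rnorm(n * 6), n, 6) %*% psd_sqrt(params$tau)
    # generator mode requires a stationary AR coefficient for every person:
    # redraw the random-effect vector of the rare person whose phi tail draw
    # crosses 1 (the enforced margin |gamma10| + 2*sqrt(tau11) < 1 makes this
    # a negligible truncation)
    phi_of <- function(u) {
      g[["gamma10"]] + g[["gamma11"]] * res + g[["gamma12"]] * lon + u[, 2]
    }
    tries <- 0L
    while (any(bad <- abs(phi_of(u)) >= 1) && tries < 100L) {
      u[bad, ] <- matrix(rnorm(sum(bad) * 6), ncol = 6) %*%
        psd_sqrt(params$tau)
      tries <- tries + 1L
    }
    if (any(abs(phi_of(u)) >= 1)) {
      abort_param("Could not draw stationary person effects; shrink tau11.")
    }
    tibble(
      person_id = traits$person_id,
      alpha = g[["gamma00"]] + g[["gamma01"]] * res + g[["gamma02"]] * lon +
        g[["gamma03"]] * u[, 5] + g[["gamma04"]] * u[, 6] + u[, 1],
      phi = g[["gamma10"]] + g[["gamma11"]] * res + g[["gamma12"]] * lon +
        u[, 2],
      beta = g[["gamma20"]] + g[["gamma21"]] * res + g[["gamma22"]] * lon +
        u[, 3],
      eta = g[["gamma30"]] + g[["gamma31"]] * res + g[["gamma32"]] * lon +
        u[, 4],
      str_b = g[["gamma40"]] + u[, 5],
      cov_b = g[["gamma50"]] + u[, 6]
    )
  })
}

#' Simulate the within-person series on the latent grid
#'
#' Latent centered stress and opposite-affect deviations are i.i.d. normal per
#' cell; the outcome deviation follows the person's AR(1) with those
#' deviations as concurrent inputs, initialized from its stationary
#' distribution. Observed-scale values are the person's latent mean plus the
#' deviation, simulated at every grid cell (phantom cells included).
#'
#' @param effects Output of [draw_person_effects()].
#' @param params A [dsem_params()].
#' @param n_cells Number of grid cells to simulate.
#' @param seed Optional seed.
#' @return Long tibble: `person_id`, `cell` (0-based), `outcome`, `stress`,
#'   `cov`.
#' @export
simulate_within_series <- function(effects, params, n_cells, seed = NULL) {
  if (any(abs(effects$phi) >= 1)) {
    abort_param("Generator requires |phi| < 1 for every person.")
  }
  local_seed(seed, {
    n <- nrow(effects)
    t_len <- as.integer(n_cells)
    s <- matrix(rnorm(n * t_len, 0, sqrt(params$sigma2_str)), n, t_len)
    p <- matrix(rnorm(n * t_len, 0, sqrt(params$sigma2_cov)), n, t_len)
    e <- matrix(rnorm(n * t_len, 0, sqrt(params$sigma2_e)), n, t_len)
    phi <- effects$phi
    # stationary variance of the outcome deviation, incl. covariate input
    innov_var <- params$sigma2_e + effects$beta^2 * params$sigma2_str +
      effects$eta^2 * params$sigma2_cov
    d <- matrix(0, n, t_len)
    d_prev <- rnorm(n, 0, sqrt(innov_var / (1 - phi^2)))
    for (t in seq_len(t_len)) {
      d[, t] <- phi * d_prev + effects$beta * s[, t] + effects$eta * p[, t] +
        e[, t]
      d_prev <- d[, t]
    }
    tibble(
      person_id = rep(effects$person_id, times = t_len),
      cell = rep(0:(t_len - 1L), each = n),
      outcome = as.vector(effects$alpha + d),
      stress = as.vector(effects$str_b + s),
      cov = as.vector(effects$cov_b + p)
    ) |> arrange(.data$person_id, .data$cell)
  })
}

#' Delete records completely at random
#'
#' Each record is independently dropped with probability `rate` (MCAR),
#' emulating prompt nonresponse.
#'
#' @param panel An `ema_panel`.
#' @param rate Deletion probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return The thinned `ema_panel`.
#' @export
apply_missingness <- function(panel, rate, seed = NULL) {
  if (rate < 0 || rate > 1) abort_param("`rate` must be in [0, 1].")
  local_seed(seed, {
    keep <- stats::runif(nrow(panel)) >= rate
    design <- panel_design(panel)
    new_ema_panel(as_tibble(panel)[keep, ], design$n_days,
                  design$slots_per_day)
  })
}

#' Simulate a complete study with known truth
#'
#' Draws traits, person effects and within-person series on the full 6-hour
#' grid, drops the phantom cells, applies record-level MCAR missingness, and
#' returns the panel together with the generating truth for parameter
#' recovery. The simulated outcome series is written to the `na` or `pa`
#' column according to `config$params$outcome`, the opposite affect to the
#' other column. Values are on the generating (standardized) scale.
#'
#' @param config A [generator_config()]; `config$seed` makes the output
#'   byte-reproducible.
#' @return List with `panel` (`ema_panel`), `traits` (`trait_table`),
#'   `effects` (person-effect truth) and `params` (generating
#'   [dsem_params()]).
#' @export
simulate_study <- function(config) {
  local_seed(config$seed, {
    traits <- simulate_traits(config)
    effects <- draw_person_effects(config$params, traits)
    n_cells <- 4L * config$n_days - 1L
    series <- simulate_within_series(effects, config$params, n_cells)
    ds <- grid_to_day_slot(series$cell)
    series$day <- ds$day
    series$slot <- ds$slot
    series <- series[!is.na(series$slot), ]  # drop phantom cells
    if (config$params$outcome == "na") {
      records <- tibble(
        person_id = series$person_id, day = series$day, slot = series$slot,
        stress = series$stress, na = series$outcome, pa = series$cov
      )
    } else {
      records <- tibble(
        person_id = series$person_id, day = series$day, slot = series$slot,
        stress = series$stress, na = series$cov, pa = series$outcome
      )
    }
    panel <- ema_panel(records, n_days = config$n_days,
                       slots_per_day = config$slots_per_day, ranges = NULL)
    panel <- apply_missingness(panel, config$missing_rate)
    list(panel = panel, traits = traits, effects = effects,
         params = config$params, config = config)
  })
}
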