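# Post-estimation quantities and descriptive statistics.

safe_cor <- function(m) {
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- m[, i]; y <- m[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      out[i, j] <- cor(x[ok], y[ok])
    }
  }
  out
}

#' Within/between descriptive statistics (Table-1 twin)
#'
#' Within-person correlations are computed on person-mean-centered occasion
#' values pooled across persons; between-person correlations across persons on
#' the person means of the momentary variables plus the raw trait composites.
#' M(SD) is reported over all occasion values (within) and over person means
#' and trait scores (between). Entries with degenerate variance are reported
#' as `NA`, never as 0.
#'
#' @param panel An `ema_panel` (at least 2 persons with 2+ observations).
#' @param traits A `trait_table` for the panel's persons.
#' @return A `descriptives` list: `within_cor` (3x3), `between_cor` (5x5),
#'   `within_msd`, `between_msd`, and `table1`, a rendered tibble with within
#'   correlations in the upper triangle and between correlations in the lower.
#' @export
descriptives_table <- function(panel, traits) {
  df <- as_tibble(panel)
  counts <- table(df$person_id)
  if (length(counts) < 2 || all(counts < 2)) {
    abort_param("Descriptives need >= 2 persons with >= 2 observations.")
  }
  vars <- c(NA_ = "na", PA = "pa", STR = "stress")

  centered <- df |>
    group_by(.data$person_id) |>
    mutate(across(all_of(unname(vars)),
                  ~ .x - mean(.x, na.rm = TRUE))) |>
    ungroup()
  wmat <- as.matrix(centered[unname(vars)])
  colnames(wmat) <- names(vars)
  within_cor <- safe_cor(wmat)

  pmeans <- df |>
    group_by(.data$person_id) |>
    summarise(across(all_of(unname(vars)), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  pmeans <- left_join(pmeans,
                      traits[c("person_id", "res_raw", "lon_raw")],
                      by = "person_id")
  bmat <- as.matrix(pmeans[c(unname(vars), "res_raw", "lon_raw")])
  colnames(bmat) <- c(names(vars), "RES", "LON")
  between_cor <- safe_cor(bmat)

  raw <- as.matrix(df[unname(vars)])
  within_msd <- tibble(
    variable = names(vars),
    mean = unname(colMeans(raw, na.rm = TRUE)),
    sd = unname(apply(raw, 2, sd, na.rm = TRUE))
  )
  between_msd <- tibble(
    variable = colnames(bmat),
    mean = unname(colMeans(bmat, na.rm = TRUE)),
    sd = unname(apply(bmat, 2, sd, na.rm = TRUE))
  )

  labs <- colnames(bmat)
  cells <- matrix("", 5, 5, dimnames = list(labs, labs))
  diag(cells) <- "1"
  for (i in 1:5) {
    for (j in 1:5) {
      if (i < j && i <= 3 && j <= 3) {           # upper: within
        cells[i, j] <- ifelse(is.na(within_cor[i, j]), "",
                              sprintf("%.3f", within_cor[i, j]))
      } else if (i > j) {                        # lower: between
        cells[i, j] <- ifelse(is.na(between_cor[i, j]), "",
                              sprintf("%.2f", between_cor[i, j]))
      }
    }
  }
  table1 <- as_tibble(cells, rownames = "variable")
  table1$`M (SD) within` <- c(
    sprintf("%.2f (%.2f)", within_msd$mean, within_msd$sd), "", ""
  )
  msd_between <- sprintf("%.2f (%.2f)", between_msd$mean, between_msd$sd)
  table1 <- bind_rows(
    table1,
    tibble(variable = "M (SD) between",
           !!!setNames(as.list(msd_between), labs),
           `M (SD) within` = "")
  )

  structure(
    list(within_cor = within_cor, between_cor = between_cor,
         within_msd = within_msd, between_msd = between_msd,
         table1 = table1),
    class = "descriptives"
  )
}

#' @export
print.descriptives <- function(x, ...) {
  cat("Within (upper triangle) / between (lower triangle) correlations:\n")
  print(x$table1, n = Inf)
  invisible(x)
}

#' Valid response rate of the design
#'
#' `100 * n_retained / (n_persons * n_design_occasions)`, reported to one
#' decimal (the unrounded value is attached as attribute `"raw"`).
#'
#' @param n_retained Number of retained (complete) data points.
#' @param n_persons Number of retained participants.
#' @param n_design_occasions Design occasions per participant.
#' @return Percentage rounded to one decimal.
#' @export
response_rate <- function(n_retained, n_persons, n_design_occasions) {
  if (n_persons <= 0 || n_design_occasions <= 0) {
    abort_param("Denominator counts must be positive.")
  }
  total <- n_persons * n_design_occasions
  if (n_retained < 0 || n_retained > total) {
    abort_integrity(sprintf(
      "Retained points (%g) exceed the design total (%g).", n_retained, total
    ))
  }
  raw <- 100 * n_retained / total
  structure(round(raw, 1), raw = raw)
}

#' 95% range of person-specific intercepts
#'
#' Under the normal random-intercept model, 95% of persons have an intercept
#' within `gamma00 +/- 1.96 * sqrt(tau00)`. Endpoints are rounded to two
#' decimals for report rendering; unrounded values are returned alongside.
#'
#' @param gamma00 Mean intercept.
#' @param tau00 Intercept variance (must be nonnegative).
#' @return One-row tibble with `lower`, `upper` (2 dp) and `lower_raw`,
#'   `upper_raw`.
#' @export
ci_interval_95 <- function(gamma00, tau00) {
  if (tau00 < 0) abort_param("`tau00` must be nonnegative.")
  half <- 1.96 * sqrt(tau00)
  tibble(
    lower = round(gamma00 - half, 2),
    upper = round(gamma00 + half, 2),
    lower_raw = gamma00 - half,
    upper_raw = gamma00 + half
  )
}

# Per-draw posterior functionals needed for standardization and R^2:
# model-implied within outcome variance per person, person SDs of the
# effects, and the standardized slope summaries. Vectorized over pooled
# draws.
posterior_functionals <- function(fit) {
  draws <- pooled_draws(fit)
  eff <- pooled_effects(fit)
  n <- dim(eff)[2]
  alpha <- eff[, , 1]; phi <- eff[, , 2]; beta <- eff[, , 3]
  eta <- eff[, , 4]; ms <- eff[, , 5]; mc <- eff[, , 6]
  s2e <- draws[, "sigma2_e"]; s2s <- draws[, "sigma2_str"]
  s2c <- draws[, "sigma2_cov"]
  phi_c <- pmin(pmax(phi, -0.995), 0.995)
  # implied within-person outcome variance (white-noise covariates)
  v <- (s2e + beta^2 * s2s + eta^2 * s2c) / (1 - phi_c^2)
  row_sd <- function(m) {
    sqrt(rowSums((m - rowMeans(m))^2) / (n - 1))
  }
  list(
    draws = draws,
    n_persons = n,
    v_mean = rowMeans(v),
    std_phi = rowMeans(phi),
    std_beta = rowMeans(beta * sqrt(s2s) / sqrt(v)),
    std_eta = rowMeans(eta * sqrt(s2c) / sqrt(v)),
    sd_alpha = row_sd(alpha), sd_phi = row_sd(phi), sd_beta = row_sd(beta),
    sd_eta = row_sd(eta), sd_ms = row_sd(ms), sd_mc = row_sd(mc),
    var_alpha = row_sd(alpha)^2,
    sd_res = sd(fit$data$res), sd_lon = sd(fit$data$lon),
    s2e = s2e
  )
}

#' Standardized coefficient summaries
#'
#' Slopes are standardized per draw as `coefficient * SD(predictor) /
#' SD(outcome)`. Within-level slopes use the model-implied within SDs and are
#' standardized per person, then averaged over persons (the lag slope
#' standardizes to itself, so the standardized autoregression is the person
#' average of `phi_i`). Between-level slopes use the person SDs of the
#' random effect being predicted and of its predictor in that draw. Intercept
#' rows are reported unstandardized. Because standardization is applied per
#' draw, the summaries are genuine posterior quantiles of standardized
#' quantities. This scheme is documented, not claimed to match any particular
#' software's standardization.
#'
#' @param fit A `dsem_fit`.
#' @param prob Interval mass (default 0.95).
#' @return Tibble with `term`, `median`, `lower`, `upper` for the 16
#'   coefficients plus `r2_within` and `r2_between` rows.
#' @export
standardize_estimates <- function(fit, prob = 0.95) {
  pf <- posterior_functionals(fit)
  d <- pf$draws
  zero_guard <- function(x) ifelse(x > 0, x, NA_real_)
  std <- cbind(
    gamma00 = d[, "gamma00"],
    gamma01 = d[, "gamma01"] * pf$sd_res / zero_guard(pf$sd_alpha),
    gamma02 = d[, "gamma02"] * pf$sd_lon / zero_guard(pf$sd_alpha),
    gamma03 = d[, "gamma03"] * pf$sd_ms / zero_guard(pf$sd_alpha),
    gamma04 = d[, "gamma04"] * pf$sd_mc / zero_guard(pf$sd_alpha),
    gamma10 = pf$std_phi,
    gamma11 = d[, "gamma11"] * pf$sd_res / zero_guard(pf$sd_phi),
    gamma12 = d[, "gamma12"] * pf$sd_lon / zero_guard(pf$sd_phi),
    gamma20 = pf$std_beta,
    gamma21 = d[, "gamma21"] * pf$sd_res / zero_guard(pf$sd_beta),
    gamma22 = d[, "gamma22"] * pf$sd_lon / zero_guard(pf$sd_beta),
    gamma30 = pf$std_eta,
    gamma31 = d[, "gamma31"] * pf$sd_res / zero_guard(pf$sd_eta),
    gamma32 = d[, "gamma32"] * pf$sd_lon / zero_guard(pf$sd_eta),
    gamma40 = d[, "gamma40"],
    gamma50 = d[, "gamma50"]
  )
  a <- (1 - prob) / 2
  out <- tibble(
    term = colnames(std),
    median = unname(apply(std, 2, median, na.rm = TRUE)),
    lower = unname(apply(std, 2, quantile, probs = a, na.rm = TRUE)),
    upper = unname(apply(std, 2, quantile, probs = 1 - a, na.rm = TRUE))
  )
  r2w <- 1 - pf$s2e / pf$v_mean
  r2b <- 1 - d[, "tau_00"] / zero_guard(pf$var_alpha)
  bind_rows(out, tibble(
    term = c("r2_within", "r2_between"),
    median = c(median(r2w), median(r2b, na.rm = TRUE)),
    lower = unname(c(quantile(r2w, a), quantile(r2b, a, na.rm = TRUE))),
    upper = unname(c(quantile(r2w, 1 - a), quantile(r2b, 1 - a, na.rm = TRUE)))
  ))
}

#' Within- and between-level variance explained
#'
#' Per draw, `R^2_within = 1 - sigma2_e / vbar` with `vbar` the
#' person-averaged model-implied within outcome variance, and
#' `R^2_between = 1 - tau00 / Var(alpha_i)` with the variance taken across
#' persons in that draw. Both are summarized by the posterior median.
#'
#' @param fit A `dsem_fit`.
#' @return One-row tibble with `r2_within` and `r2_between`.
#' @export
compute_r2 <- function(fit) {
  pf <- posterior_functionals(fit)
  r2w <- 1 - pf$s2e / pf$v_mean
  var_a <- ifelse(pf$var_alpha > 0, pf$var_alpha, NA_real_)
  r2b <- 1 - pf$draws[, "tau_00"] / var_a
  tibble(r2_within = median(r2w), r2_between = median(r2b, na.rm = TRUE))
}

table2_rows <- function() {
  tibble(
    effect = c(
      "Intercept (alpha)", "Intercept (phi)", "Intercept (beta)",
      "Intercept (eta)", "Intercept (STR)", "Intercept (P/N)",
      "alpha on RES", "alpha on LON", "alpha on STR", "alpha on P/N",
      "phi on RES", "phi on LON", "beta on RES", "beta on LON",
      "eta on RES", "eta on LON",
      "Var. (alpha)", "Var. (phi)", "Var. (beta)", "Var. (eta)",
      "Var. (STR)", "Var. (P/N)", "Res. Var.",
      "R2 within", "R2 between"
    ),
    notation = c(
      "gamma_00", "gamma_10", "gamma_20", "gamma_30", "gamma_40", "gamma_50",
      "gamma_01", "gamma_02", "gamma_03", "gamma_04",
      "gamma_11", "gamma_12", "gamma_21", "gamma_22", "gamma_31", "gamma_32",
      "tau_00", "tau_11", "tau_22", "tau_33", "tau_44", "tau_55",
      "sigma2", "R2_within", "R2_between"
    ),
    term = c(
      "gamma00", "gamma10", "gamma20", "gamma30", "gamma40", "gamma50",
      "gamma01", "gamma02", "gamma03", "gamma04",
      "gamma11", "gamma12", "gamma21", "gamma22", "gamma31", "gamma32",
      "tau_00", "tau_11", "tau_22", "tau_33", "tau_44", "tau_55",
      "sigma2_e", "r2_within", "r2_between"
    )
  )
}

summary_for_table2 <- function(x) {
  if (inherits(x, "dsem_fit")) {
    s <- summarize_posterior(x)[c("term", "median", "lower", "upper")]
    r2 <- compute_r2(x)
    s <- bind_rows(s, tibble(
      term = c("r2_within", "r2_between"),
      median = c(r2$r2_within, r2$r2_between),
      lower = NA_real_, upper = NA_real_
    ))
    return(s)
  }
  as_tibble(x)[c("term", "median", "lower", "upper")]
}

#' Render the model-summary table
#'
#' Produces the 25-row summary table (16 coefficients, 6 random-effect
#' variances, the residual variance, and the two R-squared rows) in the fixed
#' row order, with posterior medians and 95% intervals rounded to two
#' decimals for display and the unrounded values preserved in `*_raw`
#' columns. Supplying both models renders their columns side by side.
#'
#' @param x A `dsem_fit` or a summary tibble (`term`, `median`, `lower`,
#'   `upper`) covering every required row.
#' @param pa Optional second fit/summary (e.g. the positive-affect mirror).
#' @param path Optional CSV output path.
#' @return The rendered tibble (invisibly written to `path` if given).
#' @export
render_table2 <- function(x, pa = NULL, path = NULL) {
  rows <- table2_rows()
  add_model <- function(tab, s, suffix = "") {
    s <- summary_for_table2(s)
    missing <- setdiff(rows$term, s$term)
    if (length(missing) > 0) {
      abort_format(sprintf(
        "Summary is missing required row(s): %s",
        paste(missing, collapse = ", ")
      ))
    }
    s <- s[match(rows$term, s$term), ]
    tab[[paste0("median", suffix)]] <- round(s$median, 2)
    tab[[paste0("ci", suffix)]] <- ifelse(
      is.na(s$lower), "",
      sprintf("[%.2f, %.2f]", s$lower, s$upper)
    )
    tab[[paste0("median_raw", suffix)]] <- s$median
    tab[[paste0("lower_raw", suffix)]] <- s$lower
    tab[[paste0("upper_raw", suffix)]] <- s$upper
    tab
  }
  out <- rows[c("effect", "notation")]
  out <- add_model(out, x)
  if (!is.null(pa)) out <- add_model(out, pa, suffix = "_pa")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
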