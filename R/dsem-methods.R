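#' Gelman-Rubin potential scale reduction
#'
#' For each monitored scalar parameter, with `m` chains of `n` draws, within
#' variance `W` (mean of chain variances) and between variance `B`
#' (`n` times the variance of chain means):
#' `PSR = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate that the
#' chains have mixed; a parameter with zero within-chain variance has an
#' undefined PSR and is reported as `NA`.
#'
#' @param draws List of per-chain draw matrices with identical column names
#'   (at least 2 chains of at least 10 draws).
#' @return Tibble with `term` and `psr`.
#' @export
psr_diagnostic <- function(draws) {
  if (!is.list(draws) || length(draws) < 2) {
    abort_param("PSR needs at least 2 chains.")
  }
  n <- nrow(draws[[1]])
  if (n < 10) abort_param("PSR needs at least 10 draws per chain.")
  terms <- colnames(draws[[1]])
  psr <- map_dbl(terms, function(tm) {
    x <- vapply(draws, function(m) m[, tm], numeric(n))
    w <- mean(apply(x, 2, var))
    if (!is.finite(w) || w <= 0) return(NA_real_)
    b <- n * var(colMeans(x))
    sqrt(((n - 1) / n * w + b / n) / w)
  })
  tibble(term = terms, psr = psr)
}

pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

pooled_effects <- function(fit) {
  es <- fit$effects
  out <- array(NA_real_, c(sum(vapply(es, function(e) dim(e)[1], 0L)),
                           dim(es[[1]])[2], 6))
  at <- 0L
  for (e in es) {
    k <- dim(e)[1]
    out[at + seq_len(k), , ] <- e
    at <- at + k
  }
  dimnames(out) <- list(NULL, NULL, effect_names())
  out
}

#' Posterior medians and 95% equal-tailed credible intervals
#'
#' Quantiles use the linear-interpolation convention (R's default type 7).
#'
#' @param fit A `dsem_fit`, or a list of per-chain draw matrices.
#' @param prob Interval mass (default 0.95).
#' @return Tibble with `term`, `median`, `lower`, `upper` and (for fits)
#'   `psr`.
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  if (inherits(fit, "dsem_fit")) {
    draws <- pooled_draws(fit)
    psr <- fit$psr
  } else {
    draws <- if (is.list(fit)) do.call(rbind, fit) else as.matrix(fit)
    psr <- NULL
  }
  if (is.null(dim(draws)) || nrow(draws) == 0) {
    abort_param("No posterior draws to summarize.")
  }
  a <- (1 - prob) / 2
  out <- tibble(
    term = colnames(draws),
    median = unname(apply(draws, 2, median)),
    lower = unname(apply(draws, 2, quantile, probs = a)),
    upper = unname(apply(draws, 2, quantile, probs = 1 - a))
  )
  if (!is.null(psr)) out <- left_join(out, psr, by = "term")
  out
}

#' @rdname summarize_posterior
#' @param x A `dsem_fit`.
#' @param ... Unused.
#' @export
tidy.dsem_fit <- function(x, prob = 0.95, ...) {
  summarize_posterior(x, prob = prob)
}

#' One-row model overview
#'
#' @param x A `dsem_fit`.
#' @param ... Unused.
#' @return Tibble with sample sizes, draw counts, convergence and R-squared.
#' @export
glance.dsem_fit <- function(x, ...) {
  r2 <- compute_r2(x)
  tibble(
    outcome = x$spec$outcome,
    n_persons = x$data$n_persons,
    n_cells = x$data$t_len,
    n_obs = x$data$n_obs,
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]),
    max_psr = if (all(is.na(x$psr$psr))) NA_real_ else
      max(x$psr$psr, na.rm = TRUE),
    converged = x$converged,
    r2_within = r2$r2_within,
    r2_between = r2$r2_between
  )
}
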