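#' Model specification: which affect is the outcome
#'
#' The two-level model is symmetric in the two affects: the `"na"`
#' specification regresses momentary negative affect on its own lag, centered
#' momentary stress and centered momentary positive affect, with the person
#' intercept further regressed on centered traits and the latent person means
#' of stress and positive affect; the `"pa"` specification swaps the roles of
#' the two affects.
#'
#' @param outcome `"na"` or `"pa"`.
#' @return A `dsem_spec` list with `outcome` and `covariate` fields.
#' @export
dsem_spec <- function(outcome = c("na", "pa")) {
  outcome <- match.arg(outcome)
  structure(
    list(outcome = outcome, covariate = if (outcome == "na") "pa" else "na"),
    class = "dsem_spec"
  )
}

#' MCMC settings
#'
#' Defaults follow the 50,000-iteration budget read as 2 chains of 25,000
#' with the first half discarded as burn-in.
#'
#' @param n_chains Number of independent chains (>= 2 for the potential scale
#'   reduction diagnostic).
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations per chain (default half).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed; chain seeds are derived from it.
#' @param psr_threshold Convergence threshold on the potential scale
#'   reduction (default 1.1).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 25000L,
                        n_burn = floor(n_iter / 2), thin = 1L, seed = NULL,
                        psr_threshold = 1.1) {
  if (n_burn >= n_iter) abort_param("`n_burn` must be smaller than `n_iter`.")
  if (n_chains < 1) abort_param("Need at least one chain.")
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_burn = as.integer(n_burn), thin = as.integer(thin), seed = seed,
         psr_threshold = psr_threshold),
    class = "mcmc_config"
  )
}

#' Prior settings for the Gibbs sampler
#'
#' Weakly informative conjugate priors: independent normals on the regression
#' coefficients, inverse-Wishart on the 6x6 random-effect covariance, and
#' inverse-gamma on the within variances.
#'
#' @param gamma_mean,gamma_var Normal prior moments for every coefficient.
#' @param tau_scale,tau_df Inverse-Wishart scale matrix and degrees of
#'   freedom for the random-effect covariance.
#' @param var_shape,var_rate Inverse-gamma shape/rate for within variances.
#' @return A `dsem_priors` list.
#' @export
dsem_priors <- function(gamma_mean = 0, gamma_var = 1e6,
                        tau_scale = diag(0.1, 6), tau_df = 8,
                        var_shape = 0.001, var_rate = 0.001) {
  if (tau_df < 8) {
    # df >= p + 2 keeps the prior mean of tau finite (p = 6)
    abort_param("`tau_df` must be at least 8 for a 6x6 inverse-Wishart.")
  }
  structure(
    list(gamma_mean = gamma_mean, gamma_var = gamma_var,
         tau_scale = tau_scale, tau_df = tau_df,
         var_shape = var_shape, var_rate = var_rate),
    class = "dsem_priors"
  )
}
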