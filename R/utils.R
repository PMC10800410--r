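# Shared internal helpers: error classes, seeding, small numerics.

abort_format <- function(message, ...) {
  abort(message, class = "emadsem_format_error", ...)
}

abort_integrity <- function(message, ...) {
  abort(message, class = "emadsem_integrity_error", ...)
}

abort_param <- function(message, ...) {
  abort(message, class = "emadsem_parameter_error", ...)
}

abort_stat <- function(message, ...) {
  abort(message, class = "emadsem_undefined_statistic_error", ...)
}

# Evaluate `code` under a local RNG state when `seed` is given; leave the
# caller's RNG stream untouched either way only if seed is non-NULL.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_param("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Symmetric matrix square root that tolerates positive *semi*definite input
# (chol() does not). Used to draw MVN deviates with possibly degenerate
# covariance, e.g. tau = 0 in the generator.
psd_sqrt <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -tol * max(abs(vals), 1))) {
    abort_param("Covariance matrix is not positive semidefinite.")
  }
  e$vectors %*% (sqrt(pmax(vals, 0)) * t(e$vectors))
}

is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

slot_levels <- function() c("morning", "afternoon", "evening")

slot_offset <- function(slot) {
  match(slot, slot_levels()) - 1L
}
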