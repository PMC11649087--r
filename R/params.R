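#' Model parameters for the activity-regulation model
#'
#' Bundles the transition rates and network-scaling constants of the
#' active/inactive/refractory (A/I/R) compartmental model. Individuals activate
#' by contact with active nestmates at rate `beta0` (social contagion), become
#' refractory by contact with active nestmates at rate `gamma0` (reverse social
#' contagion), and leave the refractory state spontaneously at rate `delta`.
#' The average number of simultaneous interaction partners grows with colony
#' size as \eqn{\langle k\rangle = 2 E_0 N^{\alpha-1}}.
#'
#' @param beta0 activation rate per active contact (1/s, > 0).
#' @param gamma0 inactivation rate per active-active contact (1/s, > 0).
#' @param delta refractory-to-inactive rate (1/s, > 0).
#' @param E0 network scaling coefficient (dimensionless, > 0).
#' @param alpha network scaling exponent, in `[1, 2]`; 1 gives a size-independent
#'   degree, 2 approaches all-to-all contact.
#' @param N colony size (integer, >= 2).
#'
#' @return An object of class `air_params`.
#' @examples
#' p <- air_params(beta0 = 12.1, gamma0 = 1.21, delta = 0.63,
#'                 E0 = 0.0944, alpha = 1.47, N = 500)
#' mean_degree(p$E0, p$alpha, p$N)
#' @export
air_params <- function(beta0, gamma0, delta, E0, alpha, N) {
  check_positive_scalar(beta0, "beta0")
  check_positive_scalar(gamma0, "gamma0")
  check_positive_scalar(delta, "delta")
  check_positive_scalar(E0, "E0")
  check_alpha(alpha)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) ||
      N < 2 || N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  structure(
    list(beta0 = beta0, gamma0 = gamma0, delta = delta,
         E0 = E0, alpha = alpha, N = as.numeric(N)),
    class = "air_params"
  )
}

#' @export
print.air_params <- function(x, ...) {
  cat("A/I/R model parameters\n")
  cat(sprintf("  beta0  = %g 1/s (social contagion)\n", x$beta0))
  cat(sprintf("  gamma0 = %g 1/s (reverse social contagion)\n", x$gamma0))
  cat(sprintf("  delta  = %g 1/s (refractory -> inactive)\n", x$delta))
  cat(sprintf("  E0 = %g, alpha = %g, N = %d  (<k> = %.4g)\n",
              x$E0, x$alpha, as.integer(x$N), kbar(x)))
  invisible(x)
}

#' Average degree of the colony interaction network
#'
#' The mean number of simultaneous interaction partners per individual, modeled
#' as \eqn{\langle k\rangle = 2 E_0 N^{\alpha - 1}}: constant in colony size for
#' `alpha = 1`, approaching the complete graph as `alpha` approaches 2.
#'
#' @param E0 network scaling coefficient (> 0).
#' @param alpha network scaling exponent, in `[1, 2]`.
#' @param N colony size (>= 1).
#' @return The dimensionless average degree.
#' @examples
#' mean_degree(0.0944, 1.47, 500)
#' @export
mean_degree <- function(E0, alpha, N) {
  check_positive_scalar(E0, "E0")
  check_alpha(alpha)
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must be numeric and >= 1", call. = FALSE)
  }
  2 * E0 * N^(alpha - 1)
}

# mean degree of a parameter bundle
kbar <- function(params) {
  2 * params$E0 * params$N^(params$alpha - 1)
}

#' Steady-state scaling exponent of colony activity
#'
#' Exponent of the power law relating the steady-state number of active
#' individuals to colony size, \eqn{A^\star \propto N^{(3-\alpha)/2}}, for a
#' contact network whose mean degree scales with exponent `alpha - 1`.
#'
#' @param alpha network scaling exponent, in `[1, 2]`.
#' @return `(3 - alpha) / 2`.
#' @examples
#' scaling_exponent(1.5) # three-quarter scaling
#' @export
scaling_exponent <- function(alpha) {
  check_alpha(alpha)
  (3 - alpha) / 2
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 1) || any(alpha > 2)) {
    stop("`alpha` must lie in [1, 2]", call. = FALSE)
  }
  invisible(alpha)
}

as_state <- function(x) {
  if (is.list(x)) x <- unlist(x[c("A", "I", "R")])
  if (is.null(names(x))) names(x) <- c("A", "I", "R")
  x <- x[c("A", "I", "R")]
  if (any(is.na(x))) stop("state must have components A, I, R", call. = FALSE)
  x
}

check_state <- function(state, params = NULL) {
  state <- as_state(state)
  if (any(state < 0)) {
    stop("state components A, I, R must be non-negative", call. = FALSE)
  }
  state
}
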