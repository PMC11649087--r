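#' Auxiliary root function of the equilibrium quadratic
#'
#' \eqn{\varphi(x, y) = \sqrt{(1+x)^2 + y} - (1 + x)}, the positive root factor
#' of the steady-state quadratic in the active count. Computed in the
#' cancellation-free form \eqn{y / (\sqrt{(1+x)^2+y} + 1 + x)}, which stays
#' accurate when `y` is tiny. Non-negative; zero iff `y = 0`; increasing in `y`
#' and decreasing in `x` for `y > 0`.
#'
#' @param x,y non-negative numerics (recycled).
#' @return Dimensionless value(s).
#' @examples
#' air_phi(0, 3) # sqrt(4) - 1
#' @export
air_phi <- function(x, y) {
  if (any(x < 0) || any(y < 0)) {
    stop("`x` and `y` must be non-negative", call. = FALSE)
  }
  y / (sqrt((1 + x)^2 + y) + (1 + x))
}

air_equilibrium <- function(A, I, R, kind, params) {
  structure(list(A = A, I = I, R = R, kind = kind, params = params),
            class = "air_equilibrium")
}

#' @export
print.air_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (N = %d): A* = %.6g, I* = %.6g, R* = %.6g\n",
              x$kind, as.integer(x$params$N), x$A, x$I, x$R))
  invisible(x)
}

#' Coerce an equilibrium to a named state vector
#' @param x an `air_equilibrium`.
#' @param ... unused.
#' @return Named numeric `c(A =, I =, R =)`.
#' @export
as.double.air_equilibrium <- function(x, ...) {
  c(A = x$A, I = x$I, R = x$R)
}

#' Equilibria of the A/I/R model
#'
#' `trivial_equilibrium()` is the all-inactive fixed point `(0, N, 0)`,
#' which is unstable. `nontrivial_equilibrium()` is the positive fixed point:
#' the positive root of the steady-state quadratic
#' \deqn{\frac{\gamma_0\langle k\rangle}{\delta N}(A^\star)^2 +
#'       \left(1+\frac{\gamma_0}{\beta_0}\right)A^\star - N = 0,}
#' with \eqn{I^\star = (\gamma_0/\beta_0) A^\star} and
#' \eqn{R^\star = N - A^\star - I^\star}. `asymptotic_equilibrium()` is its
#' large-colony limit for `alpha > 1`:
#' \eqn{A^\star \simeq \sqrt{\delta/(2\gamma_0 E_0)}\, N^{(3-\alpha)/2}},
#' \eqn{I^\star \simeq (1/\beta_0)\sqrt{\delta\gamma_0/(2E_0)}\, N^{(3-\alpha)/2}},
#' \eqn{R^\star \simeq N} (the three components are not constrained to sum
#' to `N`).
#'
#' @param params an [air_params()] object.
#' @return An `air_equilibrium` with fields `A`, `I`, `R`, `kind`.
#' @examples
#' p <- air_params(12.1, 1.21, 0.63, 0.0944, 1.47, 500)
#' nontrivial_equilibrium(p)
#' @export
trivial_equilibrium <- function(params) {
  air_equilibrium(0, params$N, 0, "trivial", params)
}

#' @rdname trivial_equilibrium
#' @export
nontrivial_equilibrium <- function(params) {
  k <- kbar(params)
  x <- params$gamma0 / params$beta0
  y <- 4 * params$gamma0 * k / params$delta
  A <- params$delta * params$N / (2 * params$gamma0 * k) * air_phi(x, y)
  I <- x * A
  R <- params$N - A - I
  air_equilibrium(A, I, R, "nontrivial", params)
}

#' @rdname trivial_equilibrium
#' @export
asymptotic_equilibrium <- function(params) {
  if (params$alpha <= 1) {
    stop("the asymptotic equilibrium requires alpha > 1 (isometric case has no such limit)",
         call. = FALSE)
  }
  ex <- (3 - params$alpha) / 2
  A <- sqrt(params$delta / (2 * params$gamma0 * params$E0)) * params$N^ex
  I <- sqrt(params$delta * params$gamma0 / (2 * params$E0)) / params$beta0 *
    params$N^ex
  air_equilibrium(A, I, params$N, "asymptotic", params)
}

#' Accuracy indicator of the large-colony approximation
#'
#' The asymptotic equilibrium is accurate when
#' \eqn{4\gamma_0\langle k\rangle/\delta \gg (1+\gamma_0/\beta_0)^2}. Returns
#' the ratio of the two sides; larger means the approximation is better.
#' Increasing in `N` for `alpha > 1`, and it degrades as `beta0` shrinks
#' relative to `gamma0`.
#'
#' @param params an [air_params()] object.
#' @return Dimensionless ratio.
#' @export
asymptotic_validity_ratio <- function(params) {
  (4 * params$gamma0 * kbar(params) / params$delta) /
    (1 + params$gamma0 / params$beta0)^2
}

#' Jacobian of the A/I/R model
#'
#' The matrix of partial derivatives of [air_rhs()] with respect to
#' `(A, I, R)`, valid at any state. At the trivial equilibrium its spectrum is
#' \eqn{\{0, -\delta, \beta_0\langle k\rangle\}} (the positive eigenvalue makes
#' the all-inactive colony unstable); at the nontrivial equilibrium one
#' eigenvalue is the structural zero tied to conservation of `N`, and the
#' other two have negative real parts.
#'
#' @param state named numeric `c(A, I, R)`.
#' @param params an [air_params()] object.
#' @return A 3x3 matrix (1/s) with dimnames `A`, `I`, `R`.
#' @export
air_jacobian <- function(state, params) {
  state <- as_state(state)
  A <- state[["A"]]; I <- state[["I"]]
  c0 <- kbar(params) / params$N
  b <- params$beta0; g <- params$gamma0; d <- params$delta
  J <- matrix(c(
    c0 * (b * I - 2 * g * A),  c0 * b * A,   0,
    -c0 * b * I,              -c0 * b * A,   d,
    2 * c0 * g * A,            0,           -d
  ), nrow = 3, byrow = TRUE, dimnames = list(c("A", "I", "R"), c("A", "I", "R")))
  J
}

#' Routh-Hurwitz coefficients at the nontrivial equilibrium
#'
#' The characteristic polynomial of the Jacobian at the nontrivial equilibrium
#' factors as \eqn{p(s) = -s(a_0 s^2 + a_1 s + a_2)} -- the null root reflects
#' conservation of `N`. The quadratic's coefficients are recovered from the
#' matrix invariants: `a0 = 1`, `a1 = -tr(J*)`, `a2` the sum of the principal
#' 2x2 minors. Both `a1 > 0` and `a2 > 0` for all valid parameters, so the two
#' nonzero eigenvalues have negative real parts and the equilibrium is
#' marginally stable.
#'
#' @param params an [air_params()] object.
#' @return Named numeric `c(a0, a1, a2)`.
#' @export
routh_hurwitz <- function(params) {
  J <- air_jacobian(as.numeric(nontrivial_equilibrium(params)), params)
  a1 <- -sum(diag(J))
  minor <- function(i, j) J[i, i] * J[j, j] - J[i, j] * J[j, i]
  a2 <- minor(1, 2) + minor(1, 3) + minor(2, 3)
  c(a0 = 1, a1 = a1, a2 = a2)
}

#' Local stability report at an equilibrium
#'
#' Evaluates the Jacobian, its eigenvalues, and (for the nontrivial
#' equilibrium) the Routh-Hurwitz coefficients. The eigenvalue closest to zero
#' is treated as the structural zero of the conservation constraint when its
#' magnitude is below `1e-9 * max(delta, gamma0, beta0)`.
#'
#' @param params an [air_params()] object.
#' @param which `"nontrivial"` or `"trivial"`.
#' @return A list with `equilibrium`, `jacobian`, `eigenvalues`, `rh_coeffs`
#'   (nontrivial only), and `verdict` (`"unstable"` or `"marginally_stable"`).
#' @export
stability_report <- function(params, which = c("nontrivial", "trivial")) {
  which <- match.arg(which)
  eq <- switch(which,
               trivial = trivial_equilibrium(params),
               nontrivial = nontrivial_equilibrium(params))
  J <- air_jacobian(as.numeric(eq), params)
  ev <- eigen(J, only.values = TRUE)$values
  zero_tol <- 1e-9 * max(params$delta, params$gamma0, params$beta0)
  nonzero <- ev[order(abs(ev), decreasing = TRUE)][1:2]
  verdict <- if (any(Re(ev) > zero_tol)) "unstable" else "marginally_stable"
  out <- list(equilibrium = eq, jacobian = J, eigenvalues = ev,
              nonzero_eigenvalues = nonzero, verdict = verdict)
  if (which == "nontrivial") out$rh_coeffs <- routh_hurwitz(params)
  out
}

#' Lyapunov certificate of global stability
#'
#' After eliminating `I = N - A - R`, the planar dynamics in `(A, R)` admit the
#' Goh-style energy
#' \deqn{V(A,R) = \frac{(R-R^\star)^2}{2N^2} + \frac{\gamma_0}{2N^2\beta_0}
#'   \left[A^2 - (A^\star)^2 - (A^\star)^2\ln\frac{A^2}{(A^\star)^2}\right],}
#' which is positive definite on `(0, N] x [0, N]` with minimum 0 at the
#' nontrivial equilibrium. Its derivative along trajectories,
#' \deqn{\dot V = -\frac{\delta}{N^2}(R-R^\star)^2 -
#'   \frac{\langle k\rangle}{N^3}\left(\gamma_0+\frac{\gamma_0^2}{\beta_0}\right)
#'   (A-A^\star)^2 (A+A^\star),}
#' is non-positive everywhere and vanishes only at the equilibrium, ruling out
#' limit cycles: every trajectory with `A0 > 0` converges to the nontrivial
#' equilibrium. The cubic term is evaluated as the sign-definite product
#' `(A - A*)^2 (A + A*)` so rounding cannot flip its sign near `A*`.
#'
#' @param A,R active and refractory counts; `A` must be positive (the
#'   logarithm in `V` is undefined at `A = 0`), `R` in `[0, N]`. Vectorized.
#' @param params an [air_params()] object.
#' @return `lyapunov_value()`: dimensionless energy; `lyapunov_rate()`: its
#'   time derivative along the flow (1/s).
#' @export
lyapunov_value <- function(A, R, params) {
  if (any(A <= 0)) stop("`A` must be positive (log term)", call. = FALSE)
  if (any(R < 0)) stop("`R` must be non-negative", call. = FALSE)
  eq <- nontrivial_equilibrium(params)
  N <- params$N
  (R - eq$R)^2 / (2 * N^2) + params$gamma0 / (2 * N^2 * params$beta0) *
    (A^2 - eq$A^2 - eq$A^2 * log(A^2 / eq$A^2))
}

#' @rdname lyapunov_value
#' @export
lyapunov_rate <- function(A, R, params) {
  if (any(A <= 0)) stop("`A` must be positive", call. = FALSE)
  if (any(R < 0)) stop("`R` must be non-negative", call. = FALSE)
  eq <- nontrivial_equilibrium(params)
  N <- params$N
  -params$delta / N^2 * (R - eq$R)^2 -
    kbar(params) / N^3 *
    (params$gamma0 + params$gamma0^2 / params$beta0) *
    (A - eq$A)^2 * (A + eq$A)
}

#' Fit a power-law scaling exponent on the log-log scale
#'
#' Ordinary least squares of `log(value)` on `log(size)`, the standard
#' allometric fit. Used both on model equilibria (steady-state activity versus
#' colony size) and on measured per-colony quantities (edge counts versus
#' size).
#'
#' @param sizes numeric vector of sizes (>= 3 distinct values).
#' @param values positive quantities, same length as `sizes`.
#' @return A list with `exponent` (slope), `intercept` (on the log scale),
#'   `prefactor` (`exp(intercept)`), and `r_squared`.
#' @examples
#' fit_scaling_exponent(c(10, 100, 1000), 2 * c(10, 100, 1000)^0.75)$exponent
#' @export
fit_scaling_exponent <- function(sizes, values) {
  if (length(sizes) != length(values)) {
    stop("`sizes` and `values` must have equal length", call. = FALSE)
  }
  if (length(unique(sizes)) < 3) {
    stop("need at least 3 distinct sizes to fit a scaling exponent",
         call. = FALSE)
  }
  if (any(values <= 0) || any(sizes <= 0)) {
    stop("`sizes` and `values` must be positive for a log-log fit",
         call. = FALSE)
  }
  fit <- stats::lm(log(values) ~ log(sizes))
  co <- stats::coef(fit)
  ss_tot <- sum((log(values) - mean(log(values)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(exponent = unname(co[2]), intercept = unname(co[1]),
       prefactor = exp(unname(co[1])),
       r_squared = r2)
}
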