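#' Simulation parameters for a clustered population
#'
#' Collects every scalar that governs the data-generating process and the
#' prediction experiment. Defaults are the base combination of the simulation
#' study: 500 clinics with log-normal sizes (median 65, log-scale SD ln 2),
#' random-intercept variance `tau0_sq = 1`, random-slope variance
#' `tau1_sq = 0.25`, common random-effect correlation `rho = 0.3`, no unknown
#' predictor (`beta2 = 0`) and no volume effect (`gamma = 0`), residual share
#' `alpha = 0.2` of the total outcome variance, update interval `theta = 500`
#' and outcome-incorporation probability 0.8.
#'
#' By convention, when `beta2 = 0` the random slope on the unknown predictor
#' is switched off (`tau2_sq = 0`); when `beta2 != 0`, `tau2_sq` defaults to
#' `tau1_sq`. Pass `tau2_sq` explicitly to override.
#'
#' @param n_clinics Number of clinics (clusters) in the population.
#' @param mu_N Location of log clinic size; `exp(mu_N)` is the median size.
#' @param sigma_N Scale (SD) of log clinic size.
#' @param tau0_sq,tau1_sq,tau2_sq Variances of the random intercept and the
#'   random slopes on `x1` and `x2`.
#' @param rho Common correlation among all random-effect pairs.
#' @param beta0,beta1,beta2 Fixed effects: overall intercept (held at 0),
#'   slope of the known predictor `x1` (held at 1 so other effects are
#'   relative to it), and slope of the unknown predictor `x2`.
#' @param gamma Coefficient of the standardized log-volume effect `f(N_i)`.
#' @param alpha Residual share of the total outcome variance,
#'   `alpha = sigma_eps^2 / sigma_Y^2`, in (0, 1).
#' @param quad1,quad2 Optional quadratic coefficients on `x1^2`, `x2^2`
#'   (model-misspecification scenarios; default 0).
#' @param theta Update interval: number of predictions between refits of a
#'   dynamic model.
#' @param p_incorporate Probability that a predicted patient's outcome is
#'   incorporated into the training data at the next update.
#' @param training_quintile_counts Clinics drawn per size quintile for the
#'   training sample, smallest to largest quintile.
#' @param seed Default RNG seed used by generators when no seed is supplied.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [generate_population()], [compute_residual_variance()]
#' @examples
#' p <- sim_params()                       # base combination
#' p2 <- sim_params(tau0_sq = 2, theta = 1000)
#' @export
sim_params <- function(n_clinics = 500L,
                       mu_N = log(65),
                       sigma_N = log(2),
                       tau0_sq = 1,
                       tau1_sq = 0.25,
                       tau2_sq = NULL,
                       rho = 0.3,
                       beta0 = 0,
                       beta1 = 1,
                       beta2 = 0,
                       gamma = 0,
                       alpha = 0.2,
                       quad1 = 0,
                       quad2 = 0,
                       theta = 500L,
                       p_incorporate = 0.8,
                       training_quintile_counts = c(6L, 6L, 3L, 3L, 2L),
                       seed = 1L) {
  if (is.null(tau2_sq)) {
    tau2_sq <- if (beta2 == 0) 0 else tau1_sq
  }
  p <- structure(
    list(n_clinics = as.integer(n_clinics), mu_N = mu_N, sigma_N = sigma_N,
         tau0_sq = tau0_sq, tau1_sq = tau1_sq, tau2_sq = tau2_sq, rho = rho,
         beta0 = beta0, beta1 = beta1, beta2 = beta2, gamma = gamma,
         alpha = alpha, quad1 = quad1, quad2 = quad2,
         theta = as.integer(theta), p_incorporate = p_incorporate,
         training_quintile_counts = as.integer(training_quintile_counts),
         seed = as.integer(seed)),
    class = "sim_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_clinics < 1L) stop("n_clinics must be a positive integer")
  if (p$sigma_N < 0) stop("sigma_N must be non-negative")
  for (nm in c("tau0_sq", "tau1_sq", "tau2_sq")) {
    if (p[[nm]] < 0) stop(nm, " must be non-negative")
  }
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (p$p_incorporate < 0 || p$p_incorporate > 1) {
    stop("p_incorporate must lie in [0, 1]")
  }
  if (p$theta < 1L) stop("theta must be at least 1")
  if (length(p$training_quintile_counts) != 5L ||
      any(p$training_quintile_counts < 0L)) {
    stop("training_quintile_counts must be 5 non-negative counts")
  }
  # the implied random-effects covariance must be positive semidefinite
  ranef_cov(p)
  invisible(p)
}

#' Random-effects covariance matrix implied by the parameters
#'
#' Builds the 3x3 covariance of `(b0, b1, b2)` with diagonal
#' `(tau0_sq, tau1_sq, tau2_sq)` and every off-diagonal equal to
#' `rho * tau_a * tau_b`. Zero-variance components are dropped before the
#' positive-semidefiniteness check and reported as exact structural zeros
#' (the full matrix is singular whenever any tau is 0).
#'
#' @param params A [sim_params()] object.
#' @return The 3x3 covariance matrix with an attribute `"active"` giving the
#'   indices of the non-degenerate components.
#' @examples
#' ranef_cov(sim_params())
#' @export
ranef_cov <- function(params) {
  tau <- sqrt(c(params$tau0_sq, params$tau1_sq, params$tau2_sq))
  full <- params$rho * (tau %o% tau)
  diag(full) <- tau^2
  active <- which(tau > 0)
  if (length(active) > 1L) {
    ev <- eigen(full[active, active, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev))) {
      stop("random-effects covariance is not positive semidefinite for ",
           "rho = ", params$rho, " with ", length(active),
           " active components")
    }
  }
  structure(full, active = active,
            dimnames = list(c("b0", "b1", "b2"), c("b0", "b1", "b2")))
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Clustered-population simulation parameters\n")
  cat(sprintf("  clinics: %d, size ~ ceiling(exp(N(%.3f, %.3f^2)))\n",
              x$n_clinics, x$mu_N, x$sigma_N))
  cat(sprintf("  tau0^2 = %g, tau1^2 = %g, tau2^2 = %g, rho = %g\n",
              x$tau0_sq, x$tau1_sq, x$tau2_sq, x$rho))
  cat(sprintf("  beta = (%g, %g, %g), gamma = %g, alpha = %g\n",
              x$beta0, x$beta1, x$beta2, x$gamma, x$alpha))
  if (x$quad1 != 0 || x$quad2 != 0) {
    cat(sprintf("  quadratic terms: %g * x1^2, %g * x2^2\n", x$quad1, x$quad2))
  }
  cat(sprintf("  dynamic updating: theta = %d, p_incorporate = %g\n",
              x$theta, x$p_incorporate))
  cat(sprintf("  training sample: %s clinics by size quintile\n",
              paste(x$training_quintile_counts, collapse = ",")))
  invisible(x)
}
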