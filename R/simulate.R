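#' Draw clinic sizes from the ceiling-log-normal size distribution
#'
#' Sizes are `ceiling(exp(N(mu_N, sigma_N^2)))`, so the population holds many
#' small clinics and a few very large ones; at the defaults (median 65,
#' log-scale SD ln 2) sizes span roughly 10 to 500 patients.
#'
#' @param params A [sim_params()] object.
#' @param seed Base seed; the draw uses the `"sizes"` substream.
#' @return Integer vector of `n_clinics` sizes, each at least 1.
#' @examples
#' sizes <- draw_clinic_sizes(sim_params(), seed = 1)
#' median(sizes)
#' @export
draw_clinic_sizes <- function(params, seed = params$seed) {
  validate_params(params)
  with_stream(seed, "sizes", {
    as.integer(ceiling(exp(stats::rnorm(params$n_clinics, params$mu_N,
                                        params$sigma_N))))
  })
}

#' Assign size quintiles to clinics
#'
#' Clinics are ranked by size (ties broken by position, i.e. clinic id, so
#' the partition is deterministic) and split into five groups of as equal
#' size as possible, labelled 1 (smallest) to 5 (largest).
#'
#' @param sizes Vector of clinic sizes.
#' @return Integer vector of quintile labels in 1..5, one per clinic.
#' @examples
#' assign_quintiles(c(10, 20, 30, 40, 50))
#' @export
assign_quintiles <- function(sizes) {
  n <- length(sizes)
  if (n < 5L) stop("need at least 5 clinics to form size quintiles")
  ord <- order(sizes, seq_along(sizes))
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  as.integer(floor((pos - 1L) * 5L / n) + 1L)
}

#' Draw clinic-level random intercepts and slopes
#'
#' Rows are i.i.d. multivariate normal with mean zero and the covariance of
#' [ranef_cov()]: variances `(tau0_sq, tau1_sq, tau2_sq)` and common
#' correlation `rho`. Components with zero variance are returned as exact
#' zeros. A symmetric eigendecomposition square root is used so boundary
#' correlations (`rho = 1`) are handled.
#'
#' @param params A [sim_params()] object.
#' @param n_clinics Number of rows to draw (defaults to `params$n_clinics`).
#' @param seed Base seed; the draw uses the `"ranef"` substream.
#' @return An `n_clinics` x 3 matrix with columns `b0`, `b1`, `b2`.
#' @examples
#' b <- draw_random_effects(sim_params(), 1000, seed = 1)
#' round(cov(b), 2)
#' @export
draw_random_effects <- function(params, n_clinics = params$n_clinics,
                                seed = params$seed) {
  covm <- ranef_cov(params)
  active <- attr(covm, "active")
  b <- matrix(0, nrow = n_clinics, ncol = 3,
              dimnames = list(NULL, c("b0", "b1", "b2")))
  if (length(active) > 0L) {
    sub <- covm[active, active, drop = FALSE]
    ed <- eigen(sub, symmetric = TRUE)
    root <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
    z <- with_stream(seed, "ranef", {
      matrix(stats::rnorm(n_clinics * length(active)), nrow = n_clinics)
    })
    b[, active] <- z %*% root
  }
  b
}

#' Standardized log-volume effect
#'
#' Computes `f(N_i) = Omega * (ln N_i - mean(ln N_i))`, with the scaling
#' factor `Omega` set to the reciprocal of the empirical SD of `ln N_i` over
#' the population at hand, so `f` has mean exactly 0 and SD exactly 1. The
#' empirical scale is used (rather than `sigma_N`) because the ceiling in the
#' size distribution distorts the theoretical log-scale SD.
#'
#' @param sizes Vector of clinic sizes (all at least 1).
#' @return Numeric vector of volume effects; if all sizes are equal the
#'   vector is all zeros with attribute `degenerate = TRUE`.
#' @examples
#' compute_volume_effect(c(exp(1), exp(3)))
#' @export
compute_volume_effect <- function(sizes) {
  if (any(sizes < 1)) stop("all clinic sizes must be at least 1")
  ln <- log(sizes)
  s <- stats::sd(ln)
  if (!is.finite(s) || s == 0) {
    return(structure(rep(0, length(sizes)), degenerate = TRUE))
  }
  (ln - mean(ln)) / s
}

#' Analytic residual variance calibrated to the residual share alpha
#'
#' The residual variance is `alpha / (1 - alpha) * V`, where `V` is the
#' analytic variance of the linear predictor
#' `b0 + (beta1 + b1) x1 + (beta2 + b2) x2 + gamma f(N) + quad1 x1^2 +
#' quad2 x2^2` under independence of the covariates, the random effects and
#' the volume effect (all cross-covariances vanish because the covariates
#' have mean zero):
#' `V = tau0^2 + (beta1^2 + tau1^2) + (beta2^2 + tau2^2) + gamma^2 +
#' 2 quad1^2 + 2 quad2^2`, with `Var(x1) = Var(x2) = Var(f) = 1` and
#' `Var(c x^2) = 2 c^2` for standard-normal `x`. This makes the calibration
#' exact and replicate-independent. At the base combination `V = 2.25` and
#' `sigma_eps^2 = 0.5625`, i.e. `tau0 / sigma_eps = 4/3`.
#'
#' @param params A [sim_params()] object.
#' @return The residual variance `sigma_eps^2`.
#' @examples
#' compute_residual_variance(sim_params())  # 0.5625
#' @export
compute_residual_variance <- function(params) {
  validate_params(params)
  v <- params$tau0_sq +
    (params$beta1^2 + params$tau1_sq) +
    (params$beta2^2 + params$tau2_sq) +
    params$gamma^2 +
    2 * params$quad1^2 + 2 * params$quad2^2
  params$alpha / (1 - params$alpha) * v
}

#' Generate a clustered population
#'
#' Composes the size, random-effect, covariate and residual draws into a full
#' population: clinic sizes from the ceiling-log-normal distribution,
#' clinic-level random effects, standard-normal patient covariates `x1`
#' (known predictor) and `x2` (unknown predictor), the standardized
#' log-volume effect, and outcomes
#' `y = b0 + (beta1 + b1) x1 + (beta2 + b2) x2 + gamma f(N) +
#' quad1 x1^2 + quad2 x2^2 + eps` with `eps ~ N(0, sigma_eps^2)` calibrated
#' by [compute_residual_variance()]. The true conditional mean (`mu_true`,
#' the outcome minus its residual) is stored per patient, as is the residual,
#' so `y == mu_true + eps` exactly. Each component uses its own named RNG
#' substream; the same parameters and seed reproduce the population
#' bit-identically.
#'
#' @param params A [sim_params()] object.
#' @param seed Base seed (defaults to `params$seed`).
#' @return An object of class `population`: a list with `params`, `seed`,
#'   `sigma_eps_sq`, a `clinics` data frame (`clinic_id`, `size`, `quintile`,
#'   `b0`, `b1`, `b2`, `volume_effect`) and a `patients` data frame
#'   (`clinic_id`, `patient_id`, `quintile`, `x1`, `x2`, `y`, `mu_true`,
#'   `eps`).
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 50), seed = 1)
#' pop
#' @export
generate_population <- function(params, seed = params$seed) {
  validate_params(params)
  sizes <- draw_clinic_sizes(params, seed)
  quintile <- assign_quintiles(sizes)
  b <- draw_random_effects(params, params$n_clinics, seed)
  f <- compute_volume_effect(sizes)
  sigma_eps_sq <- compute_residual_variance(params)

  clinics <- data.frame(clinic_id = seq_len(params$n_clinics), size = sizes,
                        quintile = quintile, b0 = b[, 1], b1 = b[, 2],
                        b2 = b[, 3], volume_effect = as.numeric(f))

  n <- sum(sizes)
  cid <- rep.int(clinics$clinic_id, sizes)
  x <- with_stream(seed, "covariates", {
    matrix(stats::rnorm(2 * n), ncol = 2)
  })
  eps <- with_stream(seed, "residuals", {
    stats::rnorm(n, sd = sqrt(sigma_eps_sq))
  })
  x1 <- x[, 1]
  x2 <- x[, 2]
  mu_true <- clinics$b0[cid] +
    (params$beta1 + clinics$b1[cid]) * x1 +
    (params$beta2 + clinics$b2[cid]) * x2 +
    params$gamma * clinics$volume_effect[cid] +
    params$quad1 * x1^2 + params$quad2 * x2^2 +
    params$beta0

  patients <- data.frame(
    clinic_id = cid,
    patient_id = sequence(sizes),
    quintile = clinics$quintile[cid],
    x1 = x1, x2 = x2,
    y = mu_true + eps,
    mu_true = mu_true,
    eps = eps)

  structure(list(params = params, seed = as.integer(seed),
                 sigma_eps_sq = sigma_eps_sq, clinics = clinics,
                 patients = patients),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Clustered population: %d clinics, %d patients\n",
              nrow(x$clinics), nrow(x$patients)))
  cat(sprintf("  clinic size: median %d, range %d-%d\n",
              as.integer(stats::median(x$clinics$size)),
              min(x$clinics$size), max(x$clinics$size)))
  cat(sprintf("  residual variance sigma_eps^2 = %.4f (alpha = %g)\n",
              x$sigma_eps_sq, x$params$alpha))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Look up true-model predictions for patients
#'
#' The "true" model is the data-generating model without its residual term;
#' its prediction for a patient is the stored true conditional mean.
#'
#' @param population A [generate_population()] object.
#' @param rows Integer row indices into `population$patients`.
#' @return Numeric vector of `mu_true` values.
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 50), seed = 1)
#' true_model_predict(pop, 1:5)
#' @export
true_model_predict <- function(population, rows) {
  stopifnot(inherits(population, "population"))
  if (any(rows < 1L | rows > nrow(population$patients))) {
    stop("unknown patient rows requested")
  }
  population$patients$mu_true[rows]
}

#' Write a population to plain-text files
#'
#' Writes `clinics.csv`, `patients.csv` and a `params.json` sidecar holding
#' the simulation parameters, seed and calibrated residual variance.
#'
#' @param population A [generate_population()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(population$clinics, file.path(dir, "clinics.csv"),
                   row.names = FALSE)
  cols <- c("clinic_id", "patient_id", "x1", "x2", "y", "mu_true")
  utils::write.csv(population$patients[, cols],
                   file.path(dir, "patients.csv"), row.names = FALSE)
  meta <- c(unclass(population$params),
            list(sigma_eps_sq = population$sigma_eps_sq,
                 generation_seed = population$seed))
  jsonlite::write_json(meta, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a population written by [write_population()]
#'
#' @param dir Directory containing `clinics.csv`, `patients.csv`,
#'   `params.json`.
#' @return A `population` object (patient residuals and quintiles are
#'   reconstructed from the stored columns).
#' @export
read_population <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  params <- sim_params(
    n_clinics = meta$n_clinics, mu_N = meta$mu_N, sigma_N = meta$sigma_N,
    tau0_sq = meta$tau0_sq, tau1_sq = meta$tau1_sq, tau2_sq = meta$tau2_sq,
    rho = meta$rho, beta0 = meta$beta0, beta1 = meta$beta1,
    beta2 = meta$beta2, gamma = meta$gamma, alpha = meta$alpha,
    quad1 = meta$quad1, quad2 = meta$quad2, theta = meta$theta,
    p_incorporate = meta$p_incorporate,
    training_quintile_counts = meta$training_quintile_counts,
    seed = meta$seed)
  clinics <- utils::read.csv(file.path(dir, "clinics.csv"))
  patients <- utils::read.csv(file.path(dir, "patients.csv"))
  patients$quintile <- clinics$quintile[match(patients$clinic_id,
                                              clinics$clinic_id)]
  patients$eps <- patients$y - patients$mu_true
  patients <- patients[, c("clinic_id", "patient_id", "quintile", "x1", "x2",
                           "y", "mu_true", "eps")]
  structure(list(params = params, seed = as.integer(meta$generation_seed),
                 sigma_eps_sq = meta$sigma_eps_sq, clinics = clinics,
                 patients = patients),
            class = "population")
}
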