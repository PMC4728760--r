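#' Define a prediction-model specification
#'
#' The three model families of the simulation study are an ordinary linear
#' model (fixed intercept and slope on the known predictor `x1`), a mixed
#' model adding a clinic-level random intercept, and a mixed model adding a
#' random intercept and a random slope on `x1`. Each can optionally include
#' the observable clinic-size quintile as a categorical fixed effect
#' (treatment coding, quintile 1 as reference), used when the outcome depends
#' on clinic volume. The link is the identity.
#'
#' @param name Short label used in traces and result tables.
#' @param fixed Fixed-effect terms, a subset of `c("intercept", "x1")`.
#' @param random Random-effect terms, a subset of `c("intercept", "x1")`
#'   (empty for a fixed-effects-only model).
#' @param quintile Logical; include the 5-level size-quintile factor as a
#'   fixed effect.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("ri", random = "intercept")
#' @export
model_spec <- function(name, fixed = c("intercept", "x1"),
                       random = character(0), quintile = FALSE) {
  fixed <- match.arg(fixed, c("intercept", "x1"), several.ok = TRUE)
  if (length(random)) {
    random <- match.arg(random, c("intercept", "x1"), several.ok = TRUE)
  }
  structure(list(name = name, fixed = fixed, random = random,
                 quintile = isTRUE(quintile)),
            class = "model_spec")
}

#' The three model specifications of the simulation study
#'
#' @param quintile Logical; include the size-quintile fixed effect in all
#'   three models.
#' @return Named list of [model_spec()] objects: `linear`, `ri` (random
#'   intercept), `ris` (random intercept and slope).
#' @examples
#' names(default_model_specs())
#' @export
default_model_specs <- function(quintile = FALSE) {
  list(linear = model_spec("linear", quintile = quintile),
       ri = model_spec("ri", random = "intercept", quintile = quintile),
       ris = model_spec("ris", random = c("intercept", "x1"),
                        quintile = quintile))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': fixed = {%s%s}, random = {%s}\n", x$name,
              paste(x$fixed, collapse = ", "),
              if (x$quintile) ", quintile" else "",
              if (length(x$random)) paste(x$random, collapse = ", ")
              else "none"))
  invisible(x)
}

# Fixed-effect design matrix for a spec. Quintile uses treatment coding with
# quintile 1 as reference; levels 1..5 are always declared so a level absent
# from the data yields an all-zero column (dropped at fit time, coefficient
# pinned to 0, contributing the reference level at prediction time).
design_matrix <- function(spec, data) {
  cols <- list()
  if ("intercept" %in% spec$fixed) cols[["(Intercept)"]] <- rep(1, nrow(data))
  if ("x1" %in% spec$fixed) cols[["x1"]] <- data$x1
  if (spec$quintile) {
    for (q in 2:5) {
      cols[[paste0("quintile", q)]] <- as.numeric(data$quintile == q)
    }
  }
  do.call(cbind, cols)
}

random_design <- function(spec, data) {
  cols <- list()
  if ("intercept" %in% spec$random) cols[["intercept"]] <- rep(1, nrow(data))
  if ("x1" %in% spec$random) cols[["x1"]] <- data$x1
  do.call(cbind, cols)
}

# Per-cluster sufficient statistics for the REML criterion: totals X'X, X'y,
# y'y plus, per cluster, Z'Z, Z'X and Z'y (Z columns are a subset of the
# model's column space). One pass over the data; every criterion evaluation
# afterwards is O(n_clusters).
suffstats <- function(X, Z, y, cluster) {
  fac <- factor(cluster)
  M <- cbind(Z, X, y)
  K <- ncol(M)
  q <- ncol(Z)
  p <- ncol(X)
  idx <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  keep <- idx[, 1] <= q  # only z-rows of the crossproduct are needed per cluster
  zidx <- idx[keep, , drop = FALSE]
  P <- M[, zidx[, 1], drop = FALSE] * M[, zidx[, 2], drop = FALSE]
  cs <- rowsum(P, fac)

  get_col <- function(i, j) {   # z-row i, M-column j (i <= q, j >= i)
    cs[, which(zidx[, 1] == i & zidx[, 2] == j)]
  }
  # per-cluster pieces, as m-length vectors / m x p matrices
  out <- list(
    clinic_ids = rownames(cs),
    m = nrow(cs), n = length(y), p = p, q = q,
    XtX = crossprod(X), Xty = crossprod(X, y)[, 1], yty = sum(y * y))
  out$Szz <- lapply(seq_len(q), function(i) {
    lapply(i:q, function(j) get_col(i, j))
  })
  out$ZX <- lapply(seq_len(q), function(i) {
    mat <- sapply(seq_len(p), function(j) get_col(i, q + j))
    matrix(mat, nrow = out$m, ncol = p)
  })
  out$zy <- lapply(seq_len(q), function(i) get_col(i, q + p + 1))
  out
}

# Penalized REML criterion and by-products at a fixed relative covariance
# Delta = G / sigma^2. Returns the criterion plus (on request) beta, the
# profiled sigma^2, per-cluster posterior-mode random effects and the
# log-determinant pieces. Supports q = 1 and q = 2 with closed-form 2x2
# inverses, fully vectorized over clusters.
reml_eval <- function(ss, Delta, penalty_df = 1.5, want_fit = FALSE) {
  n <- ss$n; p <- ss$p; q <- ss$q; m <- ss$m
  if (q == 1L) {
    d <- Delta[1, 1]
    s11 <- ss$Szz[[1]][[1]]
    Mv <- 1 / d + s11
    W11 <- 1 / Mv
    ld <- sum(log1p(d * s11))
    corrA <- crossprod(ss$ZX[[1]], ss$ZX[[1]] * W11)
    corra <- crossprod(ss$ZX[[1]], W11 * ss$zy[[1]])[, 1]
    corry <- sum(W11 * ss$zy[[1]]^2)
    logdetDelta <- log(d)
  } else {
    L <- Delta
    det_d <- L[1, 1] * L[2, 2] - L[1, 2]^2
    Di11 <- L[2, 2] / det_d; Di22 <- L[1, 1] / det_d; Di12 <- -L[1, 2] / det_d
    s11 <- ss$Szz[[1]][[1]]; s12 <- ss$Szz[[1]][[2]]; s22 <- ss$Szz[[2]][[1]]
    M11 <- Di11 + s11; M12 <- Di12 + s12; M22 <- Di22 + s22
    detM <- M11 * M22 - M12^2
    W11 <- M22 / detM; W22 <- M11 / detM; W12 <- -M12 / detM
    ld <- m * log(det_d) + sum(log(detM))
    ZX1 <- ss$ZX[[1]]; ZX2 <- ss$ZX[[2]]
    zy1 <- ss$zy[[1]]; zy2 <- ss$zy[[2]]
    corrA <- crossprod(ZX1, ZX1 * W11) + crossprod(ZX1, ZX2 * W12) +
      crossprod(ZX2, ZX1 * W12) + crossprod(ZX2, ZX2 * W22)
    corra <- (crossprod(ZX1, W11 * zy1 + W12 * zy2) +
                crossprod(ZX2, W12 * zy1 + W22 * zy2))[, 1]
    corry <- sum(W11 * zy1^2 + 2 * W12 * zy1 * zy2 + W22 * zy2^2)
    logdetDelta <- log(det_d)
  }
  A <- ss$XtX - corrA
  a <- ss$Xty - corra
  cholA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cholA)) return(list(crit = Inf))
  u <- backsolve(cholA, a, transpose = TRUE)
  r <- max(ss$yty - corry - sum(u^2), 1e-12)
  crit <- (n - p) * (1 + log(2 * pi * r / (n - p))) + ld +
    2 * sum(log(diag(cholA))) - penalty_df * logdetDelta
  if (!want_fit) return(list(crit = crit))

  beta <- backsolve(cholA, u)
  sigma_sq <- r / (n - p)
  # empirical-Bayes conditional modes: b_i = W_i (Z_i'y_i - Z_i'X_i beta)
  if (q == 1L) {
    b <- cbind(W11 * (ss$zy[[1]] - ss$ZX[[1]] %*% beta))
  } else {
    c1 <- ss$zy[[1]] - ss$ZX[[1]] %*% beta
    c2 <- ss$zy[[2]] - ss$ZX[[2]] %*% beta
    b <- cbind(W11 * c1 + W12 * c2, W12 * c1 + W22 * c2)
  }
  list(crit = crit, beta = as.numeric(beta), sigma_sq = sigma_sq, ranef = b)
}

delta_from_par <- function(par, q) {
  if (q == 1L) {
    matrix(exp(2 * par[1]), 1, 1)
  } else {
    L <- matrix(c(exp(par[1]), par[3], 0, exp(par[2])), 2, 2)
    tcrossprod(L)
  }
}

#' Fit a prediction model by least squares or penalized REML
#'
#' Fixed-effects-only specifications are fit by ordinary least squares.
#' Mixed specifications are fit by restricted maximum likelihood with a weak
#' improper Wishart-type penalty `-penalty_df * logdet(Delta)` on the
#' relative random-effects covariance `Delta = G / sigma^2`
#' (`penalty_df = 1.5`, the conventional `nu = q + 2.5` choice), which keeps
#' the estimated covariance positive definite at small cluster counts while
#' its influence vanishes as data accrue. The criterion profiles the fixed
#' effects and residual variance analytically and is evaluated through
#' per-cluster sufficient statistics, so the cost per evaluation is
#' proportional to the number of clusters, not the number of rows. The
#' optimizer is deterministic (golden-section for one variance component,
#' Nelder-Mead with a fixed restart for two), so identical data give
#' identical fits. Cluster-specific effects are empirical-Bayes conditional
#' modes (BLUPs at the estimated variance components).
#'
#' On optimizer failure the fit is retried from an inflated start; if that
#' also fails the best candidate is returned with `converged = FALSE` so
#' callers can fall back (the dynamic engine reuses the previous cycle's
#' fit, a static caller can use the fixed-effects fit).
#'
#' All-zero design columns (e.g. a quintile level absent from the data) are
#' dropped and their coefficients pinned to 0, so predictions for such
#' levels fall back to the reference level.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with columns `y`, `x1`, `clinic_id` and, if the
#'   spec uses quintile fixed effects, `quintile`.
#' @param penalty_df Weight of the log-determinant penalty (0 gives plain
#'   REML).
#' @param delta Optional fixed relative covariance matrix (q x q); skips
#'   optimization and computes the profiled fit at these variance ratios.
#' @return An object of class `dynmix_fit`: `spec`, named fixed-effect
#'   vector `beta`, estimated random-effects covariance `G`, residual
#'   variance `sigma_sq`, relative covariance `delta`, matrix `ranef` of
#'   per-clinic effects (rownames are clinic ids), `n_obs`, `n_clusters`,
#'   `converged`, `fallback_used` and the criterion value.
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 60), seed = 3)
#' fit <- fit_model(model_spec("ri", random = "intercept"), pop$patients)
#' fit
#' @export
fit_model <- function(spec, data, penalty_df = 1.5, delta = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(data) == 0L) stop("training data are empty")
  X <- design_matrix(spec, data)
  full_names <- colnames(X)
  nonzero <- colSums(abs(X)) > 0
  X <- X[, nonzero, drop = FALSE]
  # guard against residual rank deficiency (beyond all-zero columns)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  y <- data$y

  expand_beta <- function(beta_fit) {
    beta <- stats::setNames(rep(0, length(full_names)), full_names)
    beta[colnames(X)] <- beta_fit
    beta
  }

  if (length(spec$random) == 0L) {
    ls <- stats::lm.fit(X, y)
    rss <- sum(ls$residuals^2)
    dfr <- length(y) - ncol(X)
    return(structure(list(
      spec = spec, beta = expand_beta(ls$coefficients),
      G = matrix(0, 0, 0), sigma_sq = if (dfr > 0) rss / dfr else 0,
      delta = matrix(0, 0, 0),
      ranef = matrix(0, 0, 0), n_obs = length(y),
      n_clusters = length(unique(data$clinic_id)), converged = TRUE,
      fallback_used = FALSE, criterion = NA_real_, penalty_df = penalty_df),
      class = "dynmix_fit"))
  }

  if (length(unique(data$clinic_id)) < 2L) {
    stop("mixed-model specifications need at least 2 clinics")
  }
  Z <- random_design(spec, data)
  ss <- suffstats(X, Z, y, data$clinic_id)
  q <- ss$q

  converged <- TRUE
  fallback_used <- FALSE
  if (!is.null(delta)) {
    Delta <- matrix(delta, q, q)
  } else if (q == 1L) {
    opt <- stats::optimize(function(u) {
      reml_eval(ss, delta_from_par(u, 1L), penalty_df)$crit
    }, interval = c(-13, 6), tol = 1e-10)
    Delta <- delta_from_par(opt$minimum, 1L)
  } else {
    obj <- function(par) reml_eval(ss, delta_from_par(par, q), penalty_df)$crit
    opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0) {
      retry <- stats::optim(opt$par + 1, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12))
      if (retry$value <= opt$value) opt <- retry
      converged <- opt$convergence == 0
      fallback_used <- !converged
    }
    Delta <- delta_from_par(opt$par, q)
  }

  fin <- reml_eval(ss, Delta, penalty_df, want_fit = TRUE)
  ranef <- fin$ranef
  rownames(ranef) <- ss$clinic_ids
  colnames(ranef) <- spec$random
  colnames(Delta) <- rownames(Delta) <- spec$random
  structure(list(
    spec = spec, beta = expand_beta(fin$beta), G = fin$sigma_sq * Delta,
    sigma_sq = fin$sigma_sq, delta = Delta, ranef = ranef, n_obs = ss$n,
    n_clusters = ss$m, converged = converged, fallback_used = fallback_used,
    criterion = fin$crit, penalty_df = penalty_df),
    class = "dynmix_fit")
}

#' @export
print.dynmix_fit <- function(x, ...) {
  cat(sprintf("dynmix fit '%s' (%d obs, %d clinics)\n", x$spec$name,
              x$n_obs, x$n_clusters))
  cat("  fixed effects:",
      paste(sprintf("%s = %.4f", names(x$beta), x$beta), collapse = ", "),
      "\n")
  if (length(x$spec$random)) {
    cat(sprintf("  random effects (%s): variances %s, sigma^2 = %.4f\n",
                paste(x$spec$random, collapse = " + "),
                paste(sprintf("%.4f", diag(x$G)), collapse = ", "),
                x$sigma_sq))
  } else {
    cat(sprintf("  residual variance sigma^2 = %.4f\n", x$sigma_sq))
  }
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' Returns the fixed-effects prediction plus, for clinics present in the
#' fitting data, the clinic's empirical-Bayes random-effect contribution.
#' Novel clinics are predicted at the hypothetical mean cluster
#' (`b_i = 0`); quintile levels unseen at fit time contribute the reference
#' level.
#'
#' @param object A [fit_model()] result.
#' @param newdata Data frame with `x1`, `clinic_id` and (if needed)
#'   `quintile`.
#' @param ... Unused.
#' @return Numeric vector of point predictions.
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 60), seed = 3)
#' fit <- fit_model(model_spec("linear"), pop$patients)
#' predict(fit, pop$patients[1:5, ])
#' @export
predict.dynmix_fit <- function(object, newdata, ...) {
  X <- design_matrix(object$spec, newdata)
  pred <- as.numeric(X %*% object$beta[colnames(X)])
  if (length(object$spec$random) && nrow(object$ranef)) {
    idx <- match(as.character(newdata$clinic_id), rownames(object$ranef))
    known <- !is.na(idx)
    if (any(known)) {
      Zn <- random_design(object$spec, newdata)
      contrib <- rowSums(Zn[known, , drop = FALSE] *
                           object$ranef[idx[known], , drop = FALSE])
      pred[known] <- pred[known] + contrib
    }
  }
  pred
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, variance components and per-clinic random effects
#' for audit and regression testing.
#'
#' @param fit A [fit_model()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dynmix_fit"))
  out <- list(
    name = fit$spec$name,
    fixed = as.list(fit$beta),
    G = if (length(fit$G)) as.data.frame(fit$G) else NULL,
    sigma_sq = fit$sigma_sq,
    ranef = if (nrow(fit$ranef)) {
      cbind(data.frame(clinic_id = rownames(fit$ranef)),
            as.data.frame(fit$ranef))
    } else NULL,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    converged = fit$converged, fallback_used = fit$fallback_used)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
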