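test_that("fixed-effects-only fits are ordinary least squares", {
  d <- data.frame(clinic_id = rep(1:3, each = 4), x1 = 0, y = 2.5,
                  quintile = 1L)
  fit <- fit_model(model_spec("icpt", fixed = "intercept"), d)
  expect_equal(unname(fit$beta["(Intercept)"]), 2.5)
  expect_equal(fit$sigma_sq, 0)

  d2 <- toy_clustered(n_per = 10, m = 3, tau0 = 0, sigma = 0.5, seed = 2)
  fit2 <- fit_model(model_spec("linear"), d2)
  ls <- stats::lm(y ~ x1, d2)
  expect_equal(unname(fit2$beta), unname(coef(ls)), tolerance = 1e-10)
  expect_equal(fit2$sigma_sq, summary(ls)$sigma^2, tolerance = 1e-10)
})

test_that("BLUPs at known variance ratios match the shrinkage closed form", {
  d <- toy_clustered(n_per = 6, m = 3, tau0 = 1, sigma = 0.7, seed = 5)
  delta <- 1.3 / 0.49  # tau0^2 / sigma^2 held fixed
  fit <- fit_model(model_spec("ri", random = "intercept"), d, delta = delta)
  resid <- d$y - predict(fit_model(model_spec("ri", random = "intercept"),
                                   d, delta = delta),
                         transform(d, clinic_id = -1))  # fixed part only
  for (cl in 1:3) {
    n_i <- sum(d$clinic_id == cl)
    rbar <- mean(resid[d$clinic_id == cl])
    shrunk <- n_i * delta / (1 + n_i * delta) * rbar
    expect_equal(unname(fit$ranef[as.character(cl), "intercept"]), shrunk,
                 tolerance = 1e-10)
  }
})

test_that("the criterion equals lme4's profiled REML deviance", {
  skip_if_not_installed("lme4")
  d <- toy_clustered(n_per = 12, m = 6, tau0 = 0.8, tau1 = 0.4,
                     sigma = 0.6, seed = 3)
  devfun <- lme4::lmer(y ~ x1 + (1 + x1 | clinic_id), d, REML = TRUE,
                       devFunOnly = TRUE)
  # evaluate both criteria at several relative covariances
  for (th in list(c(1, 0.5, 0.2), c(0.3, 0.1, 0.8), c(2, 0, 1))) {
    L <- matrix(c(th[1], th[2], 0, th[3]), 2, 2)
    Delta <- tcrossprod(L)
    mine <- fit_model(model_spec("ris", random = c("intercept", "x1")), d,
                      penalty_df = 0, delta = Delta)$criterion
    # lme4 theta: column-major lower triangle of the Cholesky factor
    expect_equal(mine, devfun(c(th[1], th[2], th[3])), tolerance = 1e-8)
  }
})

test_that("penalized REML matches the brute-force dense oracle", {
  # random-intercept model, 24 rows
  d1 <- toy_clustered(n_per = 6, m = 4, tau0 = 1, sigma = 0.7, seed = 7)
  fit1 <- fit_model(model_spec("ri", random = "intercept"), d1)
  or1 <- dense_reml_fit(d1$y, cbind(1, d1$x1), cbind(rep(1, nrow(d1))),
                        d1$clinic_id, penalty_df = 1.5)
  expect_equal(fit1$criterion, or1$criterion, tolerance = 1e-3)
  expect_equal(unname(fit1$beta), or1$beta, tolerance = 1e-3)
  expect_equal(fit1$G[1, 1], or1$G[1, 1], tolerance = 1e-3)
  expect_equal(fit1$sigma_sq, or1$sigma_sq, tolerance = 1e-3)

  # random intercept + slope, 30 rows
  d2 <- toy_clustered(n_per = 6, m = 5, tau0 = 1, tau1 = 0.5, sigma = 0.6,
                      seed = 8)
  fit2 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d2)
  or2 <- dense_reml_fit(d2$y, cbind(1, d2$x1), cbind(1, d2$x1),
                        d2$clinic_id, penalty_df = 1.5)
  expect_equal(fit2$criterion, or2$criterion, tolerance = 1e-3)
  expect_equal(unname(fit2$beta), or2$beta, tolerance = 1e-3)
  expect_equal(unname(fit2$G), unname(or2$G), tolerance = 5e-3)
})

test_that("unpenalized fits agree with lme4 and the penalty vanishes", {
  skip_if_not_installed("lme4")
  pop <- base_pop()
  ids <- select_training_clinics(pop, seed = 101)
  d <- pop$patients[pop$patients$clinic_id %in% ids, ]

  fit0 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d,
                    penalty_df = 0)
  lfit <- lme4::lmer(y ~ x1 + (1 + x1 | clinic_id), d, REML = TRUE)
  expect_equal(unname(fit0$beta), unname(lme4::fixef(lfit)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit0$G[1, 1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit0$G[2, 2], vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit0$sigma_sq, vc$vcov[4], tolerance = 1e-3)
  # BLUPs agree too
  re <- lme4::ranef(lfit)$clinic_id
  expect_equal(unname(fit0$ranef[rownames(re), ]), unname(as.matrix(re)),
               tolerance = 1e-3)

  # regularization influence is modest at 20 clinics (order 1.5 / (m/2))
  # and vanishes as clusters accrue: < 1% at the full 500-clinic population
  fit15 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d)
  expect_equal(fit15$G[1, 1], fit0$G[1, 1], tolerance = 0.15)
  expect_equal(unname(fit15$beta), unname(fit0$beta), tolerance = 1e-3)

  all0 <- fit_model(model_spec("ris", random = c("intercept", "x1")),
                    pop$patients, penalty_df = 0)
  all15 <- fit_model(model_spec("ris", random = c("intercept", "x1")),
                     pop$patients)
  expect_equal(all15$G[1, 1], all0$G[1, 1], tolerance = 0.01)
  expect_equal(all15$G[2, 2], all0$G[2, 2], tolerance = 0.01)
})

test_that("fits recover generating parameters on simulated training data", {
  pop <- base_pop()
  ids <- select_training_clinics(pop, seed = 101)
  d <- pop$patients[pop$patients$clinic_id %in% ids, ]
  fit <- fit_model(model_spec("ris", random = c("intercept", "x1")), d)
  # beta1 = 1 within 3 SE (SE ~ sqrt(tau1^2/m) for a random-slope model)
  se <- sqrt(0.25 / 20)
  expect_lt(abs(fit$beta["x1"] - 1), 3 * se)
  expect_equal(fit$sigma_sq, 0.5625, tolerance = 0.15)
  expect_equal(fit$G[1, 1], 1, tolerance = 0.8)
})

test_that("prediction follows the fixed + cluster-effect decomposition", {
  d <- toy_clustered(n_per = 8, m = 4, tau0 = 1, sigma = 0.5, seed = 11)
  fit <- fit_model(model_spec("ri", random = "intercept"), d)
  nd <- data.frame(clinic_id = c(1, 999), x1 = c(2, 2), quintile = 1L)
  pr <- predict(fit, nd)
  fixed_part <- fit$beta["(Intercept)"] + 2 * fit$beta["x1"]
  expect_equal(pr[2], unname(fixed_part))  # novel clinic: mean cluster
  expect_equal(pr[1], unname(fixed_part + fit$ranef["1", "intercept"]))

  # manual fit object exercises the additive decomposition directly
  fit$beta[] <- c(0, 1)
  fit$ranef[, 1] <- c(0.5, 0, 0, 0)
  expect_equal(predict(fit, data.frame(clinic_id = 1, x1 = 0)), 0.5)
  expect_equal(predict(fit, data.frame(clinic_id = 2, x1 = 2)), 2)
})

test_that("shrinkage vanishes for large clusters", {
  # one huge clinic: its prediction tends to the within-clinic LS line
  set.seed(13)
  m <- 5
  n_big <- 1e4
  cl <- c(rep(1, n_big), rep(2:m, each = 30))
  b0 <- rnorm(m); b1 <- rnorm(m, 0, 0.5)
  x1 <- rnorm(length(cl))
  y <- 0.3 + b0[cl] + (1 + b1[cl]) * x1 + rnorm(length(cl), 0, 0.7)
  d <- data.frame(clinic_id = cl, x1 = x1, y = y, quintile = 1L)
  fit <- fit_model(model_spec("ris", random = c("intercept", "x1")), d)
  within <- stats::lm(y ~ x1, d[d$clinic_id == 1, ])
  nd <- data.frame(clinic_id = 1, x1 = c(-1, 0, 1), quintile = 1L)
  expect_equal(predict(fit, nd), unname(predict(within, nd)),
               tolerance = 0.01)
})

test_that("mixed predictions collapse to the fixed-effects fit as G -> 0", {
  d <- toy_clustered(n_per = 8, m = 4, tau0 = 1, sigma = 0.5, seed = 17)
  tiny <- fit_model(model_spec("ris", random = c("intercept", "x1")), d,
                    delta = diag(1e-12, 2))
  ols <- fit_model(model_spec("linear"), d)
  expect_equal(predict(tiny, d), predict(ols, d), tolerance = 1e-6)
})

test_that("quintile fixed effects use treatment coding with safe fallback", {
  set.seed(19)
  d <- data.frame(clinic_id = rep(1:10, each = 20),
                  x1 = rnorm(200),
                  quintile = rep(c(1L, 2L, 3L, 4L, 5L), each = 40))
  d$y <- d$x1 + 0.5 * (d$quintile - 1) + rnorm(200, 0, 0.3)
  fit <- fit_model(model_spec("linq", quintile = TRUE), d)
  expect_named(fit$beta, c("(Intercept)", "x1", "quintile2", "quintile3",
                           "quintile4", "quintile5"))
  expect_equal(unname(fit$beta["quintile3"]), 1, tolerance = 0.2)

  # an absent level is pinned to 0 and predicts at the reference level
  d2 <- d[d$quintile != 5L, ]
  fit2 <- fit_model(model_spec("linq", quintile = TRUE), d2)
  expect_equal(unname(fit2$beta["quintile5"]), 0)
  nd <- data.frame(clinic_id = 999, x1 = 0, quintile = c(1L, 5L))
  expect_equal(diff(predict(fit2, nd)), 0)
})

test_that("fitting is deterministic and flags are well-formed", {
  d <- toy_clustered(n_per = 6, m = 8, tau0 = 1, tau1 = 0.4, sigma = 0.6,
                     seed = 23)
  f1 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d)
  f2 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_false(f1$fallback_used)
  # G stays positive definite under the penalty even with tau1 = 0 truth
  d0 <- toy_clustered(n_per = 6, m = 8, tau0 = 1, tau1 = 0, sigma = 0.6,
                      seed = 29)
  f0 <- fit_model(model_spec("ris", random = c("intercept", "x1")), d0)
  expect_true(all(eigen(f0$G, symmetric = TRUE)$values > 0))
  expect_error(fit_model(model_spec("ri", random = "intercept"),
                         toy_clustered(m = 1)), "at least 2 clinics")
})

test_that("fits serialize to JSON", {
  d <- toy_clustered(n_per = 6, m = 4, tau0 = 1, sigma = 0.7, seed = 31)
  fit <- fit_model(model_spec("ri", random = "intercept"), d)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sigma_sq, fit$sigma_sq)
  expect_equal(back$fixed$x1, unname(fit$beta["x1"]))
  expect_equal(nrow(back$ranef), 4)
})
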