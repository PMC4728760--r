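test_that("MAE and relative improvement follow their definitions", {
  expect_equal(mae(c(1, 2), c(0, 0)), 1.5)
  expect_equal(mae(c(3, 3), c(3, 3)), 0)
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:2), "length")

  expect_equal(relative_improvement(0.7, 1, 0.4), 0.5)
  expect_equal(relative_improvement(1, 1, 0.4), 0)   # null-equivalent
  expect_equal(relative_improvement(0.4, 1, 0.4), 1) # oracle-equivalent
  expect_gt(relative_improvement(0.3, 1, 0.4), 1)    # overfitting
  expect_lt(relative_improvement(1.2, 1, 0.4), 0)    # worse than null
  expect_error(relative_improvement(0.5, 0.4, 0.4), "degenerate")
})

test_that("baselines use the training mean and the true model", {
  pop <- base_pop()
  ids <- select_training_clinics(pop, seed = 101)
  train <- pop$patients[pop$patients$clinic_id %in% ids, ]
  bl <- ri_baselines(pop, ids, train)
  expect_equal(bl$ybar, mean(train$y))
  # phi1 in the training sample is the MAE of the residuals there
  expect_equal(bl$phi1, mean(abs(train$eps)))
  expect_false(bl$degenerate)
  # true-model MAE over a large scope ~ sigma_eps * sqrt(2/pi)
  bl_all <- ri_baselines(pop, ids, pop$patients)
  expect_equal(bl_all$phi1, 0.75 * sqrt(2 / pi), tolerance = 0.01)
  # phi0 ~ E|Y - ybar| ~ sqrt(2/pi) * sd(Y) for near-normal Y
  expect_equal(bl_all$phi0, sqrt(2 / pi) * stats::sd(pop$patients$y),
               tolerance = 0.03)

  # degenerate outcomes are flagged
  popd <- pop
  popd$patients$y <- 0
  popd$patients$mu_true <- 0
  bld <- ri_baselines(popd, ids, popd$patients)
  expect_true(bld$degenerate)
})

test_that("the true model scores RI = 1 exactly in any scope", {
  pop <- base_pop()
  ids <- select_training_clinics(pop, seed = 101)
  for (scope in list(pop$patients[pop$patients$clinic_id %in% ids, ],
                     pop$patients[1:5000, ])) {
    scope$prediction <- scope$mu_true
    bl <- ri_baselines(pop, ids, scope)
    m <- score_trace(scope, bl)
    expect_equal(m$ri, 1)
    expect_true(all(abs(m$ri_by_quintile[!is.na(m$ri_by_quintile)] - 1)
                    < 1e-12))
  }
})

test_that("per-quintile RI aggregates to overall RI by error-gap mass", {
  pop <- base_pop()
  ids <- select_training_clinics(pop, seed = 101)
  sta <- run_static(pop, ids, default_model_specs()["ri"], seed = 101)
  tr <- sta$traces$ri
  bl <- ri_baselines(pop, ids, tr)
  m <- score_trace(tr, bl)
  gap <- num <- 0
  for (q in 1:5) {
    sel <- tr$quintile == q
    p0 <- mae(rep(bl$ybar, sum(sel)), tr$y[sel])
    p1 <- mae(tr$mu_true[sel], tr$y[sel])
    w <- sum(sel) * (p0 - p1)
    num <- num + w * m$ri_by_quintile[q]
    gap <- gap + w
  }
  expect_equal(unname(num / gap), m$ri, tolerance = 1e-10)
})

test_that("RI is insensitive to the residual-variance scale", {
  # same seeds, alpha = 0.2 vs alpha = 0.5: the residual draws are shared
  # (only rescaled), so the comparison is paired; static linear training RI
  # drifts by less than 0.05
  ris <- sapply(c(0.2, 0.5), function(a) {
    vals <- sapply(1:100, function(r) {
      pop <- generate_population(sim_params(alpha = a), seed = 3000 + r)
      ids <- select_training_clinics(pop, seed = 3000 + r)
      train <- pop$patients[pop$patients$clinic_id %in% ids, ]
      fit <- fit_model(model_spec("linear"), train)
      bl <- ri_baselines(pop, ids, train)
      relative_improvement(mae(predict(fit, train), train$y),
                           bl$phi0, bl$phi1)
    })
    mean(vals)
  })
  expect_lt(abs(ris[1] - ris[2]), 0.05)
})

test_that("learning curves recover a constructed improvement profile", {
  # two replicates, 60 clinics x 30 patients; absolute error at index j is
  # exactly phi0 - RI(j) * (phi0 - phi1) with RI(j) = 1 - exp(-j / 4)
  lambda <- 4
  phi0 <- 1
  phi1 <- 0.4
  mk <- function(rep_id) {
    j <- rep(1:30, times = 60)
    ri_j <- 1 - exp(-j / lambda)
    err <- phi0 - ri_j * (phi0 - phi1)
    # outcomes 0, true means at distance phi1, training mean at distance
    # phi0: the cell-restricted baselines equal (phi0, phi1) exactly
    data.frame(replicate = rep_id,
               within_clinic_index = j,
               clinic_id = rep(1:60, each = 30),
               prediction = err, y = 0, mu_true = phi1)
  }
  events <- rbind(mk(1), mk(2))
  bls <- data.frame(replicate = 1:2, ybar = phi0)
  curve <- learning_curve(events, bls)
  expect_identical(curve$index, 1:30)
  expect_equal(curve$ri, 1 - exp(-(1:30) / lambda), tolerance = 1e-12)
  expect_identical(curve$counts, rep(120L, 30))

  # 80%-of-gains threshold by direct enumeration of the same formula
  k <- length(curve$index)
  plateau <- mean(curve$ri[(k - ceiling(0.2 * k) + 1):k])
  target <- curve$ri[1] + 0.8 * (plateau - curve$ri[1])
  expected_j <- which(1 - exp(-(1:30) / lambda) >= target)[1]
  expect_identical(gains_threshold(curve, 0.8), as.integer(expected_j))

  # flat curve: threshold collapses to the first index with a flag
  flat <- curve
  flat$ri <- rep(0.5, 30)
  expect_identical(as.integer(gains_threshold(flat)), 1L)
  expect_identical(attr(gains_threshold(flat), "flag"), "no-gains")
})

test_that("static traces give flat learning curves", {
  evs <- list()
  bls <- list()
  for (r in 1:3) {
    pop <- generate_population(
      sim_params(n_clinics = 40, mu_N = log(12), sigma_N = log(1.6)),
      seed = 76 + r)
    ids <- select_training_clinics(pop, seed = 76 + r, counts = rep(2L, 5))
    sta <- run_static(pop, ids, default_model_specs()["linear"],
                      seed = 76 + r)
    evs[[r]] <- cbind(sta$traces$linear, replicate = r)
    bl <- ri_baselines(pop, ids, sta$traces$linear)
    bls[[r]] <- data.frame(replicate = r, ybar = bl$ybar)
  }
  curve <- learning_curve(do.call(rbind, evs), do.call(rbind, bls))
  # no systematic trend: first- and second-half means agree within noise
  h <- length(curve$ri) %/% 2
  expect_lt(abs(mean(curve$ri[1:h]) - mean(curve$ri[(h + 1):(2 * h)])),
            0.15)
})

test_that("low-support tail indices are truncated", {
  events <- data.frame(replicate = 1L,
                       within_clinic_index = c(rep(1:3, each = 100),
                                               rep(4, 2)),
                       prediction = 0.5, y = 0, mu_true = 0.1)
  bls <- data.frame(replicate = 1L, ybar = 1)
  curve <- learning_curve(events, bls, min_support = 0.05)
  expect_identical(curve$index, 1:3)

  expect_error(gains_threshold(
    learning_curve(events[events$within_clinic_index == 1, ], bls)),
    "at least 2")
})

test_that("metrics serialize to CSV and JSON", {
  pop <- generate_population(
    sim_params(n_clinics = 40, mu_N = log(12), sigma_N = log(1.6)),
    seed = 78)
  ids <- select_training_clinics(pop, seed = 78, counts = rep(2L, 5))
  sta <- run_static(pop, ids, default_model_specs()["linear"], seed = 78)
  bl <- ri_baselines(pop, ids, sta$traces$linear)
  m <- list(linear = score_trace(sta$traces$linear, bl))
  prefix <- file.path(withr::local_tempdir(), "metrics")
  write_metrics(m, prefix, seed = 78, params = pop$params)
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_identical(nrow(csv), 6L)  # overall + 5 quintiles
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(js$seed, 78)
  expect_equal(js$models$linear$ri, m$linear$ri)
})
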