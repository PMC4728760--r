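#' Select the stratified training sample of clinics
#'
#' Draws a simple random sample of clinics without replacement within each
#' size quintile, with the configured per-quintile counts (default 6, 6, 3,
#' 3, 2 from smallest to largest — 20 clinics mimicking a large multi-centre
#' derivation cohort).
#'
#' @param population A [generate_population()] object.
#' @param seed Base seed; the draw uses the `"training"` substream.
#' @param counts Clinics per quintile, smallest to largest.
#' @return Sorted integer vector of selected clinic ids.
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 100), seed = 1)
#' select_training_clinics(pop, seed = 1)
#' @export
select_training_clinics <- function(population, seed = population$seed,
                                    counts =
                                      population$params$training_quintile_counts) {
  stopifnot(inherits(population, "population"))
  if (length(counts) != 5L) stop("counts must have one entry per quintile")
  with_stream(seed, "training", {
    picked <- integer(0)
    for (q in 1:5) {
      ids <- population$clinics$clinic_id[population$clinics$quintile == q]
      if (length(ids) < counts[q]) {
        stop("quintile ", q, " has ", length(ids), " clinics; ", counts[q],
             " requested")
      }
      picked <- c(picked, ids[sample.int(length(ids), counts[q])])
    }
    sort(picked)
  })
}

# Shared per-replicate draws for the prediction experiment: the global
# random permutation of the testing sample and the per-patient outcome
# incorporation indicators. All model specs under comparison share these
# draws (a paired design), so between-model differences are free of
# permutation noise.
prediction_schedule <- function(population, training_ids, p_incorporate,
                                seed) {
  test_rows <- which(!(population$patients$clinic_id %in% training_ids))
  if (length(test_rows) == 0L) stop("no testing-sample patients")
  perm <- with_stream(seed, "order", sample(test_rows))
  incorporate <- with_stream(seed, "incorporate", {
    stats::runif(length(perm)) < p_incorporate
  })
  list(rows = perm, incorporate = incorporate)
}

new_trace <- function(population, schedule, theta) {
  pats <- population$patients[schedule$rows, ]
  wci <- stats::ave(rep(1, nrow(pats)), pats$clinic_id, FUN = cumsum)
  data.frame(order_index = seq_len(nrow(pats)),
             clinic_id = pats$clinic_id,
             quintile = pats$quintile,
             within_clinic_index = as.integer(wci),
             cycle_index = as.integer((seq_len(nrow(pats)) - 1L) %/% theta),
             prediction = NA_real_,
             y = pats$y,
             mu_true = pats$mu_true,
             incorporated = schedule$incorporate)
}

#' Run static prediction models over the testing sample
#'
#' Fits each specification once on the training clinics and scores every
#' patient in the remaining (testing) clinics with that fixed fit. Every
#' testing clinic is novel, so mixed-model predictions use the hypothetical
#' mean cluster (`b_i = 0`), plus quintile fixed effects when in the spec.
#' The event order is the same global random permutation the dynamic engine
#' would use at this seed, so static and dynamic traces are comparable
#' event-by-event; the predictions themselves do not depend on the order.
#'
#' @param population A [generate_population()] object.
#' @param training_ids Clinic ids of the training sample.
#' @param specs Named list of [model_spec()] objects.
#' @param seed Base seed for the shared permutation substream.
#' @param penalty_df Covariance penalty weight passed to [fit_model()].
#' @return An object of class `prediction_run`: list with `traces` (one
#'   event data frame per spec), `fits` (the single fit per spec),
#'   `refit_log` and `training_rows`.
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 60), seed = 1)
#' ids <- select_training_clinics(pop, seed = 1, counts = c(2, 2, 2, 2, 2))
#' run <- run_static(pop, ids, default_model_specs(), seed = 1)
#' @export
run_static <- function(population, training_ids, specs,
                       seed = population$seed, penalty_df = 1.5) {
  schedule <- prediction_schedule(population, training_ids, 0, seed)
  train_rows <- which(population$patients$clinic_id %in% training_ids)
  train <- population$patients[train_rows, ]
  fits <- lapply(specs, function(sp) {
    fit <- fit_model(sp, train, penalty_df = penalty_df)
    if (!fit$converged && length(sp$random)) {
      # static fallback: fixed-effects-only fit on the same data
      fb <- fit_model(model_spec(sp$name, fixed = sp$fixed,
                                 quintile = sp$quintile), train)
      fb$fallback_used <- TRUE
      fb$spec <- sp
      fit <- fb
    }
    fit
  })
  traces <- lapply(fits, function(fit) {
    tr <- new_trace(population, schedule, theta = nrow(population$patients))
    tr$cycle_index <- 0L
    tr$incorporated <- FALSE
    tr$prediction <- predict(fit, population$patients[schedule$rows, ])
    tr
  })
  refit_log <- data.frame(
    cycle = 0L, model_name = names(fits), n_t = length(train_rows),
    m_t = length(training_ids),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    fallback = vapply(fits, function(f) f$fallback_used, logical(1)),
    row.names = NULL)
  structure(list(traces = traces, fits = fits, refit_log = refit_log,
                 training_rows = train_rows, kind = "static"),
            class = "prediction_run")
}

#' Run dynamically updated prediction models over the testing sample
#'
#' Visits the testing-sample patients in one global uniform-random
#' permutation. Predictions for each block of `theta` patients are made with
#' the current fits; the outcomes of that block's patients are then added to
#' the training data independently with probability `p_incorporate`
#' (modelling loss to follow-up: a patient not incorporated is never
#' revisited) and every specification is refit on the accumulated data.
#' The final partial block is predicted but triggers no refit, so the number
#' of refits is `floor((n_testing - 1) / theta)`. At any cycle the dynamic
#' fit is identical to a static fit on the accumulated training set. If a
#' refit fails to converge the previous cycle's fit is reused and the event
#' logged.
#'
#' @inheritParams run_static
#' @param theta Update interval (number of predictions between refits).
#' @param p_incorporate Per-patient probability that the outcome joins the
#'   training data.
#' @return A `prediction_run` with per-spec event traces, final `fits`, and
#'   a `refit_log` data frame (cycle, accumulated rows `n_t`, clinics
#'   `m_t`, convergence per spec).
#' @examples
#' pop <- generate_population(sim_params(n_clinics = 60), seed = 1)
#' ids <- select_training_clinics(pop, seed = 1, counts = c(2, 2, 2, 2, 2))
#' run <- run_dynamic(pop, ids, default_model_specs()["linear"],
#'                    theta = 200, seed = 1)
#' @export
run_dynamic <- function(population, training_ids, specs,
                        theta = population$params$theta,
                        p_incorporate = population$params$p_incorporate,
                        seed = population$seed, penalty_df = 1.5) {
  if (theta < 1L) stop("theta must be at least 1")
  schedule <- prediction_schedule(population, training_ids, p_incorporate,
                                  seed)
  n_test <- length(schedule$rows)
  train_rows <- which(population$patients$clinic_id %in% training_ids)

  traces <- lapply(specs, function(sp) new_trace(population, schedule, theta))
  acc_rows <- train_rows
  fit_on <- function(sp, prev) {
    fit <- tryCatch(
      fit_model(sp, population$patients[acc_rows, ], penalty_df = penalty_df),
      error = function(e) if (is.null(prev)) stop(e) else NULL)
    if (is.null(fit) || !fit$converged) {
      if (!is.null(prev)) {
        prev$fallback_used <- TRUE
        return(prev)
      }
    }
    fit
  }
  fits <- lapply(specs, fit_on, prev = NULL)

  n_blocks <- ceiling(n_test / theta)
  refit_log <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    lo <- (k - 1L) * theta + 1L
    hi <- min(k * theta, n_test)
    block <- schedule$rows[lo:hi]
    newdat <- population$patients[block, ]
    for (nm in names(specs)) {
      traces[[nm]]$prediction[lo:hi] <- predict(fits[[nm]], newdat)
    }
    acc_rows <- c(acc_rows, block[schedule$incorporate[lo:hi]])
    if (hi < n_test) {  # refit only while predictions remain
      fits <- Map(fit_on, specs, fits)
      refit_log[[k]] <- data.frame(
        cycle = k, model_name = names(specs), n_t = length(acc_rows),
        m_t = length(unique(population$patients$clinic_id[acc_rows])),
        converged = vapply(fits, function(f) f$converged, logical(1)),
        fallback = vapply(fits, function(f) f$fallback_used, logical(1)),
        row.names = NULL)
    }
  }
  refit_log <- do.call(rbind, refit_log[!vapply(refit_log, is.null,
                                                logical(1))])
  structure(list(traces = traces, fits = fits, refit_log = refit_log,
                 training_rows = train_rows, kind = "dynamic"),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("%s prediction run: %d models, %d scored events\n", x$kind,
              length(x$traces), nrow(x$traces[[1]])))
  if (!is.null(x$refit_log) && nrow(x$refit_log)) {
    cat(sprintf("  %d refit cycles, final training size %d rows\n",
                max(x$refit_log$cycle), max(x$refit_log$n_t)))
  }
  invisible(x)
}

#' Write prediction traces and the refit log to CSV
#'
#' @param run A [run_static()] or [run_dynamic()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(run, dir) {
  stopifnot(inherits(run, "prediction_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  events <- do.call(rbind, lapply(names(run$traces), function(nm) {
    cbind(model_name = nm, run$traces[[nm]])
  }))
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(run$refit_log)) {
    utils::write.csv(run$refit_log, file.path(dir, "refit_log.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
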