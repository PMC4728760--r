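#' Run one parameter cell of the simulation study
#'
#' For each replicate: generate a population, select the stratified training
#' sample, fit the static models (and optionally run the dynamic engine),
#' and score MAE / relative improvement in the requested scopes. Replicates
#' are seeded independently (`substream_seed(seed_base, "<cell>:<r>")`), so
#' any replicate can be re-run in isolation and results are invariant to
#' execution order.
#'
#' @param params A [sim_params()] object for the cell.
#' @param specs Named list of [model_spec()] objects (default: the three
#'   study models).
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param seed_base Base seed for replicate-seed derivation.
#' @param scopes Which samples to score: subset of
#'   `c("training", "testing")`.
#' @param dynamic Also run dynamically updated versions of all specs over
#'   the testing sample (testing scope only; considerably more expensive).
#' @param cell_name Label used in outputs and in replicate-seed derivation.
#' @param keep_traces Keep the per-replicate dynamic event traces (needed
#'   for learning curves); they can be large.
#' @return List of class `cell_result`: `cell_name`, `params`,
#'   `replicates` (long data frame: replicate, seed, scope, model, mode,
#'   mae, ri, phi0, phi1), `summary` (mean/SD per scope x model x mode),
#'   `curve_events` and `curve_baselines` when `keep_traces`, and
#'   `refit_diagnostics`.
#' @examples
#' res <- run_cell(sim_params(n_clinics = 60), n_replicates = 2,
#'                 seed_base = 1, scopes = "training",
#'                 counts = c(2, 2, 2, 2, 2))
#' res$summary
#' @param counts Training clinics per quintile (passed to
#'   [select_training_clinics()]).
#' @export
run_cell <- function(params, specs = default_model_specs(),
                     n_replicates = 10L, seed_base = params$seed,
                     scopes = c("training", "testing"), dynamic = FALSE,
                     cell_name = "cell", keep_traces = dynamic,
                     counts = params$training_quintile_counts) {
  scopes <- match.arg(scopes, c("training", "testing"), several.ok = TRUE)
  rows <- list()
  curve_events <- list()
  curve_baselines <- list()
  refit_diag <- list()

  for (r in seq_len(n_replicates)) {
    rep_seed <- substream_seed(seed_base, paste0(cell_name, ":", r))
    pop <- generate_population(params, seed = rep_seed)
    train_ids <- select_training_clinics(pop, seed = rep_seed,
                                         counts = counts)
    static <- run_static(pop, train_ids, specs, seed = rep_seed)
    train_events <- pop$patients[pop$patients$clinic_id %in% train_ids, ]

    add_row <- function(scope, model, mode, phi, bl) {
      rows[[length(rows) + 1L]] <<- data.frame(
        replicate = r, seed = rep_seed, scope = scope, model = model,
        mode = mode, mae = phi,
        ri = relative_improvement(phi, bl$phi0, bl$phi1),
        phi0 = bl$phi0, phi1 = bl$phi1)
    }

    if ("training" %in% scopes) {
      bl_tr <- ri_baselines(pop, train_ids, train_events)
      for (nm in names(specs)) {
        phi <- mae(predict(static$fits[[nm]], train_events), train_events$y)
        add_row("training", nm, "static", phi, bl_tr)
      }
    }
    if ("testing" %in% scopes) {
      test_events <- static$traces[[1]]
      bl_te <- ri_baselines(pop, train_ids, test_events)
      for (nm in names(specs)) {
        phi <- mae(static$traces[[nm]]$prediction, static$traces[[nm]]$y)
        add_row("testing", nm, "static", phi, bl_te)
      }
      if (dynamic) {
        dyn <- run_dynamic(pop, train_ids, specs, theta = params$theta,
                           p_incorporate = params$p_incorporate,
                           seed = rep_seed)
        for (nm in names(specs)) {
          phi <- mae(dyn$traces[[nm]]$prediction, dyn$traces[[nm]]$y)
          add_row("testing", nm, "dynamic", phi, bl_te)
        }
        refit_diag[[r]] <- cbind(replicate = r, dyn$refit_log)
        if (keep_traces) {
          curve_events[[r]] <- do.call(rbind, lapply(names(specs),
            function(nm) {
              tr <- dyn$traces[[nm]]
              data.frame(replicate = r, model = nm,
                         within_clinic_index = tr$within_clinic_index,
                         quintile = tr$quintile,
                         prediction = tr$prediction, y = tr$y,
                         mu_true = tr$mu_true)
            }))
          curve_baselines[[r]] <- data.frame(replicate = r,
                                             ybar = bl_te$ybar,
                                             phi0 = bl_te$phi0,
                                             phi1 = bl_te$phi1)
        }
      }
    }
  }

  replicates <- do.call(rbind, rows)
  agg <- stats::aggregate(ri ~ scope + model + mode, replicates,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v)
                                             else NA_real_))
  summary <- data.frame(agg[, c("scope", "model", "mode")],
                        mean_ri = agg$ri[, "mean"], sd_ri = agg$ri[, "sd"])
  structure(list(cell_name = cell_name, params = params,
                 n_replicates = n_replicates, seed_base = seed_base,
                 replicates = replicates, summary = summary,
                 curve_events = if (length(curve_events)) {
                   do.call(rbind, curve_events)
                 } else NULL,
                 curve_baselines = if (length(curve_baselines)) {
                   do.call(rbind, curve_baselines)
                 } else NULL,
                 refit_diagnostics = if (length(refit_diag)) {
                   do.call(rbind, refit_diag)
                 } else NULL),
            class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("cell '%s': %d replicates\n", x$cell_name, x$n_replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Define the simulation study's experiment grid
#'
#' The main grid crosses the random-intercept variance over
#' `c(0.5, 1, 2)` with the random-slope variance over `c(0, 0.25, 0.5)`
#' (9 cells); sweeps of the unknown-predictor effect `beta2` and the volume
#' effect `gamma` each cover `c(sqrt(0.5), 1, sqrt(2))` (the gamma sweep is
#' run with and without the quintile fixed effect); the update-interval
#' sweep covers `c(250, 500, 1000, 5000)`.
#'
#' @param base Base [sim_params()] (defaults to the base combination).
#' @param sweeps Named list; each element is a named list of parameter
#'   overrides applied to `base` for one cell. `default_sweeps()` builds the
#'   full study design.
#' @param n_replicates Replicates per cell.
#' @param seed_base Base seed.
#' @return List of class `experiment_grid`.
#' @examples
#' g <- experiment_grid(sweeps = list(base = list()), n_replicates = 2)
#' @export
experiment_grid <- function(base = sim_params(), sweeps = default_sweeps(),
                            n_replicates = 200L, seed_base = base$seed) {
  cells <- lapply(sweeps, function(ov) do.call(sim_params,
                                               utils::modifyList(as_args(base),
                                                                 ov)))
  structure(list(base = base, cells = cells, n_replicates = n_replicates,
                 seed_base = seed_base),
            class = "experiment_grid")
}

as_args <- function(params) {
  args <- unclass(params)
  # drop tau2_sq so the beta2/tau2 convention re-applies when beta2 is swept;
  # a sweep can still set tau2_sq explicitly
  args$tau2_sq <- NULL
  args
}

#' @rdname experiment_grid
#' @export
default_sweeps <- function() {
  sw <- list()
  for (t0 in c(0.5, 1, 2)) {
    for (t1 in c(0, 0.25, 0.5)) {
      sw[[sprintf("main_tau0_%g_tau1_%g", t0, t1)]] <-
        list(tau0_sq = t0, tau1_sq = t1)
    }
  }
  for (b2 in c(sqrt(0.5), 1, sqrt(2))) {
    sw[[sprintf("beta2_%.3f", b2)]] <- list(beta2 = b2)
  }
  for (g in c(sqrt(0.5), 1, sqrt(2))) {
    sw[[sprintf("gamma_%.3f", g)]] <- list(gamma = g)
  }
  for (th in c(250L, 500L, 1000L, 5000L)) {
    sw[[sprintf("theta_%d", th)]] <- list(theta = th)
  }
  sw
}

#' Run every cell of an experiment grid
#'
#' Cells run sequentially with independent per-replicate seeds, so results
#' are invariant to execution order. Cells whose name starts with `gamma_`
#' are additionally run with quintile fixed effects in all models (the
#' observable-volume variants).
#'
#' @param grid An [experiment_grid()].
#' @param scopes,dynamic,specs Passed to [run_cell()].
#' @param out Optional directory: per-cell results are written as they
#'   complete (resumable; completed cells are skipped on re-run).
#' @return List of class `grid_result` holding one `cell_result` per cell.
#' @export
run_grid <- function(grid, scopes = "training", dynamic = FALSE,
                     specs = default_model_specs(), out = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  results <- list()
  for (nm in names(grid$cells)) {
    quintile_variants <- if (startsWith(nm, "gamma_")) c(FALSE, TRUE)
                         else FALSE
    for (qv in quintile_variants) {
      label <- if (qv) paste0(nm, "_quintileFE") else nm
      if (!is.null(out) &&
          file.exists(file.path(out, paste0(label, ".csv")))) {
        next
      }
      sp <- if (qv) default_model_specs(quintile = TRUE) else specs
      res <- run_cell(grid$cells[[nm]], specs = sp,
                      n_replicates = grid$n_replicates,
                      seed_base = grid$seed_base, scopes = scopes,
                      dynamic = dynamic, cell_name = label)
      results[[label]] <- res
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(res$replicates,
                         file.path(out, paste0(label, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  structure(list(grid = grid, results = results), class = "grid_result")
}

#' Summarize a grid result into report tables
#'
#' Emits a wide table shaped like the study's main-results table (rows =
#' model x random-slope variance, columns = random-intercept variance,
#' entries `mean (SD)` of training-scope static RI), a long tidy table of
#' every cell, and a JSON manifest with seeds and parameter fingerprints.
#'
#' @param grid_result A [run_grid()] result.
#' @param out Optional directory to write `main_table.csv`, `cells_long.csv`
#'   and `manifest.json`.
#' @return List with `main_table` and `long` data frames.
#' @export
summarize_grid <- function(grid_result, out = NULL) {
  stopifnot(inherits(grid_result, "grid_result"))
  long <- do.call(rbind, lapply(names(grid_result$results), function(nm) {
    s <- grid_result$results[[nm]]$summary
    if (is.null(s) || !nrow(s)) return(NULL)
    cbind(cell = nm, s,
          tau0_sq = grid_result$results[[nm]]$params$tau0_sq,
          tau1_sq = grid_result$results[[nm]]$params$tau1_sq)
  }))

  main <- long[grepl("^main_", long$cell) & long$scope == "training" &
                 long$mode == "static", , drop = FALSE]
  main_table <- NULL
  if (!is.null(main) && nrow(main)) {
    cells_t0 <- sort(unique(main$tau0_sq))
    rows <- expand.grid(model = unique(main$model),
                        tau1_sq = sort(unique(main$tau1_sq), decreasing = TRUE),
                        stringsAsFactors = FALSE)
    main_table <- rows
    for (t0 in cells_t0) {
      col <- mapply(function(mo, t1) {
        hit <- main[main$model == mo & main$tau1_sq == t1 &
                      main$tau0_sq == t0, ]
        if (nrow(hit)) sprintf("%.3f (%.3f)", hit$mean_ri, hit$sd_ri)
        else NA_character_
      }, rows$model, rows$tau1_sq)
      main_table[[sprintf("tau0_sq_%g", t0)]] <- col
    }
  }

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(main_table)) {
      utils::write.csv(main_table, file.path(out, "main_table.csv"),
                       row.names = FALSE)
    }
    if (!is.null(long)) {
      utils::write.csv(long, file.path(out, "cells_long.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      seed_base = grid_result$grid$seed_base,
      n_replicates = grid_result$grid$n_replicates,
      package_version = as.character(utils::packageVersion("dynmix")),
      cells = lapply(grid_result$results, function(r) {
        list(cell = r$cell_name, n_replicates = r$n_replicates,
             seed_base = r$seed_base)
      }))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(main_table = main_table, long = long)
}
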