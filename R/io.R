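# File dialect: comma-separated, UTF-8, '.' decimal, mandatory header;
# angles in degrees, contrasts in % Michelson. A '#' comment line stating
# the units is written at the top of every file and skipped on read.

.trial_cols <- c("observer_id", "condition", "orientation_deg",
                 "contrast_pct", "correct", "trial_index")
.cell_cols <- c("condition", "orientation_deg", "contrast_pct",
                "n_trials", "n_correct")

.read_delim <- function(path, required) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.write_delim <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# angles in degrees; contrasts in % Michelson", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trial tables
#'
#' Trial tables are comma-separated text with a mandatory header and one
#' row per 2AFC trial (`observer_id, condition, orientation_deg,
#' contrast_pct, correct, trial_index`). Unknown columns are preserved.
#' Malformed rows (e.g. `correct` outside {0, 1}, negative contrast) are
#' rejected with the offending row number. An empty-but-headered file
#' yields an empty table.
#'
#' @param path File path.
#' @return `read_trials()`: the validated trial table.
#' @export
read_trials <- function(path) {
  df <- .read_delim(path, .trial_cols)
  for (col in c("orientation_deg", "contrast_pct")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) > 0L) {
    bad <- which(!(df$correct %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop("invalid `correct` value (must be 0 or 1) in data row ",
           bad[1L], " of ", path, call. = FALSE)
    }
    bad <- which(!is.finite(df$contrast_pct) | df$contrast_pct < 0)
    if (length(bad) > 0L) {
      stop("invalid `contrast_pct` in data row ", bad[1L], " of ", path,
           call. = FALSE)
    }
  }
  df
}

#' @rdname read_trials
#' @param trials A trial table.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.trial_cols %in% names(trials)))
  .write_delim(trials, path)
}

#' Read and write aggregated cell counts
#'
#' Cell-count files are comma-separated text with header `condition,
#' orientation_deg, contrast_pct, n_trials, n_correct`.
#'
#' @param path File path.
#' @return `read_cell_counts()`: the validated cell-count table.
#' @export
read_cell_counts <- function(path) {
  df <- .read_delim(path, .cell_cols)
  for (col in c("orientation_deg", "contrast_pct")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) > 0L) {
    bad <- which(df$n_trials <= 0 | df$n_correct < 0 |
                   df$n_correct > df$n_trials)
    if (length(bad) > 0L) {
      stop("invalid counts in data row ", bad[1L], " of ", path,
           call. = FALSE)
    }
  }
  df
}

#' @rdname read_cell_counts
#' @param cells A cell-count table.
#' @export
write_cell_counts <- function(cells, path) {
  stopifnot(all(.cell_cols %in% names(cells)))
  .write_delim(cells, path)
}

#' Export a fit as JSON
#'
#' Serializes a psychometric (`pf_fit`) or population-model
#' (`popcode_fit`) fit — estimates, fixed values, log-likelihood, AIC
#' where defined, convergence flags and seed — as a JSON file.
#'
#' @param fit A `pf_fit` or `popcode_fit` object.
#' @param path Output file path.
#' @param ci Optional confidence-interval matrix (from
#'   [bootstrap_pf_ci()] or [bootstrap_model_ci()]) stored alongside.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path, ci = NULL) {
  out <- if (inherits(fit, "pf_fit")) {
    list(type = "psychometric", estimates = as.list(fit$estimates),
         loglik = fit$loglik, deviance = fit$deviance,
         converged = fit$converged, boundary = fit$boundary,
         condition = fit$condition, orientation = fit$orientation,
         n_restarts = fit$n_restarts, seed = fit$seed)
  } else if (inherits(fit, "popcode_fit")) {
    list(type = "population_model", estimates = fit$estimates,
         fixed = fit$fixed, loglik = fit$loglik, aic = fit$aic,
         n_params = fit$n_params, n_neurons = fit$n_neurons,
         converged = fit$converged, restarts = fit$restarts,
         seed = fit$seed)
  } else {
    stop("`fit` must be a pf_fit or popcode_fit", call. = FALSE)
  }
  if (!is.null(ci)) {
    out$ci <- apply(ci, 1L, function(r) list(lower = r[[1L]],
                                             upper = r[[2L]]),
                    simplify = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Drives the complete workflow end-to-end: simulate a synthetic observer
#' (or read an existing trial table), aggregate to cell counts, fit
#' psychometric functions per condition x orientation, fit the full
#' population model, compute post-fit ablation predictions, optionally run
#' the nested-model AIC comparisons, and write all results plus a
#' machine-readable summary JSON. Re-running with the same configuration
#' yields byte-identical outputs.
#'
#' @param config A named list or a path to a YAML/JSON file. Recognized
#'   entries: `seed` (mandatory integer; there is no wall-clock default),
#'   `out_dir` (mandatory), `trials` (path to an existing trial table;
#'   if absent data are simulated), `design` (list of
#'   [experiment_design()] arguments), `generator` (`"model"` or `"psi"`),
#'   `psi_params` (data frame or list for `generator = "psi"`),
#'   `parameters` (path to a population parameter JSON like the bundled
#'   reference estimates; defaults to them), `n_restarts_pf`,
#'   `n_restarts_model`, `n_boot_compare` (0 disables model comparisons),
#'   `verbose`.
#' @return Invisibly, a list with the trial table, cell counts,
#'   psychometric fits, population fit, ablation tables, comparisons and
#'   the summary written to `out_dir/summary.json`.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    stop("config must specify an integer `seed`: results are only ",
         "reproducible with an explicit seed", call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config must specify `out_dir`",
                                    call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(config$verbose)
  say <- function(...) if (verbose) message(sprintf(...))

  design <- .pipeline_stage("design", do.call(experiment_design,
                                              as.list(config$design)))

  ref_path <- if (is.null(config$parameters)) {
    system.file("extdata", "reference-estimates.json", package = "ampop",
                mustWork = TRUE)
  } else config$parameters
  gen <- .pipeline_stage("parameters", {
    j <- jsonlite::read_json(ref_path, simplifyVector = TRUE)
    n <- as.integer(j$n_neurons)
    list(pop = population_params(
           k_exc = j$k_exc, k_inh = j$k_inh, p = j$p, c50 = j$c50,
           r0 = j$r0, r_max = j$r_max, t = j$t, zeta = j$zeta,
           preferred_orientations = seq(0, by = 180 / n, length.out = n)),
         am = am_params(alpha = j$alpha, beta = j$beta, gamma = j$gamma,
                        k_exc_AM = j$k_exc_AM, k_inh_AM = j$k_inh_AM,
                        inducer_orientation = j$inducer_orientation),
         epsilon = j$epsilon, n_neurons = n, t = j$t)
  })

  say("stage simulate: seed %d", seed)
  trials <- .pipeline_stage("simulate", {
    if (!is.null(config$trials)) {
      read_trials(config$trials)
    } else if (identical(config$generator, "psi")) {
      generate_from_psi(design, as.data.frame(config$psi_params), seed)
    } else {
      generate_from_model(design, gen$pop, gen$am, gen$epsilon, seed)
    }
  })
  write_trials(trials, file.path(out_dir, "trials.csv"))

  say("stage aggregate: %d trials", nrow(trials))
  cells <- .pipeline_stage("aggregate", pool_observers(trials))
  write_cell_counts(cells, file.path(out_dir, "cell_counts.csv"))

  say("stage fit-pf")
  n_pf <- if (is.null(config$n_restarts_pf)) 10L else
    as.integer(config$n_restarts_pf)
  pf_fits <- .pipeline_stage("fit-pf", {
    groups <- split(cells, paste(cells$condition, cells$orientation_deg))
    lapply(groups, fit_psychometric, n_restarts = n_pf, seed = seed)
  })
  pf_tab <- do.call(rbind, lapply(pf_fits, function(f) {
    data.frame(condition = f$condition, orientation_deg = f$orientation,
               c_m = f$estimates[["c_m"]], s = f$estimates[["s"]],
               lam = f$estimates[["lam"]], loglik = f$loglik,
               deviance = f$deviance, converged = f$converged,
               boundary = f$boundary)
  }))
  rownames(pf_tab) <- NULL
  .write_delim(pf_tab, file.path(out_dir, "pf_fits.csv"))

  say("stage fit-model")
  n_model <- if (is.null(config$n_restarts_model)) 20L else
    as.integer(config$n_restarts_model)
  spec <- model_spec(fixed = list(t = gen$t,
                                  inducer_orientation =
                                    design$inducer_orientation),
                     n_neurons = gen$n_neurons)
  fit <- .pipeline_stage("fit-model",
    fit_population_model(cells, spec, n_restarts = n_model, seed = seed))

  say("stage ablate")
  ablations <- .pipeline_stage("ablate", {
    ab_gamma <- ablate_post_fit(fit, "gamma")
    ab_ab <- ablate_post_fit(fit, c("alpha", "beta"))
    tab <- fit$fitted
    names(tab)[names(tab) == "pc"] <- "pc_full"
    tab$pc_no_suppression <- ab_gamma$pc
    tab$pc_no_excitation_inhibition <- ab_ab$pc
    tab
  })
  .write_delim(ablations, file.path(out_dir, "ablation.csv"))

  n_cmp <- if (is.null(config$n_boot_compare)) 0L else
    as.integer(config$n_boot_compare)
  comparisons <- NULL
  if (n_cmp > 0L) {
    say("stage compare: n_boot %d", n_cmp)
    comparisons <- .pipeline_stage("compare", {
      spec_g0 <- model_spec(free = setdiff(spec$free, "gamma"),
                            fixed = c(spec$fixed, list(gamma = 0)),
                            n_neurons = spec$n_neurons)
      spec_nt <- model_spec(
        free = setdiff(spec$free, c("k_exc_AM", "k_inh_AM")),
        fixed = c(spec$fixed, list(k_exc_AM = 0.001, k_inh_AM = 0.001)),
        n_neurons = spec$n_neurons)
      fit_g0 <- fit_population_model(cells, spec_g0, n_restarts = n_model,
                                     seed = seed + 1L)
      fit_nt <- fit_population_model(cells, spec_nt, n_restarts = n_model,
                                     seed = seed + 2L)
      list(no_suppression = compare_models_aic(fit, fit_g0, n_boot = n_cmp,
                                               seed = seed + 3L),
           no_tuning = compare_models_aic(fit, fit_nt, n_boot = n_cmp,
                                          seed = seed + 4L))
    })
  }

  summary <- list(
    seed = seed,
    design = list(contrast_levels = design$contrast_levels,
                  orientation_levels = design$orientation_levels,
                  conditions = design$conditions,
                  trials_per_cell = design$trials_per_cell,
                  observers = design$observers),
    n_trials = nrow(trials),
    psychometric = pf_tab,
    population_model = list(estimates = fit$estimates,
                            fixed = fit$fixed,
                            loglik = fit$loglik, aic = fit$aic,
                            n_params = fit$n_params,
                            n_neurons = fit$n_neurons,
                            converged = fit$converged),
    comparisons = if (is.null(comparisons)) NULL else list(
      no_suppression = list(
        aic_difference = comparisons$no_suppression$aic_difference,
        p_value = comparisons$no_suppression$p_value),
      no_tuning = list(
        aic_difference = comparisons$no_tuning$aic_difference,
        p_value = comparisons$no_tuning$p_value))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  say("pipeline complete: %s", out_dir)
  invisible(list(trials = trials, cells = cells, pf_fits = pf_fits,
                 fit = fit, ablations = ablations,
                 comparisons = comparisons, summary = summary))
}
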