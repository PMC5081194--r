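#' Design of the 2AFC detection experiment
#'
#' Factorial design of the detection task: contrast x target orientation x
#' condition, with a fixed number of trials per cell and one or more
#' observers. Defaults reproduce the study design the synthetic observer
#' emulates: five contrasts spanning 4-40% Michelson (near-log spaced),
#' five target orientations, AM and Flicker conditions, horizontal (0
#' degree) inducers, and at least 50 trials per cell.
#'
#' @param contrast_levels Target contrasts in % Michelson, within [0, 100].
#' @param orientation_levels Target orientations in degrees.
#' @param conditions Condition labels, subset of `c("AM", "Flicker")`.
#' @param trials_per_cell Trials per design cell per observer (> 0).
#' @param inducer_orientation Inducer orientation in degrees.
#' @param observers Number of observers.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(contrast_levels = c(4, 7, 12, 22, 40),
                              orientation_levels = c(0, 15, 30, 45, 90),
                              conditions = c("AM", "Flicker"),
                              trials_per_cell = 50L,
                              inducer_orientation = 0,
                              observers = 1L) {
  if (any(contrast_levels < 0) || any(contrast_levels > 100)) {
    stop("contrasts must lie in [0, 100] % Michelson", call. = FALSE)
  }
  if (!all(conditions %in% c("AM", "Flicker")) || length(conditions) < 1L) {
    stop("conditions must be a subset of c('AM', 'Flicker')", call. = FALSE)
  }
  trials_per_cell <- as.integer(trials_per_cell)
  observers <- as.integer(observers)
  if (trials_per_cell < 1L || observers < 1L) {
    stop("trials_per_cell and observers must be positive", call. = FALSE)
  }
  structure(list(contrast_levels = as.numeric(contrast_levels),
                 orientation_levels = as.numeric(orientation_levels),
                 conditions = as.character(conditions),
                 trials_per_cell = trials_per_cell,
                 inducer_orientation = inducer_orientation,
                 observers = observers),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "2AFC design: %d contrasts x %d orientations x %d condition(s), %d trials/cell, %d observer(s)\n",
    length(x$contrast_levels), length(x$orientation_levels),
    length(x$conditions), x$trials_per_cell, x$observers))
  invisible(x)
}

#' Expand a design into its cell table
#'
#' @param design An [experiment_design()].
#' @return Data frame with one row per (condition, orientation, contrast)
#'   cell and an `n_trials` column.
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  out <- expand.grid(contrast_pct = design$contrast_levels,
                     orientation_deg = design$orientation_levels,
                     condition = design$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[c("condition", "orientation_deg", "contrast_pct")]
  out$n_trials <- design$trials_per_cell
  out
}

# Stable per-(observer, cell) stream seed derived from the master seed, so
# that adding observers or cells never perturbs existing streams. All
# intermediates stay well below 2^53, making the arithmetic exact.
.cell_seed <- function(master, observer, cell) {
  as.integer((((master %% 2147483647) * 48271) %% 2147483647 +
                observer * 100003 + cell * 193) %% 2147483647)
}

#' Generate trial-level 2AFC data from the population model
#'
#' Simulates every trial of the design through the Monte-Carlo decoder
#' ([simulate_2afc_trial()]): unit responses are drawn from their Gaussian
#' response distributions, summed per location, and the larger sum wins.
#' Cell-level proportions correct converge on the analytic
#' [predict_pc_table()] values as trials accumulate. Each (observer, cell)
#' pair uses its own random stream derived from the master seed.
#'
#' @param design An [experiment_design()].
#' @param pop A [population_params()] object.
#' @param am An [am_params()] object applied in the AM condition (its
#'   inducer orientation is taken from the design).
#' @param epsilon Decoder efficiency in (0, 1].
#' @param seed Master integer seed (mandatory).
#' @return A trial table: data frame with columns `observer_id`,
#'   `condition`, `orientation_deg`, `contrast_pct`, `correct`,
#'   `trial_index`.
#' @export
generate_from_model <- function(design, pop, am, epsilon, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(pop, "population_params"),
            inherits(am, "am_params"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  am$inducer_orientation <- design$inducer_orientation
  cells <- design_cells(design)
  n <- design$trials_per_cell
  out <- vector("list", design$observers * nrow(cells))
  k <- 0L
  for (obs in seq_len(design$observers)) {
    for (i in seq_len(nrow(cells))) {
      set.seed(.cell_seed(seed, obs, i))
      am_i <- if (cells$condition[i] == "AM") am else NULL
      correct <- .simulate_2afc(n, cells$contrast_pct[i],
                                cells$orientation_deg[i], pop, am_i,
                                epsilon)
      k <- k + 1L
      out[[k]] <- data.frame(observer_id = obs,
                             condition = cells$condition[i],
                             orientation_deg = cells$orientation_deg[i],
                             contrast_pct = cells$contrast_pct[i],
                             correct = as.integer(correct),
                             trial_index = seq_len(n))
    }
  }
  do.call(rbind, out)
}

#' Generate trial-level 2AFC data from psychometric functions
#'
#' Bernoulli draws at `psi(contrast)` per trial, with one set of
#' psychometric parameters per (condition, orientation) cell group.
#'
#' @param design An [experiment_design()].
#' @param psi_params Data frame with columns `condition`,
#'   `orientation_deg`, `c_m`, `s`, `lam`: one row per cell group of the
#'   design (missing groups are an error).
#' @param seed Master integer seed (mandatory).
#' @return A trial table (see [generate_from_model()]).
#' @export
generate_from_psi <- function(design, psi_params, seed) {
  stopifnot(inherits(design, "experiment_design"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  psi_params <- as.data.frame(psi_params)
  need <- c("condition", "orientation_deg", "c_m", "s", "lam")
  if (!all(need %in% names(psi_params))) {
    stop("psi_params must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cells <- design_cells(design)
  key_cells <- paste(cells$condition, cells$orientation_deg)
  key_pars <- paste(psi_params$condition, psi_params$orientation_deg)
  if (!all(key_cells %in% key_pars)) {
    stop("psi_params missing for cell group(s): ",
         paste(unique(setdiff(key_cells, key_pars)), collapse = "; "),
         call. = FALSE)
  }
  idx <- match(key_cells, key_pars)
  n <- design$trials_per_cell
  out <- vector("list", design$observers * nrow(cells))
  k <- 0L
  for (obs in seq_len(design$observers)) {
    for (i in seq_len(nrow(cells))) {
      set.seed(.cell_seed(seed, obs, i))
      pr <- psi(cells$contrast_pct[i], psi_params$c_m[idx[i]],
                psi_params$s[idx[i]], psi_params$lam[idx[i]])
      k <- k + 1L
      out[[k]] <- data.frame(observer_id = obs,
                             condition = cells$condition[i],
                             orientation_deg = cells$orientation_deg[i],
                             contrast_pct = cells$contrast_pct[i],
                             correct = as.integer(stats::runif(n) < pr),
                             trial_index = seq_len(n))
    }
  }
  do.call(rbind, out)
}

#' Aggregate a trial table into cell counts
#'
#' @param trials A trial table (see [generate_from_model()]).
#' @return Data frame of cell counts: `condition`, `orientation_deg`,
#'   `contrast_pct`, `n_trials`, `n_correct`, sorted by cell.
#' @export
aggregate_trials <- function(trials) {
  need <- c("condition", "orientation_deg", "contrast_pct", "correct")
  if (!all(need %in% names(trials))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, nrow(trials)), n_correct = trials$correct),
    by = trials[c("condition", "orientation_deg", "contrast_pct")],
    FUN = sum)
  agg <- agg[order(agg$condition, agg$orientation_deg, agg$contrast_pct), ]
  rownames(agg) <- NULL
  agg
}

#' Pool trial tables across observers into cell counts
#'
#' Sums correct/total counts per (condition, orientation, contrast) cell
#' across observers. Observers may cover different subsets of the design
#' (pooled cells then simply carry unequal trial counts), but the same
#' observer id may not appear in more than one table.
#'
#' @param tables A single trial table or a list of trial tables.
#' @return Pooled cell counts (see [aggregate_trials()]).
#' @export
pool_observers <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  ids <- lapply(tables, function(t) unique(t$observer_id))
  if (anyDuplicated(unlist(ids)) > 0L) {
    stop("conflicting designs: the same observer_id appears in more than ",
         "one table", call. = FALSE)
  }
  aggregate_trials(do.call(rbind, tables))
}
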