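# Genetic-algorithm wrapper feature selection under an operations-per-second
# budget.
#
# Chromosomes are binary inclusion masks over the dataset's features. The GA
# is generational with tournament selection, uniform crossover, per-bit
# mutation and elitism; the ops budget is a hard constraint enforced by
# repair (randomly clearing selected bits until the mask is feasible), so
# every candidate ever evaluated -- and every mask ever returned -- is
# feasible. Selection happens independently inside each outer
# leave-one-subject-out fold: fold s's search only ever sees fitness values
# computed from the other subjects, so the held-out subject cannot leak into
# its own feature selection.

#' GA configuration
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Fixed number of generations (no early stopping, so a
#'   seed fully determines the run).
#' @param crossover_rate Probability that a pair of parents is recombined
#'   (uniform crossover) rather than copied.
#' @param mutation_rate Per-bit flip probability; `NULL` means `1/L`.
#' @param elite_count Chromosomes carried over unchanged each generation.
#' @param tournament_size Tournament selection size.
#' @param cost_budget Hard ops-per-second budget ([mask_cost()] units).
#' @param fitness_kind `"SDEO"` or `"KFBEO"`.
#' @param seed Integer seed; fold f of a run reseeds deterministically from
#'   it, so per-fold results are reproducible and independent of the other
#'   folds.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      elite_count = 2, tournament_size = 2,
                      cost_budget, fitness_kind = c("SDEO", "KFBEO"),
                      seed = 1L) {
  fitness_kind <- match.arg(fitness_kind)
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            elite_count >= 0, elite_count < population_size,
            cost_budget > 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_count = as.integer(elite_count),
                 tournament_size = as.integer(tournament_size),
                 cost_budget = cost_budget,
                 fitness_kind = fitness_kind,
                 seed = as.integer(seed)),
            class = "ga_config")
}

fold_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) + fold * 100003) %% .Machine$integer.max)
}

# Clear random selected bits until the mask fits the budget; if repair
# empties the mask, fall back to one random individually-feasible feature.
repair_mask <- function(mask, g, budget, feasible_single) {
  while (mask_cost(mask, g) > budget && any(mask)) {
    on <- which(mask)
    mask[on[sample.int(length(on), 1)]] <- FALSE
  }
  if (!any(mask)) {
    mask[feasible_single[sample.int(length(feasible_single), 1)]] <- TRUE
  }
  mask
}

ga_run_fold <- function(ctx, g, cfg, s) {
  L <- ctx$L
  pmut <- if (is.null(cfg$mutation_rate)) 1 / L else cfg$mutation_rate
  fitfun <- if (cfg$fitness_kind == "SDEO") sdeo_fitness else kfbeo_fitness
  feat_costs <- vapply(seq_len(L), function(i) {
    m <- rep(FALSE, L); m[i] <- TRUE; mask_cost(m, g)
  }, 0)
  feasible_single <- which(feat_costs <= cfg$cost_budget)
  if (length(feasible_single) == 0L) {
    stop("cost budget ", cfg$cost_budget, " is below the cheapest single ",
         "feature's cost (", min(feat_costs), "): no feasible mask",
         call. = FALSE)
  }
  full_cost <- mask_cost(rep(TRUE, L), g)
  p0 <- min(0.5, max(1 / L, cfg$cost_budget / (2 * full_cost)))

  memo <- new.env(parent = emptyenv())
  evalfit <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- fitfun(NULL, mask, s, ctx = ctx)
      memo[[key]] <- v
    }
    v
  }
  draw_mask <- function() {
    m <- stats::runif(L) < p0
    if (!any(m)) m[sample.int(L, 1)] <- TRUE
    repair_mask(m, g, cfg$cost_budget, feasible_single)
  }
  np <- cfg$population_size
  pop <- replicate(np, draw_mask(), simplify = FALSE)
  fit <- vapply(pop, evalfit, 0)
  trace <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    pop <- pop[ord]; fit <- fit[ord]
    nxt <- pop[seq_len(cfg$elite_count)]
    tournament <- function() {
      cand <- sample.int(np, cfg$tournament_size)
      pop[[cand[which.min(fit[cand])]]]
    }
    while (length(nxt) < np) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        take1 <- stats::runif(L) < 0.5
        ifelse(take1, p1, p2)
      } else p1
      flip <- stats::runif(L) < pmut
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(L, 1)] <- TRUE
      child <- repair_mask(child, g, cfg$cost_budget, feasible_single)
      nxt[[length(nxt) + 1L]] <- child
    }
    pop <- nxt
    fit <- vapply(pop, evalfit, 0)
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  list(mask = pop[[best]], fitness = fit[best], trace = trace)
}

#' Run GA feature selection in every outer fold
#'
#' For each subject s, runs one GA minimizing the configured fitness (SDEO
#' or KFBEO) over masks whose [mask_cost()] does not exceed the budget,
#' using only the design subjects (everyone but s). Each fold is reseeded
#' deterministically from `cfg$seed`, so results are reproducible and a
#' fold's outcome depends only on its design data.
#'
#' @param d A [labeled_dataset()].
#' @param g A `cost_graph` over the dataset's features.
#' @param cfg A [ga_config()].
#' @return Object of class `ga_result`: list with `folds` (per-subject
#'   `mask`, `fitness`, `trace`), `config`, and `feature_names`.
#' @export
ga_select <- function(d, g, cfg) {
  stopifnot(inherits(d, "labeled_dataset"), inherits(g, "cost_graph"),
            inherits(cfg, "ga_config"))
  if (length(g$deps) != ncol(d$X)) {
    stop("cost graph has ", length(g$deps), " features but dataset has ",
         ncol(d$X), call. = FALSE)
  }
  ctx <- fold_context(d)
  if (cfg$fitness_kind == "KFBEO" && length(ctx$subjects) < 3) {
    stop("KFBEO selection needs at least 3 subjects", call. = FALSE)
  }
  folds <- vector("list", length(ctx$subjects))
  names(folds) <- ctx$subjects
  for (i in seq_along(ctx$subjects)) {
    set.seed(fold_seed(cfg$seed, i))
    folds[[i]] <- ga_run_fold(ctx, g, cfg, ctx$subjects[i])
  }
  structure(list(folds = folds, config = cfg,
                 feature_names = names(g$deps)),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  ns <- vapply(x$folds, function(f) sum(f$mask), 0L)
  cat(sprintf("<ga_result> %s fitness, %d folds, %g ops/s budget; %g features/fold (mean)\n",
              x$config$fitness_kind, length(x$folds),
              x$config$cost_budget, mean(ns)))
  invisible(x)
}

#' Selection-frequency ranking over repeated runs
#'
#' Counts, for every feature, the percentage of attempts (one attempt = one
#' fold of one repetition) in which it was selected, and returns the
#' ranking sorted descending -- the stable summary of which features the
#' wrapper keeps choosing.
#'
#' @param masks List of logical selection masks (e.g. all per-fold masks of
#'   all repetitions), or a list of `ga_result` objects.
#' @param features Feature names; taken from the first mask's names or the
#'   first `ga_result` if omitted.
#' @param min_percent If positive, restrict the table to features selected
#'   more than this percentage of attempts (the conventional report uses
#'   20).
#' @return Data frame with columns `feature`, `percentage`, plus an
#'   `attempts` attribute.
#' @export
selection_frequency <- function(masks, features = NULL, min_percent = 0) {
  if (length(masks) == 0L) stop("no masks supplied", call. = FALSE)
  if (inherits(masks[[1]], "ga_result")) {
    features <- features %||% masks[[1]]$feature_names
    masks <- unlist(lapply(masks, function(r) {
      lapply(r$folds, `[[`, "mask")
    }), recursive = FALSE)
  }
  mat <- do.call(rbind, lapply(masks, as.logical))
  if (is.null(features)) {
    features <- colnames(mat) %||% paste0("f", seq_len(ncol(mat)))
  }
  pct <- 100 * colMeans(mat)
  out <- data.frame(feature = features, percentage = pct,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percentage, out$feature), ]
  rownames(out) <- NULL
  out <- out[out$percentage > min_percent, , drop = FALSE]
  attr(out, "attempts") <- nrow(mat)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Error-versus-budget comparison of the two fitness functions
#'
#' For every budget, fitness kind and repetition, runs per-fold GA
#' selection and scores the outer leave-one-subject-out test error, each
#' fold classified with its own selected mask. Repetitions differ only in
#' the GA seed.
#'
#' @param d A [labeled_dataset()].
#' @param g A `cost_graph` over its features.
#' @param budgets Numeric vector of ops-per-second budgets.
#' @param cfg Base [ga_config()] (its budget/fitness/seed fields are
#'   overridden per run).
#' @param repetitions Repetitions per (budget, fitness) cell.
#' @param fitness_kinds Kinds to compare (default both).
#' @return Object of class `selection_report`: `runs` (one row per run:
#'   fitness, budget, repetition, test error, mean selected features),
#'   `summary` (mean and sd of error per budget and fitness), and `masks`
#'   (all per-fold masks, keyed `fitness|budget|rep`).
#' @export
error_vs_budget_curve <- function(d, g, budgets, cfg, repetitions = 1,
                                  fitness_kinds = c("SDEO", "KFBEO")) {
  stopifnot(length(budgets) >= 1)
  runs <- list()
  masks <- list()
  for (kind in fitness_kinds) {
    for (bi in seq_along(budgets)) {
      for (r in seq_len(repetitions)) {
        cfg_r <- cfg
        cfg_r$cost_budget <- budgets[bi]
        cfg_r$fitness_kind <- kind
        cfg_r$seed <- fold_seed(cfg$seed, 1000 * bi + r)
        res <- ga_select(d, g, cfg_r)
        fm <- lapply(res$folds, `[[`, "mask")
        ev <- loso_error_with_masks(d, fm)
        key <- paste(kind, budgets[bi], r, sep = "|")
        masks[[key]] <- fm
        runs[[key]] <- data.frame(
          fitness = kind, budget = budgets[bi], repetition = r,
          error = ev$error,
          mean_features = mean(vapply(fm, sum, 0L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  summ <- do.call(rbind, lapply(split(runs, runs[c("fitness", "budget")],
                                      drop = TRUE), function(gp) {
    data.frame(fitness = gp$fitness[1], budget = gp$budget[1],
               mean_error = mean(gp$error), sd_error = stats::sd(gp$error),
               mean_features = mean(gp$mean_features),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, masks = masks),
            class = "selection_report")
}
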