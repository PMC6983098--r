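# File formats and the end-to-end pipeline runner.
#
# Raw signals travel as one CSV per channel (time_s, value) plus a JSON
# manifest describing subject, channel, sampling rate and label intervals.
# Feature tables are CSV with one row per emission. Run configuration is
# YAML; every stochastic step derives its seed from the top-level seed.

#' Write a recording's samples as a channel CSV
#' @param rec A [recording()].
#' @param path Output CSV path (columns `time_s`, `value`).
#' @export
write_channel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / rec$fs, value = rec$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a recording manifest as JSON
#'
#' @param entries List of entries, each a list with `subject_id`,
#'   `channel`, `fs`, `file` (channel CSV path relative to the manifest)
#'   and `labels` (data frame `start_s`, `end_s`, `class`).
#' @param path Output JSON path.
#' @export
write_manifest <- function(entries, path) {
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read recordings listed in a JSON manifest
#'
#' @param path Manifest path written by [write_manifest()].
#' @return List of [recording()] objects, one per manifest entry.
#' @export
read_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  base <- dirname(path)
  lapply(entries, function(e) {
    df <- utils::read.csv(file.path(base, e$file))
    if (!all(c("time_s", "value") %in% names(df))) {
      stop("channel CSV must have columns time_s,value: ", e$file,
           call. = FALSE)
    }
    labs <- if (!is.null(e$labels)) {
      do.call(rbind, lapply(e$labels, function(l) {
        data.frame(start_s = l$start_s, end_s = l$end_s, class = l$class,
                   stringsAsFactors = FALSE)
      }))
    }
    recording(e$channel, e$fs, df$value, e$subject_id, labs)
  })
}

#' Write / read a feature table CSV
#' @param feats Feature data frame from [extract_features()].
#' @param path CSV path.
#' @export
write_feature_table <- function(feats, path) {
  utils::write.csv(feats, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Labeled dataset from a feature table
#'
#' Drops rows with missing labels or features and converts the class
#' strings to integer labels.
#'
#' @param feats Data frame with `subject_id`, `label` and feature columns.
#' @param classes Class-name order defining labels 1..M.
#' @return A [labeled_dataset()].
#' @export
dataset_from_feature_table <- function(feats,
                                       classes = c("neutral", "sadness",
                                                   "disgust")) {
  fcols <- setdiff(names(feats), c("emission_time", "subject_id", "label"))
  keep <- !is.na(feats$label) & stats::complete.cases(feats[fcols])
  feats <- feats[keep, , drop = FALSE]
  y <- match(feats$label, classes)
  if (anyNA(y)) stop("labels outside the class set", call. = FALSE)
  labeled_dataset(as.matrix(feats[fcols]), y, feats$subject_id, classes)
}

run_config_spec <- function() {
  list(
    seed = "integer", output_dir = "character", repetitions = "integer",
    budgets = "numeric", fitness_kinds = "character",
    dataset = list(type = "character", S = "integer",
                   n_per_class = "integer", informative = "integer",
                   class_gap = "numeric", subject_sd = "numeric",
                   L_total = "integer"),
    ga = list(population_size = "integer", generations = "integer",
              crossover_rate = "numeric", mutation_rate = "numeric",
              elite_count = "integer", tournament_size = "integer"),
    cost = list(type = "character", per_feature = "numeric")
  )
}

check_config_keys <- function(cfg, spec, path = "") {
  for (k in names(cfg)) {
    kp <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(spec)) {
      stop("unknown config key: ", kp, call. = FALSE)
    }
    if (is.list(spec[[k]]) && is.list(cfg[[k]])) {
      check_config_keys(cfg[[k]], spec[[k]], kp)
    }
  }
  invisible(TRUE)
}

#' Default run configuration
#'
#' Desk-scale defaults: an 8-subject synthetic tabular dataset with strong
#' subject effects, unit feature costs, a 10-unit budget, and a small GA.
#'
#' @return Named list (a `RunConfig`).
#' @export
default_run_config <- function() {
  list(
    seed = 1L, output_dir = "affectselect_run", repetitions = 2L,
    budgets = 10, fitness_kinds = c("SDEO", "KFBEO"),
    dataset = list(type = "synthetic_tabular", S = 8L, n_per_class = 20L,
                   informative = c(1L, 2L), class_gap = 1, subject_sd = 3,
                   L_total = 20L),
    ga = list(population_size = 30L, generations = 30L,
              crossover_rate = 0.9, mutation_rate = NULL,
              elite_count = 2L, tournament_size = 2L),
    cost = list(type = "uniform", per_feature = 1)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys fail fast with the offending key path; missing keys fall
#' back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return Validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg, run_config_spec())
  out <- utils::modifyList(default_run_config(), cfg)
  out
}

#' Run the full selection pipeline and write its artifacts
#'
#' Generates (or loads) the dataset, runs GA selection for every budget,
#' fitness kind and repetition, evaluates the outer leave-one-subject-out
#' error, ranks features by selection frequency, and writes: `config.json`
#' (the fully resolved configuration), `report.json` (per-run errors and
#' per-fold masks), `ranking_<kind>.csv` and `error_vs_budget.csv`.
#'
#' @param cfg `RunConfig` list ([default_run_config()] /
#'   [read_run_config()]).
#' @param feature_table Optional feature table data frame overriding the
#'   synthetic dataset (columns as in [extract_features()] output).
#' @return Invisibly, a list with the report objects and artifact paths.
#' @export
run_pipeline <- function(cfg = default_run_config(), feature_table = NULL) {
  check_config_keys(cfg, run_config_spec())
  cfg <- utils::modifyList(default_run_config(), cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  message("affectselect: seed ", cfg$seed, ", output in ", cfg$output_dir)

  if (!is.null(feature_table)) {
    d <- dataset_from_feature_table(feature_table)
  } else if (cfg$dataset$type == "synthetic_tabular") {
    ds <- cfg$dataset
    d <- synth_feature_dataset(S = ds$S, n_per_class = ds$n_per_class,
                               informative = ds$informative,
                               class_gap = ds$class_gap,
                               subject_sd = ds$subject_sd,
                               L_total = ds$L_total, seed = cfg$seed)
  } else {
    stop("unsupported dataset type: ", cfg$dataset$type, call. = FALSE)
  }
  g <- if (cfg$cost$type == "uniform") {
    uniform_cost_graph(colnames(d$X), cfg$cost$per_feature)
  } else {
    build_cost_graph()
  }
  ga <- do.call(ga_config, c(cfg$ga, list(cost_budget = cfg$budgets[1],
                                          seed = cfg$seed)))
  message("affectselect: selecting over ", ncol(d$X), " features, ",
          length(unique(d$subjects)), " subjects")
  rep_obj <- error_vs_budget_curve(d, g, cfg$budgets, ga,
                                   repetitions = cfg$repetitions,
                                   fitness_kinds = cfg$fitness_kinds)
  paths <- list(config = file.path(cfg$output_dir, "config.json"),
                report = file.path(cfg$output_dir, "report.json"),
                curve = file.path(cfg$output_dir, "error_vs_budget.csv"))
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  jsonlite::write_json(
    list(config = cfg, runs = rep_obj$runs,
         masks = lapply(rep_obj$masks, function(fm) {
           lapply(fm, as.integer)
         })),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  utils::write.csv(rep_obj$summary, paths$curve, row.names = FALSE)
  for (kind in cfg$fitness_kinds) {
    keys <- grep(paste0("^", kind, "\\|"), names(rep_obj$masks))
    rk <- selection_frequency(unlist(rep_obj$masks[keys],
                                     recursive = FALSE),
                              features = colnames(d$X))
    p <- file.path(cfg$output_dir, paste0("ranking_", tolower(kind), ".csv"))
    utils::write.csv(rk, p, row.names = FALSE)
    paths[[paste0("ranking_", kind)]] <- p
  }
  message("affectselect: done")
  invisible(list(report = rep_obj, paths = paths, dataset = d))
}
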