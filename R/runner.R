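#' Load and validate a run configuration
#'
#' A run configuration is a YAML document (or an equivalent named list) with
#' blocks:
#'
#' * `output_dir` — where artifacts are written;
#' * `seed` — one global seed; every stage seed is derived from it
#'   deterministically, so one knob controls reproducibility;
#' * `stages` — subset of `"simulate"`, `"preprocess"`, `"scenarios"`,
#'   `"interpret"` executed in that order;
#' * `input` — `csv` path (+ optional `schema: default`) when not simulating;
#' * `simulate` — arguments of [cohort_spec()];
#' * `experiment` — `target`, `subsets` (vector of strings like `""`, `"S"`,
#'   `"CHS"`), `methods`, `k`, `inner_k`, optional `grid`;
#' * `network` — arguments of [network_config()].
#'
#' Referenced paths are checked at validation time, before any computation.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$output_dir)) abort("Config needs an output_dir.")
  # YAML 1.1 resolves a bare `n:` key to boolean false; accept it, and the
  # unambiguous alias n_records, as the cohort size
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$n <- sim$n %||% sim$n_records %||% sim[["FALSE"]]
    sim[["FALSE"]] <- NULL; sim$n_records <- NULL
    if (is.null(sim$n)) sim["n"] <- NULL
    config$simulate <- sim
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("scenarios")
  bad <- setdiff(config$stages,
                 c("simulate", "preprocess", "scenarios", "interpret"))
  if (length(bad) > 0) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  if (!("simulate" %in% config$stages)) {
    if (is.null(config$input$csv)) {
      abort("Config needs input$csv when the simulate stage is absent.")
    }
    if (!file.exists(config$input$csv)) {
      abort(paste0("Input CSV not found: ", config$input$csv))
    }
  }
  config
}

subset_from_string <- function(s, tests = c("Cytology", "Hinselmann", "Schiller")) {
  if (is.null(s) || s == "") return(character(0))
  letters_ <- strsplit(s, "")[[1]]
  idx <- match(letters_, substr(tests, 1, 1))
  if (anyNA(idx)) abort(paste0("Unknown screening initial in subset '", s, "'."))
  tests[idx]
}

config_to_network <- function(nc, seed) {
  nc <- nc %||% list()
  network_config(
    depth = nc$depth %||% 1, width = nc$width %||% 10,
    lambda = nc$lambda %||% 0.1, l1_weight = nc$l1_weight %||% 1e-4,
    bypass = nc$bypass %||% FALSE, mapping = nc$mapping %||% "semi",
    corruption_rate = nc$corruption_rate %||% 0.5,
    max_epochs = nc$max_epochs %||% 500, patience = nc$patience %||% 100,
    batch_size = nc$batch_size %||% 32,
    learning_rate = nc$learning_rate %||% 1e-3,
    val_fraction = nc$val_fraction %||% 0.1,
    seed = seed)
}

#' Run an end-to-end experiment from one configuration
#'
#' Executes the configured stages — simulate a cohort (or read one),
#' preprocess, run the scenario matrix, interpret the final model — writing
#' every artifact under `output_dir` together with a manifest recording the
#' configuration, derived seeds, package version and an md5 content hash of
#' every output file. Re-running the same configuration reproduces identical
#' artifacts.
#'
#' @param config Path to a YAML config or a named list (see
#'   [load_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  tests <- c("Cytology", "Hinselmann", "Schiller")
  features <- NULL; targets <- NULL; schema <- NULL

  if ("simulate" %in% config$stages) {
    sim <- config$simulate %||% list()
    spec <- cohort_spec(
      n = sim$n %||% 300, d_numeric = sim$d_numeric %||% 8,
      d_boolean = sim$d_boolean %||% 6,
      d_categorical = sim$d_categorical %||% 2,
      prevalence = sim$prevalence %||% 0.1,
      active_features = sim$active_features %||% c(1L, 2L, 9L),
      effect_sizes = sim$effect_sizes %||% c(2.5, 2.0, 1.5),
      refusal_rate = sim$refusal_rate %||% 0.08,
      seed = derive_seed(seed, 1))
    cohort <- generate_cohort(spec)
    csv <- file.path(out_dir, "cohort.csv")
    truth <- file.path(out_dir, "cohort_truth.yaml")
    write_cohort_csv(cohort, csv, truth_path = truth)
    note(csv); note(truth)
    features <- cohort$features
    targets <- cohort$targets
    schema <- cohort$schema
  } else {
    schema <- default_risk_schema()
    raw <- read_risk_csv(config$input$csv, schema)
    tests <- intersect(c("Hinselmann", "Schiller", "Citology"), names(raw))
    features <- encode_features(raw, schema)
    targets <- raw[intersect(risk_target_columns(), names(raw))]
  }

  exp_cfg <- config$experiment %||% list()
  target_name <- exp_cfg$target %||% "Biopsy"

  if ("preprocess" %in% config$stages) {
    pp <- preprocess_features(features)
    tsv <- file.path(out_dir, "features_normalized.tsv")
    write_feature_tsv(pp$table, tsv); note(tsv)
    stats_path <- file.path(out_dir, "preprocess_stats.yaml")
    yaml::write_yaml(list(means = as.list(pp$stats$means),
                          bounds = list(min = as.list(pp$stats$bounds$min),
                                        max = as.list(pp$stats$bounds$max))),
                     stats_path)
    note(stats_path)
  }

  scen <- NULL
  if ("scenarios" %in% config$stages) {
    subsets <- lapply(exp_cfg$subsets %||% list(""),
                      subset_from_string, tests = tests)
    methods <- unlist(exp_cfg$methods %||% c("baseline", "semi", "sym", "zero"))
    grid <- NULL
    if (!is.null(exp_cfg$grid)) grid <- do.call(hyper_grid, exp_cfg$grid)
    net <- config_to_network(config$network, seed = derive_seed(seed, 2))
    scen <- run_scenarios(features, targets, target_name = target_name,
                          subsets = subsets, methods = methods,
                          k = exp_cfg$k %||% 10, config = net, grid = grid,
                          inner_k = exp_cfg$inner_k %||% 3,
                          seed = derive_seed(seed, 3))
    tsv <- file.path(out_dir, "scenario_metrics.tsv")
    write_scenario_tsv(scen, tsv); note(tsv)
  }

  if ("interpret" %in% config$stages) {
    net <- config_to_network(config$network, seed = derive_seed(seed, 4))
    net$mapping <- config$network$mapping %||% "zero"
    if (net$mapping == "baseline") {
      abort("The interpret stage needs a model with a decoder.")
    }
    pp <- preprocess_features(features)
    cohort <- assemble_cohort(pp$table, targets, target_name)
    model <- train_embedder(cohort, net)
    model$preprocessing <- pp$stats
    mp <- file.path(out_dir, "model.json")
    write_embedder(model, mp); note(mp)
    imp <- feature_impact(model, pp$table)
    it <- file.path(out_dir, "impact_matrix.tsv")
    write_impact_tsv(imp, it); note(it)
    cl <- cluster_features(imp)
    nw <- file.path(out_dir, "feature_clusters.nwk")
    write_clustering_newick(cl, nw); note(nw)
    proj <- project_embeddings(model, cohort, seed = derive_seed(seed, 5))
    pt <- file.path(out_dir, "projection.tsv")
    readr::write_tsv(proj, pt, progress = FALSE); note(pt)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("riskembed")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1),
                       network = derive_seed(seed, 2),
                       folds = derive_seed(seed, 3),
                       interpret_model = derive_seed(seed, 4),
                       projection = derive_seed(seed, 5)),
    config = config,
    files = lapply(written, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  mpth <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpth)
  invisible(manifest)
}
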