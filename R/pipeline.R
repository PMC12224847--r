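# End-to-end pipeline: synthesize/load -> flag -> filter -> features ->
# grid search -> community detection -> characterization -> classifier
# benchmark -> odds models, with a JSON run manifest and file artifacts.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] used when `input` is `NULL`.
#' @param input optional path to a cohort CSV (as written by
#'   [write_cohort()]); when given, `synth` is ignored.
#' @param features feature selection for both matrices; `NULL` means
#'   [default_features()].
#' @param include_diseases_graph include disease flags in the similarity
#'   features (default `TRUE`).
#' @param include_diseases_ml include them in the classifier features
#'   (default `FALSE`, avoiding label leakage).
#' @param thresholds,resolutions grid-search ranges.
#' @param detector_seed seed for Louvain and the grid search.
#' @param split_fraction train fraction for the benchmark.
#' @param models classifier families to run.
#' @param reference reference pattern name for the odds models ("UADCG"
#'   falls back to the first label when naming is generic).
#' @param or_predictors covariates for the odds-ratio table; `NULL` picks
#'   every feature.
#' @param out_dir artifact directory.
#' @param seed master seed for the synthetic stage and the split.
#' @return a `cmm_pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            input = NULL,
                            features = NULL,
                            include_diseases_graph = TRUE,
                            include_diseases_ml = FALSE,
                            thresholds = seq(0.3, 0.7, by = 0.05),
                            resolutions = seq(0.5, 1.5, by = 0.05),
                            detector_seed = 0L,
                            split_fraction = 0.7,
                            models = names(.model_registry()),
                            reference = "UADCG",
                            or_predictors = NULL,
                            out_dir = tempfile("cmm_run_"),
                            seed = 0L) {
  structure(list(synth = synth, input = input, features = features,
                 include_diseases_graph = include_diseases_graph,
                 include_diseases_ml = include_diseases_ml,
                 thresholds = thresholds, resolutions = resolutions,
                 detector_seed = as.integer(detector_seed),
                 split_fraction = split_fraction, models = models,
                 reference = reference, or_predictors = or_predictors,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "cmm_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [pipeline_config()]
#' arguments (the `synth` block accepts `n_patients`, `seed`,
#' `separation`).
#'
#' @param path YAML file.
#' @return a `cmm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synth_config, c(y$synth))
  y$synth <- NULL
  do.call(pipeline_config, c(list(synth = syn), y))
}

#' Run the full CMM pattern pipeline
#'
#' Executes the nine stages in order, writing every artifact (with seeds
#' and versions) under `cfg$out_dir` and returning the run manifest. Any
#' stage failure aborts with the stage name; artifacts of completed stages
#' persist.
#'
#' @param cfg a [pipeline_config()].
#' @param last_stage name of the final stage to execute (default `"odds"`,
#'   i.e. the whole pipeline).
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, last_stage = "odds") {
  stopifnot(inherits(cfg, "cmm_pipeline_config"))
  order9 <- c("simulate", "flag", "filter", "features", "grid_search",
              "detect", "characterize", "bench", "odds")
  if (!last_stage %in% order9) stop("unknown stage", call. = FALSE)
  n_keep <- match(last_stage, order9)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cmmnet",
                   version = as.character(utils::packageVersion("cmmnet")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seeds = list(master = cfg$seed,
                                detector = cfg$detector_seed),
                   stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(name, files) {
    files <- files[file.exists(files)]
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name,
           artifacts = basename(files),
           md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(name, fn) {
    if (match(name, order9) > n_keep) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      .write_manifest(manifest, cfg$out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  p <- function(f) file.path(cfg$out_dir, f)

  run_stage("simulate", function() {
    state$cohort <- if (is.null(cfg$input)) generate_cohort(cfg$synth)
                    else read_cohort(cfg$input)
    write_cohort(state$cohort, p("cohort.csv"))
    record("simulate", c(p("cohort.csv"), p("cohort.csv.json")))
  })
  run_stage("flag", function() {
    flags <- flag_diseases(raw_measurements(state$cohort))
    for (d in .cmm_diseases) state$cohort[[d]] <- flags[[d]]
    utils::write.csv(cbind(id = state$cohort$id, flags), p("flags.csv"),
                     row.names = FALSE)
    record("flag", p("flags.csv"))
  })
  run_stage("filter", function() {
    state$cmm <- filter_cmm(state$cohort)
    write_cohort(state$cmm, p("cohort_cmm.csv"))
    record("filter", c(p("cohort_cmm.csv"), p("cohort_cmm.csv.json")))
  })
  run_stage("features", function() {
    state$fm_graph <- build_feature_matrix(
      state$cmm, cfg$features,
      include_diseases = cfg$include_diseases_graph)
    state$fm_ml <- build_feature_matrix(
      state$cmm, cfg$features,
      include_diseases = cfg$include_diseases_ml)
    write_feature_matrix(state$fm_graph, p("features_graph.tsv"))
    record("features", c(p("features_graph.tsv"),
                         p("features_graph.tsv.json")))
  })
  run_stage("grid_search", function() {
    state$gs <- grid_search(state$fm_graph, cfg$thresholds,
                            cfg$resolutions, seed = cfg$detector_seed)
    utils::write.csv(state$gs$grid, p("grid.csv"), row.names = FALSE)
    record("grid_search", p("grid.csv"))
  })
  run_stage("detect", function() {
    state$partition <- state$gs$partition
    # pattern analysis covers the included (non-isolated) nodes only;
    # subjects outside the thresholded graph carry no pattern signal
    inc <- state$gs$included
    state$cmm <- state$cmm[inc, , drop = FALSE]
    state$membership <- factor(state$partition$membership[inc])
    export_graph(state$gs$graph, p("graph_edges.tsv"))
    export_graph(state$gs$graph, p("graph.graphml"), format = "graphml")
    write_partition(state$partition, p("partition.tsv"))
    record("detect", c(p("graph_edges.tsv"), p("partition.tsv"),
                       p("partition.tsv.json")))
  })
  run_stage("characterize", function() {
    state$profile <- pattern_profile(state$cmm, state$membership)
    report_profile(state$profile, p("profile"))
    record("characterize", c(p("profile.json"), p("profile.md")))
  })
  run_stage("bench", function() {
    labs <- .pattern_names_for(state$membership, state$profile)
    sp <- stratified_split(labs, cfg$split_fraction, seed = cfg$seed)
    # scaling is fit on training rows only (leakage guard)
    tr_fm <- build_feature_matrix(state$cmm[sp$train, , drop = FALSE],
                                  cfg$features,
                                  include_diseases = cfg$include_diseases_ml)
    Xtr <- tr_fm$values
    Xte <- project_features(tr_fm, state$cmm[sp$test, , drop = FALSE])
    state$bench <- run_benchmark(Xtr, labs[sp$train], Xte, labs[sp$test],
                                 models = cfg$models, seed = cfg$seed)
    utils::write.csv(state$bench$results, p("benchmark.csv"),
                     row.names = FALSE)
    jsonlite::write_json(state$bench$results, p("benchmark.json"),
                         auto_unbox = TRUE, digits = NA)
    for (m in names(state$bench$confusions))
      utils::write.csv(as.data.frame.matrix(state$bench$confusions[[m]]),
                       p(paste0("confusion_", m, ".csv")))
    gb <- state$bench$fits$gradient_boosting
    if (!is.null(gb)) {
      imp <- feature_importance(gb, tr_fm$feature_names)
      utils::write.table(imp, p("importance.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    record("bench", c(p("benchmark.csv"), p("benchmark.json"),
                      p("importance.tsv")))
  })
  run_stage("odds", function() {
    labs <- .pattern_names_for(state$membership, state$profile)
    ref <- if (cfg$reference %in% levels(labs)) cfg$reference
           else levels(labs)[1]
    preds <- cfg$or_predictors
    if (is.null(preds)) preds <- default_features(state$cmm)
    ors <- fit_multinomial_or(state$cmm, labs, preds, reference = ref)
    write_or_table(ors, p("odds"))
    record("odds", c(p("odds.csv"), p("odds.json")))
  })

  manifest$n_stages <- length(manifest$stages)
  .write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

# pattern labels renamed by the profile's rule-based names (factor)
.pattern_names_for <- function(membership, profile) {
  nm <- profile$names
  factor(unname(nm[as.character(membership)]),
         levels = unique(nm[order(names(nm))]))
}

.write_manifest <- function(manifest, out_dir) {
  body <- manifest
  jsonlite::write_json(body, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  # timestamp kept in a separate file so manifests are reproducible
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
             file.path(out_dir, "manifest.timestamp"))
  invisible(NULL)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `flag`, `graph`, `detect`, `characterize`,
#' `bench`, `odds` run the pipeline up to (and including) that stage;
#' `all` runs everything. Usage:
#'
#' ```
#' Rscript -e 'cmmnet::cmm_cli()' all --config run.yaml --out out_dir
#' ```
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
cmm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c(simulate = "simulate", flag = "flag", graph = "grid_search",
              detect = "detect", characterize = "characterize",
              bench = "bench", odds = "odds", all = "odds")
  if (!length(args) || !(args[1] %in% names(stages))) {
    message("usage: cmm_cli <", paste(names(stages), collapse = "|"),
            "> [--config file.yaml] [--out dir] [--seed n]")
    return(invisible(1L))
  }
  cmd <- args[1]; args <- args[-1]
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else NULL
  }
  cfg <- if (!is.null(getopt("--config"))) read_pipeline_config(getopt("--config"))
         else pipeline_config()
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  if (!is.null(getopt("--seed"))) {
    cfg$seed <- as.integer(getopt("--seed"))
    cfg$synth$seed <- cfg$seed
  }
  manifest <- run_pipeline(cfg, last_stage = stages[[cmd]])
  message("wrote ", manifest$n_stages, " stages to ", cfg$out_dir)
  invisible(0L)
}
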