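known_config_keys <- list(
  top = c("seed", "out_dir", "simulate", "caller", "annotate", "stats",
          "paths"),
  annotate = c("promoter_up", "promoter_down", "downstream_bp"),
  stats = c("bins", "include_split", "min_mapq"),
  paths = c("bam", "cells", "gtf", "cre", "regions")
)

check_keys <- function(x, allowed, block) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration key '%s' in %s", bad[1], block))
  }
  x
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file with optional blocks `simulate` (arguments of
#' [sim_config()]), `caller` ([caller_params()]), `annotate`, `stats`, and
#' `paths`, plus top-level `seed` and `out_dir`. Missing values take the
#' package defaults; unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with fully defaulted blocks.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  check_keys(raw, known_config_keys$top, "top level")
  sim_args <- raw$simulate %||% list()
  check_keys(sim_args, names(formals(sim_config)), "simulate")
  caller_args <- raw$caller %||% list()
  check_keys(caller_args, names(formals(caller_params)), "caller")
  ann <- check_keys(raw$annotate %||% list(),
                    known_config_keys$annotate, "annotate")
  st <- check_keys(raw$stats %||% list(), known_config_keys$stats, "stats")
  paths <- check_keys(raw$paths %||% list(), known_config_keys$paths, "paths")
  seed <- raw$seed %||% 1L
  sim_args$seed <- sim_args$seed %||% seed
  structure(list(
    seed = as.integer(seed),
    out_dir = raw$out_dir %||% "sceccdna_run",
    simulate = do.call(sim_config, sim_args),
    caller = do.call(caller_params, caller_args),
    annotate = utils::modifyList(
      list(promoter_up = 2000, promoter_down = 200, downstream_bp = 3000),
      ann),
    stats = utils::modifyList(
      list(bins = 200, include_split = FALSE, min_mapq = 10), st),
    paths = paths
  ), class = "run_config")
}

#' Run the pipeline
#'
#' Orchestrates simulate, call, quantify and catalogue stages in dependency
#' order, writing each stage's outputs under `config$out_dir` and a JSON
#' run manifest recording the seed, parameter hashes, outputs and
#' durations. With a `paths$bam` (and `paths$cells`) entry the simulate
#' stage can be skipped and detection run on user data.
#'
#' @param config A [load_run_config()] object (or one built in code).
#' @param stages Character subset of
#'   `c("simulate", "call", "quantify", "catalogue")`.
#' @return Invisibly, a list with each executed stage's result and the
#'   manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "call", "quantify",
                                    "catalogue")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  note_stage <- function(stage, params, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      stage = stage,
      params_hash = rlang::hash(params),
      outputs = unname(unlist(outputs)),
      duration_s = round(as.numeric(Sys.time()) - t0, 2)
    )
  }

  bam <- config$paths$bam
  cells <- NULL
  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sim_dir <- file.path(config$out_dir, "simulate")
    results$simulate <- simulate_eccdna_reads(config$simulate, sim_dir)
    bam <- results$simulate$files$bam
    cells <- results$simulate$truth$cells |>
      mutate(sample_id = "sim", cluster_id = .data$cell_type)
    note_stage("simulate", unclass(config$simulate),
               results$simulate$files, t0)
  }
  if (!is.null(config$paths$cells)) {
    cells <- read_cell_table(config$paths$cells)
  }

  if ("call" %in% stages) {
    if (is.null(bam)) abort("call stage needs a BAM (simulate or paths$bam)")
    t0 <- as.numeric(Sys.time())
    call_dir <- file.path(config$out_dir, "call")
    results$call <- call_eccdna(bam, config$caller, out_dir = call_dir)
    note_stage("call", unclass(config$caller),
               list(file.path(call_dir, "calls.bed"),
                    file.path(call_dir, "calls.tsv")), t0)
  }

  if ("quantify" %in% stages) {
    if (is.null(results$call)) abort("quantify stage needs the call stage")
    if (is.null(cells)) abort("quantify stage needs a cell table")
    t0 <- as.numeric(Sys.time())
    q_dir <- file.path(config$out_dir, "quantify")
    mat <- build_matrix(results$call$evidence, results$call$calls, cells)
    io_matrix(mat, q_dir, "write")
    hf <- harboring_fraction(mat)
    readr::write_tsv(hf, file.path(q_dir, "harboring_fraction.tsv"))
    results$quantify <- list(matrix = mat, harboring = hf)
    note_stage("quantify", list(dedup = FALSE), list(q_dir), t0)
  }

  if ("catalogue" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cat_dir <- file.path(config$out_dir, "catalogue")
    dir.create(cat_dir, recursive = TRUE, showWarnings = FALSE)
    records <- if (!is.null(config$paths$regions)) {
      common_catalogue(unlist(config$paths$regions))
    } else if (!is.null(results$call)) {
      pass <- filter(results$call$calls, .data$status == "pass")
      common_catalogue(mutate(pass, sample_id = "sim"))
    } else {
      abort("catalogue stage needs call output or paths$regions")
    }
    readr::write_tsv(
      select(records$regions, "chrom", "start", "end", "region_id",
             "n_records", "n_samples"),
      file.path(cat_dir, "merged.bed"), col_names = FALSE)
    readr::write_tsv(records$membership,
                     file.path(cat_dir, "membership.tsv"))
    results$catalogue <- records
    note_stage("catalogue", list(min_samples = 1), list(cat_dir), t0)
  }

  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}
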