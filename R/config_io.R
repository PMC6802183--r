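#' Run configuration for the simulation pipeline
#'
#' Bundles everything one pipeline run depends on: the model tables, the
#' ensemble settings, the perturbation protocol, categorization rules, tree
#' settings and solver settings. Serializable to JSON; every archive
#' written by the pipeline embeds the configuration hash and seed.
#'
#' @param model_dir Directory holding the four model tables (defaults to the
#'   packaged reconstruction).
#' @param ensemble An [ensemble_config()].
#' @param o2_levels Oxygen fractions for the step protocol.
#' @param rule A [category_rule()].
#' @param tree A [tree_config()].
#' @param solver [solver_settings()].
#' @param out_dir Output directory for archives.
#' @return Object of class `run_config`.
#' @export
run_config <- function(model_dir = system.file("extdata", "model",
                                               package = "hypoxsig"),
                       ensemble = ensemble_config(),
                       o2_levels = c(0.05, 0.005, 0.001),
                       rule = category_rule(),
                       tree = tree_config(),
                       solver = solver_settings(),
                       out_dir = "results") {
  structure(list(model_dir = model_dir, ensemble = ensemble,
                 o2_levels = o2_levels, rule = rule, tree = tree,
                 solver = solver, out_dir = out_dir), class = "run_config")
}

#' Hash of a configuration (or any serializable object)
#'
#' @param x Object.
#' @return Character md5 string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write a population archive
#'
#' One wide delimited table per condition (rows = cases, columns = species)
#' plus a JSON metadata sidecar carrying the seed, configuration hash,
#' solver settings and convergence counts.
#'
#' @param population An `ensemble`.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` recorded in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_population_archive <- function(population, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  conds <- c(list(NULL), as.list(unique(unlist(
    lapply(population$records, function(r) names(r$conditions))))))
  for (cond in conds) {
    M <- steady_state_matrix(population, cond, converged_only = FALSE)
    if (nrow(M) == 0) next
    nm <- if (is.null(cond)) "baseline" else gsub("[^A-Za-z0-9._-]", "_", cond)
    p <- file.path(dir, paste0("steady_state_", nm, ".tsv"))
    utils::write.table(data.frame(case_id = rownames(M), M,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(seed = population$config$seed,
               n_cases = population$config$n_cases,
               fold_range = population$config$fold_range,
               sampled_species = population$sampled_species,
               config_hash = if (!is.null(config)) config_hash(config) else NA,
               convergence = convergence_report(population))
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read a wide steady-state table from a population archive
#'
#' @param path Path to a `steady_state_*.tsv` written by
#'   [write_population_archive()].
#' @return Numeric matrix, cases x species, rownames = case ids.
#' @export
read_population_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$case_id
  M
}
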