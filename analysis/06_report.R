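#!/usr/bin/env Rscript
# Stage 6: aggregate the pipeline outputs into one report document
# (results/report.json): model structure, convergence, phenotype fractions
# per condition, tree split features/thresholds, and drug sensitivity
# tallies. Every block is read from the archived stage outputs, so the
# report can be rebuilt without re-simulating.

suppressPackageStartupMessages(library(hypoxsig))
res <- "results"
read_if <- function(f) if (file.exists(file.path(res, f))) {
  read.delim(file.path(res, f))
} else NULL

report <- list(
  model = jsonlite::read_json(file.path(res, "model_summary.json")),
  population = jsonlite::read_json(file.path(res, "population",
                                             "metadata.json")),
  phenotype_fractions = read_if("phenotype_summary.tsv"),
  tree_thresholds = read_if("tree_thresholds.tsv"))

drug <- read_if("drug_sensitivity.tsv")
if (!is.null(drug)) {
  report$drug_sensitivity <- aggregate(case_id ~ target + o2 + class,
                                       data = drug, FUN = length)
  names(report$drug_sensitivity)[4] <- "n_cases"
}

jsonlite::write_json(report, file.path(res, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "rows")
cat("wrote results/report.json\n")
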