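#!/usr/bin/env Rscript
# Stage 3: categorize every cell's pERK and pAkt responses against its
# normoxic baseline (closed +/-10% no-change band) for each archived
# condition, and summarize the population fractions per condition.
# Resumes from the stage-2 archive; writes results/phenotypes.tsv and
# results/phenotype_summary.tsv.

suppressPackageStartupMessages(library(hypoxsig))
arch <- file.path("results", "population")
stopifnot(file.exists(file.path(arch, "steady_state_baseline.tsv")))

base <- read_population_table(file.path(arch, "steady_state_baseline.tsv"))
cond_files <- setdiff(list.files(arch, pattern = "^steady_state_.*\\.tsv$"),
                      "steady_state_baseline.tsv")
pop <- ensemble_from_states(base)
for (f in cond_files) {
  lab <- sub("^steady_state_", "", sub("\\.tsv$", "", f))
  lab <- gsub("_", "=", lab)  # archive-safe name back to the label
  M <- read_population_table(file.path(arch, f))
  for (i in seq_along(pop$records)) {
    cid <- as.character(pop$records[[i]]$case_id)
    if (cid %in% rownames(M)) {
      pop$records[[i]]$conditions[[lab]] <-
        structure(list(state = M[cid, ], converged = TRUE,
                       residual = NA_real_, t_elapsed = NA_real_),
                  class = "steady_state")
    }
  }
}

conds <- names(pop$records[[1]]$conditions)
tab <- phenotype_table(pop, conds, c("pERK", "pAkt", "pERK/tERK", "pAkt/tAkt"))
write.table(tab, file.path("results", "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

rows <- list()
for (cond in conds) {
  for (rd in c("pERK", "pAkt")) {
    s <- summarize_phenotypes(pop, cond, rd)
    print(s)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, readout = rd, n = s$n,
      t(as.matrix(s$fractions)))
  }
}
write.table(do.call(rbind, rows), file.path("results", "phenotype_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/phenotypes.tsv and results/phenotype_summary.tsv\n")
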