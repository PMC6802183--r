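#!/usr/bin/env Rscript
# Stage 4: explain the response categories with decision trees over the
# normoxic (pre-stimulus) steady-state features plus the phospho/total
# ratios: which biomolecule levels decide whether a cell's pERK is
# hypoxia-sensitive, and the two-stage pAkt analysis (change vs no-change,
# then increase vs decrease). Writes a thresholds table and DOT renderings
# under results/trees/.

suppressPackageStartupMessages(library(hypoxsig))
arch <- file.path("results", "population")
base <- read_population_table(file.path(arch, "steady_state_baseline.tsv"))
phen <- read.delim(file.path("results", "phenotypes.tsv"))
pop <- ensemble_from_states(base)
ft <- feature_table(pop)

out <- file.path("results", "trees")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
thr_rows <- list()
keep <- function(id, tr) {
  writeLines(tree_dot(tr), file.path(out, paste0(id, ".dot")))
  writeLines(capture.output(print(tr)), file.path(out, paste0(id, ".txt")))
  nd <- tr$nodes[tr$nodes$feature != "<leaf>", ]
  if (nrow(nd)) {
    thr_rows[[length(thr_rows) + 1L]] <<- data.frame(
      figure = id, feature = nd$feature, threshold = nd$threshold,
      direction = nd$direction, n = nd$n)
  }
}

lab_of <- function(cond, readout) {
  t1 <- phen[phen$condition == cond & phen$readout == readout, ]
  t1[match(rownames(ft), t1$case_id), "category"]
}

# pERK hypoxia sensitivity at the severest step (0.1% oxygen)
cat("\n-- pERK sensitivity, 0.1% O2 --\n")
cats <- lab_of("o2=0.001", "pERK")
ok <- !is.na(cats)
tr <- fit_tree(ft[ok, ], factor(ifelse(cats[ok] == "decrease",
                                       "decrease", "no_change")))
print(tr); keep("perk_sensitivity_0.001", tr)

# two-stage pAkt analysis at 0.5% oxygen
cat("\n-- pAkt two-stage, 0.5% O2 --\n")
cats <- lab_of("o2=0.005", "pAkt")
ok <- !is.na(cats)
s1 <- fit_tree(ft[ok, ], factor(ifelse(cats[ok] == "no_change",
                                       "no_change", "change")))
print(s1); keep("pakt_stage1_0.005", s1)
idx <- which(ok)[cats[ok] != "no_change"]
if (length(unique(cats[idx])) > 1) {
  s2 <- fit_tree(ft[idx, , drop = FALSE], droplevels(factor(cats[idx])))
  print(s2); keep("pakt_stage2_0.005", s2)
}

write.table(do.call(rbind, thr_rows), file.path("results", "tree_thresholds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nwrote results/tree_thresholds.tsv and results/trees/*\n")
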