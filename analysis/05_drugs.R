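#!/usr/bin/env Rscript
# Stage 5: drug-action experiments on a subset of the archived population.
# For each of the four targets (ATP-competitive RAF/MEK/Akt phosphorylation
# inhibition; VEGF-binding inhibition) the cells are run at normoxia and at
# 0.5% oxygen across the reference dose, ratios are normalized to the
# same-oxygen no-drug steady state, and per-case sensitivity classes are
# tallied. One full concentration-response curve is computed for the first
# case to report the hypoxia-induced half-inhibition shift.
#
# Usage: Rscript analysis/05_drugs.R [n_cases_subset]

suppressPackageStartupMessages(library(hypoxsig))
args <- commandArgs(trailingOnly = TRUE)
n_sub <- if (length(args) >= 1) as.integer(args[1]) else 40L

st <- solver_settings(rtol = 1e-8, atol = 1e-10)
net <- load_builtin_model(st)
base <- read_population_table(file.path("results", "population",
                                        "steady_state_baseline.tsv"))
pop <- ensemble_from_states(base)
sub <- vapply(pop$records, `[[`, 0L, "case_id")
sub <- sub[seq_len(min(n_sub, length(sub)))]

dir.create("results", showWarnings = FALSE)
rows <- list()
for (target in drug_targets()) {
  ex <- drug_experiment(target)
  res <- reference_dose_response(net, pop, ex, cases = sub, settings = st)
  res$class <- classify_sensitivity(res$ratio, ex$sensitivity_bands)
  rows[[target]] <- res
  for (o2 in ex$o2_levels) {
    cl <- table(res$class[res$o2 == o2])
    cat(sprintf("%-13s o2=%-6g sensitive=%2d intermediate=%2d ineffective=%2d\n",
                target, o2, cl["sensitive"], cl["intermediate"],
                cl["ineffective"]))
  }
}
write.table(do.call(rbind, rows), file.path("results", "drug_sensitivity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# full concentration-response curve for one case, RAF inhibition
ex <- drug_experiment("RAF_phospho")
res <- run_drug_experiment(net, pop, ex, cases = sub[1], settings = st)
write.table(res$curves, file.path("results", "dose_response_raf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cn <- dose_response_curve(res, sub[1], 1)
ch <- dose_response_curve(res, sub[1], 0.005)
shift <- half_inhibition_shift(cn, ch)
if (is.na(shift)) {
  cat("half-inhibition shift: not defined for this case (",
      attr(shift, "reason"), ")\n")
} else {
  cat(sprintf("half-inhibition [D]/Ki shift (normoxia/hypoxia): %.2f-fold\n",
              shift))
}
cat("wrote results/drug_sensitivity.tsv and results/dose_response_raf.tsv\n")
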