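#' Categorization rule for perturbation responses
#'
#' A response is the perturbed/baseline ratio of a readout. The no-change
#' band is the closed interval `[0.9, 1.1]` (within +/-10% change);
#' `decrease` is a ratio below the band, `increase` above. `fold_threshold`
#' (default 100) separates "large" from "small" VEGF fold responses.
#'
#' @param no_change_band Length-2 numeric, lower < 1 < upper.
#' @param fold_threshold Fold-change separating large from small responses.
#' @return Object of class `category_rule`.
#' @export
category_rule <- function(no_change_band = c(0.9, 1.1), fold_threshold = 100) {
  stopifnot(length(no_change_band) == 2, no_change_band[1] < 1,
            no_change_band[2] > 1)
  structure(list(no_change_band = no_change_band,
                 fold_threshold = fold_threshold), class = "category_rule")
}

#' Phosphorylated/total mapping for the shipped model
#'
#' Defines which species count as the phosphorylated and the total pool of
#' each readout ratio. Totals include complexed forms (the PIP3-bound Akt
#' pools count toward total Akt) so the ratios stay in [0, 1].
#'
#' @return Named list; each element has `num` (phosphorylated forms) and
#'   `den` (all forms).
#' @export
phospho_totals_map <- function() {
  list(
    "pAkt/tAkt" = list(num = c("pAkt", "pPIP3_Akt"),
                       den = c("Akt", "pAkt", "PIP3_Akt", "pPIP3_Akt")),
    "pERK/tERK" = list(num = "pERK",
                       den = c("ERK", "pERK"))
  )
}

readout_value <- function(state, readout, totals = phospho_totals_map()) {
  if (readout %in% names(totals)) {
    m <- totals[[readout]]
    num <- sum(state[m$num]); den <- sum(state[m$den])
    if (den <= 0) return(NA_real_)
    num / den
  } else {
    if (!(readout %in% names(state))) {
      stop("unknown readout '", readout, "'", call. = FALSE)
    }
    unname(state[readout])
  }
}

#' Perturbed/baseline response ratio of a readout
#'
#' @param record One ensemble record (with `baseline` and `conditions`).
#' @param condition Condition label (see [cell_env()] labels in
#'   `record$conditions`).
#' @param readout Species id, or a derived-ratio name from `totals`.
#' @param totals Phospho/total mapping, see [phospho_totals_map()].
#' @return The ratio, or `NA` with attribute `reason` when either steady
#'   state is non-converged or the baseline readout is non-positive.
#' @export
response_ratio <- function(record, condition, readout,
                           totals = phospho_totals_map()) {
  cond <- record$conditions[[condition]]
  if (is.null(cond)) stop("condition '", condition, "' not simulated", call. = FALSE)
  if (!record$baseline$converged || !cond$converged) {
    return(structure(NA_real_, reason = "non_converged"))
  }
  b <- readout_value(record$baseline$state, readout, totals)
  p <- readout_value(cond$state, readout, totals)
  if (!is.finite(b) || b <= 0) {
    return(structure(NA_real_, reason = "baseline_nonpositive"))
  }
  p / b
}

#' Categorize a response ratio
#'
#' `decrease` iff ratio < band lower; `no_change` iff ratio inside the
#' closed band; `increase` iff ratio > band upper. Vectorized; `NA` ratios
#' give `NA` categories.
#'
#' @param ratio Numeric vector of ratios (>= 0).
#' @param rule A [category_rule()].
#' @return Factor with levels `decrease`, `no_change`, `increase`.
#' @export
categorize <- function(ratio, rule = category_rule()) {
  lo <- rule$no_change_band[1]; hi <- rule$no_change_band[2]
  out <- ifelse(is.na(ratio), NA_character_,
         ifelse(ratio < lo, "decrease",
         ifelse(ratio > hi, "increase", "no_change")))
  factor(out, levels = c("decrease", "no_change", "increase"))
}

#' Phosphorylated-over-total ratio of a record's steady state
#'
#' @param record One ensemble record.
#' @param pair Ratio name present in `totals` (e.g. `"pAkt/tAkt"`).
#' @param condition `NULL` for the normoxic baseline, else a condition label.
#' @param totals Phospho/total mapping.
#' @return Value in [0, 1] (or `NA` if the state is unavailable).
#' @export
derived_ratio <- function(record, pair, condition = NULL,
                          totals = phospho_totals_map()) {
  if (!(pair %in% names(totals))) {
    stop("no phospho/total mapping for '", pair, "'", call. = FALSE)
  }
  ss <- if (is.null(condition)) record$baseline else record$conditions[[condition]]
  if (is.null(ss)) return(NA_real_)
  readout_value(ss$state, pair, totals)
}

#' Tidy table of per-case response ratios and categories
#'
#' @param population An `ensemble` with simulated conditions.
#' @param conditions Character vector of condition labels.
#' @param readouts Character vector of readouts (species or derived ratios).
#' @param rule A [category_rule()].
#' @param totals Phospho/total mapping.
#' @return data.frame: `case_id`, `condition`, `readout`, `ratio`,
#'   `category`, `excluded_reason`.
#' @export
phenotype_table <- function(population, conditions, readouts,
                            rule = category_rule(),
                            totals = phospho_totals_map()) {
  rows <- list()
  for (cond in conditions) {
    for (rd in readouts) {
      ratios <- vapply(population$records, function(rec) {
        as.numeric(response_ratio(rec, cond, rd, totals))
      }, numeric(1))
      reasons <- vapply(population$records, function(rec) {
        r <- response_ratio(rec, cond, rd, totals)
        if (is.na(r)) attr(r, "reason") %||% "unknown" else ""
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = vapply(population$records, `[[`, 0L, "case_id"),
        condition = cond, readout = rd, ratio = ratios,
        category = categorize(ratios, rule),
        excluded_reason = reasons, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population summary of a readout under one condition
#'
#' Category fractions are computed over converged, includable cases (the
#' denominator is reported); binomial 95% intervals accompany each fraction
#' for scaled-down runs. A log-spaced ratio histogram is attached.
#'
#' @param population An `ensemble` with simulated conditions.
#' @param condition Condition label.
#' @param readout Readout name.
#' @param rule A [category_rule()].
#' @param totals Phospho/total mapping.
#' @param bins Number of log-spaced histogram bins.
#' @return Object of class `phenotype_summary`: `condition`, `readout`,
#'   `n`, `n_excluded`, `fractions`, `ci` (2 x 3), `counts`, `hist`.
#' @export
summarize_phenotypes <- function(population, condition, readout,
                                 rule = category_rule(),
                                 totals = phospho_totals_map(), bins = 40) {
  tab <- phenotype_table(population, condition, readout, rule, totals)
  ok <- !is.na(tab$ratio)
  if (!any(ok)) stop("no converged cases to summarize", call. = FALSE)
  cats <- tab$category[ok]
  counts <- table(cats)
  n <- sum(counts)
  fractions <- as.numeric(counts) / n
  names(fractions) <- names(counts)
  ci <- vapply(as.numeric(counts), function(k) {
    as.numeric(stats::binom.test(k, n)$conf.int)
  }, numeric(2))
  colnames(ci) <- names(counts)
  r <- tab$ratio[ok]
  rng <- range(r[r > 0])
  breaks <- exp(seq(log(rng[1]) - 1e-9, log(rng[2]) + 1e-9, length.out = bins + 1))
  hcounts <- tabulate(findInterval(r[r > 0], breaks, rightmost.closed = TRUE),
                      nbins = bins)
  structure(list(condition = condition, readout = readout, n = n,
                 n_excluded = sum(!ok), fractions = fractions, ci = ci,
                 counts = counts,
                 hist = list(breaks = breaks, counts = hcounts)),
            class = "phenotype_summary")
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat(sprintf("phenotype_summary: %s | %s | n=%d (excluded %d)\n",
              x$condition, x$readout, x$n, x$n_excluded))
  for (k in names(x$fractions)) {
    cat(sprintf("  %-9s %5.1f%%  [%4.1f, %4.1f]\n", k, 100 * x$fractions[k],
                100 * x$ci[1, k], 100 * x$ci[2, k]))
  }
  invisible(x)
}

#' Maximal transient fold change of a readout after a step perturbation
#'
#' Integrates a timecourse from the record's normoxic baseline under the
#' perturbed environment and reports the maximal |fold change| of the
#' readout over the transient, together with the final (steady-state-like)
#' fold. Mirrors classifying VEGF responses by their maximal change.
#'
#' @param network Assembled `reaction_network`.
#' @param record One ensemble record with a converged baseline.
#' @param env Perturbed [cell_env()].
#' @param readout Species id (default `"VEGF"`).
#' @param t_end End of the sampled transient window.
#' @param n_samples Samples across the window (log-spaced after 0).
#' @param settings [solver_settings()].
#' @return List: `max_fold`, `final_fold`, `failed`.
#' @export
transient_fold_change <- function(network, record, env, readout = "VEGF",
                                  t_end = 2e5, n_samples = 120,
                                  settings = solver_settings()) {
  b <- readout_value(record$baseline$state, readout)
  if (!is.finite(b) || b <= 0) return(list(max_fold = NA_real_,
                                           final_fold = NA_real_, failed = TRUE))
  t_grid <- c(0, exp(seq(log(1e-2), log(t_end), length.out = n_samples - 1)))
  tc <- timecourse(network, record$baseline$state, env, t_grid, settings)
  vals <- tc[[readout]]
  list(max_fold = max(vals) / b, final_fold = vals[length(vals)] / b,
       failed = isTRUE(attr(tc, "failed")))
}

#' Feature table for tree explanation
#'
#' One row per converged case; features are the normoxic (pre-stimulus)
#' steady-state concentrations of the sampled species plus the derived
#' phospho/total ratios. Optionally the raw sampled initial concentrations
#' are used instead of equilibrated baselines.
#'
#' @param population An `ensemble`.
#' @param totals Phospho/total mapping (each becomes a feature; `/` in names
#'   is replaced by `_over_` to keep syntactic column names).
#' @param use_initials Use raw sampled initials instead of the equilibrated
#'   baseline steady state (default FALSE).
#' @param species Optional subset of species columns to keep.
#' @return data.frame of features with rownames = case ids.
#' @export
feature_table <- function(population, totals = phospho_totals_map(),
                          use_initials = FALSE, species = NULL) {
  conv <- vapply(population$records, function(r) r$baseline$converged, logical(1))
  recs <- population$records[conv]
  base <- if (use_initials) {
    do.call(rbind, lapply(recs, `[[`, "sampled_initials"))
  } else {
    do.call(rbind, lapply(recs, function(r) r$baseline$state))
  }
  keep <- species %||% population$sampled_species %||% colnames(base)
  keep <- intersect(colnames(base), keep)
  out <- as.data.frame(base[, keep, drop = FALSE])
  for (nm in names(totals)) {
    out[[gsub("/", "_over_", nm, fixed = TRUE)]] <-
      vapply(recs, derived_ratio, numeric(1), pair = nm, totals = totals)
  }
  rownames(out) <- vapply(recs, `[[`, 0L, "case_id")
  out
}
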