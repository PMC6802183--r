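#' Drug experiment specification
#'
#' One of the four drug actions (ATP-competitive inhibition of RAF, MEK or
#' Akt phosphorylation; inhibition of VEGF binding), a dose grid in
#' `[D]/K_i` units, the oxygen levels to test, and the readout. Reference
#' doses default to the values used for the published response histograms:
#' 100 (RAF), 2000 (MEK), 200 (Akt), 1000 (VEGF binding).
#'
#' @param target One of [drug_targets()].
#' @param d_over_ki_grid Ascending positive dose grid; default 13 points
#'   log-spaced over 1e-1..1e5.
#' @param o2_levels Oxygen fractions of normoxia to test.
#' @param readout Response readout (`"pERK"` for RAF/MEK, `"pAkt"` for
#'   Akt/VEGF targets by default).
#' @param reference_dose `[D]/K_i` used for sensitivity classification.
#' @param sensitivity_bands Ratio cutpoints: `sensitive` at or below the
#'   first (>= 40% reduction), `ineffective` at or above the second
#'   (< 10% reduction).
#' @return Object of class `drug_experiment`.
#' @export
drug_experiment <- function(target,
                            d_over_ki_grid = 10^seq(-1, 5, length.out = 13),
                            o2_levels = c(1, 0.005),
                            readout = NULL,
                            reference_dose = NULL,
                            sensitivity_bands = c(sensitive = 0.6,
                                                  ineffective = 0.9)) {
  stopifnot(target %in% drug_targets())
  if (is.unsorted(d_over_ki_grid, strictly = TRUE) || any(d_over_ki_grid <= 0)) {
    stop("d_over_ki_grid must be ascending and positive", call. = FALSE)
  }
  if (is.null(readout)) {
    readout <- if (target %in% c("RAF_phospho", "MEK_phospho")) "pERK" else "pAkt"
  }
  if (is.null(reference_dose)) {
    reference_dose <- c(RAF_phospho = 100, MEK_phospho = 2000,
                        AKT_phospho = 200, VEGF_binding = 1000)[[target]]
  }
  structure(list(target = target, d_over_ki_grid = d_over_ki_grid,
                 o2_levels = o2_levels, readout = readout,
                 reference_dose = reference_dose,
                 sensitivity_bands = sensitivity_bands),
            class = "drug_experiment")
}

#' Run a drug experiment over a virtual population
#'
#' For each converged case and oxygen level, the case is first brought to
#' its same-oxygen no-drug steady state, then integrated to steady state at
#' every grid dose; drug ratios are normalized to the same-oxygen no-drug
#' value so hypoxia and drug effects are not conflated. A zero dose is
#' always included (its ratio is exactly 1 by construction).
#'
#' @param network Assembled `reaction_network`.
#' @param population An `ensemble` (normoxic baselines).
#' @param experiment A [drug_experiment()].
#' @param cases Optional subset of case ids.
#' @param settings [solver_settings()].
#' @return Object of class `drug_response`: tidy data.frame `curves` with
#'   columns `case_id`, `target`, `o2`, `d_over_ki`, `value`, `ratio`,
#'   `converged`, plus the `experiment`.
#' @export
run_drug_experiment <- function(network, population, experiment,
                                cases = NULL, settings = solver_settings()) {
  plan <- network_plan(network)
  recs <- Filter(function(r) r$baseline$converged, population$records)
  if (!is.null(cases)) {
    recs <- Filter(function(r) r$case_id %in% cases, recs)
  }
  rows <- list()
  for (rec in recs) {
    for (o2 in experiment$o2_levels) {
      base_env <- cell_env(o2_fraction = o2)
      base_ss <- integrate_to_steady_state(network, rec$baseline$state,
                                           base_env, settings, plan)
      b <- if (base_ss$converged) {
        readout_value(base_ss$state, experiment$readout)
      } else NA_real_
      doses <- c(0, experiment$d_over_ki_grid)
      for (d in doses) {
        if (d == 0) {
          val <- b; conv <- base_ss$converged
        } else {
          env <- cell_env(o2_fraction = o2,
                          drugs = stats::setNames(d, experiment$target))
          ss <- integrate_to_steady_state(network, base_ss$state, env,
                                          settings, plan)
          conv <- ss$converged && base_ss$converged
          val <- if (ss$converged) readout_value(ss$state, experiment$readout)
                 else NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = rec$case_id, target = experiment$target, o2 = o2,
          d_over_ki = d, value = val,
          ratio = if (isTRUE(conv) && is.finite(b) && b > 0) val / b else NA_real_,
          converged = isTRUE(conv))
      }
    }
  }
  structure(list(curves = do.call(rbind, rows), experiment = experiment),
            class = "drug_response")
}

#' Extract one dose-response curve
#'
#' @param response A `drug_response`.
#' @param case_id Case id.
#' @param o2 Oxygen fraction.
#' @return data.frame `d_over_ki`, `ratio` (zero dose excluded).
#' @export
dose_response_curve <- function(response, case_id, o2) {
  cur <- response$curves
  cur <- cur[cur$case_id == case_id & cur$o2 == o2 & cur$d_over_ki > 0, ]
  cur[order(cur$d_over_ki), c("d_over_ki", "ratio")]
}

interp_half_inhibition <- function(curve) {
  r <- curve$ratio; d <- curve$d_over_ki
  ok <- is.finite(r)
  r <- r[ok]; d <- d[ok]
  if (length(r) < 2) return(NA_real_)
  cross <- which(r[-length(r)] > 0.5 & r[-1] <= 0.5)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  exp(log(d[i]) + (0.5 - r[i]) * (log(d[i + 1]) - log(d[i])) / (r[i + 1] - r[i]))
}

#' Fold shift of the half-inhibition dose between two curves
#'
#' Both curves must cross the 0.5 ratio; the half-inhibition `[D]/K_i` of
#' each is obtained by log-linear interpolation and the shift is
#' `d50(curve_a) / d50(curve_b)`. For a normoxia curve as `curve_a` and a
#' hypoxia curve as `curve_b`, a shift above 1 means hypoxia sensitizes
#' (less drug needed for 50% inhibition). Returns `NA` with a `reason`
#' attribute when either curve does not cross 0.5.
#'
#' @param curve_a,curve_b data.frames with `d_over_ki` and `ratio`.
#' @return Fold shift, or `NA`.
#' @export
half_inhibition_shift <- function(curve_a, curve_b) {
  da <- interp_half_inhibition(curve_a)
  db <- interp_half_inhibition(curve_b)
  if (!is.finite(da) || !is.finite(db)) {
    return(structure(NA_real_, reason = "curve does not cross 0.5"))
  }
  da / db
}

#' Classify per-case drug sensitivity at a reference dose
#'
#' `sensitive` at a ratio at or below the strong-inhibition cut (default
#' 0.6, i.e. >= 40% reduction of the readout), `ineffective` at or above
#' the weak cut (default 0.9, < 10% reduction), `intermediate` otherwise.
#'
#' @param ratio Readout ratio(s) at the reference dose (>= 0).
#' @param bands Named cutpoints `sensitive`, `ineffective`.
#' @return Factor with levels `sensitive`, `intermediate`, `ineffective`.
#' @export
classify_sensitivity <- function(ratio, bands = c(sensitive = 0.6,
                                                  ineffective = 0.9)) {
  stopifnot(bands[["sensitive"]] < bands[["ineffective"]])
  out <- ifelse(is.na(ratio), NA_character_,
         ifelse(ratio <= bands[["sensitive"]], "sensitive",
         ifelse(ratio >= bands[["ineffective"]], "ineffective",
                "intermediate")))
  factor(out, levels = c("sensitive", "intermediate", "ineffective"))
}

#' Per-case readout ratios at one reference dose
#'
#' Convenience: runs only the zero dose and the reference dose for each
#' case and oxygen level (much cheaper than a full grid) and returns the
#' per-case ratio and sensitivity class.
#'
#' @inheritParams run_drug_experiment
#' @return data.frame: `case_id`, `target`, `o2`, `ratio`, `class`.
#' @export
reference_dose_response <- function(network, population, experiment,
                                    cases = NULL,
                                    settings = solver_settings()) {
  exp1 <- experiment
  exp1$d_over_ki_grid <- experiment$reference_dose
  res <- run_drug_experiment(network, population, exp1, cases, settings)
  cur <- res$curves[res$curves$d_over_ki > 0, ]
  data.frame(case_id = cur$case_id, target = cur$target, o2 = cur$o2,
             ratio = cur$ratio,
             class = classify_sensitivity(cur$ratio, experiment$sensitivity_bands))
}
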