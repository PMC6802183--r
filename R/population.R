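#' Ensemble (virtual cell population) configuration
#'
#' The study conditions for the virtual population: every biomolecule of the
#' tumor signaling module is sampled by Latin hypercube over a 100-fold
#' log-spaced range centered on its tabulated nominal value (so the nominal
#' is the median), while the HIF/ATP-module variables are held fixed. The
#' published run uses 20,000 cases; scaled-down runs pass a smaller
#' `n_cases` explicitly.
#'
#' @param n_cases Number of virtual cells (default 20000).
#' @param fold_range Total span of the sampled range (default 100, i.e.
#'   nominal/10 to nominal*10).
#' @param seed RNG seed controlling the Latin hypercube.
#' @param sampled_species Species ids to sample; `NULL` means every species
#'   whose `module` column is `"tumor"`.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_cases = 20000, fold_range = 100, seed = 1,
                            sampled_species = NULL) {
  stopifnot(n_cases >= 0, fold_range > 1)
  structure(list(n_cases = as.integer(n_cases), fold_range = fold_range,
                 seed = as.integer(seed), sampled_species = sampled_species),
            class = "ensemble_config")
}

resolve_sampled <- function(network, cfg) {
  if (is.null(cfg$sampled_species)) {
    network$species$id[network$species$module == "tumor"]
  } else {
    missing_sp <- setdiff(cfg$sampled_species, network$species$id)
    if (length(missing_sp)) {
      stop("sampled_species not in network: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    cfg$sampled_species
  }
}

#' Latin hypercube sample of initial concentrations
#'
#' For each sampled species the `n_cases` values are a stratified
#' (one-draw-per-equal-log-width-bin) sample of a log10-uniform distribution
#' over `[nominal/sqrt(fold_range), nominal*sqrt(fold_range)]`; unsampled
#' species keep their nominal values. Deterministic for a fixed seed.
#'
#' @param nominals Named numeric vector of nominal concentrations for every
#'   species (the network's initial state).
#' @param cfg An [ensemble_config()].
#' @param sampled Character vector of species ids to sample; defaults to
#'   `cfg$sampled_species`, or every species in `nominals` when that is
#'   `NULL`.
#' @return Numeric matrix, `n_cases` rows, one column per species in
#'   `names(nominals)` order.
#' @export
lhs_sample <- function(nominals, cfg, sampled = NULL) {
  if (is.null(sampled)) {
    sampled <- if (is.null(cfg$sampled_species)) names(nominals)
               else cfg$sampled_species
  }
  if (any(nominals[sampled] <= 0)) {
    bad <- sampled[nominals[sampled] <= 0]
    stop("sampled species with non-positive nominal value: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- cfg$n_cases
  if (n == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(nominals),
                  dimnames = list(NULL, names(nominals))))
  }
  out <- matrix(rep(nominals, each = n), nrow = n,
                dimnames = list(NULL, names(nominals)))
  if (length(sampled) == 0) return(out)
  set.seed(cfg$seed)
  u <- lhs::randomLHS(n, length(sampled))
  half <- sqrt(cfg$fold_range)
  for (k in seq_along(sampled)) {
    sp <- sampled[k]
    out[, sp] <- nominals[sp] * half^(2 * u[, k] - 1)
  }
  out
}

#' Generate the virtual cell population (normoxic baselines)
#'
#' Samples initial concentrations by [lhs_sample()] and equilibrates each
#' case to its normoxic steady state. Non-converged cases are flagged and
#' retained; batch generation never aborts on a single case.
#'
#' @param network Assembled `reaction_network`.
#' @param cfg An [ensemble_config()].
#' @param settings [solver_settings()].
#' @return Object of class `ensemble`: list with `records` (one per case:
#'   `case_id`, `sampled_initials`, `baseline` steady state, `conditions`
#'   empty list) and `config`.
#' @export
generate_population <- function(network, cfg = ensemble_config(),
                                settings = solver_settings()) {
  sampled <- resolve_sampled(network, cfg)
  nominals <- initial_state(network)
  X <- lhs_sample(nominals, cfg, sampled)
  plan <- network_plan(network)
  records <- vector("list", cfg$n_cases)
  for (i in seq_len(cfg$n_cases)) {
    ss <- integrate_to_steady_state(network, X[i, ], cell_env(), settings, plan)
    records[[i]] <- list(case_id = i, sampled_initials = X[i, ],
                         baseline = ss, conditions = list())
  }
  structure(list(records = records, config = cfg,
                 sampled_species = sampled), class = "ensemble")
}

#' Add perturbed steady states to a population
#'
#' Runs each condition from every converged baseline (step-change protocol;
#' conditions are independent). Cases whose baseline did not converge are
#' skipped.
#'
#' @param network Assembled `reaction_network`.
#' @param population An `ensemble` from [generate_population()].
#' @param conditions List of [cell_env()] objects.
#' @param settings [solver_settings()].
#' @return The `ensemble` with each record's `conditions` extended (keyed by
#'   condition label).
#' @export
populate_conditions <- function(network, population, conditions,
                                settings = solver_settings()) {
  plan <- network_plan(network)
  for (i in seq_along(population$records)) {
    rec <- population$records[[i]]
    if (!rec$baseline$converged) next
    pr <- run_step_protocol(network, rec$baseline$state, conditions,
                            settings, plan)
    rec$conditions <- c(rec$conditions, pr$conditions)
    population$records[[i]] <- rec
  }
  population
}

#' Wide matrix of steady-state concentrations
#'
#' @param population An `ensemble`.
#' @param condition `NULL` for the normoxic baseline, else a condition label.
#' @param converged_only Drop non-converged cases (default TRUE).
#' @return Numeric matrix, cases x species, rownames = case ids.
#' @export
steady_state_matrix <- function(population, condition = NULL,
                                converged_only = TRUE) {
  pick <- function(rec) {
    ss <- if (is.null(condition)) rec$baseline else rec$conditions[[condition]]
    if (is.null(ss) || (converged_only && !ss$converged)) return(NULL)
    ss$state
  }
  rows <- lapply(population$records, pick)
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- vapply(population$records[keep], `[[`, 0L, "case_id")
  out
}

#' Fraction of converged cases
#'
#' @param population An `ensemble`.
#' @param condition `NULL` for baseline, else a condition label.
#' @return Named list: `n_total`, `n_converged`, `fraction`.
#' @export
convergence_report <- function(population, condition = NULL) {
  conv <- vapply(population$records, function(rec) {
    ss <- if (is.null(condition)) rec$baseline else rec$conditions[[condition]]
    !is.null(ss) && isTRUE(ss$converged)
  }, logical(1))
  list(n_total = length(conv), n_converged = sum(conv),
       fraction = if (length(conv)) mean(conv) else NA_real_)
}

#' Rebuild an ensemble from archived baseline steady states
#'
#' Reconstructs minimal ensemble records (converged baselines, no
#' conditions) from a wide cases-x-species matrix, e.g. one written by
#' [write_population_archive()] and read back with
#' [read_population_table()]. Later pipeline stages (condition runs, drug
#' experiments) can then resume from the archive.
#'
#' @param states Numeric matrix, cases x species; rownames are case ids.
#' @param sampled_species Optional sampled-species ids to record.
#' @return An `ensemble`.
#' @export
ensemble_from_states <- function(states, sampled_species = NULL) {
  records <- lapply(seq_len(nrow(states)), function(i) {
    st <- states[i, ]
    list(case_id = as.integer(rownames(states)[i] %||% i),
         sampled_initials = st,
         baseline = structure(list(state = st, converged = TRUE,
                                   residual = NA_real_, t_elapsed = NA_real_),
                              class = "steady_state"),
         conditions = list())
  })
  structure(list(records = records,
                 config = ensemble_config(n_cases = nrow(states)),
                 sampled_species = sampled_species %||% colnames(states)),
            class = "ensemble")
}

#' Labeled dataset with a planted decision threshold
#'
#' Oracle dataset for the tree explainer: the label is
#' `indicator(feature_1 > threshold)` with labels flipped at `noise_rate`;
#' the remaining features are independent uniform noise.
#'
#' @param n Number of rows.
#' @param threshold Planted split point in (0, 1).
#' @param feature_count Number of features (>= 1).
#' @param noise_rate Label-flip probability in [0, 0.5).
#' @param seed RNG seed.
#' @return data.frame with factor column `label` (levels `neg`, `pos`) and
#'   features `x1..xk`; the planted feature is `x1`.
#' @export
planted_threshold_dataset <- function(n, threshold = 0.5, feature_count = 5,
                                      noise_rate = 0, seed = 1) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5, feature_count >= 1,
            threshold > 0, threshold < 1)
  set.seed(seed)
  X <- matrix(stats::runif(n * feature_count), nrow = n)
  colnames(X) <- paste0("x", seq_len(feature_count))
  lab <- X[, 1] > threshold
  flip <- stats::runif(n) < noise_rate
  lab <- xor(lab, flip)
  data.frame(label = factor(ifelse(lab, "pos", "neg"), levels = c("neg", "pos")),
             X)
}

#' Labeled dataset with two nested planted thresholds
#'
#' Oracle for the two-stage tree procedure: stage one separates `no_change`
#' (feature `x1 <= thr1`) from `change`; within `change`, stage two separates
#' `increase` (`x2 > thr2`) from `decrease`.
#'
#' @param n Number of rows.
#' @param thr1,thr2 Planted thresholds in (0, 1).
#' @param feature_count Number of features (>= 2).
#' @param noise_rate Label-flip probability per stage.
#' @param seed RNG seed.
#' @return data.frame with factor `label` in
#'   `{no_change, increase, decrease}` and features `x1..xk`.
#' @export
planted_two_stage_dataset <- function(n, thr1 = 0.5, thr2 = 0.5,
                                      feature_count = 5, noise_rate = 0,
                                      seed = 1) {
  stopifnot(feature_count >= 2, noise_rate >= 0, noise_rate < 0.5)
  set.seed(seed)
  X <- matrix(stats::runif(n * feature_count), nrow = n)
  colnames(X) <- paste0("x", seq_len(feature_count))
  change <- X[, 1] > thr1
  change <- xor(change, stats::runif(n) < noise_rate)
  up <- X[, 2] > thr2
  up <- xor(up, stats::runif(n) < noise_rate)
  lab <- ifelse(!change, "no_change", ifelse(up, "increase", "decrease"))
  data.frame(label = factor(lab, levels = c("no_change", "increase", "decrease")),
             X)
}

#' Toy fixture networks with analytically known steady states
#'
#' Small (<= 6 dynamic species) networks exercising every rate-law type
#' across kinds, used as oracles for the integrator and assembly logic:
#' \describe{
#'   \item{linear_chain}{source -> A -> B -> C -> sink; A->B mass action,
#'     B->C Michaelis-Menten. Steady state solvable in closed form from the
#'     constant throughput flux.}
#'   \item{phospho_cycle}{E <-> pE; forward by the ATP-implicit
#'     phosphorylation law, reverse mass action. Conserved total E + pE;
#'     steady state from a quadratic.}
#'   \item{vegf_loop}{minimal HIF module (O2-controlled HIF degradation
#'     driving mRNA) assembled onto a minimal VEGF loop (mRNA-driven
#'     synthesis, degradation, receptor binding); the normoxic VEGF baseline
#'     equals the tabulated value by the re-baselining rule.}
#' }
#'
#' @param kind One of `"linear_chain"`, `"phospho_cycle"`, `"vegf_loop"`.
#' @return A `reaction_network` (assembled, for `vegf_loop`); parameters are
#'   attached as attribute `pars` for oracle computations.
#' @export
toy_fixture_network <- function(kind = c("linear_chain", "phospho_cycle",
                                         "vegf_loop")) {
  kind <- match.arg(kind)
  sp_row <- function(id, x0, module = "tumor", phospho = FALSE, pair = "") {
    data.frame(id = id, initial_conc = x0, unit = "nM", module = module,
               is_phospho_form = phospho, phospho_pair = pair,
               provenance = "toy", stringsAsFactors = FALSE)
  }
  rx_row <- function(id, reactants, products, law, params,
                     atp_dependent = FALSE, drug_target = "") {
    data.frame(id = id, reactants = reactants, products = products,
               rate_law = law, params = params, atp_dependent = atp_dependent,
               drug_target = drug_target, provenance = "toy",
               stringsAsFactors = FALSE)
  }
  if (kind == "linear_chain") {
    pars <- list(ks = 2, k1 = 0.5, vmax = 5, km = 10, kd = 0.25)
    sp <- rbind(sp_row("A", 1), sp_row("B", 1), sp_row("C", 1))
    rx <- rbind(
      rx_row("r_src", "", "A", "mass_action", sprintf("kf=%g", pars$ks)),
      rx_row("r_ab", "A", "B", "mass_action", sprintf("kf=%g", pars$k1)),
      rx_row("r_bc", "B", "C", "michaelis_menten",
             sprintf("vmax=%g;km=%g", pars$vmax, pars$km)),
      rx_row("r_sink", "C", "", "degradation", sprintf("k=%g", pars$kd)))
    net <- load_model_tables(sp, rx, clamped = character(0))
    attr(net, "pars") <- pars
    return(net)
  }
  if (kind == "phospho_cycle") {
    pars <- list(vmax = 1, k_prime = 10, kr = 0.05, total = 20)
    sp <- rbind(sp_row("E", 18), sp_row("pE", 2, phospho = TRUE, pair = "E"))
    rx <- rbind(
      rx_row("r_phos", "E", "pE", "atp_phospho",
             sprintf("vmax=%g;k_prime=%g", pars$vmax, pars$k_prime),
             atp_dependent = TRUE),
      rx_row("r_dephos", "pE", "E", "mass_action", sprintf("kf=%g", pars$kr)))
    net <- load_model_tables(sp, rx, clamped = character(0))
    attr(net, "pars") <- pars
    return(net)
  }
  # vegf_loop: minimal hif + minimal tumor, assembled
  pars <- list(ks_hif = 1, kd_hif = 0.1, k_tr = 0.2, kd_m = 0.05,
               k_syn = 4, vegf0 = 50, k1f = 1e-3, k1r = 1e-2,
               vegfr0 = 100)
  sp_h <- rbind(sp_row("O2", 1, module = "hif"),
                sp_row("HIF", 0, module = "hif"),
                sp_row("mRNA", 0, module = "hif"))
  rx_h <- rbind(
    rx_row("h_syn", "", "HIF", "mass_action", sprintf("kf=%g", pars$ks_hif)),
    rx_row("h_deg", "HIF + O2", "O2", "mass_action", sprintf("kf=%g", pars$kd_hif)),
    rx_row("h_tr", "HIF", "HIF + mRNA", "mass_action", sprintf("kf=%g", pars$k_tr)),
    rx_row("h_mdeg", "mRNA", "", "degradation", sprintf("k=%g", pars$kd_m)))
  hif <- load_model_tables(sp_h, rx_h, clamped = "O2")
  sp_t <- rbind(sp_row("VEGF", pars$vegf0), sp_row("VEGFR", pars$vegfr0),
                sp_row("VVEGFR", 5))
  rx_t <- rbind(
    rx_row("t_vegf_syn", "", "VEGF", "vegf_synthesis", sprintf("k_syn=%g", pars$k_syn)),
    rx_row("t_vegf_deg", "VEGF", "", "degradation", "k=1"),
    rx_row("t_bind", "VEGF + VEGFR", "VVEGFR", "vegf_binding",
           sprintf("k1f=%g;k1r=%g", pars$k1f, pars$k1r),
           drug_target = "VEGF_binding"))
  tumor <- load_model_tables(sp_t, rx_t, clamped = character(0))
  net <- assemble_integrated_model(hif, tumor, coupling_config())
  attr(net, "pars") <- pars
  net
}
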