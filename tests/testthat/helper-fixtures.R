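# Shared fixtures: tiny networks built in code, plus a lazily-built,
# memoized scaled-down virtual population used by the acceptance tests.

toy_species <- function(id, x0, module = "tumor", phospho = FALSE, pair = "") {
  data.frame(id = id, initial_conc = x0, unit = "nM", module = module,
             is_phospho_form = phospho, phospho_pair = pair,
             provenance = "toy", stringsAsFactors = FALSE)
}

toy_reaction <- function(id, reactants, products, law, params,
                         atp_dependent = FALSE, drug_target = "") {
  data.frame(id = id, reactants = reactants, products = products,
             rate_law = law, params = params, atp_dependent = atp_dependent,
             drug_target = drug_target, provenance = "toy",
             stringsAsFactors = FALSE)
}

# reversible two-species isomerization A <-> B
make_ab_network <- function(kf = 1, kr = 1, a0 = 2, b0 = 0) {
  load_model_tables(
    rbind(toy_species("A", a0), toy_species("B", b0)),
    toy_reaction("r_ab", "A", "B", "mass_action",
                 sprintf("kf=%g;kr=%g", kf, kr)),
    clamped = character(0))
}

# single-species decay X -> 0
make_decay_network <- function(k = 0.3, x0 = 5) {
  load_model_tables(
    toy_species("X", x0),
    toy_reaction("r_dx", "X", "", "degradation", sprintf("k=%g", k)),
    clamped = character(0))
}

# closed-form steady state of the phospho_cycle toy for a given total
phospho_cycle_ss <- function(total, vmax = 1, k_prime = 10, kr = 0.05) {
  # vmax*E/(K'+E) = kr*(T-E)  ->  kr*E^2 + (vmax + kr*K' - kr*T)*E - kr*K'*T = 0
  a <- kr; b <- vmax + kr * k_prime - kr * total; c <- -kr * k_prime * total
  e <- (-b + sqrt(b^2 - 4 * a * c)) / (2 * a)
  c(E = e, pE = total - e)
}

# builtin model + scaled-down ensemble, built once per test session
.fixture_cache <- new.env(parent = emptyenv())

builtin_model_cached <- function() {
  if (is.null(.fixture_cache$net)) {
    .fixture_cache$settings <- solver_settings(rtol = 1e-8, atol = 1e-10)
    .fixture_cache$net <- load_builtin_model(.fixture_cache$settings)
  }
  .fixture_cache$net
}

acceptance_settings <- function() {
  builtin_model_cached()
  .fixture_cache$settings
}

# scaled-down study population: 120 virtual cells, oxygen steps to 5%, 0.5%
# and 0.1% of normoxia
acceptance_population <- function() {
  if (is.null(.fixture_cache$pop)) {
    net <- builtin_model_cached()
    st <- acceptance_settings()
    pop <- generate_population(net, ensemble_config(n_cases = 120, seed = 101), st)
    pop <- populate_conditions(net, pop,
                               lapply(c(0.05, 0.005, 0.001), cell_env), st)
    .fixture_cache$pop <- pop
  }
  .fixture_cache$pop
}

acceptance_features <- function() {
  if (is.null(.fixture_cache$features)) {
    .fixture_cache$features <- feature_table(acceptance_population())
  }
  .fixture_cache$features
}
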