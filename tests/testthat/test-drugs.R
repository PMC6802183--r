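test_that("sensitivity bands classify reference-dose ratios", {
  expect_identical(as.character(classify_sensitivity(c(0.5, 0.95, 0.75))),
                   c("sensitive", "ineffective", "intermediate"))
  expect_identical(as.character(classify_sensitivity(c(0.6, 0.9))),
                   c("sensitive", "ineffective"))
})

test_that("half-inhibition shifts come from log-linear interpolation", {
  d <- 10^seq(-1, 4, length.out = 25)
  hill <- function(ec50) data.frame(d_over_ki = d, ratio = 1 / (1 + d / ec50))
  expect_equal(half_inhibition_shift(hill(10), hill(10)), 1, tolerance = 1e-9)
  expect_equal(half_inhibition_shift(hill(100), hill(10)), 10,
               tolerance = 0.02)
  flat <- data.frame(d_over_ki = d, ratio = rep(0.97, length(d)))
  out <- half_inhibition_shift(flat, hill(10))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "cross")
})

test_that("a zero dose reproduces the no-drug steady state exactly", {
  net <- toy_fixture_network("vegf_loop")
  pop <- generate_population(net, ensemble_config(n_cases = 2, seed = 2))
  ex <- drug_experiment("VEGF_binding", d_over_ki_grid = c(1, 100),
                        o2_levels = 1, readout = "VVEGFR")
  res <- run_drug_experiment(net, pop, ex)
  zero <- res$curves[res$curves$d_over_ki == 0, ]
  expect_true(all(zero$ratio == 1))
  # VEGF-binding inhibition strips the complex monotonically
  for (cid in unique(res$curves$case_id)) {
    cur <- dose_response_curve(res, cid, 1)
    expect_true(all(diff(cur$ratio) < 0))
    expect_true(all(cur$ratio < 1))
  }
})

test_that("ATP-competitive RAF inhibition suppresses pERK monotonically in the full model", {
  net <- builtin_model_cached()
  st <- acceptance_settings()
  bl <- integrate_to_steady_state(net, initial_state(net), cell_env(),
                                  settings = st)
  expect_true(bl$converged)
  doses <- c(10, 100, 1000)
  ratios <- vapply(doses, function(d) {
    ss <- integrate_to_steady_state(net, bl$state,
                                    cell_env(drugs = c(RAF_phospho = d)),
                                    settings = st)
    expect_true(ss$converged)
    ss$state[["pERK"]] / bl$state[["pERK"]]
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[3], 0.9)
  # Akt-axis inhibition suppresses pAkt below baseline at the reference dose
  ss_akt <- integrate_to_steady_state(net, bl$state,
                                      cell_env(drugs = c(AKT_phospho = 200)),
                                      settings = st)
  expect_lt(ss_akt$state[["pAkt"]] / bl$state[["pAkt"]], 1)
  # and leaves pERK comparatively unaffected (pathway selectivity)
  erk_change <- abs(ss_akt$state[["pERK"]] / bl$state[["pERK"]] - 1)
  akt_change <- abs(ss_akt$state[["pAkt"]] / bl$state[["pAkt"]] - 1)
  expect_lt(erk_change, akt_change)
})
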