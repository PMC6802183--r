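test_that("Latin hypercube sampling is stratified, centered and deterministic", {
  nominals <- c(A = 10, B = 100)
  cfg <- ensemble_config(n_cases = 100, fold_range = 100, seed = 5)
  X <- lhs_sample(nominals, cfg, sampled = "A")
  expect_identical(dim(X), c(100L, 2L))
  expect_true(all(X[, "B"] == 100))
  # one sample per equal log-width bin over [nominal/10, nominal*10]
  u <- (log10(X[, "A"] / 10) + 1) / 2 # back to (0,1)
  expect_true(all(u > 0 & u < 1))
  occupancy <- table(cut(u, breaks = seq(0, 1, length.out = 101)))
  expect_true(all(occupancy == 1))
  # determinism
  X2 <- lhs_sample(nominals, cfg, sampled = "A")
  expect_identical(X, X2)
  # range centered on the nominal: median of the stratified sample near it
  expect_equal(median(log10(X[, "A"])), 1, tolerance = 0.05)
  expect_error(lhs_sample(c(A = 0), ensemble_config(n_cases = 5), "A"),
               "non-positive")
})

test_that("population generation equilibrates each sampled case (closed-form oracle)", {
  cyc <- toy_fixture_network("phospho_cycle")
  cfg <- ensemble_config(n_cases = 12, seed = 3)
  pop <- generate_population(cyc, cfg)
  rep <- convergence_report(pop)
  expect_identical(rep$n_total, 12L)
  expect_identical(rep$n_converged, 12L)
  for (rec in pop$records) {
    total <- sum(rec$sampled_initials)
    expect_equal(unname(rec$baseline$state),
                 unname(phospho_cycle_ss(total)), tolerance = 1e-5)
  }
  # end-to-end seed determinism
  pop2 <- generate_population(cyc, cfg)
  expect_identical(lapply(pop$records, `[[`, "baseline"),
                   lapply(pop2$records, `[[`, "baseline"))
  # empty population edge
  empty <- generate_population(cyc, ensemble_config(n_cases = 0))
  expect_length(empty$records, 0L)
  expect_identical(nrow(steady_state_matrix(empty)), 0L)
})

test_that("planted threshold datasets have accuracy limited by the designed noise", {
  d0 <- planted_threshold_dataset(400, threshold = 0.5, noise_rate = 0, seed = 2)
  t0 <- fit_tree(d0[-1], d0$label, tree_config(max_depth = 1))
  expect_identical(t0$misclassification, 0)
  d1 <- planted_threshold_dataset(2000, threshold = 0.5, noise_rate = 0.1,
                                  seed = 2)
  t1 <- fit_tree(d1[-1], d1$label, tree_config(max_depth = 1))
  expect_equal(t1$misclassification, 0.1, tolerance = 0.25)
})

test_that("toy fixtures cover each rate-law family and reject unknown kinds", {
  laws <- unique(unlist(lapply(
    c("linear_chain", "phospho_cycle", "vegf_loop"),
    function(k) vapply(toy_fixture_network(k)$reactions, `[[`, "", "rate_law"))))
  expect_setequal(laws, c("mass_action", "michaelis_menten", "degradation",
                          "atp_phospho", "vegf_synthesis", "vegf_binding"))
  expect_error(toy_fixture_network("nope"))
})

test_that("population archives round-trip and carry metadata", {
  cyc <- toy_fixture_network("phospho_cycle")
  pop <- generate_population(cyc, ensemble_config(n_cases = 6, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_population_archive(pop, dir, config = run_config())
  expect_true(any(grepl("steady_state_baseline", paths)))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_identical(meta$seed, 9L)
  expect_identical(meta$convergence$n_converged, 6L)
  M <- read_population_table(grep("baseline", paths, value = TRUE))
  expect_equal(M, steady_state_matrix(pop, converged_only = FALSE),
               tolerance = 1e-12)
})
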