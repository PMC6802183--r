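# minimal hand-built ensemble records for contract tests
fake_ss <- function(state, converged = TRUE) {
  structure(list(state = state, converged = converged, residual = 0,
                 t_elapsed = 1), class = "steady_state")
}
fake_record <- function(base, cond, label = "o2=0.5", converged_cond = TRUE) {
  list(case_id = 1L, sampled_initials = base,
       baseline = fake_ss(base),
       conditions = stats::setNames(list(fake_ss(cond, converged_cond)),
                                    label))
}

test_that("response ratios and exclusion reasons follow the contract", {
  base <- c(pERK = 100, ERK = 100, pAkt = 40, Akt = 60,
            PIP3_Akt = 0, pPIP3_Akt = 0)
  rec <- fake_record(base, base)
  expect_identical(as.numeric(response_ratio(rec, "o2=0.5", "pERK")), 1)
  rec2 <- fake_record(base, replace(base, "pERK", 50))
  expect_identical(as.numeric(response_ratio(rec2, "o2=0.5", "pERK")), 0.5)
  rec3 <- fake_record(base, base, converged_cond = FALSE)
  expect_true(is.na(response_ratio(rec3, "o2=0.5", "pERK")))
  expect_identical(attr(response_ratio(rec3, "o2=0.5", "pERK"), "reason"),
                   "non_converged")
  rec4 <- fake_record(replace(base, "pERK", 0), base)
  expect_identical(attr(response_ratio(rec4, "o2=0.5", "pERK"), "reason"),
                   "baseline_nonpositive")
})

test_that("categorization uses a closed no-change band", {
  r <- c(1.0, 0.8, 1.1, 0.9, 0.8999999, 1.1000001, 4, NA)
  expect_identical(as.character(categorize(r)),
                   c("no_change", "decrease", "no_change", "no_change",
                     "decrease", "increase", "increase", NA))
})

test_that("phospho/total ratios stay in [0,1] and hit the symmetric case", {
  base <- c(pERK = 0, ERK = 120, pAkt = 60, Akt = 0, PIP3_Akt = 0,
            pPIP3_Akt = 0)
  rec <- fake_record(base, base)
  expect_identical(derived_ratio(rec, "pERK/tERK"), 0)
  expect_identical(derived_ratio(rec, "pAkt/tAkt"), 1)
  expect_error(derived_ratio(rec, "pFoo/tFoo"), "mapping")
  # symmetric cycle: equal forward/backward rate constants -> ratio 1/2
  ab <- make_ab_network(kf = 0.2, kr = 0.2, a0 = 30, b0 = 0)
  ss <- integrate_to_steady_state(ab, initial_state(ab))
  rec2 <- list(baseline = ss, conditions = list())
  tot <- list("pB/tB" = list(num = "B", den = c("A", "B")))
  expect_equal(derived_ratio(rec2, "pB/tB", totals = tot), 0.5,
               tolerance = 1e-6)
})

test_that("phenotype summaries partition converged cases exactly", {
  base <- c(pERK = 100, ERK = 100, pAkt = 40, Akt = 60, PIP3_Akt = 0,
            pPIP3_Akt = 0)
  mk <- function(f) fake_record(base, replace(base, "pERK", 100 * f))
  pop <- structure(list(records = list(mk(1), mk(0.95), mk(0.5), mk(1.3)),
                        config = ensemble_config(4), sampled_species = names(base)),
                   class = "ensemble")
  s <- summarize_phenotypes(pop, "o2=0.5", "pERK")
  expect_identical(s$n, 4L)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(s$fractions[c("decrease", "no_change", "increase")]),
               c(0.25, 0.5, 0.25))
  expect_identical(sum(s$hist$counts), 4L)
  # categorization is invariant to a global unit rescaling
  pop_scaled <- pop
  for (i in seq_along(pop_scaled$records)) {
    r <- pop_scaled$records[[i]]
    r$baseline$state <- r$baseline$state * 1000
    r$conditions[[1]]$state <- r$conditions[[1]]$state * 1000
    pop_scaled$records[[i]] <- r
  }
  s2 <- summarize_phenotypes(pop_scaled, "o2=0.5", "pERK")
  expect_identical(s$fractions, s2$fractions)
})

test_that("transient fold change finds the maximal VEGF excursion", {
  net <- toy_fixture_network("vegf_loop")
  bl <- integrate_to_steady_state(net, initial_state(net))
  rec <- list(case_id = 1L, baseline = bl, conditions = list())
  out <- transient_fold_change(net, rec, cell_env(0.25), readout = "VEGF",
                               t_end = 1e5)
  expect_false(out$failed)
  # steady-state fold for this toy is (1/f)^2 = 16; the transient peak is at
  # least the final plateau
  expect_equal(out$final_fold, 16, tolerance = 0.02)
  expect_gte(out$max_fold, out$final_fold - 1e-9)
})
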