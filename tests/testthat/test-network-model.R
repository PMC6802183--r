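test_that("model tables load, validate and preserve order", {
  net <- make_ab_network()
  expect_s3_class(net, "reaction_network")
  expect_identical(net$species$id, c("A", "B"))
  expect_length(net$reactions, 1L)
  expect_identical(dim(net$stoich), c(2L, 1L))

  bad_law <- toy_reaction("r1", "A", "B", "mass_actoin", "kf=1")
  expect_error(load_model_tables(rbind(toy_species("A", 1), toy_species("B", 1)),
                                 bad_law, clamped = character(0)),
               "unknown rate law")
  dangling <- toy_reaction("r1", "A + X", "B", "mass_action", "kf=1")
  expect_error(load_model_tables(rbind(toy_species("A", 1), toy_species("B", 1)),
                                 dangling, clamped = character(0)),
               "unknown species: X")
  incomplete <- toy_reaction("r1", "A", "B", "michaelis_menten", "km=1")
  expect_error(load_model_tables(rbind(toy_species("A", 1), toy_species("B", 1)),
                                 incomplete, clamped = character(0)),
               "incomplete params")
  neg <- toy_species("A", -1)
  expect_error(load_model_tables(neg,
                                 toy_reaction("r1", "A", "", "degradation", "k=1"),
                                 clamped = character(0)),
               "initial_conc")
  badpair <- toy_species("A", 1, phospho = TRUE, pair = "nope")
  expect_error(load_model_tables(badpair,
                                 toy_reaction("r1", "A", "", "degradation", "k=1"),
                                 clamped = character(0)),
               "phospho_pair")
})

test_that("stoichiometric coefficients and duplicate sides are parsed", {
  net <- load_model_tables(
    rbind(toy_species("A", 1), toy_species("B", 1)),
    toy_reaction("r_dim", "2 A", "B", "mass_action", "kf=0.5;kr=0.1"),
    clamped = character(0))
  expect_identical(net$stoich["A", 1], -2L)
  expect_identical(net$stoich["B", 1], 1L)
  # rate = kf*A^2 - kr*B
  dx <- rhs(net, c(A = 3, B = 4))
  expect_equal(unname(dx), c(-2, 1) * (0.5 * 9 - 0.1 * 4))
})

test_that("rhs matches hand-computed mass action and flags bad states", {
  net <- load_model_tables(
    rbind(toy_species("A", 2), toy_species("B", 0)),
    toy_reaction("r1", "A", "B", "mass_action", "kf=1"),
    clamped = character(0))
  dx <- rhs(net, c(A = 2, B = 0))
  expect_equal(unname(dx), c(-2, 2))
  expect_error(rhs(net, c(NA, 0)), "non-finite")
  expect_error(rhs(net, c(-1, 0)), "negative concentrations")
  # round-off negatives are clamped, not fatal
  expect_silent(rhs(net, c(-1e-10, 0)))
})

test_that("reference, accumulation and compiled evaluators agree", {
  net <- builtin_model_cached()
  set.seed(3)
  for (i in 1:5) {
    x <- initial_state(net) * exp(stats::runif(nrow(net$species), -1, 1))
    env <- cell_env(o2_fraction = stats::runif(1, 0.01, 1),
                    drugs = c(RAF_phospho = stats::runif(1, 0, 50)))
    d1 <- rhs(net, x, env)
    d2 <- rhs_accumulate(net, x, env)
    d3 <- rhs_fast(net, x, env)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_equal(d1, d3, tolerance = 1e-12)
  }
})

test_that("moiety analysis finds closed cycles and ignores open systems", {
  cyc <- toy_fixture_network("phospho_cycle")
  tot <- moiety_conservation_totals(cyc)
  expect_length(tot, 1L)
  v <- tot[[1]]
  expect_setequal(names(v), c("E", "pE"))
  expect_equal(v[["E"]], v[["pE"]], tolerance = 1e-9)

  open_net <- load_model_tables(
    toy_species("V", 1),
    rbind(toy_reaction("r_s", "", "V", "mass_action", "kf=1"),
          toy_reaction("r_d", "V", "", "degradation", "k=1")),
    clamped = character(0))
  expect_length(moiety_conservation_totals(open_net), 0L)
})

test_that("conserved totals of the tumor module drift below 1e-6 with open reactions disabled", {
  mods <- load_builtin_modules()
  tumor <- mods$tumor
  totals <- moiety_conservation_totals(tumor)
  expect_gt(length(totals), 5)
  # zero every synthesis/degradation rate constant
  for (j in seq_along(tumor$reactions)) {
    r <- tumor$reactions[[j]]
    open <- r$rate_law %in% c("degradation", "vegf_synthesis") ||
      length(r$reactants) == 0 || length(r$products) == 0
    if (open) {
      key <- intersect(c("kf", "k", "k_syn"), names(r$params))
      tumor$reactions[[j]]$params[[key[1]]] <- 0
    }
  }
  tc <- timecourse(tumor, initial_state(tumor), cell_env(),
                   t_grid = c(0, 10, 100, 1000, 10000),
                   settings = solver_settings(rtol = 1e-8, atol = 1e-10))
  expect_false(attr(tc, "failed"))
  X <- as.matrix(tc[, -1])
  for (v in totals) {
    tv <- X[, names(v), drop = FALSE] %*% v
    expect_lt(max(abs(tv - tv[1])) / max(abs(tv[1]), 1e-12), 1e-6)
  }
})

test_that("assembly validates its inputs and lists omissions", {
  mods <- load_builtin_modules()
  # strip the mRNA species from the hif module
  hif_bad <- mods$hif
  hif_bad$species <- hif_bad$species[hif_bad$species$id != "mRNA", ]
  expect_error(assemble_integrated_model(hif_bad, mods$tumor),
               "lacks mRNA species")
  tumor_bad <- mods$tumor
  for (j in seq_along(tumor_bad$reactions)) {
    tumor_bad$reactions[[j]]$atp_dependent <- FALSE
  }
  expect_error(assemble_integrated_model(mods$hif, tumor_bad),
               "atp_dependent")
})

test_that("toy hif + toy tumor assembly merges species and re-baselines VEGF", {
  net <- toy_fixture_network("vegf_loop")
  # species union: 3 hif + 3 tumor, no shared ids
  expect_identical(nrow(net$species), 6L)
  pars <- attr(net, "pars")
  # mRNA0 closed form: HIF = ks/kd, mRNA0 = k_tr*HIF/kd_m
  mrna0_expect <- with(pars, k_tr * (ks_hif / kd_hif) / kd_m)
  expect_equal(net$coupling$mrna0, mrna0_expect, tolerance = 1e-5)
  # re-baselined degradation constant k = k_syn / VEGF0
  deg <- net$reactions[[match("t_vegf_deg",
                              vapply(net$reactions, `[[`, "", "id"))]]
  expect_equal(deg$params$k, pars$k_syn / pars$vegf0)
})

test_that("the calibration identity holds for every converted reaction", {
  net <- builtin_model_cached()
  cal <- net$coupling$kab_calibration
  expect_gt(length(cal), 10)
  atp_cal <- net$coupling$atp_calibration_nM
  for (rec in cal) {
    expect_equal((rec$k_m_atp / atp_cal + 1) * rec$k_ab, rec$k_prime,
                 tolerance = 1e-12)
  }
})
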