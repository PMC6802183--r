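test_that("steady states match closed forms on toy networks", {
  ab <- make_ab_network(kf = 1, kr = 1, a0 = 2, b0 = 0)
  ss <- integrate_to_steady_state(ab, initial_state(ab))
  expect_true(ss$converged)
  expect_equal(unname(ss$state), c(1, 1), tolerance = 1e-6)
  # derivative at the fixed point is below tolerance
  expect_lt(max(abs(rhs(ab, ss$state))), 1e-7)

  chain <- toy_fixture_network("linear_chain")
  p <- attr(chain, "pars")
  ss2 <- integrate_to_steady_state(chain, initial_state(chain))
  expect_true(ss2$converged)
  # flux ks runs through the chain: A = ks/k1, vmax*B/(km+B) = ks, C = ks/kd
  expected <- c(A = p$ks / p$k1,
                B = p$km * p$ks / (p$vmax - p$ks),
                C = p$ks / p$kd)
  expect_equal(ss2$state, expected, tolerance = 1e-6)

  cyc <- toy_fixture_network("phospho_cycle")
  pc <- attr(cyc, "pars")
  ss3 <- integrate_to_steady_state(cyc, initial_state(cyc))
  expect_equal(unname(ss3$state), unname(phospho_cycle_ss(pc$total)),
               tolerance = 1e-6)
})

test_that("integration is deterministic and steady states are idempotent", {
  chain <- toy_fixture_network("linear_chain")
  s1 <- integrate_to_steady_state(chain, initial_state(chain))
  s2 <- integrate_to_steady_state(chain, initial_state(chain))
  expect_identical(s1$state, s2$state)
  st <- solver_settings()
  s3 <- integrate_to_steady_state(chain, s1$state, settings = st)
  expect_lt(max(abs(s3$state - s1$state) / (1 + abs(s1$state))),
            10 * st$ss_tol)
})

test_that("tightening the steady-state tolerance changes results less than the looser tolerance", {
  chain <- toy_fixture_network("linear_chain")
  loose <- solver_settings(ss_tol = 1e-7, rtol = 1e-9, atol = 1e-11)
  tight <- solver_settings(ss_tol = 1e-8, rtol = 1e-9, atol = 1e-11)
  a <- integrate_to_steady_state(chain, initial_state(chain), settings = loose)
  b <- integrate_to_steady_state(chain, initial_state(chain), settings = tight)
  expect_lt(max(abs(a$state - b$state) / (1 + abs(b$state))), 1e-7)
})

test_that("timecourse reproduces closed-form decay and starts at state0", {
  dec <- make_decay_network(k = 0.3, x0 = 5)
  tg <- seq(0, 20, by = 0.5)
  tc <- timecourse(dec, initial_state(dec), t_grid = tg)
  expect_false(attr(tc, "failed"))
  expect_identical(tc$X[1], 5)
  expect_equal(tc$X, 5 * exp(-0.3 * tg), tolerance = 1e-6)
  expect_error(timecourse(dec, initial_state(dec), t_grid = c(1, 1, 2)),
               "increasing")
})

test_that("timecourse plateau agrees with the step-protocol steady state", {
  net <- toy_fixture_network("vegf_loop")
  bl <- integrate_to_steady_state(net, initial_state(net))
  expect_true(bl$converged)
  env <- cell_env(o2_fraction = 0.5)
  pr <- run_step_protocol(net, bl$state, list(env))
  ss <- pr$conditions[["o2=0.5"]]
  expect_true(ss$converged)
  tc <- timecourse(net, bl$state, env, t_grid = c(0, 10^(0:6)))
  final <- unlist(tc[nrow(tc), -1])
  expect_equal(final, ss$state, tolerance = 1e-4)
  # hypoxia raises mRNA (1/f in this toy) and VEGF quadratically
  expect_equal(ss$state[["mRNA"]] / net$coupling$mrna0, 2, tolerance = 1e-3)
  expect_equal(ss$state[["VEGF"]] / attr(net, "pars")$vegf0, 4,
               tolerance = 5e-3)
})

test_that("an unperturbed condition reproduces the baseline", {
  net <- toy_fixture_network("vegf_loop")
  bl <- integrate_to_steady_state(net, initial_state(net))
  pr <- run_step_protocol(net, bl$state, list(cell_env()))
  ratio <- pr$conditions[[1]]$state / pmax(bl$state, 1e-12)
  expect_equal(unname(ratio), rep(1, length(ratio)), tolerance = 1e-6)
})
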