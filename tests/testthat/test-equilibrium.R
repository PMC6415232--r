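test_that("solved equilibria agree with brute-force grid minimisation", {
  cases <- list(
    list(branch = "dh", a = 0.1, z = 1, lB = 2.0, conc = 0.01),
    list(branch = "cc", a = 0.1, z = 1, lB = 2.0, conc = 0.01),
    list(branch = "cc", a = 1.0, z = 1, lB = 1.7, conc = 0.001),
    list(branch = "dh", a = 0.5, z = 2, lB = 1.0, conc = 0.01),
    list(branch = "cc", a = 0.3, z = 2, lB = 3.0, conc = 0.05)
  )
  for (cs in cases) {
    sol <- solvent_conditions(bjerrum = cs$lB, salt = salt_1_1(cs$conc))
    res <- solve_branch(cs$branch, std_chain(cs$a, cs$z), sol)
    k <- debye_kappa(cs$lB, salt_1_1(cs$conc))
    gfun <- if (cs$branch == "dh") {
      function(b) g_dh(b, cs$a, cs$lB, k)
    } else {
      function(b) g_cc(b, cs$a, cs$z, cs$lB, k)
    }
    expect_false(is.na(res$beq))
    expect_lt(abs(res$beq - grid_argmin(gfun)), 1e-6)
    expect_equal(res$g_at_beq, gfun(res$beq))
  }
})

test_that("branch equilibria at lB = 2.0 nm sit on their own sides of the threshold", {
  sol <- solvent_conditions(bjerrum = 2.0, salt = std_salt)
  dh <- solve_branch("dh", std_chain(), sol)
  cc <- solve_branch("cc", std_chain(), sol)
  expect_true(dh$valid)
  expect_true(cc$valid)
  # stretched state near 2.5 nm, contracted near 1.7 nm
  expect_lt(abs(dh$beq - 2.5), 0.1)
  expect_lt(abs(cc$beq - 1.7), 0.1)
  expect_gt(dh$beq, 2.0)
  expect_lt(cc$beq, 2.0)
  # both are genuine local minima: positive second difference
  h <- 1e-4
  k <- debye_kappa(2.0, std_salt)
  expect_gt(g_dh(dh$beq - h, 0.1, 2, k) + g_dh(dh$beq + h, 0.1, 2, k) -
              2 * g_dh(dh$beq, 0.1, 2, k), 0)
  expect_gt(g_cc(cc$beq - h, 0.1, 1, 2, k) + g_cc(cc$beq + h, 0.1, 1, 2, k) -
              2 * g_cc(cc$beq, 0.1, 1, 2, k), 0)
})

test_that("a root on the wrong side of the threshold is flagged, not erred", {
  # far below the transition range the CC root lies above z*lB
  sol <- solvent_conditions(bjerrum = 1.0, salt = std_salt)
  cc <- solve_branch("cc", std_chain(), sol)
  expect_false(cc$valid)
  expect_false(is.na(cc$beq))
  expect_match(cc$diagnostics$reason, "wrong side")
  # a bracket that excludes the minimum reports "no equilibrium"
  res <- solve_branch("dh", std_chain(), sol, b_range = c(20, 100))
  expect_true(is.na(res$beq))
  expect_match(res$diagnostics$reason, "no equilibrium")
})

test_that("stiffer springs are stretched less, on both branches", {
  a_grid <- c(0.1, 0.3, 1, 3)
  sol_cc <- solvent_conditions(bjerrum = 1.7, salt = std_salt)
  beq_cc <- vapply(a_grid, function(a)
    solve_branch("cc", std_chain(a), sol_cc)$beq, numeric(1))
  expect_true(all(diff(beq_cc) < 0))
  sol_dh <- solvent_conditions(bjerrum = 0.8, salt = std_salt)
  beq_dh <- vapply(a_grid, function(a)
    solve_branch("dh", std_chain(a), sol_dh)$beq, numeric(1))
  expect_true(all(diff(beq_dh) < 0))
})

test_that("swelling is greater at lower salt concentration", {
  for (a in c(0.2, 1, 3)) {
    b_lo <- solve_branch("cc", std_chain(a),
                         solvent_conditions(bjerrum = 1.7,
                                            salt = salt_1_1(0.001)))$beq
    b_hi <- solve_branch("cc", std_chain(a),
                         solvent_conditions(bjerrum = 1.7,
                                            salt = salt_1_1(0.01)))$beq
    expect_gt(b_lo, b_hi)
  }
})

test_that("the landscape inside the transition range is a double well", {
  sol <- solvent_conditions(bjerrum = 2.0, salt = std_salt)
  prof <- free_energy_profile(std_chain(), sol, seq(0.5, 5, by = 0.01))
  expect_equal(nrow(prof$minima), 2L)
  expect_setequal(prof$minima$branch, c("cc", "dh"))
  expect_lt(min(prof$minima$b), 2.0)
  expect_gt(max(prof$minima$b), 2.0)
  expect_false(is.null(prof$maximum))
  expect_equal(unname(prof$maximum["b"]), 2.0)
  # the junction maximum tops both minima
  expect_true(all(prof$maximum["g"] > prof$minima$g))
  # sample values are exactly the branch free energies
  k <- debye_kappa(2, std_salt)
  cc_rows <- prof$samples$branch == "cc"
  expect_identical(prof$samples$g[cc_rows],
                   g_cc(prof$samples$b[cc_rows], 0.1, 1, 2, k))
  dh_rows <- prof$samples$branch == "dh"
  expect_identical(prof$samples$g[dh_rows],
                   g_dh(prof$samples$b[dh_rows], 0.1, 2, k))
})

test_that("outside the transition range the landscape has a single minimum", {
  sol <- solvent_conditions(bjerrum = 1.0, salt = std_salt)
  prof <- free_energy_profile(std_chain(), sol, seq(0.2, 4, by = 0.005))
  expect_equal(nrow(prof$minima), 1L)
  expect_equal(prof$minima$branch, "dh")
  expect_null(prof$maximum)
  expect_error(free_energy_profile(std_chain(), sol, seq(2, 4, by = 0.01)),
               "span")
})

test_that("bistability holds inside the overlap range and nowhere else", {
  mk <- function(lB) solvent_conditions(bjerrum = lB, salt = std_salt)
  expect_true(is_bistable(std_chain(), mk(2.0))$bistable)
  expect_false(is_bistable(std_chain(), mk(1.0))$bistable)
  expect_false(is_bistable(std_chain(), mk(3.0))$bistable)
})

test_that("collapse with t = 0 reproduces the rigid CC branch", {
  for (lB in c(2.5, 5, 10)) {
    sol <- solvent_conditions(bjerrum = lB, salt = std_salt)
    rigid <- solve_branch("cc", std_chain(), sol)
    comp <- solve_collapse(std_chain(t = 0), sol)
    iter <- solve_collapse(std_chain(t = 0), sol, method = "iterative")
    expect_equal(comp$beq, rigid$beq, tolerance = 1e-10)
    expect_equal(iter$beq, rigid$beq, tolerance = 1e-8)
    expect_equal(comp$a_effective, 0.1)
  }
})

test_that("collapse solutions minimise the composite free energy", {
  for (cs in list(list(t = 4, lB = 5), list(t = 50, lB = 3))) {
    sol <- solvent_conditions(bjerrum = cs$lB, salt = std_salt)
    res <- suppressWarnings(solve_collapse(std_chain(t = cs$t), sol))
    k <- debye_kappa(cs$lB, std_salt)
    oracle <- grid_argmin(function(b) collapse_g(b, 0.1, cs$t, 1, cs$lB, k))
    expect_lt(abs(res$beq - oracle), 1e-6)
    expect_equal(res$a_effective,
                 0.1 + cs$t * cs$lB / (8 * exp(1) * res$beq),
                 tolerance = 1e-12)
  }
})

test_that("counterion stiffening drives the three collapse regimes", {
  beq_at <- function(t, lB, method = "composite") {
    sol <- solvent_conditions(bjerrum = lB, salt = std_salt)
    suppressWarnings(solve_collapse(std_chain(t = t), sol,
                                    method = method))$beq
  }
  # t = 50: strong contraction right at the condensation threshold
  expect_lt(beq_at(50, 2.5) / beq_at(0, 2.5), 0.5)
  # t = 4: little effect near threshold, substantial at large lB
  expect_gt(beq_at(4, 2.5) / beq_at(0, 2.5), 0.8)
  expect_lt(beq_at(4, 15) / beq_at(0, 15), 0.6)
  # pointwise ordering in t across the sweep
  for (lB in c(2, 5, 10, 20)) {
    b0 <- beq_at(0, lB); b4 <- beq_at(4, lB); b50 <- beq_at(50, lB)
    expect_true(b0 > b4 && b4 > b50)
  }
  # the iterative scheme shows the same regimes
  expect_lt(beq_at(50, 2.5, "iterative") / beq_at(0, 2.5, "iterative"), 0.5)
})

test_that("misuse of the solvers is rejected with clear messages", {
  sol <- solvent_conditions(bjerrum = 2, salt = std_salt)
  expect_error(solve_branch("dh", std_chain(t = 4), sol), "solve_collapse")
  expect_error(free_energy_profile(std_chain(t = 4), sol, seq(1, 3, 0.1)),
               "t = 0")
  expect_warning(
    solve_collapse(std_chain(t = 50),
                   solvent_conditions(bjerrum = 30, salt = std_salt)),
    "validity window")
})
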