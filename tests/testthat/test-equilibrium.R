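test_that("direct solves recover the analytic equilibria", {
  p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
  eqR <- solve_equilibrium(c(R = 1, C = 0, Pj = 0, Pa = 0), p,
                           absent = c("C", "Pj", "Pa"))
  expect_equal(unname(eqR$state[["R"]]), 3, tolerance = 1e-10)
  expect_equal(eqR$class, "R")
  eqCR <- solve_equilibrium(c(R = 1, C = 1, Pj = 0, Pa = 0), p, absent = "P")
  expect_equal(unname(eqCR$state[["R"]]), 11 / 39, tolerance = 1e-10)
  expect_equal(unname(eqCR$state[["C"]]), 1.235431, tolerance = 1e-6)
  expect_lt(eqCR$residual, 1e-10)
})

test_that("the coexistence equilibrium solves with all densities positive", {
  eq <- pcr_dietshift()
  eq2 <- solve_equilibrium(eq$state * 1.05, eq$params)
  expect_lt(eq2$residual, 1e-10)
  expect_true(all(eq2$state > 0))
  expect_equal(eq2$class, "PCR")
  expect_state_equal(eq2$state, eq$state, tol = 1e-8)
})

test_that("Jacobian eigenvalues report invasion growth of absent species", {
  p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
  # consumer invasion of the resource-only state: nu_c(R_max) - mu_c = 2.65
  ev <- jacobian_eigenvalues(c(R = 3, C = 0, Pj = 0, Pa = 0), p)
  expect_equal(max(Re(ev)), 2.65, tolerance = 1e-6)
  expect_equal(invasion_growth_rate(c(R = 3, C = 0, Pj = 0, Pa = 0), p, "C"),
               2.65, tolerance = 1e-9)
  # CR equilibrium is stable against predator invasion at low a_jr
  eqCR <- cr_dietshift(a_jr = 3)
  expect_true(eqCR$stable)
  expect_true(all(Re(eqCR$eigenvalues) < 0))
})

test_that("equilibrium classification flags inconsistent predator stages", {
  expect_equal(classify_equilibrium(c(R = 3, C = 0, Pj = 0, Pa = 0)), "R")
  expect_equal(classify_equilibrium(c(R = 0.28, C = 1.2, Pj = 0, Pa = 0)), "CR")
  expect_equal(classify_equilibrium(c(R = 1, C = 0, Pj = 0.1, Pa = 0.1)), "PR")
  expect_error(classify_equilibrium(c(R = 1, C = 0, Pj = 0.1, Pa = 0)),
               "inconsistent")
})

test_that("the continued CR branch matches its closed form everywhere", {
  p <- default_parameters(a_jr = 0, a_ar = 0, beta = 0)
  eq0 <- solve_equilibrium(cr_equilibrium_closed_form(p), p, absent = "P")
  br <- continue_branch(eq0, "a_jr", c(0, 6), h0 = 0.1, h_max = 0.25)
  expect_equal(br$termination, "range_end")
  for (i in seq_len(nrow(br$points))) {
    pp <- set_params(p, a_jr = br$points$param[i])
    cf <- cr_equilibrium_closed_form(pp)
    expect_lt(abs(br$points$R[i] - cf[["R"]]), 1e-8)
    expect_lt(abs(br$points$C[i] - cf[["C"]]), 1e-8)
  }
  # predator invasion boundary detected, CR stable below and unstable above
  invs <- Filter(function(b) b$kind == "invasion_boundary", br$bifurcations)
  expect_length(invs, 2)
  bnd <- sort(vapply(invs, `[[`, 0, "param_value"))
  expect_true(all(br$points$stable[br$points$param < bnd[1] - 0.01]))
  inside <- br$points$param > bnd[1] + 0.01 & br$points$param < bnd[2] - 0.01
  expect_true(all(!br$points$stable[inside]))
})

test_that("the coexistence branch turns at a fold with a zero eigenvalue", {
  eq <- pcr_dietshift()
  br <- continue_branch(eq, "a_jr", c(4.5, 0.5), h0 = 0.05)
  folds <- Filter(function(b) b$kind == "fold", br$bifurcations)
  expect_length(folds, 1)
  fold <- folds[[1]]
  # the branch turns: points exist on both sides of the fold parameter
  expect_gt(min(br$points$param), fold$param_value - 1e-4)
  # one Jacobian eigenvalue vanishes at the refined fold
  p_fold <- set_params(eq$params, a_jr = fold$param_value)
  ev <- jacobian_eigenvalues(fold$state, p_fold)
  expect_lt(min(abs(Re(ev))), 1e-6)
  # every reported point is a genuine equilibrium
  for (i in seq_len(nrow(br$points))) {
    pp <- set_params(eq$params, a_jr = br$points$param[i])
    st <- unlist(br$points[i, c("R", "C", "Pj", "Pa")])
    expect_lt(max(abs(lhigp_rhs(st, pp))), 1e-8)
  }
})

test_that("continuation truncates where a present species exits", {
  eq <- pcr_dietshift()
  br <- continue_branch(eq, "a_jr", c(4.5, 6), h0 = 0.05)
  expect_equal(br$termination, "component_exit")
  exits <- Filter(function(b) b$kind == "invasion_boundary", br$bifurcations)
  expect_gte(length(exits), 1)
  expect_true(all(vapply(exits, `[[`, 0, "param_value") > 4.5))
})

test_that("the R0 = 1 root coincides with the eigenvalue-based boundary", {
  p <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  cr_at <- function(a) {
    pp <- set_params(p, a_jr = a)
    solve_equilibrium(cr_equilibrium_closed_form(pp), pp, absent = "P")
  }
  r0_root <- uniroot(function(a)
    invasion_fitness_R0(a, cr_at(a)) - 1, c(3.6, 4.5), tol = 1e-12)$root
  ev_root <- uniroot(function(a)
    invasion_growth_rate(cr_at(a)$state, set_params(p, a_jr = a), "P"),
    c(3.6, 4.5), tol = 1e-12)$root
  expect_lt(abs(r0_root - ev_root), 1e-4)
  # and the boundary sits above the juvenile-growth threshold 39/11
  expect_gt(r0_root, 39 / 11)
})

test_that("two-parameter map recovers the documented bistability", {
  p <- default_parameters(a_jr = 3.4, a_ar = 0, beta = 0)
  map <- two_parameter_map(p, "a_jr", "beta", c(3.4, 4.5), c(0, 1), seed = 5)
  cell <- function(x, y) sort(map$class[map$x == x & map$y == y])
  # beta = 0, a_jr = 3.4: stable CR and stable PCR coexist (bistable band)
  expect_equal(cell(3.4, 0), c("CR", "PCR"))
  # beta = 0, a_jr = 4.5: CR invasible, only PCR stable
  expect_equal(cell(4.5, 0), "PCR")
  # cannibalistic predators at low a_jr cannot persist: only CR remains
  expect_equal(cell(3.4, 1), "CR")
  # gradient signs recorded on predator cells
  expect_true(all(is.na(map$gradient_sign[map$class %in% c("R", "CR")])))
  expect_equal(map$gradient_sign[map$x == 4.5 & map$y == 0 &
                                 map$class == "PCR"], -1)
})
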