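test_that("a resident mutant is exactly neutral: R0(y, y) = 1", {
  eq <- pcr_dietshift()
  expect_equal(invasion_fitness_R0(4.5, eq), 1, tolerance = 1e-8)
  # also on a predator-resource equilibrium of the diet-broadening scenario
  p <- default_parameters(a_jr = 5, a_ar = 4, beta = 0)
  eqPR <- solve_equilibrium(c(R = 0.4, C = 0, Pj = 1.5, Pa = 0.6), p,
                            absent = "C")
  expect_equal(eqPR$class, "PR")
  expect_equal(invasion_fitness_R0(5, eqPR), 1, tolerance = 1e-8)
  # and with cannibalism (mutant juveniles die to resident adults)
  p1 <- default_parameters(a_jr = 5, a_ar = 0, beta = 1)
  at <- find_attractor(c(R = 1, C = 0.5, Pj = 0.5, Pa = 0.5), p1)
  expect_equal(at$class, "PCR")
  expect_equal(invasion_fitness_R0(5, at$equilibrium), 1, tolerance = 1e-8)
})

test_that("invasion fitness into the consumer-resource state is as derived", {
  cr <- cr_dietshift(a_jr = 3)
  p <- cr$params
  # mutant at a_jr = 4: nu_j' = mu_p exactly, a_ac' = 2, R0 = nu_a'/mu_p
  R <- cr$state[["R"]]; C <- cr$state[["C"]]
  I_a <- 2 * C / (1 + 0.25 * 2 * C)
  expect_equal(invasion_fitness_R0(4, cr), (0.5 * I_a - 0.4) / 0.04,
               tolerance = 1e-9)
  expect_equal(invasion_fitness_R0(4, cr), 9.0922, tolerance = 1e-4)
  # mutant at a_jr = 3: juveniles starve at the consumer-set resource level
  expect_equal(invasion_fitness_R0(3, cr), 0)
  expect_equal(invasion_fitness_R0(39 / 11 - 1e-9, cr), 0)
})

test_that("selection gradients reproduce the directions of evolution", {
  # noncannibalistic diet shift: selection pushes a_jr down (toward suicide)
  expect_lt(selection_gradient(pcr_dietshift()), 0)
  # noncannibalistic diet broadening: selection pushes a_jr up
  p <- default_parameters(a_jr = 5, a_ar = 3, beta = 0)
  eqPR <- solve_equilibrium(c(R = 0.6, C = 0, Pj = 1, Pa = 0.5), p,
                            absent = "C")
  expect_true(eqPR$stable)
  expect_gt(selection_gradient(eqPR), 0)
  # cannibalistic diet shift below the ESS: selection pushes a_jr up
  p1 <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 1)
  at <- find_attractor(c(R = 1, C = 0.5, Pj = 0.5, Pa = 0.5), p1)
  expect_gt(selection_gradient(at$equilibrium), 0)
})

test_that("singular strategies are located and classified per scenario", {
  # cannibalistic diet shift: CSS inside the persistence window
  p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 1)
  at <- find_attractor(c(R = 1, C = 0.5, Pj = 0.5, Pa = 0.5), p)
  ss <- find_singular_strategy(at$equilibrium, c(4.5, 5.1))
  expect_equal(ss$status, "found")
  expect_true(ss$convergence_stable)
  expect_true(ss$evolutionarily_stable)
  expect_gt(ss$a_jr, 4.5)
  expect_lt(abs(ss$gradient), 1e-6)
  # cannibalistic diet broadening (a_ar = 3): CSS on the PR branch
  p3 <- default_parameters(a_jr = 5.3, a_ar = 3, beta = 1)
  eqPR <- solve_equilibrium(c(R = 0.35, C = 0, Pj = 1.8, Pa = 0.6), p3,
                            absent = "C")
  expect_true(eqPR$stable)
  ss3 <- find_singular_strategy(eqPR, c(5.3, 5.9))
  expect_equal(ss3$status, "found")
  expect_true(ss3$convergence_stable && ss3$evolutionarily_stable)
  # noncannibalistic diet shift: no root on the stable coexistence branch
  none <- find_singular_strategy(pcr_dietshift(), c(3.6, 4.6))
  expect_equal(none$status, "none_found")
  expect_lt(none$gradient_lo, 0)
  expect_lt(none$gradient_hi, 0)
})

test_that("classification matches a brute-force fitness-landscape oracle", {
  # mutant curvature at the cannibalistic diet-shift CSS, by direct grid
  p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 1)
  at <- find_attractor(c(R = 1, C = 0.5, Pj = 0.5, Pa = 0.5), p)
  ss <- find_singular_strategy(at$equilibrium, c(4.5, 5.1))
  y <- ss$a_jr
  grid <- seq(y - 0.05, y + 0.05, by = 1e-3)
  land <- vapply(grid, function(m)
    invasion_fitness_R0(m, ss$equilibrium), numeric(1))
  # landscape has an interior maximum at the strategy (evolutionary stability)
  expect_equal(grid[which.max(land)], y, tolerance = 2e-3)
  quad <- lm(land ~ poly(grid, 2, raw = TRUE))
  expect_lt(coef(quad)[3], 0)
  expect_equal(unname(sign(coef(quad)[3])), sign(ss$d2_mutant))
})

test_that("gradient near the trait bounds falls back to one-sided differences", {
  p <- default_parameters(a_jr = 6, a_ar = 4, beta = 0)
  eq <- solve_equilibrium(c(R = 0.4, C = 0, Pj = 1.5, Pa = 0.5), p,
                          absent = "C")
  g <- selection_gradient(eq)
  expect_true(isTRUE(attr(g, "one_sided")))
  expect_true(is.finite(as.numeric(g)))
})

test_that("trait evolution reaches the trade-off boundary when predators win", {
  p <- default_parameters(a_jr = 4.5, a_ar = 4, beta = 0)
  tj <- trait_trajectory(4.5, p)
  expect_equal(tj$status, "boundary_ap")
  expect_equal(tj$final_trait, 6)
  final <- tj$steps[nrow(tj$steps), ]
  expect_equal(final$class, "PR")
  expect_equal(final$a_ac, 0)
  expect_true(all(diff(tj$steps$a_jr) > 0))
})

test_that("trait trajectories export to CSV with their terminal status", {
  p <- default_parameters(a_jr = 4.5, a_ar = 4, beta = 0)
  tj <- trait_trajectory(4.5, p)
  f <- tempfile(fileext = ".csv")
  write_trait_trajectory(tj, f)
  df <- utils::read.csv(f)
  expect_named(df, c("step", "a_jr", "a_ac", "class", "R", "C", "Pj", "Pa",
                     "gradient", "status"))
  expect_equal(unique(df$status), "boundary_ap")
  unlink(f)
})
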