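test_that("ontogenetic trade-off evaluates and respects its endpoints", {
  expect_equal(tradeoff_adult_attack(0, 6, 0), 6)
  expect_equal(tradeoff_adult_attack(6, 6, 0), 0)
  # strong trade-off: (6 - 3) / (1 + 5 * 3/6)
  expect_equal(tradeoff_adult_attack(3, 6, 5), 3 / 3.5, tolerance = 1e-12)
  expect_error(tradeoff_adult_attack(7, 6, 0), "a_jr")
  expect_error(tradeoff_adult_attack(3, 6, -1), "epsilon")
})

test_that("trade-off is strictly decreasing with exact endpoints for any shape", {
  for (eps in c(-0.9, -0.5, 0, 0.7, 2, 5)) {
    a <- seq(0, 6, length.out = 201)
    v <- tradeoff_adult_attack(a, 6, eps)
    expect_true(all(diff(v) < 0), info = paste("eps =", eps))
    expect_equal(v[1], 6)
    expect_equal(v[201], 0)
    expect_true(all(v >= 0 & v <= 6))
  }
})

test_that("ingestion follows Holling type II with the pooled adult response", {
  p <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  # half-saturation: R = 1/(h_c a_cr) * ... here a_cr R = 10 at R = 1
  ing <- ingestion_rates(c(R = 1, C = 0, Pj = 0, Pa = 0), p)
  expect_equal(ing$I_c, 5)
  # at the consumer's minimum resource density I_c = (T_c + mu_c)/sigma
  ing2 <- ingestion_rates(c(R = 11 / 39, C = 0, Pj = 0, Pa = 0), p)
  expect_equal(ing2$I_c, 2.2, tolerance = 1e-10)
  # adult response at the CR equilibrium of the diet-shift scenario, a_ac = 2
  ing3 <- ingestion_rates(c(R = 0, C = 1.235431, Pj = 0, Pa = 0.5), p)
  expect_equal(ing3$I_a, 2 * 1.235431 / (1 + 0.25 * 2 * 1.235431),
               tolerance = 1e-9)
  expect_equal(ing3$I_a, 1.527378, tolerance = 1e-6)
})

test_that("ingestion saturates below the handling-time ceilings everywhere", {
  for (seed in 1:25) {
    p <- random_scenario(seed)
    set.seed(seed)
    s <- c(R = runif(1, 0, p$R_max), C = runif(1, 0, 5),
           Pj = runif(1, 0, 5), Pa = runif(1, 0, 5))
    ing <- ingestion_rates(s, p)
    expect_lt(ing$I_c, 1 / p$h_c)
    expect_lt(ing$I_j, 1 / p$h_p)
    expect_lt(ing$I_a, 1 / p$h_p)
    expect_true(all(unlist(ing) >= 0))
  }
})

test_that("net production is assimilation minus maintenance", {
  p <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  expect_equal(net_production(2.2, p, "consumer"), 0.1, tolerance = 1e-12)
  expect_equal(net_production(2, p, "juvenile"), 0.6)
  expect_equal(net_production(0, p, "adult"), -0.4)
  expect_equal(net_production(0, p, "consumer"), -1)
})

test_that("juvenile mortality adds cannibalism with the shared denominator", {
  p0 <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  expect_equal(juvenile_mortality(c(R = 1, C = 1, Pj = 1, Pa = 1), p0), 0.04)
  # a_ac = 2 at a_jr = 4; beta = 1: D_j = mu_p + 2*1 / (1 + 0.25 * 2 * 1)
  p1 <- default_parameters(a_jr = 4, a_ar = 0, beta = 1)
  expect_equal(juvenile_mortality(c(R = 0, C = 0, Pj = 1, Pa = 1), p1),
               0.04 + 2 / 1.5, tolerance = 1e-12)
  expect_equal(juvenile_mortality(c(R = 2, C = 1, Pj = 1, Pa = 0), p1), 0.04)
})

test_that("maturation rate matches its closed form and limits", {
  expect_equal(maturation_rate(0.1, 0.04, 0.01), 0.06 / (1 - 0.01^0.6),
               tolerance = 1e-12)
  expect_equal(maturation_rate(0.1, 0.04, 0.01), 0.064041, tolerance = 1e-5)
  # removable singularity nu_j == D_j: -nu_j / ln(z)
  expect_equal(maturation_rate(0.04, 0.04, 0.01), 0.04 / log(100),
               tolerance = 1e-14)
  expect_equal(maturation_rate(-0.1, 0.04, 0.01), 0)
  expect_equal(maturation_rate(0, 0.04, 0.01), 0)
})

test_that("maturation rate is continuous across nu_j = D_j", {
  # two-sided numerical limits converge to the exact limit value
  lim <- maturation_rate(0.04, 0.04, 0.01)
  for (d in 10^-(6:10)) {
    expect_equal(maturation_rate(0.04 + d, 0.04, 0.01), lim,
                 tolerance = 1e-4)
    expect_equal(maturation_rate(0.04 - d, 0.04, 0.01), lim,
                 tolerance = 1e-4)
  }
  expect_lt(abs(maturation_rate(0.04 + 1e-11, 0.04, 0.01) - lim), 1e-10)
  expect_lt(abs(maturation_rate(0.04 - 1e-11, 0.04, 0.01) - lim), 1e-10)
})

test_that("right-hand side vanishes at known equilibria", {
  p <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  # resource-only equilibrium at carrying density
  expect_equal(unname(lhigp_rhs(c(R = 3, C = 0, Pj = 0, Pa = 0), p)),
               rep(0, 4))
  # CR equilibrium from the consumer persistence condition
  expect_true(all(abs(lhigp_rhs(cr_equilibrium_closed_form(p), p)) < 1e-9))
})

test_that("absent predators stay absent and the juvenile flux reduces cleanly", {
  p <- default_parameters(a_jr = 4, a_ar = 0, beta = 0)
  for (s in list(c(R = 2, C = 0.5, Pj = 0, Pa = 0),
                 c(R = 0.1, C = 2, Pj = 0, Pa = 0))) {
    d <- lhigp_rhs(s, p)
    expect_identical(unname(d[c("Pj", "Pa")]), c(0, 0))
  }
  # with beta = 0 and Pa = 0 the juvenile equation is (nu_j - gamma - mu_p) Pj
  s <- c(R = 1.3, C = 0.4, Pj = 0.7, Pa = 0)
  r <- model_rates(s, p)
  expect_equal(unname(lhigp_rhs(s, p)[["Pj"]]),
               (r$nu_j - r$gamma - p$mu_p) * 0.7, tolerance = 1e-12)
})

test_that("parameter validation enforces the model's domain", {
  expect_error(lhigp_params(a_jr = 7, a_ar = 0, beta = 0), "a_p")
  expect_error(lhigp_params(a_jr = 4, a_ar = 0, beta = -1), "non-negative")
  expect_error(lhigp_params(a_jr = 4, a_ar = 0, beta = 0, epsilon = -1),
               "epsilon")
  expect_error(lhigp_params(a_jr = 4, a_ar = 0, beta = 0, z = 1), "z")
  expect_error(lhigp_params(a_jr = 4, a_ar = 0, beta = 0, sigma = 1.2),
               "sigma")
  expect_error(set_params(default_parameters(a_jr = 4, a_ar = 0, beta = 0),
                          nonsense = 1), "unknown")
})

test_that("parameters round-trip through YAML and JSON with strict keys", {
  p <- default_parameters(a_jr = 4.25, a_ar = 3, beta = 0.5, epsilon = 2)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(f)
  }
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(c(unclass(p), list(bogus = 1)), f)
  expect_error(read_params(f), "unknown keys")
  unlink(f)
})
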