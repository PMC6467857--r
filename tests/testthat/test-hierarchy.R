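test_that("consumer minimum resource density has its closed form", {
  p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
  expect_equal(consumer_min_resource(p), 11 / 39, tolerance = 1e-14)
  expect_equal(floor(consumer_min_resource(p) * 1e4) / 1e4, 0.2820)  # printed as truncated
  # doubling the attack rate halves the threshold
  expect_equal(consumer_min_resource(set_params(p, a_cr = 20)), 11 / 78,
               tolerance = 1e-14)
  # saturation can never cover losses
  expect_error(consumer_min_resource(set_params(p, h_c = 0.5)),
               "no persistence")
})

test_that("juvenile growth threshold inverts net production in the trait", {
  p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
  expect_equal(juvenile_growth_threshold(p, 1), 1, tolerance = 1e-14)
  # at the consumer's resource level: 39/11, printed as 3.55
  a_grow <- juvenile_growth_threshold(p, consumer_min_resource(p))
  expect_equal(a_grow, 39 / 11, tolerance = 1e-12)
  expect_equal(round(a_grow, 2), 3.55)
  expect_lt(juvenile_growth_threshold(p, 1e6), 1e-5)
  # nu_j at the threshold is exactly zero
  nu_j <- net_production(
    ingestion_rates(c(R = 11 / 39, C = 0, Pj = 0, Pa = 0),
                    set_params(p, a_jr = a_grow))$I_j, p, "juvenile")
  expect_lt(abs(nu_j), 1e-12)
})

test_that("predator minimum resource density solves R0 = 1 on resource alone", {
  # equal stage attack rates: both stages identical, closed form applies
  for (a in c(2, 4, 5.5)) {
    p <- default_parameters(a_jr = a, a_ar = a, beta = 0)
    pm <- predator_min_resource(p)
    closed <- (p$T_p + p$mu_p) / (a * (p$sigma - p$h_p * (p$T_p + p$mu_p)))
    if (closed < p$R_max) {
      expect_equal(pm$status, "ok")
      expect_equal(pm$R_star, closed, tolerance = 1e-10)
    } else expect_equal(pm$status, "no_persistence")
  }
  # diet shift: adults starve on resource alone
  p0 <- default_parameters(a_jr = 5, a_ar = 0, beta = 0)
  expect_equal(predator_min_resource(p0)$status, "no_persistence")
  # a_ar = 3: predator persists but always needs more resource than the consumer
  for (a_jr in c(2, 4, 6)) {
    p3 <- default_parameters(a_jr = a_jr, a_ar = 3, beta = 0)
    pm3 <- predator_min_resource(p3)
    if (pm3$status == "ok")
      expect_gt(pm3$R_star, consumer_min_resource(p3))
  }
})

test_that("hierarchy classes order the competitors correctly", {
  expect_equal(classify_hierarchy(
    default_parameters(a_jr = 5, a_ar = 4, beta = 0))$class,
    "predators_superior")
  expect_equal(classify_hierarchy(
    default_parameters(a_jr = 4, a_ar = 0, beta = 0))$class,
    "juveniles_grow_consumers_superior")
  expect_equal(classify_hierarchy(
    default_parameters(a_jr = 3, a_ar = 0, beta = 0))$class,
    "consumers_superior")
})

test_that("the hierarchy flips exactly at a_jr = 4 when a_ar = 4", {
  p <- default_parameters(a_jr = 3, a_ar = 4, beta = 0)
  flip <- hierarchy_flip_trait(p)
  expect_equal(flip, 4, tolerance = 1e-6)
  # at the flip the predator's and consumer's thresholds coincide (= 11/39)
  p4 <- set_params(p, a_jr = 4)
  expect_equal(predator_min_resource(p4)$R_star, 11 / 39, tolerance = 1e-8)
})

test_that("superior predators hold a PR state against consumer invasion", {
  p <- default_parameters(a_jr = 5, a_ar = 4, beta = 0)
  expect_equal(classify_hierarchy(p)$class, "predators_superior")
  eq <- solve_equilibrium(c(R = 0.4, C = 0, Pj = 1.5, Pa = 0.6), p,
                          absent = "C")
  expect_equal(eq$class, "PR")
  expect_lt(invasion_growth_rate(eq$state, p, "C"), 0)
})

test_that("hierarchy report serializes to JSON", {
  rep <- classify_hierarchy(default_parameters(a_jr = 5, a_ar = 4, beta = 0))
  f <- tempfile(fileext = ".json")
  write_hierarchy(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$class, "predators_superior")
  expect_equal(back$R_star_C, rep$R_star_C, tolerance = 1e-12)
  unlink(f)
})
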