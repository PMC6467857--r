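# shared fixtures, computed once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, compute(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# stable coexistence (PCR) equilibrium of the noncannibalistic diet-shift
# scenario at a_jr = 4.5 (paper figure-2 territory)
pcr_dietshift <- function() fixture("pcr_dietshift", function() {
  p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
  at <- find_attractor(c(R = 3, C = 0.1, Pj = 0.1, Pa = 0.1), p)
  stopifnot(at$status == "equilibrium", at$class == "PCR")
  at$equilibrium
})

# consumer-resource equilibrium (predators absent) at the same parameters
cr_dietshift <- function(a_jr = 3) {
  p <- default_parameters(a_jr = a_jr, a_ar = 0, beta = 0)
  solve_equilibrium(cr_equilibrium_closed_form(p), p, absent = "P")
}

expect_state_equal <- function(state, expected, tol = 1e-6) {
  expect_equal(unname(unlist(state)[c("R", "C", "Pj", "Pa")]),
               unname(expected), tolerance = tol)
}
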