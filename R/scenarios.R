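#' Standard parameterization of the model
#'
#' The default constants of the study system: consumer rates from a
#' half-saturation constant of 1 with quarter-power allometric scaling
#' (`h_c = 0.1`, `T_c = 1`, `mu_c = 0.1`, `a_cr = 10`); predator rates from
#' the geometric-mean predator-prey body-mass ratio of 42 via the same
#' scaling (`h_p = 0.25`, `T_p = 0.4`, `mu_p = 0.04`, see
#' [allometry_check()]); trade-off maximum `a_p = 6`; `sigma = 0.5`,
#' `z = 0.01`, `delta = 1`, `R_max = 3`, linear trade-off `epsilon = 0`.
#'
#' The trait `a_jr`, the diet-breadth axis `a_ar` and the cannibalistic
#' preference `beta` have no defaults: they define a scenario and must be
#' supplied.
#'
#' @param a_jr Juvenile resource attack rate (the trait).
#' @param a_ar Adult resource attack rate (0 diet shift; 3, 4 diet
#'   broadening).
#' @param beta Cannibalistic preference (0 noncannibalistic, 1
#'   cannibalistic).
#' @param ... Overrides for any other constant, passed to [lhigp_params()].
#' @return An [lhigp_params()] object.
#' @export
#' @examples
#' default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
default_parameters <- function(a_jr, a_ar, beta, ...) {
  if (missing(a_jr) || missing(a_ar) || missing(beta))
    stop("a_jr, a_ar and beta define the scenario and must be supplied")
  lhigp_params(a_jr = a_jr, a_ar = a_ar, beta = beta, ...)
}

#' Predator constants from the predator-prey body-mass ratio
#'
#' Mass-specific maximum ingestion (the inverse of handling time),
#' maintenance and mortality all scale with adult body mass to the power
#' \eqn{-1/4}.  A predator heavier than its prey by `mass_ratio` therefore
#' has
#' \deqn{h_p = h_c\,\mathrm{ratio}^{1/4}, \quad
#'       T_p = T_c\,\mathrm{ratio}^{-1/4}, \quad
#'       \mu_p = \mu_c\,\mathrm{ratio}^{-1/4}.}
#' Both the raw values and rounded ones are reported.  Rounding acts on the
#' allometric factor \eqn{\mathrm{ratio}^{1/4}} (to 2 significant figures:
#' \eqn{42^{1/4} = 2.5457 \to 2.5}), not on each constant separately — that
#' is the one rule that reproduces all three standard constants
#' (`0.25, 0.4, 0.04`) from ratio 42 simultaneously.
#'
#' @param mass_ratio Predator-to-prey body-mass ratio, `> 0`.
#' @param h_c,T_c,mu_c Consumer constants to scale from.
#' @return List with `raw`, `rounded` (each a named vector
#'   `(h_p, T_p, mu_p)`) and `factor_raw`, `factor_rounded`.
#' @export
#' @examples
#' allometry_check(42)$rounded  # h_p 0.25, T_p 0.4, mu_p 0.04
allometry_check <- function(mass_ratio, h_c = 0.1, T_c = 1, mu_c = 0.1) {
  stopifnot(mass_ratio > 0)
  fac <- mass_ratio^(1 / 4)
  fac2 <- signif(fac, 2)
  list(raw = c(h_p = h_c * fac, T_p = T_c / fac, mu_p = mu_c / fac),
       rounded = c(h_p = h_c * fac2, T_p = T_c / fac2, mu_p = mu_c / fac2),
       factor_raw = fac, factor_rounded = fac2)
}

#' The study's scenario grid
#'
#' The six core (`a_ar`, `beta`) scenarios — diet shift (`a_ar = 0`) and
#' diet broadening (`a_ar` 3 and 4), each without (`beta = 0`) and with
#' (`beta = 1`) cannibalism — plus the two-parameter robustness maps over
#' (`a_jr`, `beta`) at maximum resource densities `R_max` in
#' \{1.5, 3, 6\} and trade-off shapes `epsilon` in \{-0.5, 0, 2\}.  The
#' `(R_max, epsilon)` grid values other than the core `(3, 0)` and `(3, 2)`
#' combinations are marked `inferred = TRUE`: the robustness analyses name
#' the productivity and trade-off-shape axes without printing every grid
#' value.  Recommended sweep ranges: `a_jr` in `[0, 6]`, `beta` in
#' `[0, 2]`.
#'
#' @return List with `core` (data frame `name, a_ar, beta`), `maps` (data
#'   frame `a_ar, R_max, epsilon, inferred`) and `sweeps` (list of ranges).
#' @export
study_scenarios <- function() {
  core <- data.frame(
    name = c("diet-shift", "diet-shift-cannibal",
             "diet-broadening3", "diet-broadening3-cannibal",
             "diet-broadening4", "diet-broadening4-cannibal"),
    a_ar = c(0, 0, 3, 3, 4, 4),
    beta = c(0, 1, 0, 1, 0, 1))
  maps <- expand.grid(a_ar = c(0, 3, 4), R_max = c(1.5, 3, 6),
                      epsilon = c(-0.5, 0, 2))
  maps$inferred <- !(maps$R_max == 3 & maps$epsilon %in% c(0, 2))
  list(core = core, maps = maps,
       sweeps = list(a_jr = c(0, 6), beta = c(0, 2)))
}

#' Scenario defaults by name
#'
#' @param name One of the core scenario names of [study_scenarios()].
#' @param a_jr Trait value to instantiate the scenario at.
#' @param ... Further overrides passed to [default_parameters()].
#' @return An [lhigp_params()] object.
#' @export
scenario_parameters <- function(name, a_jr, ...) {
  core <- study_scenarios()$core
  i <- match(name, core$name)
  if (is.na(i))
    stop("unknown scenario '", name, "'; use one of: ",
         paste(core$name, collapse = ", "))
  default_parameters(a_jr = a_jr, a_ar = core$a_ar[i], beta = core$beta[i],
                     ...)
}

#' Write the scenario list as YAML
#'
#' @param path YAML destination.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(path) {
  sc <- study_scenarios()
  yaml::write_yaml(list(
    core = lapply(seq_len(nrow(sc$core)), function(i) as.list(sc$core[i, ])),
    maps = lapply(seq_len(nrow(sc$maps)), function(i) as.list(sc$maps[i, ])),
    sweeps = sc$sweeps), path)
  invisible(path)
}

#' Seeded random parameter draw for property tests
#'
#' Reproducible uniform draws of the scenario axes with all other constants
#' at their defaults.  Uniform sampling is deliberate: the model is a
#' deterministic ODE system and the draws only need to cover the admissible
#' parameter box, not emulate biological noise.  The `epsilon` floor of
#' `-0.9` (the weakest trade-off considered) stays clear of the trade-off's
#' pole at `-1`.
#'
#' @param seed Integer seed (mandatory; no global-state dependence).
#' @param ranges Named list of length-2 ranges for any of `a_jr`, `a_ar`,
#'   `beta`, `epsilon`, `R_max`; defaults `a_jr, a_ar` in `[0, 6]`, `beta`
#'   in `[0, 2]`, `epsilon` in `[-0.9, 5]`, `R_max` in `[0.5, 6]`.
#' @return An [lhigp_params()] object.
#' @export
#' @examples
#' identical(random_scenario(7), random_scenario(7))
random_scenario <- function(seed, ranges = list()) {
  defaults <- list(a_jr = c(0, 6), a_ar = c(0, 6), beta = c(0, 2),
                   epsilon = c(-0.9, 5), R_max = c(0.5, 6))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  rg <- utils::modifyList(defaults, ranges)
  for (nm in names(rg))
    if (length(rg[[nm]]) != 2 || rg[[nm]][1] > rg[[nm]][2])
      stop("range for ", nm, " must be an increasing length-2 vector")
  set.seed(seed)
  draw <- vapply(rg, function(r) stats::runif(1, r[1], r[2]), numeric(1))
  # keep the trait inside the trade-off domain [0, a_p] (a_p stays 6)
  lhigp_params(a_jr = min(draw[["a_jr"]], 6), a_ar = draw[["a_ar"]],
               beta = draw[["beta"]], epsilon = draw[["epsilon"]],
               R_max = draw[["R_max"]])
}

#' Seeded multiplicative perturbation of an equilibrium state
#'
#' Each present component is scaled by `(1 + u)` with `u` uniform in
#' `[-rel_magnitude, rel_magnitude]`; absent components stay exactly zero.
#' Used by the stability tests (a perturbation of a stable equilibrium must
#' decay; one of an unstable equilibrium with an unstable direction in the
#' positive cone must grow).
#'
#' @param eq An `lhigp_equilibrium` or a state vector.
#' @param rel_magnitude Relative perturbation size, in `(0, 0.5]`.
#' @param seed Integer seed.
#' @param presence_tol Components at or below this stay at zero.
#' @return A perturbed state vector.
#' @export
perturb_state <- function(eq, rel_magnitude, seed, presence_tol = 1e-8) {
  stopifnot(rel_magnitude > 0, rel_magnitude <= 0.5)
  s <- if (inherits(eq, "lhigp_equilibrium")) eq$state else state_vec(eq)
  set.seed(seed)
  u <- stats::runif(4, -rel_magnitude, rel_magnitude)
  present <- s > presence_tol
  s[present] <- s[present] * (1 + u[present])
  s
}
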