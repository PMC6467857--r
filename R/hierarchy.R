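#' Competitive-hierarchy thresholds
#'
#' Closed-form and semi-closed-form thresholds that order the consumer and
#' the intraguild predator by the resource level each needs to persist.
#' They pre-classify scenarios: whoever persists on the lower resource
#' density wins pure resource competition.
#'
#' `consumer_min_resource()` solves the consumer's equilibrium condition
#' \eqn{\nu_c(R) = \mu_c} for the resource density below which consumers
#' cannot sustain themselves:
#' \deqn{R^*_C = \frac{T_c + \mu_c}{a_{cr}\,(\sigma - h_c (T_c + \mu_c))}.}
#'
#' @param p An [lhigp_params()] object.
#' @return `consumer_min_resource()`: the threshold density `R*_C`, or an
#'   error if saturation can never cover the consumer's losses
#'   (`sigma <= h_c (T_c + mu_c)`).
#' @export
#' @examples
#' p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
#' consumer_min_resource(p)  # 0.28205...
consumer_min_resource <- function(p) {
  denom <- p$sigma - p$h_c * (p$T_c + p$mu_c)
  if (denom <= 0 || p$a_cr <= 0)
    stop("no persistence: consumer cannot cover losses at any resource density")
  (p$T_c + p$mu_c) / (p$a_cr * denom)
}

#' Trait threshold for juvenile somatic growth
#'
#' The juvenile attack rate below which juvenile net biomass production is
#' non-positive at resource level `R`:
#' \deqn{a_{jr}^{grow} = \frac{T_p}{R\,(\sigma - h_p T_p)}.}
#' Evaluated at the consumer-resource equilibrium's resource density this is
#' the lower edge of the trait range where the coexistence state co-occurs
#' with a stable consumer-resource equilibrium (juveniles cannot grow on
#' what the consumer leaves).
#'
#' @param p An [lhigp_params()] object.
#' @param R Resource density at which to evaluate the threshold.
#' @return The trait threshold, or an error if `sigma <= h_p * T_p` (no
#'   growth at any trait).
#' @export
#' @examples
#' p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
#' juvenile_growth_threshold(p, consumer_min_resource(p))  # about 3.545
juvenile_growth_threshold <- function(p, R) {
  denom <- p$sigma - p$h_p * p$T_p
  if (denom <= 0)
    stop("no growth: saturation cannot cover juvenile maintenance at any trait")
  if (R <= 0) stop("R must be positive")
  p$T_p / (R * denom)
}

#' Predator minimum resource density
#'
#' The resource density below which the predator cannot persist alone on the
#' resource: the root in `R` of the resource-only lifetime reproductive
#' success
#' \deqn{R_0(R) = z^{\,\mu_p/\nu_j(R) - 1}\; \frac{\nu_a(R)^{+}}{\mu_p} = 1,}
#' with no consumers and no resident predators (so juvenile mortality is the
#' background rate).  Solved by bisection on `(0, R_max]`.
#'
#' @param p An [lhigp_params()] object (the `a_jr` and `a_ar` fields define
#'   the predator's resource-feeding ability).
#' @param tol Bisection tolerance on `R`.
#' @return List with `status` (`"ok"` or `"no_persistence"`) and `R_star`
#'   (`NA` when the predator cannot persist on the resource alone, e.g. in
#'   the diet-shift scenario where adults starve without prey).
#' @export
predator_min_resource <- function(p, tol = 1e-12) {
  if (p$a_jr <= 0 && p$a_ar <= 0)
    return(list(status = "no_persistence", R_star = NA_real_))
  R0_of <- function(R) {
    I_j <- p$a_jr * R / (1 + p$h_p * p$a_jr * R)
    nu_j <- p$sigma * I_j - p$T_p
    if (nu_j <= 0) return(0)
    I_a <- p$a_ar * R / (1 + p$h_p * p$a_ar * R)
    nu_a <- p$sigma * I_a - p$T_p
    p$z^(p$mu_p / nu_j - 1) * max(nu_a, 0) / p$mu_p
  }
  if (R0_of(p$R_max) < 1)
    return(list(status = "no_persistence", R_star = NA_real_))
  lo <- 0; hi <- p$R_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (R0_of(mid) < 1) lo <- mid else hi <- mid
  }
  list(status = "ok", R_star = (lo + hi) / 2)
}

#' Classify the competitive hierarchy between consumer and predator
#'
#' Three mutually exclusive cases, ordered by how well the predator does in
#' pure resource competition:
#' * `"predators_superior"` — the predator persists alone on the resource
#'   down to a lower density than the consumer needs
#'   (`R*_P < R*_C`); the predator-resource state then resists consumer
#'   invasion at that trait.
#' * `"juveniles_grow_consumers_superior"` — consumers win resource
#'   competition, but juvenile predators still have positive net biomass
#'   production at the consumer's equilibrium resource density
#'   (`nu_j(R*_C) > 0`), so predators can invade through predation.
#' * `"consumers_superior"` — juveniles cannot even grow at the consumer's
#'   resource level.
#'
#' @param p An [lhigp_params()] object.
#' @return An object of class `lhigp_hierarchy`: list with `class`, `R_star_C`,
#'   `R_star_P` (`NA` if the predator cannot persist on resource alone),
#'   `a_jr_grow` (the juvenile-growth trait threshold at `R*_C`) and
#'   `nu_j_at_CR` (juvenile net production at `R*_C`).
#' @export
#' @examples
#' classify_hierarchy(default_parameters(a_jr = 5, a_ar = 4, beta = 0))$class
classify_hierarchy <- function(p) {
  R_C <- consumer_min_resource(p)
  pm <- predator_min_resource(p)
  I_j <- p$a_jr * R_C / (1 + p$h_p * p$a_jr * R_C)
  nu_j <- p$sigma * I_j - p$T_p
  a_grow <- tryCatch(juvenile_growth_threshold(p, R_C),
                     error = function(e) NA_real_)
  cls <- if (pm$status == "ok" && pm$R_star < R_C) {
    "predators_superior"
  } else if (nu_j > 0) {
    "juveniles_grow_consumers_superior"
  } else {
    "consumers_superior"
  }
  structure(list(class = cls, R_star_C = R_C, R_star_P = pm$R_star,
                 a_jr_grow = a_grow, nu_j_at_CR = nu_j),
            class = "lhigp_hierarchy")
}

#' @export
print.lhigp_hierarchy <- function(x, ...) {
  cat("competitive hierarchy:", x$class, "\n")
  cat(sprintf("  R*_C = %.6f, R*_P = %s, a_jr^grow(R*_C) = %.6f\n",
              x$R_star_C,
              if (is.na(x$R_star_P)) "none" else sprintf("%.6f", x$R_star_P),
              x$a_jr_grow))
  invisible(x)
}

#' Export a hierarchy report as JSON
#'
#' @param x An `lhigp_hierarchy` from [classify_hierarchy()].
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(x, path) {
  stopifnot(inherits(x, "lhigp_hierarchy"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Trait value where the competitive hierarchy flips
#'
#' For a diet-broadening predator (`a_ar > 0`), the juvenile trait value at
#' which the predator's minimum resource density equals the consumer's —
#' above it the predator is the superior resource competitor.  Solved by
#' bisection in the trait.
#'
#' @param p An [lhigp_params()] object with `a_ar > 0`.
#' @param bracket Trait interval to search (default `[0, a_p]`).
#' @param tol Trait tolerance.
#' @return The trait value, or `NA` when the hierarchy does not flip inside
#'   the bracket.
#' @export
#' @examples
#' hierarchy_flip_trait(default_parameters(a_jr = 4, a_ar = 4, beta = 0)) # 4
hierarchy_flip_trait <- function(p, bracket = c(0, p$a_p), tol = 1e-10) {
  gap <- function(a_jr) {
    p2 <- set_param1(p, "a_jr", a_jr)
    pm <- predator_min_resource(p2)
    # no persistence on resource alone counts as needing infinite resource
    if (pm$status != "ok") return(Inf)
    pm$R_star - consumer_min_resource(p2)
  }
  g_lo <- gap(bracket[1]); g_hi <- gap(bracket[2])
  if (sign(g_lo) == sign(g_hi)) return(NA_real_)
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(gap(mid)) == sign(g_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
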