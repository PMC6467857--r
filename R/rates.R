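#' Bioenergetic rate functions
#'
#' The per-unit-biomass rates of the stage-structured model, evaluated at a
#' community state.  Ingestion follows Holling type-II functional responses;
#' the adult predator pools resource, consumer and (discounted by the
#' cannibalistic preference `beta`) juvenile conspecifics in a single
#' saturating response
#' \deqn{I_a = \frac{a_{ar} R + a_{ac}(C + \beta P_j)}
#'            {1 + h_p\,(a_{ar} R + a_{ac}(C + \beta P_j))}.}
#' Net biomass production is assimilation minus maintenance,
#' \eqn{\nu = \sigma I - T}, and may be negative (starvation).  Juvenile
#' mortality is background mortality plus cannibalism; the cannibalistic term
#' shares the adult functional-response denominator.
#'
#' @param state A [community_state()] or any non-negative length-4 vector
#'   `(R, C, Pj, Pa)`.
#' @param p An [lhigp_params()] object.
#' @return For `ingestion_rates()`, a named list `I_c`, `I_j`, `I_a`.
#'   For `model_rates()`, a named list with all mass-specific rates:
#'   ingestion `I_c, I_j, I_a`, net production `nu_c, nu_j, nu_a`, total
#'   juvenile mortality `D_j`, maturation rate `gamma`, and the derived adult
#'   attack rate `a_ac`.
#' @export
ingestion_rates <- function(state, p) {
  s <- state_vec(state)
  a_ac <- tradeoff_adult_attack(p$a_jr, p$a_p, p$epsilon)
  enc_a <- p$a_ar * s[["R"]] + a_ac * (s[["C"]] + p$beta * s[["Pj"]])
  list(I_c = p$a_cr * s[["R"]] / (1 + p$h_c * p$a_cr * s[["R"]]),
       I_j = p$a_jr * s[["R"]] / (1 + p$h_p * p$a_jr * s[["R"]]),
       I_a = enc_a / (1 + p$h_p * enc_a))
}

#' Net biomass production from an ingestion rate
#'
#' @param I Mass-specific ingestion rate.
#' @param p An [lhigp_params()] object.
#' @param role One of `"consumer"`, `"juvenile"`, `"adult"`; selects the
#'   maintenance constant (`T_c` for consumers, `T_p` for both predator
#'   stages).
#' @return `sigma * I - T`; negative values indicate starvation.
#' @export
net_production <- function(I, p, role = c("consumer", "juvenile", "adult")) {
  role <- match.arg(role)
  p$sigma * I - if (role == "consumer") p$T_c else p$T_p
}

#' Total juvenile predator mortality
#'
#' Background mortality plus the mass-specific cannibalistic mortality
#' \eqn{a_{ac} \beta P_a / (1 + h_p(a_{ar} R + a_{ac}(C + \beta P_j)))}
#' inflicted by adult predators.
#'
#' @inheritParams ingestion_rates
#' @return The total per-capita juvenile mortality rate `D_j >= mu_p`.
#' @export
juvenile_mortality <- function(state, p) {
  s <- state_vec(state)
  a_ac <- tradeoff_adult_attack(p$a_jr, p$a_p, p$epsilon)
  enc_a <- p$a_ar * s[["R"]] + a_ac * (s[["C"]] + p$beta * s[["Pj"]])
  p$mu_p + a_ac * p$beta * s[["Pa"]] / (1 + p$h_p * enc_a)
}

#' Juvenile maturation rate
#'
#' The maturation function of the stage-structured biomass framework,
#' \deqn{\gamma(\nu_j, D_j) = \frac{\nu_j - D_j}{1 - z^{\,1 - D_j/\nu_j}},}
#' derived so that the two-stage model reproduces the equilibria of the
#' underlying continuously size-structured population: juveniles grow
#' exponentially from relative size `z` to 1 at rate `nu_j` while dying at
#' rate `D_j`.  At `nu_j == D_j` the expression has a removable singularity
#' with limit \eqn{-\nu_j / \ln z}; this is evaluated exactly, and the
#' neighbourhood of the singularity is computed cancellation-free via
#' `expm1()`.  Starving juveniles (`nu_j <= 0`) do not mature: `gamma = 0`.
#'
#' @param nu_j Mass-specific juvenile net biomass production.
#' @param D_j Total juvenile mortality rate.
#' @param z Birth-to-maturation size ratio, in (0, 1).
#' @return The maturation rate `gamma >= 0`.
#' @export
#' @examples
#' maturation_rate(0.1, 0.04, 0.01)
#' maturation_rate(0.04, 0.04, 0.01)  # removable singularity: 0.04 / log(100)
maturation_rate <- function(nu_j, D_j, z) {
  if (z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  if (nu_j <= 0) return(0)
  u <- 1 - D_j / nu_j
  if (u == 0) return(-nu_j / log(z))
  # 1 - z^u == -expm1(u * log z): stable as u -> 0
  (nu_j - D_j) / (-expm1(u * log(z)))
}

#' All mass-specific rates at a state
#'
#' @inheritParams ingestion_rates
#' @export
model_rates <- function(state, p) {
  s <- state_vec(state)
  a_ac <- tradeoff_adult_attack(p$a_jr, p$a_p, p$epsilon)
  enc_a <- p$a_ar * s[["R"]] + a_ac * (s[["C"]] + p$beta * s[["Pj"]])
  den_a <- 1 + p$h_p * enc_a
  I_c <- p$a_cr * s[["R"]] / (1 + p$h_c * p$a_cr * s[["R"]])
  I_j <- p$a_jr * s[["R"]] / (1 + p$h_p * p$a_jr * s[["R"]])
  I_a <- enc_a / den_a
  nu_c <- p$sigma * I_c - p$T_c
  nu_j <- p$sigma * I_j - p$T_p
  nu_a <- p$sigma * I_a - p$T_p
  D_j <- p$mu_p + a_ac * p$beta * s[["Pa"]] / den_a
  list(I_c = I_c, I_j = I_j, I_a = I_a,
       nu_c = nu_c, nu_j = nu_j, nu_a = nu_a,
       D_j = D_j, gamma = maturation_rate(nu_j, D_j, p$z),
       a_ac = a_ac, den_a = den_a)
}

#' Right-hand side of the four biomass ODEs
#'
#' Time derivatives of resource, consumer, juvenile- and adult-predator
#' biomass.  The resource renews by semichemostat dynamics
#' \eqn{\delta (R_{max} - R)} and is grazed by consumers, juvenile predators
#' and (when `a_ar > 0`) adult predators.  Consumers grow with their net
#' production and die from predation and background mortality.  Juvenile
#' biomass gains the adult reproduction flux and juvenile somatic growth and
#' loses maturation and mortality; adult biomass gains maturation and loses
#' background mortality.
#'
#' Starvation convention: the reproduction flux into the juvenile stage uses
#' the positive part \eqn{\nu_a^+}; a negative adult net production is
#' retained as a biomass loss term in the adult equation itself.  A negative
#' juvenile net production already acts in the juvenile equation (shrinking
#' juveniles), and the maturation rate is zero there.  At every equilibrium
#' with non-starving stages this coincides with the plain-\eqn{\nu} form.
#'
#' The function never clamps the state: non-negativity is the integrator's
#' concern (see [simulate_lhigp()]).
#'
#' @inheritParams ingestion_rates
#' @return Named numeric vector of the four time derivatives
#'   `(R, C, Pj, Pa)`.
#' @export
lhigp_rhs <- function(state, p) {
  s <- unlist(state)[c("R", "C", "Pj", "Pa")]
  r <- model_rates(s, p)
  nu_a_pos <- max(r$nu_a, 0)
  dR <- p$delta * (p$R_max - s[["R"]]) - r$I_c * s[["C"]] -
    r$I_j * s[["Pj"]] - p$a_ar * s[["R"]] / r$den_a * s[["Pa"]]
  dC <- r$nu_c * s[["C"]] - r$a_ac * s[["Pa"]] / r$den_a * s[["C"]] -
    p$mu_c * s[["C"]]
  dPj <- nu_a_pos * s[["Pa"]] + r$nu_j * s[["Pj"]] -
    r$gamma * s[["Pj"]] - r$D_j * s[["Pj"]]
  dPa <- r$gamma * s[["Pj"]] - p$mu_p * s[["Pa"]] +
    (r$nu_a - nu_a_pos) * s[["Pa"]]
  c(R = dR, C = dC, Pj = dPj, Pa = dPa)
}
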