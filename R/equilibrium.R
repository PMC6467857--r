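#' @importFrom stats rnorm runif uniroot setNames
NULL

state_names <- c("R", "C", "Pj", "Pa")

#' Finite-difference Jacobian of the ODE right-hand side
#'
#' Central differences with component-wise step `1e-7 * (1 + |x|)`; the model
#' is smooth in the interior so this is accurate to ~1e-7 in each entry,
#' ample for stability assessment and continuation.
#'
#' @param state State at which to differentiate.
#' @param p An [lhigp_params()] object.
#' @param h_scale Relative finite-difference step.
#' @return The 4 x 4 Jacobian matrix (rows and columns `R, C, Pj, Pa`).
#' @export
lhigp_jacobian <- function(state, p, h_scale = 1e-7) {
  x <- unlist(state)[state_names]
  J <- matrix(0, 4, 4, dimnames = list(state_names, state_names))
  for (j in seq_len(4)) {
    h <- h_scale * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (lhigp_rhs(xp, p) - lhigp_rhs(xm, p)) / (2 * h)
  }
  J
}

#' Eigenvalues of the Jacobian at an equilibrium
#'
#' @param eq An `lhigp_equilibrium` (from [solve_equilibrium()]) or a state
#'   vector.
#' @param p Parameters; taken from `eq` when omitted.
#' @return Complex eigenvalues of the full 4 x 4 Jacobian, sorted by
#'   decreasing real part.  Absent species contribute their invasion
#'   directions, so the leading eigenvalue also reports invasibility.
#' @export
jacobian_eigenvalues <- function(eq, p = NULL) {
  if (inherits(eq, "lhigp_equilibrium")) {
    state <- eq$state
    if (is.null(p)) p <- eq$params
  } else state <- eq
  ev <- eigen(lhigp_jacobian(state, p), only.values = TRUE)$values
  ev[order(-Re(ev))]
}

#' Invasion growth rate of an absent species
#'
#' The per-capita initial growth rate of a species absent from an
#' equilibrium, evaluated in that equilibrium's environment.  For the
#' consumer this is the scalar `nu_c - predation - mu_c`; for the predator it
#' is the dominant eigenvalue of the 2 x 2 juvenile/adult stage block
#' \deqn{\begin{pmatrix} \nu_j - \gamma - D_j & \nu_a^+ \\ \gamma & -\mu_p
#'   \end{pmatrix}}
#' so that a positive value means the predator can invade through the
#' combined growth/maturation/reproduction loop.
#'
#' @param state Equilibrium state (the species of interest at 0).
#' @param p An [lhigp_params()] object.
#' @param species `"C"` or `"P"` (the predator invades as a stage pair).
#' @return A real growth rate; `> 0` means invasion succeeds.
#' @export
invasion_growth_rate <- function(state, p, species = c("C", "P")) {
  species <- match.arg(species)
  r <- model_rates(state, p)
  s <- unlist(state)[state_names]
  if (species == "C") {
    r$nu_c - r$a_ac * s[["Pa"]] / r$den_a - p$mu_c
  } else {
    nu_a_pos <- max(r$nu_a, 0)
    B <- matrix(c(r$nu_j - r$gamma - r$D_j, nu_a_pos,
                  r$gamma, -p$mu_p + min(r$nu_a, 0)),
                2, 2, byrow = TRUE)
    max(Re(eigen(B, only.values = TRUE)$values))
  }
}

#' Classify an equilibrium by which species are present
#'
#' @param state Equilibrium state.
#' @param presence_tol Densities above this count as present.
#' @return One of `"R"`, `"CR"`, `"PR"`, `"PCR"`.  At a converged
#'   equilibrium the two predator stages must be jointly present or jointly
#'   absent; a mixed pattern is an error.
#' @export
classify_equilibrium <- function(state, presence_tol = 1e-8) {
  s <- unlist(state)[state_names]
  has_C <- s[["C"]] > presence_tol
  has_Pj <- s[["Pj"]] > presence_tol
  has_Pa <- s[["Pa"]] > presence_tol
  if (xor(has_Pj, has_Pa))
    stop("inconsistent equilibrium: one predator stage present without the other")
  has_P <- has_Pj && has_Pa
  if (has_P && has_C) "PCR" else if (has_P) "PR" else if (has_C) "CR" else "R"
}

#' Solve an equilibrium of the model directly
#'
#' Newton iteration on the reduced system of present components: species
#' listed in `absent` are pinned to exactly zero and excluded from the
#' unknowns.  Stability is then assessed on the full four-dimensional
#' Jacobian, so invasion directions of the absent species are included in
#' the reported eigenvalues.
#'
#' @param guess Non-negative initial state; entries of absent species are
#'   ignored.
#' @param p An [lhigp_params()] object.
#' @param absent Character vector naming components fixed at zero, from
#'   `c("C", "Pj", "Pa")` (use both `"Pj"` and `"Pa"`, or the shorthand
#'   `"P"`, to remove the predator).
#' @param tol Residual max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @param presence_tol Passed to [classify_equilibrium()].
#' @return An object of class `lhigp_equilibrium`: list with `state`,
#'   `params`, `residual` (max-norm of the full right-hand side),
#'   `eigenvalues`, `stable` (all real parts negative), `class`, and
#'   `converged`.
#' @details Convergence to a negative density is rejected as an error, as is
#'   non-convergence (the error carries the last iterate).  A damped step
#'   (halving) is used when a full Newton step fails to reduce the residual.
#' @export
#' @examples
#' p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
#' eq <- solve_equilibrium(c(R = 1, C = 0.5, Pj = 0.5, Pa = 0.5), p)
#' eq$class; eq$stable
solve_equilibrium <- function(guess, p, absent = character(),
                              tol = 1e-10, max_iter = 50,
                              presence_tol = 1e-8) {
  if ("P" %in% absent) absent <- union(setdiff(absent, "P"), c("Pj", "Pa"))
  if (!all(absent %in% c("C", "Pj", "Pa")))
    stop("absent must name components among C, Pj, Pa")
  x_full <- unlist(guess)[state_names]
  x_full[absent] <- 0
  free <- setdiff(state_names, absent)
  f_red <- function(xf) {
    x_full[free] <- xf
    lhigp_rhs(x_full, p)[free]
  }
  xf <- x_full[free]
  res <- f_red(xf)
  for (iter in seq_len(max_iter)) {
    if (max(abs(res)) < tol) break
    n <- length(free)
    Jr <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * (1 + abs(xf[j]))
      xp <- xf; xp[j] <- xf[j] + h
      xm <- xf; xm[j] <- xf[j] - h
      Jr[, j] <- (f_red(xp) - f_red(xm)) / (2 * h)
    }
    step <- tryCatch(solve(Jr, -res), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in Newton iteration at state: ",
           paste(signif(xf, 6), collapse = ", "))
    lambda <- 1
    repeat {
      x_new <- xf + lambda * step
      res_new <- f_red(x_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    xf <- x_new
    res <- res_new
  }
  if (max(abs(res)) >= tol)
    stop("equilibrium solver did not converge; last iterate: ",
         paste(sprintf("%s = %.6g", free, xf), collapse = ", "))
  if (any(xf < -presence_tol))
    stop("equilibrium solver converged to a negative density: ",
         paste(sprintf("%s = %.6g", free, xf), collapse = ", "))
  # convergence onto a boundary (species at 0 up to round-off) is legitimate
  xf[xf < 0] <- 0
  x_full[free] <- xf
  ev <- jacobian_eigenvalues(x_full, p)
  structure(list(state = x_full, params = p,
                 residual = max(abs(lhigp_rhs(x_full, p))),
                 eigenvalues = ev,
                 stable = all(Re(ev) < 0),
                 class = classify_equilibrium(x_full, presence_tol),
                 converged = TRUE),
            class = "lhigp_equilibrium")
}

#' @export
print.lhigp_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (%s), residual %.2e\n", x$class,
              if (x$stable) "stable" else "unstable", x$residual))
  cat("  state:", paste(sprintf("%s = %.6g", state_names, x$state),
                        collapse = ", "), "\n")
  cat("  leading eigenvalue:", format(x$eigenvalues[1], digits = 6), "\n")
  invisible(x)
}

# Solve the reduced system with selected components in log space, by
# Levenberg-Marquardt least squares: near a transcritical the interior root
# has a near-singular Jacobian and a thin Newton basin (plain iteration
# slides onto the boundary sheet, where x = 0 trivially solves its own
# equation); log coordinates exclude the boundary and LM damping handles
# the ill-conditioning.  Returns an lhigp_equilibrium or NULL.
solve_equilibrium_log <- function(guess, p, absent = character(),
                                  log_comps, tol = 1e-10) {
  if ("P" %in% absent) absent <- union(setdiff(absent, "P"), c("Pj", "Pa"))
  x_full <- unlist(guess)[state_names]
  x_full[absent] <- 0
  free <- setdiff(state_names, absent)
  log_comps <- intersect(log_comps, free)
  if (any(x_full[log_comps] <= 0)) return(NULL)
  to_x <- function(u) {
    x <- u
    x[log_comps] <- exp(u[log_comps])
    x
  }
  f_red <- function(u) {
    x_full[free] <- to_x(u)
    lhigp_rhs(x_full, p)[free]
  }
  u0 <- x_full[free]
  u0[log_comps] <- log(u0[log_comps])
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = u0, fn = f_red,
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 20000,
                                           ftol = 1e-18, ptol = 1e-15))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  u <- fit$par
  xf <- to_x(u)
  if (any(!is.finite(xf)) || any(xf < 0) || any(xf[log_comps] < 1e-13))
    return(NULL)
  # LM creeps near the singular point; a plain Newton polish from its
  # endpoint converges quadratically once inside the basin
  x_try <- x_full
  x_try[free] <- xf
  polished <- tryCatch(solve_equilibrium(x_try, p, absent = absent, tol = tol),
                       error = function(e) NULL)
  if (!is.null(polished) && all(polished$state[log_comps] > 1e-13))
    return(polished)
  if (max(abs(f_red(u))) >= 1e-8) return(NULL)
  x_full[free] <- xf
  ev <- jacobian_eigenvalues(x_full, p)
  structure(list(state = x_full, params = p,
                 residual = max(abs(lhigp_rhs(x_full, p))),
                 eigenvalues = ev,
                 stable = all(Re(ev) < 0),
                 class = classify_equilibrium(x_full),
                 converged = TRUE),
            class = "lhigp_equilibrium")
}

#' Closed-form consumer-resource equilibrium
#'
#' At the CR equilibrium the consumer's net production balances its
#' mortality, giving the resource density
#' \deqn{R^* = \frac{T_c + \mu_c}{a_{cr}(\sigma - h_c (T_c + \mu_c))},}
#' and the resource balance \eqn{\delta(R_{max} - R^*) = I_c(R^*)\, C^*}
#' gives the consumer density.  Used as an analytic oracle for the numeric
#' solver and as the environment for predator-invasion questions.
#'
#' @param p An [lhigp_params()] object.
#' @return Named vector `(R, C, Pj, Pa)` with `Pj = Pa = 0`, or an error if
#'   the consumer cannot persist (`sigma <= h_c (T_c + mu_c)` or
#'   `R* >= R_max`).
#' @export
cr_equilibrium_closed_form <- function(p) {
  denom <- p$sigma - p$h_c * (p$T_c + p$mu_c)
  if (denom <= 0 || p$a_cr <= 0)
    stop("consumer cannot persist at any resource density")
  R <- (p$T_c + p$mu_c) / (p$a_cr * denom)
  if (R >= p$R_max)
    stop("consumer cannot persist: required resource density exceeds R_max")
  I_c <- p$a_cr * R / (1 + p$h_c * p$a_cr * R)
  C <- p$delta * (p$R_max - R) / I_c
  c(R = R, C = C, Pj = 0, Pa = 0)
}
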