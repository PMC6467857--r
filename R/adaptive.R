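#' Invasion fitness of a mutant trait as lifetime reproductive success
#'
#' Expected lifetime reproductive success \eqn{R_0(y', y)} of a rare mutant
#' with juvenile resource attack rate `mutant_a_jr` in the environment set by
#' the resident equilibrium.  The mutant's adult predation attack rate
#' follows from the ontogenetic trade-off; its juveniles suffer cannibalistic
#' mortality from the *resident* adults (resident attack rate and resident
#' functional-response denominator), and its adults feed on the resident
#' resource, consumers and (discounted by `beta`) resident juveniles.
#'
#' With exponential juvenile size growth from relative size `z` to 1 at rate
#' \eqn{\nu_j'} under mortality \eqn{D_j'}, survival to maturation is
#' \eqn{z^{D_j'/\nu_j'}}; an adult lives \eqn{1/\mu_p} on average and turns
#' net production \eqn{\nu_a'^{+}} into offspring of relative size `z`, so
#' \deqn{R_0 = z^{\,D_j'/\nu_j' - 1}\; \frac{\nu_a'^{+}}{\mu_p}}
#' for \eqn{\nu_j' > 0} and \eqn{R_0 = 0} otherwise (starving juveniles
#' never mature).  This closed form is exactly consistent with the
#' stage-structured maturation function: `R0 = 1` reproduces the equilibrium
#' condition of the resident, and the root of `R0 = 1` in a parameter
#' coincides with the Jacobian-based invasion boundary.
#'
#' @param mutant_a_jr Mutant trait value, in `[0, a_p]`.
#' @param resident_eq Resident equilibrium ([solve_equilibrium()]); must be
#'   solved, with any species composition (a CR equilibrium poses the
#'   invasion-from-zero question).
#' @param p Parameters of the resident; taken from `resident_eq` when
#'   omitted.
#' @return The dimensionless lifetime reproductive success; invasion
#'   succeeds when `R0 > 1`.
#' @export
#' @examples
#' p <- default_parameters(a_jr = 3, a_ar = 0, beta = 0)
#' cr <- solve_equilibrium(cr_equilibrium_closed_form(p), p, absent = "P")
#' invasion_fitness_R0(4, cr)   # mutant with higher juvenile specialization
invasion_fitness_R0 <- function(mutant_a_jr, resident_eq, p = NULL) {
  stopifnot(inherits(resident_eq, "lhigp_equilibrium"))
  if (is.null(p)) p <- resident_eq$params
  if (mutant_a_jr < 0 || mutant_a_jr > p$a_p)
    stop("mutant trait outside [0, a_p]")
  s <- resident_eq$state
  res <- model_rates(s, p)            # resident rates set the environment
  a_ac_mut <- tradeoff_adult_attack(mutant_a_jr, p$a_p, p$epsilon)
  # mutant juvenile: feeds on resident resource, dies to resident adults
  I_j <- mutant_a_jr * s[["R"]] / (1 + p$h_p * mutant_a_jr * s[["R"]])
  nu_j <- p$sigma * I_j - p$T_p
  if (nu_j <= 0) return(0)
  D_j <- res$D_j                       # resident a_ac, resident denominator
  # mutant adult: own attack rates, resident prey field
  enc_a <- p$a_ar * s[["R"]] + a_ac_mut * (s[["C"]] + p$beta * s[["Pj"]])
  nu_a <- p$sigma * enc_a / (1 + p$h_p * enc_a) - p$T_p
  z_pow <- p$z^(D_j / nu_j - 1)
  z_pow * max(nu_a, 0) / p$mu_p
}

#' Selection gradient on juvenile resource specialization
#'
#' Central finite difference of [invasion_fitness_R0()] in the mutant trait,
#' evaluated at the resident's trait value.  Its sign gives the direction of
#' gradual evolution of `a_jr`.
#'
#' @param resident_eq Resident equilibrium with predators present.
#' @param p Parameters; taken from `resident_eq` when omitted.
#' @param step Finite-difference step (default `1e-6 * a_p`).
#' @return The derivative \eqn{\partial R_0 / \partial y'} at
#'   \eqn{y' = y}.  When the resident sits within two steps of a trait
#'   bound, a one-sided difference is used and the result carries attribute
#'   `one_sided = TRUE`.
#' @export
selection_gradient <- function(resident_eq, p = NULL, step = NULL) {
  stopifnot(inherits(resident_eq, "lhigp_equilibrium"))
  if (is.null(p)) p <- resident_eq$params
  if (!resident_eq$class %in% c("PR", "PCR"))
    stop("resident equilibrium must have predators present")
  if (is.null(step)) step <- 1e-6 * p$a_p
  y <- p$a_jr
  if (y - 2 * step < 0) {
    g <- (invasion_fitness_R0(y + step, resident_eq, p) -
            invasion_fitness_R0(y, resident_eq, p)) / step
    attr(g, "one_sided") <- TRUE
  } else if (y + 2 * step > p$a_p) {
    g <- (invasion_fitness_R0(y, resident_eq, p) -
            invasion_fitness_R0(y - step, resident_eq, p)) / step
    attr(g, "one_sided") <- TRUE
  } else {
    g <- (invasion_fitness_R0(y + step, resident_eq, p) -
            invasion_fitness_R0(y - step, resident_eq, p)) / (2 * step)
  }
  g
}

# resident equilibrium at trait y on a fixed species composition,
# warm-started from `guess`
resident_at_trait <- function(y, p, guess, free) {
  solve_on_branch(y, "a_jr", p, guess, free)
}

#' Locate an evolutionary singular strategy
#'
#' Finds a root of the selection gradient in the trait `a_jr` over
#' `trait_bracket`, re-solving the resident equilibrium (of the species
#' composition of `eq0`) at every trial trait value, and classifies it via
#' [classify_singular_strategy()].
#'
#' @param eq0 A stable resident equilibrium with predators present, solved
#'   at some trait inside the bracket; used as warm start and to fix the
#'   species composition.
#' @param trait_bracket Length-2 interval in which to search.
#' @param p Parameters; taken from `eq0` when omitted.
#' @param tol Trait tolerance of the root.
#' @return An object of class `lhigp_singular_strategy`: list with `a_jr`
#'   (the singular trait value), `equilibrium` (resident at the strategy),
#'   `gradient` (residual gradient), `convergence_stable`,
#'   `evolutionarily_stable`, `degenerate` flags and `d2_mutant`,
#'   `d_gradient` (the classifying second derivatives).  When the gradient
#'   does not change sign over the bracket, a list with
#'   `status = "none_found"` and the gradient at both ends is returned
#'   instead (not an error).  If the resident branch loses stability inside
#'   the bracket, an error names the trait value where it does.
#' @export
find_singular_strategy <- function(eq0, trait_bracket, p = NULL,
                                   tol = 1e-8) {
  stopifnot(inherits(eq0, "lhigp_equilibrium"))
  if (is.null(p)) p <- eq0$params
  free <- c("R", intersect(c("C", "Pj", "Pa"), state_names[eq0$state > 1e-8]))
  if (!any(c("Pj", "Pa") %in% free))
    stop("resident equilibrium must have predators present")
  guess_env <- new.env(); assign("g", eq0$state, envir = guess_env)
  grad_at <- function(y) {
    eq <- resident_at_trait(y, p, get("g", envir = guess_env), free)
    assign("g", eq$state, envir = guess_env)
    if (!eq$stable)
      stop("resident branch loses stability at a_jr = ", signif(y, 8))
    selection_gradient(eq, set_param1(p, "a_jr", y))
  }
  g_lo <- grad_at(trait_bracket[1])
  g_hi <- grad_at(trait_bracket[2])
  if (sign(g_lo) == sign(g_hi)) {
    return(list(status = "none_found", gradient_lo = as.numeric(g_lo),
                gradient_hi = as.numeric(g_hi), bracket = trait_bracket))
  }
  root <- stats::uniroot(function(y) as.numeric(grad_at(y)),
                         interval = trait_bracket, tol = tol)
  y_star <- root$root
  eq_star <- resident_at_trait(y_star, p, get("g", envir = guess_env), free)
  p_star <- set_param1(p, "a_jr", y_star)
  cls <- classify_singular_strategy(y_star, eq_star, p_star, free)
  structure(c(list(status = "found", a_jr = y_star, equilibrium = eq_star,
                   gradient = root$f.root), cls),
            class = "lhigp_singular_strategy")
}

#' @export
print.lhigp_singular_strategy <- function(x, ...) {
  cat(sprintf("singular strategy at a_jr = %.6f (%s equilibrium)\n",
              x$a_jr, x$equilibrium$class))
  cat(sprintf("  convergence stable: %s; evolutionarily stable: %s%s\n",
              x$convergence_stable, x$evolutionarily_stable,
              if (isTRUE(x$degenerate)) " (degenerate: near noise floor)" else ""))
  invisible(x)
}

#' Classify a singular strategy
#'
#' Evolutionary stability from the curvature of the mutant fitness landscape
#' \eqn{\partial^2 R_0 / \partial y'^2} at the singular strategy (negative:
#' no nearby mutant invades, evolutionarily stable); convergence stability
#' from the slope of the selection gradient along the resident branch
#' (negative: gradual evolution approaches the strategy).  A CSS is both.
#'
#' @param y_star Singular trait value.
#' @param eq_star Resident equilibrium at `y_star`.
#' @param p Parameters with `a_jr = y_star`.
#' @param free Species composition of the resident branch (internal).
#' @param step_mut Step for the mutant second derivative (default
#'   `1e-4 * a_p`).
#' @param step_res Step for the gradient slope along the branch (default
#'   `1e-4 * a_p`).
#' @param noise_floor Magnitudes below this are flagged `degenerate` rather
#'   than silently classified.
#' @return List with `convergence_stable`, `evolutionarily_stable`,
#'   `degenerate`, `d2_mutant` and `d_gradient`.
#' @export
classify_singular_strategy <- function(y_star, eq_star, p,
                                       free = NULL,
                                       step_mut = NULL, step_res = NULL,
                                       noise_floor = 1e-7) {
  if (is.null(free))
    free <- c("R", intersect(c("C", "Pj", "Pa"),
                             state_names[eq_star$state > 1e-8]))
  if (is.null(step_mut)) step_mut <- 1e-4 * p$a_p
  if (is.null(step_res)) step_res <- 1e-4 * p$a_p
  # mutant curvature at fixed resident environment
  f <- function(ym) invasion_fitness_R0(ym, eq_star, p)
  d2 <- (f(y_star + step_mut) - 2 * f(y_star) + f(y_star - step_mut)) /
    step_mut^2
  # gradient slope along the resident branch
  g_at <- function(y) {
    eq <- resident_at_trait(y, p, eq_star$state, free)
    as.numeric(selection_gradient(eq, set_param1(p, "a_jr", y)))
  }
  dg <- (g_at(y_star + step_res) - g_at(y_star - step_res)) / (2 * step_res)
  list(convergence_stable = dg < 0,
       evolutionarily_stable = d2 < 0,
       degenerate = abs(d2) < noise_floor || abs(dg) < noise_floor,
       d2_mutant = d2, d_gradient = dg)
}

#' Trait-substitution trajectory of juvenile resource specialization
#'
#' Deterministic gradient-sign stepping of the resident trait: at each step
#' the trait moves by `eta` in the direction of the selection gradient and
#' the resident equilibrium is re-solved by warm-started Newton from the
#' previous one.  The step is halved when the gradient changes sign
#' (approach to a singular strategy).  If the resident equilibrium
#' disappears (fold) or loses stability, the community dynamics are run from
#' the last pre-collapse state ([find_attractor()]) to identify the
#' post-transition attractor; predator absence there is evolutionary
#' suicide.
#'
#' @param y0 Initial trait value; a stable predator equilibrium must exist
#'   there (found from `state0` or multi-start if not supplied).
#' @param p Parameters (the `a_jr` field is overridden by the trajectory).
#' @param state0 Optional initial state used to locate the starting resident
#'   equilibrium.
#' @param eta Trait step size (default `0.01 * a_p`).
#' @param eta_min Minimum step; at `eta_min` an oscillating gradient sign
#'   terminates the trajectory as a singular strategy, a still-oscillating
#'   one as `undecided`.
#' @param grad_tol Gradient magnitude treated as zero (singular strategy).
#' @param max_steps Step cap.
#' @return An object of class `lhigp_trait_trajectory`: list with `steps`
#'   (data frame `step, a_jr, a_ac, class, R, C, Pj, Pa, gradient`),
#'   `status` (`"singular_strategy"`, `"boundary_ap"`,
#'   `"fold_crossed_extinction"`, or `"undecided"`), `final_trait`,
#'   `post_collapse` (attractor report after a collapse, else `NULL`) and
#'   `singular` (classified strategy when one is reached).
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
#' tj <- trait_trajectory(4.5, p)
#' tj$status  # evolutionary suicide: "fold_crossed_extinction"
#' }
trait_trajectory <- function(y0, p, state0 = NULL, eta = NULL,
                             eta_min = NULL, grad_tol = 1e-6,
                             max_steps = 2000) {
  if (is.null(eta)) eta <- 0.01 * p$a_p
  if (is.null(eta_min)) eta_min <- eta / 64
  p <- set_param1(p, "a_jr", y0)
  eq <- NULL
  if (!is.null(state0)) {
    at <- find_attractor(state0, p)
    if (at$status == "equilibrium" && at$class %in% c("PR", "PCR"))
      eq <- at$equilibrium
  } else {
    cand <- stable_classes(p, seed = 1)
    for (cls in c("PCR", "PR")) if (cls %in% names(cand)) {
      eq <- cand[[cls]]; break
    }
  }
  if (is.null(eq))
    stop("no stable predator equilibrium at y0 = ", y0)
  free <- c("R", intersect(c("C", "Pj", "Pa"), state_names[eq$state > 1e-8]))

  steps <- list()
  y <- y0
  g_prev <- NA_real_
  status <- "undecided"
  post_collapse <- NULL
  singular <- NULL
  for (k in seq_len(max_steps)) {
    g <- as.numeric(selection_gradient(eq, p))
    steps[[k]] <- data.frame(step = k - 1L, a_jr = y,
                             a_ac = tradeoff_adult_attack(y, p$a_p, p$epsilon),
                             class = eq$class, R = eq$state[["R"]],
                             C = eq$state[["C"]], Pj = eq$state[["Pj"]],
                             Pa = eq$state[["Pa"]], gradient = g)
    if (abs(g) < grad_tol) { status <- "singular_strategy"; break }
    if (!is.na(g_prev) && sign(g) != sign(g_prev)) {
      if (eta <= eta_min) { status <- "singular_strategy"; break }
      eta <- eta / 2
    }
    g_prev <- g
    y_new <- min(max(y + eta * sign(g), 0), p$a_p)
    if (y_new == y) { status <- "boundary_ap"; break }
    p_new <- set_param1(p, "a_jr", y_new)
    eq_new <- tryCatch(solve_equilibrium(eq$state, p_new,
                                         absent = setdiff(c("C", "Pj", "Pa"), free)),
                       error = function(e) NULL)
    if (!is.null(eq_new) && any(eq_new$state[free] <= 1e-8)) {
      # a component of the resident composition vanished: either a genuine
      # transcritical handoff (the boundary equilibrium is stable) or Newton
      # slid onto the boundary sheet while the true resident retains a tiny
      # density (boundary state invasible by the vanished species)
      if (eq_new$stable && eq_new$class %in% c("PR", "PCR")) {
        eq <- eq_new
        free <- c("R", intersect(c("C", "Pj", "Pa"),
                                 state_names[eq$state > 1e-8]))
        y <- y_new; p <- p_new
        next
      }
      vanished <- free[eq_new$state[free] <= 1e-8]
      retried <- NULL
      for (fac in c(1, 0.25, 0.05, 0.01)) {
        g <- eq$state
        g[vanished] <- pmax(eq$state[vanished] * fac, 1e-5)
        cand <- solve_equilibrium_log(g, p_new,
                                      absent = setdiff(c("C", "Pj", "Pa"), free),
                                      log_comps = vanished)
        if (!is.null(cand) && near_stable(cand) &&
            all(cand$state[free] > 1e-8)) { retried <- cand; break }
      }
      if (!is.null(retried)) {
        eq <- retried; y <- y_new; p <- p_new
        next
      }
      at <- find_attractor(perturb_state_raw(eq$state, free), p_new)
      if (at$status == "equilibrium" && at$class %in% c("PR", "PCR")) {
        eq <- at$equilibrium
        free <- c("R", intersect(c("C", "Pj", "Pa"),
                                 state_names[eq$state > 1e-8]))
        y <- y_new; p <- p_new
        next
      }
      status <- "fold_crossed_extinction"
      post_collapse <- at
      y <- y_new; p <- p_new
      break
    }
    if (!is.null(eq_new) && !eq_new$stable) {
      # distinguish a weak internal oscillatory instability (small-amplitude
      # cycles around the equilibrium, which still carry the resident
      # environment) from a genuine destabilization
      absent_sp <- c(if (!"C" %in% free) "C",
                     if (!"Pj" %in% free) "P")
      inv_pos <- length(absent_sp) &&
        any(vapply(absent_sp, function(sp)
          invasion_growth_rate(eq_new$state, p_new, sp), numeric(1)) > 0)
      lead <- eq_new$eigenvalues[1]
      if (!inv_pos && (Im(lead) != 0 || Re(lead) < 1e-3)) {
        # weak oscillatory instability (small-amplitude cycles) or a
        # near-neutral direction within finite-difference noise: the
        # equilibrium still carries the resident environment
        eq <- eq_new; y <- y_new; p <- p_new
        next
      }
      # absent species invades (attractor switch) or a real unstable
      # direction opened: run the dynamics, seeding any invader
      s0 <- perturb_state_raw(eq_new$state, free)
      if (inv_pos) {
        inv_comp <- setdiff(state_names[-1], free)
        s0[inv_comp] <- 1e-6
      }
      at <- find_attractor(s0, p_new)
      if (at$status == "equilibrium" && at$class %in% c("PR", "PCR")) {
        eq <- at$equilibrium
        free <- c("R", intersect(c("C", "Pj", "Pa"),
                                 state_names[eq$state > 1e-8]))
        y <- y_new; p <- p_new
        next
      }
      status <- "fold_crossed_extinction"
      post_collapse <- at
      y <- y_new; p <- p_new
      break
    }
    if (is.null(eq_new)) {
      # plain Newton failed: near a transcritical the interior root may
      # still exist with a tiny density; log-space iteration finds it or
      # certifies there is none (a genuine fold)
      sp <- setdiff(free, "R")
      sets <- c(as.list(sp[order(eq$state[sp])]), list(sp))
      cand <- NULL
      for (lc in sets) {
        cand <- solve_equilibrium_log(eq$state, p_new,
                                      absent = setdiff(c("C", "Pj", "Pa"), free),
                                      log_comps = lc)
        if (!is.null(cand) && near_stable(cand) && all(cand$state[free] > 1e-8))
          break
        cand <- NULL
      }
      if (!is.null(cand)) {
        eq <- cand; y <- y_new; p <- p_new
        next
      }
      # the equilibrium vanished (fold): the dynamics decide what remains
      at <- find_attractor(perturb_state_raw(eq$state, free), p_new)
      if (at$status == "equilibrium" && at$class %in% c("PR", "PCR")) {
        eq <- at$equilibrium
        free <- c("R", intersect(c("C", "Pj", "Pa"),
                                 state_names[eq$state > 1e-8]))
        y <- y_new; p <- p_new
        next
      }
      status <- "fold_crossed_extinction"
      post_collapse <- at
      y <- y_new; p <- p_new
      break
    }
    eq <- eq_new; y <- y_new; p <- p_new
    if (y >= p$a_p) { status <- "boundary_ap"; break }
  }
  if (status == "singular_strategy") {
    singular <- tryCatch(
      classify_singular_strategy(y, eq, p), error = function(e) NULL)
  }
  structure(list(steps = do.call(rbind, steps), status = status,
                 final_trait = y, post_collapse = post_collapse,
                 singular = singular, params = p),
            class = "lhigp_trait_trajectory")
}

# stability up to a near-neutral tolerance: leading eigenvalues within
# finite-difference noise of zero (|Re| < 1e-3) count as stable when judging
# whether an equilibrium can carry the resident environment
near_stable <- function(eq, tol = 1e-3) all(Re(eq$eigenvalues) < tol)

# tiny deterministic nudge off the equilibrium so the dynamics can leave an
# unstable state (absent species stay absent)
perturb_state_raw <- function(state, free) {
  s <- state
  s[free] <- s[free] * 1.01 + 1e-8
  s
}

#' @export
print.lhigp_trait_trajectory <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf("trait trajectory: %d steps, a_jr %.4f -> %.4f, status %s\n",
              n, x$steps$a_jr[1], x$final_trait, x$status))
  if (!is.null(x$post_collapse))
    cat("  post-collapse attractor:", x$post_collapse$status,
        x$post_collapse$class, "\n")
  invisible(x)
}

#' Export a trait trajectory as CSV
#'
#' @param x An `lhigp_trait_trajectory`.
#' @param path CSV destination; columns `step, a_jr, a_ac, class, R, C, Pj,
#'   Pa, gradient` plus a `status` column repeated on every row.
#' @return `path`, invisibly.
#' @export
write_trait_trajectory <- function(x, path) {
  stopifnot(inherits(x, "lhigp_trait_trajectory"))
  df <- x$steps
  df$status <- x$status
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
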