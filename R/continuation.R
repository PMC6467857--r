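sweepable_params <- c("a_jr", "beta", "R_max", "a_ar", "epsilon")

# replace one named parameter, revalidating
set_param1 <- function(p, param, value) {
  do.call(set_params, c(list(p), stats::setNames(list(value), param)))
}

# solve the reduced system at a fixed parameter value, warm-started; `free`
# fixes the branch's species composition (absent components pinned at 0)
solve_on_branch <- function(q, param, p, guess, free, tol = 1e-10) {
  p2 <- set_param1(p, param, q)
  absent <- setdiff(c("C", "Pj", "Pa"), free)
  solve_equilibrium(guess, p2, absent = absent, tol = tol)
}

#' Continue an equilibrium branch in one parameter
#'
#' Follows the equilibrium of a fixed species composition (that of `eq0`)
#' through parameter space by secant-predictor / Newton-corrector
#' continuation in the combined (state, parameter) space, which carries the
#' branch around folds.  When the swept parameter is `a_jr`, the adult
#' predation attack rate is re-derived from the ontogenetic trade-off at
#' every step.
#'
#' Three kinds of events are monitored between consecutive accepted points
#' and refined to a parameter tolerance of about `1e-6`:
#' * **fold** — the branch turns in the parameter (the secant tangent's
#'   parameter component changes sign); refined by re-parameterizing the
#'   branch locally by its fastest-moving state coordinate and extremizing
#'   the parameter along it.  At the refined fold one Jacobian eigenvalue
#'   of the reduced system vanishes.
#' * **invasion boundary** — the invasion growth rate of an absent species
#'   ([invasion_growth_rate()]) changes sign; refined by bisection in the
#'   parameter with warm-started solves.
#' * **component exit** — a present species' density reaches zero (the
#'   branch connects to a lower-dimensional one, e.g. PCR to PR when the
#'   consumer is starved out); refined by bisection, then the branch is
#'   truncated.
#'
#' @param eq0 Starting equilibrium ([solve_equilibrium()]), solved at
#'   `range[1]`.
#' @param param Parameter to sweep: one of `a_jr`, `beta`, `R_max`, `a_ar`,
#'   `epsilon`.
#' @param range Length-2 numeric: sweep interval (continuation starts at
#'   `range[1]` and heads toward `range[2]`; after a fold it may return to
#'   `range[1]`).
#' @param h0,h_max,h_min Initial, maximum and minimum continuation step
#'   (arclength in combined space).
#' @param max_points Safety cap on the number of accepted points.
#' @param presence_tol Density regarded as zero.
#' @return An object of class `lhigp_branch`: list with `points` (data frame
#'   `param, R, C, Pj, Pa, class, stable, leading_eigenvalue_re`),
#'   `bifurcations` (list of records with `kind`, `param_value`, `state`,
#'   `species`), `param`, `composition` and `termination` (one of
#'   `"range_end"`, `"component_exit"`, `"step_collapse"`, `"max_points"`).
#' @export
#' @examples
#' p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
#' eq <- solve_equilibrium(c(R = 0.54, C = 0.67, Pj = 0.07, Pa = 0.55), p)
#' br <- continue_branch(eq, "a_jr", c(4.5, 6), h0 = 0.05)
#' vapply(br$bifurcations, `[[`, "", "kind")
continue_branch <- function(eq0, param, range, h0 = 0.02, h_max = 0.1,
                            h_min = 1e-8, max_points = 2000,
                            presence_tol = 1e-8) {
  stopifnot(inherits(eq0, "lhigp_equilibrium"), param %in% sweepable_params,
            length(range) == 2, range[1] != range[2])
  p <- eq0$params
  if (abs(p[[param]] - range[1]) > 1e-8)
    stop("eq0 must be solved at range[1] of the swept parameter")
  dir <- sign(range[2] - range[1])
  lo <- min(range); hi <- max(range)
  free <- c("R", intersect(c("C", "Pj", "Pa"),
                           state_names[eq0$state > presence_tol]))
  absent <- setdiff(c("C", "Pj", "Pa"), free)
  absent_species <- c(if ("C" %in% absent) "C",
                      if ("Pj" %in% absent) "P")
  n_unknown <- length(free) + 1L

  as_full <- function(u) {
    x <- stats::setNames(numeric(4), state_names)
    x[free] <- u
    x
  }
  record <- function(eq, q) {
    data.frame(param = q, R = eq$state[["R"]], C = eq$state[["C"]],
               Pj = eq$state[["Pj"]], Pa = eq$state[["Pa"]],
               class = eq$class, stable = eq$stable,
               leading_eigenvalue_re = Re(eq$eigenvalues[1]))
  }
  inv_growth <- function(eq, q) {
    p2 <- set_param1(p, param, q)
    vapply(absent_species, function(sp)
      invasion_growth_rate(eq$state, p2, sp), numeric(1))
  }

  # hard domain bounds of the swept parameter (the trade-off is undefined
  # for a_jr outside [0, a_p]; Newton iterates must not wander there)
  dom <- switch(param,
                a_jr = c(0, p$a_p),
                epsilon = c(-1 + 1e-9, Inf),
                c(0, Inf))
  q_min <- max(lo, dom[1]); q_max <- min(hi, dom[2])

  # pseudo-arclength corrector: Newton on [rhs_free; tangent.(w - w_pred)]
  corrector <- function(w_pred, tangent) {
    wk <- w_pred
    Fof <- function(wv) {
      p2 <- set_param1(p, param, wv[n_unknown])
      c(lhigp_rhs(as_full(wv[-n_unknown]), p2)[free],
        sum(tangent * (wv - w_pred)))
    }
    for (iter in 1:30) {
      wk[n_unknown] <- min(max(wk[n_unknown], q_min), q_max)
      Fv <- tryCatch(Fof(wk), error = function(e) NULL)
      if (is.null(Fv)) return(NULL)
      if (max(abs(Fv)) < 1e-10) return(wk)
      J <- matrix(0, n_unknown, n_unknown)
      ok <- tryCatch({
        for (j in seq_len(n_unknown)) {
          hh <- 1e-7 * (1 + abs(wk[j]))
          wp <- wk; wp[j] <- min(wk[j] + hh, if (j == n_unknown) q_max else Inf)
          wm <- wk; wm[j] <- max(wk[j] - hh, if (j == n_unknown) q_min else -Inf)
          J[, j] <- (Fof(wp) - Fof(wm)) / (wp[j] - wm[j])
        }
        TRUE
      }, error = function(e) FALSE)
      if (!ok) return(NULL)
      step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      wk <- wk + step
      if (any(!is.finite(wk))) return(NULL)
    }
    NULL
  }

  # --- event refiners ------------------------------------------------------
  refine_invasion <- function(q_a, q_b, g_a, g_b, guess, species) {
    for (it in 1:60) {
      if (abs(q_b - q_a) < 1e-7) break
      q_m <- (q_a + q_b) / 2
      eq_m <- tryCatch(solve_on_branch(q_m, param, p, guess, free),
                       error = function(e) NULL)
      if (is.null(eq_m)) break
      g_m <- invasion_growth_rate(eq_m$state, set_param1(p, param, q_m),
                                  species)
      guess <- eq_m$state
      if (sign(g_m) == sign(g_a)) { q_a <- q_m; g_a <- g_m }
      else { q_b <- q_m; g_b <- g_m }
    }
    eq_b <- tryCatch(solve_on_branch((q_a + q_b) / 2, param, p, guess, free),
                     error = function(e) NULL)
    list(kind = "invasion_boundary", param_value = (q_a + q_b) / 2,
         state = if (!is.null(eq_b)) eq_b$state else as_full(guess[free]),
         species = species)
  }

  refine_component_exit <- function(q_a, q_b, guess, species) {
    # bisect on the exiting component's density along the branch
    dens <- function(q) {
      eq <- tryCatch(solve_on_branch(q, param, p, guess, free, tol = 1e-9),
                     error = function(e) NULL)
      if (is.null(eq)) return(NULL)
      guess <<- eq$state
      eq$state[[species]]
    }
    d_a <- dens(q_a)
    for (it in 1:60) {
      if (abs(q_b - q_a) < 1e-7) break
      q_m <- (q_a + q_b) / 2
      d_m <- dens(q_m)
      if (is.null(d_m) || d_m <= presence_tol) q_b <- q_m
      else q_a <- q_m
    }
    list(kind = "invasion_boundary", param_value = (q_a + q_b) / 2,
         state = as_full(guess[free]), species = species)
  }

  refine_fold <- function(i_lo, i_hi) {
    # re-parameterize by the state coordinate moving fastest across the fold
    u_lo <- eqs[[i_lo]]$state[free]; u_hi <- eqs[[i_hi]]$state[free]
    k <- free[which.max(abs(u_hi - u_lo))]
    others <- setdiff(free, k)
    guess_env <- new.env()
    assign("g", c(eqs[[i_lo]]$state[others], qs[i_lo]), envir = guess_env)
    q_of <- function(xk) {
      # solve rhs_free = 0 with component k pinned at xk; unknowns (others, q)
      wk <- get("g", envir = guess_env)
      Fof <- function(wv) {
        p2 <- set_param1(p, param, wv[length(wv)])
        x <- as_full(numeric(length(free)))
        x[others] <- wv[-length(wv)]
        x[k] <- xk
        lhigp_rhs(x, p2)[free]
      }
      for (iter in 1:30) {
        Fv <- tryCatch(Fof(wk), error = function(e) NULL)
        if (is.null(Fv)) return(NA_real_)
        if (max(abs(Fv)) < 1e-10) break
        J <- matrix(0, length(wk), length(wk))
        ok <- tryCatch({
          for (j in seq_along(wk)) {
            hh <- 1e-7 * (1 + abs(wk[j]))
            wp <- wk; wp[j] <- wk[j] + hh
            wm <- wk; wm[j] <- wk[j] - hh
            J[, j] <- (Fof(wp) - Fof(wm)) / (2 * hh)
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok) return(NA_real_)
        step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
        if (is.null(step)) return(NA_real_)
        wk <- wk + step
      }
      assign("g", wk, envir = guess_env)
      wk[length(wk)]
    }
    xk_lo <- u_lo[[k]]; xk_hi <- u_hi[[k]]
    # the parameter is extremal at the fold
    q_mid <- q_of((xk_lo + xk_hi) / 2)
    maximize <- !is.na(q_mid) && q_mid >= max(qs[i_lo], qs[i_hi])
    opt <- stats::optimize(q_of, interval = sort(c(xk_lo, xk_hi)),
                           maximum = maximize, tol = 1e-9)
    xk_star <- if (maximize) opt$maximum else opt$minimum
    q_star <- if (maximize) opt$objective else opt$objective
    wk <- get("g", envir = guess_env)
    x_star <- as_full(numeric(length(free)))
    x_star[others] <- wk[-length(wk)]
    x_star[k] <- xk_star
    list(kind = "fold", param_value = q_star, state = x_star, species = NULL)
  }

  check_events <- function(i) {
    # called after accepting point i; compares i-1 vs i (and i-2 for folds)
    g_prev <- invs[[i - 1]]; g_cur <- invs[[i]]
    for (sp in absent_species) {
      if (!is.na(g_prev[sp]) && !is.na(g_cur[sp]) &&
          sign(g_prev[sp]) * sign(g_cur[sp]) < 0) {
        bifs[[length(bifs) + 1]] <<- refine_invasion(
          qs[i - 1], qs[i], g_prev[sp], g_cur[sp], eqs[[i - 1]]$state, sp)
      }
    }
    if (i >= 3) {
      dq1 <- qs[i - 1] - qs[i - 2]
      dq2 <- qs[i] - qs[i - 1]
      if (dq1 * dq2 < 0)
        bifs[[length(bifs) + 1]] <<- refine_fold(i - 2, i)
    }
  }
  # ------------------------------------------------------------------------

  eqs <- list(eq0)
  qs <- range[1]
  invs <- list(inv_growth(eq0, range[1]))
  pts <- record(eq0, range[1])
  bifs <- list()
  termination <- "max_points"

  # second point by a small fixed-parameter step
  h <- h0
  q1 <- range[1] + dir * min(h, abs(range[2] - range[1]) / 2)
  eq1 <- tryCatch(solve_on_branch(q1, param, p, eq0$state, free),
                  error = function(e) NULL)
  if (is.null(eq1) || any(eq1$state[free] <= presence_tol)) {
    return(structure(list(points = pts, bifurcations = bifs, param = param,
                          composition = free, termination = "step_collapse"),
                     class = "lhigp_branch"))
  }
  eqs[[2]] <- eq1; qs[2] <- q1
  invs[[2]] <- inv_growth(eq1, q1)
  pts <- rbind(pts, record(eq1, q1))
  check_events(2)

  i <- 2L
  while (i < max_points) {
    w_prev <- c(unname(eqs[[i - 1]]$state[free]), qs[i - 1])
    w_cur <- c(unname(eqs[[i]]$state[free]), qs[i])
    tangent <- (w_cur - w_prev) / sqrt(sum((w_cur - w_prev)^2))
    # predictor leaving the sweep range: finish with a fixed-parameter
    # solve exactly at the boundary instead of creeping toward it
    q_pred <- w_cur[n_unknown] + h * tangent[n_unknown]
    if (q_pred > hi - 1e-9 || q_pred < lo + 1e-9) {
      q_end <- if (q_pred > hi - 1e-9) hi else lo
      eq_end <- tryCatch(solve_on_branch(q_end, param, p,
                                         as_full(w_cur[-n_unknown]), free),
                         error = function(e) NULL)
      if (!is.null(eq_end) && all(eq_end$state[free] > presence_tol)) {
        i <- i + 1L
        eqs[[i]] <- eq_end; qs[i] <- q_end
        invs[[i]] <- inv_growth(eq_end, q_end)
        pts <- rbind(pts, record(eq_end, q_end))
        check_events(i)
        termination <- "range_end"
        break
      }
    }
    accepted <- FALSE
    while (!accepted && h >= h_min) {
      w_new <- corrector(w_cur + h * tangent, tangent)
      if (!is.null(w_new) && all(w_new[-n_unknown] > -1e-6)) accepted <- TRUE
      else h <- h / 2
    }
    if (!accepted) { termination <- "step_collapse"; break }
    q_new <- w_new[n_unknown]
    guess <- as_full(pmax(w_new[-n_unknown], 0))

    # range end: clamp to the boundary with a fixed-parameter solve
    if (q_new >= hi - 1e-9 || q_new <= lo + 1e-9) {
      q_end <- if (q_new >= hi - 1e-9) hi else lo
      eq_end <- tryCatch(solve_on_branch(q_end, param, p, guess, free),
                         error = function(e) NULL)
      if (!is.null(eq_end) && all(eq_end$state[free] > presence_tol)) {
        i <- i + 1L
        eqs[[i]] <- eq_end; qs[i] <- q_end
        invs[[i]] <- inv_growth(eq_end, q_end)
        pts <- rbind(pts, record(eq_end, q_end))
        check_events(i)
      }
      termination <- "range_end"
      break
    }

    eq_new <- tryCatch(solve_on_branch(q_new, param, p, guess, free),
                       error = function(e) NULL)
    if (is.null(eq_new)) { h <- h / 2; next }

    # present component exiting through zero
    if (any(eq_new$state[free] <= presence_tol)) {
      exit_sp <- free[eq_new$state[free] <= presence_tol][1]
      bifs[[length(bifs) + 1]] <- refine_component_exit(
        qs[i], q_new, eqs[[i]]$state, exit_sp)
      termination <- "component_exit"
      break
    }

    i <- i + 1L
    eqs[[i]] <- eq_new; qs[i] <- q_new
    invs[[i]] <- inv_growth(eq_new, q_new)
    pts <- rbind(pts, record(eq_new, q_new))
    check_events(i)
    h <- min(h * 1.3, h_max)
  }
  if (i >= max_points) termination <- "max_points"

  structure(list(points = pts, bifurcations = bifs, param = param,
                 composition = free, termination = termination),
            class = "lhigp_branch")
}

#' @export
print.lhigp_branch <- function(x, ...) {
  cat(sprintf("lhigp branch in %s: %d points, composition {%s}, ends by %s\n",
              x$param, nrow(x$points), paste(x$composition, collapse = ","),
              x$termination))
  for (b in x$bifurcations)
    cat(sprintf("  %s at %s = %.6f%s\n", b$kind, x$param, b$param_value,
                if (!is.null(b$species)) paste0(" (", b$species, ")") else ""))
  invisible(x)
}

#' Export a branch as CSV / JSON
#'
#' Writes the branch points as a CSV (`param, R, C, Pj, Pa, class, stable,
#' leading_eigenvalue_re`) and, optionally, the detected bifurcation points
#' as a JSON array of records `kind, param_value, state, species`.
#'
#' @param branch An `lhigp_branch`.
#' @param csv_path CSV destination.
#' @param json_path Optional JSON destination for the bifurcation points.
#' @return `csv_path`, invisibly.
#' @export
write_branch <- function(branch, csv_path, json_path = NULL) {
  stopifnot(inherits(branch, "lhigp_branch"))
  utils::write.csv(branch$points, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    recs <- lapply(branch$bifurcations, function(b)
      list(kind = b$kind, param_value = b$param_value,
           state = as.list(b$state),
           species = if (is.null(b$species)) NULL else b$species))
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Stable equilibria over a two-parameter grid
#'
#' For every cell of a rectangular grid in two parameters, finds the set of
#' stable equilibrium classes by direct Newton solves from four canonical
#' starting guesses (resource-only, consumer-resource, predator-resource,
#' full coexistence) plus `n_random` seeded random guesses per cell — the
#' multi-start is essential because the model has documented bistability.
#' For each stable equilibrium with predators present the sign of the
#' selection gradient on the juvenile-specialization trait is recorded.
#'
#' @param p Baseline parameters (values of the two swept parameters in `p`
#'   are ignored).
#' @param x_param,y_param Names of the two swept parameters (see
#'   [continue_branch()] for the admissible set).
#' @param x_grid,y_grid Numeric grid vectors.
#' @param seed Integer seed for the random starts.
#' @param n_random Random starting guesses per cell.
#' @param presence_tol Density regarded as zero.
#' @return Data frame with one row per (cell, stable class): columns `x`,
#'   `y`, `class`, `R`, `C`, `Pj`, `Pa`, `gradient_sign` (`+1`, `-1` or
#'   `NA` for classes without predators or where the gradient is
#'   unavailable).  Cells where no stable equilibrium was found appear with
#'   `class = "undecided"`.
#' @export
two_parameter_map <- function(p, x_param, y_param, x_grid, y_grid,
                              seed = 1, n_random = 2, presence_tol = 1e-8) {
  stopifnot(x_param %in% sweepable_params, y_param %in% sweepable_params,
            length(x_grid) >= 1, length(y_grid) >= 1)
  rows <- list()
  for (ix in seq_along(x_grid)) for (iy in seq_along(y_grid)) {
    p2 <- set_param1(set_param1(p, x_param, x_grid[ix]), y_param, y_grid[iy])
    found <- stable_classes(p2, seed = seed + 1000L * ix + iy,
                            n_random = n_random,
                            presence_tol = presence_tol)
    if (!length(found)) {
      rows[[length(rows) + 1]] <- data.frame(
        x = x_grid[ix], y = y_grid[iy], class = "undecided",
        R = NA_real_, C = NA_real_, Pj = NA_real_, Pa = NA_real_,
        gradient_sign = NA_real_)
      next
    }
    for (eq in found) {
      gsign <- NA_real_
      if (eq$class %in% c("PR", "PCR"))
        gsign <- tryCatch(sign(selection_gradient(eq, p2)),
                          error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        x = x_grid[ix], y = y_grid[iy], class = eq$class,
        R = eq$state[["R"]], C = eq$state[["C"]],
        Pj = eq$state[["Pj"]], Pa = eq$state[["Pa"]],
        gradient_sign = gsign)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c("x", "y")
  attr(out, "x_param") <- x_param
  attr(out, "y_param") <- y_param
  out
}

# all stable equilibria at fixed parameters, by multi-start Newton with a
# short dynamics fallback; adult-dominated and juvenile-dominated predator
# guesses are both needed (cannibalism shifts the stage distribution)
stable_classes <- function(p, seed = 1, n_random = 2, presence_tol = 1e-8,
                           dynamics_fallback = TRUE) {
  guesses <- list(
    R = list(absent = c("C", "Pj", "Pa"),
             list(c(R = p$R_max, C = 0, Pj = 0, Pa = 0))),
    CR = list(absent = c("Pj", "Pa"),
              list(tryCatch(cr_equilibrium_closed_form(p),
                            error = function(e) NULL))),
    PR = list(absent = "C",
              list(c(R = 0.5 * p$R_max, C = 0, Pj = 0.3, Pa = 0.5),
                   c(R = 0.12 * p$R_max, C = 0, Pj = 1.8, Pa = 0.6))),
    PCR = list(absent = character(),
               list(c(R = 0.5 * p$R_max, C = 0.3, Pj = 0.2, Pa = 0.4),
                    c(R = 0.12 * p$R_max, C = 0.3, Pj = 1.7, Pa = 0.3))))
  set.seed(seed)
  rand <- replicate(n_random,
                    c(R = stats::runif(1, 0.05, 1) * p$R_max,
                      C = stats::runif(1, 0.01, 1),
                      Pj = stats::runif(1, 0.01, 2),
                      Pa = stats::runif(1, 0.01, 1)),
                    simplify = FALSE)
  found <- list()
  for (cls in names(guesses)) {
    spec <- guesses[[cls]]
    canon <- Filter(Negate(is.null), spec[[2]])
    if (!length(canon)) next
    starts <- c(canon, lapply(rand, function(r) {
      r[spec$absent] <- 0
      r
    }))
    for (g in starts) {
      eq <- tryCatch(solve_equilibrium(g, p, absent = spec$absent,
                                       presence_tol = presence_tol),
                     error = function(e) NULL)
      if (is.null(eq) || !eq$stable) next
      if (eq$class != cls) next  # collapsed onto a different composition
      if (!cls %in% names(found)) found[[cls]] <- eq
    }
  }
  if (dynamics_fallback && !any(c("PR", "PCR") %in% names(found))) {
    for (s0 in list(c(R = 0.5 * p$R_max, C = 0.3, Pj = 0.3, Pa = 0.3),
                    c(R = 0.5 * p$R_max, C = 0, Pj = 0.3, Pa = 0.3))) {
      at <- tryCatch(find_attractor(s0, p, t_max = 5000),
                     error = function(e) NULL)
      if (!is.null(at) && at$status == "equilibrium" &&
          at$class %in% c("PR", "PCR") && !at$class %in% names(found))
        found[[at$class]] <- at$equilibrium
    }
  }
  found
}
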