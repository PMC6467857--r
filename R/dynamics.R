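#' Integrate the community dynamics
#'
#' Stiff-capable integration of the four biomass ODEs with `deSolve::lsoda`.
#' Integration proceeds in segments; after each segment any component that
#' has fallen below `extinct_tol` is clamped to exactly zero and the event is
#' logged.  The hard clamp matters near transcritical exits, where densities
#' decay exponentially to tiny positive values that would otherwise fake
#' persistence.
#'
#' @param state0 Non-negative initial state `(R, C, Pj, Pa)`.
#' @param p An [lhigp_params()] object.
#' @param t_end Final time (> 0).
#' @param n_out Number of output times (evenly spaced from 0 to `t_end`).
#' @param extinct_tol Density below which a species is declared extinct and
#'   clamped to zero.
#' @param atol,rtol Absolute and relative integration tolerances.
#' @param n_segments Number of integration segments between which the
#'   extinction clamp is applied.
#' @return An object of class `lhigp_trajectory`: list with `times` (output
#'   grid), `states` (matrix, one row per time, columns `R, C, Pj, Pa`),
#'   `events` (data frame with `time`, `species`), and `params`.
#' @export
#' @examples
#' p <- default_parameters(a_jr = 4.5, a_ar = 0, beta = 0)
#' tr <- simulate_lhigp(c(R = 3, C = 0.1, Pj = 0, Pa = 0), p, t_end = 200)
#' tail(tr$states, 1)  # converges to the consumer-resource equilibrium
simulate_lhigp <- function(state0, p, t_end = 1000, n_out = 200,
                           extinct_tol = 1e-9, atol = 1e-10, rtol = 1e-8,
                           n_segments = 20) {
  x <- as_state(state0)
  stopifnot(t_end > 0, n_segments >= 1)
  deriv <- function(t, y, parms) list(unname(lhigp_rhs(y, p)))
  seg_bounds <- seq(0, t_end, length.out = n_segments + 1)
  out_times <- seq(0, t_end, length.out = n_out)
  times_all <- numeric(0)
  states_all <- NULL
  events <- data.frame(time = numeric(0), species = character(0))
  y <- unclass(x)
  for (k in seq_len(n_segments)) {
    tt <- sort(unique(c(seg_bounds[k], out_times[out_times >= seg_bounds[k] &
                                                   out_times <= seg_bounds[k + 1]],
                        seg_bounds[k + 1])))
    sol <- tryCatch(
      deSolve::lsoda(y, tt, deriv, parms = NULL, atol = atol, rtol = rtol),
      warning = function(w) {
        stop("integrator failure at t = ", seg_bounds[k], " (",
             conditionMessage(w), "); last state: ",
             paste(sprintf("%s = %.4g", state_names, y), collapse = ", "))
      })
    seg_states <- sol[, state_names, drop = FALSE]
    seg_states[seg_states < 0 & seg_states > -extinct_tol] <- 0
    times_all <- c(times_all, sol[, "time"])
    states_all <- rbind(states_all, seg_states)
    y <- seg_states[nrow(seg_states), ]
    gone <- state_names[y < extinct_tol & y > 0]
    gone <- setdiff(gone, "R")  # resource cannot go extinct (semichemostat)
    if (length(gone)) {
      y[gone] <- 0
      events <- rbind(events, data.frame(time = seg_bounds[k + 1],
                                         species = gone))
    }
  }
  keep <- !duplicated(times_all)
  structure(list(times = times_all[keep],
                 states = states_all[keep, , drop = FALSE],
                 events = events, params = p),
            class = "lhigp_trajectory")
}

#' @export
print.lhigp_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("lhigp trajectory: %d output times over [0, %g]\n",
              n, max(x$times)))
  cat("  final state:",
      paste(sprintf("%s = %.6g", state_names, x$states[n, ]),
            collapse = ", "), "\n")
  if (nrow(x$events))
    cat("  extinctions:",
        paste(sprintf("%s @ t=%g", x$events$species, x$events$time),
              collapse = "; "), "\n")
  invisible(x)
}

#' Export a trajectory as a tidy data frame / CSV
#'
#' @param x An `lhigp_trajectory`.
#' @param path Optional CSV path; when given, the table is also written.
#' @return Data frame with columns `t, R, C, Pj, Pa` (invisibly when
#'   writing).
#' @export
trajectory_frame <- function(x, path = NULL) {
  stopifnot(inherits(x, "lhigp_trajectory"))
  df <- data.frame(t = x$times, x$states)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Run the dynamics to an attractor and classify it
#'
#' Integrates in windows of length `window` until the relative change of
#' every component across a window falls below `conv_tol`, then polishes the
#' endpoint with [solve_equilibrium()] (restricted to the surviving species)
#' and classifies it.  If the state keeps oscillating with non-vanishing
#' amplitude, a cycle flag is returned together with the min/max envelope
#' over the last window instead of an equilibrium; if neither settles before
#' `t_max`, status is `"undecided"`.
#'
#' @inheritParams simulate_lhigp
#' @param window Length of one test window.
#' @param t_max Total integration-time budget.
#' @param conv_tol Relative-change tolerance declaring convergence.
#' @param cycle_tol Relative amplitude above which a non-converged window is
#'   reported as a cycle.
#' @return List with `status` (`"equilibrium"`, `"cycle"`, or
#'   `"undecided"`), `class` (equilibrium class, for status
#'   `"equilibrium"`), `equilibrium` (polished `lhigp_equilibrium` or
#'   `NULL`), `state` (final raw state), `envelope` (min/max per component,
#'   for cycles), and `events` (extinction log).
#' @export
find_attractor <- function(state0, p, window = 200, t_max = 20000,
                           conv_tol = 1e-9, cycle_tol = 1e-4,
                           extinct_tol = 1e-9, atol = 1e-10, rtol = 1e-8) {
  y <- as_state(state0)
  t_done <- 0
  events <- data.frame(time = numeric(0), species = character(0))
  last_amp <- Inf
  while (t_done < t_max) {
    tr <- simulate_lhigp(y, p, t_end = window, n_out = 101,
                         extinct_tol = extinct_tol, atol = atol, rtol = rtol,
                         n_segments = 4)
    if (nrow(tr$events)) {
      ev <- tr$events
      ev$time <- ev$time + t_done
      events <- rbind(events, ev)
    }
    y_new <- tr$states[nrow(tr$states), ]
    # slow exponential exits: a species already tiny whose boundary
    # equilibrium (without it) is stable against its re-invasion will reach
    # the extinction clamp eventually; conclude analytically rather than
    # integrating out the long tail
    small <- setdiff(state_names[y_new < 1e-3 & y_new <= unclass(y)], "R")
    small <- small[y_new[small] > 0]
    if (length(small)) {
      y_try <- y_new; y_try[small] <- 0
      absent_try <- setdiff(state_names[y_try <= extinct_tol], "R")
      eq_try <- tryCatch(solve_equilibrium(y_try, p, absent = absent_try),
                         error = function(e) NULL)
      if (!is.null(eq_try) && eq_try$stable) {
        events <- rbind(events,
                        data.frame(time = t_done + window, species = small))
        return(list(status = "equilibrium", class = eq_try$class,
                    equilibrium = eq_try, state = eq_try$state,
                    envelope = NULL, events = events))
      }
    }
    scale <- pmax(abs(y_new), 1e-6)
    half <- tr$states[seq(51, 101), , drop = FALSE]
    amp <- max((apply(half, 2, max) - apply(half, 2, min)) / scale)
    step_change <- max(abs(y_new - y) / scale)
    t_done <- t_done + window
    y <- y_new
    if (step_change < conv_tol && amp < cycle_tol) {
      absent <- state_names[y <= extinct_tol]
      absent <- setdiff(absent, "R")
      eq <- tryCatch(solve_equilibrium(y, p, absent = absent),
                     error = function(e) NULL)
      if (is.null(eq))
        return(list(status = "undecided", class = NA_character_,
                    equilibrium = NULL, state = y, envelope = NULL,
                    events = events))
      return(list(status = "equilibrium", class = eq$class,
                  equilibrium = eq, state = eq$state, envelope = NULL,
                  events = events))
    }
    # persistent oscillation: amplitude stationary across windows (a slowly
    # growing or decaying mode changes amplitude between windows and must
    # not be mistaken for a limit cycle), and genuinely non-monotone
    oscillating <- any(vapply(seq_len(4), function(j) {
      rng <- max(half[, j]) - min(half[, j])
      if (rng / scale[j] <= cycle_tol) return(FALSE)
      sum(abs(diff(sign(diff(half[, j]))))) >= 2  # interior extrema exist
    }, logical(1)))
    if (amp > cycle_tol && t_done >= 3 * window && oscillating &&
        is.finite(last_amp) && abs(amp / last_amp - 1) < 0.05) {
      return(list(status = "cycle", class = NA_character_,
                  equilibrium = NULL, state = y,
                  envelope = rbind(min = apply(half, 2, min),
                                   max = apply(half, 2, max)),
                  events = events))
    }
    last_amp <- amp
  }
  list(status = "undecided", class = NA_character_, equilibrium = NULL,
       state = y, envelope = NULL, events = events)
}
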