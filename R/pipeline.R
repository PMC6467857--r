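#' High-level analysis runs
#'
#' Thin orchestration over the package's machinery, mirroring the three
#' standard products of the analysis: a one-parameter equilibrium branch
#' sweep with its bifurcation points, a trait-substitution trajectory, and a
#' two-parameter stability map.  Every run writes its outputs plus a
#' `resolved_config.json` (the fully resolved settings) into `out_dir`, so
#' any result file can be regenerated from the JSON next to it.  All runs
#' are deterministic given their configuration.
#'
#' @param scenario Core scenario name (see [study_scenarios()]), or `NULL`
#'   to give `a_ar` and `beta` directly.
#' @param a_jr Trait value (start of sweep / trajectory).
#' @param a_ar,beta Scenario axes (used when `scenario` is `NULL`;
#'   overriding a named scenario is an error).
#' @param sweep For `run_branch()`: list with `param`, `from`, `to` (and
#'   optionally `h0`, `h_max`).
#' @param out_dir Output directory (created if needed).
#' @param ... Additional parameter overrides passed to
#'   [default_parameters()].
#' @return The result object (branch, trajectory, or map), invisibly;
#'   called for the side effect of writing files.
#' @name pipeline
NULL

resolve_scenario <- function(scenario, a_jr, a_ar, beta, ...) {
  if (!is.null(scenario)) {
    if (!missing(a_ar) || !missing(beta))
      stop("give either a scenario name or a_ar/beta, not both")
    p <- scenario_parameters(scenario, a_jr = a_jr, ...)
  } else {
    p <- default_parameters(a_jr = a_jr, a_ar = a_ar, beta = beta, ...)
  }
  p
}

write_resolved_config <- function(out_dir, kind, p, extra = list()) {
  cfg <- c(list(kind = kind, parameters = unclass(p)), extra)
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline
#' @export
run_branch <- function(scenario = NULL, a_jr, a_ar, beta,
                       sweep = list(param = "a_jr", from = a_jr, to = 6),
                       out_dir = ".", ...) {
  p <- resolve_scenario(scenario, a_jr, a_ar, beta, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(all(c("param", "from", "to") %in% names(sweep)))
  p <- set_param1(p, sweep$param, sweep$from)
  cand <- stable_classes(p, seed = 1)
  if (!length(cand))
    stop("no stable equilibrium found at the sweep start")
  pref <- intersect(c("PCR", "PR", "CR", "R"), names(cand))
  eq0 <- cand[[pref[1]]]
  br <- continue_branch(eq0, sweep$param, c(sweep$from, sweep$to),
                        h0 = if (is.null(sweep$h0)) 0.02 else sweep$h0,
                        h_max = if (is.null(sweep$h_max)) 0.1 else sweep$h_max)
  write_branch(br, file.path(out_dir, "branch.csv"),
               file.path(out_dir, "bifurcations.json"))
  write_resolved_config(out_dir, "branch", p, list(sweep = sweep))
  message("branch: ", nrow(br$points), " points, ",
          length(br$bifurcations), " bifurcation(s), ends by ",
          br$termination)
  invisible(br)
}

#' @rdname pipeline
#' @export
run_trait_evolution <- function(scenario = NULL, a_jr, a_ar, beta,
                                out_dir = ".", ...) {
  p <- resolve_scenario(scenario, a_jr, a_ar, beta, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tj <- trait_trajectory(a_jr, p)
  write_trait_trajectory(tj, file.path(out_dir, "trait_trajectory.csv"))
  write_resolved_config(out_dir, "evolve", p, list(y0 = a_jr))
  message("trait trajectory: status ", tj$status, ", final a_jr ",
          signif(tj$final_trait, 6))
  invisible(tj)
}

#' @rdname pipeline
#' @param x_param,y_param,x_grid,y_grid Grid specification for
#'   `run_region_map()`.
#' @param seed Seed for the multi-start random guesses.
#' @export
run_region_map <- function(scenario = NULL, a_jr = 3, a_ar, beta = 0,
                           x_param = "a_jr", y_param = "beta",
                           x_grid = seq(0.5, 6, by = 0.5),
                           y_grid = seq(0, 2, by = 0.25),
                           seed = 1, out_dir = ".", ...) {
  p <- resolve_scenario(scenario, a_jr, a_ar, beta, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(x_grid) < 1 || length(y_grid) < 1)
    stop("empty grid")
  map <- two_parameter_map(p, x_param, y_param, x_grid, y_grid, seed = seed)
  utils::write.csv(map, file.path(out_dir, "region_map.csv"),
                   row.names = FALSE)
  write_resolved_config(out_dir, "map", p,
                        list(x_param = x_param, y_param = y_param,
                             x_grid = x_grid, y_grid = y_grid, seed = seed))
  message("region map: ", length(x_grid), " x ", length(y_grid),
          " cells, ", sum(map$class == "undecided"), " undecided")
  invisible(map)
}
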