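#' Model parameters for the life-history intraguild predation model
#'
#' Constructs and validates the full parameter set of the stage-structured
#' biomass model: a basal resource with semichemostat renewal, an unstructured
#' specialist consumer, and an intraguild predator split into a juvenile and an
#' adult biomass compartment.  Juveniles feed on the resource with attack-rate
#' constant `a_jr` (the evolving trait); adults attack consumers and,
#' discounted by the cannibalistic preference `beta`, conspecific juveniles
#' with attack-rate constant `a_ac`, and feed on the resource with `a_ar`.
#' `a_ac` is never stored: it is derived from `a_jr` through the ontogenetic
#' trade-off [tradeoff_adult_attack()] whenever rates are evaluated.
#'
#' All quantities are in dimensionless model units (biomass densities, and
#' rates per unit time).
#'
#' @param a_jr Juvenile attack-rate constant on the resource, the evolving
#'   trait; must lie in `[0, a_p]`.
#' @param a_ar Adult attack-rate constant on the resource.  `a_ar = 0` is the
#'   diet-shift scenario (adults feed only by predation); `a_ar > 0` is diet
#'   broadening.
#' @param beta Cannibalistic preference: feeding rate of adults on juvenile
#'   conspecifics relative to the interspecific predation attack rate; `>= 0`.
#' @param a_cr Consumer attack-rate constant on the resource.
#' @param a_p Maximum attack rate in the ontogenetic trade-off.
#' @param epsilon Trade-off shape: `0` linear, `(-1, 0)` weak (concave),
#'   `> 0` strong (convex).  Must exceed `-1`.
#' @param h_c,h_p Handling-time constants of consumer and predator.
#' @param T_c,T_p Mass-specific maintenance rates of consumer and predator.
#' @param mu_c,mu_p Background mortality rates of consumer and predator.
#' @param sigma Conversion efficiency, in `(0, 1]`.
#' @param z Ratio of size at birth to size at maturation, in `(0, 1)`.
#' @param delta Resource turnover rate of the semichemostat.
#' @param R_max Maximum (supply) resource density.
#'
#' @return An object of class `lhigp_params`: a validated named list of the
#'   sixteen model constants.
#' @seealso [default_parameters()] for the standard parameterization,
#'   [tradeoff_adult_attack()] for the derived adult predation attack rate.
#' @export
#' @examples
#' p <- lhigp_params(a_jr = 4.5, a_ar = 0, beta = 0)
#' tradeoff_adult_attack(p$a_jr, p$a_p, p$epsilon)
lhigp_params <- function(a_jr, a_ar, beta,
                         a_cr = 10, a_p = 6, epsilon = 0,
                         h_c = 0.1, h_p = 0.25,
                         T_c = 1, T_p = 0.4,
                         mu_c = 0.1, mu_p = 0.04,
                         sigma = 0.5, z = 0.01,
                         delta = 1, R_max = 3) {
  p <- list(a_cr = a_cr, a_jr = a_jr, a_ar = a_ar, a_p = a_p,
            epsilon = epsilon, beta = beta, h_c = h_c, h_p = h_p,
            T_c = T_c, T_p = T_p, mu_c = mu_c, mu_p = mu_p,
            sigma = sigma, z = z, delta = delta, R_max = R_max)
  validate_lhigp_params(p)
  structure(p, class = "lhigp_params")
}

lhigp_param_names <- c("a_cr", "a_jr", "a_ar", "a_p", "epsilon", "beta",
                       "h_c", "h_p", "T_c", "T_p", "mu_c", "mu_p",
                       "sigma", "z", "delta", "R_max")

validate_lhigp_params <- function(p) {
  missing <- setdiff(lhigp_param_names, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  for (nm in lhigp_param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  nonneg <- setdiff(lhigp_param_names, "epsilon")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "))
  if (p$epsilon <= -1) stop("epsilon must exceed -1")
  if (p$z <= 0 || p$z >= 1) stop("z must lie in (0, 1)")
  if (p$sigma <= 0 || p$sigma > 1) stop("sigma must lie in (0, 1]")
  if (p$a_jr > p$a_p)
    stop("a_jr must not exceed the trade-off maximum a_p")
  invisible(p)
}

#' @export
print.lhigp_params <- function(x, ...) {
  cat("Life-history intraguild predation parameters\n")
  cat(sprintf("  trait a_jr = %g (a_ac = %g via trade-off, a_p = %g, eps = %g)\n",
              x$a_jr, tradeoff_adult_attack(x$a_jr, x$a_p, x$epsilon),
              x$a_p, x$epsilon))
  cat(sprintf("  scenario: a_ar = %g (%s), beta = %g\n", x$a_ar,
              if (x$a_ar > 0) "diet broadening" else "diet shift", x$beta))
  others <- setdiff(lhigp_param_names, c("a_jr", "a_ar", "beta", "a_p", "epsilon"))
  cat("  ", paste(sprintf("%s = %g", others, unlist(x[others])),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and the result
#' re-validated.  Unknown field names are an error.
#'
#' @param p An [lhigp_params()] object.
#' @param ... Named scalar replacements, e.g. `a_jr = 4`.
#' @return A new `lhigp_params` object.
#' @export
set_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), lhigp_param_names)
  if (length(unknown) || is.null(names(repl)) || any(names(repl) == ""))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- repl
  validate_lhigp_params(p)
  structure(p[lhigp_param_names], class = "lhigp_params")
}

#' Ontogenetic trade-off between juvenile foraging and adult predation
#'
#' The adult predation attack rate `a_ac` is tied to the juvenile resource
#' attack rate `a_jr` by
#' \deqn{a_{ac} = \frac{a_p - a_{jr}}{1 + \varepsilon\, a_{jr}/a_p},}
#' so that specialization of juveniles on resource feeding comes at the cost
#' of adult predation ability and vice versa.  The function is strictly
#' decreasing on `[0, a_p]` with endpoints `a_ac(0) = a_p` and
#' `a_ac(a_p) = 0` for every admissible shape `epsilon > -1`.
#'
#' @param a_jr Juvenile attack rate (trait), in `[0, a_p]`.  Vectorized.
#' @param a_p Maximum attack rate.
#' @param epsilon Trade-off shape, `> -1`.
#' @return The adult predation attack rate `a_ac`, same length as `a_jr`.
#' @export
#' @examples
#' tradeoff_adult_attack(3, a_p = 6, epsilon = 5)  # strong trade-off
tradeoff_adult_attack <- function(a_jr, a_p, epsilon) {
  if (epsilon <= -1) stop("epsilon must exceed -1")
  if (any(a_jr < 0 | a_jr > a_p)) stop("a_jr must lie in [0, a_p]")
  (a_p - a_jr) / (1 + epsilon * a_jr / a_p)
}

#' Read or write a parameter set as YAML or JSON
#'
#' Parameters serialize to a flat mapping of the sixteen field names.  On
#' reading, unknown keys and missing fields are errors and the result is
#' re-validated.
#'
#' @param p An [lhigp_params()] object.
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_params()` returns an `lhigp_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "lhigp_params"))
  x <- lapply(unclass(p), identity)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognized extension (use .yaml or .json): ", path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unrecognized extension (use .yaml or .json): ", path)
  unknown <- setdiff(names(x), lhigp_param_names)
  if (length(unknown))
    stop("unknown keys in parameter file: ", paste(unknown, collapse = ", "))
  p <- lapply(x, as.numeric)
  validate_lhigp_params(p)
  structure(p[lhigp_param_names], class = "lhigp_params")
}

#' Community state vector
#'
#' A named non-negative vector of the four biomass densities: resource `R`,
#' consumer `C`, juvenile predators `Pj`, adult predators `Pa`.
#'
#' @param R,C,Pj,Pa Biomass densities, all `>= 0`.
#' @return A named numeric vector of length 4 with class `lhigp_state`.
#' @export
community_state <- function(R, C = 0, Pj = 0, Pa = 0) {
  s <- c(R = R, C = C, Pj = Pj, Pa = Pa)
  if (any(!is.finite(s)) || any(s < 0))
    stop("state components must be finite and non-negative")
  structure(s, class = "lhigp_state")
}

# light coercion for hot paths: names only, no sign checks (finite-difference
# Jacobians and stiff integrators may probe marginally negative states)
state_vec <- function(x) {
  x <- unlist(x)
  if (is.null(names(x))) names(x) <- c("R", "C", "Pj", "Pa")
  x[c("R", "C", "Pj", "Pa")]
}

as_state <- function(x) {
  if (inherits(x, "lhigp_state")) return(x)
  x <- unlist(x)
  if (length(x) != 4L) stop("state must have 4 components (R, C, Pj, Pa)")
  if (is.null(names(x)) || !all(c("R", "C", "Pj", "Pa") %in% names(x)))
    names(x) <- c("R", "C", "Pj", "Pa")
  community_state(x[["R"]], x[["C"]], x[["Pj"]], x[["Pa"]])
}
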