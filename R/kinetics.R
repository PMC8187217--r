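#' Kinetics specifications
#'
#' Transition intensities generalise mass-action through per-species rate
#' functions \eqn{\theta_i} with \eqn{\theta_i(x) = 0} exactly when
#' \eqn{x \le 0}: a reaction with reactant complex \eqn{\nu} fires at rate
#' \deqn{\kappa \prod_i \prod_{j=0}^{\nu_i - 1} \theta_i(x_i - j).}
#' Mass-action is \eqn{\theta(x) = x}, recovering the falling factorial.
#' Hill type I is \eqn{x \mapsto x^m / (k^m + x^m)} (stochastic
#' Michaelis-Menten for \eqn{m = 1}); Hill type II is
#' \eqn{x \mapsto k_1^m / (k_2^m + x^m)} for \eqn{x \ge 1}, forced to zero
#' at \eqn{x \le 0} so that the support condition on \eqn{\theta} holds.
#'
#' @param g a `"crn"` object (or character vector of species names).
#' @param ... named per-species kinetics created by [mass_action()],
#'   [hill_I()], [hill_II()] or [theta_table()]; unnamed species default to
#'   mass-action.
#' @return An object of class `"crn_kinetics"`: a named list of theta
#'   descriptors.
#' @export
kinetics_spec <- function(g, ...) {
  species <- if (inherits(g, "crn")) g$species else as.character(g)
  kin <- default_kinetics(species)
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("per-species kinetics must be named")
    unknown <- setdiff(names(extra), species)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    for (sp in names(extra)) kin[[sp]] <- validate_theta(extra[[sp]])
  }
  class(kin) <- "crn_kinetics"
  kin
}

default_kinetics <- function(species) {
  kin <- stats::setNames(rep(list(mass_action()), length(species)), species)
  class(kin) <- "crn_kinetics"
  kin
}

#' @rdname kinetics_spec
#' @export
mass_action <- function() {
  structure(list(type = "mass_action", params = list()), class = "crn_theta")
}

#' @rdname kinetics_spec
#' @param m positive integer Hill coefficient.
#' @param k,k1,k2 positive Hill constants.
#' @export
hill_I <- function(m = 1, k = 1) {
  stopifnot(m >= 1, k > 0)
  structure(list(type = "hill_I", params = list(m = m, k = k)),
            class = "crn_theta")
}

#' @rdname kinetics_spec
#' @export
hill_II <- function(m = 1, k1 = 1, k2 = 1) {
  stopifnot(m >= 1, k1 > 0, k2 > 0)
  structure(list(type = "hill_II", params = list(m = m, k1 = k1, k2 = k2)),
            class = "crn_theta")
}

#' @rdname kinetics_spec
#' @param values positive numeric vector giving \eqn{\theta(1), \theta(2), \ldots};
#'   values beyond the table continue with the last entry.
#' @export
theta_table <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, all(values > 0))
  structure(list(type = "table", params = list(values = values)),
            class = "crn_theta")
}

validate_theta <- function(th) {
  if (!inherits(th, "crn_theta"))
    stop("kinetics entries must be created by mass_action()/hill_I()/hill_II()/theta_table()")
  th
}

#' Evaluate a per-species rate function
#'
#' @param th a `"crn_theta"` descriptor.
#' @param x integer vector of molecule counts.
#' @return Numeric vector of \eqn{\theta(x)}; zero for `x <= 0`.
#' @export
theta_eval <- function(th, x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  pos <- x > 0
  if (!any(pos)) return(out)
  xp <- x[pos]
  p <- th$params
  out[pos] <- switch(th$type,
    mass_action = xp,
    hill_I = xp^p$m / (p$k^p$m + xp^p$m),
    hill_II = p$k1^p$m / (p$k2^p$m + xp^p$m),
    table = p$values[pmin(xp, length(p$values))],
    stop("unknown theta type ", th$type))
  out
}

is_mass_action <- function(kin) {
  is.null(kin) ||
    all(vapply(kin, function(k) k$type == "mass_action", logical(1)))
}

## resolve the kinetics to use: explicit argument wins over g$kinetics
resolve_kinetics <- function(g, kin = NULL) {
  if (!is.null(kin)) {
    if (!inherits(kin, "crn_kinetics")) stop("kin must be a kinetics_spec()")
    missing <- setdiff(g$species, names(kin))
    if (length(missing)) {
      add <- default_kinetics(missing)
      kin <- c(kin, add)[g$species]
      class(kin) <- "crn_kinetics"
    }
    return(kin)
  }
  if (!is.null(g$kinetics)) return(g$kinetics)
  default_kinetics(g$species)
}

format_theta <- function(th) {
  p <- th$params
  switch(th$type,
    mass_action = "mass_action",
    hill_I = sprintf("hill_I(m=%g, k=%g)", p$m, p$k),
    hill_II = sprintf("hill_II(m=%g, k1=%g, k2=%g)", p$m, p$k1, p$k2),
    table = sprintf("table(%s)", paste(format(p$values), collapse = ",")))
}

parse_theta <- function(txt, line) {
  if (txt == "mass_action") return(mass_action())
  m <- regmatches(txt, regexec("^([a-zA-Z_]+)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3L) stop("line ", line, ": cannot parse kinetics '", txt, "'")
  fun <- m[2]
  args <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  vals <- list()
  for (a in args) {
    kv <- strsplit(a, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("line ", line, ": malformed kinetics argument")
    vals[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  switch(fun,
    hill_I = hill_I(m = vals$m, k = vals$k),
    hill_II = hill_II(m = vals$m, k1 = vals$k1, k2 = vals$k2),
    stop("line ", line, ": unknown kinetics '", fun, "'"))
}

#' @export
print.crn_kinetics <- function(x, ...) {
  cat("Kinetics:\n")
  for (sp in names(x)) cat(" ", sp, "=", format_theta(x[[sp]]), "\n")
  invisible(x)
}
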