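## States are integer vectors in the network's species order; sets of
## states are integer matrices with one row per state. Hashing uses the
## comma-joined string key.

state_key <- function(x) paste(x, collapse = ",")
state_keys <- function(states) apply(states, 1L, paste, collapse = ",")

as_state <- function(g, x) {
  x <- as.integer(x)
  if (length(x) != length(g$species))
    stop("state must have one count per species")
  if (any(x < 0)) stop("state counts must be nonnegative")
  x
}

#' Transition intensity of one reaction
#'
#' Under mass-action kinetics the intensity is the falling factorial
#' \eqn{\kappa \, x! / (x - \nu)!} for \eqn{x \ge \nu} (componentwise) and 0
#' otherwise; under general kinetics it is
#' \eqn{\kappa \prod_i \prod_{j=0}^{\nu_i - 1} \theta_i(x_i - j)}. The two
#' agree when every \eqn{\theta_i(x) = x}.
#'
#' @param g a `"crn"` object.
#' @param j reaction index.
#' @param x state (integer vector over species).
#' @param kin optional [kinetics_spec()]; defaults to the network's kinetics
#'   or mass-action.
#' @return Nonnegative numeric intensity.
#' @export
intensity <- function(g, j, x, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  x <- as_state(g, x)
  propensities(g, kin, x)[j]
}

## all reaction intensities at state x
propensities <- function(g, kin, x) {
  nu <- g$reactant
  m <- nrow(nu)
  out <- g$rate
  if (is_mass_action(kin)) {
    for (i in seq_along(x)) {
      col <- nu[, i]
      active <- col > 0L
      if (!any(active)) next
      for (j in which(active)) {
        if (x[i] < col[j]) { out[j] <- 0; next }
        out[j] <- out[j] * prod(x[i] - seq_len(col[j]) + 1L)
      }
    }
    return(out)
  }
  for (i in seq_along(x)) {
    col <- nu[, i]
    for (j in which(col > 0L)) {
      if (out[j] == 0) next
      out[j] <- out[j] * prod(theta_eval(kin[[i]], x[i] - seq_len(col[j]) + 1L))
    }
  }
  out
}

## vectorised propensities: states (n x s) -> intensity matrix (n x m)
propensity_matrix <- function(g, kin, states) {
  n <- nrow(states)
  m <- n_reactions(g)
  P <- matrix(rep(g$rate, each = n), n, m)
  ma <- is_mass_action(kin)
  for (j in seq_len(m)) {
    for (i in seq_along(g$species)) {
      nu <- g$reactant[j, i]
      if (nu == 0L) next
      xi_col <- states[, i]
      for (t in 0:(nu - 1L)) {
        P[, j] <- P[, j] * (if (ma) pmax(xi_col - t, 0)
                            else theta_eval(kin[[i]], xi_col - t))
      }
    }
  }
  P
}

#' Aggregated successor states
#'
#' One entry per distinct jump vector \eqn{\xi = \nu' - \nu} with positive
#' total intensity at `x`; entries with zero rate are omitted.
#'
#' @inheritParams intensity
#' @return A list with components `states` (integer matrix of successor
#'   states, one row per jump) and `rates` (aggregate intensities).
#' @export
successors <- function(g, x, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  x <- as_state(g, x)
  lam <- propensities(g, kin, x)
  keep <- lam > 0
  if (!any(keep)) {
    return(list(states = matrix(integer(), 0, length(x)), rates = numeric()))
  }
  xi <- reaction_vectors(g)[keep, , drop = FALSE]
  key <- apply(xi, 1L, paste, collapse = ",")
  agg <- tapply(lam[keep], factor(key, levels = unique(key)), sum)
  uxi <- xi[!duplicated(key), , drop = FALSE]
  succ <- uxi + matrix(as.integer(x), nrow(uxi), length(x), byrow = TRUE)
  storage.mode(succ) <- "integer"
  list(states = succ, rates = as.numeric(agg))
}

## per-species exploration cap: conservation-based when available, else
## seed maximum plus a margin
default_cap <- function(g, x0, margin = 10L) {
  cons <- conservation_vector(g)
  if (!is.null(cons)) {
    total <- sum(cons * x0)
    return(as.integer(floor(total / cons)))
  }
  rep(max(x0, g$reactant, g$product) + margin, length(g$species))
}

#' Forward-reachable set of states
#'
#' Breadth-first closure of `x0` under positive-rate jumps, never expanding
#' past the per-species cap. A suppressed out-of-cap jump sets
#' `truncated = TRUE`, in which case conclusions drawn from the set only
#' hold within the explored box.
#'
#' @inheritParams intensity
#' @param x0 initial state.
#' @param cap per-species upper bound (recycled); defaults to a
#'   conservation-law bound when the network is conservative, otherwise the
#'   seed maximum plus a margin of 10.
#' @param max_states abort if the explored set grows beyond this size.
#' @return A list with `states` (integer matrix) and `truncated` (logical).
#' @export
reachable_set <- function(g, x0, kin = NULL, cap = NULL, max_states = 50000L) {
  kin <- resolve_kinetics(g, kin)
  x0 <- as_state(g, x0)
  if (is.null(cap)) cap <- default_cap(g, x0)
  cap <- as.integer(rep(cap, length.out = length(x0)))
  if (any(x0 > cap)) stop("cap must dominate the initial state")
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(state_key(x0), TRUE, envir = seen)
  frontier <- matrix(x0, 1L)
  chunks <- list(frontier)
  n_total <- 1L
  truncated <- FALSE
  xi <- reaction_vectors(g)
  ## breadth-first by whole frontiers, propensities vectorised per level
  while (nrow(frontier)) {
    P <- propensity_matrix(g, kin, frontier)
    targets <- list()
    for (j in seq_len(n_reactions(g))) {
      from <- which(P[, j] > 0)
      if (!length(from)) next
      targets[[length(targets) + 1L]] <- frontier[from, , drop = FALSE] +
        matrix(xi[j, ], length(from), ncol(frontier), byrow = TRUE)
    }
    if (!length(targets)) break
    cand <- do.call(rbind, targets)
    over <- rowSums(cand > matrix(cap, nrow(cand), length(cap),
                                  byrow = TRUE)) > 0
    if (any(over)) truncated <- TRUE
    cand <- cand[!over, , drop = FALSE]
    if (!nrow(cand)) break
    keys <- state_keys(cand)
    first <- !duplicated(keys)
    cand <- cand[first, , drop = FALSE]
    keys <- keys[first]
    new <- !vapply(keys, exists, logical(1),
                   envir = seen, inherits = FALSE)
    cand <- cand[new, , drop = FALSE]
    for (k in keys[new]) assign(k, TRUE, envir = seen)
    n_total <- n_total + nrow(cand)
    if (n_total > max_states)
      stop("reachable set exceeded max_states = ", max_states)
    if (nrow(cand)) chunks[[length(chunks) + 1L]] <- cand
    frontier <- cand
  }
  states <- do.call(rbind, chunks)
  storage.mode(states) <- "integer"
  list(states = states, truncated = truncated)
}

#' Irreducible component containing a state
#'
#' The forward-reachable set of `x0`, flagged `closed` when it is a genuine
#' irreducible component: every one-step successor stays inside and all
#' states are mutually accessible (checked via strong connectivity of the
#' induced transition graph). Closure is only decided when the exploration
#' was not truncated.
#'
#' @inheritParams reachable_set
#' @return An object of class `"crn_component"`: list with `states`
#'   (integer matrix), `closed`, `truncated`, `seed`.
#' @export
irreducible_component <- function(g, x0, kin = NULL, cap = NULL,
                                  max_states = 50000L) {
  kin <- resolve_kinetics(g, kin)
  rs <- reachable_set(g, x0, kin, cap, max_states)
  closed <- FALSE
  if (!rs$truncated) {
    ## the set is forward-closed by construction, so it is an irreducible
    ## component exactly when its transition graph is strongly connected
    if (nrow(rs$states) == 1L) {
      closed <- TRUE
    } else {
      Q <- generator_matrix(g, rs$states, kin)
      gr <- igraph::graph_from_adjacency_matrix(Q != 0, mode = "directed",
                                                diag = FALSE)
      closed <- igraph::components(gr, mode = "strong")$no == 1L
    }
  }
  structure(list(states = rs$states, closed = closed,
                 truncated = rs$truncated, seed = as_state(g, x0)),
            class = "crn_component")
}

#' @export
print.crn_component <- function(x, ...) {
  cat(sprintf("Irreducible component: %d states, closed=%s, truncated=%s\n",
              nrow(x$states), x$closed, x$truncated))
  invisible(x)
}

#' Essentiality of a reaction network
#'
#' A network is essential when the whole state space is a union of
#' irreducible components. Equivalently, for every reaction the reactant
#' complex (as a state) is accessible from the product complex. Each
#' accessibility question is decided by a capped search; if the cap was hit
#' before the reactant was found the overall verdict is `"inconclusive"`
#' rather than a guess.
#'
#' @inheritParams intensity
#' @param cap optional per-species cap for the searches.
#' @param margin cap margin above the complex coordinates for
#'   non-conservative networks.
#' @return `"essential"`, `"not_essential"` or `"inconclusive"`.
#' @export
is_essential <- function(g, kin = NULL, cap = NULL, margin = 10L) {
  kin <- resolve_kinetics(g, kin)
  cons <- conservation_vector(g)
  inconclusive <- FALSE
  for (j in seq_len(n_reactions(g))) {
    target <- state_key(g$reactant[j, ])
    start <- g$product[j, ]
    capj <- cap
    if (is.null(capj)) {
      capj <- if (!is.null(cons)) {
        as.integer(floor(sum(cons * start) / cons))
      } else {
        pmax(g$reactant[j, ], start) + margin
      }
    }
    rs <- reachable_set(g, start, kin, cap = capj)
    found <- target %in% state_keys(rs$states)
    if (!found) {
      if (rs$truncated) inconclusive <- TRUE else return("not_essential")
    }
  }
  if (inconclusive) "inconclusive" else "essential"
}

#' Project states onto a species subset
#'
#' Coordinate projection of a set of states onto an ordered subset of the
#' species, with duplicate projected states collapsed.
#'
#' @param states integer matrix of states (rows) or a `"crn_component"`.
#' @param g the `"crn"` the states refer to.
#' @param subset character vector of species names (or integer indices).
#' @return Integer matrix of distinct projected states, columns named by the
#'   subset.
#' @export
project_states <- function(states, g, subset) {
  if (inherits(states, "crn_component")) states <- states$states
  if (is.character(subset)) {
    idx <- match(subset, g$species)
    if (anyNA(idx)) stop("unknown species: ",
                         paste(subset[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(subset)
  proj <- states[, idx, drop = FALSE]
  colnames(proj) <- g$species[idx]
  proj[!duplicated(state_keys(proj)), , drop = FALSE]
}
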