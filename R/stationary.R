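#' Generator matrix restricted to a set of states
#'
#' Sparse infinitesimal generator `Q` with `Q[x, y]` the total intensity of
#' jumps from state `x` to state `y`; jumps leaving the state set are
#' dropped, so for a closed component this is the exact generator.
#'
#' @inheritParams intensity
#' @param comp a `"crn_component"` (or integer matrix of states).
#' @return A sparse `dgCMatrix`.
#' @export
generator_matrix <- function(g, comp, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  states <- if (inherits(comp, "crn_component")) comp$states else comp
  n <- nrow(states)
  keys <- state_keys(states)
  P <- propensity_matrix(g, kin, states)
  xi <- reaction_vectors(g)
  ii <- jj <- list(); vv <- list()
  for (j in seq_len(n_reactions(g))) {
    from <- which(P[, j] > 0)
    if (!length(from)) next
    targets <- states[from, , drop = FALSE] +
      matrix(xi[j, ], length(from), ncol(states), byrow = TRUE)
    to <- match(state_keys(targets), keys)
    keep <- !is.na(to)   # jumps leaving the state set are dropped
    if (!any(keep)) next
    ii[[length(ii) + 1L]] <- from[keep]
    jj[[length(jj) + 1L]] <- to[keep]
    vv[[length(vv) + 1L]] <- P[from[keep], j]
  }
  Q <- Matrix::sparseMatrix(i = unlist(ii) %||% integer(),
                            j = unlist(jj) %||% integer(),
                            x = unlist(vv) %||% numeric(),
                            dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

#' Stationary distribution by direct master-equation solve
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` on a finite component via the null
#' space of the transposed generator with one row replaced by the
#' normalisation constraint (dense LU below 2000 states, sparse LU above).
#' A finite closed communicating class has a unique stationary
#' distribution; a residual above tolerance signals a defect and raises an
#' error.
#'
#' @inheritParams generator_matrix
#' @param allow_truncated solve on a truncated component as a
#'   reflecting-boundary approximation of the infinite dynamics (tail mass
#'   beyond the cap should be negligible for the result to be meaningful).
#' @param tol residual tolerance, scaled by the maximum intensity.
#' @return A `"crn_distribution"` with explicit probabilities and the
#'   master-equation residual.
#' @export
solve_master_direct <- function(g, comp, kin = NULL, allow_truncated = FALSE,
                                tol = 1e-10) {
  kin <- resolve_kinetics(g, kin)
  if (!inherits(comp, "crn_component")) stop("comp must be a crn_component")
  if (comp$truncated && !allow_truncated)
    stop("component is truncated; pass allow_truncated = TRUE for a reflecting-boundary solve")
  if (!comp$closed && !comp$truncated)
    stop("component is not closed; its stationary distribution is not defined")
  Q <- generator_matrix(g, comp, kin)
  n <- nrow(Q)
  if (n == 1L)
    return(new_distribution(g, comp, p = 1, residual = 0))
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- if (n < 2000L) {
    solve(as.matrix(A), b)
  } else {
    as.numeric(Matrix::solve(A, b))
  }
  p[p < 0 & p > -1e-14] <- 0
  if (any(p < 0)) stop("negative stationary probabilities: null space defect")
  p <- p / sum(p)
  resid <- max(abs(as.numeric(p %*% Q)))
  scale <- max(abs(Matrix::diag(Q)))
  if (resid > tol * max(1, scale))
    stop("master-equation residual ", format(resid),
         " exceeds tolerance; the component may not be a single communicating class")
  new_distribution(g, comp, p = p, residual = resid)
}

new_distribution <- function(g, comp, p = NULL, logp = NULL, form = "explicit",
                             fs = NULL, logZ = NULL, residual = NA_real_) {
  states <- if (inherits(comp, "crn_component")) comp$states else comp
  if (is.null(logp)) logp <- log(p)
  if (is.null(p)) p <- exp(logp)
  structure(list(states = states, p = as.numeric(p),
                 logp = as.numeric(logp), component = comp, form = form,
                 fs = fs, logZ = logZ, residual = residual,
                 species = g$species),
            class = "crn_distribution")
}

#' @export
print.crn_distribution <- function(x, ...) {
  cat(sprintf("Stationary distribution (%s form) on %d states\n",
              x$form, nrow(x$states)))
  if (!is.na(x$residual))
    cat("master-equation residual:", format(x$residual), "\n")
  invisible(x)
}

## fast state -> probability lookup (0 outside the support)
distribution_lookup <- function(dist) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  keys <- state_keys(dist$states)
  for (i in seq_along(keys)) assign(keys[i], dist$p[i], envir = env)
  function(x) {
    k <- state_key(x)
    if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else 0
  }
}

#' Total variation distance between two distributions on the same support
#' @param d1,d2 `"crn_distribution"` objects (state order may differ).
#' @return Total variation distance in `[0, 1]`.
#' @export
total_variation <- function(d1, d2) {
  k1 <- state_keys(d1$states)
  k2 <- state_keys(d2$states)
  all_keys <- union(k1, k2)
  p1 <- stats::setNames(rep(0, length(all_keys)), all_keys)
  p2 <- p1
  p1[k1] <- d1$p
  p2[k2] <- d2$p
  sum(abs(p1 - p2)) / 2
}

#' Master-equation residual of a candidate distribution
#'
#' Maximum over states of the absolute imbalance between probability inflow
#' and outflow, i.e. \eqn{\|\pi Q\|_\infty} on the component. Zero (to
#' numerical tolerance) exactly for stationary distributions.
#'
#' @inheritParams generator_matrix
#' @param dist a `"crn_distribution"` supported on the component.
#' @return Nonnegative numeric residual.
#' @export
master_equation_residual <- function(g, dist, kin = NULL) {
  Q <- generator_matrix(g, dist$states, resolve_kinetics(g, kin))
  max(abs(as.numeric(dist$p %*% Q)))
}

## ---- balance partitions -------------------------------------------------

new_balance_partition <- function(tuples, label) {
  structure(list(tuples = tuples, label = label),
            class = "crn_balance_partition")
}

#' Balance partitions of the reaction set
#'
#' A balance partition is a set of tuples `(L_i, R_i)` of reaction subsets
#' whose left parts and right parts each partition the reactions. Classical
#' special cases: reaction balance pairs each reaction with its reverse;
#' complex balance indexes tuples by complexes (into / out of each
#' complex); reaction-vector balance indexes them by the jump vector.
#' `partition_by_parts()` builds the two-sided partition `{(R_j, R_j)}`
#' induced by a decomposition into reaction subsets.
#'
#' @param g a `"crn"` object.
#' @return A `"crn_balance_partition"`.
#' @export
reaction_balanced_partition <- function(g) {
  rev_of <- match_reverse(g)
  if (anyNA(rev_of))
    stop("reaction balance needs every reverse reaction present")
  tuples <- lapply(seq_len(n_reactions(g)), function(j)
    list(L = rev_of[j], R = j))
  new_balance_partition(tuples, "reaction_balanced")
}

#' @rdname reaction_balanced_partition
#' @export
complex_balanced_partition <- function(g) {
  ci <- complex_index(g)
  tuples <- lapply(seq_len(nrow(ci$complexes)), function(z)
    list(L = which(ci$product == z), R = which(ci$reactant == z)))
  new_balance_partition(tuples, "complex_balanced")
}

#' @rdname reaction_balanced_partition
#' @export
reaction_vector_balanced_partition <- function(g) {
  xi <- reaction_vectors(g)
  key <- apply(xi, 1L, paste, collapse = ",")
  rkey <- apply(-xi, 1L, paste, collapse = ",")
  seen <- character()
  tuples <- list()
  for (k in unique(key)) {
    mk <- rkey[match(k, key)]
    if (k %in% seen) next
    seen <- c(seen, k, mk)
    tuples[[length(tuples) + 1L]] <- list(L = which(key == mk),
                                          R = which(key == k))
    if (mk != k)
      tuples[[length(tuples) + 1L]] <- list(L = which(key == k),
                                            R = which(key == mk))
  }
  new_balance_partition(tuples, "reaction_vector_balanced")
}

#' @rdname reaction_balanced_partition
#' @param parts list of integer vectors of reaction indices forming a
#'   partition of the reaction set.
#' @export
partition_by_parts <- function(g, parts) {
  idx <- sort(unlist(parts))
  if (!identical(as.integer(idx), seq_len(n_reactions(g))))
    stop("parts must partition the reaction set")
  new_balance_partition(lapply(parts, function(p)
    list(L = as.integer(p), R = as.integer(p))), "per_part")
}

validate_partition <- function(g, part) {
  if (!inherits(part, "crn_balance_partition"))
    stop("partition must be a crn_balance_partition")
  m <- n_reactions(g)
  L <- sort(unlist(lapply(part$tuples, `[[`, "L")))
  R <- sort(unlist(lapply(part$tuples, `[[`, "R")))
  if (!identical(as.integer(L), seq_len(m)) ||
      !identical(as.integer(R), seq_len(m)))
    stop("tuples must partition the reaction set on both sides")
  invisible(part)
}

#' Check generalized balance of a distribution
#'
#' For every tuple `(L_i, R_i)` of the partition and every state `x` of the
#' support, verifies the restricted master equation
#' \deqn{\sum_{\nu \to \nu' \in L_i} \pi(x + \nu - \nu')
#'   \lambda_{\nu \to \nu'}(x + \nu - \nu') =
#'   \pi(x) \sum_{\nu \to \nu' \in R_i} \lambda_{\nu \to \nu'}(x),}
#' with \eqn{\pi = 0} outside the support. Generalized balance for any
#' valid partition implies stationarity.
#'
#' @inheritParams master_equation_residual
#' @param partition a `"crn_balance_partition"`.
#' @param tol absolute residual tolerance.
#' @return List with `balanced` (logical) and `residual` (max absolute
#'   imbalance over tuples and states).
#' @export
check_generalized_balance <- function(g, dist, partition, kin = NULL,
                                      tol = 1e-9) {
  kin <- resolve_kinetics(g, kin)
  validate_partition(g, partition)
  states <- dist$states
  n <- nrow(states)
  keys <- state_keys(states)
  P <- propensity_matrix(g, kin, states)
  xi <- reaction_vectors(g)
  ## per reaction: probability inflow into each state x from x + nu - nu',
  ## zero when the predecessor lies outside the support
  inflow <- matrix(0, n, n_reactions(g))
  for (j in seq_len(n_reactions(g))) {
    pred <- states - matrix(xi[j, ], n, ncol(states), byrow = TRUE)
    pidx <- match(apply(pred, 1L, paste, collapse = ","), keys)
    ok <- !is.na(pidx)
    inflow[ok, j] <- dist$p[pidx[ok]] * P[pidx[ok], j]
  }
  worst <- 0
  for (tp in partition$tuples) {
    lhs <- rowSums(inflow[, tp$L, drop = FALSE])
    rhs <- dist$p * rowSums(P[, tp$R, drop = FALSE])
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  list(balanced = worst < tol, residual = worst)
}
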