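#' Linkage classes of a reaction network
#'
#' Connected components of the (undirected) reaction graph, whose vertices
#' are the complexes and whose arrows are the reactions.
#'
#' @param g a `"crn"` object.
#' @return A list of character vectors of complex labels, one per class,
#'   with attribute `"membership"` (integer class index per complex).
#' @export
linkage_classes <- function(g) {
  ci <- complex_index(g)
  n <- nrow(ci$complexes)
  gr <- igraph::graph_from_edgelist(cbind(ci$reactant, ci$product),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  memb <- igraph::components(gr)$membership
  out <- split(rownames(ci$complexes), memb)
  names(out) <- NULL
  attr(out, "membership") <- as.integer(memb)
  out
}

## Exact rank of an integer matrix by fraction-free Gaussian elimination,
## avoiding floating-point rank decisions in the deficiency.
integer_rank <- function(m) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (!nrow(m) || !ncol(m)) return(0L)
  rank <- 0L
  row <- 1L
  for (col in seq_len(ncol(m))) {
    piv <- which(m[row:nrow(m), col] != 0)
    if (!length(piv)) next
    piv <- row + piv[1L] - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    for (r in seq_len(nrow(m))[-row]) {
      if (m[r, col] != 0) {
        m[r, ] <- m[r, ] * m[row, col] - m[row, ] * m[r, col]
        d <- max(abs(m[r, ]))
        if (d > 1e12) m[r, ] <- m[r, ] / gcd_vector(m[r, ])
      }
    }
    rank <- rank + 1L
    if (row == nrow(m)) break
    row <- row + 1L
  }
  rank
}

gcd_vector <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(function(a, b) {
    while (b > 0.5) { t <- a %% b; a <- b; b <- t }
    a
  }, v)
}

#' Reaction vectors of a network
#' @param g a `"crn"` object.
#' @return Integer matrix (reactions x species) of `product - reactant`.
#' @export
reaction_vectors <- function(g) g$product - g$reactant

#' Reversibility class of a network
#'
#' A network is reversible when every reaction has its reverse present, and
#' weakly reversible when every connected component of the reaction graph is
#' strongly connected (equivalently, every reaction lies on a directed
#' cycle).
#'
#' @param g a `"crn"` object.
#' @return `"reversible"`, `"weakly_reversible"` or `"neither"`.
#' @export
reversibility_class <- function(g) {
  if (!anyNA(match_reverse(g))) return("reversible")
  ci <- complex_index(g)
  gr <- igraph::graph_from_edgelist(cbind(ci$reactant, ci$product),
                                    directed = TRUE)
  gr <- igraph::add_vertices(gr, max(0L, nrow(ci$complexes) - igraph::vcount(gr)))
  strong <- igraph::components(gr, mode = "strong")$no
  weak <- igraph::components(gr, mode = "weak")$no
  if (strong == weak) "weakly_reversible" else "neither"
}

#' Conservation vector of a network
#'
#' Searches for a strictly positive species weighting `c` preserved by every
#' reaction, i.e. with `(product - reactant) %*% c == 0`. Feasibility is
#' decided by a linear program over `c >= 1` (positivity is scale-invariant),
#' and the floating-point solution is rounded to small rationals and
#' re-verified exactly in integer arithmetic whenever possible.
#'
#' @param g a `"crn"` object.
#' @return A positive numeric vector over species (integer-valued when an
#'   exact rational representative was found), or `NULL` when the network is
#'   not conservative.
#' @export
conservation_vector <- function(g) {
  n <- length(g$species)
  D <- reaction_vectors(g)
  if (n == 0L) return(NULL)
  if (nrow(D) == 0L || all(D == 0))
    return(stats::setNames(rep(1, n), g$species))
  ## reduce to a linearly independent set of constraints (the reaction
  ## vectors are usually highly redundant, which trips up the solver);
  ## the candidate is still verified against the full set below
  Dfull <- D
  qd <- qr(t(D))
  D <- D[qd$pivot[seq_len(qd$rank)], , drop = FALSE]
  ## substitute c = y + 1, y >= 0: D y = -D 1
  rhs <- -rowSums(D)
  A3 <- matrix(as.numeric(D), nrow(D), n)
  neg <- rhs < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  ## the harmless bound row works around a simplex() failure when only
  ## equality constraints are supplied
  sol <- tryCatch(
    boot::simplex(a = rep(1, n), A1 = matrix(1, 1, n), b1 = 1e9,
                  A3 = A3, b3 = rhs, maxi = FALSE),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved != 1) return(NULL)
  cand <- as.numeric(sol$soln) + 1
  if (max(abs(Dfull %*% cand)) > 1e-7 * max(abs(cand))) return(NULL)
  exact <- rationalize_conservation(Dfull, cand)
  if (!is.null(exact)) cand <- exact
  stats::setNames(cand, g$species)
}

## try to round a floating-point conservation vector to an exact integer one
rationalize_conservation <- function(D, cand) {
  for (den in c(1, 2, 3, 4, 6, 12, 24, 60)) {
    ci <- round(cand * den)
    if (any(ci < 1)) next
    if (max(abs(cand * den - ci)) > 1e-6 * den) next
    if (all(D %*% ci == 0)) return(ci)
  }
  NULL
}

#' Structural report of a reaction network
#'
#' Computes counts of species, complexes and linkage classes, the dimension
#' of the stoichiometric subspace (exact integer rank of the reaction
#' vectors), the deficiency `|C| - l - dim T`, the reversibility class and
#' conservativity.
#'
#' @param g a `"crn"` object.
#' @return An object of class `"crn_structure"` with fields `n_species`,
#'   `n_complexes`, `n_linkage_classes`, `stoich_dim`, `deficiency`,
#'   `reversible`, `weakly_reversible`, `conservative`,
#'   `conservation_vector`.
#' @export
structural_report <- function(g) {
  lc <- linkage_classes(g)
  rev <- reversibility_class(g)
  cons <- conservation_vector(g)
  sdim <- integer_rank(reaction_vectors(g))
  ncx <- nrow(complexes(g))
  out <- structure(list(
    n_species = length(g$species),
    n_complexes = ncx,
    n_linkage_classes = length(lc),
    stoich_dim = sdim,
    deficiency = ncx - length(lc) - sdim,
    reversible = rev == "reversible",
    weakly_reversible = rev %in% c("reversible", "weakly_reversible"),
    conservative = !is.null(cons),
    conservation_vector = cons), class = "crn_structure")
  stopifnot(out$deficiency >= 0)
  out
}

#' Deficiency of a reaction network
#' @param g a `"crn"` object.
#' @return Integer deficiency \eqn{\delta = |C| - \ell - \dim T \ge 0}.
#' @export
deficiency <- function(g) structural_report(g)$deficiency

#' @export
print.crn_structure <- function(x, ...) {
  cat(sprintf(paste0("species %d, complexes %d, linkage classes %d, ",
                     "dim T = %d, deficiency = %d\n"),
              x$n_species, x$n_complexes, x$n_linkage_classes,
              x$stoich_dim, x$deficiency))
  cat(sprintf("reversible: %s, weakly reversible: %s, conservative: %s\n",
              x$reversible, x$weakly_reversible, x$conservative))
  if (!is.null(x$conservation_vector))
    cat("conservation vector:",
        paste(format(x$conservation_vector), collapse = ", "), "\n")
  invisible(x)
}

#' Point of complex balance of a mass-action network
#'
#' A positive concentration vector `c` is a point of complex balance when,
#' at each complex, total deterministic mass-action inflow equals total
#' outflow. Kernel vectors of the kinetic Laplacian of each linkage class
#' (positive on strongly connected classes, by Perron-Frobenius) prescribe
#' the complex evaluations up to a per-class scale; `log c` then solves a
#' linear system, and the candidate is accepted only if the complex-balance
#' residual vanishes numerically.
#'
#' @param g a `"crn"` object.
#' @param tol relative residual tolerance for accepting the candidate.
#' @return A positive numeric vector over species, or `NULL` when the
#'   network admits no (numerically detectable) point of complex balance at
#'   the given rates.
#' @export
complex_balance_point <- function(g, tol = 1e-8) {
  if (reversibility_class(g) == "neither") return(NULL)
  ci <- complex_index(g)
  ncx <- nrow(ci$complexes)
  ## kinetic Laplacian: d psi / dt = A psi, psi_z = c^z
  A <- matrix(0, ncx, ncx)
  for (j in seq_len(n_reactions(g))) {
    A[ci$product[j], ci$reactant[j]] <- A[ci$product[j], ci$reactant[j]] + g$rate[j]
    A[ci$reactant[j], ci$reactant[j]] <- A[ci$reactant[j], ci$reactant[j]] - g$rate[j]
  }
  memb <- attr(linkage_classes(g), "membership")
  K <- numeric(ncx)
  for (cl in unique(memb)) {
    idx <- which(memb == cl)
    ns <- svd(A[idx, idx, drop = FALSE])
    v <- ns$v[, length(idx)]
    if (max(abs(A[idx, idx] %*% v)) > 1e-10 * max(1, max(abs(A[idx, idx]))))
      return(NULL)
    if (sum(v) < 0) v <- -v
    if (any(v <= 0)) return(NULL)
    K[idx] <- v
  }
  ## (z - z')^T log c = log K_z - log K_z' within linkage classes
  eqs <- list(); rhs <- numeric()
  for (cl in unique(memb)) {
    idx <- which(memb == cl)
    base <- idx[1]
    for (z in idx[-1]) {
      eqs[[length(eqs) + 1L]] <- ci$complexes[z, ] - ci$complexes[base, ]
      rhs <- c(rhs, log(K[z]) - log(K[base]))
    }
  }
  n <- length(g$species)
  if (!length(eqs)) return(stats::setNames(rep(1, n), g$species))
  M <- do.call(rbind, eqs)
  fit <- stats::lm.fit(M, rhs)
  logc <- fit$coefficients
  logc[is.na(logc)] <- 0
  cvec <- exp(logc)
  resid <- complex_balance_residual(g, cvec)
  if (resid > tol) return(NULL)
  stats::setNames(cvec, g$species)
}

## relative residual of the deterministic complex balance equations at c
complex_balance_residual <- function(g, cvec) {
  ci <- complex_index(g)
  psi <- apply(ci$complexes, 1L, function(z) prod(cvec^z))
  flow_in <- flow_out <- numeric(nrow(ci$complexes))
  for (j in seq_len(n_reactions(g))) {
    w <- g$rate[j] * psi[ci$reactant[j]]
    flow_out[ci$reactant[j]] <- flow_out[ci$reactant[j]] + w
    flow_in[ci$product[j]] <- flow_in[ci$product[j]] + w
  }
  max(abs(flow_in - flow_out)) / max(flow_out)
}
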