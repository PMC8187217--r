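#' Enumerate reaction bipartitions
#'
#' Every nonempty reaction subset `R1` together with its complement `R2`
#' (which may be empty) is a bipartition; there are `2^m - 1` ordered ones
#' for `m` reactions. Subsets are generated by increasing size, then
#' lexicographically, so the order is deterministic. Beyond `limit`
#' reactions the exhaustive enumeration is refused (exponential blow-up);
#' use the greedy decomposition search instead.
#'
#' @param g a `"crn"` object.
#' @param unordered drop the ordered duplicates (`{R1, R2}` as a set),
#'   halving the enumeration.
#' @param limit maximum number of reactions for exhaustive enumeration.
#' @return List of lists with integer fields `R1`, `R2`.
#' @export
enumerate_reaction_bipartitions <- function(g, unordered = FALSE,
                                            limit = 16L) {
  m <- n_reactions(g)
  if (m < 1L) stop("network has no reactions")
  if (m > limit)
    stop("refusing exhaustive enumeration for ", m,
         " reactions (limit ", limit, ")")
  out <- list()
  for (size in seq_len(m)) {
    subs <- utils::combn(m, size, simplify = FALSE)
    for (s in subs) {
      comp <- setdiff(seq_len(m), s)
      if (unordered && length(comp) && length(comp) < size) next
      if (unordered && length(comp) == size && comp[1] < s[1]) next
      out[[length(out) + 1L]] <- list(R1 = s, R2 = comp)
    }
  }
  out
}

new_decomposition <- function(g, parts) {
  structure(list(parts = parts,
                 networks = lapply(parts, function(p) subnetwork(g, p)),
                 parent = g),
            class = "crn_decomposition")
}

#' @export
print.crn_decomposition <- function(x, ...) {
  cat(sprintf("Decomposition into %d reaction-disjoint parts:\n",
              length(x$parts)))
  for (j in seq_along(x$parts)) {
    cat(sprintf("  part %d: reactions %s; species %s\n", j,
                paste(x$parts[[j]], collapse = ","),
                paste(x$networks[[j]]$species, collapse = ",")))
  }
  invisible(x)
}

## atoms of the greedy search: a reaction together with its reverse
reaction_atoms <- function(g) {
  rev_of <- match_reverse(g)
  m <- n_reactions(g)
  atom <- integer(m)
  nxt <- 0L
  for (j in seq_len(m)) {
    if (atom[j] > 0L) next
    nxt <- nxt + 1L
    atom[j] <- nxt
    if (!is.na(rev_of[j])) atom[rev_of[j]] <- nxt
  }
  split(seq_len(m), atom)
}

## greedy candidate: group reversible-pair atoms by their species support
greedy_parts <- function(g) {
  atoms <- reaction_atoms(g)
  supp <- vapply(atoms, function(idx) {
    s <- colSums(g$reactant[idx, , drop = FALSE]) +
      colSums(g$product[idx, , drop = FALSE]) > 0
    paste(which(s), collapse = ",")
  }, character(1))
  parts <- lapply(split(atoms, supp), function(a) sort(unlist(a)))
  names(parts) <- NULL
  parts[order(vapply(parts, min, integer(1)))]
}

#' Reaction-disjoint decompositions into essential parts
#'
#' Searches for partitions of the reaction set whose induced subnetworks
#' are all essential — the hypothesis under which the stationary
#' distribution of the join can be assembled from the parts. The default
#' greedy strategy groups reversible reaction pairs by their species
#' support, which finds the natural split of glued-motif networks directly;
#' the exhaustive strategy filters all unordered bipartitions and refines
#' each part recursively. Results are ranked finest first (more parts are
#' easier to solve).
#'
#' @inheritParams intensity
#' @param strategy `"greedy"`, `"exhaustive"`, or `"both"`.
#' @param max_parts recursion bound for the exhaustive refinement.
#' @param limit bipartition enumeration limit for the exhaustive strategy.
#' @return List of `"crn_decomposition"` objects (possibly empty).
#' @export
essential_decompositions <- function(g, kin = NULL,
                                     strategy = c("both", "greedy",
                                                  "exhaustive"),
                                     max_parts = 8L, limit = 16L) {
  strategy <- match.arg(strategy)
  kin <- resolve_kinetics(g, kin)
  out <- list()
  seen <- character()
  add <- function(parts) {
    parts <- lapply(parts, unname)
    parts <- parts[order(vapply(parts, min, integer(1)))]
    key <- paste(vapply(parts, paste, character(1), collapse = ","),
                 collapse = "|")
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- new_decomposition(g, parts)
  }
  ess_cache <- new.env(parent = emptyenv(), hash = TRUE)
  part_essential <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (exists(key, envir = ess_cache, inherits = FALSE))
      return(get(key, envir = ess_cache))
    sub <- subnetwork(g, idx)
    ans <- is_essential(sub, restrict_kinetics(g, kin, sub)) == "essential"
    assign(key, ans, envir = ess_cache)
    ans
  }
  if (strategy %in% c("both", "greedy")) {
    parts <- greedy_parts(g)
    if (length(parts) > 1L && all(vapply(parts, part_essential, logical(1))))
      add(parts)
  }
  if (strategy %in% c("both", "exhaustive") && n_reactions(g) <= limit) {
    refine <- function(idx, depth) {
      ## finest essential split of the reaction subset idx (itself essential)
      if (length(idx) > 1L && depth < max_parts) {
        sub <- subnetwork(g, idx)
        bps <- enumerate_reaction_bipartitions(sub, unordered = TRUE,
                                               limit = limit)
        for (bp in bps) {
          if (!length(bp$R2)) next
          a <- idx[bp$R1]; b <- idx[bp$R2]
          if (part_essential(a) && part_essential(b))
            return(c(refine(a, depth + 1L), refine(b, depth + 1L)))
        }
      }
      list(idx)
    }
    bps <- enumerate_reaction_bipartitions(g, unordered = TRUE, limit = limit)
    for (bp in bps) {
      if (!length(bp$R2)) next
      if (part_essential(bp$R1) && part_essential(bp$R2)) {
        add(list(bp$R1, bp$R2))
        add(c(refine(bp$R1, 2L), refine(bp$R2, 2L)))
      }
    }
  }
  out[order(-vapply(out, function(d) length(d$parts), integer(1)))]
}

## kinetics of a subnetwork, inherited from the parent spec
restrict_kinetics <- function(g, kin, sub) {
  k <- kin[sub$species]
  class(k) <- "crn_kinetics"
  k
}

## ---- part solvers -------------------------------------------------------

## Two-species transfer family: all jumps are +/-(e_U - e_W); reactions
## into U have exactly one W in the reactant, reactions out of U have a
## pure-U reactant. Covers the exchange motif U <-> W, 2U <-> U + W and its
## autocatalytic generalisations W + (m-1)U -> mU. The per-component
## stationary distribution is f_U(u) f_W(w) with ratios derived from the
## one-dimensional reaction-vector balance recursion.
solve_part_transfer <- function(part_g, kin, max_level) {
  if (length(part_g$species) != 2L) return(NULL)
  xi <- reaction_vectors(part_g)
  for (u in 1:2) {
    w <- 3L - u
    ju <- which(xi[, u] == 1L & xi[, w] == -1L)   # into U
    jw <- which(xi[, u] == -1L & xi[, w] == 1L)   # out of U
    if (length(ju) + length(jw) != nrow(xi)) next
    if (!length(ju) || !length(jw)) next
    if (any(part_g$reactant[ju, w] != 1L)) next
    if (any(part_g$reactant[jw, w] != 0L) || any(part_g$reactant[jw, u] < 1L))
      next
    th_u <- kin[[part_g$species[u]]]
    th_w <- kin[[part_g$species[w]]]
    kap <- part_g$rate
    mu_in <- part_g$reactant[ju, u]    # (m - 1) copies of U in the reactant
    mu_out <- part_g$reactant[jw, u]
    g_in <- function(t) {
      vapply(t, function(tt) sum(vapply(seq_along(ju), function(q) {
        m1 <- mu_in[q]
        kap[ju[q]] * (if (m1 > 0) prod(theta_eval(th_u, tt - seq_len(m1) + 1L))
                      else 1)
      }, numeric(1))), numeric(1))
    }
    g_out <- function(l) {
      vapply(l, function(ll) sum(vapply(seq_along(jw), function(q) {
        m <- mu_out[q]
        kap[jw[q]] * (if (m > 1) prod(theta_eval(th_u, ll - seq_len(m - 1L)))
                      else 1)
      }, numeric(1))), numeric(1))
    }
    ratio_u <- function(l) g_in(l - 1) / (theta_eval(th_u, l) * g_out(l))
    probe <- ratio_u(seq_len(max(1L, max_level)))
    if (any(!is.finite(probe)) || any(probe <= 0)) next
    is_motif <- nrow(xi) == 4L && setequal(mu_in, c(0L, 1L)) &&
      setequal(mu_out, c(1L, 2L))
    fs <- stats::setNames(list(
      pff(ratio_u, tag = if (is_motif) "motif" else "transfer",
          params = list(rates = kap)),
      pff_poisson(1, th_w)), part_g$species[c(u, w)])
    return(list(fs = fs, tilt_free = TRUE,
                solver = if (is_motif) "motif" else "transfer"))
  }
  NULL
}

solve_part_complex_balanced <- function(part_g, kin) {
  if (!is_mass_action(kin)) {
    ## Poisson-type forms under general kinetics require deficiency zero
    ## and weak reversibility; the complex balance point is computed from
    ## the mass-action structure (rates only).
    sr <- structural_report(part_g)
    if (!(sr$weakly_reversible && sr$deficiency == 0L)) return(NULL)
  }
  cb <- complex_balance_point(part_g)
  if (is.null(cb)) return(NULL)
  fs <- stats::setNames(lapply(seq_along(part_g$species), function(i)
    pff_poisson(cb[[i]], kin[[part_g$species[i]]])), part_g$species)
  list(fs = fs, tilt_free = !is.null(conservation_vector(part_g)),
       solver = "complex_balanced", cb_point = cb)
}

solve_part_direct_factorize <- function(part_g, kin, proj_states,
                                        max_states = 4000L) {
  if (is.null(conservation_vector(part_g))) return(NULL)
  seed <- proj_states[which.max(rowSums(proj_states)), ]
  ic <- tryCatch(irreducible_component(part_g, seed, kin,
                                       max_states = max_states),
                 error = function(e) NULL)
  if (is.null(ic) || !ic$closed) return(NULL)
  dist <- tryCatch(solve_master_direct(part_g, ic, kin),
                   error = function(e) NULL)
  if (is.null(dist)) return(NULL)
  fac <- factorize_product_form(dist)
  if (!fac$product_form) return(NULL)
  fs <- list()
  for (i in seq_along(part_g$species)) {
    tab <- fac$tables[[part_g$species[i]]]
    lev <- as.integer(tab$level)
    ord <- order(lev)
    lev <- lev[ord]
    logf <- tab$log_f[ord] - tab$log_f[ord][1]
    if (!identical(lev, seq.int(lev[1], lev[length(lev)])) || lev[1] != 0L)
      return(NULL)  # need a contiguous range anchored at zero
    lr <- diff(c(0, logf))
    fs[[part_g$species[i]]] <-
      pff(local({ lr0 <- lr; function(l) {
        if (any(l > length(lr0))) stop("level outside factorised range")
        exp(lr0[l])
      }}), tag = "table")
  }
  list(fs = fs, tilt_free = TRUE, solver = "direct_factorize")
}

## try registered solvers in order on one part
solve_part <- function(part_g, kin, proj_states) {
  max_level <- max(proj_states)
  res <- solve_part_transfer(part_g, kin, max_level)
  if (!is.null(res)) return(res)
  res <- solve_part_complex_balanced(part_g, kin)
  if (!is.null(res)) return(res)
  solve_part_direct_factorize(part_g, kin, proj_states)
}

## ---- matching and assembly ----------------------------------------------

## constant ratio r_j(l) / r_k(l) over l = 1..L, or NULL if not constant
constant_ratio <- function(fj, fk, L, tol = 1e-10) {
  l <- seq_len(L)
  q <- pff_ratio(fj, l) / pff_ratio(fk, l)
  if (any(!is.finite(q))) return(NULL)
  if (max(q) - min(q) > tol * max(abs(q))) return(NULL)
  q[1]
}

#' Assemble the stationary distribution of a join from its parts
#'
#' Given a reaction-disjoint decomposition whose parts each carry
#' product-form functions on the projections of the component, the
#' functions of species shared between parts must be proportional
#' (per-species positive constants are allowed). Conservative parts carry a
#' free exponential tilt `d`; the assembly solves for one tilt per part so
#' that all shared-species ratio sequences coincide exactly, refuses when
#' no such tilts exist (the proportionality hypothesis fails), and
#' otherwise normalises \eqn{\pi(x) \propto \prod_i f_i(x_i)} over the
#' component and verifies generalized balance with the per-part partition
#' \eqn{\{(R_j, R_j)\}_j}.
#'
#' @param g the joined `"crn"`.
#' @param dec a `"crn_decomposition"` of `g`.
#' @param part_forms list (one per part) of lists with fields `fs` (named
#'   list of [pff()] functions over the part's species) and `tilt_free`
#'   (logical: does the part admit a free tilt, i.e. is it conservative).
#' @param comp a `"crn_component"` of `g`.
#' @param kin optional kinetics.
#' @param force assemble even when matching fails (for demonstrating that
#'   the naive product then violates the master equation).
#' @param match_tol relative tolerance of the exact ratio matching.
#' @param verify_tol tolerance of the generalized-balance verification.
#' @return A `"crn_distribution"` with attributes `tilts` (per part),
#'   `balance` (generalized-balance check) and `summability`; or an object
#'   of class `"crn_refusal"` describing the failed matching condition.
#' @export
assemble_stationary <- function(g, dec, part_forms, comp, kin = NULL,
                                force = FALSE, match_tol = 1e-10,
                                verify_tol = 1e-9) {
  kin <- resolve_kinetics(g, kin)
  np <- length(dec$parts)
  stopifnot(length(part_forms) == np)
  states <- comp$states
  maxs <- apply(states, 2L, max)
  part_species <- lapply(dec$networks, `[[`, "species")
  tilt_free <- vapply(part_forms, `[[`, logical(1), "tilt_free")
  ## shared-species edges between parts
  edges <- list()
  if (np > 1L) for (j in seq_len(np - 1L)) for (k in seq.int(j + 1L, np)) {
    sh <- intersect(part_species[[j]], part_species[[k]])
    if (length(sh)) edges[[length(edges) + 1L]] <- list(j = j, k = k, sh = sh)
  }
  d <- rep(NA_real_, np)
  refusal <- NULL
  edge_ratio <- function(e) {
    ## required tilt quotient d_k / d_j, identical across shared species
    t_all <- vapply(e$sh, function(s) {
      L <- max(1L, maxs[[match(s, g$species)]])
      r <- constant_ratio(part_forms[[e$j]]$fs[[s]],
                          part_forms[[e$k]]$fs[[s]], L, match_tol)
      if (is.null(r)) NA_real_ else r
    }, numeric(1))
    if (anyNA(t_all)) return(NULL)
    if (max(t_all) - min(t_all) > match_tol * max(t_all)) return(NULL)
    t_all[[1]]
  }
  ## propagate tilts over each connected block of the part graph
  adj <- lapply(seq_len(np), function(j) integer())
  for (ei in seq_along(edges)) {
    e <- edges[[ei]]
    adj[[e$j]] <- c(adj[[e$j]], ei)
    adj[[e$k]] <- c(adj[[e$k]], ei)
  }
  for (blockseed in seq_len(np)) {
    if (!is.na(d[blockseed])) next
    ## prefer rooting at a part without tilt freedom: its d is pinned to 1
    block <- block_members(blockseed, adj, edges, np)
    root <- block[which(!tilt_free[block])[1]]
    if (is.na(root)) root <- block[1]
    d[root] <- 1
    queue <- root
    while (length(queue) && is.null(refusal)) {
      j <- queue[1]; queue <- queue[-1]
      for (ei in adj[[j]]) {
        e <- edges[[ei]]
        other <- if (e$j == j) e$k else e$j
        t <- edge_ratio(e)
        if (is.null(t)) {
          refusal <- sprintf(
            "shared species %s between parts %d and %d: product-form functions are not proportional",
            paste(e$sh, collapse = ","), e$j, e$k)
          break
        }
        need <- if (e$j == j) d[j] * t else d[j] / t
        if (is.na(d[other])) {
          if (!tilt_free[other] && abs(need - 1) > 1e-8) {
            refusal <- sprintf(
              "part %d admits no free tilt but matching requires d = %g",
              other, need)
            break
          }
          d[other] <- need
          queue <- c(queue, other)
        } else if (abs(d[other] - need) > 1e-8 * max(d[other], need)) {
          refusal <- sprintf(
            "inconsistent tilts for part %d (%g vs %g)", other, d[other], need)
          break
        }
      }
    }
    if (!is.null(refusal) && !force) break
  }
  if (!is.null(refusal) && !force) {
    return(structure(list(message = refusal, tilts = d),
                     class = "crn_refusal"))
  }
  d[is.na(d)] <- 1
  fs <- list()
  for (i in seq_along(g$species)) {
    sp <- g$species[i]
    owner <- which(vapply(part_species, function(s) sp %in% s, logical(1)))[1]
    fs[[sp]] <- pff_tilt(part_forms[[owner]]$fs[[sp]], d[owner])
  }
  dist <- product_form_distribution(g, fs, comp)
  bal <- check_generalized_balance(
    g, dist, partition_by_parts(g, dec$parts), kin, tol = verify_tol)
  dist$residual <- master_equation_residual(g, dist, kin)
  attr(dist, "tilts") <- d
  attr(dist, "balance") <- bal
  attr(dist, "forced") <- !is.null(refusal)
  attr(dist, "summability") <-
    if (!comp$truncated) "summable"
    else ratio_test_summability(fs, finite = FALSE)
  dist
}

block_members <- function(seed, adj, edges, np) {
  seen <- logical(np)
  seen[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    j <- queue[1]; queue <- queue[-1]
    for (ei in adj[[j]]) {
      e <- edges[[ei]]
      other <- if (e$j == j) e$k else e$j
      if (!seen[other]) { seen[other] <- TRUE; queue <- c(queue, other) }
    }
  }
  which(seen)
}

#' @export
print.crn_refusal <- function(x, ...) {
  cat("Assembly refused:", x$message, "\n")
  invisible(x)
}

#' Solve for a stationary distribution via decomposition
#'
#' Driver: searches for a reaction-disjoint decomposition into essential
#' parts, solves each part by the first applicable registered solver
#' (two-species exchange/transfer motifs; Poisson form at a point of
#' complex balance; direct solve plus factorisation for small conservative
#' parts), matches the shared-species functions by tuning the free tilts,
#' assembles and verifies. Falls back to a direct master-equation solve on
#' finite components when no solvable decomposition exists.
#'
#' @inheritParams assemble_stationary
#' @param strategy decomposition search strategy: `"auto"` (greedy, with a
#'   bounded exhaustive fallback), or as in [essential_decompositions()].
#' @param exhaustive_limit largest reaction count for which the `"auto"`
#'   strategy falls back to exhaustive bipartition search.
#' @param fallback_direct solve directly when decomposition fails.
#' @return List with `dist` (a `"crn_distribution"` or `NULL`) and
#'   `provenance` (method, parts, solvers, tilts, residuals, refusals).
#' @export
solve_by_decomposition <- function(g, comp, kin = NULL,
                                   strategy = c("auto", "greedy",
                                                "exhaustive", "both"),
                                   exhaustive_limit = 12L,
                                   fallback_direct = TRUE) {
  strategy <- match.arg(strategy)
  kin <- resolve_kinetics(g, kin)
  decs <- if (strategy == "auto") {
    ## greedy first; the exponential search only when it finds nothing
    d <- essential_decompositions(g, kin, strategy = "greedy")
    if (!length(d) && n_reactions(g) <= exhaustive_limit)
      d <- essential_decompositions(g, kin, strategy = "exhaustive",
                                    limit = exhaustive_limit)
    d
  } else {
    essential_decompositions(g, kin, strategy = strategy)
  }
  ## the trivial one-part decomposition: the network itself, when essential,
  ## may be directly solvable by a registered closed form
  if (is_essential(g, kin) == "essential")
    decs <- c(decs, list(new_decomposition(g, list(seq_len(n_reactions(g))))))
  refusals <- character()
  for (dec in decs) {
    part_forms <- vector("list", length(dec$parts))
    ok <- TRUE
    for (j in seq_along(dec$parts)) {
      part_g <- dec$networks[[j]]
      proj <- project_states(comp$states, g, part_g$species)
      res <- solve_part(part_g, restrict_kinetics(g, kin, part_g), proj)
      if (is.null(res)) { ok <- FALSE; break }
      part_forms[[j]] <- res
    }
    if (!ok) next
    dist <- assemble_stationary(g, dec, part_forms, comp, kin)
    if (inherits(dist, "crn_refusal")) {
      refusals <- c(refusals, dist$message)
      next
    }
    return(list(dist = dist, provenance = list(
      method = "decomposition",
      parts = dec$parts,
      part_species = lapply(dec$networks, `[[`, "species"),
      solvers = vapply(part_forms, `[[`, character(1), "solver"),
      tilts = attr(dist, "tilts"),
      balance_residual = attr(dist, "balance")$residual,
      master_residual = dist$residual,
      summability = attr(dist, "summability"),
      refusals = refusals)))
  }
  if (fallback_direct && !comp$truncated && comp$closed) {
    dist <- solve_master_direct(g, comp, kin)
    return(list(dist = dist, provenance = list(
      method = "direct", refusals = refusals)))
  }
  list(dist = NULL, provenance = list(method = "undecomposable",
                                      refusals = refusals))
}
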