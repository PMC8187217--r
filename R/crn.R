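#' Reaction networks
#'
#' A reaction network is a triple of species, complexes and reactions.
#' Complexes are nonnegative integer combinations of species; every reaction
#' converts one complex into a distinct complex at a positive rate.
#'
#' Internally a network is stored as a list with components
#' \describe{
#'   \item{species}{character vector, species in order of first appearance}
#'   \item{reactant, product}{integer matrices (reactions x species) of
#'     stoichiometric coefficients}
#'   \item{rate}{positive numeric vector of rate constants}
#'   \item{kinetics}{optional [kinetics_spec()]; `NULL` means mass-action}
#' }
#'
#' @param species character vector of species names.
#' @param reactant,product integer matrices with one row per reaction and one
#'   column per species.
#' @param rate numeric vector of positive rate constants.
#' @param kinetics optional kinetics specification, see [kinetics_spec()].
#' @return An object of class `"crn"`.
#' @export
reaction_network <- function(species, reactant, product, rate, kinetics = NULL) {
  species <- as.character(species)
  reactant <- as.matrix(reactant)
  product <- as.matrix(product)
  storage.mode(reactant) <- "integer"
  storage.mode(product) <- "integer"
  if (ncol(reactant) != length(species) || ncol(product) != length(species))
    stop("stoichiometry matrices must have one column per species")
  if (nrow(reactant) != nrow(product) || nrow(reactant) != length(rate))
    stop("reactant, product and rate must describe the same reactions")
  if (any(reactant < 0) || any(product < 0))
    stop("stoichiometric coefficients must be nonnegative")
  if (length(rate) && (any(!is.finite(rate)) || any(rate <= 0)))
    stop("all rate constants must be positive")
  same <- which(rowSums(reactant != product) == 0L)
  if (length(same))
    stop("reactant equals product in reaction ", same[1])
  colnames(reactant) <- colnames(product) <- species
  g <- structure(
    list(species = species, reactant = reactant, product = product,
         rate = as.numeric(rate), kinetics = kinetics),
    class = "crn")
  merge_duplicate_reactions(g)
}

## Duplicate reactions (same reactant and product complex) are merged by
## summing their rates, matching the rate rule for gluing over reactions.
merge_duplicate_reactions <- function(g, warn = TRUE) {
  if (nrow(g$reactant) < 2L) return(g)
  key <- paste(apply(g$reactant, 1L, paste, collapse = ","),
               apply(g$product, 1L, paste, collapse = ","), sep = ">")
  if (!anyDuplicated(key)) return(g)
  if (warn) warning("duplicate reactions merged with summed rates")
  keep <- !duplicated(key)
  rate <- as.numeric(tapply(g$rate, factor(key, levels = key[keep]), sum))
  g$reactant <- g$reactant[keep, , drop = FALSE]
  g$product <- g$product[keep, , drop = FALSE]
  g$rate <- rate
  g
}

#' Number of reactions of a network
#' @param g a `"crn"` object.
#' @return Integer.
#' @export
n_reactions <- function(g) nrow(g$reactant)

#' Complexes of a network
#'
#' @param g a `"crn"` object.
#' @return Integer matrix of distinct complexes (rows), in order of first
#'   appearance as reactant then product, with rownames their labels.
#' @export
complexes <- function(g) {
  all <- rbind(g$reactant, g$product)
  key <- apply(all, 1L, paste, collapse = ",")
  cx <- all[!duplicated(key), , drop = FALSE]
  rownames(cx) <- apply(cx, 1L, format_complex, species = g$species)
  cx
}

## "2 S1 + S2" style label; the empty complex prints as "0".
format_complex <- function(coeffs, species) {
  nz <- which(coeffs > 0)
  if (!length(nz)) return("0")
  paste(ifelse(coeffs[nz] == 1L, species[nz],
               paste(coeffs[nz], species[nz])), collapse = " + ")
}

## index of each reaction's reactant/product in the complex matrix
complex_index <- function(g) {
  cx <- complexes(g)
  ckey <- apply(cx, 1L, paste, collapse = ",")
  list(
    complexes = cx,
    reactant = match(apply(g$reactant, 1L, paste, collapse = ","), ckey),
    product = match(apply(g$product, 1L, paste, collapse = ","), ckey))
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d complexes, %d reactions\n",
              length(x$species), nrow(complexes(x)), n_reactions(x)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (j in seq_len(n_reactions(x))) {
    cat(sprintf("  %s -> %s ; rate=%g\n",
                format_complex(x$reactant[j, ], x$species),
                format_complex(x$product[j, ], x$species), x$rate[j]))
  }
  if (!is.null(x$kinetics)) {
    nm <- !vapply(x$kinetics, function(k) k$type == "mass_action", logical(1))
    if (any(nm))
      cat("kinetics:", paste(names(x$kinetics)[nm], collapse = ", "),
          "non-mass-action\n")
  }
  invisible(x)
}

#' Parse a reaction network from reaction-list text
#'
#' One reaction per line, e.g. `"S1 -> S2 ; rate=1.0"` or
#' `"2 S1 <-> S1 + S2 ; rates=0.3,0.4"`. The zero complex is written `0`
#' (or the empty-set symbol). Lines starting with `#` are comments. Optional
#' kinetics lines have the form `kinetics: S1 = hill_I(m=1, k=2)`,
#' `kinetics: S2 = hill_II(m=2, k1=1, k2=3)` or `kinetics: S1 = mass_action`.
#' Species are ordered by first appearance; reversible (`<->`) lines expand
#' into two reactions.
#'
#' @param text character: either a single file path or the lines themselves.
#' @return A `"crn"` object.
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && !grepl("->", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  species <- character()
  rows <- list()
  kin_lines <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (grepl("^kinetics\\s*:", raw)) {
      kin_lines[[length(kin_lines) + 1L]] <- list(line = ln, text = raw)
      next
    }
    parts <- strsplit(raw, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", ln, ": expected '<reaction> ; rate=...'")
    lhsrhs <- parts[1]
    rev <- grepl("<->", lhsrhs, fixed = TRUE)
    sides <- strsplit(lhsrhs, if (rev) "<->" else "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) stop("line ", ln, ": malformed reaction arrow")
    lhs <- parse_complex(sides[1], ln)
    rhs <- parse_complex(sides[2], ln)
    for (s in c(names(lhs), names(rhs)))
      if (!(s %in% species)) species <- c(species, s)
    spec <- trimws(parts[2])
    if (rev) {
      m <- regmatches(spec, regexec("^rates\\s*=\\s*([^,]+),(.+)$", spec))[[1]]
      if (length(m) != 3L) stop("line ", ln, ": expected 'rates=<fwd>,<rev>'")
      r <- suppressWarnings(as.numeric(trimws(m[2:3])))
    } else {
      m <- regmatches(spec, regexec("^rate\\s*=\\s*(.+)$", spec))[[1]]
      if (length(m) != 2L) stop("line ", ln, ": expected 'rate=<r>'")
      r <- suppressWarnings(as.numeric(trimws(m[2])))
    }
    if (any(is.na(r)) || any(r <= 0))
      stop("line ", ln, ": rate constants must be positive numbers")
    if (identical(lhs, rhs))
      stop("line ", ln, ": reactant equals product")
    rows[[length(rows) + 1L]] <- list(lhs = lhs, rhs = rhs, rate = r[1])
    if (rev)
      rows[[length(rows) + 1L]] <- list(lhs = rhs, rhs = lhs, rate = r[2])
  }
  if (!length(rows)) stop("no reactions found")
  n <- length(species)
  reactant <- matrix(0L, length(rows), n)
  product <- matrix(0L, length(rows), n)
  for (j in seq_along(rows)) {
    reactant[j, match(names(rows[[j]]$lhs), species)] <- rows[[j]]$lhs
    product[j, match(names(rows[[j]]$rhs), species)] <- rows[[j]]$rhs
  }
  kin <- NULL
  if (length(kin_lines)) {
    kin <- default_kinetics(species)
    for (kl in kin_lines) {
      m <- regmatches(kl$text,
        regexec("^kinetics\\s*:\\s*(\\S+)\\s*=\\s*(.+)$", kl$text))[[1]]
      if (length(m) != 3L) stop("line ", kl$line, ": malformed kinetics line")
      sp <- m[2]
      if (!(sp %in% species))
        stop("line ", kl$line, ": unknown species '", sp, "'")
      kin[[sp]] <- parse_theta(trimws(m[3]), kl$line)
    }
    class(kin) <- "crn_kinetics"
  }
  reaction_network(species, reactant, product,
                   vapply(rows, `[[`, numeric(1), "rate"), kinetics = kin)
}

## parse one side of a reaction, returning a named integer vector
parse_complex <- function(txt, line) {
  txt <- trimws(txt)
  if (!nzchar(txt))
    stop("line ", line, ": empty complex (write the zero complex as '0')")
  if (txt %in% c("0", "∅", "Ø")) return(stats::setNames(integer(), character()))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- integer()
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(m) != 3L)
      stop("line ", line, ": cannot parse complex term '", tm, "'")
    k <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    sp <- m[3]
    out[sp] <- if (sp %in% names(out)) out[[sp]] + k else k
  }
  out[out > 0L]
}

#' Write a network in the reaction-list text format
#'
#' Reversible reaction pairs are recombined into `<->` lines; the output
#' round-trips through [parse_network()].
#'
#' @param g a `"crn"` object.
#' @param path optional file path; if `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when writing to a file.
#' @export
write_network <- function(g, path = NULL) {
  m <- n_reactions(g)
  done <- logical(m)
  lines <- character()
  rev_of <- match_reverse(g)
  for (j in seq_len(m)) {
    if (done[j]) next
    lhs <- format_complex(g$reactant[j, ], g$species)
    rhs <- format_complex(g$product[j, ], g$species)
    k <- rev_of[j]
    if (!is.na(k) && !done[k]) {
      lines <- c(lines, sprintf("%s <-> %s ; rates=%.17g,%.17g", lhs, rhs,
                                g$rate[j], g$rate[k]))
      done[c(j, k)] <- TRUE
    } else {
      lines <- c(lines, sprintf("%s -> %s ; rate=%.17g", lhs, rhs,
                                g$rate[j]))
      done[j] <- TRUE
    }
  }
  if (!is.null(g$kinetics)) {
    for (sp in names(g$kinetics)) {
      k <- g$kinetics[[sp]]
      if (k$type == "mass_action") next
      lines <- c(lines, sprintf("kinetics: %s = %s", sp, format_theta(k)))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

## index of the reverse reaction of each reaction, NA if absent
match_reverse <- function(g) {
  key <- paste(apply(g$reactant, 1L, paste, collapse = ","),
               apply(g$product, 1L, paste, collapse = ","), sep = ">")
  rkey <- paste(apply(g$product, 1L, paste, collapse = ","),
                apply(g$reactant, 1L, paste, collapse = ","), sep = ">")
  match(rkey, key)
}

#' Union (join) of two reaction networks
#'
#' Species, complexes and reactions are combined by set union. A reaction
#' present in both networks ("gluing over reactions") appears once with the
#' sum of the two rates; otherwise the union is reaction-disjoint and keeps
#' all rates unchanged.
#'
#' @param g1,g2 `"crn"` objects.
#' @return A `"crn"` object with attribute `"reaction_disjoint"` (logical)
#'   indicating whether the inputs had no reaction in common.
#' @export
network_union <- function(g1, g2) {
  species <- c(g1$species, setdiff(g2$species, g1$species))
  lift <- function(g) {
    r <- matrix(0L, n_reactions(g), length(species))
    p <- matrix(0L, n_reactions(g), length(species))
    idx <- match(g$species, species)
    r[, idx] <- g$reactant
    p[, idx] <- g$product
    list(r = r, p = p)
  }
  a <- lift(g1); b <- lift(g2)
  reactant <- rbind(a$r, b$r)
  product <- rbind(a$p, b$p)
  rate <- c(g1$rate, g2$rate)
  key <- paste(apply(reactant, 1L, paste, collapse = ","),
               apply(product, 1L, paste, collapse = ","), sep = ">")
  disjoint <- !any(key[seq_len(n_reactions(g1))] %in%
                     key[-seq_len(n_reactions(g1))])
  kin <- union_kinetics(g1, g2, species)
  g <- suppressWarnings(
    reaction_network(species, reactant, product, rate, kinetics = kin))
  attr(g, "reaction_disjoint") <- disjoint
  g
}

union_kinetics <- function(g1, g2, species) {
  if (is.null(g1$kinetics) && is.null(g2$kinetics)) return(NULL)
  kin <- default_kinetics(species)
  for (g in list(g1, g2)) {
    if (is.null(g$kinetics)) next
    for (sp in names(g$kinetics)) {
      k <- g$kinetics[[sp]]
      if (k$type == "mass_action") next
      old <- kin[[sp]]
      if (old$type != "mass_action" && !identical(old[c("type", "params")],
                                                  k[c("type", "params")]))
        stop("conflicting kinetics for species ", sp, " in union")
      kin[[sp]] <- k
    }
  }
  class(kin) <- "crn_kinetics"
  kin
}

#' Restrict a network to a subset of its reactions
#'
#' The subnetwork keeps only the species that occur in the selected
#' reactions (in the parent's order) and inherits rates and kinetics
#' unchanged.
#'
#' @param g a `"crn"` object.
#' @param idx integer vector of reaction indices.
#' @return A `"crn"` object.
#' @export
subnetwork <- function(g, idx) {
  idx <- sort(unique(as.integer(idx)))
  r <- g$reactant[idx, , drop = FALSE]
  p <- g$product[idx, , drop = FALSE]
  keep <- colSums(r) + colSums(p) > 0
  kin <- g$kinetics
  if (!is.null(kin)) {
    kin <- kin[g$species[keep]]
    class(kin) <- "crn_kinetics"
  }
  reaction_network(g$species[keep], r[, keep, drop = FALSE],
                   p[, keep, drop = FALSE], g$rate[idx], kinetics = kin)
}
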