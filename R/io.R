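#' JSON serialisation of reaction networks
#'
#' @param g a `"crn"` object.
#' @return `network_to_json()`: a JSON string with fields `species` and
#'   `reactions` (each with sparse `reactant`/`product` coefficient maps
#'   and `rate`).
#' @export
network_to_json <- function(g) {
  reactions <- lapply(seq_len(n_reactions(g)), function(j) {
    list(reactant = complex_map(g$reactant[j, ], g$species),
         product = complex_map(g$product[j, ], g$species),
         rate = g$rate[j])
  })
  jsonlite::toJSON(list(species = g$species, reactions = reactions),
                   auto_unbox = TRUE, digits = NA)
}

complex_map <- function(coeffs, species) {
  nz <- which(coeffs > 0)
  stats::setNames(as.list(as.integer(coeffs[nz])), species[nz])
}

#' @rdname network_to_json
#' @param json a JSON string or file path produced by `network_to_json()`.
#' @export
network_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  species <- unlist(obj$species)
  m <- length(obj$reactions)
  reactant <- matrix(0L, m, length(species))
  product <- matrix(0L, m, length(species))
  rate <- numeric(m)
  for (j in seq_len(m)) {
    r <- obj$reactions[[j]]
    for (sp in names(r$reactant))
      reactant[j, match(sp, species)] <- as.integer(r$reactant[[sp]])
    for (sp in names(r$product))
      product[j, match(sp, species)] <- as.integer(r$product[[sp]])
    rate[j] <- as.numeric(r$rate)
  }
  reaction_network(species, reactant, product, rate)
}

#' Export an irreducible component as JSON
#' @param comp a `"crn_component"`.
#' @return JSON string with the state list and closure flags.
#' @export
component_to_json <- function(comp) {
  jsonlite::toJSON(list(
    states = unname(apply(comp$states, 1L, as.integer, simplify = FALSE)),
    closed = comp$closed, truncated = comp$truncated,
    seed = as.integer(comp$seed)), auto_unbox = TRUE, digits = NA)
}

#' Export a distribution as a TSV table
#'
#' One row per state: the state coordinates (one column per species) and
#' its probability.
#'
#' @param dist a `"crn_distribution"`.
#' @param path optional output file; if `NULL` the data frame is returned.
#' @return Data frame, invisibly when written to a file.
#' @export
distribution_to_tsv <- function(dist, path = NULL) {
  df <- as.data.frame(dist$states)
  names(df) <- dist$species
  df$probability <- dist$p
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(df))
  }
  df
}

#' @rdname distribution_to_tsv
#' @param max_level tabulate product-form ratios up to this level.
#' @return `distribution_to_json()`: JSON string; product-form
#'   distributions include per-species ratio tables and the normalising
#'   constant.
#' @export
distribution_to_json <- function(dist, max_level = NULL) {
  out <- list(
    form = dist$form,
    species = dist$species,
    states = unname(apply(dist$states, 1L, as.integer, simplify = FALSE)),
    probability = dist$p,
    residual = if (is.na(dist$residual)) NULL else dist$residual)
  if (identical(dist$form, "product")) {
    if (is.null(max_level)) max_level <- max(dist$states)
    out$log_Z <- dist$logZ
    out$ratios <- lapply(dist$fs, function(f)
      as.numeric(pff_ratio(f, seq_len(max(1L, max_level)))))
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}
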