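#' Generate benchmark reaction networks with known answers
#'
#' Builds named reference networks (the worked examples: the reversible
#' three-species deficiency-two network, the gene-expression motif, the
#' detailed-balance counterexample, and so on) and randomised families of
#' glued exchange motifs, together with the structural and distributional
#' ground truth that is known for each.
#'
#' Kinds:
#' \describe{
#'   \item{`example1`}{`S1 <-> S2 <-> S3`, `2S1 <-> S1+S2`, `2S3 <-> S2+S3`;
#'     reversible, deficiency 2, conservative; product-form stationary
#'     distribution assembled from its two exchange motifs. `params$rates`
#'     optionally gives the 8 rate constants `k1..k8`.}
#'   \item{`motif`}{the two-species exchange motif `U <-> W`,
#'     `2U <-> U+W`; `params$rates` gives `k1..k4`.}
#'   \item{`motif_chain`}{`params$length` motifs glued over one common fast
#'     species, rates drawn log-uniformly from `[0.1, 10]`; conservative,
#'     assembles for every draw.}
#'   \item{`eq15`}{autocatalytic two-species family `S1 <-> S2` plus
#'     `S2 + (m-1) S1 -> m S1` for each `m` in `params$m` (default `c(2, 3)`).}
#'   \item{`birth_death`}{`0 <-> S2` with rates `kp`, `km`: complex
#'     balanced, Poisson(c = kp/km) stationary law.}
#'   \item{`three_molecular`}{`3 S3 <-> 3 S5`: complex balanced,
#'     conservative.}
#'   \item{`remark4`}{`2A <-> A+B`, `A+2B <-> 3B`: deficiency 1, each part
#'     detailed balanced.}
#'   \item{`remark7`}{`X -> Y`, `3Y -> 3X` joined with `0 <-> W`.}
#'   \item{`remark8`}{gene expression `0 <-> S1`, `S2 -> 0`,
#'     `S1 -> S1+S2`: essential but with no essential bipartition.}
#'   \item{`remark13`}{`S0 -> S1 <-> S2 <-> S3`: not essential.}
#'   \item{`remark16b4`}{exchange motif joined with `0 <-> S2`; infinite
#'     components, summable for all positive rates.}
#'   \item{`example5`}{two open motif-plus-exchange branches sharing `S1`;
#'     assembles only when the branch parameters match.}
#'   \item{`disjoint_union`}{two exchange motifs on disjoint species.}
#' }
#'
#' @param kind fixture name, see Details.
#' @param params list of fixture parameters.
#' @param seed integer seed for randomised fixtures.
#' @return A list with `network` (a `"crn"`), and where known `truth`
#'   (structural ground truth) and `product_form` (named list of [pff()]
#'   functions for an assembled stationary distribution with all free
#'   tilts at 1).
#' @export
generate_fixture <- function(kind, params = list(), seed = 1L) {
  switch(kind,
    example1 = fixture_example1(params),
    motif = fixture_motif(params),
    motif_chain = fixture_motif_chain(params, seed),
    eq15 = fixture_eq15(params),
    birth_death = fixture_birth_death(params),
    three_molecular = fixture_three_molecular(params),
    remark4 = fixture_simple(
      c("2 A <-> A + B ; rates=1,1", "A + 2 B <-> 3 B ; rates=1,1"),
      truth = list(deficiency = 1L, reversible = TRUE, essential = TRUE,
                   conservative = TRUE, n_linkage_classes = 2L)),
    remark7 = fixture_simple(
      c("X -> Y ; rate=1", "3 Y -> 3 X ; rate=1", "0 <-> W ; rates=1,1"),
      truth = list(essential = FALSE)),
    remark8 = fixture_simple(
      c("0 <-> S1 ; rates=1,1", "S2 -> 0 ; rate=1", "S1 -> S1 + S2 ; rate=1"),
      truth = list(essential = TRUE, conservative = FALSE)),
    remark13 = fixture_simple(
      c("S0 -> S1 ; rate=1", "S1 <-> S2 ; rates=1,1",
        "S2 <-> S3 ; rates=1,1"),
      truth = list(essential = FALSE, reversible = FALSE)),
    remark16b4 = fixture_remark16b4(params),
    example5 = fixture_example5(params),
    disjoint_union = fixture_disjoint_union(params),
    stop("unknown fixture kind '", kind, "'"))
}

fixture_simple <- function(lines, truth = list()) {
  list(network = parse_network(lines), truth = truth)
}

motif_lines <- function(u, w, k) {
  c(sprintf("%s <-> %s ; rates=%.17g,%.17g", u, w, k[1], k[2]),
    sprintf("2 %s <-> %s + %s ; rates=%.17g,%.17g", u, u, w, k[3], k[4]))
}

fixture_motif <- function(params) {
  k <- params$rates %||% c(1, 1, 1, 1)
  stopifnot(length(k) == 4L, all(k > 0))
  g <- parse_network(motif_lines("S1", "S2", k))
  pf <- motif_product_form(k[1], k[2], k[3], k[4])
  list(network = g,
       truth = list(deficiency = 1L, reversible = TRUE, essential = TRUE,
                    conservative = TRUE),
       product_form = list(S1 = pf$f_slow, S2 = pf$f_fast),
       rates = k)
}

fixture_example1 <- function(params) {
  k <- params$rates %||% rep(1, 8)
  stopifnot(length(k) == 8L, all(k > 0))
  g <- parse_network(c(
    sprintf("S1 <-> S2 ; rates=%.17g,%.17g", k[1], k[2]),
    sprintf("S2 <-> S3 ; rates=%.17g,%.17g", k[5], k[6]),
    sprintf("2 S1 <-> S1 + S2 ; rates=%.17g,%.17g", k[3], k[4]),
    sprintf("2 S3 <-> S2 + S3 ; rates=%.17g,%.17g", k[7], k[8])))
  pf1 <- motif_product_form(k[1], k[2], k[3], k[4])
  pf2 <- motif_product_form(k[6], k[5], k[7], k[8])
  list(network = g,
       truth = list(deficiency = 2L, reversible = TRUE, essential = TRUE,
                    conservative = TRUE, n_linkage_classes = 3L),
       product_form = list(S1 = pf1$f_slow, S2 = pf1$f_fast,
                           S3 = pf2$f_slow),
       rates = k)
}

fixture_motif_chain <- function(params, seed) {
  L <- params$length %||% 3L
  stopifnot(L >= 1L)
  set.seed(seed)
  rates <- matrix(exp(stats::runif(4L * L, log(0.1), log(10))), nrow = L)
  lines <- character()
  pfs <- list()
  for (j in seq_len(L)) {
    u <- paste0("U", j)
    lines <- c(lines, motif_lines(u, "S2", rates[j, ]))
    pf <- motif_product_form(rates[j, 1], rates[j, 2],
                             rates[j, 3], rates[j, 4])
    pfs[[u]] <- pf$f_slow
  }
  pfs[["S2"]] <- pff_poisson(1)
  g <- parse_network(lines)
  list(network = g,
       truth = list(reversible = TRUE, essential = TRUE,
                    conservative = TRUE),
       product_form = pfs[g$species],
       rates = rates)
}

fixture_eq15 <- function(params) {
  ms <- params$m %||% c(2L, 3L)
  k12 <- params$k12 %||% 1
  k21 <- params$k21 %||% 1
  km <- params$km %||% rep(1, length(ms))
  lines <- c(sprintf("S1 <-> S2 ; rates=%.17g,%.17g", k12, k21))
  for (i in seq_along(ms)) {
    m <- ms[i]
    lhs <- if (m >= 2) sprintf("S2 + %d S1", m - 1L) else "S2"
    lines <- c(lines, sprintf("%s -> %d S1 ; rate=%.17g", lhs, m, km[i]))
  }
  list(network = parse_network(lines),
       truth = list(essential = TRUE, conservative = TRUE,
                    reversible = FALSE))
}

fixture_birth_death <- function(params) {
  kp <- params$kp %||% 2
  km <- params$km %||% 1
  g <- parse_network(sprintf("0 <-> S2 ; rates=%.17g,%.17g", kp, km))
  list(network = g,
       truth = list(deficiency = 0L, reversible = TRUE, essential = TRUE,
                    conservative = FALSE),
       cb_point = c(S2 = kp / km),
       product_form = list(S2 = pff_poisson(kp / km)))
}

fixture_three_molecular <- function(params) {
  kf <- params$kf %||% 1
  kr <- params$kr %||% 2
  g <- parse_network(sprintf("3 S3 <-> 3 S5 ; rates=%.17g,%.17g", kf, kr))
  c3 <- 1
  c5 <- (kf / kr)^(1 / 3)
  list(network = g,
       truth = list(deficiency = 0L, reversible = TRUE, essential = TRUE,
                    conservative = TRUE),
       cb_point = c(S3 = c3, S5 = c5),
       product_form = list(S3 = pff_poisson(c3), S5 = pff_poisson(c5)))
}

fixture_remark16b4 <- function(params) {
  k <- params$rates %||% c(1, 2, 3, 4)
  kp <- params$kp %||% 2
  km <- params$km %||% 1
  g <- parse_network(c(motif_lines("S1", "S2", k),
                       sprintf("0 <-> S2 ; rates=%.17g,%.17g", kp, km)))
  c2 <- kp / km
  pf <- motif_product_form(k[1], k[2], k[3], k[4], d = c2)
  list(network = g,
       truth = list(essential = TRUE, conservative = FALSE,
                    reversible = TRUE),
       product_form = list(S1 = pf$f_slow, S2 = pff_poisson(c2)),
       c2 = c2, rates = k)
}

## two open branches sharing the autocatalytic species S1; branch b:
## S1 <-> Sb (k1, k2), 2S1 <-> S1+Sb (k3, k4), 0 <-> Sb (kp, km)
fixture_example5 <- function(params) {
  a <- params$branch1 %||% c(k1 = 1, k2 = 2, k3 = 3, k4 = 4, kp = 2, km = 1)
  b <- params$branch2 %||% a
  g <- parse_network(c(
    motif_lines("S1", "S2", a[1:4]),
    sprintf("0 <-> S2 ; rates=%.17g,%.17g", a[5], a[6]),
    motif_lines("S1", "S3", b[1:4]),
    sprintf("0 <-> S3 ; rates=%.17g,%.17g", b[5], b[6])))
  list(network = g, truth = list(essential = TRUE, conservative = FALSE),
       branch1 = a, branch2 = b)
}

fixture_disjoint_union <- function(params) {
  k1 <- params$rates1 %||% c(1, 2, 3, 4)
  k2 <- params$rates2 %||% c(4, 3, 2, 1)
  g <- parse_network(c(motif_lines("A1", "A2", k1),
                       motif_lines("B1", "B2", k2)))
  pf1 <- motif_product_form(k1[1], k1[2], k1[3], k1[4])
  pf2 <- motif_product_form(k2[1], k2[2], k2[3], k2[4])
  list(network = g,
       truth = list(reversible = TRUE, essential = TRUE,
                    conservative = TRUE),
       product_form = list(A1 = pf1$f_slow, A2 = pf1$f_fast,
                           B1 = pf2$f_slow, B2 = pf2$f_fast))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
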