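test_that("reaction-list parsing builds validated networks", {
  g <- parse_network("S1 -> S2 ; rate=1.0")
  expect_s3_class(g, "crn")
  expect_equal(g$species, c("S1", "S2"))
  expect_equal(nrow(complexes(g)), 2L)
  expect_equal(n_reactions(g), 1L)

  g2 <- parse_network("2 S1 <-> S1 + S2 ; rates=0.3,0.4")
  expect_equal(n_reactions(g2), 2L)
  expect_equal(g2$rate, c(0.3, 0.4))
  expect_equal(g2$reactant[1, ], c(S1 = 2L, S2 = 0L))
  expect_equal(g2$product[2, ], c(S1 = 2L, S2 = 0L))

  expect_error(parse_network("S1 -> S1 ; rate=1"), "reactant equals product")
  expect_error(parse_network("S1 -> S2 ; rate=-1"), "positive")
  expect_error(parse_network("S1 -> S2"), "line 1")
  # zero complex notation
  g3 <- parse_network("0 <-> S2 ; rates=2,1")
  expect_equal(sum(g3$reactant[1, ]), 0L)
})

test_that("duplicate reactions are merged with summed rates", {
  expect_warning(
    g <- parse_network(c("S1 -> S2 ; rate=1", "S1 -> S2 ; rate=2.5")),
    "merged")
  expect_equal(n_reactions(g), 1L)
  expect_equal(g$rate, 3.5)
})

test_that("write/parse round-trips networks, including kinetics blocks", {
  for (kind in c("example1", "remark4", "remark8", "remark13",
                 "remark16b4")) {
    g <- generate_fixture(kind)$network
    g2 <- parse_network(write_network(g))
    expect_equal(g2$species, g$species)
    expect_equal(unname(g2$reactant), unname(g$reactant))
    expect_equal(unname(g2$product), unname(g$product))
    expect_equal(g2$rate, g$rate)
  }
  lines <- c("S1 <-> S2 ; rates=1.25,2.5",
             "kinetics: S1 = hill_I(m=1, k=2)")
  g <- parse_network(lines)
  expect_equal(g$kinetics$S1$type, "hill_I")
  g2 <- parse_network(write_network(g))
  expect_equal(g2$kinetics$S1$params, g$kinetics$S1$params)
})

test_that("network union follows the set-union and summed-rate rules", {
  g1 <- parse_network(c("S1 <-> S2 ; rates=1,2",
                        "2 S1 <-> S1 + S2 ; rates=3,4"))
  g2 <- parse_network(c("S2 <-> S3 ; rates=5,6",
                        "2 S3 <-> S2 + S3 ; rates=7,8"))
  gu <- network_union(g1, g2)
  expect_equal(gu$species, c("S1", "S2", "S3"))
  expect_equal(n_reactions(gu), 8L)
  expect_true(attr(gu, "reaction_disjoint"))
  ref <- generate_fixture("example1", list(rates = 1:8))$network
  expect_equal(sort(apply(cbind(gu$reactant, gu$product, gu$rate), 1, paste,
                          collapse = "|")),
               sort(apply(cbind(ref$reactant, ref$product, ref$rate), 1,
                          paste, collapse = "|")))

  # gluing over reactions: union with itself doubles every rate
  gs <- network_union(g1, g1)
  expect_false(attr(gs, "reaction_disjoint"))
  expect_equal(gs$rate, 2 * g1$rate)
  expect_equal(n_reactions(gs), n_reactions(g1))

  # disjoint species: species counts add
  gd <- network_union(g1, parse_network("A <-> B ; rates=1,1"))
  expect_equal(length(gd$species), 4L)
  expect_true(attr(gd, "reaction_disjoint"))
})

test_that("union is commutative/associative up to species order, empty-ish identity", {
  g1 <- generate_fixture("motif", list(rates = c(1, 2, 3, 4)))$network
  g2 <- parse_network("S2 <-> S3 ; rates=5,6")
  a <- network_union(g1, g2)
  b <- network_union(g2, g1)
  key <- function(g) sort(apply(cbind(g$reactant[, sort(g$species)],
                                      g$product[, sort(g$species)], g$rate),
                                1, paste, collapse = "|"))
  expect_equal(key(a), key(b))
  g3 <- parse_network("S3 <-> S4 ; rates=1,1")
  expect_equal(key(network_union(network_union(g1, g2), g3)),
               key(network_union(g1, network_union(g2, g3))))
})

test_that("linkage classes partition the complexes of the reaction graph", {
  lc <- linkage_classes(generate_fixture("example1")$network)
  expect_equal(length(lc), 3L)
  sets <- lapply(lc, sort)
  expect_true(list(sort(c("S1", "S2", "S3"))) %in% sets ||
                any(vapply(sets, identical, logical(1),
                           sort(c("S1", "S2", "S3")))))
  expect_true(any(vapply(sets, identical, logical(1),
                         sort(c("2 S1", "S1 + S2")))))
  expect_true(any(vapply(sets, identical, logical(1),
                         sort(c("2 S3", "S2 + S3")))))
  expect_equal(length(linkage_classes(parse_network("S1 -> S2 ; rate=1"))),
               1L)
  expect_equal(length(linkage_classes(generate_fixture("remark4")$network)),
               2L)
})

test_that("deficiency matches the reference values", {
  expect_equal(deficiency(generate_fixture("example1")$network), 2L)
  expect_equal(deficiency(generate_fixture("remark4")$network), 1L)
  sr <- structural_report(parse_network("S1 <-> S2 ; rates=1,1"))
  expect_equal(sr$n_complexes, 2L)
  expect_equal(sr$n_linkage_classes, 1L)
  expect_equal(sr$stoich_dim, 1L)
  expect_equal(sr$deficiency, 0L)
})

test_that("reversibility classification distinguishes the three classes", {
  expect_equal(reversibility_class(generate_fixture("example1")$network),
               "reversible")
  expect_equal(reversibility_class(generate_fixture("remark13")$network),
               "neither")
  g3 <- parse_network(c("A -> B ; rate=1", "B -> C ; rate=1",
                        "C -> A ; rate=1"))
  expect_equal(reversibility_class(g3), "weakly_reversible")
})

test_that("conservation vectors are found, exact, and absent when infeasible", {
  cv <- conservation_vector(generate_fixture("example1")$network)
  expect_equal(unname(cv), c(1, 1, 1))
  g <- generate_fixture("example1")$network
  expect_true(all(reaction_vectors(g) %*% cv == 0))

  expect_null(conservation_vector(generate_fixture("remark8")$network))

  # vacuous constraints: all-ones for a reaction-free network
  g0 <- reaction_network(c("A", "B"), matrix(integer(), 0, 2),
                         matrix(integer(), 0, 2), numeric())
  expect_equal(unname(conservation_vector(g0)), c(1, 1))

  # weighted law: A + 2B <-> 0 ... use 2A <-> B which needs c = (1, 2)
  gw <- parse_network("2 A <-> B ; rates=1,1")
  cw <- conservation_vector(gw)
  expect_true(all(reaction_vectors(gw) %*% cw == 0))
  expect_true(all(cw >= 1))
})

test_that("structural invariants hold on random networks", {
  for (seed in 1:25) {
    g <- random_network(seed)
    sr <- structural_report(g)
    expect_gte(sr$deficiency, 0L)
    if (sr$reversible) expect_true(sr$weakly_reversible)
    if (sr$conservative)
      expect_lt(max(abs(reaction_vectors(g) %*% sr$conservation_vector)),
                1e-7)
    ## round-trip up to the writer's species reordering (first appearance)
    g2 <- parse_network(write_network(g))
    expect_setequal(g2$species, g$species)
    key <- function(gg) sort(apply(cbind(gg$reactant[, sort(gg$species)],
                                         gg$product[, sort(gg$species)],
                                         gg$rate), 1, paste, collapse = "|"))
    expect_equal(key(g2), key(g))
  }
})
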