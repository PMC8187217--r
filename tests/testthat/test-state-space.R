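test_that("mass-action intensities are falling factorials with availability", {
  g <- parse_network(c("2 S1 -> S1 + S2 ; rate=1", "S1 -> S2 ; rate=2"))
  expect_equal(intensity(g, 1, c(3, 0)), 3 * 2)
  expect_equal(intensity(g, 2, c(0, 5)), 0)
  expect_equal(intensity(g, 2, c(4, 0)), 8)
})

test_that("general kinetics reproduce the worked Hill value and mass-action", {
  g <- parse_network("S1 -> S2 ; rate=1")
  kin <- kinetics_spec(g, S1 = hill_I(m = 1, k = 2))
  expect_equal(intensity(g, 1, c(4, 0), kin = kin), 4 / (2 + 4))
  # theta support condition
  expect_equal(theta_eval(hill_I(1, 2), 0), 0)
  expect_equal(theta_eval(hill_II(2, 1, 3), 0), 0)
  expect_gt(theta_eval(hill_II(2, 1, 3), 1), 0)
})

test_that("general intensity equals the falling factorial when theta(x)=x", {
  g <- generate_fixture("example1", list(rates = random_rates(8, 3)))$network
  kin_tab <- kinetics_spec(g, S1 = theta_table(1:50), S2 = theta_table(1:50),
                           S3 = theta_table(1:50))
  comp <- irreducible_component(g, c(2, 1, 1))
  for (s in seq_len(nrow(comp$states))) {
    x <- comp$states[s, ]
    for (j in seq_len(n_reactions(g)))
      expect_equal(intensity(g, j, x, kin = kin_tab), intensity(g, j, x))
  }
})

test_that("successors aggregate intensities by jump vector", {
  g <- parse_network("S1 <-> S2 ; rates=1,1")
  sc <- successors(g, c(1, 1))
  expect_equal(nrow(sc$states), 2L)
  key <- apply(sc$states, 1, paste, collapse = ",")
  expect_setequal(key, c("0,2", "2,0"))
  expect_equal(sc$rates, c(1, 1))

  # no active reactions
  expect_equal(nrow(successors(g, c(0, 0))$states), 0L)

  # aggregation over the two reactions sharing one jump vector
  g1 <- generate_fixture("example1", list(rates = 1:8))$network
  sc1 <- successors(g1, c(1, 1, 0))
  key1 <- apply(sc1$states, 1, paste, collapse = ",")
  i <- match("0,2,0", key1)  # jumps S1->S2 (k1*1) and 2S1->S1+S2 (k3*0)
  expect_equal(sc1$rates[i], 1 * 1)
  j <- match("2,0,0", key1)  # S2->S1 (k2*1) + S1+S2->2S1 (k4*1*1)
  expect_equal(sc1$rates[j], 2 * 1 + 4 * 1)
})

test_that("reachable sets honour caps and report truncation", {
  g <- parse_network("S1 <-> S2 ; rates=1,1")
  rs <- reachable_set(g, c(3, 0))
  expect_equal(nrow(rs$states), 4L)
  expect_false(rs$truncated)

  gb <- parse_network("0 <-> S2 ; rates=1,1")
  rb <- reachable_set(gb, 0L, cap = 5L)
  expect_equal(sort(rb$states[, 1]), 0:5)
  expect_true(rb$truncated)

  g2 <- parse_network(c("2 S1 -> S1 + S2 ; rate=1"))
  r2 <- reachable_set(g2, c(0, 1))
  expect_equal(nrow(r2$states), 1L)
  expect_false(r2$truncated)
})

test_that("irreducible components detect closure via mutual accessibility", {
  g <- parse_network("S1 <-> S2 ; rates=1,1")
  ic <- irreducible_component(g, c(3, 0))
  expect_equal(nrow(ic$states), 4L)
  expect_true(ic$closed)

  gr <- generate_fixture("remark13")$network
  icr <- irreducible_component(gr, c(1, 0, 0, 0))
  expect_false(icr$closed)  # S0 -> S1 is irreversible

  g2 <- parse_network(c("2 S1 -> S1 + S2 ; rate=1"))
  ic2 <- irreducible_component(g2, c(1, 0))
  expect_true(ic2$closed)
  expect_equal(nrow(ic2$states), 1L)
})

test_that("essentiality verdicts match the reference networks", {
  expect_equal(is_essential(generate_fixture("remark8")$network),
               "essential")
  expect_equal(is_essential(generate_fixture("remark13")$network),
               "not_essential")
  expect_equal(is_essential(generate_fixture("example1")$network),
               "essential")
})

test_that("reversible implies weakly reversible implies essential on fixtures", {
  for (seed in 1:10) {
    k <- random_rates(4, seed)
    g <- generate_fixture("motif", list(rates = k))$network
    expect_equal(reversibility_class(g), "reversible")
    expect_equal(is_essential(g), "essential")
  }
  g3 <- parse_network(c("A -> B ; rate=1", "B -> C ; rate=2",
                        "C -> A ; rate=0.5"))
  expect_equal(reversibility_class(g3), "weakly_reversible")
  expect_equal(is_essential(g3), "essential")
})

test_that("a reaction-disjoint union of essential parts is essential", {
  for (seed in 1:5) {
    g1 <- generate_fixture("motif", list(rates = random_rates(4, seed)))$network
    g2 <- parse_network(sprintf("A <-> B ; rates=%.17g,%.17g",
                                random_rates(1, seed + 100),
                                random_rates(1, seed + 200)))
    expect_equal(is_essential(g1), "essential")
    expect_equal(is_essential(g2), "essential")
    expect_equal(is_essential(network_union(g1, g2)), "essential")
  }
})

test_that("projections collapse duplicates and preserve full subsets", {
  g <- generate_fixture("example1")$network
  st <- matrix(c(1, 2, 3), 1)
  expect_equal(unname(project_states(st, g, c("S1", "S2"))),
               matrix(c(1, 2), 1))
  expect_error(project_states(st, g, "nope"), "unknown species")

  comp <- irreducible_component(g, c(4, 0, 0))
  proj <- project_states(comp, g, c("S1", "S2"))
  # the projection of the simplex x1+x2+x3 = N is the triangle x1+x2 <= N
  expect_equal(nrow(proj), sum(outer(0:4, 0:4, "+") <= 4))
  expect_true(all(rowSums(proj) <= 4))

  full <- project_states(comp, g, g$species)
  expect_equal(nrow(full), nrow(comp$states))
})

test_that("projections of components of an essential join cover components of the part", {
  # essential G = G1 u G2 with G1 essential: p1 of a closed component is a
  # disjoint union of closed components of G1
  g <- generate_fixture("example1", list(rates = random_rates(8, 17)))$network
  decs <- essential_decompositions(g, strategy = "greedy")
  dec <- decs[[1]]
  comp <- irreducible_component(g, c(3, 0, 0))
  for (j in seq_along(dec$parts)) {
    part <- dec$networks[[j]]
    proj <- project_states(comp, g, part$species)
    seen <- character()
    while (nrow(proj)) {
      ic <- irreducible_component(part, proj[1, ])
      expect_true(ic$closed)
      keys <- apply(ic$states, 1, paste, collapse = ",")
      pkeys <- apply(proj, 1, paste, collapse = ",")
      # the whole component lies inside the projection
      expect_true(all(keys %in% pkeys))
      proj <- proj[!(pkeys %in% keys), , drop = FALSE]
    }
  }
})

test_that("conservative networks yield finite, untruncated exploration", {
  for (seed in c(2, 9)) {
    g <- generate_fixture("motif_chain", list(length = 2), seed = seed)$network
    rs <- reachable_set(g, c(2, 1, 1))
    expect_false(rs$truncated)
    expect_true(all(rowSums(rs$states) == 4))
  }
})
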