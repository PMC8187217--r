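test_that("bipartition enumeration counts 2^m - 1 ordered pairs", {
  g3 <- parse_network(c("A -> B ; rate=1", "B -> C ; rate=1",
                        "C -> A ; rate=1"))
  expect_length(enumerate_reaction_bipartitions(g3), 7L)
  g1 <- parse_network("A -> B ; rate=1")
  bp <- enumerate_reaction_bipartitions(g1)
  expect_length(bp, 1L)
  expect_equal(bp[[1]]$R1, 1L)
  expect_length(bp[[1]]$R2, 0L)
  # unordered deduplication halves the count (2^(m-1))
  expect_length(enumerate_reaction_bipartitions(g3, unordered = TRUE), 4L)
  expect_error(enumerate_reaction_bipartitions(g3, limit = 2L), "refusing")
})

test_that("the reference split of the three-species network is found", {
  g <- generate_fixture("example1")$network
  bps <- enumerate_reaction_bipartitions(g, unordered = TRUE)
  expect_length(bps, 2^7)
  # reactions 1,2 = S1<->S2; 5,6 = 2S1<->S1+S2 (the S1,S2 motif)
  target <- sort(c(1L, 2L, 5L, 6L))
  hits <- vapply(bps, function(bp)
    identical(sort(bp$R1), target) || identical(sort(bp$R2), target),
    logical(1))
  expect_equal(sum(hits), 1L)

  decs <- essential_decompositions(g, strategy = "greedy")
  expect_length(decs, 1L)
  expect_equal(lapply(decs[[1]]$parts, sort),
               list(c(1L, 2L, 5L, 6L), c(3L, 4L, 7L, 8L)))
  expect_equal(decs[[1]]$networks[[1]]$species, c("S1", "S2"))
})

test_that("the gene-expression network admits no essential bipartition", {
  g <- generate_fixture("remark8")$network
  decs <- essential_decompositions(g, strategy = "both")
  expect_length(decs, 0L)
})

test_that("a disjoint union of motifs splits along its parts", {
  fx <- generate_fixture("disjoint_union")
  decs <- essential_decompositions(fx$network, strategy = "greedy")
  expect_length(decs, 1L)
  expect_length(decs[[1]]$parts, 2L)
  expect_setequal(decs[[1]]$networks[[1]]$species, c("A1", "A2"))
})

test_that("assembly reproduces the direct solution of the three-species join", {
  for (seed in 1:8) {
    k <- random_rates(8, seed + 400)
    fx <- generate_fixture("example1", list(rates = k))
    g <- fx$network
    N <- sample(3:8, 1)
    comp <- irreducible_component(g, c(N, 0, 0))
    res <- solve_by_decomposition(g, comp)
    expect_equal(res$provenance$method, "decomposition")
    d <- solve_master_direct(g, comp)
    expect_lt(total_variation(res$dist, d), 1e-10)
    expect_lt(res$provenance$balance_residual, 1e-9)
  }
})

test_that("random glued-motif stars assemble for every rate draw", {
  for (seed in 1:10) {
    set.seed(seed)
    L <- sample(2:3, 1)
    N <- sample(3:6, 1)
    fx <- generate_fixture("motif_chain", list(length = L), seed = seed)
    g <- fx$network
    x0 <- rep(0L, length(g$species))
    x0[1] <- N
    comp <- irreducible_component(g, x0)
    res <- solve_by_decomposition(g, comp)
    expect_equal(res$provenance$method, "decomposition")
    expect_length(res$provenance$parts, L)
    d <- solve_master_direct(g, comp)
    expect_lt(total_variation(res$dist, d), 1e-9)
    expect_lt(res$provenance$balance_residual, 1e-9)
  }
})

test_that("stars with general kinetics on the private species still assemble", {
  # rate- and kinetics-independence of the glued family: the shared fast
  # species keeps one fixed theta, private species vary freely
  for (seed in 1:4) {
    fx <- generate_fixture("motif_chain", list(length = 2), seed = seed)
    g <- fx$network
    kin <- kinetics_spec(g)
    kin[["U1"]] <- hill_I(m = 1, k = 1.5)
    kin[["U2"]] <- theta_table(sqrt(1:20))
    class(kin) <- "crn_kinetics"
    comp <- irreducible_component(g, c(3, 1, 0), kin = kin)
    res <- solve_by_decomposition(g, comp, kin = kin)
    expect_equal(res$provenance$method, "decomposition")
    d <- solve_master_direct(g, comp, kin = kin)
    expect_lt(total_variation(res$dist, d), 1e-9)
  }
})

test_that("disjoint unions assemble as outer products", {
  fx <- generate_fixture("disjoint_union")
  g <- fx$network
  comp <- irreducible_component(g, c(2, 1, 1, 2))
  res <- solve_by_decomposition(g, comp)
  expect_equal(res$provenance$method, "decomposition")
  d <- solve_master_direct(g, comp)
  expect_lt(total_variation(res$dist, d), 1e-10)
  # marginals multiply: P(x_A, x_B) = P(x_A) P(x_B)
  keyA <- apply(res$dist$states[, 1:2], 1, paste, collapse = ",")
  keyB <- apply(res$dist$states[, 3:4], 1, paste, collapse = ",")
  pA <- tapply(res$dist$p, keyA, sum)
  pB <- tapply(res$dist$p, keyB, sum)
  expect_equal(as.numeric(pA[keyA] * pB[keyB]), res$dist$p,
               tolerance = 1e-10)
})

test_that("the open motif-exchange join assembles with the matched tilt", {
  fx <- generate_fixture("remark16b4", list(rates = c(1, 2, 3, 4),
                                            kp = 2, km = 1))
  g <- fx$network
  comp <- irreducible_component(g, c(0, 0), cap = c(25, 35))
  expect_true(comp$truncated)
  res <- solve_by_decomposition(g, comp, fallback_direct = FALSE)
  expect_equal(res$provenance$method, "decomposition")
  # the conservative motif part is tilted to the complex-balance value c2
  expect_true(any(abs(res$provenance$tilts - 2) < 1e-8))
  expect_equal(res$provenance$summability, "summable")
  d <- solve_master_direct(g, comp, allow_truncated = TRUE)
  expect_lt(total_variation(res$dist, d), 1e-9)
})

test_that("mismatched branch parameters cause refusal, matched ones assemble", {
  base <- c(k1 = 1, k2 = 2, k3 = 3, k4 = 4, kp = 2, km = 1)
  fx <- generate_fixture("example5")
  comp <- irreducible_component(fx$network, c(0, 0, 0), cap = c(6, 9, 9))
  res <- solve_by_decomposition(fx$network, comp, fallback_direct = FALSE)
  expect_equal(res$provenance$method, "decomposition")

  pert <- base
  pert["k2"] <- base["k2"] * 1.35
  fxp <- generate_fixture("example5", list(branch2 = pert))
  resp <- solve_by_decomposition(fxp$network, comp, fallback_direct = FALSE)
  expect_equal(resp$provenance$method, "undecomposable")
  expect_true(length(resp$provenance$refusals) > 0)

  # the naive product then violates the master equation
  decs <- essential_decompositions(fxp$network, strategy = "greedy")
  dec <- decs[[1]]
  kin <- crndecomp:::resolve_kinetics(fxp$network)
  pforms <- lapply(seq_along(dec$parts), function(j) {
    part <- dec$networks[[j]]
    crndecomp:::solve_part(part,
                           crndecomp:::restrict_kinetics(fxp$network, kin,
                                                         part),
                           project_states(comp$states, fxp$network,
                                          part$species))
  })
  naive <- assemble_stationary(fxp$network, dec, pforms, comp, force = TRUE)
  expect_true(attr(naive, "forced"))
  expect_gt(master_equation_residual(fxp$network, naive), 1e-3)
})

test_that("the driver falls back to a direct solve when parts are unsolvable", {
  g <- generate_fixture("remark8")$network
  comp <- irreducible_component(g, c(0, 0), cap = c(15, 15))
  # truncated and undecomposable: no fallback possible
  res <- solve_by_decomposition(g, comp, fallback_direct = TRUE)
  expect_equal(res$provenance$method, "undecomposable")

  # finite conservative network without registered closed form
  g2 <- generate_fixture("remark4")$network
  c2 <- irreducible_component(g2, c(3, 1))
  r2 <- solve_by_decomposition(g2, c2)
  expect_false(is.null(r2$dist))
  expect_lt(master_equation_residual(g2, r2$dist), 1e-9)
})
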