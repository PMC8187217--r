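# Independent oracles and fixture helpers shared across the test files.

# Stationary distribution of a birth-death chain on 0..N from the
# detailed-balance recursion pi(x)/pi(x-1) = up(x-1)/down(x): independent
# of the package's null-space solver.
chain_stationary <- function(up, down, N) {
  logp <- c(0, cumsum(log(up(0:(N - 1))) - log(down(1:N))))
  p <- exp(logp - max(logp))
  p / sum(p)
}

# Stationary distribution from an explicit generator by eigen decomposition
# of t(Q) (a different algorithm than the package's LU null-space solve).
eigen_stationary <- function(Q) {
  e <- eigen(t(as.matrix(Q)))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  v / sum(v)
}

# map a distribution's probabilities onto a reference state ordering
probs_at <- function(dist, states) {
  key <- apply(states, 1L, paste, collapse = ",")
  dk <- apply(dist$states, 1L, paste, collapse = ",")
  dist$p[match(key, dk)]
}

# random small mass-action networks for property sweeps
random_network <- function(seed, n_species = 3L, n_reactions = 4L) {
  set.seed(seed)
  species <- paste0("X", seq_len(n_species))
  repeat {
    reactant <- matrix(sample(0:2, n_species * n_reactions, replace = TRUE,
                              prob = c(0.5, 0.35, 0.15)),
                       n_reactions, n_species)
    product <- matrix(sample(0:2, n_species * n_reactions, replace = TRUE,
                             prob = c(0.5, 0.35, 0.15)),
                      n_reactions, n_species)
    distinct <- rowSums(reactant != product) > 0
    used <- colSums(reactant) + colSums(product) > 0
    if (all(distinct) && all(used)) break
  }
  g <- suppressWarnings(reaction_network(
    species, reactant, product, rate = round(exp(stats::runif(n_reactions,
                                                              log(0.1),
                                                              log(10))), 6)))
  g
}

random_rates <- function(n, seed) {
  set.seed(seed)
  exp(stats::runif(n, log(0.1), log(10)))
}
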