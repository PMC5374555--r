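# Independent oracles and graph generators shared across the test suite.
# The oracles deliberately use dense, brute-force formulations so they share
# no code path with the package's sparse implementations.

# random connected graph: a random spanning tree plus extra random edges,
# binary weights (curated-interaction convention)
random_connected_net <- function(n, extra = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  from <- to <- character(0)
  nodes <- sprintf("g%02d", seq_len(n))
  for (i in 2:n) {
    from <- c(from, nodes[sample(i - 1L, 1L)])
    to <- c(to, nodes[i])
  }
  for (e in seq_len(extra)) {
    pair <- sample(nodes, 2L)
    from <- c(from, pair[1L]); to <- c(to, pair[2L])
  }
  ppi_network(data.frame(from = from, to = to, weight = 1))
}

# dense transition matrix by explicit division
dense_transition <- function(net) {
  A <- as.matrix(net$adjacency)
  sweep(A, 1, rowSums(A), "/")
}

# brute-force direct-neighbour similarity: explicit self-inclusive
# neighbourhood intersection with a double loop over shared members
dn_oracle <- function(net, vi, vj) {
  A <- as.matrix(net$adjacency)
  gamma <- function(v) c(v, colnames(A)[A[v, ] > 0])
  common <- intersect(gamma(vi), gamma(vj))
  w <- function(x, y) if (x == y) 1 else A[x, y]
  num <- 0
  for (k in common) num <- num + w(vi, k) * w(vj, k)
  num / sqrt(max(sum(A[vi, ]), sum(A[vj, ])))
}

# all-pairs local random walk similarity from dense explicit matrix powers
lrw_oracle_matrix <- function(net, t) {
  P <- dense_transition(net)
  Pt <- diag(nrow(P))
  for (s in seq_len(t)) Pt <- Pt %*% P
  K <- net$strength
  M <- net$n_edges
  L <- outer(K / M, rep(1, length(K))) * Pt +
    base::t(outer(K / M, rep(1, length(K))) * Pt)
  diag(L) <- 0
  dimnames(L) <- dimnames(P)
  L
}

# direct linear solve of the random-walk-with-restart stationary equation
rwr_oracle <- function(net, seeds, restart) {
  P <- dense_transition(net)
  n <- nrow(P)
  p0 <- setNames(numeric(n), rownames(P))
  p0[seeds] <- 1 / length(seeds)
  solve(diag(n) - (1 - restart) * t(P), restart * p0)
}

# brute-force complex co-membership similarity by explicit enumeration
complex_sim_oracle <- function(complexes, net, vi, vj) {
  total <- 0
  for (id in names(complexes)) {
    m <- complexes[[id]]
    if (vi %in% m && vj %in% m) total <- total + complex_score(net, m)
  }
  total
}

# small reusable fixture bundle with informative GO and complex structure
toy_bundle <- function(seed = 11) {
  spec <- fixture_spec(n_background = 60, n_modules = 3, seed = seed)
  generate_fixtures(spec)
}
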