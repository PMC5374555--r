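#' Random-walk transition matrix of a network
#'
#' Row-stochastic matrix `P` with `P[i, j] = w(i, j) / K_i`: the probability
#' that a walker at gene `i` steps to gene `j`. On a binary network this is
#' the usual degree-normalised adjacency; on a weighted network the step
#' probabilities are proportional to edge weights.
#'
#' @param net a [ppi_network()].
#' @return sparse row-stochastic matrix with gene dimnames.
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  P <- Matrix::Diagonal(x = 1 / net$strength) %*% net$adjacency
  dimnames(P) <- dimnames(net$adjacency)
  P
}

#' t-step random walk probability profile from a source gene
#'
#' Starting from the indicator distribution of `source`, applies the
#' transition matrix `t` times: `pi(s + 1) = P^T pi(s)`. The result is the
#' probability of finding the walker at each gene after exactly `t` steps.
#' Implemented as sparse matrix-vector products, so the cost is
#' `O(t * |E|)` per source.
#'
#' @param net a [ppi_network()].
#' @param source source gene.
#' @param t number of steps (integer >= 0; `t = 0` returns the indicator of
#'   the source).
#' @return An object of class `walk_profile`: list with `source`, `t` and
#'   `prob`, a named probability vector over all genes.
#' @export
walk_profile <- function(net, source, t) {
  check_genes(net, source)
  if (length(source) != 1L) stop("source must be a single gene")
  if (t < 0 || t != floor(t)) stop("t must be a non-negative integer")
  prob <- walk_profiles(net, source, t)[1L, ]
  structure(list(source = source, t = as.integer(t), prob = prob),
            class = "walk_profile")
}

# internal: t-step profiles for several sources at once.
# Row s of the result is pi_{sources[s]}(t); computed as rows of the
# indicator matrix evolved by right-multiplication with P. An optional
# environment caches profiles per source (the network and t are fixed for
# the lifetime of a cache), which makes repeated ranking tasks on the same
# network cheap.
walk_profiles <- function(net, sources, t, cache = NULL) {
  n <- length(net$nodes)
  if (!is.null(cache)) {
    missing <- sources[!vapply(sources, function(s) exists(s, envir = cache, inherits = FALSE), TRUE)]
    if (length(missing) > 0L) {
      fresh <- walk_profiles(net, missing, t, cache = NULL)
      for (s in missing) assign(s, fresh[s, ], envir = cache)
    }
    out <- do.call(rbind, lapply(sources, get, envir = cache))
    dimnames(out) <- list(sources, net$nodes)
    return(out)
  }
  P <- transition_matrix(net)
  X <- Matrix::sparseMatrix(
    i = seq_along(sources), j = match(sources, net$nodes), x = 1,
    dims = c(length(sources), n)
  )
  s <- 0L
  while (s < t) {
    X <- X %*% P
    s <- s + 1L
  }
  out <- as.matrix(X)
  dimnames(out) <- list(sources, net$nodes)
  out
}

#' Direct-neighbour similarity of an interacting gene pair
#'
#' For two genes that interact, measures how much of their neighbourhoods
#' they share. The neighbourhood of a gene includes the gene itself, so for
#' an interacting pair each endpoint contributes to the overlap. The sum of
#' weight products over the shared neighbourhood is divided by
#' `sqrt(max(K_i, K_j))`, penalising hub genes whose many interactions would
#' otherwise inflate the score:
#' \deqn{DN(i, j) = \frac{\sum_{k \in \Gamma_i \cap \Gamma_j} w(i,k)\,w(j,k)}
#'   {\sqrt{\max(K_i, K_j)}}}
#' with \eqn{w(v, v) = 1} and \eqn{\Gamma_v} the neighbours of `v` plus `v`.
#'
#' @param net a [ppi_network()].
#' @param v_i,v_j an interacting gene pair (an error is raised for
#'   non-adjacent pairs; use [topo_similarity()] to route automatically).
#' @return non-negative similarity score.
#' @export
dn_similarity <- function(net, v_i, v_j) {
  check_genes(net, c(v_i, v_j))
  if (v_i == v_j) stop("self-similarity is undefined")
  if (!has_edge(net, v_i, v_j)) {
    stop(sprintf("genes %s and %s do not interact; use lrw_similarity()", v_i, v_j))
  }
  wi <- net$adjacency[v_i, ]
  wj <- net$adjacency[v_j, ]
  wi[match(v_i, net$nodes)] <- 1  # self-inclusion: w(v, v) = 1
  wj[match(v_j, net$nodes)] <- 1
  sum(wi * wj) / sqrt(max(net$strength[[v_i]], net$strength[[v_j]]))
}

#' Local random walk similarity of a gene pair
#'
#' Truncated random-walk similarity for genes that need not interact
#' directly: the `t`-step visiting probabilities in both directions,
#' weighted by the walker's stationary occupancy of each source,
#' \deqn{LRW_{ij}(t) = \frac{K_i}{M}\pi_{ij}(t) + \frac{K_j}{M}\pi_{ji}(t)}
#' where `M` is the number of interactions in the network. Truncating at a
#' small `t` keeps the score local: genes reachable only through long
#' detours score near zero, and genes in different connected components
#' score exactly zero.
#'
#' @param net a [ppi_network()].
#' @param v_i,v_j distinct genes in the network.
#' @param t walk length (integer >= 1, default 3).
#' @param cache optional environment memoising walk profiles per source
#'   gene (see [walk_profiles] usage in ranking).
#' @return non-negative, symmetric similarity score.
#' @export
lrw_similarity <- function(net, v_i, v_j, t = 3, cache = NULL) {
  check_genes(net, c(v_i, v_j))
  if (v_i == v_j) stop("self-similarity is undefined")
  if (t < 1 || t != floor(t)) stop("t must be an integer >= 1")
  pr <- walk_profiles(net, c(v_i, v_j), t, cache = cache)
  M <- net$n_edges
  unname(net$strength[[v_i]] / M * pr[v_i, v_j] + net$strength[[v_j]] / M * pr[v_j, v_i])
}

#' Topological similarity of a gene pair
#'
#' Routes a pair to the appropriate similarity: interacting pairs are scored
#' by [dn_similarity()] (shared direct neighbours with a hub penalty),
#' non-interacting pairs by [lrw_similarity()] (t-step local random walk).
#'
#' @inheritParams lrw_similarity
#' @return non-negative, symmetric similarity score.
#' @export
topo_similarity <- function(net, v_i, v_j, t = 3, cache = NULL) {
  check_genes(net, c(v_i, v_j))
  if (v_i == v_j) stop("self-similarity is undefined")
  if (has_edge(net, v_i, v_j)) {
    dn_similarity(net, v_i, v_j)
  } else {
    lrw_similarity(net, v_i, v_j, t = t, cache = cache)
  }
}

# internal: dense |rows| x |cols| matrix of pairwise topological similarity.
# mode "auto" applies the adjacency routing (DN for edges, LRW otherwise);
# mode "lrw" scores every pair by the local random walk, which is the
# LRW-only comparator method. Entries where the row and column gene
# coincide are set to 0 (self-similarity is excluded everywhere).
topo_sim_matrix <- function(net, rows, cols, t = 3, cache = NULL, mode = c("auto", "lrw")) {
  mode <- match.arg(mode)
  check_genes(net, c(rows, cols))
  K <- net$strength
  M <- net$n_edges

  pr_rows <- walk_profiles(net, rows, t, cache = cache)
  pr_cols <- walk_profiles(net, cols, t, cache = cache)
  lrw <- (K[rows] / M) * pr_rows[, cols, drop = FALSE] +
    base::t((K[cols] / M) * pr_cols[, rows, drop = FALSE])

  if (mode == "lrw") {
    out <- lrw
  } else {
    Aself <- net$adjacency + Matrix::Diagonal(length(net$nodes), 1)
    dimnames(Aself) <- dimnames(net$adjacency)
    num <- as.matrix(Aself[rows, , drop = FALSE] %*% Aself[, cols, drop = FALSE])
    denom <- sqrt(outer(K[rows], K[cols], pmax))
    dn <- num / denom
    adj <- as.matrix(net$adjacency[rows, cols, drop = FALSE]) > 0
    out <- ifelse(adj, dn, lrw)
  }
  self <- outer(rows, cols, `==`)
  out[self] <- 0
  dimnames(out) <- list(rows, cols)
  out
}
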