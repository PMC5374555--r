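#' Combined topological and biological similarity of a gene pair
#'
#' Convex combination of the three similarity channels:
#' \deqn{Sim(i, j) = (1 - \alpha - \beta)\,Topo(i, j) + \alpha\,SimGO(i, j)
#'   + \beta\,SimCOM(i, j)}
#' With `alpha = beta = 0` the score is purely topological; `alpha = 1`
#' reduces to GO similarity and `beta = 1` to complex similarity. This
#' pairwise form combines the raw (unrescaled) channels; ranking functions
#' rescale each channel to a common `[0, 1]` scale per task by default (see
#' [rank_candidates()]).
#'
#' @param net a [ppi_network()].
#' @param annot a [go_annotation_set()] (may be `NULL` when `alpha = 0`).
#' @param catalog a [complex_catalog()] (may be `NULL` when `beta = 0`).
#' @param v_i,v_j distinct genes in the network.
#' @param alpha weight of the GO channel in `[0, 1]` (default 0.1).
#' @param beta weight of the complex channel in `[0, 1]` (default 0.1).
#' @param t local random walk length (default 3).
#' @return non-negative, symmetric similarity score.
#' @export
combined_similarity <- function(net, annot, catalog, v_i, v_j,
                                alpha = 0.1, beta = 0.1, t = 3) {
  check_weights(alpha, beta)
  topo <- topo_similarity(net, v_i, v_j, t = t)
  go <- if (alpha > 0) go_similarity(annot, v_i, v_j) else 0
  com <- if (beta > 0) complex_similarity(catalog, net, v_i, v_j) else 0
  (1 - alpha - beta) * topo + alpha * go + beta * com
}

check_weights <- function(alpha, beta) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("alpha and beta must lie in [0, 1]")
  }
  if (alpha + beta > 1) stop("alpha + beta must not exceed 1")
  invisible(TRUE)
}

# internal: seeds x candidates matrices for the three channels.
# topo_mode "lrw" replaces the adjacency-routed similarity with the pure
# local random walk comparator.
similarity_components <- function(net, annot, catalog, seeds, candidates,
                                  alpha, beta, t = 3, cache = NULL,
                                  topo_mode = c("auto", "lrw")) {
  topo_mode <- match.arg(topo_mode)
  list(
    topo = topo_sim_matrix(net, seeds, candidates, t = t, cache = cache, mode = topo_mode),
    go = if (alpha > 0) go_sim_matrix(annot, seeds, candidates) else NULL,
    com = if (beta > 0) com_sim_matrix(catalog, net, seeds, candidates) else NULL
  )
}

rescale_by_max <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Rank candidate genes against a disease's known genes
#'
#' Scores every candidate by the summed similarity to all known (seed)
#' genes, \eqn{Score_c = \sum_{i \in seeds} Sim(i, c)}, and ranks candidates
#' by descending score. Ranks are pessimistic: a candidate's rank is the
#' number of candidates scoring at least as high, so tied candidates all
#' receive the rank of the last of their tie group, and a candidate with
#' score 0 receives rank equal to the candidate-set size.
#'
#' Because the three similarity channels live on incommensurate scales, each
#' channel is by default rescaled by its maximum over all (seed, candidate)
#' pairs of the task before the weights are applied; set
#' `normalize = FALSE` for the raw combination (under which scores are
#' additive over disjoint seed sets).
#'
#' @param net a [ppi_network()].
#' @param annot a [go_annotation_set()] (`NULL` allowed when `alpha = 0`).
#' @param catalog a [complex_catalog()] (`NULL` allowed when `beta = 0`).
#' @param known character vector of known disease genes (seeds); genes
#'   absent from the network are dropped with a warning.
#' @param candidates character vector of candidate genes, disjoint from
#'   `known`; candidates absent from the network score 0.
#' @param alpha,beta channel weights (defaults 0.1 and 0.1).
#' @param t local random walk length (default 3).
#' @param normalize rescale each channel to `[0, 1]` per task (default
#'   `TRUE`).
#' @param topo_mode `"auto"` (direct-neighbour score for interacting pairs,
#'   local random walk otherwise) or `"lrw"` (random walk for every pair).
#' @param cache optional environment memoising walk profiles across ranking
#'   tasks on the same network.
#' @return An object of class `ranking_result`: a data.frame with columns
#'   `gene`, `score`, `rank`, ordered by decreasing score, with the
#'   parameters in attributes.
#' @export
rank_candidates <- function(net, annot = NULL, catalog = NULL, known, candidates,
                            alpha = 0.1, beta = 0.1, t = 3, normalize = TRUE,
                            topo_mode = c("auto", "lrw"), cache = NULL) {
  topo_mode <- match.arg(topo_mode)
  check_weights(alpha, beta)
  known <- unique(as.character(known))
  candidates <- unique(as.character(candidates))
  if (length(known) == 0L) stop("the set of known genes is empty")
  if (length(intersect(known, candidates)) > 0L) {
    stop("known genes and candidates must be disjoint")
  }
  seeds <- intersect(known, net$nodes)
  if (length(seeds) < length(known)) {
    warning(sprintf("%d known gene(s) not in the network were dropped",
                    length(known) - length(seeds)))
  }
  if (length(seeds) == 0L) stop("no known gene is present in the network")
  if (length(candidates) == 0L) stop("the candidate set is empty")
  if (alpha > 0 && is.null(annot)) stop("alpha > 0 requires GO annotations")
  if (beta > 0 && is.null(catalog)) stop("beta > 0 requires a complex catalog")

  in_net <- intersect(candidates, net$nodes)
  scores <- stats::setNames(numeric(length(candidates)), candidates)
  if (length(in_net) > 0L) {
    comp <- similarity_components(net, annot, catalog, seeds, in_net,
                                  alpha, beta, t = t, cache = cache,
                                  topo_mode = topo_mode)
    if (normalize) comp <- lapply(comp, function(m) if (is.null(m)) NULL else rescale_by_max(m))
    combined <- (1 - alpha - beta) * comp$topo
    if (!is.null(comp$go)) combined <- combined + alpha * comp$go
    if (!is.null(comp$com)) combined <- combined + beta * comp$com
    scores[in_net] <- colSums(combined)
  }

  rank <- vapply(scores, function(s) sum(scores >= s), 0L)
  rank[scores == 0] <- length(candidates)
  ord <- order(-scores, names(scores))
  out <- data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
                    rank = unname(rank[ord]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("ranking_result", "data.frame"),
            params = list(alpha = alpha, beta = beta, t = t,
                          normalize = normalize, topo_mode = topo_mode),
            known = seeds)
}

#' @export
print.ranking_result <- function(x, n = 10L, ...) {
  p <- attr(x, "params")
  cat(sprintf("Candidate ranking (%d candidates, %d seeds; alpha = %g, beta = %g, t = %d)\n",
              nrow(x), length(attr(x, "known")), p$alpha, p$beta, p$t))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more candidates\n", nrow(x) - n))
  invisible(x)
}

#' Rank all network genes to predict novel disease genes
#'
#' Genome-wide prediction mode: every gene in the network except the known
#' genes is treated as a candidate, and the `top_n` highest-ranked genes are
#' returned.
#'
#' @inheritParams rank_candidates
#' @param top_n number of top predictions to return (clamped to the number
#'   of candidates; default 10).
#' @return A `ranking_result` restricted to the top `top_n` genes.
#' @export
rank_genome <- function(net, annot = NULL, catalog = NULL, known,
                        alpha = 0.1, beta = 0.1, t = 3, top_n = 10,
                        normalize = TRUE, cache = NULL) {
  candidates <- setdiff(net$nodes, known)
  if (length(candidates) == 0L) stop("no candidate genes remain after excluding known genes")
  res <- rank_candidates(net, annot, catalog, known, candidates,
                         alpha = alpha, beta = beta, t = t,
                         normalize = normalize, cache = cache)
  out <- utils::head(res, min(top_n, nrow(res)))
  attributes(out)$params <- attr(res, "params")
  attributes(out)$known <- attr(res, "known")
  class(out) <- class(res)
  out
}

#' Read a disease-to-known-genes table
#'
#' Each line is `disease_id<TAB>gene1;gene2;...`; `#` comment lines are
#' ignored.
#'
#' @param path path to the TSV file.
#' @return named list mapping disease id to a character vector of genes.
#' @export
read_disease_genes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("disease", "genes"))
  lapply(stats::setNames(strsplit(tab$genes, ";", fixed = TRUE), tab$disease), unique)
}
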