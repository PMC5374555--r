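#' Configuration for the leave-one-out decoy evaluation
#'
#' @param method similarity variant to evaluate: `"dignifi"` (topological
#'   only), `"simgo"` (topological + GO), `"simcom"` (topological +
#'   complexes), `"simbio"` (all three channels), `"lrw"` (local random walk
#'   for every pair), or `"rwr"` (random walk with restart baseline).
#' @param ks values of k at which success rates are reported (default 1:10).
#' @param decoys number of decoy genes mixed with each held-out target
#'   (default 99, giving 100-gene candidate sets).
#' @param seed base RNG seed; the decoy draw of trial `i` uses
#'   `seed + i`, so reports are reproducible and trials independent.
#' @param alpha,beta channel weights used by the GO/complex variants
#'   (defaults 0.1 and 0.1).
#' @param t local random walk length (default 3).
#' @param min_genes diseases with fewer known genes in the network are
#'   skipped (default 5).
#' @param restart restart probability of the RWR baseline (default 0.8).
#' @param normalize per-task channel rescaling (default `TRUE`).
#' @return An `eval_config` list.
#' @export
eval_config <- function(method = c("simbio", "dignifi", "simgo", "simcom", "lrw", "rwr"),
                        ks = 1:10, decoys = 99, seed = 1,
                        alpha = 0.1, beta = 0.1, t = 3,
                        min_genes = 5, restart = 0.8, normalize = TRUE) {
  method <- match.arg(method)
  if (decoys < 1) stop("decoys must be >= 1")
  if (any(ks < 1) || any(ks > decoys + 1)) stop("ks must lie in [1, decoys + 1]")
  check_weights(alpha, beta)
  structure(list(method = method, ks = sort(unique(as.integer(ks))),
                 decoys = as.integer(decoys), seed = as.integer(seed),
                 alpha = alpha, beta = beta, t = as.integer(t),
                 min_genes = as.integer(min_genes), restart = restart,
                 normalize = normalize),
            class = "eval_config")
}

method_weights <- function(cfg) {
  switch(cfg$method,
         dignifi = c(0, 0), lrw = c(0, 0), rwr = c(0, 0),
         simgo = c(cfg$alpha, 0),
         simcom = c(0, cfg$beta),
         simbio = c(cfg$alpha, cfg$beta))
}

#' Leave-one-out cross-validation with random decoys
#'
#' For every disease with at least `min_genes` known genes in the network
#' and every known gene of that disease: hold the gene out as the target,
#' seed with the remaining known genes, mix the target with `decoys` genes
#' drawn uniformly without replacement from the network genes excluding all
#' of the disease's known genes, rank the candidate set, and record the
#' target's rank. A target whose score is zero receives rank equal to the
#' candidate-set size. Success at k is the fraction of trials in which the
#' target ranked within the top k.
#'
#' @param net a [ppi_network()].
#' @param annot a [go_annotation_set()] (`NULL` allowed for purely
#'   topological methods).
#' @param catalog a [complex_catalog()] (`NULL` allowed likewise).
#' @param diseases named list mapping disease id to its known genes, as
#'   returned by [read_disease_genes()].
#' @param cfg an [eval_config()].
#' @return An object of class `eval_report`: list with `trials` (data.frame
#'   `disease`, `target`, `rank`), `success` (data.frame `k`, `successes`,
#'   `trials`, `rate`) and the configuration.
#' @export
loocv <- function(net, annot = NULL, catalog = NULL, diseases, cfg = eval_config()) {
  stopifnot(inherits(cfg, "eval_config"))
  wt <- method_weights(cfg)
  if (wt[1] > 0 && is.null(annot)) stop("method requires GO annotations")
  if (wt[2] > 0 && is.null(catalog)) stop("method requires a complex catalog")
  if (wt[2] > 0 && !is.null(catalog) && is.null(catalog$scores)) {
    catalog <- score_catalog(catalog, net)
  }
  cache <- new.env(parent = emptyenv())

  records <- list()
  trial <- 0L
  for (d in names(diseases)) {
    known_all <- intersect(unique(diseases[[d]]), net$nodes)
    if (length(known_all) < cfg$min_genes) {
      message(sprintf("loocv: skipping %s (%d gene(s) in network < min_genes = %d)",
                      d, length(known_all), cfg$min_genes))
      next
    }
    pool <- setdiff(net$nodes, known_all)
    if (length(pool) < cfg$decoys) {
      stop(sprintf("network too small to draw %d decoys for %s", cfg$decoys, d))
    }
    for (target in known_all) {
      trial <- trial + 1L
      seeds <- setdiff(known_all, target)
      decoys <- with_trial_seed(cfg$seed + trial, sample(pool, cfg$decoys))
      candidates <- c(target, decoys)
      rank <- rank_trial(net, annot, catalog, seeds, candidates, target, cfg, wt, cache)
      records[[trial]] <- data.frame(disease = d, target = target, rank = rank,
                                     stringsAsFactors = FALSE)
    }
  }
  if (trial == 0L) stop("no disease passed the min_genes filter")
  trials <- do.call(rbind, records)
  success <- data.frame(
    k = cfg$ks,
    successes = vapply(cfg$ks, function(k) sum(trials$rank <= k), 0L),
    trials = nrow(trials)
  )
  success$rate <- success$successes / success$trials
  structure(list(trials = trials, success = success, config = cfg),
            class = "eval_report")
}

# draw with a local, restored RNG state so evaluation does not perturb the
# caller's random stream
with_trial_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rank_trial <- function(net, annot, catalog, seeds, candidates, target, cfg, wt, cache) {
  if (cfg$method == "rwr") {
    scores <- rwr_scores(net, seeds, restart = cfg$restart)
    s <- scores[candidates]
    rank <- sum(s >= s[[target]])
    if (s[[target]] == 0) rank <- length(candidates)
    return(rank)
  }
  res <- rank_candidates(net, annot, catalog, seeds, candidates,
                         alpha = wt[1], beta = wt[2], t = cfg$t,
                         normalize = cfg$normalize,
                         topo_mode = if (cfg$method == "lrw") "lrw" else "auto",
                         cache = cache)
  res$rank[match(target, res$gene)]
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation: method %s, %d trials, %d decoys per trial\n",
              x$config$method, nrow(x$trials), x$config$decoys))
  print.data.frame(transform(x$success, rate = sprintf("%.2f%%", 100 * rate)))
  invisible(x)
}

#' Success rate at rank k
#'
#' The fraction of validation trials in which the held-out target gene was
#' ranked within the top `k` of its candidate set.
#'
#' @param report an `eval_report` from [loocv()], or a numeric vector of
#'   per-trial ranks.
#' @param k rank cutoff (integer >= 1).
#' @return success rate in `[0, 1]`.
#' @export
success_at_k <- function(report, k) {
  if (k < 1) stop("k must be >= 1")
  ranks <- if (inherits(report, "eval_report")) report$trials$rank else as.numeric(report)
  if (length(ranks) == 0L) stop("no trials to evaluate")
  mean(ranks <= k)
}

#' Random walk with restart scores
#'
#' Global diffusion baseline: iterates
#' \deqn{p(s+1) = (1 - r)\,P^T p(s) + r\,p_0}
#' with `p0` uniform over the seed genes, until the L1 change falls below
#' `tol`. The stationary probability of each gene is its candidate score.
#' With `r = 1` the walker never moves and the seed distribution is
#' returned.
#'
#' @param net a [ppi_network()].
#' @param seeds non-empty set of seed genes, all in the network.
#' @param restart restart probability in (0, 1] (default 0.8).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return named probability vector over all genes (sums to 1).
#' @export
rwr_scores <- function(net, seeds, restart = 0.8, tol = 1e-10, max_iter = 10000) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  check_genes(net, seeds)
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  P <- transition_matrix(net)
  n <- length(net$nodes)
  p0 <- stats::setNames(numeric(n), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  for (iter in seq_len(max_iter)) {
    p_new <- (1 - restart) * as.vector(Matrix::crossprod(P, p)) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- stats::setNames(p_new, net$nodes)
    if (delta < tol) return(p)
  }
  stop(sprintf("random walk with restart did not converge in %d iterations (last L1 change %.3e)",
               max_iter, delta))
}

#' Compare two sets of per-trial ranks
#'
#' Thin reporting utility: a two-tailed t test on the per-trial ranks of two
#' methods over the same trials, used to ask whether the rank distributions
#' differ beyond chance.
#'
#' @param ranks_a,ranks_b numeric vectors of per-trial ranks (or
#'   `eval_report` objects over identical trials).
#' @param paired treat the trials as paired (default `TRUE` when lengths
#'   match).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_rankings <- function(ranks_a, ranks_b, paired = NULL) {
  if (inherits(ranks_a, "eval_report")) ranks_a <- ranks_a$trials$rank
  if (inherits(ranks_b, "eval_report")) ranks_b <- ranks_b$trials$rank
  if (is.null(paired)) paired <- length(ranks_a) == length(ranks_b)
  stats::t.test(ranks_a, ranks_b, paired = paired)
}
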