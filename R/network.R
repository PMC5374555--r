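#' Construct a cleaned PPI network from an edge table
#'
#' Builds the undirected, weighted interaction network used throughout the
#' package. Cleaning applies the standard preprocessing for curated PPI data:
#' self-interactions are dropped, duplicate records of the same unordered
#' gene pair are collapsed (keeping the maximum weight), zero-weight edges
#' are removed, and any gene left without an interaction disappears from the
#' node set, so every retained gene has strength `K > 0` and random-walk
#' transition rows are always defined.
#'
#' @param edges data.frame with columns `from`, `to` (gene identifiers,
#'   treated as opaque case-sensitive strings) and optionally `weight`
#'   (non-negative; defaults to 1 for curated binary interactions).
#' @return An object of class `ppi_network`: a list with
#'   \describe{
#'     \item{edges}{cleaned edge table (`from`, `to`, `weight`), one row per
#'       unordered pair}
#'     \item{nodes}{character vector of gene identifiers}
#'     \item{adjacency}{symmetric sparse weight matrix with gene dimnames}
#'     \item{strength}{named vector `K`, the total edge weight incident to
#'       each gene}
#'     \item{n_edges}{`M`, the number of (unordered) interactions}
#'   }
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  if (anyNA(weight) || any(weight < 0)) {
    stop("edge weights must be non-negative numbers")
  }

  keep <- from != to & weight > 0
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  if (length(from) == 0L) {
    stop("network is empty after removing self-interactions and zero-weight edges")
  }

  # canonical unordered orientation, then collapse duplicates keeping max weight
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, max)
  first <- !duplicated(key)
  ord <- match(names(w), key[first])
  edge_tab <- data.frame(
    from = a[first][ord], to = b[first][ord],
    weight = as.numeric(w), stringsAsFactors = FALSE
  )
  edge_tab <- edge_tab[order(edge_tab$from, edge_tab$to), , drop = FALSE]
  rownames(edge_tab) <- NULL

  nodes <- sort(unique(c(edge_tab$from, edge_tab$to)))
  i <- match(edge_tab$from, nodes)
  j <- match(edge_tab$to, nodes)
  adjacency <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edge_tab$weight, 2L),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  strength <- Matrix::rowSums(adjacency)
  names(strength) <- nodes

  structure(
    list(
      edges = edge_tab,
      nodes = nodes,
      adjacency = adjacency,
      strength = strength,
      n_edges = nrow(edge_tab)
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "PPI network: %d genes, %d interactions (total edge weight %.6g)\n",
    length(x$nodes), x$n_edges, sum(x$edges$weight)
  ))
  invisible(x)
}

#' Read a PPI network from an edge-list file
#'
#' Parses a whitespace/tab-separated edge list (`geneA geneB [weight]`,
#' lines beginning with `#` ignored) and returns the cleaned
#' [ppi_network()]. Duplicate records keep the maximum weight,
#' self-interactions are dropped, and genes without any surviving
#' interaction are removed.
#'
#' @param path path to the edge-list file.
#' @param weighted if `TRUE`, a third numeric column is read as the edge
#'   weight (missing third column means weight 1); if `FALSE` all edges get
#'   weight 1.
#' @param quiet suppress the node/edge count message.
#' @return A [ppi_network()].
#' @export
read_network <- function(path, weighted = FALSE, quiet = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed edge list: line %d has fewer than 2 fields", idx[which(nf < 2L)[1L]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  if (weighted) {
    wtxt <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1", "")
    weight <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(weight)) {
      stop(sprintf("malformed edge list: line %d has a non-numeric weight", idx[which(is.na(weight))[1L]]))
    }
  } else {
    weight <- rep(1, length(from))
  }
  net <- ppi_network(data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE))
  if (!quiet) {
    message(sprintf("read_network: %d genes, %d interactions after cleaning", length(net$nodes), net$n_edges))
  }
  net
}

#' Write a PPI network to an edge-list file
#'
#' Writes a tab-separated `from to weight` edge list. Reading the file back
#' with [read_network()] (with `weighted = TRUE`) reproduces the network
#' exactly, including fractional weights, which are printed with full
#' double precision.
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  lines <- sprintf(
    "%s\t%s\t%s",
    net$edges$from, net$edges$to,
    vapply(net$edges$weight, function(w) format(w, digits = 17), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-pair literature co-occurrence table
#'
#' Reads a tab-separated table `geneA geneB count`, where `count` is the
#' number of articles mentioning both genes. Self-pairs are dropped and
#' duplicate unordered pairs keep the maximum count.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `from`, `to`, `count`.
#' @export
read_cooccurrence <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("from", "to", "count"))
  cooccurrence_table(tab)
}

#' Validate a co-occurrence table
#'
#' @param tab data.frame with columns `from`, `to`, `count`.
#' @return the cleaned table (self-pairs removed, unordered pairs unique).
#' @export
cooccurrence_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("from", "to", "count") %in% names(tab)))
  from <- as.character(tab$from); to <- as.character(tab$to)
  count <- as.numeric(tab$count)
  if (anyNA(count) || any(count < 0) || any(count != floor(count))) {
    stop("article counts must be non-negative integers")
  }
  keep <- from != to
  a <- pmin(from[keep], to[keep]); b <- pmax(from[keep], to[keep])
  key <- paste(a, b, sep = "\r")
  cnt <- tapply(count[keep], key, max)
  first <- !duplicated(key)
  ord <- match(names(cnt), key[first])
  out <- data.frame(from = a[first][ord], to = b[first][ord],
                    count = as.numeric(cnt), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enrich a PPI network with literature co-occurrence pairs
#'
#' Gene pairs co-mentioned in at least `min_articles` articles that are not
#' already interactions are added as new edges with weight 1, treating
#' literature-derived links the same as curated binary interactions. Pairs
#' already present leave the network unchanged, so the operation is
#' idempotent.
#'
#' @param net a [ppi_network()].
#' @param co a co-occurrence table as returned by [read_cooccurrence()] or
#'   [cooccurrence_table()].
#' @param min_articles minimum article count for a pair to be trusted
#'   (default 30).
#' @param quiet suppress the added/overlapping count message.
#' @return A new [ppi_network()] containing the union of edges.
#' @export
enrich_with_cooccurrence <- function(net, co, min_articles = 30, quiet = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  if (min_articles < 1) stop("min_articles must be >= 1")
  co <- cooccurrence_table(co)
  pass <- co[co$count >= min_articles, , drop = FALSE]
  existing <- paste(net$edges$from, net$edges$to, sep = "\r")
  key <- paste(pmin(pass$from, pass$to), pmax(pass$from, pass$to), sep = "\r")
  new <- pass[!(key %in% existing), , drop = FALSE]
  if (!quiet) {
    message(sprintf(
      "enrich_with_cooccurrence: %d pairs pass threshold, %d overlap existing edges, %d added",
      nrow(pass), nrow(pass) - nrow(new), nrow(new)
    ))
  }
  if (nrow(new) == 0L) return(net)
  ppi_network(rbind(
    net$edges,
    data.frame(from = new$from, to = new$to, weight = 1, stringsAsFactors = FALSE)
  ))
}

# internal: TRUE if (i, j) is an edge
has_edge <- function(net, i, j) {
  net$adjacency[i, j] > 0
}

check_genes <- function(net, genes) {
  missing <- setdiff(genes, net$nodes)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in network: %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
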