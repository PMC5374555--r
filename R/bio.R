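#' Build a GO annotation set from a gene-to-term mapping
#'
#' Pools annotations from all three ontology aspects (biological process,
#' molecular function, cellular component) into one gene-to-term map and
#' derives, per term, its annotation size (the number of genes carrying that
#' term) together with `S_max`, the largest annotation size over all terms
#' in the corpus. Annotation sizes are the information signal behind
#' [go_similarity()]: a term annotating few genes is specific, a term
#' annotating `S_max` genes carries no information.
#'
#' @param gene2terms named list mapping each gene to a character vector of
#'   GO term ids.
#' @return An object of class `go_annotation_set`: list with `gene2terms`
#'   (duplicates removed), `term_sizes` (named integer vector) and `s_max`.
#' @export
go_annotation_set <- function(gene2terms) {
  stopifnot(is.list(gene2terms), !is.null(names(gene2terms)))
  gene2terms <- lapply(gene2terms, function(x) unique(as.character(x)))
  gene2terms <- gene2terms[lengths(gene2terms) > 0L]
  if (length(gene2terms) == 0L) stop("annotation set is empty")
  term_sizes <- table(unlist(gene2terms, use.names = FALSE))
  term_sizes <- stats::setNames(as.integer(term_sizes), names(term_sizes))
  structure(
    list(gene2terms = gene2terms, term_sizes = term_sizes,
         s_max = max(term_sizes)),
    class = "go_annotation_set"
  )
}

#' @export
print.go_annotation_set <- function(x, ...) {
  cat(sprintf("GO annotation set: %d genes, %d terms, S_max = %d\n",
              length(x$gene2terms), length(x$term_sizes), x$s_max))
  invisible(x)
}

#' Read GO annotations from a simplified two-column TSV
#'
#' Each line is `gene<TAB>term`; `#` comment lines are ignored.
#'
#' @param path path to the TSV file.
#' @return A [go_annotation_set()].
#' @export
read_gene2go <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("gene", "term"))
  go_annotation_set(split(tab$term, tab$gene))
}

#' Read GO annotations from a GAF 2.x file
#'
#' Uses column 2 (gene symbol), column 5 (GO id) and column 7 (evidence
#' code) of the Gene Ontology Annotation File format; header lines starting
#' with `!` are skipped. All three ontology aspects are pooled.
#'
#' @param path path to the GAF file.
#' @param exclude_iea drop electronically inferred (IEA) annotations
#'   (default `FALSE`: all evidence codes are kept to maximise coverage).
#' @return A [go_annotation_set()].
#' @export
read_gaf <- function(path, exclude_iea = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 7L
  if (any(short)) stop(sprintf("malformed GAF record at line %d", which(short)[1L]))
  gene <- vapply(fields, `[[`, "", 2L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  if (exclude_iea) {
    keep <- evidence != "IEA"
    gene <- gene[keep]; term <- term[keep]
  }
  go_annotation_set(split(term, gene))
}

#' GO semantic similarity of a gene pair
#'
#' Information-content style similarity from shared annotations: among the
#' GO terms annotating both genes, take the one with the smallest annotation
#' size (the most specific shared term) and score
#' \deqn{SimGO(i, j) = -\log\left(\frac{\min_k |S_k|}{S_{max}}\right)}
#' where \eqn{|S_k|} is the number of genes annotated with shared term
#' \eqn{g_k} and \eqn{S_{max}} the largest annotation size in the corpus.
#' Genes with no shared term — or genes absent from the annotation corpus —
#' score 0; so does a pair whose only shared term is the most general one.
#'
#' @param annot a [go_annotation_set()].
#' @param v_i,v_j gene identifiers.
#' @param log_base base of the logarithm (default natural log; the choice
#'   only rescales the score and is absorbed by the combination weight
#'   `alpha`).
#' @return non-negative, symmetric similarity score.
#' @export
go_similarity <- function(annot, v_i, v_j, log_base = exp(1)) {
  stopifnot(inherits(annot, "go_annotation_set"))
  ti <- annot$gene2terms[[v_i]]
  tj <- annot$gene2terms[[v_j]]
  if (is.null(ti) || is.null(tj)) {
    warning(sprintf("gene(s) without GO annotations: %s",
                    paste(c(v_i, v_j)[c(is.null(ti), is.null(tj))], collapse = ", ")))
    return(0)
  }
  shared <- intersect(ti, tj)
  if (length(shared) == 0L) return(0)
  -log(min(annot$term_sizes[shared]) / annot$s_max, base = log_base)
}

# internal: |rows| x |cols| GO similarity matrix; unannotated genes score 0
# silently (ranking treats missing annotation as absence of evidence).
go_sim_matrix <- function(annot, rows, cols, log_base = exp(1)) {
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  trow <- annot$gene2terms[rows]
  tcol <- annot$gene2terms[cols]
  sizes <- annot$term_sizes
  smax <- annot$s_max
  for (i in seq_along(rows)) {
    ti <- trow[[i]]
    if (is.null(ti)) next
    si <- sizes[ti]
    for (j in seq_along(cols)) {
      tj <- tcol[[j]]
      if (is.null(tj) || rows[i] == cols[j]) next
      m <- si[ti %in% tj]
      if (length(m) > 0L) out[i, j] <- -log(min(m) / smax, base = log_base)
    }
  }
  out
}

#' Build a protein complex catalog
#'
#' @param complexes named list mapping complex id to a character vector of
#'   member genes.
#' @return An object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes), !is.null(names(complexes)))
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  structure(list(complexes = complexes, scores = NULL), class = "complex_catalog")
}

#' Read a protein complex catalog from TSV
#'
#' Each line is `complex_id<TAB>gene1;gene2;...` (a CORUM-export-like
#' layout); `#` comment lines are ignored.
#'
#' @param path path to the TSV file.
#' @return A [complex_catalog()].
#' @export
read_complexes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("id", "members"))
  complex_catalog(stats::setNames(strsplit(tab$members, ";", fixed = TRUE), tab$id))
}

#' Network reliability score of a protein complex
#'
#' How richly a complex's members interact in the network:
#' \deqn{Score(C) = density(C) \cdot \frac{w^{in}(C)}{w^{in}(C) + w^{bound}(C)}}
#' where the density is `2 |E_C| / (|V_C| (|V_C| - 1))` on the subgraph
#' induced by the members present in the network, `w_in` is the total weight
#' of edges with both endpoints in the complex and `w_bound` the total
#' weight of edges crossing its boundary. A complex with fewer than two
#' members in the network, or whose present members share no interaction,
#' scores 0. On a binary network the score lies in `[0, 1]` and equals 1
#' exactly for an isolated clique.
#'
#' @param net a [ppi_network()].
#' @param members character vector of member genes (genes absent from the
#'   network are ignored).
#' @return score in `[0, 1]` for edge weights in `[0, 1]`.
#' @export
complex_score <- function(net, members) {
  stopifnot(inherits(net, "ppi_network"))
  present <- intersect(unique(members), net$nodes)
  p <- length(present)
  if (p < 2L) return(0)
  sub <- net$adjacency[present, present, drop = FALSE]
  w_in <- sum(sub) / 2
  if (w_in == 0) return(0)
  n_in <- Matrix::nnzero(sub) / 2
  density <- 2 * n_in / (p * (p - 1))
  w_bound <- sum(net$strength[present]) - 2 * w_in
  density * w_in / (w_in + w_bound)
}

#' Score every complex in a catalog against a network
#'
#' Computes [complex_score()] for each complex and indexes gene
#' co-membership, which makes repeated [complex_similarity()] calls cheap.
#'
#' @param catalog a [complex_catalog()].
#' @param net a [ppi_network()].
#' @return the catalog with a `scores` vector and a `gene2complexes` index.
#' @export
score_catalog <- function(catalog, net) {
  stopifnot(inherits(catalog, "complex_catalog"))
  scores <- vapply(catalog$complexes, function(m) complex_score(net, m), 0)
  pairs <- data.frame(
    gene = unlist(catalog$complexes, use.names = FALSE),
    id = rep(names(catalog$complexes), lengths(catalog$complexes)),
    stringsAsFactors = FALSE
  )
  catalog$scores <- scores
  catalog$gene2complexes <- split(pairs$id, pairs$gene)
  catalog
}

#' Protein-complex similarity of a gene pair
#'
#' Sum of the reliability scores of all complexes containing both genes;
#' 0 when the genes share no complex.
#'
#' @param catalog a [complex_catalog()], scored with [score_catalog()] (an
#'   unscored catalog is scored on the fly).
#' @param net a [ppi_network()].
#' @param v_i,v_j gene identifiers.
#' @return non-negative, symmetric similarity score.
#' @export
complex_similarity <- function(catalog, net, v_i, v_j) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (is.null(catalog$scores)) catalog <- score_catalog(catalog, net)
  shared <- intersect(catalog$gene2complexes[[v_i]], catalog$gene2complexes[[v_j]])
  if (length(shared) == 0L) return(0)
  sum(catalog$scores[shared])
}

# internal: |rows| x |cols| complex similarity matrix from a scored catalog
com_sim_matrix <- function(catalog, net, rows, cols) {
  if (is.null(catalog$scores)) catalog <- score_catalog(catalog, net)
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  crow <- catalog$gene2complexes[rows]
  ccol <- catalog$gene2complexes[cols]
  for (i in seq_along(rows)) {
    ci <- crow[[i]]
    if (is.null(ci)) next
    for (j in seq_along(cols)) {
      cj <- ccol[[j]]
      if (is.null(cj) || rows[i] == cols[j]) next
      shared <- ci[ci %in% cj]
      if (length(shared) > 0L) out[i, j] <- sum(catalog$scores[shared])
    }
  }
  out
}
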