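#' Specification of a synthetic disease-module benchmark
#'
#' Describes a self-contained synthetic data set with known ground truth:
#' a scale-free background interactome grown by preferential attachment,
#' plus a number of planted disease modules — small gene sets wired densely
#' among themselves and sparsely to the background — each annotated with
#' specific GO terms, partly wrapped as a protein complex, and registered as
#' one disease. The defaults define the package's reference benchmark.
#'
#' @param n_background number of background genes (default 500).
#' @param pa_edges preferential-attachment edges added per background gene
#'   (default 2, giving a sparse heavy-tailed degree distribution).
#' @param n_modules number of planted disease modules (default 20).
#' @param module_size genes per module (default 6; must be >= 3).
#' @param p_within probability of an edge between two genes of the same
#'   module (default 0.8; any module gene left unconnected is linked to a
#'   random module partner so every planted gene enters the network).
#' @param p_out probability of an edge between a module gene and each
#'   background gene (default 0.005, keeping modules weakly coupled to the
#'   interactome).
#' @param terms_per_module specific GO terms annotating exactly the genes of
#'   each module (default 2).
#' @param n_background_terms size of the pool of broad GO terms (default 30).
#' @param background_terms_per_gene broad terms drawn per background gene
#'   (default 3; the largest resulting term defines `S_max`).
#' @param module_background_terms broad terms drawn per module gene
#'   (default 1, so module genes also carry uninformative annotations).
#' @param complex_fraction fraction of each module wrapped as a protein
#'   complex (default 0.8).
#' @param n_noise_complexes additional complexes made of random background
#'   genes (default 5, size 4 each).
#' @param seed RNG seed; the same spec and seed give byte-identical
#'   fixtures (default 42, the reference benchmark).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_background = 500, pa_edges = 2,
                         n_modules = 20, module_size = 6,
                         p_within = 0.8, p_out = 0.005,
                         terms_per_module = 2, n_background_terms = 30,
                         background_terms_per_gene = 3,
                         module_background_terms = 1,
                         complex_fraction = 0.8, n_noise_complexes = 5,
                         seed = 42) {
  probs <- c(p_within = p_within, p_out = p_out, complex_fraction = complex_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop(sprintf("probabilities out of [0, 1]: %s", paste(names(probs)[bad], collapse = ", ")))
  if (module_size < 3) stop("module_size must be >= 3")
  if (n_background < 2 || pa_edges < 1 || n_modules < 1) {
    stop("need n_background >= 2, pa_edges >= 1, n_modules >= 1")
  }
  background_density <- pa_edges * 2 / n_background
  if (p_within <= background_density) {
    stop(sprintf("p_within (%g) must exceed the background edge density (%g)",
                 p_within, background_density))
  }
  structure(as.list(environment())[c(
    "n_background", "pa_edges", "n_modules", "module_size", "p_within",
    "p_out", "terms_per_module", "n_background_terms",
    "background_terms_per_gene", "module_background_terms",
    "complex_fraction", "n_noise_complexes", "seed"
  )], class = "fixture_spec")
}

#' Generate a synthetic disease-module benchmark
#'
#' Builds the four inputs of a prioritization run from a [fixture_spec()]:
#' the PPI network (background preferential-attachment graph plus planted
#' modules), GO annotations (module-specific terms plus a broad background
#' pool), a protein-complex catalog (a subset of each module plus noise
#' complexes), and a disease map listing each module's genes as one
#' disease. Output is fully determined by the spec's seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `network` ([ppi_network()]), `annotations`
#'   ([go_annotation_set()]), `complexes` ([complex_catalog()]), `diseases`
#'   (named list) and `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)

  bg_genes <- sprintf("BG%04d", seq_len(spec$n_background))
  g <- igraph::sample_pa(spec$n_background, m = spec$pa_edges, directed = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = bg_genes[as.integer(el[, 1])],
                      to = bg_genes[as.integer(el[, 2])],
                      stringsAsFactors = FALSE)

  module_genes <- lapply(seq_len(spec$n_modules), function(m) {
    sprintf("D%02dG%d", m, seq_len(spec$module_size))
  })
  for (m in seq_len(spec$n_modules)) {
    genes <- module_genes[[m]]
    pairs <- utils::combn(genes, 2)
    on <- stats::runif(ncol(pairs)) < spec$p_within
    within <- data.frame(from = pairs[1, on], to = pairs[2, on],
                         stringsAsFactors = FALSE)
    # guarantee every planted gene has at least one within-module edge
    lonely <- setdiff(genes, c(within$from, within$to))
    if (length(lonely) > 0L) {
      partner <- vapply(lonely, function(gn) sample(setdiff(genes, gn), 1L), "")
      within <- rbind(within, data.frame(from = lonely, to = partner,
                                         stringsAsFactors = FALSE))
    }
    out_mask <- matrix(stats::runif(length(genes) * spec$n_background) < spec$p_out,
                       nrow = length(genes))
    idx <- which(out_mask, arr.ind = TRUE)
    outward <- data.frame(from = genes[idx[, 1]], to = bg_genes[idx[, 2]],
                          stringsAsFactors = FALSE)
    edges <- rbind(edges, within, outward)
  }
  edges$weight <- 1
  network <- ppi_network(edges)

  bg_terms <- sprintf("GO:BG%04d", seq_len(spec$n_background_terms))
  annot <- lapply(stats::setNames(bg_genes, bg_genes), function(gn) {
    sample(bg_terms, min(spec$background_terms_per_gene, length(bg_terms)))
  })
  for (m in seq_len(spec$n_modules)) {
    terms <- sprintf("GO:M%02dT%d", m, seq_len(spec$terms_per_module))
    for (gn in module_genes[[m]]) {
      extra <- if (spec$module_background_terms > 0) {
        sample(bg_terms, min(spec$module_background_terms, length(bg_terms)))
      } else character()
      annot[[gn]] <- c(terms, extra)
    }
  }
  annotations <- go_annotation_set(annot)

  complexes <- list()
  for (m in seq_len(spec$n_modules)) {
    size <- max(2L, round(spec$complex_fraction * spec$module_size))
    complexes[[sprintf("CPX_M%02d", m)]] <- sort(sample(module_genes[[m]], size))
  }
  for (i in seq_len(spec$n_noise_complexes)) {
    complexes[[sprintf("CPX_BG%02d", i)]] <- sort(sample(bg_genes, 4L))
  }
  catalog <- complex_catalog(complexes)

  diseases <- stats::setNames(module_genes, sprintf("DIS%02d", seq_len(spec$n_modules)))

  list(network = network, annotations = annotations, complexes = catalog,
       diseases = diseases, spec = spec)
}

#' Write synthetic fixtures in the package's input file formats
#'
#' Emits `ppi.tsv` (edge list), `annot.tsv` (gene-term pairs),
#' `complexes.tsv` and `diseases.tsv` into a directory, in exactly the
#' formats the readers ([read_network()], [read_gene2go()],
#' [read_complexes()], [read_disease_genes()]) consume, so tests can cover
#' the I/O paths end to end.
#'
#' @param fixtures result of [generate_fixtures()].
#' @param dir output directory (created if missing).
#' @return named vector of the four file paths, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "ppi.tsv"),
             annotations = file.path(dir, "annot.tsv"),
             complexes = file.path(dir, "complexes.tsv"),
             diseases = file.path(dir, "diseases.tsv"))
  write_network(fixtures$network, paths[["network"]])
  g2t <- fixtures$annotations$gene2terms
  writeLines(sprintf("%s\t%s", rep(names(g2t), lengths(g2t)),
                     unlist(g2t, use.names = FALSE)),
             paths[["annotations"]])
  cx <- fixtures$complexes$complexes
  writeLines(sprintf("%s\t%s", names(cx),
                     vapply(cx, paste, "", collapse = ";")),
             paths[["complexes"]])
  writeLines(sprintf("%s\t%s", names(fixtures$diseases),
                     vapply(fixtures$diseases, paste, "", collapse = ";")),
             paths[["diseases"]])
  invisible(paths)
}

#' Curated degenerate networks for edge-case testing
#'
#' Small pathological graphs exercising boundary behaviour of the
#' similarity measures: an isolated interacting pair, a three-gene path, a
#' triangle, a star (one hub), two disconnected cliques, and a hub bridging
#' two cliques.
#'
#' @return named list of lists, each with `network` (a [ppi_network()]) and
#'   `description`.
#' @export
degenerate_networks <- function() {
  mk <- function(from, to) {
    ppi_network(data.frame(from = from, to = to, weight = 1,
                           stringsAsFactors = FALSE))
  }
  list(
    dyad = list(
      network = mk("A", "B"),
      description = "isolated interacting pair; both strengths 1"
    ),
    path = list(
      network = mk(c("A", "B"), c("B", "C")),
      description = "three-gene path; endpoints meet only by a 2-step walk"
    ),
    triangle = list(
      network = mk(c("A", "B", "C"), c("B", "C", "A")),
      description = "triangle; every edge has one shared neighbour"
    ),
    star = list(
      network = mk(rep("HUB", 5), paste0("L", 1:5)),
      description = "star; the hub penalty depresses leaf-hub similarity"
    ),
    two_cliques = list(
      network = mk(c("A", "A", "B", "X", "X", "Y"),
                   c("B", "C", "C", "Y", "Z", "Z")),
      description = "two disconnected triangles; cross-component walk probability is zero"
    ),
    bridged_cliques = list(
      network = mk(c("A", "A", "B", "X", "X", "Y", "HUB", "HUB"),
                   c("B", "C", "C", "Y", "Z", "Z", "A", "X")),
      description = "two triangles joined through a hub gene"
    )
  )
}
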