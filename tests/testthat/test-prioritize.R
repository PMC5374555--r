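test_that("combination weights are validated and degenerate correctly", {
  bundle <- toy_bundle()
  net <- bundle$network; annot <- bundle$annotations
  catalog <- score_catalog(bundle$complexes, net)
  g <- bundle$diseases$DIS01[1:2]
  expect_error(combined_similarity(net, annot, catalog, g[1], g[2],
                                   alpha = 0.7, beta = 0.5), "exceed 1")
  expect_equal(combined_similarity(net, annot, catalog, g[1], g[2],
                                   alpha = 0, beta = 0),
               topo_similarity(net, g[1], g[2]), tolerance = 1e-12)
  expect_equal(combined_similarity(net, annot, catalog, g[1], g[2],
                                   alpha = 1, beta = 0),
               go_similarity(annot, g[1], g[2]), tolerance = 1e-12)
  expect_equal(combined_similarity(net, annot, catalog, g[1], g[2],
                                   alpha = 0, beta = 1),
               complex_similarity(catalog, net, g[1], g[2]), tolerance = 1e-12)
})

test_that("ranking validates its inputs", {
  net <- degenerate_networks()$triangle$network
  expect_error(rank_candidates(net, known = character(), candidates = "A"),
               "empty")
  expect_error(rank_candidates(net, known = "A", candidates = c("A", "B")),
               "disjoint")
  expect_warning(
    res <- rank_candidates(net, known = c("A", "GHOST"), candidates = "B",
                           alpha = 0, beta = 0),
    "not in the network"
  )
  expect_equal(nrow(res), 1L)
  expect_error(suppressWarnings(
    rank_candidates(net, known = "GHOST", candidates = "B", alpha = 0, beta = 0)
  ), "no known gene")
})

test_that("tied candidates all receive the pessimistic (last) rank", {
  star <- degenerate_networks()$star$network
  res <- rank_candidates(star, known = "HUB", candidates = paste0("L", 1:5),
                         alpha = 0, beta = 0)
  expect_equal(res$rank, rep(5L, 5))
  expect_true(all(res$score > 0))
})

test_that("zero-score candidates rank at the candidate-set size", {
  two <- degenerate_networks()$two_cliques$network
  res <- rank_candidates(two, known = c("A", "B"), candidates = c("C", "X", "Y"),
                         alpha = 0, beta = 0)
  expect_equal(res$score[match(c("X", "Y"), res$gene)], c(0, 0))
  expect_equal(res$rank[match(c("X", "Y"), res$gene)], c(3L, 3L))
  expect_equal(res$rank[match("C", res$gene)], 1L)
  # candidates absent from the network also score zero
  res2 <- rank_candidates(two, known = c("A", "B"), candidates = c("C", "OFFNET"),
                          alpha = 0, beta = 0)
  expect_equal(res2$score[res2$gene == "OFFNET"], 0)
  expect_equal(res2$rank[res2$gene == "OFFNET"], 2L)
})

test_that("candidate order never affects scores or ranks", {
  bundle <- toy_bundle()
  catalog <- score_catalog(bundle$complexes, bundle$network)
  known <- bundle$diseases$DIS02[-1]
  cands <- c(bundle$diseases$DIS02[1], sort(setdiff(bundle$network$nodes, unlist(bundle$diseases)))[1:20])
  ref <- rank_candidates(bundle$network, bundle$annotations, catalog, known, cands)
  set.seed(2)
  for (i in 1:3) {
    perm <- rank_candidates(bundle$network, bundle$annotations, catalog, known,
                            sample(cands))
    expect_equal(perm[order(perm$gene), ], ref[order(ref$gene), ],
                 ignore_attr = TRUE)
  }
})

test_that("scores are additive over disjoint seed sets when rescaling is off", {
  bundle <- toy_bundle()
  net <- bundle$network
  catalog <- score_catalog(bundle$complexes, net)
  known <- bundle$diseases$DIS03
  a <- known[1:3]; b <- known[4:6]
  cands <- sort(setdiff(net$nodes, known))[1:25]
  sc <- function(k) {
    res <- rank_candidates(net, bundle$annotations, catalog, k, cands,
                           normalize = FALSE)
    res$score[order(res$gene)]
  }
  expect_equal(sc(known), sc(a) + sc(b), tolerance = 1e-10)
})

test_that("raising a candidate's similarity to a seed never worsens its rank", {
  # add an edge between the candidate and a seed: its score gains a DN term
  base <- random_connected_net(15, seed = 8)
  known <- base$nodes[1:3]
  cands <- base$nodes[4:12]
  pick <- cands[5]
  before <- rank_candidates(base, known = known, candidates = cands,
                            alpha = 0, beta = 0, normalize = FALSE)
  boosted <- ppi_network(rbind(base$edges,
                               data.frame(from = pick, to = known[1], weight = 1)))
  after <- rank_candidates(boosted, known = known, candidates = cands,
                           alpha = 0, beta = 0, normalize = FALSE)
  expect_lte(after$rank[after$gene == pick], before$rank[before$gene == pick])
})

test_that("genome-wide mode excludes known genes and clamps top_n", {
  bundle <- toy_bundle()
  net <- bundle$network
  known <- bundle$diseases$DIS01
  res <- rank_genome(net, bundle$annotations,
                     score_catalog(bundle$complexes, net), known, top_n = 10)
  expect_equal(nrow(res), 10L)
  expect_length(intersect(res$gene, known), 0L)
  all_res <- rank_genome(net, known = known, alpha = 0, beta = 0, top_n = 1e6)
  expect_equal(nrow(all_res), length(setdiff(net$nodes, known)))
  tiny <- degenerate_networks()$dyad$network
  expect_error(rank_genome(tiny, known = c("A", "B"), alpha = 0, beta = 0),
               "no candidate genes")
})

test_that("disease gene table reader parses the semicolon format", {
  path <- withr::local_tempfile(lines = c("DIS1\tA;B;C", "DIS2\tX;Y"))
  dm <- read_disease_genes(path)
  expect_identical(dm, list(DIS1 = c("A", "B", "C"), DIS2 = c("X", "Y")))
})
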