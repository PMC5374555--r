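test_that("success rates count ranks at or below k", {
  ranks <- c(1, 5, 100)
  expect_equal(success_at_k(ranks, 1), 1 / 3)
  expect_equal(success_at_k(ranks, 5), 2 / 3)
  expect_equal(success_at_k(ranks, 100), 1)
  expect_error(success_at_k(numeric(), 1), "no trials")
  expect_error(success_at_k(ranks, 0), "k must be")
})

test_that("success rates print to the same two-decimal percentages as ratio arithmetic", {
  ranks <- c(rep(1, 576), rep(100, 1184 - 576))
  expect_equal(sprintf("%.2f%%", 100 * success_at_k(ranks, 1)), "48.65%")
  ranks <- c(rep(1, 553), rep(100, 1184 - 553))
  expect_equal(sprintf("%.2f%%", 100 * success_at_k(ranks, 1)), "46.71%")
})

test_that("evaluation configuration is validated", {
  expect_error(eval_config(decoys = 0), "decoys")
  expect_error(eval_config(ks = 0:5), "ks must lie")
  expect_error(eval_config(ks = 1:20, decoys = 9), "ks must lie")
  expect_error(eval_config(alpha = 0.8, beta = 0.8), "exceed 1")
  expect_identical(eval_config(method = "dignifi")$method, "dignifi")
})

test_that("leave-one-out reports are deterministic under a fixed seed", {
  bundle <- toy_bundle()
  catalog <- score_catalog(bundle$complexes, bundle$network)
  cfg <- eval_config(method = "simbio", decoys = 20, ks = 1:5, seed = 9,
                     min_genes = 5)
  r1 <- loocv(bundle$network, bundle$annotations, catalog, bundle$diseases, cfg)
  r2 <- loocv(bundle$network, bundle$annotations, catalog, bundle$diseases, cfg)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$success, r2$success)
  # a different seed keeps the trial layout (diseases and targets) intact
  r3 <- loocv(bundle$network, bundle$annotations, catalog, bundle$diseases,
              eval_config(method = "simbio", decoys = 20, ks = 1:5, seed = 10))
  expect_identical(r3$trials[c("disease", "target")],
                   r1$trials[c("disease", "target")])
})

test_that("success@k is monotone in k and consistent with the trial records", {
  bundle <- toy_bundle()
  cfg <- eval_config(method = "dignifi", decoys = 20, ks = 1:10, seed = 4)
  rep <- loocv(bundle$network, diseases = bundle$diseases, cfg = cfg)
  expect_true(all(diff(rep$success$rate) >= 0))
  for (k in c(1, 5, 10)) {
    expect_equal(success_at_k(rep, k),
                 rep$success$rate[rep$success$k == k])
  }
})

test_that("diseases below the min-genes filter are skipped with a message", {
  bundle <- toy_bundle()
  diseases <- c(bundle$diseases, list(TINY = bundle$network$nodes[1:2]))
  cfg <- eval_config(method = "dignifi", decoys = 10, ks = 1:3, seed = 1)
  expect_message(
    rep <- loocv(bundle$network, diseases = diseases, cfg = cfg),
    "skipping TINY"
  )
  expect_false("TINY" %in% rep$trials$disease)
  expect_error(
    suppressMessages(loocv(bundle$network, diseases = list(TINY = "BG0001"), cfg = cfg)),
    "no disease passed"
  )
})

test_that("a target unreachable by walk, annotation or complex ranks last", {
  # disease genes in one clique, target planted in a disconnected clique
  two <- degenerate_networks()$two_cliques$network
  res <- rank_candidates(two, known = c("A", "B", "C"),
                         candidates = c("X", "Y", "Z"), alpha = 0, beta = 0)
  expect_equal(res$score, rep(0, 3))
  expect_equal(res$rank, rep(3L, 3))
})

test_that("random walk with restart matches a closed-form dyad and the seed fixed point", {
  dy <- degenerate_networks()$dyad$network
  r <- 0.8
  # two-state balance: p_A = (1 - r) p_B + r, p_B = (1 - r) p_A
  pA <- 1 / (1 + (1 - r)) ; pB <- (1 - r) * pA
  p <- rwr_scores(dy, "A", restart = r)
  expect_equal(unname(p), c(pA, pB), tolerance = 1e-9)
  expect_equal(rwr_scores(dy, "A", restart = 1), c(A = 1, B = 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(rwr_scores(dy, character()), "non-empty")
  expect_error(rwr_scores(dy, "A", restart = 0.8, max_iter = 1), "did not converge")
})

test_that("iterated restart walk agrees with a direct linear solve", {
  set.seed(12)
  for (g in 1:5) {
    net <- random_connected_net(sample(10:50, 1))
    seeds <- sample(net$nodes, sample(1:3, 1))
    p <- rwr_scores(net, seeds, restart = 0.8)
    expect_equal(unname(p), unname(rwr_oracle(net, seeds, 0.8)[net$nodes]),
                 tolerance = 1e-8)
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
})

test_that("the restart-walk baseline runs inside the decoy protocol", {
  bundle <- toy_bundle()
  cfg <- eval_config(method = "rwr", decoys = 20, ks = 1:5, seed = 6)
  rep <- loocv(bundle$network, diseases = bundle$diseases, cfg = cfg)
  expect_equal(nrow(rep$trials), 18L)  # 3 modules x 6 genes
  expect_true(all(rep$trials$rank >= 1 & rep$trials$rank <= 21))
})

test_that("the LRW-only comparator scores adjacent pairs by the walk, not DN", {
  bundle <- toy_bundle()
  known <- bundle$diseases$DIS01[-1]
  target <- bundle$diseases$DIS01[1]
  cands <- c(target, sort(setdiff(bundle$network$nodes, bundle$diseases$DIS01))[1:10])
  lrw_res <- rank_candidates(bundle$network, known = known, candidates = cands,
                             alpha = 0, beta = 0, topo_mode = "lrw",
                             normalize = FALSE)
  expected <- sum(vapply(known, function(s) {
    lrw_similarity(bundle$network, s, target)
  }, 0))
  expect_equal(lrw_res$score[lrw_res$gene == target], expected, tolerance = 1e-10)
})

test_that("rank-list comparison wraps a two-tailed t test", {
  out <- compare_rankings(c(1, 2, 3, 10, 20), c(5, 9, 14, 30, 40))
  expect_s3_class(out, "htest")
  expect_match(out$alternative, "two.sided")
})

test_that("decoy draws do not disturb the caller's random stream", {
  bundle <- toy_bundle()
  cfg <- eval_config(method = "dignifi", decoys = 10, ks = 1:3, seed = 2)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(loocv(bundle$network, diseases = bundle$diseases, cfg = cfg))
  expect_identical(runif(1), before)
})
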