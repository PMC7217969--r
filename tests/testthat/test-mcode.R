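test_that("vertex weights match hand computations", {
  # isolated 5-clique: every closed neighborhood is K5 -> 4-core, density 1
  k5 <- complexes_to_edges(gene_set_collection(list(K = sprintf("V%d", 1:5))))
  w <- mcode_vertex_weights(k5)
  expect_equal(unname(w), rep(4, 5))
  # star with 10 leaves: center weight = 1 * density(K1,10), leaves get 0
  star <- toy_net(paste0("HUB-L", sprintf("%02d", 1:10)))
  ws <- mcode_vertex_weights(star)
  expect_equal(unname(ws["HUB"]), 1 * 2 * 10 / (11 * 10))
  expect_true(all(ws[names(ws) != "HUB"] == 0))
  # isolated / degree-1 vertices are below the degree cutoff
  path2 <- toy_net("A-B", nodes = "Z")
  expect_true(all(mcode_vertex_weights(path2) == 0))
})

test_that("vertex weights equal the brute-force k-core oracle on random graphs", {
  for (s in 1:8) {
    net <- er_net(12, 0.3, seed = s)
    adj <- net_adj(net)
    w <- mcode_vertex_weights(net)
    for (v in seq_along(net$nodes)) {
      expect_equal(unname(w[net$nodes[v]]), oracle_vertex_weight(adj, v),
                   tolerance = 1e-12,
                   label = sprintf("seed %d vertex %s", s, net$nodes[v]))
    }
  }
})

test_that("weights are invariant under relabeling", {
  net <- er_net(15, 0.25, seed = 2)
  w <- mcode_vertex_weights(net)
  relab <- stats::setNames(sprintf("Z%02d", seq_along(net$nodes)), net$nodes)
  net2 <- interaction_network(data.frame(from = unname(relab[net$edges$from]),
                                         to = unname(relab[net$edges$to])),
                              nodes = unname(relab))
  w2 <- mcode_vertex_weights(net2)
  expect_equal(unname(w2[unname(relab[names(w)])]), unname(w))
})

test_that("two disjoint 5-cliques resolve into exactly the two cliques", {
  c1 <- sprintf("A%d", 1:5); c2 <- sprintf("B%d", 1:5)
  net <- complexes_to_edges(gene_set_collection(list(K1 = c1, K2 = c2)))
  mods <- mcode_find_modules(net)
  expect_length(mods, 2L)
  got <- lapply(mods, `[[`, "genes")
  expect_setequal(got[[1]], sort(c1))
  expect_setequal(got[[2]], sort(c2))
  # exhaustive oracle on this 10-node instance: the 5-cliques are the
  # maximum of density x size over all subgraphs
  adj <- net_adj(net)
  best <- 0
  for (size in 3:6) {
    for (sub in utils::combn(10, size, simplify = FALSE)) {
      m <- adj[sub, sub]
      best <- max(best, sum(m) / (size * (size - 1)) * size)
    }
  }
  expect_equal(mods[[1]]$mcode_score, best)  # score 5 = density 1 x 5 nodes
})

test_that("a single bridge merges equal-weight cliques (VWP cannot separate)", {
  # every vertex of a bridged clique pair weighs exactly 4 (its closed
  # neighborhood's highest core is its own clique), so the bridge endpoint
  # always passes the seed-relative weight threshold and the expansion
  # walks across the bridge: one module holding both cliques
  c1 <- sprintf("A%d", 1:5); c2 <- sprintf("B%d", 1:5)
  net <- merge_networks(
    complexes_to_edges(gene_set_collection(list(K1 = c1, K2 = c2))),
    toy_net("A1-B1"))
  w <- mcode_vertex_weights(net)
  expect_equal(unname(w), rep(4, 10))
  mods <- mcode_find_modules(net)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$genes, c(c1, c2))
})

test_that("module assignment is a partition", {
  for (s in 1:5) {
    net <- er_net(40, 0.12, seed = s)
    mods <- mcode_find_modules(net)
    allg <- unlist(lapply(mods, `[[`, "genes"))
    expect_equal(anyDuplicated(allg), 0L)
  }
})

test_that("sparse random graphs never produce dense modules", {
  # G(30, 0.05) is supercritical, so chains/cycles of degree-2 vertices often
  # survive the 2-core filter (see the methods vignette) -- but no module
  # approaches planted-complex density: scores stay at triangle level (<= 4)
  # while a planted 8-clique scores 8.
  scores <- vapply(1:50, function(s) {
    mods <- mcode_find_modules(er_net(30, 0.05, seed = s))
    if (length(mods)) max(vapply(mods, `[[`, 0, "mcode_score")) else 0
  }, 0)
  expect_lte(max(scores), 4)
})

test_that("a planted 8-clique is recovered from background noise", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_genes = 100L,
                      planted_complexes = list(list(size = 8L, within_edge_prob = 1.0)),
                      sl_complex_idx = 1L, background_edge_prob = 0.05)
    w <- gen_network_and_truth(cfg)
    mods <- mcode_find_modules(w$network)
    truth <- w$truth$sets$COMPLEX1
    if (length(mods)) {
      j <- length(intersect(mods[[1]]$genes, truth)) /
        length(union(mods[[1]]$genes, truth))
      if (j >= 0.9) ok <- ok + 1L
    }
  }
  expect_gte(ok, 19L)
})

test_that("filter_multistudy_modules keeps multiply-supported modules", {
  m1 <- structure(list(genes = c("A", "B"), mcode_score = 2, size = 2L),
                  class = "ModuleResult")
  m2 <- structure(list(genes = c("C", "D"), mcode_score = 2, size = 2L),
                  class = "ModuleResult")
  s1 <- toy_study("S1", c("A", "X", "Y"), 1:3, k = 1)   # hit: A
  s2 <- toy_study("S2", c("B", "X", "Y"), 1:3, k = 1)   # hit: B
  kept <- filter_multistudy_modules(list(m1, m2), list(s1, s2))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$studies_present, c("S1", "S2"))
  # min_studies = 1 keeps any module with at least one hit; a module with
  # no hits at all (m2) is dropped under any positive threshold
  expect_length(filter_multistudy_modules(list(m1, m2), list(s1, s2),
                                          min_studies = 1L), 1L)
  expect_length(filter_multistudy_modules(list(m1, m2), list(s1, s2),
                                          min_studies = 0L), 2L)
  expect_length(filter_multistudy_modules(list(m2), list(s1, s2)), 0L)
})

test_that("enrich_module matches closed-form hypergeometric point masses", {
  background <- sprintf("G%04d", 1:1000)
  set10 <- background[1:10]
  gsc <- gene_set_collection(list(HIT = set10, MISS = background[900:920]))
  module <- structure(list(genes = set10), class = "ModuleResult")
  res <- enrich_module(module, gsc, background)
  hit <- res[res$set_name == "HIT", ]
  expect_equal(hit$overlap, 10L)
  expect_equal(hit$p_value, choose(10, 10) * choose(990, 0) / choose(1000, 10),
               tolerance = 1e-12)
  miss <- res[res$set_name == "MISS", ]
  expect_equal(miss$overlap, 0L)
  expect_equal(miss$p_value, 1)
  expect_equal(miss$adjusted_p, 1)
  expect_error(enrich_module(module, gsc, background[-1]), "missing")
})

test_that("enrichment p-values are calibrated for random modules", {
  background <- sprintf("G%03d", 1:200)
  set.seed(9)
  gsc <- gene_set_collection(stats::setNames(
    lapply(1:20, function(i) sample(background, 10)), paste0("P", 1:20)))
  n_sig <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    mod <- sample(background, 12)
    sum(enrich_module(mod, gsc, background)$adjusted_p < 0.05)
  }, 0L)
  expect_gte(mean(n_sig == 0L), 0.95)
})

test_that("extract_network_sl_genes unions modules and flags novelty", {
  m1 <- structure(list(genes = c("A", "B")), class = "ModuleResult")
  m2 <- structure(list(genes = c("B", "C")), class = "ModuleResult")
  st <- toy_study("S1", c("A", "X", "Y"), 1:3, k = 1)  # hit: A
  out <- extract_network_sl_genes(list(m1, m2), list(st))
  expect_setequal(out$gene, c("A", "B", "C"))
  expect_equal(out$in_input_hits[out$gene == "A"], TRUE)
  expect_equal(novel_fraction(out), 2 / 3)
  # all module genes already hits -> novel fraction 0
  out2 <- extract_network_sl_genes(list(m1),
                                   list(toy_study("S", c("A", "B"), 1:2, k = 2)))
  expect_equal(novel_fraction(out2), 0)
})
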