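test_that("top_k_hits orders by score with lexicographic ties", {
  st <- toy_study("S", c("A", "B", "C"), c(1, 2, 3))
  expect_equal(top_k_hits(st, 2), c("A", "B"))
  st2 <- toy_study("S", c("B", "A", "C"), c(1, 1, 3))
  expect_equal(top_k_hits(st2, 1), "A")  # tie -> lexicographic
  expect_equal(top_k_hits(st, 3), c("A", "B", "C"))
  expect_warning(got <- top_k_hits(st, 5), "exceeds")
  expect_equal(got, c("A", "B", "C"))
})

test_that("overlap_hypergeom matches exhaustive enumeration (universe 20)", {
  genes <- sprintf("G%02d", 1:20)
  # study2's top-5 are G01..G05 (the 'marked' genes in study1's universe);
  # study1's top-5 are G04..G08 -> overlap x = 2; all scores distinct
  s1 <- toy_study("S1", genes, c(20, 21, 22, 1:5, 30:41), k = 5)
  s2 <- toy_study("S2", genes, c(1:5, 10:24), k = 5)
  ov <- overlap_hypergeom(s1, s2, k = 5)
  expect_equal(ov$x, 2L)
  expect_equal(ov$m, 5L)
  expect_equal(ov$p_value, oracle_hyper_tail(20, 5, 5, 2), tolerance = 1e-12)
  # strict-tail variant reproduces the printed 1-phyper convention
  ovs <- overlap_hypergeom(s1, s2, k = 5, tail = "gt")
  expect_equal(ovs$p_value, oracle_hyper_tail(20, 5, 5, 2, strict = TRUE),
               tolerance = 1e-12)
  # closed-form sum oracle for the same urn
  closed <- sum(vapply(2:5, function(j)
    choose(5, j) * choose(15, 5 - j), 0)) / choose(20, 5)
  expect_equal(ov$p_value, closed, tolerance = 1e-12)
})

test_that("overlap_hypergeom handles identical and disjoint hit sets", {
  genes <- sprintf("G%02d", 1:20)
  same <- toy_study("A", genes, 1:20, k = 5)
  ov <- overlap_hypergeom(same, same, k = 5)
  expect_equal(ov$x, 5L)
  # point mass: all 5 marked drawn
  expect_equal(ov$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  s1 <- toy_study("A", genes, c(1:5, rep(10, 15)), k = 5)
  s2 <- toy_study("B", genes, c(rep(10, 15), 1:5), k = 5)
  ov2 <- overlap_hypergeom(s1, s2, k = 5)
  expect_equal(ov2$x, 0L)
  expect_equal(ov2$p_value, 1)
})

test_that("count_cross_study_edges counts spanning edges once", {
  net <- toy_net(c("A-B", "B-C", "C-D"))
  expect_equal(count_cross_study_edges(net, c("A", "C"), c("B", "D")), 3L)
  expect_equal(count_cross_study_edges(interaction_network(), "A", "B"), 0L)
  # hitsA = hitsB = S counts edges internal to S
  expect_equal(count_cross_study_edges(net, c("A", "B", "C"), c("A", "B", "C")), 2L)
})

test_that("count_cross_study_edges is symmetric, monotone, equals brute force", {
  for (s in 1:5) {
    net <- er_net(30, 0.1, seed = s)
    set.seed(s)
    A <- sample(net$nodes, 8); B <- sample(net$nodes, 8)
    n1 <- count_cross_study_edges(net, A, B)
    expect_equal(n1, count_cross_study_edges(net, B, A))
    expect_equal(n1, oracle_cross_edges(net, A, B))
    # adding an edge never decreases the count
    bigger <- merge_networks(net, toy_net(paste0(A[1], "-", B[1])))
    expect_gte(count_cross_study_edges(bigger, A, B), n1)
  }
})

test_that("permutation_null_p is deterministic and flags extreme observations", {
  net <- toy_net(c("A-B", "B-C", "C-D", "D-E", "A-C"))
  genes <- c("A", "B", "C", "D", "E", "F", "G", "H")
  s1 <- toy_study("S1", genes, 1:8, k = 2)
  s2 <- toy_study("S2", genes, c(3, 1, 2, 4:8), k = 2)
  p1 <- permutation_null_p(net, s1, s2, k = 2, n_perm = 500, seed = 7)
  p2 <- permutation_null_p(net, s1, s2, k = 2, n_perm = 500, seed = 7)
  expect_identical(p1$null_counts, p2$null_counts)
  expect_equal(p1$observed, count_cross_study_edges(net, s1$hits, s2$hits))
  # a null draw can never beat the theoretical maximum on this toy net:
  # hits {A,B} vs {B,C} span A-B, B-C, A-C = 3 of 5 edges; force an
  # unbeatable observed count via a clique network
  k5 <- complexes_to_edges(gene_set_collection(list(K = c("A", "B", "C"))))
  sA <- toy_study("X", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
                  c(1, 2, 10, 10, 10, 10, 10, 10, 10, 3), k = 3)
  sB <- toy_study("Y", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
                  c(1, 2, 3, 10, 10, 10, 10, 10, 10, 10), k = 3)
  pr <- permutation_null_p(k5, sA, sB, k = 3, n_perm = 200, seed = 1)
  expect_true(pr$observed >= max(pr$null_counts))
  expect_error(permutation_null_p(net, s1, s2, k = 99), "exceeds")
})

test_that("permutation p is invariant under consistent gene relabeling", {
  net <- er_net(25, 0.12, seed = 3)
  genes <- net$nodes
  set.seed(4)
  s1 <- toy_study("S1", genes, rnorm(length(genes)), k = 6)
  s2 <- toy_study("S2", genes, rnorm(length(genes)), k = 6)
  # bijective relabeling preserving order of the universe vector
  relab <- stats::setNames(sprintf("X%02d", seq_along(genes)), genes)
  net2 <- interaction_network(data.frame(from = unname(relab[net$edges$from]),
                                         to = unname(relab[net$edges$to])),
                              nodes = unname(relab))
  r1 <- toy_study("S1", unname(relab[names(s1$scores)]), unname(s1$scores), k = 6)
  r2 <- toy_study("S2", unname(relab[names(s2$scores)]), unname(s2$scores), k = 6)
  a <- permutation_null_p(net, s1, s2, k = 6, n_perm = 300, seed = 11)
  b <- permutation_null_p(net2, r1, r2, k = 6, n_perm = 300, seed = 11)
  expect_equal(a$observed, b$observed)
  expect_equal(a$p_empirical, b$p_empirical)
})

test_that("degree-rewire null runs and reports its mode", {
  net <- er_net(20, 0.2, seed = 5)
  set.seed(6)
  s1 <- toy_study("S1", net$nodes, rnorm(20), k = 5)
  s2 <- toy_study("S2", net$nodes, rnorm(20), k = 5)
  pr <- permutation_null_p(net, s1, s2, k = 5, n_perm = 50, seed = 2,
                           null_mode = "degree-rewire")
  expect_equal(pr$null_mode, "degree-rewire")
  expect_length(pr$null_counts, 50L)
  expect_true(pr$p_empirical > 0 && pr$p_empirical <= 1)
})

test_that("ranked hit-list TSVs round-trip into studies", {
  df <- data.frame(study_id = rep(c("S1", "S2"), each = 3),
                   gene = c("A", "B", "C", "B", "C", "D"),
                   score = c(1, 2, 3, 3, 2, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  studies <- read_studies_tsv(path, k = 2)
  expect_named(studies, c("S1", "S2"))
  expect_equal(studies$S1$hits, c("A", "B"))
  expect_equal(studies$S2$hits, c("D", "C"))
})
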