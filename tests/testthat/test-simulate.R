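small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_genes = 30L,
               planted_complexes = list(list(size = 6L, within_edge_prob = 1.0)),
               sl_complex_idx = 1L, background_edge_prob = 0.05,
               tested_fraction = 1, hit_k = 5L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("sim_config validates its fields", {
  expect_error(sim_config(background_edge_prob = 1.5), "probabilities")
  expect_error(sim_config(n_genes = 10L,
                          planted_complexes = list(list(size = 20L, within_edge_prob = 1))),
               "exceed")
  expect_error(sim_config(sl_complex_idx = 9L), "out of range")
  expect_error(sim_config(suppressor_rescue = 2), "suppressor_rescue")
})

test_that("generators are pure functions of (cfg, seed)", {
  cfg <- small_cfg(seed = 42)
  a <- gen_network_and_truth(cfg); b <- gen_network_and_truth(cfg)
  expect_identical(a$network$edges, b$network$edges)
  s1 <- gen_studies(cfg, a$truth); s2 <- gen_studies(cfg, b$truth)
  expect_identical(lapply(s1, `[[`, "scores"), lapply(s2, `[[`, "scores"))
  g <- sprintf("G%04d", 1:4)
  expect_identical(gen_screen_counts(cfg, g), gen_screen_counts(cfg, g))
  expect_identical(gen_emap_counts(cfg, g[1:2], g),
                   gen_emap_counts(cfg, g[1:2], g))
  # different seed changes output
  expect_false(identical(a$network$edges,
                         gen_network_and_truth(small_cfg(seed = 43))$network$edges))
})

test_that("planted complexes are cliques at within_edge_prob 1", {
  cfg <- small_cfg()
  w <- gen_network_and_truth(cfg)
  members <- w$truth$sets$COMPLEX1
  sub <- w$network$edges[w$network$edges$from %in% members &
                         w$network$edges$to %in% members, ]
  expect_equal(nrow(sub), choose(6, 2))
  # background 0 puts every edge inside a planted complex
  cfg0 <- small_cfg(background_edge_prob = 0)
  w0 <- gen_network_and_truth(cfg0)
  expect_true(all(w0$network$edges$from %in% members &
                  w0$network$edges$to %in% members))
})

test_that("q = 1 with huge delta separates planted genes completely", {
  cfg <- small_cfg(detection_prob = 1, pathway_effect = 10)
  w <- gen_network_and_truth(cfg)
  st <- gen_studies(cfg, w$truth)[[1]]
  planted <- w$truth$sets$COMPLEX1
  ord <- names(sort(st$scores))
  expect_setequal(ord[seq_along(planted)], planted)
})

test_that("delta = 0 leaves planted genes uniform among ranks", {
  # binomial oracle: with no score shift a planted gene lands in the top k
  # with probability k/n; aggregate the count over 500 seeded studies
  cfg <- small_cfg(pathway_effect = 0)
  w <- gen_network_and_truth(cfg)
  planted <- w$truth$sets$COMPLEX1
  tot <- 0L
  for (s in 1:500) {
    cfgs <- small_cfg(seed = s, pathway_effect = 0)
    st <- gen_studies(cfgs, w$truth)[[1]]
    tot <- tot + length(intersect(st$hits, planted))
  }
  p <- cfg$hit_k / cfg$n_genes
  expected <- 500 * length(planted) * p
  sdev <- sqrt(500 * length(planted) * p * (1 - p))
  expect_lt(abs(tot - expected), 4 * sdev)
})

test_that("screen counts honor the planted effect wiring", {
  cfg <- small_cfg(count_cv = 0)
  g <- c("SLG", "NULLG")
  tab <- gen_screen_counts(cfg, g, sl_genes = "SLG")
  # noiseless: counts are exactly base x effect
  kras_min <- tab[tab$cell_line == "KRAS" & tab$condition == "minimal", ]
  expect_equal(unique(kras_min$cell_count[kras_min$perturbation == "SLG"]),
               cfg$base_count * cfg$sl_effect)
  expect_equal(unique(kras_min$cell_count[kras_min$perturbation == "NULLG"]),
               cfg$base_count)
  # effect is confined to the sensitized stratum
  other <- tab[!(tab$cell_line == "KRAS" & tab$condition == "minimal") &
               tab$perturbation == "SLG", ]
  expect_true(all(other$cell_count == cfg$base_count))
  # every plate carries NT wells
  expect_true(all(tapply(tab$perturbation == "NT", tab$plate_id, any)))
})

test_that("emap counts follow multiplicative neutrality with rescue", {
  cfg <- small_cfg(count_cv = 0, suppressor_rescue = 1)
  qs <- c("Q1", "Q2"); ars <- c("A1", "A2", "A3", "A4")
  supp <- data.frame(query = "Q1", array = "A1")
  tab <- gen_emap_counts(cfg, qs, ars, suppressor_pairs = supp,
                         query_effects = c(Q1 = 0.5, Q2 = 0.4),
                         array_effects = c(A1 = 1, A2 = 1, A3 = 0.8, A4 = 1))
  look <- function(q, a) unique(tab$cell_count[tab$query_gene == q &
                                               tab$array_gene == a])
  # neutral pair: product of single effects
  expect_equal(look("Q2", "A3"), cfg$base_count * 0.4 * 0.8)
  # fully rescued suppressor pair returns to base despite Q1's deficit
  expect_equal(look("Q1", "A1"), cfg$base_count)
  expect_equal(look("Q1", "A2"), cfg$base_count * 0.5)
  expect_error(gen_emap_counts(cfg, qs, ars,
                               suppressor_pairs = data.frame(query = "QX", array = "A1")),
               "outside")
})

test_that("drug counts are inert without planted effects", {
  cfg <- small_cfg(count_cv = 0)
  tab <- gen_drug_counts(cfg, c("DMSO", "KILLER"),
                         drug_effects = list(KILLER = c(1, 0.8, 0.5, 0.2)))
  auc <- drug_auc(tab)
  expect_equal(auc$delta_auc[auc$drug == "DMSO"], 0)
  expect_equal(auc$delta_auc[auc$drug == "KILLER"], 4 - sum(c(1, 0.8, 0.5, 0.2)))
  expect_equal(auc$drug[1], "KILLER")  # ranked most selective first
})
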