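#' Simulation configuration
#'
#' One object states the synthetic world every generator draws from: a gene
#' universe with planted dense protein complexes over background random
#' edges; several independent screens that each detect complex members only
#' partially (producing pathway-level but weak gene-level convergence);
#' quadruplicate plate counts for isogenic cell lines across media
#' conditions with planted synthetic-lethal deficits; and a combinatorial
#' knockdown map with planted suppressors. Identical seed implies
#' bit-identical outputs from every generator.
#'
#' Defaults: a 400-gene universe with one large planted synthetic-lethal
#' complex of 44 genes (proteasome-scale; complexes enter real networks as
#' cliques, so within-pair edge probability is 1) plus two 8-gene decoy
#' complexes, over 0.2% background edges; three studies each testing 36%
#' of the universe with a score shift of delta = 3 for detected SL-complex
#' members and per-member detection probability q = 0.4, hit lists of 25;
#' quadruplicate wells of ~1000 cells with 10% lognormal count noise; a
#' planted knockdown deficit halving proliferation; full suppressor rescue.
#'
#' @param seed integer master seed.
#' @param n_genes gene-universe size.
#' @param planted_complexes list of `list(size =, within_edge_prob =)`.
#' @param background_edge_prob background edge probability.
#' @param sl_complex_idx indices of planted complexes that are truly
#'   synthetic lethal.
#' @param n_studies number of independent screens.
#' @param tested_fraction fraction of the universe each study tests
#'   (recycled across studies).
#' @param hit_k top-k hit-list size per study.
#' @param pathway_effect score shift delta subtracted for detected
#'   SL-complex members (lower score = stronger synthetic lethal).
#' @param detection_prob per-study, per-member Bernoulli detection
#'   probability q.
#' @param n_reps replicate wells per perturbation (default 4).
#' @param count_cv lognormal coefficient of variation of well counts.
#' @param base_count expected cells per unperturbed well.
#' @param sl_effect multiplicative proliferation deficit of a planted SL
#'   gene in the sensitized (mutant, minimal-media) stratum.
#' @param suppressor_rescue fraction of the deficit rescued for planted
#'   suppressor pairs (1 = full rescue).
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 400L,
                       planted_complexes = list(list(size = 44L, within_edge_prob = 1.0),
                                                list(size = 8L, within_edge_prob = 1.0),
                                                list(size = 8L, within_edge_prob = 1.0)),
                       background_edge_prob = 0.002,
                       sl_complex_idx = 1L,
                       n_studies = 3L,
                       tested_fraction = 0.36,
                       hit_k = 25L,
                       pathway_effect = 3,
                       detection_prob = 0.4,
                       n_reps = 4L,
                       count_cv = 0.1,
                       base_count = 1000,
                       sl_effect = 0.5,
                       suppressor_rescue = 1.0) {
  probs <- c(background_edge_prob, detection_prob, tested_fraction,
             vapply(planted_complexes, `[[`, 0, "within_edge_prob"))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_genes < 2L || n_studies < 1L || hit_k < 1L || n_reps < 1L)
    stop("counts must be positive")
  if (count_cv < 0 || base_count <= 0 || sl_effect <= 0)
    stop("count_cv >= 0, base_count > 0, sl_effect > 0 required")
  if (suppressor_rescue < 0 || suppressor_rescue > 1)
    stop("suppressor_rescue must lie in [0, 1]")
  sizes <- vapply(planted_complexes, function(pc) as.integer(pc$size), 0L)
  if (sum(sizes) > n_genes)
    stop("planted complex sizes exceed n_genes")
  if (length(sl_complex_idx) &&
      any(sl_complex_idx < 1L | sl_complex_idx > length(planted_complexes)))
    stop("sl_complex_idx out of range")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 planted_complexes = planted_complexes,
                 background_edge_prob = background_edge_prob,
                 sl_complex_idx = as.integer(sl_complex_idx),
                 n_studies = as.integer(n_studies),
                 tested_fraction = rep_len(tested_fraction, n_studies),
                 hit_k = as.integer(hit_k),
                 pathway_effect = pathway_effect,
                 detection_prob = detection_prob,
                 n_reps = as.integer(n_reps), count_cv = count_cv,
                 base_count = base_count, sl_effect = sl_effect,
                 suppressor_rescue = suppressor_rescue),
            class = "SimulationConfig")
}

# deterministic per-stage seed streams derived from the master seed, so
# toggling one generator never perturbs another's randomness
stage_seed <- function(seed, stage) {
  offsets <- c(network = 1L, studies = 2L, screen = 3L, emap = 4L, drugs = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 7919 + offsets[[stage]] * 104729) %% 2147483647)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

sim_gene_names <- function(n) sprintf("G%04d", seq_len(n))

#' Generate the interaction network and ground-truth complexes
#'
#' Plants near-clique complexes (each within-pair edge drawn with the
#' configured probability) over disjoint gene blocks, adds background
#' random edges between all remaining pairs, and returns both the network
#' and the ground-truth membership. The truth collection carries the
#' universe and the names of the truly synthetic-lethal complexes
#' (attribute `sl_complexes`).
#'
#' @param cfg a [sim_config()].
#' @return list: `network` (an [interaction_network()]) and `truth`
#'   (a [gene_set_collection()] with attribute `sl_complexes`).
#' @export
gen_network_and_truth <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- sim_gene_names(cfg$n_genes)
  with_local_seed(stage_seed(cfg$seed, "network"), {
    sets <- list()
    offset <- 0L
    edges <- list()
    planted_pairs <- character()
    for (i in seq_along(cfg$planted_complexes)) {
      pc <- cfg$planted_complexes[[i]]
      members <- genes[offset + seq_len(pc$size)]
      offset <- offset + pc$size
      sets[[paste0("COMPLEX", i)]] <- members
      if (pc$size >= 2L) {
        idx <- utils::combn(pc$size, 2L)
        keep <- stats::runif(ncol(idx)) < pc$within_edge_prob
        if (any(keep))
          edges[[length(edges) + 1L]] <-
            data.frame(from = members[idx[1L, keep]],
                       to = members[idx[2L, keep]],
                       stringsAsFactors = FALSE)
        planted_pairs <- c(planted_pairs,
                           paste(members[idx[1L, ]], members[idx[2L, ]]))
      }
    }
    if (cfg$background_edge_prob > 0) {
      idx <- utils::combn(cfg$n_genes, 2L)
      pair_key <- paste(genes[idx[1L, ]], genes[idx[2L, ]])
      eligible <- !(pair_key %in% planted_pairs)
      keep <- eligible & stats::runif(ncol(idx)) < cfg$background_edge_prob
      if (any(keep))
        edges[[length(edges) + 1L]] <-
          data.frame(from = genes[idx[1L, keep]], to = genes[idx[2L, keep]],
                     stringsAsFactors = FALSE)
    }
    edf <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character())
    net <- interaction_network(edf, nodes = genes, default_source = "synthetic")
    truth <- gene_set_collection(sets, universe = genes)
    attr(truth, "sl_complexes") <- names(sets)[cfg$sl_complex_idx]
    list(network = net, truth = truth)
  })
}

#' Generate score-ranked screen studies
#'
#' Each study tests a random subset of the universe; every tested gene
#' receives a standard-normal score, and members of truly synthetic-lethal
#' complexes that the study detects (independent Bernoulli(q) per member
#' per study) are shifted down by delta. Lower score = stronger synthetic
#' lethal; hits are the top `hit_k` by ascending score. With q < 1 the
#' studies converge on the planted complexes at the pathway level while
#' sharing few individual hit genes.
#'
#' @param cfg a [sim_config()].
#' @param truth ground-truth collection from [gen_network_and_truth()].
#' @return named list of [screen_study()] objects (`STUDY1`, ...), each
#'   with attribute `detected` (the planted genes the study detected).
#' @export
gen_studies <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(truth, "GeneSetCollection"))
  universe <- truth$universe
  if (is.null(universe)) stop("truth collection lacks a universe")
  sl_sets <- attr(truth, "sl_complexes")
  sl_genes <- unique(unlist(truth$sets[sl_sets]))
  with_local_seed(stage_seed(cfg$seed, "studies"), {
    studies <- list()
    for (s in seq_len(cfg$n_studies)) {
      n_tested <- max(2L, round(cfg$tested_fraction[s] * length(universe)))
      tested <- sort(sample(universe, n_tested))
      if (cfg$hit_k > n_tested)
        stop("hit_k exceeds tested genes in study ", s)
      scores <- stats::rnorm(n_tested)
      names(scores) <- tested
      present <- intersect(sl_genes, tested)
      detected <- present[stats::runif(length(present)) < cfg$detection_prob]
      scores[detected] <- scores[detected] - cfg$pathway_effect
      st <- screen_study(paste0("STUDY", s), scores, k = cfg$hit_k)
      attr(st, "detected") <- detected
      studies[[st$study_id]] <- st
    }
    studies
  })
}

lognormal_counts <- function(n, expected, cv) {
  if (cv == 0) return(rep(expected, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so the mean (not the median) equals `expected`
  stats::rlnorm(n, meanlog = log(expected) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate single-knockdown plate counts
#'
#' One plate per (cell line, condition, replicate) — quadruplicate screens
#' are run as replicate plates, each carrying every gene once plus its own
#' NT control wells, so per-plate normalization noise is part of the
#' replicate-to-replicate variance the t test sees. Well counts are lognormal
#' around `base_count * effect`, where the effect is `sl_effect` for the
#' given SL genes in the sensitized stratum (default: mutant cells in
#' minimal media) and 1 elsewhere; an explicit `effects` table overrides
#' this default wiring.
#'
#' @param cfg a [sim_config()].
#' @param genes character vector of perturbed genes.
#' @param conditions media conditions (default minimal/intermediate/full).
#' @param cell_lines cell lines (default KRAS/eGFP).
#' @param sl_genes genes carrying the planted deficit (default none).
#' @param sensitized `c(cell_line, condition)` stratum where the deficit
#'   manifests (default `c("KRAS", "minimal")`).
#' @param effects optional data.frame `gene`, `cell_line`, `condition`,
#'   `effect` giving explicit multiplicative effects (overrides
#'   `sl_genes`).
#' @param n_nt NT control wells per plate (default 4).
#' @return a [plate_table()].
#' @export
gen_screen_counts <- function(cfg, genes,
                              conditions = c("minimal", "intermediate", "full"),
                              cell_lines = c("KRAS", "eGFP"),
                              sl_genes = character(),
                              sensitized = c("KRAS", "minimal"),
                              effects = NULL, n_nt = 4L) {
  stopifnot(inherits(cfg, "SimulationConfig"), length(genes) >= 1L)
  genes <- toupper(genes)
  lookup_effect <- function(g, line, cond) {
    if (!is.null(effects)) {
      i <- which(effects$gene == g & effects$cell_line == line &
                 effects$condition == cond)
      if (length(i)) return(effects$effect[i[1L]])
      return(1)
    }
    if (g %in% toupper(sl_genes) && line == sensitized[1L] &&
        cond == sensitized[2L]) cfg$sl_effect else 1
  }
  with_local_seed(stage_seed(cfg$seed, "screen"), {
    rows <- list()
    for (line in cell_lines) for (cond in conditions) {
      for (r in seq_len(cfg$n_reps)) {
        plate <- paste(line, cond, paste0("r", r), sep = "_")
        eff <- vapply(genes, function(g) lookup_effect(g, line, cond), 0)
        cnt <- lognormal_counts(length(genes), 1, cfg$count_cv) *
          cfg$base_count * eff
        nt <- lognormal_counts(n_nt, cfg$base_count, cfg$count_cv)
        rows[[length(rows) + 1L]] <-
          data.frame(plate_id = plate,
                     well = c(genes, paste0("NT", seq_len(n_nt))),
                     cell_line = line, condition = cond,
                     perturbation = c(genes, rep("NT", n_nt)),
                     replicate = c(rep(r, length(genes)), seq_len(n_nt)),
                     cell_count = c(cnt, nt), stringsAsFactors = FALSE)
      }
    }
    plate_table(do.call(rbind, rows))
  })
}

#' Generate combinatorial (E-MAP) plate counts
#'
#' One plate per query gene holding the full array in `n_reps` replicate
#' wells. Expected double-knockdown proliferation is the product of the
#' single-knockdown effects (multiplicative neutrality); for configured
#' suppressor pairs the product effect is rescued toward 1 by
#' `suppressor_rescue`. Counts are lognormal around
#' `base_count * effect`.
#'
#' @param cfg a [sim_config()].
#' @param queries character vector of query genes.
#' @param arrays character vector of array genes.
#' @param suppressor_pairs optional data.frame `query`, `array` of planted
#'   suppressors; every pair must lie in `queries` x `arrays`.
#' @param query_effects named single-knockdown effects for queries
#'   (default 0.5 each — queries are synthetic-lethal genes assayed in
#'   their sensitized context).
#' @param array_effects named single-knockdown effects for arrays
#'   (default 1 each).
#' @return data.frame of wells: `plate_id`, `well`, `query_gene`,
#'   `array_gene`, `replicate`, `cell_count`.
#' @export
gen_emap_counts <- function(cfg, queries, arrays, suppressor_pairs = NULL,
                            query_effects = NULL, array_effects = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            length(queries) >= 1L, length(arrays) >= 3L)
  queries <- toupper(queries); arrays <- toupper(arrays)
  if (is.null(query_effects))
    query_effects <- stats::setNames(rep(0.5, length(queries)), queries)
  if (is.null(array_effects))
    array_effects <- stats::setNames(rep(1, length(arrays)), arrays)
  if (!is.null(suppressor_pairs)) {
    stopifnot(all(c("query", "array") %in% names(suppressor_pairs)))
    suppressor_pairs$query <- toupper(suppressor_pairs$query)
    suppressor_pairs$array <- toupper(suppressor_pairs$array)
    bad <- !(suppressor_pairs$query %in% queries &
             suppressor_pairs$array %in% arrays)
    if (any(bad)) stop("suppressor pair(s) outside queries x arrays")
    supp_key <- paste(suppressor_pairs$query, suppressor_pairs$array)
  } else supp_key <- character()
  with_local_seed(stage_seed(cfg$seed, "emap"), {
    rows <- list()
    for (q in queries) {
      plate <- paste0("EMAP_", q)
      for (a in arrays) {
        eff <- query_effects[[q]] * array_effects[[a]]
        if (paste(q, a) %in% supp_key)
          eff <- eff + cfg$suppressor_rescue * (1 - eff)
        cnt <- lognormal_counts(cfg$n_reps, cfg$base_count * eff, cfg$count_cv)
        rows[[length(rows) + 1L]] <-
          data.frame(plate_id = plate, well = paste0(a, "_r", seq_len(cfg$n_reps)),
                     query_gene = q, array_gene = a,
                     replicate = seq_len(cfg$n_reps), cell_count = cnt,
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a drug dose-response table
#'
#' Four-dose proliferation series for each drug in two arms, around 1
#' (DMSO-normalized) with lognormal noise; `drug_effects` gives the
#' per-dose multiplicative effect in the mutant arm (a KRAS-selective
#' drug suppresses proliferation there only).
#'
#' @param cfg a [sim_config()].
#' @param drugs character vector of drug names.
#' @param drug_effects optional named list: per drug, a length-4 vector of
#'   mutant-arm effects (default all 1 = inert).
#' @param n_doses doses per series (default 4).
#' @return data.frame `drug`, `arm`, `dose`, `norm_prolif`.
#' @export
gen_drug_counts <- function(cfg, drugs, drug_effects = NULL, n_doses = 4L) {
  stopifnot(inherits(cfg, "SimulationConfig"), length(drugs) >= 1L)
  with_local_seed(stage_seed(cfg$seed, "drugs"), {
    rows <- list()
    for (d in drugs) {
      eff <- if (!is.null(drug_effects) && d %in% names(drug_effects))
        rep_len(drug_effects[[d]], n_doses) else rep(1, n_doses)
      for (arm in c("eGFP_full", "KRAS_minimal")) {
        mult <- if (arm == "KRAS_minimal") eff else rep(1, n_doses)
        val <- lognormal_counts(n_doses, 1, cfg$count_cv) * mult
        rows[[length(rows) + 1L]] <-
          data.frame(drug = d, arm = arm, dose = seq_len(n_doses),
                     norm_prolif = val, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
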