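#' Pipeline configuration
#'
#' Validates and freezes every knob of an end-to-end run. Unknown keys are
#' rejected so typos cannot silently revert a parameter to its default.
#' The single master seed is expanded into independent per-stage streams
#' (see [sim_config()]), so toggling one stage does not perturb another's
#' randomness.
#'
#' @param out_dir run directory (created if absent).
#' @param seed master integer seed.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param k top-k hit-list size (default: the simulation's `hit_k`).
#' @param n_perm permutations for the connectivity test (default 1000 for
#'   a desk-scale run; raise to 10000 for publication-grade p-values).
#' @param null_mode `"gene-resample"` or `"degree-rewire"`.
#' @param mcode an [mcode_params()].
#' @param min_studies multi-study module filter (default 2).
#' @param fdr_thresholds screen hit-call FDRs.
#' @param emap_cutoff |Z| interaction-call cutoff (default 2).
#' @param bundle_alpha pathway-bundle significance level (default 0.01).
#' @param percentile_cutoffs held-out accuracy cutoffs (default 1 and 5).
#' @param stages character vector of stages to run, in dependency order.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL, k = NULL,
                            n_perm = 1000L,
                            null_mode = c("gene-resample", "degree-rewire"),
                            mcode = mcode_params(), min_studies = 2L,
                            fdr_thresholds = c(0.01, 0.05, 0.10),
                            emap_cutoff = 2, bundle_alpha = 0.01,
                            percentile_cutoffs = c(1, 5),
                            stages = c("simulate", "integrate", "cluster",
                                       "validate", "score-screen",
                                       "score-emap", "rank-context")) {
  null_mode <- match.arg(null_mode)
  known <- c("simulate", "integrate", "cluster", "validate", "score-screen",
             "score-emap", "rank-context")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim)) sim <- sim_config(seed = seed)
  else { stopifnot(inherits(sim, "SimulationConfig")); sim$seed <- as.integer(seed) }
  if (is.null(k)) k <- sim$hit_k
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 k = as.integer(k), n_perm = as.integer(n_perm),
                 null_mode = null_mode, mcode = mcode,
                 min_studies = as.integer(min_studies),
                 fdr_thresholds = fdr_thresholds,
                 emap_cutoff = emap_cutoff, bundle_alpha = bundle_alpha,
                 percentile_cutoffs = percentile_cutoffs, stages = stages),
            class = "PipelineConfig")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL    # hash the scientific parameters, not the run path
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

plog <- function(...) message("[netsl] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order against one run
#' directory; each stage reads the files earlier stages wrote, so
#' synthetic and user-supplied inputs are interchangeable. A
#' `summary.json` with seeds, parameters, config hash and package version
#' is written last. Identical config + seed reproduces identical outputs.
#'
#' Stage outputs (TSV unless noted): `network.sif`, `truth.gmt`,
#' `studies.tsv` (simulate); `overlap.tsv`, `connectivity.tsv` (integrate);
#' `modules.json`, `modules.gmt`, `network_sl_genes.tsv` (cluster);
#' `holdout_accuracy.tsv` (validate); `screen_scores.tsv`,
#' `condition_matrix.tsv` (score-screen); `emap_scores.tsv`,
#' `suppressors.tsv`, `bundles.tsv` (score-emap); `context_rank.tsv`
#' (rank-context).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (st in config$stages) {
    plog("stage: ", st)
    res <- tryCatch(
      switch(st,
             "simulate" = stage_simulate(config, res),
             "integrate" = stage_integrate(config, res),
             "cluster" = stage_cluster(config, res),
             "validate" = stage_validate(config, res),
             "score-screen" = stage_score_screen(config, res),
             "score-emap" = stage_score_emap(config, res),
             "rank-context" = stage_rank_context(config, res)),
      error = function(e) stop("stage '", st, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  summary <- list(package = "netsl",
                  version = as.character(utils::packageVersion("netsl")),
                  seed = config$seed, config_hash = config_hash(config),
                  stages = config$stages,
                  n_perm = config$n_perm, null_mode = config$null_mode,
                  k = config$k)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "summary.json"))
  invisible(res)
}

stage_simulate <- function(config, res) {
  world <- gen_network_and_truth(config$sim)
  studies <- gen_studies(config$sim, world$truth)
  write_sif(world$network, file.path(config$out_dir, "network.sif"))
  write_gmt(world$truth, file.path(config$out_dir, "truth.gmt"))
  stab <- do.call(rbind, lapply(studies, function(s)
    data.frame(study_id = s$study_id, gene = names(s$scores),
               score = unname(s$scores), stringsAsFactors = FALSE)))
  write_tsv(stab, file.path(config$out_dir, "studies.tsv"))
  res$world <- world; res$studies <- studies
  res
}

load_inputs <- function(config, res) {
  if (is.null(res$world)) {
    net <- read_sif(file.path(config$out_dir, "network.sif"))
    truth <- read_gmt(file.path(config$out_dir, "truth.gmt"))
    res$world <- list(network = net, truth = truth)
  }
  if (is.null(res$studies))
    res$studies <- read_studies_tsv(file.path(config$out_dir, "studies.tsv"),
                                    k = config$k)
  res
}

stage_integrate <- function(config, res) {
  res <- load_inputs(config, res)
  ids <- names(res$studies)
  ov <- list(); pm <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    o <- overlap_hypergeom(res$studies[[i]], res$studies[[j]], k = config$k)
    ov[[length(ov) + 1L]] <-
      data.frame(study1 = ids[i], study2 = ids[j], x = o$x, m = o$m,
                 k = o$k, universe = o$universe_size, p_value = o$p_value)
    if (i < j) {
      p <- permutation_null_p(res$world$network, res$studies[[i]],
                              res$studies[[j]], k = config$k,
                              n_perm = config$n_perm,
                              seed = stage_seed(config$seed, "network") + i * 131L + j,
                              null_mode = config$null_mode)
      pm[[length(pm) + 1L]] <-
        data.frame(study1 = ids[i], study2 = ids[j], observed = p$observed,
                   null_mean = mean(p$null_counts),
                   fold_over_null = p$fold_over_null,
                   p_empirical = p$p_empirical, p_string = p$p_string,
                   null_mode = p$null_mode, n_perm = p$n_perm)
    }
  }
  write_tsv(do.call(rbind, ov), file.path(config$out_dir, "overlap.tsv"))
  write_tsv(do.call(rbind, pm), file.path(config$out_dir, "connectivity.tsv"))
  res
}

stage_cluster <- function(config, res) {
  res <- load_inputs(config, res)
  all_hits <- unique(unlist(lapply(res$studies, function(s) s$hits)))
  sub <- restrict_to_seed_incident(res$world$network, all_hits)
  modules <- mcode_find_modules(sub, config$mcode)
  kept <- filter_multistudy_modules(modules, res$studies, config$min_studies)
  background <- res$world$network$nodes
  kept <- lapply(kept, function(m) {
    m$enrichments <- enrich_module(m, res$world$truth, background)
    m
  })
  sl <- extract_network_sl_genes(kept, res$studies)
  json <- lapply(seq_along(kept), function(i) {
    m <- kept[[i]]
    list(module = i, genes = m$genes, mcode_score = m$mcode_score,
         studies_present = m$studies_present,
         enrichments = m$enrichments)
  })
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(config$out_dir, "modules.json"))
  if (length(kept)) {
    msets <- stats::setNames(lapply(kept, `[[`, "genes"),
                             paste0("MODULE", seq_along(kept)))
    write_gmt(gene_set_collection(msets), file.path(config$out_dir, "modules.gmt"))
  }
  write_tsv(sl, file.path(config$out_dir, "network_sl_genes.tsv"))
  res$modules <- kept; res$sl_genes <- sl
  res
}

stage_validate <- function(config, res) {
  res <- load_inputs(config, res)
  if (is.null(res$sl_genes))
    res$sl_genes <- utils::read.delim(file.path(config$out_dir, "network_sl_genes.tsv"),
                                      stringsAsFactors = FALSE)
  # a held-out screen of the same world, from an independent seed stream
  hcfg <- config$sim
  hcfg$seed <- stage_seed(config$seed, "drugs") + 17L
  hcfg$n_studies <- 1L
  holdout <- gen_studies(hcfg, res$world$truth)[[1L]]
  pct <- percentile_rank(holdout$scores)
  rows <- list()
  for (cut in config$percentile_cutoffs) {
    acc <- accuracy_at_percentile(res$sl_genes$gene, pct, cut)
    rows[[length(rows) + 1L]] <-
      data.frame(category = "network_sl", cutoff = cut,
                 n_tested = acc$n_tested, n_top = acc$n_top,
                 accuracy = acc$accuracy)
  }
  write_tsv(do.call(rbind, rows), file.path(config$out_dir, "holdout_accuracy.tsv"))
  res$holdout <- holdout
  res
}

stage_score_screen <- function(config, res) {
  res <- load_inputs(config, res)
  truth <- res$world$truth
  sl_sets <- attr(truth, "sl_complexes")
  if (is.null(sl_sets)) sl_sets <- names(truth$sets)[config$sim$sl_complex_idx]
  sl_genes <- unique(unlist(truth$sets[sl_sets]))
  screened <- sort(unique(c(sl_genes,
                            utils::head(setdiff(truth$universe, sl_genes), 40L))))
  counts <- gen_screen_counts(config$sim, screened, sl_genes = sl_genes)
  conditions <- unique(counts$condition)
  smat <- qmat <- matrix(NA_real_, length(screened), length(conditions),
                         dimnames = list(screened, conditions))
  long <- list()
  for (cond in conditions) {
    sc <- score_screen(counts, kras_arm = c("KRAS", cond),
                       ctrl_arm = c("eGFP", "full"),
                       fdr_thresholds = config$fdr_thresholds)
    smat[sc$gene, cond] <- sc$S
    qmat[sc$gene, cond] <- sc$fdr_q
    sc$condition <- cond
    long[[length(long) + 1L]] <- sc
  }
  write_tsv(do.call(rbind, long), file.path(config$out_dir, "screen_scores.tsv"))
  cm <- data.frame(gene = rownames(smat), smat, check.names = FALSE)
  write_tsv(cm, file.path(config$out_dir, "condition_matrix.tsv"))
  res$screen <- list(S = smat, q = qmat, counts = counts,
                     concordance = condition_concordance(smat, qmat))
  res
}

read_condition_matrix <- function(config) {
  path <- file.path(config$out_dir, "condition_matrix.tsv")
  if (!file.exists(path))
    stop("missing upstream output ", path, "; run the score-screen stage first")
  cm <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(`rownames<-`(cm[, -1L, drop = FALSE], cm$gene))
}

stage_score_emap <- function(config, res) {
  res <- load_inputs(config, res)
  if (is.null(res$screen))
    res$screen <- list(S = read_condition_matrix(config))
  S_min <- res$screen$S[, "minimal"]
  queries <- names(sort(S_min))[seq_len(min(8L, length(S_min)))]
  arrays <- utils::head(res$world$truth$universe, 40L)
  # plant suppressors for every query except the strongest SL gene,
  # which stays suppressor-free (the context-independent candidate)
  supp <- do.call(rbind, lapply(queries[-1L], function(q)
    data.frame(query = q, array = arrays[1:2], stringsAsFactors = FALSE)))
  emap <- gen_emap_counts(config$sim, queries, arrays, suppressor_pairs = supp)
  z <- emap_score_plates(emap)
  scores <- average_replicates(z, expected_reps = config$sim$n_reps)
  calls <- call_interactions(scores, cutoff = config$emap_cutoff)
  supp_counts <- suppressor_counts(scores, cutoff = config$emap_cutoff)
  bundles <- pathway_bundle_test(scores, res$world$truth,
                                 alpha = config$bundle_alpha)
  write_tsv(calls$calls, file.path(config$out_dir, "emap_scores.tsv"))
  write_tsv(data.frame(query_gene = names(supp_counts$per_query),
                       n_suppressors = unname(supp_counts$per_query)),
            file.path(config$out_dir, "suppressors.tsv"))
  write_tsv(bundles, file.path(config$out_dir, "bundles.tsv"))
  res$emap <- list(scores = scores, calls = calls, suppressors = supp_counts,
                   bundles = bundles)
  res
}

stage_rank_context <- function(config, res) {
  res <- load_inputs(config, res)
  if (is.null(res$screen))
    res$screen <- list(S = read_condition_matrix(config))
  if (is.null(res$emap)) {
    path <- file.path(config$out_dir, "suppressors.tsv")
    if (!file.exists(path))
      stop("missing upstream output ", path, "; run the score-emap stage first")
    sup <- utils::read.delim(path, stringsAsFactors = FALSE)
    res$emap <- list(suppressors = list(
      per_query = stats::setNames(sup$n_suppressors, sup$query_gene)))
  }
  if (is.null(res$sl_genes)) {
    path <- file.path(config$out_dir, "network_sl_genes.tsv")
    if (file.exists(path))
      res$sl_genes <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  queries <- names(res$emap$suppressors$per_query)
  cellular <- apply(res$screen$S[queries, , drop = FALSE], 1L,
                    cellular_context_score)
  sl_genes <- if (!is.null(res$sl_genes)) res$sl_genes$gene else character()
  entries <- data.frame(gene = queries,
                        cellular_score = unname(cellular),
                        genetic_score = unname(res$emap$suppressors$per_query[queries]),
                        category = ifelse(queries %in% sl_genes,
                                          "Network SL", "other"),
                        stringsAsFactors = FALSE)
  ranked <- composite_rank(entries)
  write_tsv(ranked, file.path(config$out_dir, "context_rank.tsv"))
  res$context <- ranked
  res
}

#' Command-line entry point
#'
#' Thin dispatcher over [run_pipeline()]; install target for
#' `inst/cli/netsl.R`. Subcommands: `run-all` plus each stage name; flags
#' `--out DIR` (required), `--seed N`, `--n-perm N`,
#' `--null-mode gene-resample|degree-rewire`, `--k N`.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return exit status 0, invisibly.
#' @export
netsl_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: netsl.R <run-all|simulate|integrate|cluster|validate|",
         "score-screen|score-emap|rank-context> --out DIR [--seed N] ",
         "[--n-perm N] [--null-mode M] [--k N]")
  cmd <- args[1L]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) args[i[1L] + 1L] else default
  }
  out <- getopt("--out", NULL)
  if (is.null(out)) stop("--out DIR is required")
  seed <- as.integer(getopt("--seed", "1"))
  n_perm <- as.integer(getopt("--n-perm", "1000"))
  null_mode <- getopt("--null-mode", "gene-resample")
  sim <- sim_config(seed = seed)
  k <- as.integer(getopt("--k", as.character(sim$hit_k)))
  stages <- if (cmd == "run-all")
    c("simulate", "integrate", "cluster", "validate", "score-screen",
      "score-emap", "rank-context")
  else cmd
  config <- pipeline_config(out_dir = out, seed = seed, sim = sim, k = k,
                            n_perm = n_perm, null_mode = null_mode,
                            stages = stages)
  run_pipeline(config)
  invisible(0L)
}
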