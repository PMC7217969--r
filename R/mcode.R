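#' MCODE parameters
#'
#' Defaults follow the published molecular-complex-detection algorithm:
#' vertices below the degree cutoff are ignored, seeded modules grow to
#' neighbors whose weight is within the vertex-weight-percentage (VWP) of
#' the seed, modules must contain a 2-core, and the haircut step trims
#' degree-1 members. Fluff expansion is off by default.
#'
#' @param degree_cutoff minimum degree for a vertex to receive weight
#'   (default 2).
#' @param node_score_cutoff the VWP in \[0, 1\] (default 0.2): a neighbor
#'   joins a module when its weight >= seed weight * (1 - VWP).
#' @param k_core minimum core a module must contain (default 2).
#' @param max_depth maximum breadth-first expansion depth from the seed
#'   (default 100).
#' @param haircut iteratively remove degree-1 module members (default TRUE).
#' @param fluff unused placeholder, kept FALSE (default algorithm setting).
#' @param include_loops ignored; networks are loop-free by construction.
#' @return a list of class `McodeParams`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, include_loops = FALSE) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1,
            degree_cutoff >= 0, k_core >= 0, max_depth >= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 include_loops = isTRUE(include_loops)),
            class = "McodeParams")
}

edge_density_simple <- function(n_v, n_e) {
  if (n_v < 2L) return(0)
  2 * n_e / (n_v * (n_v - 1))
}

# highest k-core of an igraph graph: vertices with maximal coreness, as the
# induced subgraph; returns list(k, graph)
highest_k_core <- function(g) {
  if (igraph::vcount(g) == 0L) return(list(k = 0L, graph = g))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, graph = igraph::induced_subgraph(g, which(core == k)))
}

#' MCODE vertex weighting
#'
#' For each vertex the closed neighborhood (the vertex and its neighbors)
#' is extracted, its highest k-core found, and the weight set to
#' k * density of that core (density = 2E / V(V-1)). Vertices with degree
#' below `degree_cutoff` receive weight 0. This is the
#' core-clustering-coefficient weighting that rewards locally dense
#' regions while discounting sparse hubs.
#'
#' @param net an [interaction_network()].
#' @param params [mcode_params()].
#' @return named numeric vector of weights over `net$nodes`.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "InteractionNetwork"))
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (v in which(deg >= params$degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    hk <- highest_k_core(sub)
    w[net$nodes[v]] <- hk$k *
      edge_density_simple(igraph::vcount(hk$graph), igraph::ecount(hk$graph))
  }
  w
}

#' MCODE dense-module discovery
#'
#' Greedy seeded expansion over [mcode_vertex_weights()]: modules are
#' seeded from the highest-weight unassigned vertex and grown breadth-first
#' to unassigned neighbors whose weight is at least
#' `seed_weight * (1 - VWP)`, to at most `max_depth` steps from the seed.
#' Each vertex belongs to at most one module. Modules whose induced
#' subgraph contains no `k_core`-core are discarded; the haircut step then
#' iteratively removes degree-1 members. Module score = edge density of the
#' final induced subgraph times its node count. Output is sorted by score
#' (descending), ties by size then by lexicographically smallest member.
#' Tie-breaking everywhere is lexicographic on gene symbol, so results are
#' deterministic.
#'
#' @param net an [interaction_network()].
#' @param params [mcode_params()].
#' @return list of `ModuleResult` lists: `genes` (sorted), `mcode_score`,
#'   `seed`, `density`, `size`.
#' @export
mcode_find_modules <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "InteractionNetwork"))
  w <- mcode_vertex_weights(net, params)
  g <- as_igraph(net)
  nodes <- net$nodes
  assigned <- stats::setNames(logical(length(nodes)), nodes)
  adj <- igraph::adjacent_vertices(g, seq_along(nodes))
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  # seeds in decreasing weight, ties lexicographic (names are sorted already)
  seed_order <- nodes[order(-w, nodes)]
  modules <- list()
  for (s in seed_order) {
    if (assigned[s] || w[s] <= 0) next
    thresh <- w[s] * (1 - params$node_score_cutoff)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character()
      for (v in frontier) {
        cand <- adj[[v]]
        cand <- cand[!assigned[cand] & w[cand] >= thresh]
        if (length(cand)) {
          assigned[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    if (max(core) < params$k_core) {
      # failed modules release their vertices so they may join a later,
      # denser module (final assignment stays a partition)
      assigned[members] <- FALSE
      next
    }
    if (params$haircut) {
      repeat {
        dv <- igraph::degree(sub)
        drop <- which(dv < 2L)
        if (length(drop) == 0L || igraph::vcount(sub) <= 2L) break
        sub <- igraph::induced_subgraph(sub, setdiff(seq_len(igraph::vcount(sub)), drop))
      }
    }
    genes <- sort(igraph::V(sub)$name)
    if (length(genes) < 2L) {
      assigned[members] <- FALSE
      next
    }
    assigned[setdiff(members, genes)] <- FALSE  # haircut-trimmed vertices
    dens <- edge_density_simple(igraph::vcount(sub), igraph::ecount(sub))
    modules[[length(modules) + 1L]] <-
      structure(list(genes = genes, mcode_score = dens * length(genes),
                     density = dens, size = length(genes), seed = s,
                     studies_present = NULL, enrichments = NULL),
                class = "ModuleResult")
  }
  if (length(modules)) {
    scores <- vapply(modules, `[[`, 0, "mcode_score")
    sizes <- vapply(modules, `[[`, 0L, "size")
    first <- vapply(modules, function(m) m$genes[1L], "")
    modules <- modules[order(-scores, -sizes, first)]
  }
  modules
}

#' @export
print.ModuleResult <- function(x, ...) {
  cat(sprintf("ModuleResult: %d genes, score %.2f (density %.2f), seed %s\n",
              x$size, x$mcode_score, x$density, x$seed))
  if (!is.null(x$studies_present))
    cat("  studies:", paste(x$studies_present, collapse = ", "), "\n")
  invisible(x)
}

#' Keep modules supported by multiple studies
#'
#' A module is retained when its genes include top-k hits from at least
#' `min_studies` distinct studies; each retained module is annotated with
#' the supporting study ids.
#'
#' @param modules list of `ModuleResult` from [mcode_find_modules()].
#' @param studies list of [screen_study()] objects.
#' @param min_studies minimum distinct supporting studies (default 2).
#' @return filtered, annotated list of `ModuleResult`.
#' @export
filter_multistudy_modules <- function(modules, studies, min_studies = 2L) {
  stopifnot(is.list(modules), is.list(studies))
  hit_sets <- lapply(studies, function(s) s$hits)
  ids <- vapply(studies, function(s) s$study_id, "")
  out <- list()
  for (m in modules) {
    present <- ids[vapply(hit_sets, function(h) any(m$genes %in% h), NA)]
    if (length(present) >= min_studies) {
      m$studies_present <- sort(present)
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Gene-set enrichment of one module
#'
#' Upper-tail hypergeometric enrichment of the module genes against each
#' set in the collection, with the stated background universe;
#' Benjamini-Hochberg adjustment across the sets tested for this module.
#'
#' @param module a `ModuleResult` (or plain character vector of genes).
#' @param collection a [gene_set_collection()] of complexes/pathways.
#' @param background character vector; must contain all module genes.
#' @return data.frame: `set_name`, `set_size`, `overlap`, `p_value`,
#'   `adjusted_p`, sorted by `p_value`.
#' @export
enrich_module <- function(module, collection, background) {
  genes <- if (inherits(module, "ModuleResult")) module$genes
           else toupper(as.character(module))
  stopifnot(inherits(collection, "GeneSetCollection"))
  background <- unique(toupper(as.character(background)))
  missing <- setdiff(genes, background)
  if (length(missing))
    stop("background missing module genes: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  N <- length(background)
  kk <- length(genes)
  res <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], background)
    x <- length(intersect(genes, set))
    m <- length(set)
    p <- stats::phyper(x - 1L, m, N - m, kk, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, overlap = x, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- bh_fdr(res$p_value)
  res[order(res$p_value, res$set_name), , drop = FALSE]
}

#' Extract network synthetic-lethal genes
#'
#' Union of genes over the retained multi-study modules, annotated with the
#' module each gene came from and whether it already appeared in any input
#' study's top-k hit list. Genes absent from every input hit list are the
#' "novel" predictions contributed by the network analysis; their fraction
#' is attached as attribute `novel_fraction` and via [novel_fraction()].
#'
#' @param filtered_modules list of `ModuleResult` (typically from
#'   [filter_multistudy_modules()]).
#' @param studies list of [screen_study()] objects whose hits define
#'   "already reported".
#' @return data.frame `gene`, `module`, `in_input_hits`, with attribute
#'   `novel_fraction`.
#' @export
extract_network_sl_genes <- function(filtered_modules, studies = list()) {
  stopifnot(is.list(filtered_modules))
  if (length(filtered_modules) == 0L) {
    out <- data.frame(gene = character(), module = integer(),
                      in_input_hits = logical())
    attr(out, "novel_fraction") <- NA_real_
    return(out)
  }
  all_hits <- unique(unlist(lapply(studies, function(s) s$hits)))
  rows <- lapply(seq_along(filtered_modules), function(i) {
    data.frame(gene = filtered_modules[[i]]$genes, module = i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$gene), , drop = FALSE]  # first (best) module wins
  out$in_input_hits <- out$gene %in% all_hits
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "novel_fraction") <- mean(!out$in_input_hits)
  out
}

#' Novel fraction of a network-SL gene table
#'
#' @param sl_genes result of [extract_network_sl_genes()].
#' @return fraction of genes not present in any input hit list.
#' @export
novel_fraction <- function(sl_genes) {
  if (nrow(sl_genes) == 0L) return(NA_real_)
  mean(!sl_genes$in_input_hits)
}
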