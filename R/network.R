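#' Gene-level interaction networks
#'
#' An `InteractionNetwork` is a simple undirected graph over gene symbols.
#' Edges carry a provenance label (`"complex"`, `"functional"`,
#' `"synthetic"`, ...). Construction enforces the class invariants: symbols
#' are uppercased, self-loops dropped, each unordered pair stored once (with
#' provenance labels merged into a `;`-separated label set), and every edge
#' endpoint is a node.
#'
#' @param edges a data.frame with character columns `from`, `to` and
#'   optionally `source`; may have zero rows.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes.
#' @param default_source provenance label applied when `edges$source` is
#'   absent.
#' @return an object of class `InteractionNetwork` with elements `nodes`
#'   (sorted character vector) and `edges` (data.frame `from`, `to`,
#'   `source`, with `from < to` lexicographically).
#' @export
interaction_network <- function(edges = NULL, nodes = NULL,
                                default_source = "synthetic") {
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        source = character(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- toupper(trimws(as.character(edges$from)))
  to <- toupper(trimws(as.character(edges$to)))
  src <- if ("source" %in% names(edges)) as.character(edges$source)
         else rep(default_source, length(from))
  keep <- !is.na(from) & !is.na(to) & nzchar(from) & nzchar(to)
  if (any(!keep))
    message("interaction_network: dropped ", sum(!keep),
            " edges with blank/NA endpoints")
  from <- from[keep]; to <- to[keep]; src <- src[keep]
  loop <- from == to
  from <- from[!loop]; to <- to[!loop]; src <- src[!loop]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (length(key)) {
    src_merged <- vapply(split(src, key), function(s)
      paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";"),
      "")
    first <- !duplicated(key)
    ek <- key[first]
    edges <- data.frame(from = a[first], to = b[first],
                        source = src_merged[ek], stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        source = character(), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$from, edges$to,
                         if (!is.null(nodes)) toupper(trimws(as.character(nodes))))))
  nodes <- nodes[nzchar(nodes) & !is.na(nodes)]
  structure(list(nodes = nodes, edges = edges), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$source)
    cat("  sources:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of edges / nodes
#' @param net an `InteractionNetwork`.
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Expand complexes into clique edges
#'
#' Each gene set (protein complex) is expanded into the clique over its
#' members: every unordered within-set pair becomes an edge labeled
#' `"complex"`. Singleton complexes contribute their gene as an isolated
#' node but no edges.
#'
#' @param collection a [gene_set_collection()].
#' @return an [interaction_network()] with `complex`-sourced edges.
#' @examples
#' gsc <- gene_set_collection(list(C1 = c("A", "B", "C")))
#' n_edges(complexes_to_edges(gsc))  # 3
#' @export
complexes_to_edges <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(collection$sets) == 0L) stop("empty collection")
  pairs <- lapply(collection$sets, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2L) return(NULL)
    idx <- utils::combn(length(g), 2L)
    data.frame(from = g[idx[1L, ]], to = g[idx[2L, ]], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, pairs)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  interaction_network(edges, nodes = unlist(collection$sets, use.names = FALSE),
                      default_source = "complex")
}

#' Threshold a weighted edge list
#'
#' Keeps functional-interaction edges with weight strictly greater than
#' `min_weight` (the field convention for confidence-scored interaction
#' lists, e.g. "scores > 2"), deduplicates symmetric pairs and drops
#' self-loops.
#'
#' @param edge_table data.frame with columns `from`, `to`, `weight` (or the
#'   first three columns are taken in that order).
#' @param min_weight numeric threshold; strict comparison. Default 2.
#' @return an [interaction_network()] with `functional`-sourced edges.
#' @export
threshold_weighted_edges <- function(edge_table, min_weight = 2) {
  stopifnot(is.data.frame(edge_table), ncol(edge_table) >= 3L)
  if (!all(c("from", "to", "weight") %in% names(edge_table)))
    names(edge_table)[1:3] <- c("from", "to", "weight")
  w <- suppressWarnings(as.numeric(edge_table$weight))
  bad <- which(is.na(w) & !is.na(edge_table$weight))
  if (length(bad))
    stop("non-numeric weight in row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  if (anyNA(w)) stop("missing weight in row(s): ",
                     paste(utils::head(which(is.na(w)), 5L), collapse = ", "))
  keep <- w > min_weight
  interaction_network(edge_table[keep, c("from", "to"), drop = FALSE],
                      default_source = "functional")
}

#' Merge two networks
#'
#' Union of nodes and edges; one edge per unordered pair with provenance
#' labels merged into a sorted label set. Merging is commutative and
#' idempotent.
#'
#' @param a,b `InteractionNetwork` objects.
#' @return the merged `InteractionNetwork`.
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "InteractionNetwork"), inherits(b, "InteractionNetwork"))
  interaction_network(rbind(a$edges, b$edges), nodes = c(a$nodes, b$nodes))
}

#' Restrict a network to seed-incident edges
#'
#' Keeps edges with at least one endpoint in `seeds` (e.g. "interactions
#' where at least one protein was identified in a previous screen");
#' isolated nodes are removed.
#'
#' @param net an `InteractionNetwork`.
#' @param seeds character vector of gene symbols.
#' @return the seed-incident subnetwork.
#' @export
restrict_to_seed_incident <- function(net, seeds) {
  stopifnot(inherits(net, "InteractionNetwork"))
  seeds <- toupper(trimws(as.character(seeds)))
  keep <- net$edges$from %in% seeds | net$edges$to %in% seeds
  interaction_network(net$edges[keep, , drop = FALSE])
}

#' Convert to an igraph graph
#'
#' @param net an `InteractionNetwork`.
#' @return an undirected simple [igraph::graph] with vertex names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "InteractionNetwork"))
  igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Read a SIF-style TSV written by [write_sif()]
#'
#' Three-field lines are `from`, `source`, `to`; single-field lines are
#' isolated nodes.
#'
#' @param path file path.
#' @return an [interaction_network()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(fields)
  if (any(!len %in% c(1L, 3L)))
    stop("SIF lines must have 1 or 3 fields: ", path)
  ed <- fields[len == 3L]
  edges <- if (length(ed))
    data.frame(from = vapply(ed, `[[`, "", 1L),
               source = vapply(ed, `[[`, "", 2L),
               to = vapply(ed, `[[`, "", 3L), stringsAsFactors = FALSE)
  else NULL
  iso <- unlist(fields[len == 1L])
  interaction_network(edges, nodes = iso)
}

#' Read a TSV edge list
#'
#' Expects a header with columns `from`, `to` and optionally `weight`,
#' `source` (legacy `geneA`/`geneB` accepted).
#'
#' @param path file path.
#' @return data.frame of the raw rows (not yet an `InteractionNetwork`).
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "geneA"] <- "from"
  names(df)[names(df) == "geneB"] <- "to"
  if (!all(c("from", "to") %in% names(df)))
    stop("edge TSV must have columns from/to (or geneA/geneB): ", path)
  df
}

#' Write a network as SIF-style TSV
#'
#' Columns `from`, `source`, `to` (the Cytoscape simple-interaction format),
#' plus isolated nodes as single-field lines.
#'
#' @param net an `InteractionNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "InteractionNetwork"))
  lines <- character()
  if (nrow(net$edges))
    lines <- paste(net$edges$from, net$edges$source, net$edges$to, sep = "\t")
  iso <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}
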