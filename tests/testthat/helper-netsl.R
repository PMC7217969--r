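# shared fixtures and independent oracles, built in code

# tiny network from "A-B" edge strings
toy_net <- function(edges, nodes = NULL) {
  if (length(edges) == 0L) return(interaction_network(nodes = nodes))
  parts <- strsplit(edges, "-", fixed = TRUE)
  interaction_network(data.frame(from = vapply(parts, `[[`, "", 1L),
                                 to = vapply(parts, `[[`, "", 2L)),
                      nodes = nodes)
}

# study with scores assigned in gene order
toy_study <- function(id, genes, scores, k = length(genes)) {
  screen_study(id, stats::setNames(scores, genes), k = k)
}

# independent k-core oracle: adjacency-matrix peeling, no igraph
oracle_highest_kcore <- function(adj) {
  best_k <- 0L; best_vs <- integer()
  n <- nrow(adj)
  for (k in seq_len(max(1L, n))) {
    keep <- rep(TRUE, n)
    repeat {
      deg <- rowSums(adj[keep, keep, drop = FALSE])
      drop <- which(deg < k)
      if (length(drop) == 0L) break
      keep[which(keep)[drop]] <- FALSE
      if (!any(keep)) break
    }
    if (any(keep)) { best_k <- k; best_vs <- which(keep) } else break
  }
  list(k = best_k, vertices = best_vs)
}

# oracle MCODE vertex weight from the stated formula, via matrix peeling
oracle_vertex_weight <- function(adj, v, degree_cutoff = 2L) {
  if (sum(adj[v, ]) < degree_cutoff) return(0)
  nb <- c(v, which(adj[v, ] > 0))
  sub <- adj[nb, nb, drop = FALSE]
  hk <- oracle_highest_kcore(sub)
  if (hk$k == 0L) return(0)
  m <- sub[hk$vertices, hk$vertices, drop = FALSE]
  nv <- length(hk$vertices)
  dens <- if (nv < 2L) 0 else sum(m) / (nv * (nv - 1))
  hk$k * dens
}

# adjacency matrix of an InteractionNetwork
net_adj <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
    adj[i] <- 1L; adj[i[, 2:1, drop = FALSE]] <- 1L
  }
  adj
}

# brute-force count of edges spanning two gene sets
oracle_cross_edges <- function(net, A, B) {
  cnt <- 0L
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges$from[i]; v <- net$edges$to[i]
    if ((u %in% A && v %in% B) || (u %in% B && v %in% A)) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive upper-tail hypergeometric by enumerating all k-subsets
oracle_hyper_tail <- function(N, m, k, x, strict = FALSE) {
  subsets <- utils::combn(N, k)
  marked <- seq_len(m)
  overlaps <- apply(subsets, 2L, function(s) sum(s %in% marked))
  if (strict) mean(overlaps > x) else mean(overlaps >= x)
}

# pooled-variance two-sample t p-value from the textbook formula
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

# one-sample t p-value from the textbook formula
oracle_one_sample_t_p <- function(x, mu = 0) {
  tstat <- (mean(x) - mu) / (stats::sd(x) / sqrt(length(x)))
  2 * stats::pt(-abs(tstat), df = length(x) - 1)
}

# ER random graph as an InteractionNetwork
er_net <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("N%02d", seq_len(n))
  if (nrow(el) == 0L) return(interaction_network(nodes = nodes))
  interaction_network(data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]]),
                      nodes = nodes)
}
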