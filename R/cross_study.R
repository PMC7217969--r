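#' Screen studies and cross-study statistics
#'
#' A `ScreenStudy` holds one loss-of-function screen: its tested universe,
#' a per-gene score oriented so that lower = stronger synthetic-lethal
#' effect, and the ordered top-k hit list.
#'
#' @param study_id character scalar.
#' @param scores named numeric vector, one score per tested gene (lower =
#'   stronger synthetic lethal).
#' @param k hit-list size (top-k by ascending score). Default 250, the
#'   conventional cutoff for published KRAS synthetic-lethal hit lists.
#' @return an object of class `ScreenStudy` with elements `study_id`,
#'   `tested`, `scores`, `hits`, `k`.
#' @export
screen_study <- function(study_id, scores, k = 250) {
  stopifnot(is.character(study_id), length(study_id) == 1L,
            is.numeric(scores), length(scores) >= 1L)
  nm <- names(scores)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("scores must be a named vector (gene symbols)")
  names(scores) <- toupper(trimws(nm))
  if (anyDuplicated(names(scores)))
    stop("duplicate gene symbols in study ", study_id)
  if (anyNA(scores)) stop("NA scores in study ", study_id)
  out <- structure(list(study_id = study_id, tested = names(scores),
                        scores = scores, hits = NULL, k = as.integer(k)),
                   class = "ScreenStudy")
  out$hits <- top_k_hits(out, k)
  out
}

#' @export
print.ScreenStudy <- function(x, ...) {
  cat("ScreenStudy", x$study_id, ":", length(x$tested), "tested genes,",
      length(x$hits), "hits\n")
  invisible(x)
}

#' Top-k hits of a study
#'
#' The k lowest-score genes; ties at the boundary broken by lexicographic
#' gene symbol so the list is deterministic. If `k` exceeds the tested
#' universe, all genes are returned with a warning.
#'
#' @param study a [screen_study()].
#' @param k hit-list size, >= 1.
#' @return ordered character vector of gene symbols.
#' @export
top_k_hits <- function(study, k) {
  stopifnot(inherits(study, "ScreenStudy"), k >= 1L)
  n <- length(study$scores)
  if (k > n) {
    warning("k = ", k, " exceeds tested universe (", n, "); returning all genes")
    k <- n
  }
  ord <- order(study$scores, names(study$scores))
  names(study$scores)[ord][seq_len(k)]
}

#' Gene-level overlap between two studies (hypergeometric test)
#'
#' Tests whether the top-k hits of `study1` overlap the top-k hits of
#' `study2` more than expected by chance, accounting for each study's
#' tested universe. `study2`'s hits are first restricted to genes tested
#' in `study1`; the urn is then `study1`'s universe with the restricted
#' `study2` hits marked, and `study1`'s top-k are the draws. Upper-tail
#' probability `P(X >= x)` by default; `tail = "gt"` gives the strict tail
#' `P(X > x)` (the `1 - phyper(x, ...)` convention some studies print).
#' The test is asymmetric in (study1, study2); report both orientations if
#' in doubt.
#'
#' @param study1,study2 [screen_study()] objects.
#' @param k hit-list size (default: `study1$k`).
#' @param tail `"geq"` (default) or `"gt"`.
#' @return an `OverlapResult` list: `x` observed overlap, `m` marked genes,
#'   `n` unmarked, `k` draws, `p_value`, `tail`, `universe_size`.
#' @export
overlap_hypergeom <- function(study1, study2, k = study1$k,
                              tail = c("geq", "gt")) {
  stopifnot(inherits(study1, "ScreenStudy"), inherits(study2, "ScreenStudy"))
  tail <- match.arg(tail)
  if (length(study1$tested) == 0L || length(study2$tested) == 0L)
    stop("empty tested universe")
  hits1 <- top_k_hits(study1, k)
  hits2 <- intersect(top_k_hits(study2, k), study1$tested)
  N <- length(study1$tested)
  m <- length(hits2)
  kk <- length(hits1)
  x <- length(intersect(hits1, hits2))
  q <- if (tail == "geq") x - 1L else x
  p <- stats::phyper(q, m, N - m, kk, lower.tail = FALSE)
  structure(list(x = x, m = m, n = N - m, k = kk, universe_size = N,
                 p_value = p, tail = tail,
                 study1 = study1$study_id, study2 = study2$study_id),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Overlap %s vs %s: x=%d of k=%d (m=%d marked in N=%d), P(X %s x) = %.3g\n",
              x$study1, x$study2, x$x, x$k, x$m, x$universe_size,
              if (x$tail == "geq") ">=" else ">", x$p_value))
  invisible(x)
}

#' Count network edges spanning two hit sets
#'
#' Counts unordered edges with one endpoint in `hitsA` and the other in
#' `hitsB`. An edge whose endpoints are both in the intersection counts
#' once. Symmetric in (A, B) and monotone under edge addition.
#'
#' @param net an [interaction_network()].
#' @param hitsA,hitsB character vectors of gene symbols.
#' @return integer edge count.
#' @export
count_cross_study_edges <- function(net, hitsA, hitsB) {
  stopifnot(inherits(net, "InteractionNetwork"))
  if (nrow(net$edges) == 0L) return(0L)
  hitsA <- toupper(hitsA); hitsB <- toupper(hitsB)
  fA <- net$edges$from %in% hitsA; tA <- net$edges$to %in% hitsA
  fB <- net$edges$from %in% hitsB; tB <- net$edges$to %in% hitsB
  sum((fA & tB) | (fB & tA))
}

#' Permutation test for cross-study network connectivity
#'
#' Compares the observed number of network edges spanning the two studies'
#' top-k hit sets to a permutation null. Two null models are available:
#'
#' * `"gene-resample"` (default): each iteration draws k genes uniformly
#'   without replacement from each study's own tested universe and recounts
#'   spanning edges — controls for hit-list size and per-study test space.
#' * `"degree-rewire"`: each iteration degree-preservingly rewires the
#'   network and recounts edges between the real hit sets — controls for
#'   the degree sequence instead.
#'
#' The empirical p-value is the fraction of null draws reaching at least
#' the observed count; when none does it is reported as `< 1/n_perm`.
#'
#' @param net an [interaction_network()].
#' @param studyA,studyB [screen_study()] objects.
#' @param k hit-list size (default `studyA$k`).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @param null_mode `"gene-resample"` or `"degree-rewire"`.
#' @return a `PermutationResult` list: `observed`, `null_counts`,
#'   `p_empirical` (numeric, min `1/n_perm`), `p_string`,
#'   `fold_over_null`, `null_mode`, `n_perm`, `seed`.
#' @export
permutation_null_p <- function(net, studyA, studyB, k = studyA$k,
                               n_perm = 10000, seed = 1,
                               null_mode = c("gene-resample", "degree-rewire")) {
  stopifnot(inherits(net, "InteractionNetwork"),
            inherits(studyA, "ScreenStudy"), inherits(studyB, "ScreenStudy"),
            n_perm >= 1)
  null_mode <- match.arg(null_mode)
  if (k > length(studyA$tested) || k > length(studyB$tested))
    stop("k exceeds a study's tested universe")
  hitsA <- top_k_hits(studyA, k)
  hitsB <- top_k_hits(studyB, k)
  observed <- count_cross_study_edges(net, hitsA, hitsB)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  if (null_mode == "gene-resample") {
    # integer-coded edges for speed in the permutation loop
    univA <- studyA$tested; univB <- studyB$tested
    all_genes <- net$nodes
    ef <- match(net$edges$from, all_genes)
    et <- match(net$edges$to, all_genes)
    inA <- logical(length(all_genes)); inB <- logical(length(all_genes))
    idxA <- match(univA, all_genes); idxA <- idxA[!is.na(idxA)]
    idxB <- match(univB, all_genes); idxB <- idxB[!is.na(idxB)]
    null_counts <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      # sample from the full tested universes; genes absent from the network
      # contribute no edges, exactly as in the observed statistic
      sA <- sample(univA, k); sB <- sample(univB, k)
      inA[] <- FALSE; inB[] <- FALSE
      inA[match(sA, all_genes, nomatch = 0L)] <- TRUE
      inB[match(sB, all_genes, nomatch = 0L)] <- TRUE
      null_counts[i] <- sum((inA[ef] & inB[et]) | (inB[ef] & inA[et]))
    }
  } else {
    g <- as_igraph(net)
    null_counts <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = max(10L * igraph::ecount(g), 100L)))
      ed <- igraph::as_edgelist(gr, names = TRUE)
      fA <- ed[, 1L] %in% hitsA; tA <- ed[, 2L] %in% hitsA
      fB <- ed[, 1L] %in% hitsB; tB <- ed[, 2L] %in% hitsB
      null_counts[i] <- sum((fA & tB) | (fB & tA))
    }
  }
  n_ge <- sum(null_counts >= observed)
  p <- max(n_ge, 1L) / n_perm
  p_string <- if (n_ge == 0L) paste0("< ", format(1 / n_perm)) else format(p)
  mu <- mean(null_counts)
  structure(list(observed = observed, null_counts = null_counts,
                 p_empirical = p, p_string = p_string,
                 fold_over_null = if (mu > 0) observed / mu else NA_real_,
                 null_mode = null_mode, n_perm = as.integer(n_perm),
                 seed = seed,
                 studyA = studyA$study_id, studyB = studyB$study_id),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Cross-study connectivity %s vs %s: observed %d edges, %.1f-fold over null, p %s (%s, %d perms)\n",
              x$studyA, x$studyB, x$observed,
              x$fold_over_null, x$p_string, x$null_mode, x$n_perm))
  invisible(x)
}

#' Read ranked hit-list TSVs into studies
#'
#' Expects columns `study_id`, `gene`, `score`; one [screen_study()] is
#' built per distinct `study_id`.
#'
#' @param path TSV path.
#' @param k hit-list size per study.
#' @return named list of `ScreenStudy` objects.
#' @export
read_studies_tsv <- function(path, k = 250) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "gene", "score") %in% names(df)))
  out <- lapply(split(df, df$study_id), function(d) {
    screen_study(d$study_id[1L], stats::setNames(d$score, d$gene), k = k)
  })
  out[order(names(out))]
}
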