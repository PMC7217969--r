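#' Cellular-context score: condition variance of interaction scores
#'
#' The variance (sample variance, n-1 denominator) of a gene's
#' genetic-interaction scores across growth conditions. A gene whose
#' synthetic-lethal effect persists across conditions scores near 0;
#' condition-specific effects score high. Translation-invariant by
#' construction. `population = TRUE` switches to the n denominator.
#'
#' @param gi_scores numeric vector of per-condition S values (>= 2).
#' @param population use the population variance (default FALSE).
#' @return nonnegative variance.
#' @examples
#' cellular_context_score(c(0, 0, -6))  # 12
#' @export
cellular_context_score <- function(gi_scores, population = FALSE) {
  gi_scores <- as.numeric(gi_scores)
  if (length(gi_scores) < 2L) stop("need scores for >= 2 conditions")
  if (anyNA(gi_scores)) stop("NA scores")
  v <- stats::var(gi_scores)
  if (population) v <- v * (length(gi_scores) - 1) / length(gi_scores)
  v
}

#' Composite context-independence ranking
#'
#' Combines the cellular-context score (condition variance of S) and the
#' genetic-context score (suppressor count) into a composite = product.
#' Genes are ranked by ascending composite — rank 1 is the most
#' context-independent candidate (low variance, few suppressors); ties
#' share the mean rank. The composite is also Z-normalized across genes
#' for display; the ranking itself uses the raw composite. Genes with a
#' missing genetic score are excluded (not imputed).
#'
#' @param entries data.frame with columns `gene`, `cellular_score`,
#'   `genetic_score`, and optionally `category`.
#' @return `ContextRank` data.frame: `gene`, `cellular_score`,
#'   `genetic_score`, `composite`, `composite_z`, `rank`, `category`,
#'   sorted by rank.
#' @export
composite_rank <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("gene", "cellular_score", "genetic_score") %in% names(entries)))
  if (nrow(entries) == 0L) stop("empty input")
  keep <- !is.na(entries$genetic_score) & !is.na(entries$cellular_score)
  if (any(!keep))
    message("composite_rank: excluding ", sum(!keep),
            " gene(s) with missing scores")
  e <- entries[keep, , drop = FALSE]
  if (nrow(e) == 0L) stop("no genes with complete scores")
  if (any(e$cellular_score < 0)) stop("cellular_score must be >= 0")
  if (any(e$genetic_score < 0)) stop("genetic_score must be >= 0")
  composite <- e$cellular_score * e$genetic_score
  sdc <- stats::sd(composite)
  out <- data.frame(gene = e$gene,
                    cellular_score = e$cellular_score,
                    genetic_score = e$genetic_score,
                    composite = composite,
                    composite_z = if (is.na(sdc) || sdc == 0) rep(0, length(composite))
                                  else (composite - mean(composite)) / sdc,
                    rank = rank(composite, ties.method = "average"),
                    category = if ("category" %in% names(e)) e$category
                               else rep("other", nrow(e)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("ContextRank", class(out)))
  out
}

# exact one-sided P(rank sum of group A <= observed) by enumeration of all
# C(n, nA) assignments of the pooled observed rank values
rank_sum_exact_p <- function(ranksA, ranksB, alternative) {
  pooled <- c(ranksA, ranksB)
  nA <- length(ranksA)
  combs <- utils::combn(length(pooled), nA)
  sums <- colSums(matrix(pooled[combs], nrow = nA))
  wA <- sum(ranksA)
  p_less <- mean(sums <= wA)
  p_greater <- mean(sums >= wA)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# normal approximation with tie correction and continuity correction
rank_sum_normal_p <- function(ranksA, ranksB, alternative) {
  nA <- length(ranksA); nB <- length(ranksB); n <- nA + nB
  pooled <- c(ranksA, ranksB)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  mu <- nA * (n + 1) / 2
  sigma2 <- nA * nB / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(if (alternative == "two.sided") 1 else 0.5)
  wA <- sum(ranksA)
  sig <- sqrt(sigma2)
  p_less <- stats::pnorm((wA + 0.5 - mu) / sig)
  p_greater <- stats::pnorm((wA - 0.5 - mu) / sig, lower.tail = FALSE)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

#' Rank-sum test between gene categories
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of whether one category occupies
#' smaller (more context-independent) ranks than another. Exact by full
#' enumeration of rank assignments when the combined group size is <= 20;
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param ranks numeric vector of composite ranks (e.g. `$rank` of
#'   [composite_rank()]).
#' @param categories character vector aligned with `ranks`.
#' @param groupA,groupB category labels to compare; the one-sided
#'   alternative is "groupA ranks are smaller".
#' @param alternative `"less"` (default), `"greater"`, or `"two.sided"`.
#' @param exact_max maximum combined size for exact enumeration
#'   (default 20).
#' @return list: `p_value`, `method` (`"exact"`/`"normal"`), `nA`, `nB`,
#'   `rank_sum_A`.
#' @export
group_rank_test <- function(ranks, categories, groupA, groupB,
                            alternative = c("less", "greater", "two.sided"),
                            exact_max = 20L) {
  alternative <- match.arg(alternative)
  stopifnot(length(ranks) == length(categories))
  ranksA <- ranks[categories == groupA]
  ranksB <- ranks[categories == groupB]
  if (length(ranksA) == 0L || length(ranksB) == 0L)
    stop("both groups must be nonempty")
  n <- length(ranksA) + length(ranksB)
  # re-rank within the two groups so the test depends only on relative order
  rr <- rank(c(ranksA, ranksB), ties.method = "average")
  ranksA <- rr[seq_along(ranksA)]
  ranksB <- rr[-seq_along(ranksA)]
  if (n <= exact_max) {
    p <- rank_sum_exact_p(ranksA, ranksB, alternative)
    method <- "exact"
  } else {
    p <- rank_sum_normal_p(ranksA, ranksB, alternative)
    method <- "normal"
  }
  list(p_value = p, method = method, nA = length(ranksA), nB = length(ranksB),
       rank_sum_A = sum(ranksA))
}
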