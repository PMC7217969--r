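#' Percentile-rank a differential-essentiality screen
#'
#' Converts per-gene differential scores (mutant minus wild-type
#' essentiality, oriented so synthetic lethal = negative) into percentiles
#' `100 * rank / n`, rank 1 = most negative. Ties share the mean rank, so
#' percentiles are invariant under any monotone transform of the scores.
#'
#' @param diff_scores named numeric vector, one score per gene.
#' @return named numeric vector of percentiles in (0, 100].
#' @examples
#' percentile_rank(c(A = -5, B = 0, C = 5))
#' @export
percentile_rank <- function(diff_scores) {
  if (length(diff_scores) < 2L) stop("need >= 2 genes")
  nm <- names(diff_scores)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("diff_scores must be named by gene")
  if (anyNA(diff_scores)) stop("NA scores")
  pct <- 100 * rank(diff_scores, ties.method = "average") / length(diff_scores)
  stats::setNames(pct, toupper(nm))
}

#' Top-percentile accuracy of a candidate gene set
#'
#' Restricts the candidates to genes present in the percentile table (the
#' study's tested universe) and reports the fraction falling at or below
#' the percentile cutoff — how often the candidates land in the held-out
#' screen's strongest tail.
#'
#' @param candidates character vector of gene symbols.
#' @param table percentiles from [percentile_rank()].
#' @param cutoff percentile cutoff in (0, 100] (default 5).
#' @return list: `n_tested`, `n_top`, `accuracy` (NA with `defined = FALSE`
#'   when no candidate was tested).
#' @export
accuracy_at_percentile <- function(candidates, table, cutoff = 5) {
  stopifnot(cutoff > 0, cutoff <= 100)
  cand <- intersect(unique(toupper(candidates)), names(table))
  if (length(cand) == 0L)
    return(list(n_tested = 0L, n_top = 0L, accuracy = NA_real_, defined = FALSE))
  top <- sum(table[cand] <= cutoff)
  list(n_tested = length(cand), n_top = as.integer(top),
       accuracy = top / length(cand), defined = TRUE)
}
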