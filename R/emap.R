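#' E-MAP plate normalization
#'
#' One combinatorial-knockdown plate holds a constant query gene against
#' the full esiRNA array. Counts are normalized to the plate median and
#' Z-scored against the plate's own distribution (population SD). Because
#' every well on a plate shares the query knockdown, plate-median
#' normalization implicitly absorbs the query's single-knockdown fitness
#' effect, so Z measures deviation from the plate-typical double-knockdown
#' outcome. A robust variant uses median/MAD instead of mean/SD.
#'
#' @param counts numeric well counts of one plate (>= 3 wells).
#' @param robust use median/MAD location/scale (default FALSE).
#' @return numeric vector of per-well Z values; all 0 when the plate has
#'   zero spread.
#' @examples
#' emap_normalize(c(1, 2, 3))  # -1.22, 0, 1.22
#' @export
emap_normalize <- function(counts, robust = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty plate")
  if (length(counts) < 3L) stop("plate must have >= 3 wells")
  med <- stats::median(counts)
  if (med == 0) stop("plate median is zero")
  v <- counts / med
  if (robust) {
    ctr <- stats::median(v)
    sc <- stats::mad(v)
  } else {
    ctr <- mean(v)
    sc <- sqrt(mean((v - ctr)^2))  # population SD
  }
  if (sc == 0) return(rep(0, length(v)))
  (v - ctr) / sc
}

#' Z-score an E-MAP plate table
#'
#' Applies [emap_normalize()] per plate and returns the long table with a
#' `z` column. The table must carry `query_gene` and `array_gene` columns
#' (plus `plate_id`, `replicate`, `cell_count`).
#'
#' @param table data.frame of E-MAP wells.
#' @param robust passed to [emap_normalize()].
#' @return the table with a `z` column added.
#' @export
emap_score_plates <- function(table, robust = FALSE) {
  need <- c("plate_id", "query_gene", "array_gene", "replicate", "cell_count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("E-MAP table missing column(s): ",
                         paste(miss, collapse = ", "))
  table$z <- NA_real_
  for (p in unique(table$plate_id)) {
    i <- table$plate_id == p
    table$z[i] <- emap_normalize(table$cell_count[i], robust = robust)
  }
  table
}

#' Average replicate Z-scores per gene pair
#'
#' Mean Z over the (nominally four) replicate wells of each
#' (query, array) combination; pairs with fewer replicates than
#' `expected_reps` are averaged over what is available and flagged.
#'
#' @param ztable output of [emap_score_plates()].
#' @param expected_reps nominal replicate count (default 4).
#' @return data.frame `query_gene`, `array_gene`, `z_mean`, `n_reps`,
#'   `incomplete`.
#' @export
average_replicates <- function(ztable, expected_reps = 4L) {
  stopifnot(all(c("query_gene", "array_gene", "z") %in% names(ztable)))
  if (nrow(ztable) == 0L) stop("no replicate rows")
  agg <- stats::aggregate(z ~ query_gene + array_gene, ztable,
                          function(x) c(mean(x), length(x)))
  out <- data.frame(query_gene = agg$query_gene, array_gene = agg$array_gene,
                    z_mean = agg$z[, 1L], n_reps = as.integer(agg$z[, 2L]),
                    stringsAsFactors = FALSE)
  out$incomplete <- out$n_reps < expected_reps
  out <- out[order(out$query_gene, out$array_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call genetic interactions from mean Z-scores
#'
#' Positive (buffering/suppressing) interactions have `z_mean > cutoff`,
#' negative (aggravating) `z_mean < -cutoff`; the conventional cutoff is
#' 2 SD.
#'
#' @param scores data.frame from [average_replicates()].
#' @param cutoff |Z| call threshold (default 2).
#' @return list: `calls` (the scores with a `call` column), `summary`
#'   (`n_pairs`, `n_positive`, `n_negative`, `strong_fraction`).
#' @export
call_interactions <- function(scores, cutoff = 2) {
  stopifnot("z_mean" %in% names(scores))
  call <- ifelse(scores$z_mean > cutoff, "positive",
                 ifelse(scores$z_mean < -cutoff, "negative", "neutral"))
  scores$call <- call
  n_pos <- sum(call == "positive"); n_neg <- sum(call == "negative")
  list(calls = scores,
       summary = list(n_pairs = nrow(scores), n_positive = n_pos,
                      n_negative = n_neg,
                      strong_fraction = if (nrow(scores)) (n_pos + n_neg) / nrow(scores) else NA_real_))
}

#' Suppressor counts per query gene
#'
#' A suppressor of a synthetic-lethal query is an array gene whose
#' co-knockdown rescues the query's fitness defect: a positive interaction
#' (`z_mean > cutoff`). Returns the per-query count and its mean across
#' queries — the genetic-context burden used by the composite ranking.
#'
#' @param scores data.frame from [average_replicates()] (or with a
#'   `z_mean` column and `query_gene`).
#' @param cutoff positive-call threshold (default 2).
#' @return list: `per_query` (named integer vector over all queries,
#'   including zeros), `mean_per_query`.
#' @export
suppressor_counts <- function(scores, cutoff = 2) {
  stopifnot(all(c("query_gene", "z_mean") %in% names(scores)))
  queries <- sort(unique(scores$query_gene))
  pos <- scores$z_mean > cutoff
  per <- vapply(queries, function(q) sum(pos & scores$query_gene == q), 0L)
  list(per_query = per, mean_per_query = mean(per))
}

#' Pathway-bundle significance of genetic interactions
#'
#' For each (query gene, pathway) with at least `min_members` scored array
#' genes, tests whether the member mean-Z scores deviate from zero as a
#' bundle: two-sided one-sample t test against 0, direction = sign of the
#' member mean. Bundles with |mean| ~ 0 and p ~ 1 are reported neutral.
#'
#' @param scores data.frame from [average_replicates()].
#' @param pathways a [gene_set_collection()] over array genes.
#' @param min_members minimum scored members per bundle (default 3).
#' @param alpha significance threshold annotated on output (default 0.01).
#' @return data.frame `query_gene`, `pathway`, `n_members`, `mean_z`,
#'   `t_p_value`, `direction`, `significant`; skipped bundles are absent.
#' @export
pathway_bundle_test <- function(scores, pathways, min_members = 3L,
                                alpha = 0.01) {
  stopifnot(all(c("query_gene", "array_gene", "z_mean") %in% names(scores)),
            inherits(pathways, "GeneSetCollection"))
  rows <- list()
  for (q in sort(unique(scores$query_gene))) {
    sq <- scores[scores$query_gene == q, , drop = FALSE]
    for (pw in names(pathways$sets)) {
      zs <- sq$z_mean[sq$array_gene %in% pathways$sets[[pw]]]
      if (length(zs) < min_members) next
      if (stats::sd(zs) == 0) {
        p <- if (mean(zs) == 0) 1 else 0
      } else {
        p <- stats::t.test(zs, mu = 0)$p.value
      }
      dir <- if (mean(zs) > 0) "positive" else if (mean(zs) < 0) "negative" else "neutral"
      rows[[length(rows) + 1L]] <-
        data.frame(query_gene = q, pathway = pw, n_members = length(zs),
                   mean_z = mean(zs), t_p_value = p, direction = dir,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_gene = character(), pathway = character(),
                      n_members = integer(), mean_z = numeric(),
                      t_p_value = numeric(), direction = character(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$significant <- out$t_p_value < alpha
  rownames(out) <- NULL
  out
}
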