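#' Plate-count tables
#'
#' Long-form table of imaged cell counts from an arrayed RNAi screen: one
#' row per well with `plate_id`, `well`, `cell_line`, `condition`,
#' `perturbation` (a gene symbol, a `"Q+A"` gene pair, or `"NT"` for the
#' non-targeting control), `replicate` and `cell_count`. Every plate must
#' carry at least one NT well (the per-plate normalization anchor).
#'
#' @param df a data.frame with the columns above.
#' @param require_nt check the NT-per-plate invariant (default TRUE).
#' @return the validated data.frame with class `PlateTable` prepended.
#' @export
plate_table <- function(df, require_nt = TRUE) {
  need <- c("plate_id", "well", "cell_line", "condition", "perturbation",
            "replicate", "cell_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$cell_count < 0, na.rm = TRUE)) stop("negative cell counts")
  if (require_nt) {
    has_nt <- tapply(df$perturbation == "NT", df$plate_id, any)
    if (any(!has_nt))
      stop("plate(s) without NT control wells: ",
           paste(names(has_nt)[!has_nt], collapse = ", "))
  }
  key <- paste(df$plate_id, df$perturbation, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (plate, perturbation, replicate) rows")
  class(df) <- unique(c("PlateTable", class(df)))
  df
}

#' Normalize counts to per-plate non-targeting controls
#'
#' Divides each well's count by the mean NT-control count of its own
#' plate, adding a `norm_prolif` column. Invariant to any per-plate
#' multiplicative scaling (imaging/seeding batch effects).
#'
#' @param table a [plate_table()].
#' @return the table with a `norm_prolif` column.
#' @export
normalize_to_nt <- function(table) {
  table <- plate_table(as.data.frame(table))
  nt <- table[table$perturbation == "NT", , drop = FALSE]
  nt_mean <- tapply(nt$cell_count, nt$plate_id, mean)
  if (any(nt_mean == 0))
    stop("NT mean is zero on plate(s): ",
         paste(names(nt_mean)[nt_mean == 0], collapse = ", "))
  idx <- match(table$plate_id, names(nt_mean))
  if (anyNA(idx))
    stop("plate(s) without NT control wells: ",
         paste(unique(table$plate_id[is.na(idx)]), collapse = ", "))
  table$norm_prolif <- table$cell_count / as.numeric(nt_mean[idx])
  table
}

# cap for -log10(p) so S never becomes infinite at p underflow
.S_CAP <- 300

#' Genetic-interaction score for one gene
#'
#' Two-sided two-sample Student's t test (pooled variance by default)
#' comparing normalized proliferation after knockdown in the mutant arm
#' versus the control arm. The score is
#' `S = sign(mean(mutant) - mean(control)) * (-log10 p)`: negative S marks
#' synthetic sickness/lethality, positive S enhancement. Equal means (or
#' p = 1) give S = 0; `-log10(p)` is capped at 300.
#'
#' @param norm_kras numeric replicate values for the mutant (KRAS) arm.
#' @param norm_egfp numeric replicate values for the control (eGFP) arm.
#' @param var_equal pooled-variance t (default TRUE); FALSE gives Welch.
#' @return a `GIScore` list: `S`, `p_value`, `mean_kras`, `mean_egfp`,
#'   `n_reps` (c(kras, egfp)).
#' @export
gi_score <- function(norm_kras, norm_egfp, var_equal = TRUE) {
  norm_kras <- as.numeric(norm_kras); norm_egfp <- as.numeric(norm_egfp)
  if (length(norm_kras) < 2L || length(norm_egfp) < 2L)
    stop("need >= 2 replicates per arm")
  d <- mean(norm_kras) - mean(norm_egfp)
  if (stats::sd(norm_kras) == 0 && stats::sd(norm_egfp) == 0) {
    p <- if (d == 0) 1 else 0     # degenerate zero-variance arms
  } else {
    p <- stats::t.test(norm_kras, norm_egfp, var.equal = var_equal)$p.value
  }
  s <- if (d == 0 || p == 1) 0 else sign(d) * min(-log10(max(p, 10^(-.S_CAP))), .S_CAP)
  structure(list(S = s, p_value = p,
                 mean_kras = mean(norm_kras), mean_egfp = mean(norm_egfp),
                 n_reps = c(kras = length(norm_kras), egfp = length(norm_egfp))),
            class = "GIScore")
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjusted q-values: `q_(i) = min_{j >= i} p_(j) * n / j`
#' over the order statistics, capped at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric())
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * n / seq(n, 1)))
  q[order(ord)]
}

#' Score an isogenic knockdown screen
#'
#' Full per-gene scoring of one contrast: normalize counts to per-plate NT
#' controls, compute [gi_score()] for every gene between the two arms, and
#' adjust p-values across genes with [bh_fdr()]. The conventional contrast
#' is the sensitized mutant arm (KRAS cells, minimal media) against the
#' control arm (eGFP cells, full media). Hits are genes below an FDR
#' threshold, labeled by direction: synthetic lethal (S < 0) or enhancer
#' (S > 0).
#'
#' @param table a [plate_table()] of raw counts.
#' @param kras_arm `c(cell_line, condition)` of the mutant arm
#'   (default `c("KRAS", "minimal")`).
#' @param ctrl_arm `c(cell_line, condition)` of the control arm
#'   (default `c("eGFP", "full")`).
#' @param fdr_thresholds thresholds at which hit calls are annotated
#'   (default 1%, 5%, 10%).
#' @param var_equal pooled-variance t (default TRUE).
#' @return data.frame, one row per gene: `gene`, `S`, `p_value`, `fdr_q`,
#'   `mean_kras`, `mean_egfp`, `direction`, plus logical `hit_fdr<t>`
#'   columns. Sorted by `S`.
#' @export
score_screen <- function(table, kras_arm = c("KRAS", "minimal"),
                         ctrl_arm = c("eGFP", "full"),
                         fdr_thresholds = c(0.01, 0.05, 0.10),
                         var_equal = TRUE) {
  norm <- normalize_to_nt(table)
  pick <- function(arm) norm[norm$cell_line == arm[1L] &
                             norm$condition == arm[2L] &
                             norm$perturbation != "NT", , drop = FALSE]
  kras <- pick(kras_arm); ctrl <- pick(ctrl_arm)
  if (nrow(kras) == 0L) stop("arm not present in table: ",
                             paste(kras_arm, collapse = "/"))
  if (nrow(ctrl) == 0L) stop("arm not present in table: ",
                             paste(ctrl_arm, collapse = "/"))
  genes <- sort(intersect(unique(kras$perturbation), unique(ctrl$perturbation)))
  rows <- lapply(genes, function(g) {
    gs <- gi_score(kras$norm_prolif[kras$perturbation == g],
                   ctrl$norm_prolif[ctrl$perturbation == g],
                   var_equal = var_equal)
    data.frame(gene = g, S = gs$S, p_value = gs$p_value,
               mean_kras = gs$mean_kras, mean_egfp = gs$mean_egfp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr_q <- bh_fdr(res$p_value)
  res$direction <- ifelse(res$S < 0, "synthetic_lethal",
                          ifelse(res$S > 0, "enhancer", "neutral"))
  for (t in fdr_thresholds)
    res[[sprintf("hit_fdr%g", 100 * t)]] <- res$fdr_q < t
  res <- res[order(res$S, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Concordance of interaction scores across conditions
#'
#' Pairwise Pearson correlation of per-gene S vectors between conditions
#' (or alleles), plus per-gene consistency labels: `consistent_SL` (a
#' synthetic-lethal hit in every condition), `condition_specific` (hit in
#' at least one but not all), `non_hit`.
#'
#' @param S a gene x condition numeric matrix of interaction scores.
#' @param q optional matching matrix of FDR q-values (needed for labels).
#' @param fdr hit threshold used for labeling (default 0.10).
#' @return list: `r` (condition x condition Pearson matrix, NA when < 3
#'   shared genes), `labels` (named character vector, NULL when `q`
#'   missing).
#' @export
condition_concordance <- function(S, q = NULL, fdr = 0.10) {
  S <- as.matrix(S)
  if (ncol(S) < 2L) stop("need >= 2 conditions")
  nc <- ncol(S)
  r <- matrix(NA_real_, nc, nc, dimnames = list(colnames(S), colnames(S)))
  diag(r) <- 1
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    ok <- stats::complete.cases(S[, c(i, j)])
    if (sum(ok) >= 3L)
      r[i, j] <- r[j, i] <- stats::cor(S[ok, i], S[ok, j])
  }
  labels <- NULL
  if (!is.null(q)) {
    q <- as.matrix(q)
    stopifnot(all(dim(q) == dim(S)))
    hit <- q < fdr & S < 0
    n_hit <- rowSums(hit, na.rm = TRUE)
    n_cond <- rowSums(!is.na(hit))
    labels <- ifelse(n_hit == 0, "non_hit",
                     ifelse(n_hit == n_cond, "consistent_SL",
                            "condition_specific"))
    names(labels) <- rownames(S)
  }
  list(r = r, labels = labels)
}

#' Drug-screen AUC ranking
#'
#' Per drug and arm, the dose-response AUC is the plain sum of normalized
#' proliferation values over the dose series (default 4 doses). Drugs are
#' ranked by `delta_auc = AUC(control arm) - AUC(mutant arm)`, most
#' mutant-selective first.
#'
#' @param dose_table data.frame with columns `drug`, `arm`, `dose`,
#'   `norm_prolif` (replicates already averaged, one row per dose).
#' @param ctrl_arm,kras_arm arm labels (defaults `"eGFP_full"`,
#'   `"KRAS_minimal"`).
#' @param n_doses required doses per drug/arm (default 4).
#' @return data.frame `drug`, `auc_ctrl`, `auc_kras`, `delta_auc`, `rank`,
#'   sorted by `delta_auc` descending.
#' @export
drug_auc <- function(dose_table, ctrl_arm = "eGFP_full",
                     kras_arm = "KRAS_minimal", n_doses = 4L) {
  need <- c("drug", "arm", "dose", "norm_prolif")
  stopifnot(all(need %in% names(dose_table)))
  cnt <- table(dose_table$drug, dose_table$arm)
  if (any(cnt[cnt > 0] != n_doses))
    stop("each drug/arm must have exactly ", n_doses, " doses")
  agg <- stats::aggregate(norm_prolif ~ drug + arm, dose_table, sum)
  wide <- stats::reshape(agg, idvar = "drug", timevar = "arm", direction = "wide")
  cc <- paste0("norm_prolif.", ctrl_arm); kc <- paste0("norm_prolif.", kras_arm)
  if (!all(c(cc, kc) %in% names(wide)))
    stop("missing arm(s): need ", ctrl_arm, " and ", kras_arm)
  out <- data.frame(drug = wide$drug, auc_ctrl = wide[[cc]],
                    auc_kras = wide[[kc]], stringsAsFactors = FALSE)
  out$delta_auc <- out$auc_ctrl - out$auc_kras
  out <- out[order(-out$delta_auc, out$drug), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
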