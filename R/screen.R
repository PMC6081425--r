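# Candidate TDMD target screen: 3C-score classes, contextual expression
# filters, pool contributions, and ranking.

.c3_levels <- c("NONE", "LOW", "MID", "HIGH")

#' Classify a 3' pairing contribution (3C) score
#'
#' 3C-targets fall into three classes of increasing 3' complementarity:
#' LOW for scores in (-0.03, -0.01], MID in (-0.05, -0.03], and HIGH at or
#' below -0.05. Scores above the -0.01 entry threshold are NONE (not a
#' 3C-target). Boundaries are assigned to the more-negative class.
#'
#' @param c3_score Numeric vector of non-positive TargetScan 3' pairing
#'   contribution scores.
#' @param config A [tdmd_config()] carrying the class boundaries.
#' @return Ordered factor with levels NONE < LOW < MID < HIGH.
#' @export
classify_3c <- function(c3_score, config = tdmd_config()) {
  if (any(c3_score > 0)) {
    stop("positive 3C-score: the 3' pairing contribution is non-positive")
  }
  cls <- ifelse(c3_score <= config$c3_high, "HIGH",
         ifelse(c3_score <= config$c3_mid, "MID",
         ifelse(c3_score <= config$c3_entry, "LOW", "NONE")))
  factor(cls, levels = .c3_levels, ordered = TRUE)
}

.check_records <- function(records) {
  need <- c("gene", "mirna", "c3_score")
  if (!all(need %in% names(records))) {
    stop("target records need columns: ", paste(need, collapse = ", "))
  }
  records
}

#' Filter target records by contextual expression
#'
#' Keeps the miRNA:target pairs whose gene is expressed (reaches at least
#' `rpkm_min` RPKM in one or more conditions) and whose miRNA exceeds
#' `cpm_min` CPM (strictly). Genes or miRNAs absent from the matrices are
#' treated as not expressed (and reported via a message).
#'
#' @param records data.frame of target records (columns `gene`, `mirna`,
#'   `c3_score`, optionally `site_type`, `conserved`).
#' @param gene_expr Gene RPKM matrix (genes x conditions).
#' @param mirna_expr miRNA CPM matrix (miRNAs x conditions).
#' @param rpkm_min,cpm_min Expression thresholds.
#' @return The retained rows of `records`.
#' @export
filter_expressed <- function(records, gene_expr, mirna_expr,
                             rpkm_min = 1, cpm_min = 10) {
  .check_records(records)
  gmax <- apply(gene_expr, 1, max)
  mmax <- apply(mirna_expr, 1, max)
  missing_g <- setdiff(unique(records$gene), names(gmax))
  missing_m <- setdiff(unique(records$mirna), names(mmax))
  if (length(missing_g)) {
    message(length(missing_g),
            " gene(s) absent from the expression matrix, treated as not expressed")
  }
  if (length(missing_m)) {
    message(length(missing_m),
            " miRNA(s) absent from the CPM matrix, treated as not expressed")
  }
  gene_ok <- records$gene %in% names(gmax)[gmax >= rpkm_min]
  mirna_ok <- records$mirna %in% names(mmax)[mmax > cpm_min]
  records[gene_ok & mirna_ok, , drop = FALSE]
}

#' Fraction of 3C-targets per miRNA
#'
#' For each miRNA, the percentage of its predicted targets carrying a 3C
#' site (score at or below the entry threshold), broken down by class. The
#' input must include the non-3C predictions to form the denominator.
#'
#' @inheritParams filter_expressed
#' @param config A [tdmd_config()].
#' @return List with `per_mirna` (data.frame: `mirna`, `n_pred`, `n_3c`,
#'   `pct_3c`, `pct_low`, `pct_mid`, `pct_high`) and `overall` (aggregate
#'   percentage of 3C interactions over all predictions).
#' @export
fraction_3c <- function(records, config = tdmd_config()) {
  .check_records(records)
  cls <- classify_3c(records$c3_score, config)
  tab <- table(records$mirna, cls)
  n_pred <- rowSums(tab)
  keep <- n_pred > 0
  if (any(!keep)) message(sum(!keep), " miRNA(s) with zero predictions omitted")
  tab <- tab[keep, , drop = FALSE]
  n_pred <- n_pred[keep]
  n_3c <- rowSums(tab[, c("LOW", "MID", "HIGH"), drop = FALSE])
  per <- data.frame(
    mirna = rownames(tab),
    n_pred = as.integer(n_pred),
    n_3c = as.integer(n_3c),
    pct_3c = 100 * n_3c / n_pred,
    pct_low = 100 * tab[, "LOW"] / n_pred,
    pct_mid = 100 * tab[, "MID"] / n_pred,
    pct_high = 100 * tab[, "HIGH"] / n_pred,
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_mirna = per,
       overall = 100 * sum(n_3c) / sum(n_pred))
}

#' Contribution of each target to a miRNA's 3C pool
#'
#' For one miRNA and one condition, expresses each 3C-target's RPKM as a
#' percentage of the summed RPKM of all the miRNA's 3C-targets at or above
#' `class_floor` (RPKM_target / RPKM_sum-of-all-3C-targets x 100).
#'
#' @inheritParams filter_expressed
#' @param mirna miRNA name.
#' @param condition Column of `gene_expr` to use.
#' @param class_floor Lowest 3C class entering the pool (`"LOW"`, `"MID"`,
#'   or `"HIGH"`).
#' @param config A [tdmd_config()].
#' @return Named numeric vector of percentages (one entry per pool gene),
#'   summing to 100. A zero-sum pool yields `NA`s with a warning.
#' @export
pool_contribution <- function(records, gene_expr, mirna, condition,
                              class_floor = "LOW", config = tdmd_config()) {
  .check_records(records)
  floor_lvl <- match.arg(class_floor, .c3_levels[-1])
  cls <- classify_3c(records$c3_score, config)
  pool <- records$gene[records$mirna == mirna &
                         cls >= factor(floor_lvl, .c3_levels, ordered = TRUE)]
  pool <- unique(pool)
  if (!length(pool)) stop("no 3C-targets of ", mirna, " at floor ", floor_lvl)
  rpkm <- ifelse(pool %in% rownames(gene_expr),
                 gene_expr[match(pool, rownames(gene_expr)), condition], 0)
  names(rpkm) <- pool
  total <- sum(rpkm)
  if (total == 0) {
    warning("zero-sum 3C pool for ", mirna, " in condition ", condition)
    return(stats::setNames(rep(NA_real_, length(pool)), pool))
  }
  100 * rpkm / total
}

#' Rank candidate TDMD targets
#'
#' For every 3C miRNA:target pair, computes the maximum log2 fold-change of
#' the target across the time course (relative to the reference condition,
#' with a pseudocount), the maximum percentage contribution to the miRNA's
#' 3C pool over all conditions, and the maximum RPKM. Pairs are ranked by
#' (3C class, max pool contribution, max log2 FC), all descending.
#'
#' @inheritParams pool_contribution
#' @param gene_expr Gene RPKM matrix over the time course; the reference
#'   condition is its first column unless `reference` names another.
#' @param reference Reference condition for fold-changes (default the first
#'   column, i.e. the 0 h / unstimulated state).
#' @return data.frame with one row per (gene, miRNA) pair:
#'   `gene`, `mirna`, `c3_class`, `c3_score`, `max_log2fc`, `max_pool_pct`,
#'   `max_rpkm`, ordered best candidate first.
#' @export
rank_candidates <- function(records, gene_expr, class_floor = "LOW",
                            reference = colnames(gene_expr)[1],
                            config = tdmd_config()) {
  .check_records(records)
  if (ncol(gene_expr) < 2) stop("need at least 2 conditions")
  pc <- config$log2fc_pseudocount
  floor_lvl <- factor(match.arg(class_floor, .c3_levels[-1]),
                      .c3_levels, ordered = TRUE)
  cls <- classify_3c(records$c3_score, config)
  rec <- records[cls >= floor_lvl, , drop = FALSE]
  rec$c3_class <- as.character(cls[cls >= floor_lvl])
  rec <- rec[rec$gene %in% rownames(gene_expr), , drop = FALSE]
  if (!nrow(rec)) stop("no 3C pairs with expression data at floor ",
                       as.character(floor_lvl))

  pool_pct <- matrix(0, nrow(rec), ncol(gene_expr))
  for (mi in unique(rec$mirna)) {
    rows <- which(rec$mirna == mi)
    for (j in seq_len(ncol(gene_expr))) {
      pc_j <- pool_contribution(records, gene_expr, mi,
                                condition = colnames(gene_expr)[j],
                                class_floor = as.character(floor_lvl),
                                config = config)
      pool_pct[rows, j] <- pc_j[rec$gene[rows]]
    }
  }
  expr <- gene_expr[rec$gene, , drop = FALSE]
  ref <- expr[, reference]
  lfc <- log2(sweep(expr + pc, 1, ref + pc, "/"))
  out <- data.frame(
    gene = rec$gene, mirna = rec$mirna,
    c3_class = factor(rec$c3_class, .c3_levels, ordered = TRUE),
    c3_score = rec$c3_score,
    max_log2fc = apply(lfc, 1, max),
    max_pool_pct = apply(pool_pct, 1, max),
    max_rpkm = apply(expr, 1, max),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-as.integer(out$c3_class), -out$max_pool_pct,
                   -out$max_log2fc, out$gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full candidate screen
#'
#' Convenience wrapper chaining [filter_expressed()] and
#' [rank_candidates()]: the screen applied to a target table plus gene and
#' miRNA expression matrices.
#'
#' @inheritParams filter_expressed
#' @inheritParams rank_candidates
#' @return The ranked candidate table (see [rank_candidates()]).
#' @export
tdmd_screen <- function(records, gene_expr, mirna_expr,
                        class_floor = "LOW", config = tdmd_config()) {
  kept <- filter_expressed(records, gene_expr, mirna_expr,
                           rpkm_min = config$rpkm_min,
                           cpm_min = config$cpm_min)
  rank_candidates(kept, gene_expr, class_floor = class_floor, config = config)
}
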