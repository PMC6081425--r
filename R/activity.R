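# miRNA activity statistics: target-set repression shifts, ECDFs,
# per-miRNA summaries, differential miRNA expression, the serum DEG
# filter, cluster enrichment, and the binned flow-cytometry sensor
# estimator.

.reg_contrast <- function(reg, contrast) {
  stopifnot(is.data.frame(reg), "gene" %in% names(reg))
  if (!contrast %in% names(reg)) stop("no such contrast: ", contrast)
  stats::setNames(reg[[contrast]], reg$gene)
}

#' Median repression shift of a target set
#'
#' Difference between the median log2 fold-change of a target set and that
#' of the non-target background, with a two-sided Wilcoxon rank-sum test.
#' Negative shifts mean the set is more repressed than the background. No
#' multiple-testing correction is applied (raw Wilcoxon p-values); apply
#' [stats::p.adjust()] across sets if desired.
#'
#' @param reg Regulation table: data.frame with a `gene` column and one
#'   numeric log2 fold-change column per contrast.
#' @param genes Character vector: the target set.
#' @param contrast Name of the log2 fold-change column to use.
#' @return List with `delta_median`, `p_value`, `n_set`, `n_background`.
#' @export
target_set_shift <- function(reg, genes, contrast) {
  lfc <- .reg_contrast(reg, contrast)
  in_set <- names(lfc) %in% genes
  if (!any(in_set)) stop("empty target set after intersecting with the table")
  if (all(in_set)) stop("empty background: the set covers every gene")
  wt <- stats::wilcox.test(lfc[in_set], lfc[!in_set], exact = FALSE)
  list(delta_median = stats::median(lfc[in_set]) -
         stats::median(lfc[!in_set]),
       p_value = wt$p.value,
       n_set = sum(in_set), n_background = sum(!in_set))
}

#' Empirical CDF points of log2 fold-changes per target set
#'
#' One ECDF per supplied set, plus the complement of their union
#' (`"Other"`), in long format ready for step plotting.
#'
#' @inheritParams target_set_shift
#' @param sets Named list of gene-identifier vectors.
#' @param include_other Add the non-target complement curve.
#' @return data.frame with columns `set`, `log2fc`, `ecdf`.
#' @export
cdf_table <- function(reg, sets, contrast, include_other = TRUE) {
  lfc <- .reg_contrast(reg, contrast)
  if (include_other) {
    sets <- c(sets, list(Other = setdiff(names(lfc), unlist(sets))))
  }
  out <- lapply(names(sets), function(nm) {
    v <- sort(lfc[names(lfc) %in% sets[[nm]]])
    if (!length(v)) return(NULL)
    data.frame(set = nm, log2fc = v, ecdf = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median target regulation per miRNA
#'
#' For each miRNA with at least `min_targets` targets present in the
#' regulation table (e.g. chimera-derived target sets filtered to
#' expressed genes), the median log2 fold-change of its targets.
#'
#' @inheritParams target_set_shift
#' @param target_sets Named list: miRNA -> character vector of target genes.
#' @param min_targets Minimum expressed targets for a miRNA to be reported.
#' @return data.frame with columns `mirna`, `n_targets`, `median_log2fc`;
#'   miRNAs below the threshold are omitted.
#' @export
per_mirna_summary <- function(reg, target_sets, contrast, min_targets = 50L) {
  lfc <- .reg_contrast(reg, contrast)
  rows <- lapply(names(target_sets), function(mi) {
    v <- lfc[names(lfc) %in% target_sets[[mi]]]
    if (length(v) < min_targets) return(NULL)
    data.frame(mirna = mi, n_targets = length(v),
               median_log2fc = stats::median(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mirna = character(0), n_targets = integer(0),
                      median_log2fc = numeric(0)))
  }
  rownames(out) <- NULL
  out
}

#' Differential miRNA expression between two groups
#'
#' Per-miRNA mean log2(CPM + pseudocount) difference (KO minus WT) and
#' two-sided Welch's t-test.
#'
#' @param cpm_wt,cpm_ko CPM matrices (miRNAs x replicates) with matching
#'   row names; at least 2 replicates per group.
#' @param pseudocount Added to CPM before the log transform.
#' @return data.frame with columns `mirna`, `log2fc`, `p_value`.
#' @export
mirna_differential <- function(cpm_wt, cpm_ko, pseudocount = 1) {
  if (ncol(cpm_wt) < 2 || ncol(cpm_ko) < 2) {
    stop("need at least 2 replicates per group")
  }
  if (!identical(rownames(cpm_wt), rownames(cpm_ko))) {
    stop("row names of the two matrices must match")
  }
  lw <- log2(cpm_wt + pseudocount)
  lk <- log2(cpm_ko + pseudocount)
  res <- t(vapply(seq_len(nrow(lw)), function(i) {
    a <- lk[i, ]
    b <- lw[i, ]
    d <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(c(d, if (d == 0) 1 else NA_real_))
    }
    c(d, stats::t.test(a, b)$p.value)
  }, numeric(2)))
  data.frame(mirna = rownames(cpm_wt), log2fc = res[, 1], p_value = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serum-stimulation differentially expressed genes
#'
#' A gene is called differentially expressed when it is expressed (maximum
#' RPKM above `rpkm_min` across the three series) and shows
#' |log2 FC| > `lfc_min`, with concordant sign, in BOTH mutant clones at
#' one or more common time points.
#'
#' @param expr_wt,expr_ko1,expr_ko2 RPKM matrices (genes x time points)
#'   with matching dimnames.
#' @param rpkm_min Expression threshold (strict).
#' @param lfc_min Fold-change threshold (strict, on |log2 FC|).
#' @param pseudocount Added to RPKM before the log ratio.
#' @return Character vector of gene identifiers.
#' @export
serum_deg_filter <- function(expr_wt, expr_ko1, expr_ko2,
                             rpkm_min = 1, lfc_min = 1, pseudocount = 0.1) {
  stopifnot(identical(dimnames(expr_wt), dimnames(expr_ko1)),
            identical(dimnames(expr_wt), dimnames(expr_ko2)))
  lfc1 <- log2((expr_ko1 + pseudocount) / (expr_wt + pseudocount))
  lfc2 <- log2((expr_ko2 + pseudocount) / (expr_wt + pseudocount))
  expressed <- pmax(apply(expr_wt, 1, max), apply(expr_ko1, 1, max),
                    apply(expr_ko2, 1, max)) > rpkm_min
  concordant <- abs(lfc1) > lfc_min & abs(lfc2) > lfc_min &
    sign(lfc1) == sign(lfc2)
  rownames(expr_wt)[expressed & apply(concordant, 1, any)]
}

#' Target enrichment per cluster
#'
#' For each cluster of a DEG partition, a 2x2 contingency test
#' (in-cluster x in-target-set) by Pearson's chi-square (no continuity
#' correction).
#'
#' @param cluster_assignments Named vector: gene -> cluster label; the
#'   clusters partition the DEG list.
#' @param target_set Character vector of target genes.
#' @param universe Gene universe for the contingency tables (defaults to
#'   the clustered genes).
#' @return data.frame with one row per cluster: `cluster`, `n`,
#'   `n_targets`, `expected`, `enrichment` (observed/expected), `chi2`,
#'   `p_value`. Cells with a zero expected count are flagged by `NA`
#'   statistics.
#' @export
cluster_enrichment <- function(cluster_assignments, target_set,
                               universe = names(cluster_assignments)) {
  stopifnot(!is.null(names(cluster_assignments)))
  in_set <- universe %in% target_set
  rows <- lapply(sort(unique(cluster_assignments)), function(cl) {
    in_cl <- universe %in% names(cluster_assignments)[cluster_assignments == cl]
    tab <- table(factor(in_cl, c(TRUE, FALSE)), factor(in_set, c(TRUE, FALSE)))
    expected <- sum(in_cl) * sum(in_set) / length(universe)
    if (any(outer(rowSums(tab), colSums(tab)) == 0)) {
      chi2 <- NA_real_
      p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic)
      p <- ct$p.value
    }
    data.frame(cluster = cl, n = sum(in_cl), n_targets = sum(in_cl & in_set),
               expected = expected,
               enrichment = if (expected > 0) sum(in_cl & in_set) / expected
                            else NA_real_,
               chi2 = chi2, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned flow-cytometry estimate of sensor repression
#'
#' Estimates the fold-repression of a miRNA sensor against a scrambled
#' control from two-channel flow data. Both channels are log-transformed;
#' each population is sorted by its co-reporter (dNGFR) level and split
#' into `n_bins` equal-count bins; the per-bin mean log sensor (dGFP)
#' levels of the two populations are compared at matched bin rank, so that
#' fold = control / sensor and repression gives folds above 1. The summary
#' is the arithmetic mean of the per-bin folds.
#'
#' @param sensor,control data.frames with numeric columns `dGFP` and
#'   `dNGFR` (positive intensities), one row per cell.
#' @param n_bins Number of co-reporter bins.
#' @param bin_size Expected cells per bin; when a population holds fewer
#'   than `n_bins * bin_size` events the bin size is reduced to
#'   `floor(n / n_bins)` (with a message).
#' @return List with `mean_fold` and `per_bin` (data.frame: `bin`,
#'   `dngfr_sensor`, `dngfr_control` geometric means, `fold`).
#' @export
sensor_repression <- function(sensor, control, n_bins = 100L,
                              bin_size = 1000L) {
  for (pop in list(sensor, control)) {
    stopifnot(all(c("dGFP", "dNGFR") %in% names(pop)))
    if (!nrow(pop)) stop("empty population")
  }
  bin_stats <- function(pop) {
    n <- nrow(pop)
    if (n < n_bins * bin_size) {
      message("population of ", n, " events: bin size reduced to ",
              n %/% n_bins)
    }
    if (n < n_bins) stop("fewer events than bins")
    ord <- order(pop$dNGFR)
    bins <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
    data.frame(
      bin = seq_len(n_bins),
      mean_log_gfp = tapply(log(pop$dGFP[ord]), bins, mean),
      mean_log_ngfr = tapply(log(pop$dNGFR[ord]), bins, mean))
  }
  bs <- bin_stats(sensor)
  bc <- bin_stats(control)
  fold <- exp(bc$mean_log_gfp - bs$mean_log_gfp)
  list(mean_fold = mean(fold),
       per_bin = data.frame(bin = bs$bin,
                            dngfr_sensor = exp(bs$mean_log_ngfr),
                            dngfr_control = exp(bc$mean_log_ngfr),
                            fold = fold))
}
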