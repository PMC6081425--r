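# Absolute quantification: qPCR standard curves, copies per cell,
# target-per-miRNA ratios, and half-life arithmetic.

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of quantification cycle (Cq) against
#' log10(known copies), as obtained from a titration of synthetic
#' oligonucleotide or plasmid standards. The amplification efficiency is
#' derived from the slope as `10^(-1/slope) - 1` (a perfect doubling per
#' cycle gives slope -3.3219 and efficiency 1).
#'
#' @param points data.frame with columns `known_copies` (> 0) and
#'   `measured_Cq`; at least 3 points, ideally spanning two or more orders
#'   of magnitude.
#' @return Object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `r2`, `efficiency`, `copies_range`, and the `lm` fit.
#' @export
fit_standard_curve <- function(points) {
  stopifnot(all(c("known_copies", "measured_Cq") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 standard points")
  if (any(points$known_copies <= 0)) stop("known copies must be positive")
  span <- log10(max(points$known_copies) / min(points$known_copies))
  if (span < 2) {
    warning("standards span fewer than 2 orders of magnitude")
  }
  fit <- stats::lm(measured_Cq ~ log10(known_copies), data = points)
  slope <- unname(stats::coef(fit)[2])
  curve <- list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r2 = suppressWarnings(summary(fit)$r.squared),  # perfect fits warn
    efficiency = 10^(-1 / slope) - 1,
    copies_range = range(points$known_copies),
    fit = fit)
  class(curve) <- "standard_curve"
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n  r2 = %.4f, efficiency = %.1f%%, calibrated %g-%g copies\n",
    x$intercept, x$slope, x$r2, 100 * x$efficiency,
    x$copies_range[1], x$copies_range[2]))
  invisible(x)
}

#' Copies per cell from a measured Cq
#'
#' Inverts the standard curve (`copies = 10^((Cq - intercept) / slope)`)
#' and scales by the number of cell equivalents in the reaction. Cq values
#' outside the calibrated range are flagged with a warning and in the
#' `extrapolated` attribute.
#'
#' @param measured_Cq Numeric vector of Cq values.
#' @param curve A `"standard_curve"` object.
#' @param cells_per_rxn Cell equivalents per reaction (> 0).
#' @return Numeric vector of copies per cell (attribute `extrapolated`
#'   marks values outside the calibrated range).
#' @export
copies_per_cell <- function(measured_Cq, curve, cells_per_rxn = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (cells_per_rxn <= 0) stop("cells_per_rxn must be positive")
  copies <- 10^((measured_Cq - curve$intercept) / curve$slope)
  out_of_range <- copies < curve$copies_range[1] |
    copies > curve$copies_range[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " Cq value(s) outside the calibrated range")
  }
  structure(copies / cells_per_rxn, extrapolated = out_of_range)
}

#' Target-per-miRNA (TPM) ratio
#'
#' The stoichiometry of a putative TDMD interaction: target copies per cell
#' divided by miRNA copies per cell, in the same condition. TDMD operates
#' already at TPM around 1 and strengthens sharply above 10.
#'
#' @param target_cpc Target copies per cell (>= 0).
#' @param mirna_cpc miRNA copies per cell (> 0). Supply a summed family
#'   subset for a pooled denominator.
#' @return The TPM ratio (numeric).
#' @export
tpm_ratio <- function(target_cpc, mirna_cpc) {
  if (any(mirna_cpc <= 0)) stop("miRNA copies per cell must be positive")
  if (any(target_cpc < 0)) stop("target copies per cell must be non-negative")
  target_cpc / mirna_cpc
}

#' Half-life implied by a log2 fold-change
#'
#' Under pure exponential loss with negligible synthesis, a level change of
#' `log2fc` (< 0) over `elapsed_h` hours implies a half-life of
#' `-elapsed_h / log2fc` hours: a log2 FC of -1 over 4 h is exactly a 4-h
#' half-life.
#'
#' @param log2fc Negative log2 fold-change(s).
#' @param elapsed_h Elapsed time in hours (> 0).
#' @return Half-life in hours (vectorised over `log2fc`).
#' @export
half_life_from_log2fc <- function(log2fc, elapsed_h) {
  if (any(elapsed_h <= 0)) stop("elapsed time must be positive")
  if (any(log2fc >= 0)) stop("log2 fold-change must be negative (no decay)")
  -elapsed_h / log2fc
}
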