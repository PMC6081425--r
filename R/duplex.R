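# Duplex anatomy of miRNA:MRE interactions.
#
# Conventions used throughout this file:
#  * miRNA given 5'->3' (positions m1..mL, 1-based); target site given
#    5'->3' (positions s1..sn). In the duplex the strands are antiparallel,
#    so with the seed helix anchored at the site 3' end, miRNA position i
#    pairs with target position n + 1 - i.
#  * The seed is miRNA positions 2-8; target position t1 (= sn) sits
#    opposite m1 and is never paired -- the A1 rule asks for an adenosine
#    there regardless of the miRNA position-1 identity.
#  * Coordinates reported by scan_utr are 0-based, half-open.

.base_pairs <- function(a, b, wobble = FALSE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (wobble) wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  wc
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Classify the seed match of a target site
#'
#' Returns the highest class in the canonical hierarchy
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer whose pattern matches at the 3' end of
#' the site. The A1 rule requires an A at target position 1 (the position
#' opposite miRNA position 1) for the 8mer and 7mer-A1 classes, regardless
#' of the miRNA position-1 identity.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA; length >= 8).
#' @param site Target-site sequence, 5'->3' (>= 6 nt).
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"none"`.
#' @export
classify_seed <- function(mirna, site) {
  m <- norm_seq(mirna, "DNA")
  s <- norm_seq(site, "DNA")
  if (nchar(m) < 8) stop("miRNA shorter than 8 nt")
  if (nchar(s) < 6) stop("site shorter than 6 nt")
  n <- nchar(s)
  seed7 <- rev_comp(substr(m, 2, 8))   # matches target s[n-7..n-1]
  seed6 <- rev_comp(substr(m, 2, 7))   # matches target s[n-6..n-1]
  t1A <- substr(s, n, n) == "A"
  m8_match <- n >= 8 && substr(s, n - 7, n - 1) == seed7
  hex_match <- n >= 7 && substr(s, n - 6, n - 1) == seed6
  if (m8_match && t1A) return("8mer")
  if (m8_match) return("7mer-m8")
  if (hex_match && t1A) return("7mer-A1")
  if (hex_match) return("6mer")
  # degenerate 6-nt site: the hexamer alone, with no t1 position supplied
  if (n == 6 && s == seed6) return("6mer")
  "none"
}

#' Anatomy of the 3' supplementary helix of a miRNA:site duplex
#'
#' Anchors the seed helix at the site 3' end, then searches every placement
#' of a second ("supplementary") helix pairing the remaining target 5'
#' segment with the miRNA 3' region, and keeps the placement maximising the
#' number of contiguous paired bases. Ties are broken by (1) longer helix,
#' (2) smaller target-strand bulge, (3) helix closest to the seed (smaller
#' miRNA-strand bulge). Pairing is strict Watson-Crick by default; G:U
#' wobbles can be counted via `allow_wobble`.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site Target-site sequence 5'->3'.
#' @param seed_class Optional precomputed seed class; computed from the
#'   sequences when `NULL`. Must not be `"none"`.
#' @param allow_wobble Count G:U pairs in the supplementary helix.
#' @return An object of class `"duplex_anatomy"`: a list with elements
#'   `seed_class`, `three_prime_len` (nt of contiguous supplementary
#'   pairing), `bulge_target_len` and `bulge_mirna_len` (unpaired
#'   nucleotides between the two helices on each strand; `NA` when no
#'   supplementary pairing exists), `mismatch_count_3p` (miRNA 3'-region
#'   nucleotides left out of the helix), and the helix placement.
#' @export
align_supplementary <- function(mirna, site, seed_class = NULL,
                                allow_wobble = FALSE) {
  m_seq <- norm_seq(mirna, "DNA")
  s_seq <- norm_seq(site, "DNA")
  if (is.null(seed_class)) seed_class <- classify_seed(m_seq, s_seq)
  if (identical(seed_class, "none")) {
    stop("no seed match: supplementary alignment undefined")
  }
  m <- .chars(m_seq)
  s <- .chars(s_seq)
  L <- length(m)
  n <- length(s)
  # seed helix spans m2..m8 for 8mer/7mer-m8, m2..m7 for the weaker classes
  seed_end_m <- if (seed_class %in% c("8mer", "7mer-m8")) 8L else 7L
  rem_m <- if (L > seed_end_m) m[(seed_end_m + 1):L] else character(0)
  rem_n <- n - seed_end_m               # target nts 5' of the seed helix
                                        # (seed helix ends at s[n-seed_end_m+1])
  rem_s <- if (rem_n > 0) s[seq_len(rem_n)] else character(0)

  best <- list(h = 0L, j = NA_integer_, k = NA_integer_)
  if (length(rem_m) && length(rem_s)) {
    for (j in seq_along(rem_m)) {       # miRNA-side helix start (3' region)
      for (k in rev(seq_along(rem_s))) {  # target-side helix 3' end
        if (!.base_pairs(rem_m[j], rem_s[k], allow_wobble)) next
        # only score maximal helices: skip if extendable towards the seed
        if (j > 1 && k < length(rem_s) &&
            .base_pairs(rem_m[j - 1], rem_s[k + 1], allow_wobble)) next
        h <- 1L
        while (j + h <= length(rem_m) && k - h >= 1 &&
               .base_pairs(rem_m[j + h], rem_s[k - h], allow_wobble)) {
          h <- h + 1L
        }
        tb <- length(rem_s) - k         # target bulge
        mb <- j - 1L                    # miRNA bulge
        if (h > best$h ||
            (h == best$h && !is.na(best$k) &&
             (tb < length(rem_s) - best$k ||
              (tb == length(rem_s) - best$k && mb < best$j - 1L)))) {
          best <- list(h = h, j = j, k = k)
        }
      }
    }
  }
  out <- list(
    seed_class = seed_class,
    three_prime_len = best$h,
    bulge_target_len = if (best$h > 0) length(rem_s) - best$k else NA_integer_,
    bulge_mirna_len = if (best$h > 0) best$j - 1L else NA_integer_,
    mismatch_count_3p = length(rem_m) - best$h,
    helix_mirna_start = if (best$h > 0) seed_end_m + best$j else NA_integer_,
    helix_target_end = if (best$h > 0) best$k else NA_integer_,
    mirna = m_seq, site = s_seq, allow_wobble = allow_wobble
  )
  class(out) <- "duplex_anatomy"
  out
}

#' @export
print.duplex_anatomy <- function(x, ...) {
  cat("miRNA:site duplex anatomy\n",
      "  seed class:        ", x$seed_class, "\n",
      "  3' supplementary:  ", x$three_prime_len, " nt contiguous\n",
      "  central bulge:     ", x$bulge_target_len, " nt (target) / ",
      x$bulge_mirna_len, " nt (miRNA)\n",
      "  unpaired 3' nts:   ", x$mismatch_count_3p, "\n", sep = "")
  invisible(x)
}

#' TDMD eligibility of a duplex
#'
#' A duplex is eligible for target-directed degradation when it combines a
#' high-affinity seed (8mer or 7mer-m8), at least `min_3p` nucleotides of
#' contiguous 3' supplementary pairing, and a target-strand central bulge
#' within `bulge_range`.
#'
#' @param anatomy A `"duplex_anatomy"` object.
#' @param config A [tdmd_config()]; the `"strict"` preset narrows the bulge
#'   window to 3-4 nt.
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
tdmd_eligible <- function(anatomy, config = tdmd_config()) {
  stopifnot(inherits(anatomy, "duplex_anatomy"))
  reasons <- character(0)
  if (!anatomy$seed_class %in% c("8mer", "7mer-m8")) {
    reasons <- c(reasons, "seed class below 7mer-m8")
  }
  if (anatomy$three_prime_len < config$min_3p) {
    reasons <- c(reasons, "3' pairing below minimum")
  }
  b <- anatomy$bulge_target_len
  if (is.na(b) || b < config$bulge_range[1] || b > config$bulge_range[2]) {
    reasons <- c(reasons, "central bulge outside allowed range")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Scan a UTR for miRNA target sites
#'
#' Applies [classify_seed()] at every position of the (sense-strand) UTR
#' and computes the duplex anatomy of every seed-matched site. Sites whose
#' seed-match windows overlap are resolved by keeping the higher seed class
#' (5'-most site on ties).
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param utr UTR sequence 5'->3' (a character string, or a one-row
#'   data.frame as returned by [read_fasta()]).
#' @param allow_wobble Count G:U pairs in the supplementary helix.
#' @param max_bulge Upstream slack (nt) added to the site window so the
#'   supplementary helix can sit up to `max_bulge` nucleotides away from
#'   the seed helix.
#' @return data.frame with one row per retained site: 0-based half-open
#'   `start`/`end` of the site window, `seed_class`, `three_prime_len`,
#'   `bulge_target_len`, `bulge_mirna_len`, `site_seq`; ordered 5'->3'.
#' @export
scan_utr <- function(mirna, utr, allow_wobble = FALSE, max_bulge = 7L) {
  if (is.data.frame(utr)) utr <- utr$seq[1]
  m_seq <- norm_seq(mirna, "DNA")
  u <- norm_seq(utr, "DNA")
  n <- nchar(u)
  empty <- data.frame(start = integer(0), end = integer(0),
                      seed_class = character(0), three_prime_len = integer(0),
                      bulge_target_len = integer(0),
                      bulge_mirna_len = integer(0),
                      site_seq = character(0), stringsAsFactors = FALSE)
  if (n < 7) return(empty)
  win <- nchar(m_seq) + max_bulge
  hits <- list()
  for (p in 7:n) {                       # p = 1-based position of t1
    site <- substr(u, max(1L, p - win + 1L), p)
    cls <- classify_seed(m_seq, site)
    if (cls == "none") next
    an <- align_supplementary(m_seq, site, seed_class = cls,
                              allow_wobble = allow_wobble)
    hits[[length(hits) + 1L]] <- data.frame(
      start = max(1L, p - win + 1L) - 1L, end = p,
      seed_class = cls, three_prime_len = an$three_prime_len,
      bulge_target_len = an$bulge_target_len,
      bulge_mirna_len = an$bulge_mirna_len,
      site_seq = site, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  # overlap resolution on the 8-nt seed-match window, higher class wins
  rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)
  res <- res[order(-rank[res$seed_class], res$end), , drop = FALSE]
  kept <- logical(0)
  kept_iv <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(res))) {
    seed_start <- res$end[i] - 8L
    overlaps <- nrow(kept_iv) > 0 &&
      any(seed_start < kept_iv[, 2] & res$end[i] > kept_iv[, 1])
    kept[i] <- !overlaps
    if (!overlaps) kept_iv <- rbind(kept_iv, c(seed_start, res$end[i]))
  }
  res <- res[kept, , drop = FALSE]
  res <- res[order(res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
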