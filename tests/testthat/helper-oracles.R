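# Independent oracles and small generators used across the suite.

# Brute-force oracle for the 3' supplementary alignment: enumerates every
# seed-anchored two-helix decomposition (j = miRNA helix start offset in
# the 3' region, k = 3'-most paired target position, h = helix length) and
# picks the best by (longer helix, smaller target bulge, smaller miRNA
# bulge). Kept deliberately naive and separate from the implementation.
oracle_supplementary <- function(mirna, site, seed_class,
                                 allow_wobble = FALSE) {
  pair_ok <- function(a, b) {
    ok <- paste0(a, b) %in% c("AT", "TA", "GC", "CG")
    if (allow_wobble) ok <- ok || paste0(a, b) %in% c("GT", "TG")
    ok
  }
  m <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("U", "T", toupper(site)), "")[[1]]
  seed_end <- if (seed_class %in% c("8mer", "7mer-m8")) 8L else 7L
  rem_m <- if (length(m) > seed_end) m[(seed_end + 1):length(m)] else character(0)
  rem_s <- if (length(s) > seed_end) s[1:(length(s) - seed_end)] else character(0)
  cands <- list()
  for (j in seq_along(rem_m)) {
    for (k in seq_along(rem_s)) {
      for (h in 1:min(length(rem_m) - j + 1L, k)) {
        all_pair <- all(vapply(0:(h - 1), function(i) {
          pair_ok(rem_m[j + i], rem_s[k - i])
        }, logical(1)))
        if (all_pair) {
          cands[[length(cands) + 1L]] <-
            c(h = h, tb = length(rem_s) - k, mb = j - 1L)
        }
      }
    }
  }
  if (!length(cands)) {
    return(list(three_prime_len = 0L, bulge_target_len = NA_integer_,
                bulge_mirna_len = NA_integer_))
  }
  tab <- do.call(rbind, cands)
  tab <- tab[order(-tab[, "h"], tab[, "tb"], tab[, "mb"]), , drop = FALSE]
  list(three_prime_len = unname(tab[1, "h"]),
       bulge_target_len = unname(tab[1, "tb"]),
       bulge_mirna_len = unname(tab[1, "mb"]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random miRNA plus a site guaranteed to carry a seed match
random_seeded_pair <- function() {
  m <- random_dna(sample(18:25, 1))
  seed7 <- rev_comp(substr(m, 2, 8))
  t1 <- sample(c("A", "C", "G", "T"), 1)
  upstream <- random_dna(sample(2:22, 1))
  list(mirna = m, site = paste0(upstream, seed7, t1))
}

# small reference panel for isomiR tests: distinct canonicals, G/C-leading
# downstream contexts so templated extensions never mimic A/U tails
toy_refs <- function() {
  mirna_ref_context(
    name = c("mir-t1", "mir-t2", "mir-t3"),
    canonical_seq = c("TGAGGTAGTAGGTTGTATAGTT",
                      "TAGCTTATCAGACTGATGTTGA",
                      "TGGAGTGTGACAATGGTGTTTG"),
    downstream_genomic = c("GCGGCA", "CGCAGG", "GGCACG"))
}

mir30_fixture <- function() {
  fam <- read_fasta(tdmd_extdata("mir30_family_mature.fa"))
  stats::setNames(fam$seq, fam$id)
}

serpine1_mre <- function() {
  utr <- read_fasta(tdmd_extdata("serpine1_mcherry_3utr.fa"))$seq
  seg <- regmatches(utr, regexpr("ACGCGT.*?GAGCTC", utr))
  substr(seg, 7, nchar(seg) - 6)
}
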