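# isomiR classification from small-RNA reads: canonical, templated 3'
# extensions, non-templated tails (A-, U-, mixed forms) and trimmed forms.

.isomir_classes <- c("CANONICAL", "TEMPLATED_3P", "NT_A", "NT_U",
                     "NT_MIXED", "TRIM", "OTHER")

#' Reference context for a mature miRNA
#'
#' Couples a canonical mature sequence with the genomic sequence
#' immediately 3' of its end, which is what separates templated extensions
#' from genuinely non-templated tails.
#'
#' @param name miRNA name(s).
#' @param canonical_seq Mature sequence(s), 5'->3' (RNA or DNA).
#' @param downstream_genomic At least 6 nt of genomic sequence 3' of the
#'   canonical end, per miRNA.
#' @return data.frame with columns `name`, `canonical_seq`,
#'   `downstream_genomic` (DNA alphabet).
#' @export
mirna_ref_context <- function(name, canonical_seq, downstream_genomic) {
  canonical_seq <- norm_seq(canonical_seq, "DNA")
  downstream_genomic <- norm_seq(downstream_genomic, "DNA")
  if (any(nchar(downstream_genomic) < 6)) {
    stop("downstream genomic context must be at least 6 nt")
  }
  if (anyDuplicated(name)) stop("duplicate miRNA name")
  data.frame(name = name, canonical_seq = canonical_seq,
             downstream_genomic = downstream_genomic,
             stringsAsFactors = FALSE)
}

#' Classify one read against its reference miRNA
#'
#' The read is assumed to originate from the given reference (see
#' [assign_reads()]). Classes: `CANONICAL` (identical to the mature
#' sequence); `TRIM` (canonical shortened at the 3' end by at most
#' `max_trim` nt); `TEMPLATED_3P` (3' extension fully matching the
#' downstream genomic sequence); `NT_A` / `NT_U` (extension, after
#' stripping its longest templated prefix, composed entirely of A or of U);
#' `NT_MIXED` (non-templated extension containing both); `OTHER`
#' (unassignable within the windows, including 5' offsets).
#'
#' @param read_seq Read sequence (adapter-trimmed).
#' @param canonical_seq,downstream_genomic Reference context (see
#'   [mirna_ref_context()]).
#' @param max_trim,max_tail Largest 3' shortening / non-templated tail
#'   considered (nt).
#' @return One of `CANONICAL`, `TEMPLATED_3P`, `NT_A`, `NT_U`, `NT_MIXED`,
#'   `TRIM`, `OTHER`.
#' @export
classify_read <- function(read_seq, canonical_seq, downstream_genomic,
                          max_trim = 4L, max_tail = 4L) {
  r <- norm_seq(read_seq, "DNA")
  can <- norm_seq(canonical_seq, "DNA")
  down <- norm_seq(downstream_genomic, "DNA")
  L <- nchar(can)
  if (r == can) return("CANONICAL")
  if (nchar(r) < L) {
    if (nchar(r) >= L - max_trim && r == substr(can, 1, nchar(r))) {
      return("TRIM")
    }
    return("OTHER")
  }
  if (substr(r, 1, L) != can) return("OTHER")   # 5' offset or internal edit
  ext <- substr(r, L + 1, nchar(r))
  # longest templated prefix of the extension
  tp <- 0L
  while (tp < nchar(ext) && tp < nchar(down) &&
         substr(ext, tp + 1, tp + 1) == substr(down, tp + 1, tp + 1)) {
    tp <- tp + 1L
  }
  tail <- substr(ext, tp + 1, nchar(ext))
  if (!nzchar(tail)) {
    return(if (nchar(ext) <= max_tail) "TEMPLATED_3P" else "OTHER")
  }
  if (nchar(tail) > max_tail) return("OTHER")
  if (grepl("^A+$", tail)) return("NT_A")
  if (grepl("^T+$", tail)) return("NT_U")
  "NT_MIXED"
}

#' Assign reads to reference miRNAs by exact prefix
#'
#' Candidate references are found by an exact-prefix dictionary over the
#' trim window (a read must start with the reference's canonical sequence
#' shortened by at most `max_trim` nt). When prefixes of related miRNAs
#' nest (as within a miRNA family), a candidate only keeps the read if the
#' read is explainable under it, i.e. [classify_read()] does not return
#' `OTHER`. Reads explainable under two or more references are ambiguous
#' and set aside (logged); reads matching none go to the unassigned pool.
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `seq` column (as from [read_fastq()]).
#' @param refs Reference table from [mirna_ref_context()].
#' @param max_trim,max_tail Classification windows, as in [classify_read()].
#' @return List with `groups` (named list of read-sequence vectors, one per
#'   reference), `ambiguous` and `unassigned` (character vectors).
#' @export
assign_reads <- function(reads, refs, max_trim = 4L, max_tail = 4L) {
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- if (length(reads)) norm_seq(reads, "DNA") else character(0)
  keys <- substr(refs$canonical_seq, 1, nchar(refs$canonical_seq) - max_trim)
  hit <- vapply(keys, function(k) startsWith(reads, k),
                logical(length(reads)))
  hit <- matrix(hit, nrow = length(reads), ncol = length(keys))
  # reads hitting several nested prefixes are resolved by explainability:
  # a candidate keeps the read only if classify_read() is not OTHER
  multi <- which(rowSums(hit) > 1L)
  for (i in multi) {
    for (j in which(hit[i, ])) {
      cls <- classify_read(reads[i], refs$canonical_seq[j],
                           refs$downstream_genomic[j],
                           max_trim = max_trim, max_tail = max_tail)
      hit[i, j] <- cls != "OTHER"
    }
  }
  n_hits <- rowSums(hit)
  assigned_to <- max.col(hit, ties.method = "first")
  assigned_to[n_hits != 1L] <- NA_integer_
  groups <- lapply(seq_along(keys), function(j) {
    reads[!is.na(assigned_to) & assigned_to == j]
  })
  names(groups) <- refs$name
  ambiguous <- reads[n_hits > 1L]
  if (length(ambiguous)) {
    message(length(ambiguous), " ambiguous read(s) set aside")
  }
  list(groups = groups, ambiguous = ambiguous,
       unassigned = reads[n_hits == 0L])
}

#' isomiR profile of assigned read groups
#'
#' Counts and percentages per isomiR class for each miRNA, plus the derived
#' summary fractions: `pct_3NT` (all non-templated tails: A + U + mixed),
#' `pct_TRIM`, `pct_A_forms`, `pct_U_forms`. Percentages are over the
#' miRNA's total assigned reads.
#'
#' @param groups Output of [assign_reads()] (or its `groups` element).
#' @param refs Reference table from [mirna_ref_context()].
#' @param max_trim,max_tail Classification windows, as in [classify_read()].
#' @return data.frame with one row per profiled miRNA: `n_reads`, one count
#'   and one percentage column per class, and the summary fractions.
#'   miRNAs with zero assigned reads are omitted (with a message).
#' @export
isomir_profile <- function(groups, refs, max_trim = 4L, max_tail = 4L) {
  if (is.list(groups) && "groups" %in% names(groups)) groups <- groups$groups
  rows <- list()
  for (nm in names(groups)) {
    reads <- groups[[nm]]
    if (!length(reads)) {
      message("no reads assigned to ", nm, "; profile omitted")
      next
    }
    ref <- refs[refs$name == nm, ]
    cls <- vapply(reads, classify_read, character(1),
                  canonical_seq = ref$canonical_seq,
                  downstream_genomic = ref$downstream_genomic,
                  max_trim = max_trim, max_tail = max_tail,
                  USE.NAMES = FALSE)
    counts <- table(factor(cls, levels = .isomir_classes))
    n <- length(reads)
    pct <- 100 * as.numeric(counts) / n
    names(pct) <- paste0("pct_", names(counts))
    row <- data.frame(mirna = nm, n_reads = n, t(as.numeric(counts)),
                      t(pct), stringsAsFactors = FALSE)
    names(row)[3:(2 + length(counts))] <- paste0("n_", names(counts))
    rows[[nm]] <- row
  }
  if (!length(rows)) {
    stop("no non-empty read groups to profile")
  }
  out <- do.call(rbind, rows)
  out$pct_3NT <- out$pct_NT_A + out$pct_NT_U + out$pct_NT_MIXED
  out$pct_TRIM_forms <- out$pct_TRIM
  out$pct_A_forms <- out$pct_NT_A
  out$pct_U_forms <- out$pct_NT_U
  rownames(out) <- NULL
  out
}

#' Library-size (and amplification-corrected) CPM normalisation
#'
#' Counts-per-million against the library size, optionally divided by a
#' per-condition amplification correction factor (e.g. for serum-induced
#' global RNA amplification; factors are supplied externally).
#'
#' @param counts Count matrix (miRNAs x conditions).
#' @param library_sizes Positive library sizes, one per condition.
#' @param amplification_factors Positive correction factors, length 1 or
#'   one per condition (default 1: no correction).
#' @return CPM matrix of the same shape as `counts`.
#' @export
normalize_cpm <- function(counts, library_sizes, amplification_factors = 1) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(amplification_factors <= 0)) {
    stop("amplification factors must be positive")
  }
  if (length(library_sizes) != ncol(counts)) {
    stop("need one library size per condition")
  }
  factors <- rep_len(amplification_factors, ncol(counts))
  cpm <- sweep(counts, 2, library_sizes, "/") * 1e6
  sweep(cpm, 2, factors, "/")
}
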