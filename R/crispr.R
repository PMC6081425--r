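# SpCas9 protospacer matching, cut-site arithmetic and deletion intervals.
#
# Coordinates are 0-based half-open on the supplied (plus) strand; a cut
# site is the integer coordinate of the bond 5' of that position, i.e. a
# blunt cut between positions cut-1 and cut.

#' Locate a protospacer in a sequence
#'
#' Strips lowercase cloning characters from the printed oligo (the
#' `caccg`/`aaac` U6 cloning overhangs, including the extra 5' g required
#' for U6 transcription), then searches both strands for exact 20-nt
#' matches and checks for an NGG PAM immediately 3' of the protospacer on
#' the matched strand.
#'
#' @param guide_seq Guide oligo; lowercase characters are treated as
#'   cloning artefacts and removed (with a message), leaving a 20-nt
#'   protospacer.
#' @param target Target sequence (character string or one-row data.frame
#'   from [read_fasta()]).
#' @param name Guide name used in the output.
#' @return data.frame of class `"guide_match"`, one row per match:
#'   `guide`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open,
#'   plus-strand coordinates of the protospacer), `pam`, `pam_valid`.
#' @export
find_protospacer <- function(guide_seq, target, name = "guide") {
  if (is.data.frame(target)) target <- target$seq[1]
  stripped <- gsub("[a-z]", "", guide_seq)
  if (nchar(stripped) != nchar(guide_seq)) {
    message(name, ": removed ", nchar(guide_seq) - nchar(stripped),
            " lowercase cloning character(s)")
  }
  guide <- norm_seq(stripped, "DNA")
  if (nchar(guide) != 20) {
    stop("protospacer must be 20 nt after stripping cloning overhangs, got ",
         nchar(guide))
  }
  seq <- norm_seq(target, "DNA")
  n <- nchar(seq)
  one_strand <- function(query, strand) {
    pos <- gregexpr(query, seq, fixed = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    res <- lapply(pos, function(p) {
      start0 <- p - 1L
      if (strand == "+") {
        pam <- if (start0 + 23 <= n) substr(seq, p + 20, p + 22) else ""
      } else {
        pam <- if (start0 - 3 >= 0) rev_comp(substr(seq, p - 3, p - 1)) else ""
      }
      data.frame(guide = name, strand = strand,
                 start = start0, end = start0 + 20L, pam = pam,
                 pam_valid = nchar(pam) == 3 &&
                   substr(pam, 2, 3) == "GG",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- rbind(one_strand(guide, "+"), one_strand(rev_comp(guide), "-"))
  if (is.null(out)) {
    out <- data.frame(guide = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      pam = character(0), pam_valid = logical(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_match", "data.frame")
  out
}

#' SpCas9 blunt cut site of a guide match
#'
#' The standard SpCas9 blunt cut falls 3 bp 5' of the PAM, between
#' protospacer positions 17 and 18 (PAM-proximal), resolved to plus-strand
#' reference coordinates.
#'
#' @param match One row of a [find_protospacer()] result with a valid PAM.
#' @return Integer cut coordinate (0-based; the cut lies between positions
#'   `cut - 1` and `cut`).
#' @export
cut_site <- function(match) {
  if (nrow(match) != 1) stop("cut_site expects exactly one match row")
  if (!match$pam_valid) stop("invalid PAM (", match$pam, "): no defined cut")
  if (match$strand == "+") match$start + 17L else match$start + 3L
}

#' Deletion interval between two guide cuts
#'
#' Computes the fragment excised by two blunt cuts on one sequence, and
#' the miRNA sites removed with it (each panel miRNA's [scan_utr()]
#' restricted to the excised segment). A guide matching the sequence more
#' than once is a hard error listing the positions, as a unique site is a
#' precondition for a clean deletion screen.
#'
#' @param m1,m2 [find_protospacer()] results for the two guides (one match
#'   each).
#' @param seq Target sequence (character string or one-row data.frame).
#' @param mirna_panel Optional named character vector of mature miRNA
#'   sequences to scan against the excised segment.
#' @return List of class `"deletion_interval"`: `cut1`, `cut2` (sorted),
#'   `length`, `excised`, `retained`, and `removed_sites` (named list of
#'   [scan_utr()] tables on the excised segment).
#' @export
deletion_interval <- function(m1, m2, seq, mirna_panel = NULL) {
  if (is.data.frame(seq) && "seq" %in% names(seq)) seq <- seq$seq[1]
  s <- norm_seq(seq, "DNA")
  for (m in list(m1, m2)) {
    if (nrow(m) > 1) {
      stop("guide '", m$guide[1], "' matches at multiple positions: ",
           paste(m$start, collapse = ", "))
    }
    if (nrow(m) == 0) stop("guide has no match")
  }
  cuts <- sort(c(cut_site(m1), cut_site(m2)))
  excised <- substr(s, cuts[1] + 1, cuts[2])
  retained <- paste0(substr(s, 1, cuts[1]),
                     substr(s, cuts[2] + 1, nchar(s)))
  removed <- NULL
  if (!is.null(mirna_panel)) {
    removed <- lapply(mirna_panel, function(mi) {
      if (nchar(excised) >= 7) scan_utr(mi, excised) else
        scan_utr(mi, "AAAAAAA")[0, ]
    })
  }
  out <- list(cut1 = cuts[1], cut2 = cuts[2], length = cuts[2] - cuts[1],
              excised = excised, retained = retained,
              removed_sites = removed)
  class(out) <- "deletion_interval"
  out
}

#' @export
print.deletion_interval <- function(x, ...) {
  cat("Deletion interval: cuts at ", x$cut1, " and ", x$cut2,
      " (", x$length, " nt excised)\n", sep = "")
  if (!is.null(x$removed_sites)) {
    for (nm in names(x$removed_sites)) {
      n <- nrow(x$removed_sites[[nm]])
      if (n) cat("  removes ", n, " site(s) for ", nm, "\n", sep = "")
    }
  }
  invisible(x)
}
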