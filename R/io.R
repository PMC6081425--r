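#' Normalise a nucleotide sequence
#'
#' Uppercases a sequence and optionally interconverts the DNA and RNA
#' alphabets (T <-> U). Internally the package works on the DNA alphabet;
#' RNA is emitted on request.
#'
#' @param seq Character vector of sequences (alphabet ACGTU, any case).
#' @param alphabet `"DNA"` converts U to T, `"RNA"` converts T to U,
#'   `"as-is"` only uppercases.
#' @return Character vector of normalised sequences.
#' @export
norm_seq <- function(seq, alphabet = c("DNA", "RNA", "as-is")) {
  alphabet <- match.arg(alphabet)
  out <- toupper(seq)
  bad <- grepl("[^ACGTU]", out)
  if (any(bad)) {
    stop("illegal character in sequence ", which(bad)[1],
         " (allowed alphabet: ACGTU, case-insensitive)")
  }
  switch(alphabet,
         "DNA" = chartr("U", "T", out),
         "RNA" = chartr("T", "U", out),
         "as-is" = out)
}

#' Reverse-complement a sequence
#'
#' @param seq Character vector (DNA or RNA; RNA is handled via the internal
#'   DNA representation and returned as RNA).
#' @return Character vector of reverse complements, same alphabet as input.
#' @export
rev_comp <- function(seq) {
  is_rna <- grepl("U", toupper(seq))
  dna <- norm_seq(seq, "DNA")
  rc <- vapply(dna, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  ifelse(is_rna, chartr("T", "U", rc), rc)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param alphabet Passed to [norm_seq()]; default stores sequences in the
#'   DNA alphabet.
#' @return A data.frame with columns `id` and `seq`, one row per record, in
#'   file order. An empty file yields a zero-row data.frame.
#' @export
read_fasta <- function(path, alphabet = "DNA") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(first, ">")) {
    stop("malformed FASTA header at line 1 of ", path,
         ": expected '>', got ", substr(first, 1, 20))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (any(!nzchar(ids))) {
    stop("empty FASTA record id (record ", which(!nzchar(ids))[1], ")")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  }
  seqs <- tryCatch(norm_seq(unname(as.character(set)), alphabet),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at a fixed 80-column width, so that
#' `write_fasta(read_fasta(x))` round-trips byte-identically for files
#' already following that policy.
#'
#' @param records data.frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrapping width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", records$id[i]),
      substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (optionally gzip-compressed) into memory.
#'
#' @param path Path to a FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4L + 1L, " in ", path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  if (any(!startsWith(ids, "@"))) {
    stop("malformed FASTQ header at record index ",
         which(!startsWith(ids, "@"))[1])
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  mismatch <- nchar(seqs) != nchar(quals)
  if (any(mismatch)) {
    stop("sequence/quality length mismatch at record index ",
         which(mismatch)[1])
  }
  data.frame(id = sub("^@", "", ids), seq = toupper(seqs), qual = quals,
             stringsAsFactors = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of condition labels and a first column of unique
#' row (gene or miRNA) labels. All values must be finite and non-negative
#' (RPKM for genes, CPM for miRNAs).
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) {
    stop("duplicate row label: ", labels[duplicated(labels)][1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop("non-numeric or missing cell at row '", labels[bad[1]],
           "', column '", colnames(vals)[j], "'")
    }
    if (any(v < 0)) {
      stop("negative value at row '", labels[which(v < 0)[1]],
           "', column '", colnames(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- labels
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param label Header label for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, label = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its documented
#' default. All defaults are the values used throughout the package's
#' analyses; any of them can be overridden here or in a YAML config file
#' (see [read_config()]).
#'
#' @param c3_entry 3C-score entry threshold: scores above it are not
#'   3C-targets (default -0.01).
#' @param c3_mid,c3_high Class boundaries separating LOW/MID and MID/HIGH
#'   3C-targets; boundaries are closed on the more-negative side.
#' @param rpkm_min Minimum gene RPKM, in at least one condition, to count a
#'   gene as expressed (default 1).
#' @param cpm_min miRNA CPM threshold; expression must exceed it strictly
#'   (default 10).
#' @param min_3p Minimum contiguous 3' supplementary pairing (nt) for TDMD
#'   eligibility (default 8).
#' @param bulge_range Allowed target-strand central-bulge lengths (nt) for
#'   eligibility. The `"default"` preset is 1-7 nt (a 7-nt bulge still
#'   supports degradation, with only modest reduction); the `"strict"`
#'   preset is 3-4 nt (a bulge greater than 2 and smaller than 5).
#' @param preset Either `"default"` or `"strict"`; sets `bulge_range`
#'   unless that is supplied explicitly.
#' @param allow_wobble Count G:U wobbles as pairs in the 3' supplementary
#'   helix (default FALSE: strict Watson-Crick, the auditable rule).
#' @param max_trim,max_tail isomiR classification windows (nt).
#' @param log2fc_pseudocount Pseudocount (RPKM) used in log2 fold-change
#'   computations (default 0.1).
#' @param seed Optional RNG seed recorded in the configuration.
#' @param ... Additional named settings stored verbatim.
#' @return A list of class `"tdmd_config"`.
#' @export
tdmd_config <- function(c3_entry = -0.01, c3_mid = -0.03, c3_high = -0.05,
                        rpkm_min = 1, cpm_min = 10,
                        min_3p = 8, bulge_range = NULL,
                        preset = c("default", "strict"),
                        allow_wobble = FALSE,
                        max_trim = 4, max_tail = 4,
                        log2fc_pseudocount = 0.1,
                        seed = NULL, ...) {
  preset <- match.arg(preset)
  if (is.null(bulge_range)) {
    bulge_range <- if (preset == "strict") c(3L, 4L) else c(1L, 7L)
  }
  stopifnot(c3_entry < 0, c3_mid < c3_entry, c3_high < c3_mid,
            length(bulge_range) == 2, bulge_range[1] <= bulge_range[2])
  structure(list(c3_entry = c3_entry, c3_mid = c3_mid, c3_high = c3_high,
                 rpkm_min = rpkm_min, cpm_min = cpm_min,
                 min_3p = min_3p, bulge_range = bulge_range, preset = preset,
                 allow_wobble = allow_wobble,
                 max_trim = max_trim, max_tail = max_tail,
                 log2fc_pseudocount = log2fc_pseudocount,
                 seed = seed, ...),
            class = "tdmd_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Settings in the file override the documented defaults of [tdmd_config()].
#'
#' @param path Path to a YAML file.
#' @return For `read_config`, a `"tdmd_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(tdmd_config, vals)
}

#' @rdname read_config
#' @param config A `"tdmd_config"` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Locate a bundled example data file
#'
#' The package ships small plain-text fixtures: the mCherry-Serpine1 3'UTR
#' construct, the miR-30c-5p sensor insert, mature miR-30 family sequences,
#' the two MRE-flanking sgRNA oligos, and the MRE variant inserts.
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of available file names).
#' @export
tdmd_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "tdmdtools")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no such extdata file: ", file)
  path
}
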