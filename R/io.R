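## File formats. Sequence I/O goes through Biostrings; interval and table
## formats are plain TSV handled with data.table.

#' Write a ReadSet to FASTA or FASTQ
#'
#' FASTA output is collapsed to unique sequences using the `id_count` header
#' dialect (`>seq000001_12` means multiplicity 12). FASTQ output is
#' uncollapsed with a constant quality of `I` (Phred 40).
#'
#' @param reads a `read_set` (or coercible object).
#' @param path output file path.
#' @param format `"fasta"` (collapsed) or `"fastq"`.
#' @param collapse collapse identical sequences in FASTA output (default TRUE).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        collapse = TRUE) {
  reads <- as_read_set(reads)
  format <- match.arg(format)
  tab <- reads$reads
  if (format == "fasta") {
    if (collapse) {
      tab <- tab[, .(count = sum(count)), by = seq]
      tab[, read_id := sprintf("seq%06d", .I)]
    }
    x <- Biostrings::DNAStringSet(tab$seq)
    names(x) <- sprintf("%s_%d", tab$read_id, tab$count)
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    tab <- tab[rep(seq_len(.N), count)]
    x <- Biostrings::DNAStringSet(tab$seq)
    names(x) <- sprintf("%s.%d", tab$read_id, seq_len(nrow(tab)))
    qual <- Biostrings::BStringSet(strrep("I", nchar(tab$seq)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Read a ReadSet from FASTA or FASTQ
#'
#' FASTA headers in the `id_count` dialect (`>id_12`) are parsed back into
#' multiplicities; headers without a trailing `_<integer>` get count 1.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"` (guessed from the extension when
#'   missing).
#' @param library_id label for the resulting library.
#' @return a `read_set`.
#' @export
read_reads <- function(path, format = NULL, library_id = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(x))
  counts <- rep(1L, length(x))
  if (format == "fasta") {
    has_count <- grepl("_[0-9]+$", ids)
    counts[has_count] <- as.integer(sub("^.*_", "", ids[has_count]))
    ids[has_count] <- sub("_[0-9]+$", "", ids[has_count])
  }
  if (anyDuplicated(ids)) ids <- sprintf("%s.%d", ids, seq_along(ids))
  read_set(as.character(x), ids = ids, counts = counts,
           library_id = library_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path input FASTA.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param intervals a data.frame/data.table with columns `chrom`, `start`,
#'   `end` and optionally `name`, `score`, `strand`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  dt <- as.data.table(intervals)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  stopifnot(all(c("chrom", "start", "end") %in% cols))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based, half-open)
#'
#' @param path input BED path.
#' @return a `data.table` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  setnames(dt, seq_len(ncol(dt)),
           c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(dt))])
  dt
}

#' Write an AlignmentSet as SAM
#'
#' Minimal single-end SAM: flags 0/16, MAPQ 255, `NM` tag carrying the
#' mismatch count. Coordinates are converted from the package's 0-based
#' half-open convention to SAM's 1-based POS.
#'
#' @param aln an `alignment_set`.
#' @param path output path.
#' @param seqs optional named character vector mapping read ids to sequences
#'   (written in the SEQ column; `*` when absent).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqs = NULL) {
  stopifnot(inherits(aln, "alignment_set"))
  ref_len <- attr(aln, "ref_lengths")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_len), ref_len), con)
  tab <- aln$alignments
  if (nrow(tab)) {
    sq <- if (is.null(seqs)) rep("*", nrow(tab)) else {
      s <- unname(seqs[tab$read_id])
      ifelse(tab$strand == "-", revcomp(s), s)
    }
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     tab$read_id, ifelse(tab$strand == "-", 16L, 0L),
                     tab$ref_id, tab$start + 1L, tab$read_len, sq, tab$n_mm)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a SAM file into an AlignmentSet
#'
#' Supports the subset written by [write_sam()]: single-end ungapped
#' alignments with flags 0/16 and an `NM` tag.
#'
#' @param path SAM file path.
#' @return an `alignment_set` (mismatch base detail columns are `NA`; the
#'   mismatch count from `NM` is retained).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_len <- setNames(as.integer(sub("^.*LN:", "", sq)),
                      sub("\tLN:.*$", "", sub("^.*SN:", "", sq)))
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body)) {
    tab <- data.table(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_mm = integer(), mm_offset = integer(),
                      mm_ref = character(), mm_read = character(),
                      read_len = integer(), count = integer(),
                      n_hits = integer())
    return(new_alignment_set(tab, ref_len, mode = "all", max_mm = 1L,
                             n_reads_in = 0L))
  }
  f <- tstrsplit(body, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  rl <- as.integer(sub("M$", "", f[[6]]))
  nm <- rep(NA_integer_, length(body))
  nm_re <- regmatches(body, regexpr("NM:i:[0-9]+", body))
  nm[grepl("NM:i:", body)] <- as.integer(sub("NM:i:", "", nm_re))
  tab <- data.table(read_id = f[[1]], ref_id = f[[3]],
                    start = as.integer(f[[4]]) - 1L,
                    end = as.integer(f[[4]]) - 1L + rl,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    n_mm = nm, mm_offset = NA_integer_,
                    mm_ref = NA_character_, mm_read = NA_character_,
                    read_len = rl, count = 1L)
  tab[, n_hits := .N, by = read_id]
  new_alignment_set(tab, ref_len, mode = "all", max_mm = 1L,
                    n_reads_in = length(unique(tab$read_id)))
}
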