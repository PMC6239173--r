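## Alignment with bowtie "-v"-like semantics: at most `max_mm` mismatches,
## best-stratum reporting (0-mismatch placements suppress 1-mismatch
## placements of the same read), and three multimapper modes.

new_alignment_set <- function(tab, ref_lengths, mode, max_mm, n_reads_in,
                              ref_ids = names(ref_lengths)) {
  structure(list(alignments = tab,
                 totals = list(
                   n_reads_in = n_reads_in,
                   n_reads_aligned = length(unique(tab$read_id)),
                   n_read_units_aligned = if (nrow(tab))
                     sum(tab[!duplicated(read_id)]$count) else 0L)),
            ref_lengths = ref_lengths, ref_ids = ref_ids, mode = mode,
            max_mm = max_mm, class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf(
    "AlignmentSet (mode %s, max_mm %d): %d placements, %d/%d reads aligned\n",
    attr(x, "mode"), attr(x, "max_mm"), nrow(x$alignments),
    x$totals$n_reads_aligned, x$totals$n_reads_in))
  invisible(x)
}

#' Align reads to a reference set with at most one mismatch
#'
#' Reports, per read, the placements in the best mismatch stratum: if a read
#' has any 0-mismatch placement, its 1-mismatch placements are suppressed.
#' `mode = "all"` reports every best-stratum placement; `"unique"` keeps only
#' reads with exactly one best-stratum placement; `"random_one"` keeps one
#' placement per read chosen uniformly at random (seeded). Mismatch bases
#' are recorded in plus-strand reference space; `N` never matches and counts
#' as a mismatch.
#'
#' @param reads a `read_set`, `sim_library` or character vector of read
#'   sequences.
#' @param ref named character vector of reference sequences.
#' @param max_mm maximum mismatches, 0 or 1.
#' @param mode `"all"`, `"unique"` or `"random_one"`.
#' @param seed seed for `"random_one"` tie breaking.
#' @param strand `"both"` (default) or `"plus"` (sense-only alignment, used
#'   for miRNA precursor counting).
#' @return an `alignment_set`: list with `alignments` (a `data.table` with
#'   columns `read_id`, `ref_id`, `start`, `end` (0-based half-open),
#'   `strand`, `n_mm`, `mm_offset`, `mm_ref`, `mm_read`, `read_len`,
#'   `count`, `n_hits`) and `totals`; reference lengths, mode and `max_mm`
#'   are carried as attributes. The 5' end of a minus-strand placement is
#'   `end - 1`.
#' @export
align <- function(reads, ref, max_mm = 1L, mode = c("all", "unique",
                                                    "random_one"),
                  seed = NULL, strand = c("both", "plus")) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  if (length(ref) == 0L) stop("reference set is empty")
  if (is.null(names(ref)) || anyDuplicated(names(ref)))
    stop("reference sequences must carry unique names")
  if (mode == "random_one" && is.null(seed))
    stop("mode 'random_one' requires a seed")
  rs <- as_read_set(reads)
  tab <- rs$reads

  ## collapse to unique sequences for the C++ search
  useq <- unique(tab$seq)
  hits <- cpp_align(useq, unname(ref), as.integer(max_mm), strand == "both")
  hits <- as.data.table(hits)

  ## expand unique-sequence hits back to read records
  tab2 <- copy(tab)[, `:=`(uidx = chmatch(seq, useq), read_len = nchar(seq))]
  aln <- hits[tab2, on = c(read = "uidx"), allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(aln) == 0L) {
    empty <- data.table(read_id = character(), ref_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), n_mm = integer(),
                        mm_offset = integer(), mm_ref = character(),
                        mm_read = character(), read_len = integer(),
                        count = integer(), n_hits = integer())
    return(new_alignment_set(empty, setNames(nchar(ref), names(ref)), mode,
                             max_mm, nrow(tab)))
  }
  ref_names <- names(ref)
  aln[, `:=`(ref_id = ref_names[ref],
             end = start + read_len,
             strand = ifelse(strand == 1L, "+", "-"),
             mm_offset = ifelse(n_mm > 0L, mm_offset, NA_integer_),
             mm_ref = ifelse(n_mm > 0L, mm_ref, NA_character_),
             mm_read = ifelse(n_mm > 0L, mm_read, NA_character_))]
  aln[, n_hits := .N, by = read_id]

  if (mode == "unique") {
    aln <- aln[n_hits == 1L]
  } else if (mode == "random_one") {
    setorder(aln, read_id, ref_id, start, strand)
    aln <- with_rng(seed, {
      aln[, keep := seq_len(.N) == sample.int(.N, 1L), by = read_id]
      aln[keep == TRUE][, keep := NULL]
    })
  }
  keep_cols <- c("read_id", "ref_id", "start", "end", "strand", "n_mm",
                 "mm_offset", "mm_ref", "mm_read", "read_len", "count",
                 "n_hits")
  aln <- aln[, keep_cols, with = FALSE]
  setorder(aln, read_id, ref_id, start)
  new_alignment_set(aln, setNames(nchar(ref), names(ref)), mode, max_mm,
                    nrow(tab))
}

#' Filter reads matching a blocklist
#'
#' Removes every read that aligns to any blocklist sequence (rRNA, tRNA,
#' abundant viruses) with at most one mismatch on either strand; surviving
#' reads keep their multiplicities.
#'
#' @param reads a `read_set`, `sim_library` or character vector.
#' @param blocklist named character vector of blocklist sequences.
#' @param max_mm mismatch allowance for the blocklist match (default 1).
#' @return a `read_set` of surviving reads (for `sim_library` input the
#'   truth table is subset alongside and a `sim_library` is returned).
#' @export
filter_blocklist <- function(reads, blocklist, max_mm = 1L) {
  rs <- as_read_set(reads)
  if (length(blocklist) == 0L) return(if (inherits(reads, "sim_library")) reads else rs)
  useq <- unique(rs$reads$seq)
  hits <- cpp_align(useq, unname(blocklist), as.integer(max_mm), TRUE)
  bad <- useq[unique(hits$read)]
  keep <- !(rs$reads$seq %in% bad)
  out <- read_set(rs$reads$seq[keep], ids = rs$reads$read_id[keep],
                  counts = rs$reads$count[keep], library_id = rs$library_id)
  if (inherits(reads, "sim_library")) {
    structure(list(reads = out,
                   truth = reads$truth[read_id %in% out$reads$read_id],
                   library_id = reads$library_id),
              class = "sim_library")
  } else out
}

#' Restrict an AlignmentSet to a read-length window
#'
#' @param aln an `alignment_set`.
#' @param min_len,max_len inclusive read-length bounds in nt.
#' @return an `alignment_set` containing only placements of reads with
#'   `min_len <= length <= max_len`.
#' @export
size_select <- function(aln, min_len, max_len) {
  stopifnot(inherits(aln, "alignment_set"), min_len <= max_len)
  tab <- aln$alignments[read_len >= min_len & read_len <= max_len]
  new_alignment_set(tab, attr(aln, "ref_lengths"), attr(aln, "mode"),
                    attr(aln, "max_mm"), aln$totals$n_reads_in)
}

#' Per-library aligned-read totals as a table
#'
#' @param ... named `alignment_set` objects (names become library ids).
#' @return a `data.table` with columns `library`, `n_reads_in`,
#'   `n_reads_aligned`.
#' @export
alignment_totals <- function(...) {
  alns <- list(...)
  rbindlist(lapply(names(alns), function(nm)
    data.table(library = nm, n_reads_in = alns[[nm]]$totals$n_reads_in,
               n_reads_aligned = alns[[nm]]$totals$n_reads_aligned)))
}
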