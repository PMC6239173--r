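## ReadSet: the basic container for a small RNA library. One row per read
## record (read_id, seq, count); simulated libraries carry one record per
## read with count 1, collapsed FASTA input carries multiplicities.

#' Construct a ReadSet
#'
#' @param seqs character vector of read sequences (uppercase ACGT/N).
#' @param ids optional read identifiers (default `r1..rn`).
#' @param counts integer multiplicities (default 1).
#' @param library_id label for the library.
#' @return an object of class `read_set`: a list with elements `reads`
#'   (a `data.table` with columns `read_id`, `seq`, `count`), `library_id`
#'   and `total_reads` (sum of multiplicities).
#' @export
read_set <- function(seqs, ids = NULL, counts = NULL, library_id = "lib") {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) && any(!grepl("^[ACGTN]+$", seqs)))
    stop("read sequences must be non-empty and over the alphabet ACGTN")
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(seqs))
  if (anyDuplicated(ids)) stop("read ids must be unique")
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  counts <- as.integer(counts)
  if (length(seqs) && any(counts < 1L)) stop("multiplicities must be >= 1")
  reads <- data.table(read_id = as.character(ids), seq = seqs, count = counts)
  structure(list(reads = reads, library_id = library_id,
                 total_reads = sum(counts)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %d records, %d reads\n",
              x$library_id, nrow(x$reads), x$total_reads))
  invisible(x)
}

# Accept read_set, sim_library or bare character vector
as_read_set <- function(x, library_id = "lib") {
  if (inherits(x, "read_set")) return(x)
  if (inherits(x, "sim_library")) return(x$reads)
  if (is.character(x)) {
    ids <- names(x)
    if (!is.null(ids) && anyDuplicated(ids)) ids <- NULL
    return(read_set(x, ids = ids, library_id = library_id))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a ReadSet")
}

sim_truth <- function(x) {
  if (inherits(x, "sim_library")) x$truth else NULL
}
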