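## ADAR editing read-out: 12-way substitution spectrum of 21-nt reads
## aligned to the TE insertion collection, and the A-to-G excess score.

.bases <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Mismatch-type spectrum of 21-nt TE-aligned reads
#'
#' For each ordered substitution type (reference base to read base, 12
#' types) reports the fraction of aligned 21-nt reads carrying that
#' mismatch, with the total number of aligned 21-nt reads as denominator
#' (perfect-match reads inflate only the denominator). Mismatches of
#' antisense placements are complemented so that every type is expressed on
#' the transcribed (sense) strand: planted A-to-I editing reads out as
#' A-to-G regardless of alignment orientation.
#'
#' @param aln an `alignment_set` of 21-nt reads against the TE insertion
#'   collection, one placement per read (mode `random_one` or `unique`).
#' @return object of class `mismatch_spectrum`: a `data.table` with columns
#'   `ref_base`, `read_base`, `count`, `fraction`; the total number of
#'   aligned reads is kept as attribute `total`.
#' @export
mismatch_spectrum <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  tab <- aln$alignments[read_len == 21L]
  tab <- tab[!duplicated(read_id)]
  if (nrow(tab) == 0L) stop("no aligned 21-nt reads")
  total <- tab[, sum(count)]
  mm <- tab[n_mm == 1L]
  grid <- CJ(ref_base = .bases, read_base = .bases)[ref_base != read_base]
  if (nrow(mm)) {
    rb <- ifelse(mm$strand == "-", .comp[mm$mm_ref], mm$mm_ref)
    qb <- ifelse(mm$strand == "-", .comp[mm$mm_read], mm$mm_read)
    obs <- data.table(ref_base = rb, read_base = qb, n = mm$count)[
      , .(count = sum(n)), by = .(ref_base, read_base)]
    out <- obs[grid, on = c("ref_base", "read_base")]
    out[is.na(count), count := 0]
  } else {
    out <- copy(grid)[, count := 0]
  }
  out[, fraction := count / total]
  setorder(out, ref_base, read_base)
  structure(out, class = c("mismatch_spectrum", class(out)), total = total)
}

#' A-to-G excess score
#'
#' The A-to-G fraction minus the mean of the 11 other substitution-type
#' fractions; positive values indicate an editing-like excess.
#'
#' @param spectrum a `mismatch_spectrum`.
#' @return scalar excess.
#' @export
ag_excess <- function(spectrum) {
  stopifnot(inherits(spectrum, "mismatch_spectrum"))
  s <- as.data.table(unclass(spectrum))
  ag <- s[ref_base == "A" & read_base == "G", fraction]
  other <- s[!(ref_base == "A" & read_base == "G"), fraction]
  ag - mean(other)
}

#' Write a mismatch spectrum as TSV
#'
#' @param spectrum a `mismatch_spectrum`.
#' @param path output path.
#' @param library library label written in the first column.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, library = "lib") {
  s <- as.data.table(unclass(spectrum))
  out <- data.table(library = library, s)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
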