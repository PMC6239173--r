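## Convenience pipelines gluing the module operations together the way the
## analyses use them.

#' Quantify 21-nt antisense TE siRNAs across libraries
#'
#' For each library: blocklist filtering, selection of 21-nt reads, unique
#' one-mismatch alignment to the TE family consensus set and antisense
#' counting; miRNA precursor counts are obtained alongside and pooled into
#' the count matrix as the normalization anchor, then median-of-ratios size
#' factors are computed and applied.
#'
#' @param libraries named list of `sim_library`/`read_set` objects.
#' @param ref a `reference_bundle`.
#' @param seed integer seed (drives multimapper assignment in the miRNA
#'   counting).
#' @return a normalized `count_matrix` (TE family and miRNA rows,
#'   role-tagged).
#' @export
quantify_sirna <- function(libraries, ref, seed = 1L) {
  stopifnot(is.list(libraries), !is.null(names(libraries)),
            inherits(ref, "reference_bundle"))
  fam_counts <- list()
  filtered <- list()
  for (nm in names(libraries)) {
    filt <- filter_blocklist(libraries[[nm]], ref$blocklist)
    filtered[[nm]] <- filt
    rs <- as_read_set(filt)
    sel <- rs$reads[nchar(seq) == 21L]
    rs21 <- read_set(sel$seq, ids = sel$read_id, counts = sel$count,
                     library_id = nm)
    aln <- align(rs21, ref$te_families, max_mm = 1L, mode = "unique")
    fam_counts[[nm]] <- family_counts_21as(aln)
  }
  mir <- mirna_counts(filtered, ref$mirnas, seed = seed)
  normalize_counts(count_matrix(fam_counts, mir))
}

#' Write a JSON contamination report
#'
#' Bundles the outcome of a spike-in analysis: library classification,
#' 10-nt overlap z and pair count, the spike response curve and the top-k
#' miRNA signature overlap.
#'
#' @param call library classification of the spiked mixture.
#' @param sig an `overlap_signature`.
#' @param spike_curve optional data.frame with columns `fraction`, `z10`.
#' @param overlap optional result of [contamination_signature()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_contamination_report <- function(call, sig, spike_curve = NULL,
                                       overlap = NULL, path) {
  stopifnot(inherits(sig, "overlap_signature"))
  rep <- list(call = call, z_10 = unname(sig$z[["10"]]),
              n_pairs_10 = sig$n_pairs_10,
              overlap_window = list(d = sig$d, pairs = unname(sig$c_d),
                                    z = unname(sig$z)))
  if (!is.null(spike_curve)) rep$spike_curve <- spike_curve
  if (!is.null(overlap))
    rep$mirna_signature <- list(k = overlap$k, overlap = overlap$overlap,
                                top_features = overlap$top_features,
                                alpha = overlap$alpha)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
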