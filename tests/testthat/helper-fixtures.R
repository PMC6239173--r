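## Shared fixtures: built once per test run, deterministic.

# small reference bundle used across module tests
tiny_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_reference(n_families = 4, n_insertions_per_family = 2,
                               n_mirnas = 25, n_clusters = 2, seed = 101)
    cache
  }
})

# moderate simulated library on the tiny reference
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_library(
        library_spec(20000, pingpong_rho = 0.4, editing_rate = 0.03,
                     seq_error_rate = 0.01, cluster_unique_frac = 0.05,
                     seed = 202, library_id = "tiny"),
        tiny_ref())
    cache
  }
})

# the stated acceptance world: head and gonadal library specs (desk scale)
head_spec <- function(seed)
  library_spec(245000,
               class_mix = c(mirna = 0.35, sirna_21 = 0.25,
                             pirna_like = 0.10, degradation = 0.25,
                             blocklist_decoy = 0.05),
               pingpong_rho = 0, library_id = "head", seed = seed)

gonad_spec <- function(seed, rho = 0.6)
  library_spec(50000,
               class_mix = c(mirna = 0.30, sirna_21 = 0.15,
                             pirna_like = 0.30, degradation = 0.20,
                             blocklist_decoy = 0.05),
               pingpong_rho = rho,
               antisense_bias = c(mirna = 0, sirna_21 = 0.5,
                                  pirna_like = 0.8, degradation = 0.1,
                                  blocklist_decoy = 0.5),
               pirna_hotspots = 100, library_id = "gonad", seed = seed)

acceptance_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_reference(n_families = 5, n_insertions_per_family = 2,
                               n_mirnas = 60, n_clusters = 2, seed = 1)
    cache
  }
})

# random uppercase DNA strings (test-local; uses the session RNG)
random_dna_test <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# brute-force BH step-up, used as the adjustment oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force ping-pong pair counting: enumerate every sense/antisense
# alignment pair per reference (product weighting = one unit per read pair)
pingpong_oracle <- function(aln_tab, d_min = 5L, d_max = 15L) {
  cd <- setNames(numeric(d_max - d_min + 1L), as.character(d_min:d_max))
  s <- aln_tab[aln_tab$strand == "+", , drop = FALSE]
  a <- aln_tab[aln_tab$strand == "-", , drop = FALSE]
  if (nrow(s) == 0 || nrow(a) == 0) return(cd)
  for (r in intersect(unique(s$ref_id), unique(a$ref_id))) {
    si <- s[s$ref_id == r, ]
    ai <- a[a$ref_id == r, ]
    d <- outer(ai$end - 1L, si$start, "-") + 1L
    w <- outer(ai$count, si$count, "*")
    for (k in d_min:d_max)
      cd[as.character(k)] <- cd[as.character(k)] + sum(w[d == k])
  }
  cd
}

# sliding-window scan oracle (naive O(N*M) verification, no index)
scan_align_oracle <- function(seqs, ref, max_mm = 1L) {
  h <- teSmallRNA:::cpp_align_scan(unname(seqs), unname(ref),
                                   as.integer(max_mm), TRUE)
  data.frame(read = h$read, ref_id = names(ref)[h$ref], start = h$start,
             strand = ifelse(h$strand == 1L, "+", "-"), n_mm = h$n_mm)
}

# Biostrings-based alignment oracle: all placements with <= max_mm
# mismatches, best stratum per read, both strands. Independent of the
# package's k-mer/pigeonhole search.
biostrings_align_oracle <- function(seqs, ref, max_mm = 1L) {
  subj <- Biostrings::DNAStringSet(ref)
  out <- list()
  seqs <- unname(seqs)
  for (L in sort(unique(nchar(seqs)))) {
    idx <- which(nchar(seqs) == L)
    pd <- Biostrings::DNAStringSet(seqs[idx])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pd else Biostrings::reverseComplement(pd)
      pdict <- Biostrings::PDict(pat, max.mismatch = max_mm)
      for (r in seq_along(subj)) {
        m <- Biostrings::matchPDict(pdict, subj[[r]], max.mismatch = max_mm)
        starts <- Biostrings::startIndex(m)
        for (q in seq_along(starts)) {
          st <- starts[[q]]
          if (is.null(st) || !length(st)) next
          nmm <- vapply(st, function(s0)
            Biostrings::neditAt(pat[[q]], subj[[r]], at = s0,
                                with.indels = FALSE), integer(1))
          out[[length(out) + 1L]] <- data.frame(
            read = idx[q], ref_id = names(ref)[r], start = st - 1L,
            strand = strand, n_mm = nmm)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(read = integer(), ref_id = character(),
                      start = integer(), strand = character(),
                      n_mm = integer()))
  res <- do.call(rbind, out)
  ## best stratum per read
  best <- tapply(res$n_mm, res$read, min)
  res <- res[res$n_mm == best[as.character(res$read)], ]
  res[order(res$read, res$ref_id, res$start, res$strand), ]
}
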