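## Synthetic reference bundle: TE family consensus sequences, diverged
## genomic insertions, piRNA clusters built from TE fragments plus
## cluster-unique spacer sequence, miRNA precursors and a blocklist of
## rRNA/tRNA-like decoys. All coordinates are 0-based half-open on a single
## synthetic chromosome.

#' Generate a synthetic reference bundle
#'
#' Builds the full reference world used by the simulator and by every
#' downstream analysis stage: TE family consensus sequences (3--8 kb),
#' per-family genomic insertions diverged from the consensus, piRNA clusters
#' assembled from TE fragments in mixed orientation with at least one >= 200
#' nt subsequence that occurs at no insertion (the cluster-unique region),
#' miRNA precursors (60--120 nt, with an embedded 21--23 nt mature
#' sequence), and rRNA/tRNA-like blocklist decoys. Insertions and clusters
#' are laid out on one synthetic chromosome separated by random spacers.
#'
#' @param n_families number of TE families (>= 1).
#' @param n_insertions_per_family genomic insertions per family (>= 1).
#' @param n_mirnas number of miRNA precursors (>= 1).
#' @param n_clusters number of piRNA clusters (>= 1).
#' @param divergence per-base substitution rate applied to insertions
#'   relative to their family consensus (default 0.02).
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @return an object of class `reference_bundle`: a list with elements
#'   `te_families` (named character), `te_insertions` (`data.table`:
#'   id, family_id, seq, start, end), `genome` (named character of length 1,
#'   chromosome `chrS`), `pirna_clusters` (`data.table`: id, seq, start,
#'   end), `cluster_unique` (`data.table` of genome intervals unique to
#'   clusters), `mirnas` (`data.table`: id, precursor, mature, mat_start)
#'   and `blocklist` (named character).
#' @export
#' @examples
#' ref <- make_reference(n_families = 2, n_insertions_per_family = 1,
#'                       n_mirnas = 5, n_clusters = 1, seed = 1)
#' names(ref$te_families)
make_reference <- function(n_families, n_insertions_per_family, n_mirnas,
                           n_clusters, divergence = 0.02, seed = 1L) {
  stopifnot(n_families >= 1, n_insertions_per_family >= 1,
            n_mirnas >= 1, n_clusters >= 1,
            divergence >= 0, divergence < 1)
  with_rng(seed, {
    fam_len <- sample(3000:8000, n_families, replace = TRUE)
    fams <- setNames(random_dna(fam_len), sprintf("TE%02d", seq_len(n_families)))

    ## insertions: diverged copies of the consensus
    ins <- data.table(
      id = character(), family_id = character(), seq = character())
    for (f in names(fams)) {
      for (j in seq_len(n_insertions_per_family)) {
        s <- mutate_seq(fams[[f]], divergence)
        ins <- rbind(ins, data.table(
          id = sprintf("%s_ins%d", f, j), family_id = f, seq = s))
      }
    }

    ## clusters: TE fragments in mixed orientation + a unique insert
    clusters <- vector("list", n_clusters)
    uniq_local <- vector("list", n_clusters)
    for (k in seq_len(n_clusters)) {
      n_frag <- sample(3:6, 1)
      parts <- character()
      for (q in seq_len(n_frag)) {
        f <- sample(names(fams), 1)
        L <- sample(200:800, 1)
        p0 <- sample.int(nchar(fams[[f]]) - L + 1L, 1) - 1L
        frag <- substr(fams[[f]], p0 + 1L, p0 + L)
        if (runif(1) < 0.5) frag <- revcomp(frag)
        parts <- c(parts, frag)
      }
      ## unique insert: random sequence, verified absent from every insertion
      repeat {
        u <- random_dna(300)
        if (!seq_occurs(u, ins$seq) && !seq_occurs(revcomp(u), ins$seq)) break
      }
      at <- sample.int(length(parts) + 1L, 1)
      parts <- append(parts, u, after = at - 1L)
      seqc <- paste(parts, collapse = "")
      off <- sum(nchar(parts[seq_len(at - 1L)]))
      clusters[[k]] <- seqc
      uniq_local[[k]] <- c(off, off + nchar(u)) # cluster-local, 0-based half-open
    }

    ## genome layout: spacer + insertions + clusters
    pieces <- character(); labels <- list(); pos <- 0L
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      p0 <- pos; pos <<- pos + nchar(s); c(p0, pos)
    }
    add_piece(random_dna(sample(150:300, 1)))
    for (i in seq_len(nrow(ins))) {
      iv <- add_piece(ins$seq[i])
      labels[[length(labels) + 1L]] <- list(type = "insertion", id = ins$id[i],
                                            start = iv[1], end = iv[2])
      add_piece(random_dna(sample(150:300, 1)))
    }
    clus <- data.table(id = character(), seq = character(),
                       start = integer(), end = integer())
    cuniq <- data.table(cluster_id = character(), start = integer(),
                        end = integer())
    for (k in seq_len(n_clusters)) {
      iv <- add_piece(clusters[[k]])
      cid <- sprintf("cluster%d", k)
      clus <- rbind(clus, data.table(id = cid, seq = clusters[[k]],
                                     start = iv[1], end = iv[2]))
      cuniq <- rbind(cuniq, data.table(
        cluster_id = cid, start = iv[1] + uniq_local[[k]][1],
        end = iv[1] + uniq_local[[k]][2]))
      add_piece(random_dna(sample(150:300, 1)))
    }
    genome <- setNames(paste(pieces, collapse = ""), "chrS")
    ins_iv <- rbindlist(labels)[, .(id, start, end)]
    ins <- ins[ins_iv, on = "id"]

    ## miRNA precursors with an embedded mature sequence
    pre_len <- sample(60:120, n_mirnas, replace = TRUE)
    mat_len <- sample(21:23, n_mirnas, replace = TRUE)
    pre <- random_dna(pre_len)
    mat_start <- vapply(pre_len - mat_len,
                        function(m) sample.int(m + 1L, 1) - 1L, integer(1))
    mirnas <- data.table(
      id = sprintf("mir%03d", seq_len(n_mirnas)),
      precursor = pre,
      mature = substr(pre, mat_start + 1L, mat_start + mat_len),
      mat_start = mat_start)

    blocklist <- setNames(
      random_dna(sample(500:1500, 4, replace = TRUE)),
      c("rRNA_1", "rRNA_2", "tRNA_1", "virus_1"))

    structure(list(te_families = fams, te_insertions = ins, genome = genome,
                   pirna_clusters = clus, cluster_unique = cuniq,
                   mirnas = mirnas, blocklist = blocklist, seed = seed),
              class = "reference_bundle")
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf(paste0("ReferenceBundle: %d TE families, %d insertions, ",
                     "%d clusters, %d miRNAs, genome %d nt (seed %s)\n"),
              length(x$te_families), nrow(x$te_insertions),
              nrow(x$pirna_clusters), nrow(x$mirnas),
              nchar(x$genome), format(x$seed)))
  invisible(x)
}

# substitute a fraction of bases, never to the original base
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  L <- nchar(s)
  n_mut <- rbinom(1, L, rate)
  if (n_mut == 0) return(s)
  pos <- sample.int(L, n_mut)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# does `needle` occur as an exact substring of any of `haystacks`?
seq_occurs <- function(needle, haystacks) {
  any(vapply(haystacks, function(h) grepl(needle, h, fixed = TRUE),
             logical(1)))
}

#' Export a reference bundle to disk
#'
#' Writes the TE family consensus, insertions, genome, miRNA precursor and
#' blocklist FASTA files, plus BED files for insertion, cluster and
#' cluster-unique intervals (0-based, half-open).
#'
#' @param ref a `reference_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ref$te_families, file.path(dir, "te_families.fa"))
  write_fasta(setNames(ref$te_insertions$seq, ref$te_insertions$id),
              file.path(dir, "te_insertions.fa"))
  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_fasta(setNames(ref$mirnas$precursor, ref$mirnas$id),
              file.path(dir, "mirna_precursors.fa"))
  write_fasta(ref$blocklist, file.path(dir, "blocklist.fa"))
  write_bed(data.table(chrom = "chrS", start = ref$te_insertions$start,
                       end = ref$te_insertions$end,
                       name = ref$te_insertions$id),
            file.path(dir, "te_insertions.bed"))
  write_bed(data.table(chrom = "chrS", start = ref$pirna_clusters$start,
                       end = ref$pirna_clusters$end,
                       name = ref$pirna_clusters$id),
            file.path(dir, "pirna_clusters.bed"))
  write_bed(data.table(chrom = "chrS", start = ref$cluster_unique$start,
                       end = ref$cluster_unique$end,
                       name = ref$cluster_unique$cluster_id),
            file.path(dir, "cluster_unique.bed"))
  invisible(dir)
}
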