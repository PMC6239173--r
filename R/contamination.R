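## Gonadal contamination QC: spike-in simulation re-testing the ping-pong
## signature, miRNA counting against precursors, a self-contained exact
## conditional binomial differential-abundance test with BH adjustment, and
## the top-k contamination signature overlap.

#' Spike gonadal reads into a head library and re-test the signature
#'
#' Mixes `n_spike` reads of the gonadal library into `n_head` reads of the
#' head library, aligns the mixture's 24--28 nt reads to the TE family
#' consensus set (one mismatch, one random placement per multimapper) and
#' recomputes the ping-pong overlap signature and classification.
#'
#' @param head head library (`sim_library` or `read_set`), expected
#'   ping-pong negative.
#' @param gonad gonadal library to draw the spike from.
#' @param n_head,n_spike reads sampled from each library.
#' @param seed integer seed driving mixing and multimapper placement.
#' @param ref a `reference_bundle` (its `te_families` are the alignment
#'   target).
#' @param size_range read-size window for the signature (default 24--28).
#' @param pair_mode pair-count weighting, see [overlap_counts()].
#' @return list with `signature` (an `overlap_signature`), `call`,
#'   `spike_fraction` (realised `n_spike / (n_head + n_spike)`) and
#'   `origin` (read counts per origin library in the mixture).
#' @export
spike_and_test <- function(head, gonad, n_head, n_spike, seed, ref,
                           size_range = c(24, 28),
                           pair_mode = c("product", "unique")) {
  stopifnot(inherits(ref, "reference_bundle"))
  mix <- mix_libraries(head, gonad, n_head, n_spike, seed = seed,
                       library_id = "spiked")
  ## restrict to the signature size window before aligning
  len <- nchar(mix$truth$seq)
  sel <- len >= size_range[1] & len <= size_range[2]
  sub <- read_set(mix$truth$seq[sel], ids = mix$truth$read_id[sel],
                  library_id = "spiked")
  aln <- align(sub, ref$te_families, max_mm = 1L, mode = "random_one",
               seed = child_seed(seed, 1))
  sig <- pingpong_signature(aln, size_range = size_range,
                            pair_mode = match.arg(pair_mode))
  list(signature = sig, call = sig$call,
       spike_fraction = n_spike / (n_head + n_spike),
       origin = mix$truth[, .N, by = origin_library])
}

#' Count reads per miRNA precursor
#'
#' A read counts toward a precursor when it aligns sense within it with at
#' most one mismatch; reads matching several precursors are assigned to one
#' chosen uniformly at random (seeded).
#'
#' @param libraries named list of `read_set`/`sim_library` objects.
#' @param mirnas miRNA precursor set: the `mirnas` table of a
#'   `reference_bundle`, or a named character vector of precursor
#'   sequences.
#' @param seed integer seed for multimapper assignment.
#' @return an object of class `mirna_count_table`: list with `counts`
#'   (integer matrix, precursors x libraries), `totals` (total reads per
#'   library, >= column sums) and `libraries`.
#' @export
mirna_counts <- function(libraries, mirnas, seed = 1L) {
  if (inherits(libraries, c("read_set", "sim_library")))
    libraries <- list(lib = libraries)
  pre <- if (is.data.frame(mirnas)) setNames(mirnas$precursor, mirnas$id)
         else mirnas
  counts <- matrix(0L, nrow = length(pre), ncol = length(libraries),
                   dimnames = list(names(pre), names(libraries)))
  totals <- integer(length(libraries))
  for (j in seq_along(libraries)) {
    rs <- as_read_set(libraries[[j]])
    totals[j] <- rs$total_reads
    aln <- align(rs, pre, max_mm = 1L, mode = "random_one",
                 seed = child_seed(seed, j), strand = "plus")
    tab <- aln$alignments[, .(n = sum(count)), by = ref_id]
    counts[tab$ref_id, j] <- tab$n
  }
  structure(list(counts = counts, totals = setNames(totals, names(libraries)),
                 libraries = names(libraries)),
            class = "mirna_count_table")
}

#' Build a miRNA count table from a count matrix
#'
#' Wraps a pre-computed matrix (e.g. from a multinomial sampling
#' simulation) in the container used by [differential_mirna()].
#'
#' @param counts integer matrix, miRNAs x libraries (dimnames required).
#' @param totals per-library total read counts (default: column sums).
#' @return a `mirna_count_table`.
#' @export
mirna_count_table <- function(counts, totals = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  if (any(totals < colSums(counts)))
    stop("library totals must be >= column sums")
  structure(list(counts = counts,
                 totals = setNames(as.numeric(totals), colnames(counts)),
                 libraries = colnames(counts)),
            class = "mirna_count_table")
}

#' Differential miRNA abundance between two library groups
#'
#' Unpaired: per miRNA, counts are pooled within each group and the pooled
#' count in group A is tested against the conditional binomial null
#' `x_A ~ Binomial(x_A + x_B, T_A / (T_A + T_B))` where `T` are the group
#' totals of the tested universe (two-sided exact test). Blocked: per
#' block, the direction of the totals-normalised difference is computed and
#' an exact two-sided sign test over blocks is applied (zero differences
#' dropped). p-values are Benjamini-Hochberg adjusted across all tested
#' miRNAs. Log2 fold changes compare totals-normalised group means with a
#' 0.5 pseudocount on counts.
#'
#' @param tbl a `mirna_count_table`.
#' @param group_a,group_b character vectors of library names.
#' @param blocks optional named vector mapping each library in
#'   `group_a`/`group_b` to a block label; each block must contain exactly
#'   one library of each group.
#' @return an object of class `differential_result`: a `data.table` with
#'   columns `feature`, `count_a`, `count_b`, `log2fc`, `pval`, `padj`.
#' @export
differential_mirna <- function(tbl, group_a, group_b, blocks = NULL) {
  stopifnot(inherits(tbl, "mirna_count_table"))
  m <- tbl$counts
  stopifnot(all(c(group_a, group_b) %in% colnames(m)))
  tot <- colSums(m)
  if (any(tot[c(group_a, group_b)] == 0))
    stop("zero-total library in the comparison")
  if (is.null(blocks) && (length(group_a) < 2L || length(group_b) < 2L))
    stop("the unpaired test needs at least 2 libraries per group")

  norm <- sweep(m + 0.5, 2, tot, "/")
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  lfc <- log2(mean_a / mean_b)
  xa <- rowSums(m[, group_a, drop = FALSE])
  xb <- rowSums(m[, group_b, drop = FALSE])

  if (is.null(blocks)) {
    p0 <- sum(tot[group_a]) / sum(tot[c(group_a, group_b)])
    pv <- vapply(seq_len(nrow(m)), function(i) {
      n <- xa[i] + xb[i]
      if (n == 0) return(1)
      binom.test(xa[i], n, p0, alternative = "two.sided")$p.value
    }, numeric(1))
  } else {
    stopifnot(!is.null(names(blocks)),
              all(c(group_a, group_b) %in% names(blocks)))
    bl <- unique(blocks[c(group_a, group_b)])
    pairs <- lapply(bl, function(b) {
      a <- intersect(group_a, names(blocks)[blocks == b])
      c2 <- intersect(group_b, names(blocks)[blocks == b])
      if (length(a) != 1L || length(c2) != 1L)
        stop("each block must pair one library of each group")
      c(a, c2)
    })
    pv <- vapply(seq_len(nrow(m)), function(i) {
      d <- vapply(pairs, function(p)
        m[i, p[1]] / tot[p[1]] - m[i, p[2]] / tot[p[2]], numeric(1))
      d <- d[d != 0]
      if (!length(d)) return(1)
      k <- sum(d > 0)
      binom.test(k, length(d), 0.5, alternative = "two.sided")$p.value
    }, numeric(1))
  }
  res <- data.table(feature = rownames(m), count_a = xa, count_b = xb,
                    log2fc = lfc, pval = pv,
                    padj = p.adjust(pv, method = "BH"))
  structure(res, class = c("differential_result", class(res)))
}

#' Top-k contamination signature overlap
#'
#' Ranks the simulated-contamination differential result by significance
#' (adjusted p, then raw p, then absolute log2 fold change) and reports how
#' many of its `k` top miRNAs are significant (adjusted p < `alpha`) in the
#' observed comparison.
#'
#' @param sim_de differential result of the spiked-vs-clean simulation.
#' @param obs_de differential result of the observed positive-vs-negative
#'   comparison (same miRNA universe).
#' @param k number of top simulated hits to examine (default 10).
#' @param alpha adjusted-p threshold in `obs_de` (default 0.01).
#' @return list with `k`, `overlap`, `top_features`, `obs_padj` (adjusted
#'   p of the top features in `obs_de`) and `alpha`.
#' @export
contamination_signature <- function(sim_de, obs_de, k = 10L, alpha = 0.01) {
  stopifnot(inherits(sim_de, "differential_result"),
            inherits(obs_de, "differential_result"))
  if (!setequal(sim_de$feature, obs_de$feature))
    stop("the two results must share the same miRNA universe")
  if (k > nrow(sim_de)) stop("k exceeds the size of the miRNA universe")
  sim <- as.data.table(sim_de)[order(padj, pval, -abs(log2fc))]
  top <- head(sim$feature, k)
  obs <- as.data.table(obs_de)
  op <- obs$padj[match(top, obs$feature)]
  list(k = as.integer(k), overlap = sum(op < alpha), top_features = top,
       obs_padj = setNames(op, top), alpha = alpha)
}

#' Sample a miRNA count table from per-library profiles
#'
#' Multinomial sampling utility for calibration studies: each library's
#' counts are drawn as `Multinomial(depth, profile)`.
#'
#' @param profiles numeric matrix, miRNAs x libraries, of relative
#'   abundances (columns are normalised internally).
#' @param depth per-library read depth (scalar or vector).
#' @param seed integer seed.
#' @return a `mirna_count_table`.
#' @export
simulate_mirna_table <- function(profiles, depth, seed = 1L) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            !is.null(colnames(profiles)))
  depth <- rep_len(depth, ncol(profiles))
  with_rng(seed, {
    counts <- vapply(seq_len(ncol(profiles)), function(j)
      as.vector(rmultinom(1, depth[j], profiles[, j] / sum(profiles[, j]))),
      integer(nrow(profiles)))
    dimnames(counts) <- dimnames(profiles)
    mirna_count_table(counts, totals = depth)
  })
}
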