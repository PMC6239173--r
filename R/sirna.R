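## TE siRNA quantification: strand/size profiles in cp10m, 21-nt antisense
## per-family counts (unique mappers), miRNA-anchored median-of-ratios
## normalization, fold-change tables and the Mann-Whitney comparison, and
## piRNA-cluster-exclusive read partitioning.

#' Strand- and size-resolved TE read profile
#'
#' Counts TE-matched reads by (read length 18--30, strand) and normalises to
#' counts per 10 million mapped reads (cp10m): `cp10m = raw * 1e7 /
#' denominator`.
#'
#' @param aln an `alignment_set` of TE-matched reads (blocklist filtering
#'   already applied); multimapper placements should be reduced to one per
#'   read beforehand (mode `unique` or `random_one`) so each read counts
#'   once.
#' @param denominator cp10m denominator: total mapped reads of the library
#'   (> 0).
#' @param lengths read-length window to tabulate (default 18:30).
#' @return object of class `size_profile`: a `data.table` with columns
#'   `read_len`, `strand`, `raw`, `cp10m`; the denominator is kept as an
#'   attribute.
#' @export
size_profile <- function(aln, denominator, lengths = 18:30) {
  stopifnot(inherits(aln, "alignment_set"))
  if (is.na(denominator) || denominator <= 0)
    stop("cp10m denominator must be positive")
  tab <- aln$alignments[!duplicated(read_id)]
  grid <- CJ(read_len = lengths, strand = c("+", "-"))
  obs <- tab[read_len %in% lengths, .(raw = sum(count)),
             by = .(read_len, strand)]
  prof <- obs[grid, on = c("read_len", "strand")]
  prof[is.na(raw), raw := 0]
  prof[, cp10m := raw * 1e7 / denominator]
  setorder(prof, read_len, strand)
  structure(prof, class = c("size_profile", class(prof)),
            denominator = denominator)
}

#' 21-nt antisense read counts per TE family
#'
#' The canonical siRNA quantification: 21-nt reads uniquely aligned to the
#' family consensus set (one mismatch allowed), counting antisense
#' placements only.
#'
#' @param aln an `alignment_set` produced with `mode = "unique"` against the
#'   TE family consensus sequences.
#' @return named integer vector of antisense 21-nt read counts over every
#'   reference family (zeros included).
#' @export
family_counts_21as <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!identical(attr(aln, "mode"), "unique"))
    warning("family_counts_21as expects unique-mode alignments")
  tab <- aln$alignments[read_len == 21L & strand == "-"]
  fams <- attr(aln, "ref_ids")
  out <- setNames(integer(length(fams)), fams)
  if (nrow(tab)) {
    agg <- tab[, .(n = sum(count)), by = ref_id]
    out[agg$ref_id] <- as.integer(agg$n)
  }
  out
}

#' Assemble a feature x library count matrix
#'
#' Pools 21-nt antisense TE family counts with miRNA counts (the
#' size-factor anchor set) into one matrix with per-feature role tags.
#'
#' @param family_counts named list (per library) of vectors from
#'   [family_counts_21as()].
#' @param mirna_tbl optional `mirna_count_table` over the same libraries.
#' @return object of class `count_matrix`: list with `counts` (matrix),
#'   `roles` (`"te_family"`/`"mirna"` per row), `size_factors` (NULL until
#'   [size_factors()] is applied via [normalize_counts()]) and `normalized`.
#' @export
count_matrix <- function(family_counts, mirna_tbl = NULL) {
  stopifnot(is.list(family_counts), !is.null(names(family_counts)))
  fam <- do.call(cbind, family_counts)
  roles <- rep("te_family", nrow(fam))
  if (!is.null(mirna_tbl)) {
    stopifnot(inherits(mirna_tbl, "mirna_count_table"))
    mir <- mirna_tbl$counts[, colnames(fam), drop = FALSE]
    fam <- rbind(fam, mir)
    roles <- c(roles, rep("mirna", nrow(mir)))
  }
  structure(list(counts = fam, roles = roles, size_factors = NULL,
                 normalized = NULL),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For every feature with strictly positive counts in all libraries the
#' geometric mean across libraries is computed; a library's size factor is
#' the median over those features of `count / geometric mean`.
#'
#' @param m a `count_matrix` or plain numeric matrix.
#' @return named numeric vector of size factors (> 0).
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no feature has positive counts in every library")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    median(cnt / exp(loggeo[use])))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Apply size-factor normalization to a count matrix
#'
#' @param m a `count_matrix`.
#' @param sf size factors (default: computed by [size_factors()]).
#' @return the `count_matrix` with `size_factors` and `normalized`
#'   (`counts / factor`, per library) filled in.
#' @export
normalize_counts <- function(m, sf = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  sf <- sf %||% size_factors(m)
  m$size_factors <- sf
  m$normalized <- sweep(m$counts, 2, sf, "/")
  m
}

#' Abundance filters for TE families
#'
#' Two rules from the analysis stages: `"cp10m_gt20"` keeps families whose
#' across-library mean exceeds 20 (strict), `"norm21as_ge5"` keeps families
#' whose mean normalised 21-nt antisense count is at least 5.
#'
#' @param values numeric matrix (families x libraries) of cp10m or
#'   normalised counts, restricted to TE family rows.
#' @param rule `"cp10m_gt20"` or `"norm21as_ge5"`.
#' @return character vector of family names passing the filter.
#' @export
filter_families <- function(values, rule = c("cp10m_gt20", "norm21as_ge5")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  mu <- rowMeans(values)
  keep <- if (rule == "cp10m_gt20") mu > 20 else mu >= 5
  rownames(values)[keep]
}

#' Per-family log2 fold changes of normalized counts
#'
#' `log2(mean normalized mutant / mean normalized control)` per family, no
#' pseudocount: the abundance filter guarantees positive control means; a
#' zero mutant mean yields `-Inf`, flagged and excluded from distribution
#' tests.
#'
#' @param m a normalized `count_matrix` (see [normalize_counts()]).
#' @param mutant,control library name vectors.
#' @param families families to report (e.g. from [filter_families()]);
#'   default: all TE family rows.
#' @return object of class `fold_change_table`: a `data.table` with columns
#'   `family`, `mean_mutant`, `mean_control`, `log2fc`, `finite`.
#' @export
log2fc <- function(m, mutant, control, families = NULL) {
  stopifnot(inherits(m, "count_matrix"), !is.null(m$normalized))
  norm <- m$normalized
  fam_rows <- rownames(norm)[m$roles == "te_family"]
  families <- families %||% fam_rows
  stopifnot(all(families %in% fam_rows))
  a <- rowMeans(norm[families, mutant, drop = FALSE])
  b <- rowMeans(norm[families, control, drop = FALSE])
  if (any(b == 0))
    stop("zero control mean for a reported family; apply the abundance filter")
  fc <- log2(a / b)
  out <- data.table(family = families, mean_mutant = a, mean_control = b,
                    log2fc = fc, finite = is.finite(fc))
  structure(out, class = c("fold_change_table", class(out)))
}

#' Compare two fold-change distributions
#'
#' Two-sided Mann-Whitney U over the finite log2 fold changes of both
#' tables (see [mann_whitney()]).
#'
#' @param a,b `fold_change_table` objects (or numeric vectors).
#' @return list with `U`, `p_value`, `method`.
#' @export
compare_fc_distributions <- function(a, b) {
  va <- if (is.numeric(a)) a else a$log2fc[a$finite]
  vb <- if (is.numeric(b)) b else b$log2fc[b$finite]
  mann_whitney(va, vb)
}

#' Quantify reads mapping exclusively to piRNA clusters
#'
#' A 21-nt read is cluster-exclusive when every one of its best-stratum
#' genome placements lies within a piRNA cluster interval and none overlaps
#' a TE insertion interval outside clusters. Reports sense/antisense
#' exclusive counts and the fraction relative to all TE-matched reads
#' (reads with any placement touching an insertion or cluster).
#'
#' @param aln an `alignment_set` against the genome, `mode = "all"`.
#' @param clusters interval table (`data.table`/`data.frame` with `start`,
#'   `end`), e.g. `ref$pirna_clusters`.
#' @param te_insertions interval table of TE insertions, e.g.
#'   `ref$te_insertions`.
#' @return list with `n_exclusive`, `exclusive_sense`,
#'   `exclusive_antisense`, `n_te_matched` and `fraction`
#'   (`n_exclusive / n_te_matched`).
#' @export
cluster_exclusive_quant <- function(aln, clusters, te_insertions) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!identical(attr(aln, "mode"), "all"))
    warning("cluster_exclusive_quant expects mode='all' alignments")
  tab <- aln$alignments
  if (nrow(tab) == 0L)
    return(list(n_exclusive = 0L, exclusive_sense = 0L,
                exclusive_antisense = 0L, n_te_matched = 0L, fraction = NA_real_))
  cl <- IRanges::IRanges(start = clusters$start + 1L, end = clusters$end)
  ins <- IRanges::IRanges(start = te_insertions$start + 1L,
                          end = te_insertions$end)
  if (length(IRanges::findOverlaps(cl, ins)) > 0L)
    warning("cluster and insertion annotations overlap; exclusivity rule applies")
  q <- IRanges::IRanges(start = tab$start + 1L, end = tab$end)
  in_cluster <- IRanges::overlapsAny(q, cl, type = "within")
  hits_insertion <- IRanges::overlapsAny(q, ins)
  per_read <- tab[, .(all_in_cluster = all(in_cluster[.I]),
                      any_insertion = any(hits_insertion[.I]),
                      te_matched = any(in_cluster[.I] | hits_insertion[.I]),
                      count = count[1L],
                      strand = strand[1L]), by = read_id]
  excl <- per_read[all_in_cluster & !any_insertion]
  n_te <- per_read[te_matched == TRUE, sum(count)]
  list(n_exclusive = excl[, sum(count)],
       exclusive_sense = excl[strand == "+", sum(count)],
       exclusive_antisense = excl[strand == "-", sum(count)],
       n_te_matched = n_te,
       fraction = if (n_te > 0) excl[, sum(count)] / n_te else NA_real_)
}
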