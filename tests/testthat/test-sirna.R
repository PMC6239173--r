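test_that("size_profile tabulates by length/strand and normalises cp10m", {
  ## library of 21-nt sense reads only
  set.seed(51)
  ref <- c(TE = random_dna_test(600))
  reads <- substring(ref[["TE"]], 1:50, 21:70)
  aln <- align(reads, ref, mode = "all")
  prof <- size_profile(aln, denominator = 5e6)
  expect_equal(prof[read_len == 21 & strand == "+"]$raw, 50)
  expect_equal(sum(prof$raw), 50)
  ## denominator 5e6, raw 50 -> cp10m 100
  expect_equal(prof[read_len == 21 & strand == "+"]$cp10m, 100)
  expect_error(size_profile(aln, 0), "positive")
  ## doubling raw and denominator leaves cp10m unchanged
  aln2 <- align(c(reads, reads), ref, mode = "all")
  ## (duplicate seqs collapse to multiplicity via read ids; emulate by count)
  prof2 <- size_profile(aln, denominator = 2 * 5e6)
  expect_equal(prof2$cp10m * 2, prof$cp10m)
})

test_that("size_profile matches ground-truth class sizes", {
  sim <- tiny_sim()
  ref <- tiny_ref()
  filt <- filter_blocklist(sim, ref$blocklist)
  aln <- align(filt, ref$te_families, mode = "random_one", seed = 52)
  denom <- aln$totals$n_reads_aligned
  prof <- size_profile(aln, denom)
  ## TE-derived classes drive the profile; compare to planted truth
  tt <- sim$truth[class %in% c("sirna_21", "pirna_like", "degradation")]
  planted <- tt[, .N, by = .(read_len = nchar(seq))]
  got <- prof[, .(raw = sum(raw)), by = read_len]
  m <- merge(planted, got, by = "read_len")
  ## within 12% per length bin (alignment losses from errors, multimapping)
  expect_true(all(abs(m$raw - m$N) / m$N < 0.12))
})

test_that("family_counts_21as counts unique antisense 21-mers per family", {
  set.seed(53)
  fams <- setNames(random_dna_test(c(500, 500)), c("TE1", "TE2"))
  sense <- substring(fams[["TE1"]], 11:20, 31:40)    # sense-only on TE1
  anti <- revcomp(substring(fams[["TE2"]], 101:130, 121:150)) # antisense TE2
  aln <- align(c(sense, anti), fams, mode = "unique")
  fc <- family_counts_21as(aln)
  expect_equal(unname(fc["TE1"]), 0L)
  expect_equal(unname(fc["TE2"]), 30L)
  ## duplicated family sequence: unique mode zeroes both copies
  fams_dup <- c(fams, TE1copy = fams[["TE1"]])
  aln_dup <- align(c(sense, anti), fams_dup, mode = "unique")
  fc_dup <- family_counts_21as(aln_dup)
  expect_equal(unname(fc_dup["TE1"]), 0L)
  expect_equal(unname(fc_dup["TE1copy"]), 0L)
  expect_equal(unname(fc_dup["TE2"]), 30L)
})

test_that("planted antisense siRNAs are recovered per family", {
  ref <- tiny_ref()
  sim <- simulate_library(library_spec(
    8000, class_mix = c(mirna = 0, sirna_21 = 1, pirna_like = 0,
                        degradation = 0, blocklist_decoy = 0),
    seq_error_rate = 0, seed = 54), ref)
  rs <- as_read_set(sim)
  aln <- align(rs, ref$te_families, mode = "unique")
  got <- family_counts_21as(aln)
  planted <- sim$truth[strand == "-", .N, by = source_id]
  m <- merge(planted, data.table::data.table(source_id = names(got),
                                             n = as.integer(got)),
             by = "source_id")
  ## unique-mode and mutation losses only; counts near-planted
  expect_true(all(abs(m$n - m$N) / m$N < 0.05))
})

test_that("size_factors: identity, equivariance and oracles", {
  set.seed(55)
  m <- matrix(rpois(300, 60) + 1, ncol = 3,
              dimnames = list(sprintf("f%d", 1:100), c("A", "B", "C")))
  ## two identical libraries -> factors 1
  m2 <- cbind(A = m[, 1], B = m[, 1])
  expect_equal(unname(size_factors(m2)), c(1, 1))
  ## scaling equivariance: B = 2A exactly
  m3 <- cbind(A = m[, 1], B = 2L * m[, 1])
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), 2)
  ## brute-force median-of-ratios oracle
  sf <- size_factors(m)
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- geo > 0 & is.finite(geo)
  oracle <- apply(m, 2, function(cnt) median(cnt[ok] / geo[ok]))
  expect_equal(sf, oracle, tolerance = 1e-12)
  ## independent package oracle (it takes the median in log space, which
  ## differs from the linear median only by even-n interpolation)
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-4)
  ## all-zero features everywhere -> failure
  z <- matrix(0, 3, 2, dimnames = list(letters[1:3], c("A", "B")))
  z[1, 1] <- 5
  expect_error(size_factors(z), "positive counts")
})

test_that("filter_families applies the stated boundary rules", {
  vals <- matrix(c(21, 21, 20, 20, 5, 5, 4.9, 4.9), nrow = 4, byrow = TRUE,
                 dimnames = list(c("hi", "edge20", "edge5", "lo"), NULL))
  expect_equal(filter_families(vals, "cp10m_gt20"), "hi") # 20 dropped, strict
  expect_setequal(filter_families(vals, "norm21as_ge5"),
                  c("hi", "edge20", "edge5")) # 5.0 kept
})

test_that("log2fc: identical groups are 0; planted effects recovered", {
  counts <- matrix(c(40, 40, 40, 40,
                     10, 10, 20, 20), nrow = 2, byrow = TRUE,
                   dimnames = list(c("f1", "f2"), c("m1", "m2", "c1", "c2")))
  mt <- count_matrix(list(m1 = counts[, 1], m2 = counts[, 2],
                          c1 = counts[, 3], c2 = counts[, 4]))
  mt <- normalize_counts(mt, sf = setNames(rep(1, 4), colnames(counts)))
  fc <- log2fc(mt, c("m1", "m2"), c("c1", "c2"))
  expect_equal(fc[family == "f1"]$log2fc, 0)
  expect_equal(fc[family == "f2"]$log2fc, -1)
  ## zero mutant mean -> -Inf flagged
  counts2 <- counts; counts2[1, 1:2] <- 0
  mt2 <- normalize_counts(count_matrix(list(m1 = counts2[, 1],
                                            m2 = counts2[, 2],
                                            c1 = counts2[, 3],
                                            c2 = counts2[, 4])),
                          sf = setNames(rep(1, 4), colnames(counts)))
  fc2 <- log2fc(mt2, c("m1", "m2"), c("c1", "c2"))
  expect_false(fc2[family == "f1"]$finite)
  expect_equal(fc2[family == "f1"]$log2fc, -Inf)
})

test_that("planted global 2-fold siRNA increase is recovered end-to-end", {
  ref <- tiny_ref()
  mk_lib <- function(fc, id, seed)
    simulate_library(library_spec(
      60000, class_mix = c(mirna = 0.45, sirna_21 = 0.30, pirna_like = 0.05,
                           degradation = 0.15, blocklist_decoy = 0.05),
      sirna_fc = fc, seq_error_rate = 0.005, library_id = id, seed = seed),
      ref)
  libs <- list(c1 = mk_lib(1, "c1", 61), c2 = mk_lib(1, "c2", 62),
               m1 = mk_lib(2, "m1", 63), m2 = mk_lib(2, "m2", 64))
  cm <- quantify_sirna(libs, ref, seed = 65)
  keep <- filter_families(cm$normalized[cm$roles == "te_family", ,
                                        drop = FALSE], "norm21as_ge5")
  fc <- log2fc(cm, c("m1", "m2"), c("c1", "c2"), families = keep)
  expect_gt(length(keep), 2)
  expect_lt(abs(median(fc$log2fc) - 1), 0.2)
})

test_that("mann_whitney exact branch matches enumeration and wilcox.test", {
  ## frozen enumeration example: U = 0, two-sided p = 2/20
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  ## identical samples -> p = 1
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  ## tie-free random cases against the stats::wilcox.test oracle
  set.seed(56)
  for (i in 1:10) {
    x <- sample(1:100, sample(3:8, 1))
    y <- sample(101:200, sample(3:8, 1)) - sample(1:120, 1)
    if (anyDuplicated(c(x, y))) next # wilcox.test has no exact tie handling
    w <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    got <- mann_whitney(x, y)
    expect_equal(got$U, unname(w$statistic))
    expect_equal(got$p_value, w$p.value, tolerance = 1e-9)
  }
  ## exact and normal branches agree within 10% at n = 9 for moderate p
  ## (a normal approximation cannot track exact tail probabilities)
  set.seed(57)
  n_checked <- 0
  for (i in 1:40) {
    x <- rnorm(9); y <- rnorm(9, 0.4)
    pe <- mann_whitney(x, y, exact_max = 9)$p_value
    if (pe < 0.15 || pe > 0.9) next
    pn <- mann_whitney(x, y, exact_max = 8)$p_value
    expect_lt(abs(pe - pn) / pe, 0.10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 9)
  ## compare_fc_distributions drops infinite values
  a <- structure(data.table::data.table(
    family = c("x", "y", "z"), mean_mutant = 1, mean_control = 1,
    log2fc = c(1, 2, -Inf), finite = c(TRUE, TRUE, FALSE)),
    class = c("fold_change_table", "data.table", "data.frame"))
  r2 <- compare_fc_distributions(a, c(1, 2))
  expect_equal(r2$p_value, 1)
})

test_that("cluster-exclusive partition honours the exclusivity rule", {
  ref <- tiny_ref()
  cu <- ref$cluster_unique
  ## a read from a cluster-unique subsequence is counted
  u_read <- substr(ref$genome, cu$start[1] + 11L, cu$start[1] + 31L)
  ## a read from an insertion (shared with its cluster copy or not) is not
  ins_read <- substr(ref$te_insertions$seq[1], 51, 71)
  aln <- align(c(u_read, ins_read), ref$genome, mode = "all")
  res <- cluster_exclusive_quant(aln, ref$pirna_clusters, ref$te_insertions)
  expect_equal(res$n_exclusive, 1)
  expect_equal(res$exclusive_sense, 1)
  ## invariance: adding more insertion-only reads leaves exclusives fixed
  more <- substring(ref$te_insertions$seq[2], 101:120, 121:140)
  aln2 <- align(c(u_read, ins_read, more), ref$genome, mode = "all")
  res2 <- cluster_exclusive_quant(aln2, ref$pirna_clusters,
                                  ref$te_insertions)
  expect_equal(res2$n_exclusive, res$n_exclusive)
  expect_gt(res2$n_te_matched, res$n_te_matched)
})

test_that("planted cluster-unique fraction is recovered", {
  ref <- tiny_ref()
  sim <- simulate_library(library_spec(
    30000, class_mix = c(mirna = 0, sirna_21 = 1, pirna_like = 0,
                         degradation = 0, blocklist_decoy = 0),
    cluster_unique_frac = 0.03, sirna_source = "insertions",
    seq_error_rate = 0, seed = 66), ref)
  aln <- align(sim, ref$genome, mode = "all")
  res <- cluster_exclusive_quant(aln, ref$pirna_clusters, ref$te_insertions)
  planted <- sum(sim$truth$source_id %in% ref$pirna_clusters$id)
  ## every planted cluster-unique read is recovered, no false positives
  expect_equal(res$n_exclusive, planted)
  expect_lt(abs(res$fraction - 0.03), 3 * sqrt(0.03 * 0.97 / 30000) + 0.002)
})
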