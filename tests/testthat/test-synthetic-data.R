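test_that("make_reference honours requested counts and uniqueness", {
  ref <- make_reference(5, 2, 20, 2, seed = 1)
  expect_length(ref$te_families, 5)
  expect_equal(nrow(ref$te_insertions), 10)
  expect_equal(nrow(ref$mirnas), 20)
  expect_equal(nrow(ref$pirna_clusters), 2)
  expect_true(all(nchar(ref$te_families) >= 3000 &
                    nchar(ref$te_families) <= 8000))
  ## ids unique across all sets
  ids <- c(names(ref$te_families), ref$te_insertions$id,
           ref$pirna_clusters$id, ref$mirnas$id, names(ref$blocklist))
  expect_equal(anyDuplicated(ids), 0L)
  ## all sequences uppercase ACGT
  allseq <- c(ref$te_families, ref$te_insertions$seq, ref$genome,
              ref$mirnas$precursor, ref$blocklist)
  expect_true(all(grepl("^[ACGT]+$", allseq)))
  ## cluster-unique subsequences >= 200 nt and absent from every insertion
  expect_true(all(ref$cluster_unique$end - ref$cluster_unique$start >= 200))
  for (i in seq_len(nrow(ref$cluster_unique))) {
    u <- substr(ref$genome, ref$cluster_unique$start[i] + 1L,
                ref$cluster_unique$end[i])
    hit <- vapply(ref$te_insertions$seq, function(s)
      grepl(u, s, fixed = TRUE) || grepl(revcomp(u), s, fixed = TRUE),
      logical(1))
    expect_false(any(hit))
  }
  ## mature sequence is a subsequence of its precursor at mat_start
  with(ref$mirnas, expect_equal(
    substr(precursor, mat_start + 1L, mat_start + nchar(mature)), mature))
})

test_that("make_reference is deterministic per seed and varies across seeds", {
  a <- make_reference(3, 1, 5, 1, seed = 7)
  b <- make_reference(3, 1, 5, 1, seed = 7)
  c <- make_reference(3, 1, 5, 1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$te_families, c$te_families))
})

test_that("simulate_library conserves counts, sizes and determinism", {
  ref <- tiny_ref()
  spec <- library_spec(15000, pingpong_rho = 0.3, seed = 5)
  sim <- simulate_library(spec, ref)
  tt <- sim$truth
  expect_equal(nrow(tt), 15000)
  expect_equal(nrow(sim$reads$reads), 15000)
  expect_setequal(tt$read_id, sim$reads$reads$read_id)
  ## class conservation
  expect_equal(sum(table(tt$class)), 15000)
  ## size contracts
  expect_true(all(nchar(tt[class == "sirna_21"]$seq) == 21))
  pl <- nchar(tt[class == "pirna_like"]$seq)
  expect_true(all(pl >= 24 & pl <= 28))
  expect_equal(as.integer(names(which.max(table(pl)))), 26)
  expect_true(all(nchar(tt[class == "degradation"]$seq) %in% 18:30))
  ## determinism
  sim2 <- simulate_library(spec, ref)
  expect_identical(sim$truth, sim2$truth)
})

test_that("planted ping-pong partner count follows the binomial oracle", {
  ref <- tiny_ref()
  spec <- library_spec(24000,
                       class_mix = c(mirna = 0, sirna_21 = 0,
                                     pirna_like = 1, degradation = 0,
                                     blocklist_decoy = 0),
                       antisense_bias = c(mirna = 0, sirna_21 = 0.5,
                                          pirna_like = 0.6,
                                          degradation = 0.1,
                                          blocklist_decoy = 0.5),
                       pingpong_rho = 0.5, seq_error_rate = 0, seed = 9)
  tt <- simulate_library(spec, ref)$truth
  n_as <- sum(tt$strand == "-" & !tt$is_partner)
  n_partner <- sum(tt$is_partner)
  ## binomial oracle: partners ~ Binomial(n_antisense, rho) within 3 sd
  expect_lt(abs(n_partner - 0.5 * n_as), 3 * sqrt(n_as * 0.25) + 1)
  ## partner geometry: sense 5' = antisense 5' - 9 on the same family
  partners <- tt[is_partner == TRUE]
  prim <- tt[strand == "-" & is_partner == FALSE]
  ## every partner 5' must match some antisense 5' - 9 on its family
  key_part <- paste(partners$source_id, partners$pos5)
  key_prim <- paste(prim$source_id, prim$pos5 - 9L)
  expect_true(all(key_part %in% key_prim))
  ## first 10 bases of partner and its mate are reverse-complementary
  m <- match(key_part, key_prim)
  expect_equal(substr(partners$seq, 1, 10),
               revcomp(substr(prim$seq[m], 1, 10)))
})

test_that("pingpong_rho = 0 plants no partners", {
  ref <- tiny_ref()
  tt <- simulate_library(library_spec(5000, pingpong_rho = 0, seed = 3),
                         ref)$truth
  expect_equal(sum(tt$is_partner), 0)
})

test_that("editing and error rates follow their binomial oracles", {
  ref <- tiny_ref()
  spec <- library_spec(20000,
                       class_mix = c(mirna = 0, sirna_21 = 1, pirna_like = 0,
                                     degradation = 0, blocklist_decoy = 0),
                       editing_rate = 0.05, seq_error_rate = 0, seed = 13)
  tt <- simulate_library(spec, ref)$truth
  expect_lt(abs(sum(tt$edited) - 1000), 3 * sqrt(20000 * 0.05 * 0.95))
  ## edited reads have exactly one A->G relative to their source window
  ed <- tt[edited == TRUE][1:50]
  src <- substr(ref$te_families[ed$source_id], ed$start + 1L, ed$end)
  src[ed$strand == "-"] <- revcomp(src[ed$strand == "-"])
  diffs <- mapply(function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    i <- which(ca != cb)
    if (length(i) != 1L) return(NA_character_)
    paste0(ca[i], cb[i])
  }, src, ed$seq)
  expect_true(all(diffs == "AG"))
})

test_that("invalid specs fail loudly", {
  expect_error(library_spec(100, class_mix = c(mirna = 1, sirna_21 = 0,
                                               pirna_like = 0,
                                               degradation = 0,
                                               blocklist_decoy = 0.5)),
               "sum to 1")
  expect_error(library_spec(100, pingpong_rho = 0.4,
                            class_mix = c(mirna = 0.5, sirna_21 = 0.5,
                                          pirna_like = 0, degradation = 0,
                                          blocklist_decoy = 0)),
               "pirna_like")
  expect_error(library_spec(100, pingpong_rho = 1.2), "probabilities")
})

test_that("mix_libraries conserves reads and records origins", {
  ref <- tiny_ref()
  a <- simulate_library(library_spec(3000, library_id = "A", seed = 1), ref)
  b <- simulate_library(library_spec(2000, library_id = "B", seed = 2), ref)
  mix <- mix_libraries(a, b, 2500, 50, seed = 4)
  expect_equal(nrow(mix$truth), 2550)
  tab <- table(mix$truth$origin_library)
  expect_equal(as.integer(tab[c("A", "B")]), c(2500, 50))
  ## deterministic per seed; different for another seed
  mix2 <- mix_libraries(a, b, 2500, 50, seed = 4)
  expect_identical(mix$truth, mix2$truth)
  mix3 <- mix_libraries(a, b, 2500, 50, seed = 5)
  expect_false(identical(mix$truth$seq, mix3$truth$seq))
  ## oversampling fails
  expect_error(mix_libraries(a, b, 3001, 0, seed = 1), "exceeds")
  ## n_from_b = 0: pure subsample of a
  sub <- mix_libraries(a, b, 1000, 0, seed = 6)
  expect_true(all(sub$truth$origin_library == "A"))
  expect_true(all(sub$truth$seq %in% a$truth$seq))
})

test_that("downsample keeps proportions (hypergeometric oracle)", {
  ref <- tiny_ref()
  a <- simulate_library(library_spec(20000, seed = 21), ref)
  d <- downsample(a, 5000, seed = 22)
  expect_equal(nrow(d$truth), 5000)
  ## hypergeometric 3 sd check on the miRNA class proportion
  K <- sum(a$truth$class == "mirna"); N <- 20000; n <- 5000
  mu <- n * K / N
  sd_h <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
  expect_lt(abs(sum(d$truth$class == "mirna") - mu), 3 * sd_h)
  expect_error(downsample(a, 20001, seed = 1), "downsample")
  expect_equal(nrow(downsample(a, 0, seed = 1)$truth), 0)
})

test_that("reads and truth round-trip through FASTA/FASTQ/TSV", {
  ref <- tiny_ref()
  sim <- simulate_library(library_spec(500, seed = 31), ref)
  fa <- tempfile(fileext = ".fa")
  write_reads(sim, fa)
  back <- read_reads(fa)
  expect_equal(back$total_reads, 500)
  ## collapsed: multiplicity-weighted sequence multiset is preserved
  orig <- sort(sim$truth$seq)
  rt <- sort(rep(back$reads$seq, back$reads$count))
  expect_equal(rt, orig)
  fq <- tempfile(fileext = ".fq")
  write_reads(sim, fq, format = "fastq")
  backq <- read_reads(fq)
  expect_equal(sort(backq$reads$seq), orig)
  tsv <- tempfile(fileext = ".tsv")
  write_truth(sim, tsv)
  tt <- data.table::fread(tsv)
  expect_equal(nrow(tt), 500)
  expect_equal(tt$seq, sim$truth$seq)
})
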