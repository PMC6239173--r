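---
title: "Methods: simulating and scoring transposon-targeting small RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring transposon-targeting small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`teSmallRNA` implements the computational core of a somatic small RNA
analysis: deciding whether piRNA-sized (24–28 nt) reads in a head library
carry a genuine ping-pong signature or reflect gonadal contamination, and
quantifying the 21-nt siRNA response against transposable-element (TE)
families. Because the real sequencing libraries are not bundled, every
analysis is exercised against a seeded simulator that plants known
structure; the tests then ask whether each stage recovers what was planted.

The statistical objects are:

* **Ping-pong signature.** Secondary piRNA amplification leaves sense and
  antisense piRNA 5′ ends overlapping by exactly 10 nt. For 24–28 nt reads
  aligned to TE consensus sequences we count, for each overlap
  $d \in \{5,\dots,15\}$, the number of sense/antisense read pairs whose 5′
  ends satisfy $\mathrm{pos}^{as}_{5'} = \mathrm{pos}^{s}_{5'} + d - 1$,
  weighting each position pair by the product of read multiplicities. The
  counts $c_d$ are z-scored within the window:
  $z_d = (c_d - \bar c)/\sigma(c)$ with the population (divide-by-$n$)
  standard deviation, since the 11 bins are the entire population of
  interest, not a sample. A library is called **positive** when
  $z_{10} \ge 2$ and $c_{10} > 20$, **negative** when $z_{10} < 0$, and
  intermediate otherwise. The published threshold appears both as
  "$\ge 2$" and "higher than 2"; we apply $\ge 2$ and cover the boundary
  with a test.
* **Contamination detection.** A ping-pong-negative head library is spiked
  with 2% of reads from a strongly ping-pong-positive gonadal library and
  re-scored; separately, miRNA abundance is compared between contaminated
  and clean libraries, and the top 10 miRNAs of the simulated-contamination
  comparison are looked up in the observed comparison (top-$k$ overlap at
  adjusted $p < 0.01$).
* **siRNA quantification.** 21-nt reads uniquely aligned (one mismatch) to
  TE family consensus sequences, counting antisense placements only —
  degraded TE transcripts align sense with little size specificity, so the
  antisense 21-mers are the cleanest siRNA proxy. Counts are pooled with
  miRNA precursor counts and normalised by median-of-ratios size factors;
  the miRNA rows anchor the normalisation so that a global shift in siRNA
  output is measured rather than normalised away. Families are filtered on
  abundance (mean > 20 cp10m for size profiles, mean ≥ 5 normalised 21-nt
  antisense reads for fold-change analyses; the strict/non-strict
  boundaries follow the wording of each published rule). Log2 fold changes
  compare means of normalised counts between genotype groups without
  pseudocount — the abundance filter guarantees positive denominators, and
  a zero mutant mean is reported as $-\infty$ and excluded from
  distribution tests. Fold-change distributions are compared with a
  two-sided Mann–Whitney U test.
* **Editing spectrum.** 21-nt reads aligned (one mismatch) to the TE
  insertion collection are tabulated by substitution type; each of the 12
  ordered types is reported as a fraction of all aligned 21-nt reads.
  ADAR deamination manifests as an A→G excess over the other 11 types.
* **Cluster-exclusive partition.** A 21-nt read is piRNA-cluster-exclusive
  when every best-stratum genome placement falls within a cluster interval
  and none overlaps a TE insertion outside clusters.

## Alignment semantics

The aligner reproduces bowtie `-v 1` semantics: at most one mismatch,
qualities ignored, and best-stratum reporting (a read with any perfect
placement contributes no 1-mismatch placements). Three multimapper modes
are exposed: `all`, `unique` (exactly one best-stratum placement, the
"only uniquely matching reads" rule), and `random_one` (one placement
drawn uniformly, seeded — the `-M 1` behaviour). Coordinates are 0-based
half-open; the 5′ end of a minus-strand placement is `end − 1`. `N` never
matches, so reads with more than one `N` are unalignable at one mismatch.
The implementation indexes reference 9-mers and uses the pigeonhole
argument (a one-mismatch placement of a read of length ≥ 18 has an exact
first or last 9-mer); its contract is checked against a naive
sliding-window scan that verifies every window of every reference, and
against `Biostrings::matchPDict` on a smaller fixture.

## The simulator: what is planted and how

`simulate_library()` draws a library of `n_reads` reads from five classes
(tissue miRNAs, 21-nt siRNAs, 24–28 nt piRNA-like reads, sense-biased
degradation fragments of 18–30 nt, and blocklist decoys) over a synthetic
reference bundle (TE family consensus of 3–8 kb, diverged genomic
insertion copies, piRNA clusters assembled from TE fragments plus a ≥200
nt cluster-unique insert, miRNA precursors, rRNA/tRNA-like decoys).
Parameters, defaults, and the reasoning behind the non-obvious ones:

| parameter | default | meaning |
|---|---|---|
| `class_mix` | 0.30/0.30/0.10/0.25/0.05 | class proportions; head-like libraries are siRNA- and degradation-dominated with ~10% piRNA-sized reads |
| `pingpong_rho` | 0 | probability that an antisense piRNA-like read receives a sense partner with an exact 10-nt 5′–5′ overlap |
| `antisense_bias` | per class | probability a read is antisense; degradation is 90% sense, gonadal piRNA-like reads are antisense-dominated |
| `sirna_fc` | 1 | per-family multiplier of siRNA abundance (the planted genotype effect) |
| `editing_rate` | 0 | per-read probability of one A→G substitution in the siRNA class |
| `seq_error_rate` | 0.01 | per-read probability of one uniform substitution |
| `mirna_profile` | uniform | tissue-specific miRNA abundance vector |
| `cluster_unique_frac` | 0 | fraction of siRNA reads drawn from cluster-unique genome subsequences |
| `sirna_source` | consensus | draw family siRNAs from the consensus or from genomic insertion copies |
| `pirna_hotspots` | none | number of distinct piRNA-like 5′ positions per family |

Design choices that were genuinely open:

* **piRNA-like length distribution.** Only the 24–28 nt range is
  documented; we use a discrete triangular distribution peaked at 26 as a
  stand-in, not an inference about the real shape.
* **Ping-pong partner geometry.** The partner is a sense read whose 5′ end
  sits 10 nt inside the antisense read, so the first ten bases of the two
  reads are reverse-complementary; partner length is drawn independently
  from the size distribution. Partners consume slots of the piRNA-like
  class, so class counts always sum to `n_reads`.
* **5′ hotspots.** Real piRNA 5′ ends concentrate at discrete biogenesis
  positions. This matters for contamination: a planted read *pair* in a
  uniformly-placed library survives a 2% subsample with probability
  ~0.0004, so a subsampled spike could never carry a signature. With
  `pirna_hotspots` set (the gonadal stated world uses 100 per family), the
  pairing lives in the 5′ *position profile*, which subsampling preserves —
  exactly the property that makes real spike-in experiments work. Head
  libraries keep uniform placements, modelling piRNA-sized degradation
  rather than genuine piRNA biogenesis.
* **`sirna_fc` changes absolute abundance.** The siRNA class weight is
  multiplied by `mean(sirna_fc)` before the class mix is renormalised, so a
  global 2-fold plant doubles siRNA output instead of being absorbed by the
  proportions; the miRNA-anchored normalisation then recovers the planted
  fold change exactly in expectation.
* **Editing target.** A→G editing applies to the 21-nt siRNA class only:
  ADAR deaminates double-stranded RNA, the Dicer-2 substrate, whereas
  piRNA-like and degradation reads are modelled as single-stranded. At most
  one A per read is edited (position uniform among A's) to preserve
  one-mismatch alignability; a flagged read without an A has its source
  window redrawn (a ~0.2% corner case for 21-mers).
* **`sirna_source = "insertions"`.** Genome-level analyses (cluster
  partitioning, mismatch spectra) align reads to insertion copies. Reads
  drawn from the consensus are unrealistic there: their perfect cluster
  placements suppress the diverged insertions' 1-mismatch placements under
  the best-stratum rule (inflating "cluster-exclusive" counts), and
  consensus-to-insertion divergence would swamp the editing signal. Those
  analyses therefore simulate reads from the genomic copies, as in real
  data.

All randomness flows from one seeded generator per call (Mersenne-Twister
with fixed sample semantics); the caller's RNG state is untouched, and
identical spec + seed reproduces a library record-for-record.

## Contamination statistics

miRNA differential abundance uses an exact conditional binomial test
instead of a negative-binomial count model: under the simulator's
multinomial sampling, pooled counts for one miRNA given both groups'
pooled totals are binomial, so the test is exactly calibrated in the world
the package can actually test (type-I error is checked by simulation).
This is a deliberate substitution — the contract is calibration, not
numerical identity with any particular count-model package. The paired
design (each spiked library blocked with its source library) uses an exact
sign test on per-block directions of totals-normalised differences. Sign
tests produce heavily tied p-values (the smallest attainable p with $B$
blocks is $2^{1-B}$), so the top-$k$ ranking orders by adjusted p, then
raw p, then absolute log2 fold change. Benjamini–Hochberg adjustment uses
`stats::p.adjust`, verified against a step-up enumeration oracle in the
tests. Log2 fold changes use totals-normalised means with a 0.5
pseudocount on counts (the source analyses are silent on this point).

## Numerical choices and degenerate inputs

* Population standard deviation in the z-score; an all-equal count vector
  has $\sigma = 0$ and is defined to give all-zero z-scores, hence an
  intermediate (never positive) call.
* Mann–Whitney U: full enumeration of group assignments for per-group
  sizes ≤ 8 (ties handled via midranks, which reproduce the
  half-count-per-tie convention exactly); otherwise a normal approximation
  with tie correction and 0.5 continuity correction. Exact and approximate
  branches agree within ~10% for moderate p-values; no approximation can
  track exact tail p-values at $n = 9$, so the branch boundary is what it
  is. Degenerate all-tied input returns p = 1.
* cp10m denominator: total reads aligned anywhere in the reference bundle
  after blocklist filtering. The published "per 10 million mapped reads"
  does not pin down the mapped set; this contract is fixed here and used
  consistently.
* Group summary for fold changes is the mean of normalised counts across
  replicate libraries (pooled counts would weight libraries by depth).
* Size factors require at least one feature with positive counts in every
  library and fail loudly otherwise; scaling a library by $c$ scales
  factor *ratios* by $c$ exactly (the geometric-mean reference absorbs
  $c^{1/n}$).

## What a green test does and does not establish

The simulator produces uniformly random reference sequence, a single
synthetic chromosome, substitution-only errors, and no adapter artifacts,
quality structure, RNA modifications, or realistic TE nesting. Green
acceptance tests therefore establish that the *pipeline logic* — alignment
semantics, pair counting, classification thresholds, normalisation,
filters, spectra, partition rules — recovers planted truth at desk scale
(2.5 × 10⁵-read libraries, 1:10 the published scale). They do not
establish anything about real fly heads, and the simulator's hotspot and
class-mix parameters are modelling choices, not estimates from data.
Known limitations: no indels or spliced alignment, no genome-scale index
performance guarantees, no per-site editing-level estimation, and no
attempt to reproduce real TE sequence content or miRNA identities.
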