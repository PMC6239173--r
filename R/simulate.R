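## Seeded small RNA library simulator with planted ground truth. Read
## classes: tissue miRNAs, 21-nt siRNAs (TE-derived, optionally
## cluster-unique), 24--28 nt piRNA-like reads with planted ping-pong
## partners, sense-biased degradation fragments, and blocklist decoys.

.sim_classes <- c("mirna", "sirna_21", "pirna_like", "degradation",
                  "blocklist_decoy")

#' Specify a simulated small RNA library
#'
#' Collects and validates all simulator parameters. Identical spec + seed
#' yields byte-identical output from [simulate_library()].
#'
#' @param n_reads total number of reads to emit.
#' @param class_mix named numeric vector of class proportions over
#'   `mirna`, `sirna_21`, `pirna_like`, `degradation`, `blocklist_decoy`;
#'   must sum to 1. The `sirna_21` share is additionally scaled by
#'   `mean(sirna_fc)` before renormalisation, so a global fold change in
#'   `sirna_fc` changes absolute siRNA abundance rather than being
#'   normalised away.
#' @param pingpong_rho probability in `[0,1]` that an antisense piRNA-like
#'   read receives a sense partner whose 5' end overlaps its own 5' end by
#'   exactly 10 nt.
#' @param antisense_bias named per-class probability that a read is
#'   antisense to its source.
#' @param sirna_fc per-TE-family multiplier of 21-nt siRNA abundance
#'   (scalar recycled, or named vector over the reference's families).
#' @param editing_rate per-read probability of a single A-to-G substitution;
#'   applied to the dsRNA-derived class (`sirna_21`).
#' @param seq_error_rate per-read probability of one uniform random
#'   substitution (sequencing error), any class.
#' @param mirna_profile relative abundance over the reference miRNAs
#'   (default uniform); the tissue-specific expression profile.
#' @param cluster_unique_frac fraction of the `sirna_21` class drawn from
#'   cluster-unique genome subsequences instead of family consensus.
#' @param sirna_source where family siRNA reads are drawn from:
#'   `"consensus"` (the family consensus sequence, default) or
#'   `"insertions"` (the genomic insertion copies, possibly diverged from
#'   the consensus; the realistic substrate for genome-level analyses such
#'   as cluster-exclusive partitioning and mismatch spectra).
#' @param pirna_hotspots number of distinct piRNA-like 5' positions per TE
#'   family, or `NULL` (default) for uniform positions. Real piRNA 5' ends
#'   cluster at discrete biogenesis sites; hotspot structure is what lets a
#'   small contaminating fraction of a gonadal library carry its ping-pong
#'   signature into a mixture.
#' @param library_id library label.
#' @param seed integer seed.
#' @return an object of class `library_spec` (a validated list).
#' @export
library_spec <- function(n_reads,
                         class_mix = c(mirna = 0.30, sirna_21 = 0.30,
                                       pirna_like = 0.10, degradation = 0.25,
                                       blocklist_decoy = 0.05),
                         pingpong_rho = 0,
                         antisense_bias = c(mirna = 0, sirna_21 = 0.5,
                                            pirna_like = 0.5,
                                            degradation = 0.1,
                                            blocklist_decoy = 0.5),
                         sirna_fc = 1,
                         editing_rate = 0,
                         seq_error_rate = 0.01,
                         mirna_profile = NULL,
                         cluster_unique_frac = 0,
                         sirna_source = c("consensus", "insertions"),
                         pirna_hotspots = NULL,
                         library_id = "simlib",
                         seed = 1L) {
  stopifnot(n_reads >= 1)
  if (!all(.sim_classes %in% names(class_mix)))
    stop("class_mix must be named with all of: ",
         paste(.sim_classes, collapse = ", "))
  class_mix <- class_mix[.sim_classes]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix entries must be >= 0")
  probs <- c(pingpong_rho, editing_rate, seq_error_rate, cluster_unique_frac,
             antisense_bias)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (!all(.sim_classes %in% names(antisense_bias)))
    stop("antisense_bias must cover every class")
  if (pingpong_rho > 0 && class_mix[["pirna_like"]] == 0)
    stop("pingpong_rho > 0 requires a nonzero pirna_like class")
  if (any(sirna_fc != 1) && class_mix[["sirna_21"]] == 0)
    stop("a planted sirna_fc effect requires a nonzero sirna_21 class")
  if (cluster_unique_frac > 0 && class_mix[["sirna_21"]] == 0)
    stop("cluster_unique_frac > 0 requires a nonzero sirna_21 class")
  if (!is.null(mirna_profile)) {
    if (any(mirna_profile < 0) || sum(mirna_profile) <= 0)
      stop("mirna_profile must be non-negative with positive sum")
  }
  if (!is.null(pirna_hotspots) && pirna_hotspots < 1)
    stop("pirna_hotspots must be >= 1 or NULL")
  structure(list(n_reads = as.integer(n_reads), class_mix = class_mix,
                 pingpong_rho = pingpong_rho,
                 antisense_bias = antisense_bias[.sim_classes],
                 sirna_fc = sirna_fc, editing_rate = editing_rate,
                 seq_error_rate = seq_error_rate,
                 mirna_profile = mirna_profile,
                 cluster_unique_frac = cluster_unique_frac,
                 sirna_source = match.arg(sirna_source),
                 pirna_hotspots = if (is.null(pirna_hotspots)) NULL
                                  else as.integer(pirna_hotspots),
                 library_id = library_id, seed = as.integer(seed)),
            class = "library_spec")
}

# discrete triangular length distribution for piRNA-like reads
.pirna_sizes <- 24:28
.pirna_size_prob <- c(1, 2, 3, 2, 1) / 9

# sample reads from a set of source sequences; returns a data.table
sample_windows <- function(src_id, src_seq, pick, len, minus) {
  src_len <- nchar(src_seq)
  L <- len
  maxstart <- src_len[pick] - L
  if (any(maxstart < 0)) stop("read length exceeds source sequence length")
  start <- floor(runif(length(pick)) * (maxstart + 1))
  s <- substring(src_seq[pick], start + 1L, start + L)
  s[minus] <- revcomp(s[minus])
  data.table(source_id = src_id[pick], seq = s,
             strand = ifelse(minus, "-", "+"),
             start = as.integer(start), end = as.integer(start + L))
}

#' Simulate a small RNA library with planted ground truth
#'
#' Draws class counts from the (fold-change adjusted) class mix and emits
#' exactly `spec$n_reads` reads. Antisense piRNA-like reads receive, with
#' probability `pingpong_rho`, a sense partner read whose 5' end overlaps
#' the antisense 5' end by exactly 10 nt (the first ten bases of the two
#' reads are reverse-complementary); partners consume slots of the
#' piRNA-like class so totals are conserved. A-to-G editing (one A per
#' read) is applied to the siRNA class at `editing_rate`; one uniform
#' substitution is applied to any read at `seq_error_rate`.
#'
#' @param spec a [library_spec()].
#' @param ref a [make_reference()] bundle.
#' @return an object of class `sim_library`: list with `reads` (a
#'   `read_set`, one record per read, count 1) and `truth` (a `data.table`
#'   with per-read class, source feature, strand, coordinates, 5' position,
#'   edited/error/partner flags and origin library).
#' @export
simulate_library <- function(spec, ref) {
  stopifnot(inherits(spec, "library_spec"), inherits(ref, "reference_bundle"))
  fam_ids <- names(ref$te_families)
  fc <- spec$sirna_fc
  if (length(fc) == 1L && is.null(names(fc)))
    fc <- setNames(rep(fc, length(fam_ids)), fam_ids)
  if (!all(fam_ids %in% names(fc)))
    stop("sirna_fc must name every TE family (or be a scalar)")
  fc <- fc[fam_ids]

  with_rng(spec$seed, {
    ## class weights: global siRNA fold changes scale the class share
    w <- spec$class_mix
    w[["sirna_21"]] <- w[["sirna_21"]] * mean(fc)
    n_cls <- as.vector(rmultinom(1, spec$n_reads, w / sum(w)))
    names(n_cls) <- .sim_classes

    parts <- list()

    ## miRNA class: mature sequences, sense
    if (n_cls[["mirna"]] > 0) {
      prof <- spec$mirna_profile %||% rep(1, nrow(ref$mirnas))
      if (length(prof) != nrow(ref$mirnas))
        stop("mirna_profile length must equal the number of miRNAs")
      pick <- sample.int(nrow(ref$mirnas), n_cls[["mirna"]], replace = TRUE,
                         prob = prof / sum(prof))
      m <- ref$mirnas[pick]
      parts$mirna <- data.table(
        class = "mirna", source_id = m$id, seq = m$mature, strand = "+",
        start = m$mat_start, end = m$mat_start + nchar(m$mature),
        is_partner = FALSE)
    }

    ## siRNA class: 21-nt, family-weighted by fc; optional cluster-unique part
    if (n_cls[["sirna_21"]] > 0) {
      n_s <- n_cls[["sirna_21"]]
      n_cu <- rbinom(1, n_s, spec$cluster_unique_frac)
      n_fam <- n_s - n_cu
      if (n_fam > 0) {
        minus <- runif(n_fam) < spec$antisense_bias[["sirna_21"]]
        if (spec$sirna_source == "consensus") {
          pick <- sample.int(length(fam_ids), n_fam, replace = TRUE,
                             prob = fc / sum(fc))
          d <- sample_windows(fam_ids, unname(ref$te_families), pick, 21L,
                              minus)
        } else {
          ## genomic insertion copies, family-weighted by fc
          ins <- ref$te_insertions
          wt <- fc[ins$family_id] / sum(fc[ins$family_id])
          pick <- sample.int(nrow(ins), n_fam, replace = TRUE, prob = wt)
          d <- sample_windows(ins$id, ins$seq, pick, 21L, minus)
          ## lift coordinates to the genome
          off <- ins$start[pick]
          d[, `:=`(start = start + off, end = end + off)]
        }
        d[, `:=`(class = "sirna_21", is_partner = FALSE)]
        parts$sirna <- d
      }
      if (n_cu > 0) {
        cu <- ref$cluster_unique
        iv <- sample.int(nrow(cu), n_cu, replace = TRUE)
        maxstart <- cu$end[iv] - 21L - cu$start[iv]
        start <- cu$start[iv] + floor(runif(n_cu) * (maxstart + 1))
        s <- substring(ref$genome[[1]], start + 1L, start + 21L)
        minus <- runif(n_cu) < 0.5
        s[minus] <- revcomp(s[minus])
        parts$sirna_cu <- data.table(
          class = "sirna_21", source_id = cu$cluster_id[iv], seq = s,
          strand = ifelse(minus, "-", "+"), start = as.integer(start),
          end = as.integer(start + 21L), is_partner = FALSE)
      }
    }

    ## piRNA-like class with planted ping-pong partners
    if (n_cls[["pirna_like"]] > 0)
      parts$pirna <- simulate_pirna_class(
        n_cls[["pirna_like"]], ref, spec$antisense_bias[["pirna_like"]],
        spec$pingpong_rho, spec$pirna_hotspots)

    ## degradation: sense-biased, lengths 18--30
    if (n_cls[["degradation"]] > 0) {
      n_d <- n_cls[["degradation"]]
      pick <- sample.int(length(fam_ids), n_d, replace = TRUE)
      len <- sample(18:30, n_d, replace = TRUE)
      minus <- runif(n_d) < spec$antisense_bias[["degradation"]]
      d <- rbindlist(lapply(split(seq_len(n_d), len), function(ix)
        sample_windows(fam_ids, unname(ref$te_families), pick[ix],
                       len[ix[1]], minus[ix])))
      d[, `:=`(class = "degradation", is_partner = FALSE)]
      parts$degradation <- d
    }

    ## blocklist decoys
    if (n_cls[["blocklist_decoy"]] > 0) {
      n_b <- n_cls[["blocklist_decoy"]]
      bl <- ref$blocklist
      pick <- sample.int(length(bl), n_b, replace = TRUE)
      len <- sample(18:30, n_b, replace = TRUE)
      minus <- runif(n_b) < spec$antisense_bias[["blocklist_decoy"]]
      d <- rbindlist(lapply(split(seq_len(n_b), len), function(ix)
        sample_windows(names(bl), unname(bl), pick[ix], len[ix[1]],
                       minus[ix])))
      d[, `:=`(class = "blocklist_decoy", is_partner = FALSE)]
      parts$decoy <- d
    }

    truth <- rbindlist(parts, use.names = TRUE)
    stopifnot(nrow(truth) == spec$n_reads)

    ## 5' coordinate on the source reference
    truth[, pos5 := ifelse(strand == "+", start, end - 1L)]

    ## A-to-G editing on the dsRNA-derived (siRNA) class
    truth[, edited := FALSE]
    if (spec$editing_rate > 0) {
      idx <- which(truth$class == "sirna_21" &
                     runif(nrow(truth)) < spec$editing_rate)
      if (length(idx)) {
        res <- apply_editing(truth$seq[idx])
        ## reads without an A: resample the source window (consensus-drawn
        ## family reads only; A-less 21-mers are a ~0.2% corner case)
        miss <- if (spec$sirna_source == "consensus") idx[is.na(res)]
                else integer()
        for (i in miss) {
          for (try in 1:20) {
            repl <- resample_sirna_read(truth[i], ref, fam_ids)
            if (grepl("A", repl$seq, fixed = TRUE)) {
              truth[i, c("source_id", "seq", "strand", "start", "end",
                         "pos5") :=
                      repl[, .(source_id, seq, strand, start, end,
                               ifelse(strand == "+", start, end - 1L))]]
              break
            }
          }
        }
        res2 <- apply_editing(truth$seq[miss])
        ok <- idx[!is.na(res)]
        truth[ok, seq := res[!is.na(res)]]
        ok2 <- miss[!is.na(res2)]
        if (length(ok2)) truth[ok2, seq := res2[!is.na(res2)]]
        truth[c(ok, ok2), edited := TRUE]
      }
    }

    ## sequencing error: one uniform substitution per selected read
    truth[, error := FALSE]
    if (spec$seq_error_rate > 0) {
      idx <- which(runif(nrow(truth)) < spec$seq_error_rate)
      if (length(idx)) {
        truth[idx, seq := apply_seq_error(seq)]
        truth[idx, error := TRUE]
      }
    }

    truth[, read_id := sprintf("%s_r%07d", spec$library_id, seq_len(.N))]
    truth[, origin_library := spec$library_id]
    setcolorder(truth, c("read_id", "class", "source_id", "strand", "start",
                         "end", "pos5", "edited", "error", "is_partner",
                         "origin_library", "seq"))
    rs <- read_set(truth$seq, ids = truth$read_id,
                   library_id = spec$library_id)
    structure(list(reads = rs, truth = truth, spec = spec,
                   library_id = spec$library_id),
              class = "sim_library")
  })
}

# piRNA-like reads: primaries with antisense bias; each antisense primary
# plants, with probability rho, a sense partner read whose 5' end sits 10 nt
# into the antisense read (5'-5' overlap exactly 10). Partners consume class
# slots so the class total is exact. With `hotspots` set, antisense 5' ends
# (and non-partner sense 5' ends) are drawn from a fixed per-family pool of
# positions instead of uniformly.
simulate_pirna_class <- function(n_class, ref, antisense_bias, rho,
                                 hotspots = NULL) {
  fam_ids <- names(ref$te_families)
  fam_seqs <- unname(ref$te_families)
  fam_len <- nchar(fam_seqs)

  minus <- runif(n_class) < antisense_bias
  partner <- minus & (runif(n_class) < rho)
  cost <- 1L + partner
  keep <- cumsum(cost) <= n_class
  minus <- minus[keep]; partner <- partner[keep]
  short <- n_class - sum(1L + partner)
  if (short > 0) { # fill leftover slots with partner-less primaries
    extra_minus <- runif(short) < antisense_bias
    minus <- c(minus, extra_minus)
    partner <- c(partner, rep(FALSE, short))
  }
  n_p <- length(minus)
  pick <- sample.int(length(fam_ids), n_p, replace = TRUE)
  len <- sample(.pirna_sizes, n_p, replace = TRUE, prob = .pirna_size_prob)

  ## primary end coordinate: always leave room for a partner so hotspot
  ## pools stay valid for both partnered and partner-less reads
  lo <- pmax(len, 29L)
  hi <- fam_len[pick] - 18L
  if (is.null(hotspots)) {
    end <- lo + floor(runif(n_p) * (hi - lo + 1))
    ## sense (non-partner) primaries are unconstrained at the high end
    end[!minus] <- len[!minus] +
      floor(runif(sum(!minus)) * (fam_len[pick[!minus]] - len[!minus] + 1))
  } else {
    ## per-family pools of antisense end positions and sense start positions
    as_pool <- lapply(seq_along(fam_ids), function(f)
      29L + floor(runif(hotspots) * (fam_len[f] - 18L - 29L + 1)))
    s_pool <- lapply(seq_along(fam_ids), function(f)
      floor(runif(hotspots) * (fam_len[f] - 28L + 1)))
    slot <- 1L + floor(runif(n_p) * hotspots)
    end <- integer(n_p)
    for (f in seq_along(fam_ids)) {
      i_as <- which(pick == f & minus)
      end[i_as] <- as_pool[[f]][slot[i_as]]
      i_s <- which(pick == f & !minus)
      end[i_s] <- s_pool[[f]][slot[i_s]] + len[i_s]
    }
  }
  start <- end - len
  s <- substring(fam_seqs[pick], start + 1L, end)
  s[minus] <- revcomp(s[minus])
  prim <- data.table(class = "pirna_like", source_id = fam_ids[pick], seq = s,
                     strand = ifelse(minus, "-", "+"),
                     start = as.integer(start), end = as.integer(end),
                     is_partner = FALSE)

  ## partners: sense reads with 5' at (antisense 5') - 9
  pi <- which(partner)
  if (length(pi)) {
    p_start <- end[pi] - 10L
    p_len <- sample(.pirna_sizes, length(pi), replace = TRUE,
                    prob = .pirna_size_prob)
    p_len <- pmin(p_len, fam_len[pick[pi]] - p_start) # clamp at family end
    p_seq <- substring(fam_seqs[pick[pi]], p_start + 1L, p_start + p_len)
    part <- data.table(class = "pirna_like", source_id = fam_ids[pick[pi]],
                       seq = p_seq, strand = "+",
                       start = as.integer(p_start),
                       end = as.integer(p_start + p_len), is_partner = TRUE)
    rbind(prim, part)
  } else prim
}

# substitute one random A per read with G; NA when the read has no A
apply_editing <- function(seqs) {
  if (!length(seqs)) return(character())
  out <- rep(NA_character_, length(seqs))
  apos <- gregexpr("A", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    p <- apos[[i]]
    if (p[1] == -1L) next
    at <- p[[sample.int(length(p), 1)]]
    s <- seqs[i]
    substr(s, at, at) <- "G"
    out[i] <- s
  }
  out
}

# one uniform random substitution per read (to a different base)
apply_seq_error <- function(seqs) {
  L <- nchar(seqs)
  pos <- 1L + floor(runif(length(seqs)) * L)
  old <- substr(seqs, pos, pos)
  bases <- c("A", "C", "G", "T")
  new <- vapply(old, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  new[old == "N"] <- sample(bases, sum(old == "N"), replace = TRUE)
  substr(seqs, pos, pos) <- new
  seqs
}

# redraw a single 21-nt family siRNA read (used by the editing resampler)
resample_sirna_read <- function(row, ref, fam_ids) {
  pick <- sample.int(length(fam_ids), 1)
  minus <- row$strand == "-"
  sample_windows(fam_ids, unname(ref$te_families), pick, 21L, minus)
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("Simulated library '%s': %d reads\n", x$library_id,
              nrow(x$truth)))
  print(x$truth[, .N, by = class])
  invisible(x)
}

#' Mix two libraries (contamination model)
#'
#' Samples reads without replacement from each input and concatenates them,
#' recording the origin library per read in the ground truth.
#'
#' @param a,b `sim_library` or `read_set` objects.
#' @param n_from_a,n_from_b numbers of reads to draw from each.
#' @param seed integer seed.
#' @param library_id label of the mixture.
#' @return a `sim_library` whose truth carries `origin_library`.
#' @export
mix_libraries <- function(a, b, n_from_a, n_from_b, seed,
                          library_id = "mix") {
  ta <- library_truth(a); tb <- library_truth(b)
  if (n_from_a > nrow(ta)) stop("n_from_a exceeds available reads in a")
  if (n_from_b > nrow(tb)) stop("n_from_b exceeds available reads in b")
  with_rng(seed, {
    sa <- ta[sort(sample.int(nrow(ta), n_from_a))]
    sb <- tb[sort(sample.int(nrow(tb), n_from_b))]
    out <- rbind(sa, sb, use.names = TRUE)
    out[, read_id := sprintf("%s_r%07d", library_id, seq_len(.N))]
    rs <- read_set(out$seq, ids = out$read_id, library_id = library_id)
    structure(list(reads = rs, truth = out, library_id = library_id),
              class = "sim_library")
  })
}

# per-read truth table for a library; synthesised for plain read_sets
library_truth <- function(x) {
  if (inherits(x, "sim_library")) return(copy(x$truth))
  rs <- as_read_set(x)
  tab <- rs$reads[rep(seq_len(.N), count)]
  data.table(read_id = sprintf("%s.%d", tab$read_id, seq_len(nrow(tab))),
             class = NA_character_, source_id = NA_character_,
             strand = NA_character_, start = NA_integer_, end = NA_integer_,
             pos5 = NA_integer_, edited = NA, error = NA, is_partner = NA,
             origin_library = rs$library_id, seq = tab$seq)
}

#' Downsample a library without replacement
#'
#' @param x a `sim_library` or `read_set`.
#' @param n number of reads to keep (`n <=` library size).
#' @param seed integer seed.
#' @param library_id label of the result (default: input label).
#' @return same class as the mixing output: a `sim_library`.
#' @export
downsample <- function(x, n, seed, library_id = NULL) {
  tt <- library_truth(x)
  if (n > nrow(tt)) stop("cannot downsample ", nrow(tt), " reads to ", n)
  lid <- library_id %||%
    (if (inherits(x, "sim_library")) x$library_id else as_read_set(x)$library_id)
  with_rng(seed, {
    out <- tt[sort(sample.int(nrow(tt), n))]
    rs <- read_set(out$seq, ids = out$read_id, library_id = lid)
    structure(list(reads = rs, truth = out, library_id = lid),
              class = "sim_library")
  })
}

#' Write simulator ground truth as TSV
#'
#' @param x a `sim_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "sim_library"))
  fwrite(x$truth, path, sep = "\t")
  invisible(path)
}
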