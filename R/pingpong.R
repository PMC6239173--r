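## Ping-pong 5'-overlap signature: pair counts for 5'-5' overlaps of 5--15
## nt between sense and antisense reads, z-score transformation over that
## window, and the positive/negative library call.

#' Build a 5'-end profile from an AlignmentSet
#'
#' Sums read multiplicities per (reference, strand, 5' coordinate). The 5'
#' end of a sense placement is its `start`; the 5' end of an antisense
#' placement is `end - 1`.
#'
#' @param aln an `alignment_set`.
#' @param size_range inclusive read-length window, default `c(24, 28)`
#'   (the piRNA size range).
#' @return an object of class `fiveprime_profile`: a `data.table` with
#'   columns `ref_id`, `strand`, `pos5`, `n`.
#' @export
fiveprime_profile <- function(aln, size_range = c(24, 28)) {
  stopifnot(inherits(aln, "alignment_set"))
  tab <- aln$alignments
  if (!is.null(size_range))
    tab <- tab[read_len >= size_range[1] & read_len <= size_range[2]]
  prof <- tab[, .(ref_id, strand,
                  pos5 = ifelse(strand == "+", start, end - 1L), count)][
    , .(n = sum(count)), by = .(ref_id, strand, pos5)]
  setorder(prof, ref_id, strand, pos5)
  structure(prof, class = c("fiveprime_profile", class(prof)),
            size_range = size_range)
}

#' Count sense/antisense 5'-overlap pairs
#'
#' For overlap `d`, a sense 5' end at position `p` pairs with an antisense
#' 5' end at `p + d - 1` (the two 5' ends span `d` reverse-complementary
#' bases). In `pair_mode = "product"` each position pair contributes the
#' product of its read multiplicities ("number of pairs"); in `"unique"`
#' each matched position pair contributes 1.
#'
#' @param profile a [fiveprime_profile()].
#' @param d_min,d_max overlap window bounds (default 5 and 15).
#' @param pair_mode `"product"` (default) or `"unique"`.
#' @return named numeric vector `c_d` for `d = d_min..d_max`, aggregated
#'   over references.
#' @export
overlap_counts <- function(profile, d_min = 5L, d_max = 15L,
                           pair_mode = c("product", "unique")) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(d_min <= d_max)
  prof <- as.data.table(unclass(profile))
  sense <- prof[strand == "+", .(ref_id, pos5, n)]
  anti <- prof[strand == "-", .(ref_id, pos5, n)]
  ds <- d_min:d_max
  cd <- setNames(numeric(length(ds)), as.character(ds))
  if (nrow(sense) == 0L || nrow(anti) == 0L) return(cd)
  for (i in seq_along(ds)) {
    d <- ds[i]
    m <- anti[sense[, .(ref_id, pos5_as = pos5 + d - 1L, n)],
              on = c("ref_id", pos5 = "pos5_as"), nomatch = NULL]
    ## columns after join: n (antisense), i.n (sense)
    cd[i] <- if (nrow(m) == 0L) 0 else
      if (pair_mode == "product") sum(as.numeric(m$n) * m$i.n) else nrow(m)
  }
  cd
}

#' z-score an overlap pair-count vector
#'
#' Transforms the counts for overlaps `d = 5..15` into z-scores: each count
#' minus the window mean, divided by the population (divide-by-n) standard
#' deviation over the window. When the standard deviation is zero all
#' z-scores are defined as 0.
#'
#' @param c_d named numeric vector of pair counts over the overlap window.
#' @return an object of class `overlap_signature`: list with `d`, `c_d`,
#'   `z`, `n_pairs_10` (`c_d` at overlap 10, NA if outside the window) and
#'   `call` (from [classify_pingpong()]).
#' @export
pp_signature <- function(c_d) {
  stopifnot(is.numeric(c_d), !is.null(names(c_d)))
  d <- as.integer(names(c_d))
  mu <- mean(c_d)
  sdp <- sqrt(mean((c_d - mu)^2))
  z <- if (sdp > 0) (c_d - mu) / sdp else rep(0, length(c_d))
  names(z) <- names(c_d)
  n10 <- if ("10" %in% names(c_d)) unname(c_d[["10"]]) else NA_real_
  sig <- structure(list(d = d, c_d = c_d, z = z, n_pairs_10 = n10,
                        call = NA_character_),
                   class = "overlap_signature")
  sig$call <- classify_pingpong(sig)
  sig
}

#' Classify a library from its overlap signature
#'
#' A library is ping-pong positive when the z-score at the 10-nt overlap is
#' at least 2 and more than 20 pairs overlap by 10 nt; negative when the
#' 10-nt z-score is below 0; intermediate otherwise.
#'
#' @param sig an `overlap_signature`.
#' @return `"positive"`, `"negative"` or `"intermediate"`.
#' @export
classify_pingpong <- function(sig) {
  stopifnot(inherits(sig, "overlap_signature"))
  z10 <- unname(sig$z[["10"]])
  n10 <- sig$n_pairs_10
  if (is.na(z10) || is.na(n10)) return(NA_character_)
  if (z10 >= 2 && n10 > 20) "positive"
  else if (z10 < 0) "negative"
  else "intermediate"
}

#' @export
print.overlap_signature <- function(x, ...) {
  cat("Ping-pong overlap signature\n")
  print(data.table(d = x$d, pairs = unname(x$c_d), z = round(unname(x$z), 3)))
  cat(sprintf("z_10 = %.3f, pairs_10 = %s, call = %s\n",
              x$z[["10"]], format(x$n_pairs_10), x$call))
  invisible(x)
}

#' Full ping-pong signature pipeline on an AlignmentSet
#'
#' Convenience wrapper: 5' profile in the given size window, overlap pair
#' counts for `d = 5..15`, z-scores and classification.
#'
#' @inheritParams fiveprime_profile
#' @inheritParams overlap_counts
#' @return an `overlap_signature`.
#' @export
pingpong_signature <- function(aln, size_range = c(24, 28),
                               pair_mode = c("product", "unique")) {
  prof <- fiveprime_profile(aln, size_range = size_range)
  pp_signature(overlap_counts(prof, pair_mode = match.arg(pair_mode)))
}

#' Write an overlap signature as TSV
#'
#' Columns `d`, `pairs`, `z`, followed by a one-line call record
#' (commented).
#'
#' @param sig an `overlap_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "overlap_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("d\tpairs\tz", con)
  writeLines(sprintf("%d\t%s\t%.6g", sig$d, format(unname(sig$c_d)),
                     unname(sig$z)), con)
  writeLines(sprintf("# call=%s z10=%.6g pairs10=%s", sig$call,
                     sig$z[["10"]], format(sig$n_pairs_10)), con)
  invisible(path)
}
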