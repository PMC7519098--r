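## Repeat censuses: MISA-style perfect microsatellites and REPuter-style
## maximal repeat pairs.

#' Canonical form of an SSR motif
#'
#' Lexicographic minimum over all rotations of the motif and of its
#' reverse complement, so that the census is strand-symmetric.
#'
#' @param motif character vector of motifs
#' @return character vector of canonical motifs
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    rot <- function(s) {
      n <- nchar(s)
      vapply(seq_len(n) - 1L, function(i) {
        paste0(substr(s, i + 1L, n), substr(s, 1L, i))
      }, character(1))
    }
    min(c(rot(m), rot(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
is_primitive_motif <- function(m) {
  L <- nchar(m)
  if (L == 1L) return(TRUE)
  for (d in seq_len(L - 1L)) {
    if (L %% d == 0L && m == strrep(substr(m, 1L, d), L %/% d)) return(FALSE)
  }
  TRUE
}

#' Scan for perfect microsatellites (SSRs)
#'
#' MISA-dialect scan for maximal perfect tandem repeats of 1-6 bp motifs.
#' A run qualifies when its full repeat count meets the class threshold;
#' a partial trailing unit is not part of the reported locus, so
#' `end - start = motif length x repeat_count`. Runs whose motif is a
#' self-repetition of a shorter motif are reported once, at the smallest
#' unit. Overlapping candidates of different unit sizes are resolved in
#' favour of the smaller unit, then the longer run, then the leftmost
#' start. Non-ACGT characters break runs. The scan is linear in the given
#' sequence (repeats across the circular origin are not joined).
#'
#' @param genome a [plastome()] or DNA string
#' @param thresholds named integer vector: minimum repeat count per unit
#'   size 1-6 (default the common plastome setting 10/5/4/3/3/3)
#' @param compound_gap loci closer than this many bp are grouped into one
#'   compound SSR
#' @return data.frame with one row per locus: `start`, `end` (0-based
#'   half-open), `motif`, `canonical_motif`, `unit`, `repeat_count`,
#'   `compound_group`
#' @export
scan_ssrs <- function(genome,
                      thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                     `4` = 3L, `5` = 3L, `6` = 3L),
                      compound_gap = 100L) {
  g <- as_plastome(genome)
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  x <- seq_chars(g$seq)
  n <- length(x)
  ok <- x %in% DNA_BASES
  cand <- list()
  for (m in 1:6) {
    if (n <= m) next
    eq <- x[(m + 1L):n] == x[seq_len(n - m)] & ok[(m + 1L):n] & ok[seq_len(n - m)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      total <- r$lengths[j] + m                 # bp length of the periodic run
      count <- total %/% m
      if (count < thresholds[[as.character(m)]]) next
      s0 <- starts[j] - 1L                      # 0-based
      motif <- substr(g$seq, s0 + 1L, s0 + m)
      if (!is_primitive_motif(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = s0, end = s0 + m * count, motif = motif,
        unit = m, repeat_count = count)
    }
  }
  if (!length(cand)) {
    out <- data.frame(start = integer(), end = integer(), motif = character(),
                      canonical_motif = character(), unit = integer(),
                      repeat_count = integer(), compound_group = integer())
    return(out)
  }
  cand <- do.call(rbind, cand)
  ## resolution priority: smaller unit, longer run (bp), leftmost
  cand <- cand[order(cand$unit, -(cand$end - cand$start), cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  taken <- matrix(integer(), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    if (!nrow(taken) ||
        !any(pmax(taken[, 1], cand$start[i]) < pmin(taken[, 2], cand$end[i]))) {
      sel[i] <- TRUE
      taken <- rbind(taken, c(cand$start[i], cand$end[i]))
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$canonical_motif <- canonical_motif(out$motif)
  gap_new <- c(TRUE, out$start[-1L] > out$end[-nrow(out)] + compound_gap)
  out$compound_group <- cumsum(gap_new)
  rownames(out) <- NULL
  out[, c("start", "end", "motif", "canonical_motif", "unit",
          "repeat_count", "compound_group")]
}

#' Summarise an SSR census
#'
#' @param loci output of [scan_ssrs()]
#' @return list with per-unit-class counts, the total locus count, and the
#'   total counting each compound group once
#' @export
ssr_summary <- function(loci) {
  per_class <- table(factor(loci$unit, levels = 1:6))
  names(per_class) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  list(per_class = per_class,
       n_loci = nrow(loci),
       n_compound_grouped = length(unique(loci$compound_group)))
}

#' Find maximal repeat pairs
#'
#' REPuter-dialect exact maximal repeats of four kinds: direct (forward
#' copy), inverted (reversed copy), complement (complemented copy) and
#' palindromic (reverse-complemented copy). A pair is maximal when no
#' single-base extension on either side preserves the relation. The scan
#' is linear in the given sequence; pairs are reported once with
#' `pos1 <= pos2` (a location equal to its own image, e.g. a reversed-copy
#' match of a symmetric motif, is reported once with `pos1 == pos2`).
#' The trivial whole-sequence self identity is excluded.
#'
#' @param genome a [plastome()] or DNA string
#' @param min_len minimum repeat length in bp (>= 2)
#' @param kinds repeat kinds to scan
#' @param partition optional `quadripartite_partition`; adds an `in_ir`
#'   flag for pairs whose copies both lie inside the IR intervals (hits
#'   duplicated by the two identical IR copies)
#' @return data.frame `kind`, `pos1`, `pos2` (0-based starts), `length`
#' @export
find_maximal_repeats <- function(genome, min_len = 18L,
                                 kinds = c("direct", "inverted",
                                           "complement", "palindromic"),
                                 partition = NULL) {
  g <- as_plastome(genome)
  stopifnot(min_len >= 2L)
  s <- g$seq
  n <- g$length
  k <- max(2L, min(as.integer(min_len), 12L))
  out <- list()
  for (kind in kinds) {
    T <- switch(kind,
                direct = s,
                inverted = dna_reverse(s),
                complement = dna_complement(s),
                palindromic = revcomp(s))
    runs <- diagonal_runs(s, T, k)
    if (kind == "direct") runs <- runs[runs$i != runs$p, , drop = FALSE]
    runs <- runs[runs$len >= min_len, , drop = FALSE]
    if (!nrow(runs)) next
    pos2 <- if (kind %in% c("inverted", "palindromic")) {
      n - runs$p - runs$len
    } else runs$p
    df <- data.frame(kind = kind,
                     pos1 = pmin(runs$i, pos2),
                     pos2 = pmax(runs$i, pos2),
                     length = runs$len)
    out[[length(out) + 1L]] <- unique(df)
  }
  if (!length(out)) {
    return(data.frame(kind = character(), pos1 = integer(),
                      pos2 = integer(), length = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$kind, res$pos1, res$pos2), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(partition)) {
    in_iv <- function(pos, len, iv) {
      ((pos - iv[1]) %% n) + len <= iv[2]
    }
    res$in_ir <- (in_iv(res$pos1, res$length, partition$ira) |
                  in_iv(res$pos1, res$length, partition$irb)) &
                 (in_iv(res$pos2, res$length, partition$ira) |
                  in_iv(res$pos2, res$length, partition$irb))
  }
  res
}
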