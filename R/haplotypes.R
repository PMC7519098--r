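## Structural haplotypes: the two SSC-orientation forms of a plastome,
## long-read classification between them, and the circular-LSC screen.
##
## The two forms differ only in SSC orientation, so a read is informative
## only when its single contiguous match to one form extends from the LSC
## across a full IR copy into the SSC: locally, an IR-SSC junction of one
## form equals the reverse complement of the other form's opposite
## junction, and only the LSC context breaks the tie. Classification
## therefore requires both a junction-spanning contiguous match and a
## score margin over the other form.

#' Build the two SSC-orientation structural forms
#'
#' Rotates the genome to start at the LSC and returns form A
#' (LSC + IRa + SSC + IRb, the input orientation) and form B with the SSC
#' reverse-complemented.
#'
#' @param genome a [plastome()] or DNA string
#' @param partition its `quadripartite_partition`
#' @return a `structure_pair`: list with `form_A`, `form_B` ([plastome()]s
#'   rotated to LSC start), `junctions` (named 0-based positions) and the
#'   rotated `partition`
#' @export
build_structure_pair <- function(genome, partition) {
  rot <- rotate_to_lsc(genome, partition)
  g <- rot$genome; part <- rot$partition
  L <- part$lsc[2]; I <- part$ira[2]; S <- part$ssc[2]
  n <- part$genome_length
  lsc <- substr(g$seq, 1L, L)
  ira <- substr(g$seq, L + 1L, L + I)
  ssc <- substr(g$seq, L + I + 1L, L + I + S)
  irb <- substr(g$seq, L + I + S + 1L, n)
  structure(list(
    form_A = plastome(paste0(lsc, ira, ssc, irb), id = paste0(g$id, "_A")),
    form_B = plastome(paste0(lsc, ira, revcomp(ssc), irb), id = paste0(g$id, "_B")),
    junctions = c("LSC/IRa" = L, "IRa/SSC" = L + I,
                  "SSC/IRb" = L + I + S, "IRb/LSC" = 0L),
    partition = part), class = "structure_pair")
}

#' @export
print.structure_pair <- function(x, ...) {
  cat(sprintf("<structure pair> %d bp; junctions at %s\n",
              x$form_A$length,
              paste(sprintf("%s=%d", names(x$junctions), x$junctions),
                    collapse = ", ")))
  invisible(x)
}

## Best contiguous (single-diagonal) match of a read against a circular
## reference: k-mer anchors on the doubled reference chained per diagonal.
## Returns the best orientation's span in doubled-reference coordinates
## and its matched-base score.
#' @keywords internal
best_span <- function(read, ref_seq, k = 16L) {
  ref2 <- paste0(ref_seq, ref_seq)
  one <- function(rd) {
    runs <- diagonal_runs(ref2, rd, k)
    if (!nrow(runs)) return(list(score = 0, lo = NA, hi = NA))
    d <- runs$i - runs$p
    best <- NULL
    for (dd in unique(d)) {
      r <- runs[d == dd, , drop = FALSE]
      sc <- sum(r$len)
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, lo = min(r$i), hi = max(r$i + r$len))
      }
    }
    best
  }
  fw <- one(read)
  rv <- one(revcomp(read))
  if (fw$score >= rv$score) c(fw, orientation = "+") else c(rv, orientation = "-")
}

#' @keywords internal
span_covers <- function(span, pos, flank, n) {
  if (is.na(span$lo)) return(FALSE)
  for (p in c(pos, pos + n)) {
    if (span$lo <= p - flank && span$hi >= p + flank) return(TRUE)
  }
  FALSE
}

#' Classify one long read between the two structural forms
#'
#' The read (or its reverse complement) is matched against each form as a
#' single contiguous diagonal of exact k-mer anchors. A read is assigned
#' to a form when (i) its best match spans an informative junction
#' (IRa/SSC or SSC/IRb; the LSC junctions are identical between forms)
#' with at least `min_flank` matched context on each side, and (ii) its
#' matched-base score exceeds the other form's by at least `min_margin`.
#' Reads shorter than `min_read_len` are ambiguous by definition. Because
#' each IR-SSC junction is locally the reverse complement of the other
#' form's opposite junction, the margin criterion is what anchors the call
#' to the LSC context; informative reads must therefore span a full IR
#' copy.
#'
#' @param read read sequence (string)
#' @param pair a [build_structure_pair()] result
#' @param min_read_len reads below this length are ambiguous (30 kb for
#'   real plastomes, where the IR is ~26 kb)
#' @param min_flank required matched context on each side of the junction
#' @param min_margin required matched-base score margin over the rival form
#' @param k anchor k-mer size
#' @param read_id identifier carried into the result
#' @return one-row data.frame: `read_id`, `length`, `assignment`
#'   ("A", "B" or "ambiguous"), `junctions_spanned`, `score_margin`
#' @export
classify_read <- function(read, pair, min_read_len = 30000L,
                          min_flank = 1000L, min_margin = 50L, k = 16L,
                          read_id = NA_character_) {
  len <- nchar(read)
  res <- data.frame(read_id = read_id, length = len,
                    assignment = "ambiguous", junctions_spanned = "",
                    score_margin = 0)
  if (len < min_read_len) return(res)
  n <- pair$form_A$length
  inf_j <- pair$junctions[c("IRa/SSC", "SSC/IRb")]
  spans <- list()
  scores <- c(A = 0, B = 0)
  for (f in c("A", "B")) {
    sp <- best_span(read, pair[[paste0("form_", f)]]$seq, k = k)
    jn <- names(inf_j)[vapply(inf_j, function(p) {
      span_covers(sp, p, min_flank, n)
    }, logical(1))]
    spans[[f]] <- jn
    scores[[f]] <- sp$score
  }
  margin <- abs(scores[["A"]] - scores[["B"]])
  winner <- if (scores[["A"]] >= scores[["B"]]) "A" else "B"
  if (length(spans[[winner]]) && margin >= min_margin) {
    res$assignment <- winner
    res$junctions_spanned <- paste(spans[[winner]], collapse = ",")
    res$score_margin <- margin
  }
  res
}

#' Count haplotype support over a read set
#'
#' Classifies every read and reports support counts for the two forms,
#' the ambiguous count, and a two-sided exact binomial test of the
#' assigned counts against the equimolar 50:50 expectation.
#'
#' @param reads named character vector of read sequences
#' @param pair a [build_structure_pair()] result
#' @param ... passed to [classify_read()]
#' @return list with `counts` (named n_A/n_B/n_ambiguous), `p_value`, and
#'   `per_read` (data.frame)
#' @export
count_support <- function(reads, pair, ...) {
  per <- do.call(rbind, lapply(seq_along(reads), function(i) {
    classify_read(reads[[i]], pair, ...,
                  read_id = names(reads)[i] %||% sprintf("read%d", i))
  }))
  if (is.null(per)) {
    per <- data.frame(read_id = character(), length = integer(),
                      assignment = character(), junctions_spanned = character(),
                      score_margin = numeric())
  }
  nA <- sum(per$assignment == "A"); nB <- sum(per$assignment == "B")
  pv <- if (nA + nB > 0) binom.test(nA, nA + nB, 0.5)$p.value else NA_real_
  list(counts = c(n_A = nA, n_B = nB,
                  n_ambiguous = sum(per$assignment == "ambiguous")),
       p_value = pv, per_read = per)
}

#' Screen reads for the circular-LSC junction
#'
#' Builds the diagnostic query LSC-end + LSC-start and reports reads whose
#' best contiguous match spans the end-to-start junction with `flank`
#' matched context on both sides. Reads matching only one part, or
#' matching both parts in the normal genome arrangement (different
#' diagonals), are excluded.
#'
#' @param reads named character vector of read sequences
#' @param genome a [plastome()] or DNA string
#' @param partition its `quadripartite_partition`
#' @param end_len bp taken from the LSC end
#' @param start_len bp taken from the LSC start (the classic screen used
#'   a 2371 bp combined query)
#' @param flank required matched context on each side of the junction
#' @param k anchor k-mer size
#' @return data.frame `read_id`, `score` for junction-spanning reads
#' @export
detect_circular_lsc <- function(reads, genome, partition,
                                end_len = 1000L, start_len = 1371L,
                                flank = 200L, k = 16L) {
  rot <- rotate_to_lsc(genome, partition)
  L <- rot$partition$lsc[2]
  stopifnot(end_len <= L, start_len <= L)
  lsc <- substr(rot$genome$seq, 1L, L)
  query <- paste0(substr(lsc, L - end_len + 1L, L), substr(lsc, 1L, start_len))
  j <- end_len
  hits <- NULL
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    one <- function(x) {
      runs <- diagonal_runs(query, x, k)
      if (!nrow(runs)) return(NULL)
      d <- runs$i - runs$p
      best <- NULL
      for (dd in unique(d)) {
        r <- runs[d == dd, , drop = FALSE]
        sc <- sum(r$len)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, lo = min(r$i), hi = max(r$i + r$len))
      }
      best
    }
    sp <- one(rd); spr <- one(revcomp(rd))
    if (!is.null(spr) && (is.null(sp) || spr$score > sp$score)) sp <- spr
    if (!is.null(sp) && sp$lo <= j - flank && sp$hi >= j + flank) {
      hits <- rbind(hits, data.frame(
        read_id = names(reads)[i] %||% sprintf("read%d", i),
        score = sp$score))
    }
  }
  if (is.null(hits)) data.frame(read_id = character(), score = numeric())
  else hits
}
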