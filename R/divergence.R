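## Pairwise divergence from a whole-genome alignment: SNP/indel calling,
## sliding-window variability and low-identity region detection.

#' Construct a pairwise alignment object
#'
#' @param ref,qry equal-length gapped DNA strings ("-" for gaps)
#' @param ref_id,qry_id sequence identifiers
#' @return a `pairwise_alignment` object
#' @export
pairwise_alignment <- function(ref, qry, ref_id = "ref", qry_id = "qry") {
  ref <- toupper(ref); qry <- toupper(qry)
  if (nchar(ref) != nchar(qry)) stop("gapped lengths differ")
  r <- seq_chars(ref); q <- seq_chars(qry)
  if (any(r == "-" & q == "-")) stop("column gapped in both rows")
  structure(list(ref_id = ref_id, qry_id = qry_id, ref = ref, qry = qry,
                 length = nchar(ref)),
            class = "pairwise_alignment")
}

#' Read a pairwise alignment from aligned FASTA
#'
#' @param path aligned FASTA with exactly two records (reference first)
#' @return a `pairwise_alignment`
#' @export
read_pairwise_alignment <- function(path) {
  x <- read_seqs(path)
  if (length(x) != 2L) stop("aligned FASTA must contain exactly two records")
  pairwise_alignment(x[[1L]], x[[2L]],
                     ref_id = names(x)[1L], qry_id = names(x)[2L])
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise alignment> %s vs %s: %d columns\n",
              x$ref_id, x$qry_id, x$length))
  invisible(x)
}

## per-column ref coordinate (0-based; NA on ref-gap columns)
#' @keywords internal
aln_ref_pos <- function(r) {
  pos <- cumsum(r != "-") - 1L
  pos[r == "-"] <- NA_integer_
  pos
}

#' Call SNPs and indels from a pairwise alignment
#'
#' Every column where both rows carry different unambiguous bases is one
#' SNP; every maximal single-row gap run is one indel event (adjacent gap
#' columns merge). Columns carrying ambiguity codes are excluded from SNP
#' calling and counted in `excluded_columns`. Indel events report the
#' 0-based reference coordinate of the first deleted base (deletions) or
#' of the reference base following the inserted block (insertions).
#'
#' @param aln a [pairwise_alignment()]
#' @param partition optional `quadripartite_partition` in reference
#'   coordinates; when given a second tally excluding variants inside IRb
#'   is reported, since the duplicated IR can be counted as one or two
#'   regions
#' @return list with `variants` (data.frame type/ref_pos/ref_allele/
#'   alt_allele), `n_snps`, `n_indels`, `excluded_columns`, and (with a
#'   partition) `n_snps_irb_masked` / `n_indels_irb_masked`
#' @export
call_snps_indels <- function(aln, partition = NULL) {
  r <- seq_chars(aln$ref); q <- seq_chars(aln$qry)
  rp <- aln_ref_pos(r)
  base_r <- r %in% DNA_BASES; base_q <- q %in% DNA_BASES
  ambig <- (!base_r & r != "-") | (!base_q & q != "-")
  n_ambig <- sum(ambig)
  if (n_ambig) message(n_ambig, " column(s) with ambiguity codes excluded")

  snp <- which(base_r & base_q & r != q & !ambig)
  variants <- if (length(snp)) {
    data.frame(type = "SNP", ref_pos = rp[snp],
               ref_allele = r[snp], alt_allele = q[snp])
  } else NULL

  gap_events <- function(is_gap, row) {
    rl <- rle(is_gap)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    out <- NULL
    for (j in which(rl$values)) {
      cols <- starts[j]:ends[j]
      if (row == "qry") {                      # deletion from the reference
        out <- rbind(out, data.frame(
          type = "indel", ref_pos = rp[starts[j]],
          ref_allele = paste(r[cols], collapse = ""), alt_allele = "-"))
      } else {                                 # insertion in the query
        nxt <- if (ends[j] < length(r)) rp[ends[j] + 1L] else NA_integer_
        out <- rbind(out, data.frame(
          type = "indel",
          ref_pos = if (is.na(nxt)) sum(r != "-") else nxt,
          ref_allele = "-", alt_allele = paste(q[cols], collapse = "")))
      }
    }
    out
  }
  variants <- rbind(variants, gap_events(q == "-", "qry"),
                    gap_events(r == "-", "ref"))
  if (is.null(variants)) {
    variants <- data.frame(type = character(), ref_pos = integer(),
                           ref_allele = character(), alt_allele = character())
  }
  variants <- variants[order(variants$ref_pos, variants$type), , drop = FALSE]
  rownames(variants) <- NULL
  res <- list(variants = variants,
              n_snps = sum(variants$type == "SNP"),
              n_indels = sum(variants$type == "indel"),
              excluded_columns = n_ambig)
  if (!is.null(partition)) {
    n <- partition$genome_length
    irb <- partition$irb
    in_irb <- ((variants$ref_pos - irb[1]) %% n) < irb[2]
    res$n_snps_irb_masked <- sum(variants$type == "SNP" & !in_irb)
    res$n_indels_irb_masked <- sum(variants$type == "indel" & !in_irb)
  }
  res
}

#' Sliding-window nucleotide divergence
#'
#' Per-window p-distance over gap-free unambiguous columns, in reference
#' coordinates (the DnaSP convention: gap columns are excluded from both
#' numerator and denominator). Windows with zero compared sites report
#' divergence `NA` and are flagged.
#'
#' @param aln a [pairwise_alignment()]
#' @param window window size in bp (reference scale)
#' @param step step size in bp; `window >= step >= 1`
#' @return data.frame `start`, `end` (0-based half-open, reference),
#'   `compared_sites`, `differences`, `divergence`, `undefined`
#' @export
sliding_divergence <- function(aln, window = 600L, step = 200L) {
  stopifnot(window >= step, step >= 1L)
  r <- seq_chars(aln$ref); q <- seq_chars(aln$qry)
  rp <- aln_ref_pos(r)
  ref_len <- sum(r != "-")
  comp <- diff_ <- integer(ref_len)                # per reference position
  on_ref <- !is.na(rp)
  cmp_col <- on_ref & q != "-" & r %in% DNA_BASES & q %in% DNA_BASES
  comp[rp[cmp_col] + 1L] <- 1L
  dif_col <- cmp_col & r != q
  diff_[rp[dif_col] + 1L] <- 1L

  if (ref_len < window) {
    message("window larger than alignment; using one whole-alignment window")
    starts <- 0L
    ends <- ref_len
  } else {
    starts <- seq.int(0L, ref_len - window, by = step)
    ends <- starts + window
  }
  ccum <- c(0L, cumsum(comp)); dcum <- c(0L, cumsum(diff_))
  cs <- ccum[ends + 1L] - ccum[starts + 1L]
  ds <- dcum[ends + 1L] - dcum[starts + 1L]
  data.frame(start = starts, end = ends, compared_sites = cs,
             differences = ds,
             divergence = ifelse(cs > 0L, ds / cs, NA_real_),
             undefined = cs == 0L)
}

#' Detect low-identity regions
#'
#' Windowed identity in the mVISTA convention: gap characters count as
#' mismatches (insertions in the query are charged to the reference
#' position following them). Maximal runs of consecutive windows with
#' identity below the threshold are merged and reported as reference
#' intervals.
#'
#' @param aln a [pairwise_alignment()]
#' @param window window size in bp (reference scale)
#' @param step window step in bp
#' @param identity_threshold windows with identity strictly below this are
#'   reported
#' @return data.frame `start`, `end` (0-based half-open reference
#'   intervals), `min_identity`
#' @export
low_identity_regions <- function(aln, window = 600L, step = 200L,
                                 identity_threshold = 0.5) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  r <- seq_chars(aln$ref); q <- seq_chars(aln$qry)
  rp <- aln_ref_pos(r)
  ref_len <- sum(r != "-")
  match_ <- ins <- integer(ref_len)
  on_ref <- !is.na(rp)
  m_col <- on_ref & r == q & r %in% DNA_BASES
  match_[rp[m_col] + 1L] <- 1L
  ## charge each query-insertion column to the next reference position
  gap_cols <- which(!on_ref)
  for (cc in gap_cols) {
    nxt <- if (cc < length(r)) rp[which(on_ref & seq_along(r) > cc)[1L]] else NA
    at <- if (is.na(nxt)) ref_len else nxt + 1L
    ins[min(at, ref_len)] <- ins[min(at, ref_len)] + 1L
  }
  if (ref_len < window) { starts <- 0L; ends <- ref_len }
  else {
    starts <- seq.int(0L, ref_len - window, by = step)
    ends <- starts + window
  }
  mcum <- c(0L, cumsum(match_)); icum <- c(0L, cumsum(ins))
  ms <- mcum[ends + 1L] - mcum[starts + 1L]
  is_ <- icum[ends + 1L] - icum[starts + 1L]
  ident <- ms / ((ends - starts) + is_)
  low <- ident < identity_threshold
  if (!any(low)) {
    return(data.frame(start = integer(), end = integer(),
                      min_identity = numeric()))
  }
  ## merge overlapping/adjacent low windows
  lo <- starts[low]; hi <- ends[low]; idv <- ident[low]
  out <- NULL
  cur_s <- lo[1L]; cur_e <- hi[1L]; cur_m <- idv[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= cur_e) {
      cur_e <- max(cur_e, hi[i]); cur_m <- min(cur_m, idv[i])
    } else {
      out <- rbind(out, data.frame(start = cur_s, end = cur_e,
                                   min_identity = cur_m))
      cur_s <- lo[i]; cur_e <- hi[i]; cur_m <- idv[i]
    }
  }
  rbind(out, data.frame(start = cur_s, end = cur_e, min_identity = cur_m))
}
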