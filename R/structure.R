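## Quadripartite structure: inverted-repeat detection, circle partition,
## junction genes and GC content by annotation class.

#' Detect the inverted-repeat pair and partition a plastome
#'
#' Finds the maximal-length pair of disjoint intervals on the circular
#' genome whose sequences are reverse complements of each other (within
#' `max_mismatch` substitutions), then partitions the circle into
#' LSC / IRa / SSC / IRb. The large single-copy region (LSC) is the longer
#' of the two single-copy arcs; IRa is the inverted-repeat copy immediately
#' downstream of the LSC, so the circle reads LSC, IRa, SSC, IRb.
#'
#' Detection is exact-match seed-and-extend on k-mers shared between the
#' forward strand and the reverse complement, chained along diagonals;
#' plastid IRs are near-perfect copies, so `max_mismatch = 0` is the
#' default. The input may start anywhere on the circle.
#'
#' @param genome a [plastome()] or DNA string
#' @param min_ir_len minimum acceptable IR length in bp
#' @param max_mismatch maximum substitutions tolerated between the two
#'   IR copies (gaps are never tolerated)
#' @return a `quadripartite_partition`: list with 0-based half-open
#'   circular intervals `lsc`, `ira`, `ssc`, `irb` (each `c(start, len)`),
#'   `ir_len`, `mismatch_count` and `genome_length`
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 1000L,
                                    max_mismatch = 0L) {
  g <- as_plastome(genome)
  s <- g$seq
  n <- g$length
  k <- max(4L, min(as.integer(min_ir_len), 12L))
  S2 <- paste0(s, s)
  B2 <- paste0(revcomp(s), revcomp(s))
  runs <- diagonal_runs(S2, B2, k)
  runs <- runs[runs$i < n & runs$p < n, , drop = FALSE]
  runs$len <- pmin(runs$len, n)
  runs <- merge_runs_with_mismatches(runs, max_mismatch)

  cand <- NULL
  if (nrow(runs)) {
    a1 <- runs$i %% n
    a2 <- (n - (runs$p %% n) - runs$len) %% n
    cand <- data.frame(a1 = a1, a2 = a2, len = runs$len)
    ## canonicalise the unordered pair and drop duplicates / self matches
    swap <- cand$a2 < cand$a1
    tmp <- cand$a1[swap]; cand$a1[swap] <- cand$a2[swap]; cand$a2[swap] <- tmp
    cand <- unique(cand)
    cand <- cand[cand$a1 != cand$a2, , drop = FALSE]
    ## the two intervals must be disjoint on the circle
    disj <- (cand$a2 - cand$a1) %% n >= cand$len &
            (cand$a1 - cand$a2) %% n >= cand$len
    cand <- cand[disj, , drop = FALSE]
    cand <- cand[order(-cand$len, cand$a1), , drop = FALSE]
  }

  if (is.null(cand) || nrow(cand) == 0L || cand$len[1L] < min_ir_len) {
    best <- if (!is.null(cand) && nrow(cand)) cand[1L, ] else NULL
    msg <- if (is.null(best)) {
      sprintf("no inverted repeat of length >= %d found (no candidate)", min_ir_len)
    } else {
      sprintf("no inverted repeat of length >= %d found (best candidate: %d bp at [%d, %d))",
              min_ir_len, best$len, best$a1, best$a1 + best$len)
    }
    stop(structure(class = c("plastcomp_no_ir", "error", "condition"),
                   list(message = msg, call = sys.call(-1), best = best)))
  }

  hit <- cand[1L, ]
  L <- hit$len
  end1 <- (hit$a1 + L) %% n
  end2 <- (hit$a2 + L) %% n
  arc1 <- (hit$a2 - end1) %% n          # single-copy arc after interval 1
  arc2 <- (hit$a1 - end2) %% n          # single-copy arc after interval 2
  if (arc1 >= arc2) {
    lsc <- c(end1, arc1); ira <- c(hit$a2, L)
    ssc <- c(end2, arc2); irb <- c(hit$a1, L)
  } else {
    lsc <- c(end2, arc2); ira <- c(hit$a1, L)
    ssc <- c(end1, arc1); irb <- c(hit$a2, L)
  }
  mm <- count_mismatches(revcomp(circ_substr(s, ira[1], L)),
                         circ_substr(s, irb[1], L))
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 ir_len = L, mismatch_count = mm, genome_length = n),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf("<quadripartite partition> genome %d bp\n", x$genome_length))
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- x[[r]]
    cat(sprintf("  %-4s %7d bp  [%d, %d) (0-based, circular)\n",
                toupper(r), iv[2], iv[1], iv[1] + iv[2]))
  }
  cat(sprintf("  IR copies differ at %d position(s)\n", x$mismatch_count))
  invisible(x)
}

#' Region sizes of a partition
#' @param partition a `quadripartite_partition`
#' @return named integer vector `c(lsc, ira, ssc, irb)`
#' @export
partition_sizes <- function(partition) {
  c(lsc = partition$lsc[2], ira = partition$ira[2],
    ssc = partition$ssc[2], irb = partition$irb[2])
}

## Boundary positions (0-based, circular), in circle order.
#' @keywords internal
partition_boundaries <- function(partition) {
  n <- partition$genome_length
  c("LSC/IRa" = (partition$lsc[1] + partition$lsc[2]) %% n,
    "IRa/SSC" = (partition$ira[1] + partition$ira[2]) %% n,
    "SSC/IRb" = (partition$ssc[1] + partition$ssc[2]) %% n,
    "IRb/LSC" = (partition$irb[1] + partition$irb[2]) %% n)
}

#' Rotate a genome so that the circle starts at the LSC start
#'
#' @param genome a [plastome()] or DNA string
#' @param partition its `quadripartite_partition`
#' @return a list with the rotated `genome` (a [plastome()]), the updated
#'   `partition`, and `offset`, the 0-based position of the old origin of
#'   the rotation
#' @export
rotate_to_lsc <- function(genome, partition) {
  g <- as_plastome(genome)
  n <- g$length
  off <- partition$lsc[1]
  rot <- plastome(circ_substr(g$seq, off, n), id = g$id)
  shift <- function(iv) c((iv[1] - off) %% n, iv[2])
  part <- structure(list(lsc = shift(partition$lsc), ira = shift(partition$ira),
                         ssc = shift(partition$ssc), irb = shift(partition$irb),
                         ir_len = partition$ir_len,
                         mismatch_count = partition$mismatch_count,
                         genome_length = n),
                    class = "quadripartite_partition")
  list(genome = rot, partition = part, offset = off)
}

#' Write a partition as a 4-record BED file
#'
#' Regions wrapping the circular origin are written as two blocks of one
#' BED record using the thickStart-free 4-column form split at the origin.
#'
#' @param partition a `quadripartite_partition`
#' @param path output BED path
#' @param seqid sequence name for column 1
#' @return `path`, invisibly
#' @export
write_partition_bed <- function(partition, path, seqid = "plastome") {
  n <- partition$genome_length
  rows <- list()
  for (r in c("lsc", "ira", "ssc", "irb")) {
    iv <- partition[[r]]
    if (iv[1] + iv[2] <= n) {
      rows[[length(rows) + 1L]] <- data.frame(chrom = seqid, start = iv[1],
                                              end = iv[1] + iv[2],
                                              name = toupper(r))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(chrom = seqid, start = iv[1],
                                              end = n, name = toupper(r))
      rows[[length(rows) + 1L]] <- data.frame(chrom = seqid, start = 0L,
                                              end = iv[1] + iv[2] - n,
                                              name = toupper(r))
    }
  }
  rows <- do.call(rbind, rows)
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genes spanning quadripartite junctions
#'
#' Reports every gene whose span (first to last exon, circularly) strictly
#' contains a partition boundary; genes lying entirely inside one region
#' are excluded.
#'
#' @param partition a `quadripartite_partition`
#' @param features a feature table (see [feature_table()])
#' @return data.frame with columns `gene`, `junction`, `boundary_pos`
#'   (0-based)
#' @export
junction_spanning_genes <- function(partition, features) {
  out <- data.frame(gene = character(), junction = character(),
                    boundary_pos = integer())
  if (is.null(features) || nrow(features) == 0L) return(out)
  n <- partition$genome_length
  bnd <- partition_boundaries(partition)
  sp <- gene_spans(features)
  for (i in seq_len(nrow(sp))) {
    for (j in seq_along(bnd)) {
      b <- bnd[j]
      if ((sp$start[i] < b && b < sp$end[i]) ||
          (sp$start[i] < b + n && b + n < sp$end[i])) {
        out <- rbind(out, data.frame(gene = sp$name[i],
                                     junction = names(bnd)[j],
                                     boundary_pos = unname(b)))
      }
    }
  }
  out
}

#' GC content by annotation class and by region
#'
#' Every genome position is assigned one class with priority
#' exon > intron > UTR > intergenic. Introns are the gaps between exons of
#' a gene; the UTR class is a fixed window of `utr_len` bp on each side of
#' every gene span (the operational UTR definition is a parameter because
#' plastome annotations rarely delimit UTRs). The whole-genome GC equals
#' the class-size-weighted mean of class GC values by construction.
#'
#' @param genome a [plastome()] or DNA string
#' @param features a feature table
#' @param partition optional `quadripartite_partition`; when given,
#'   per-region GC rows (LSC/IRa/SSC/IRb) are appended
#' @param utr_len UTR window in bp on each side of a gene span
#' @return data.frame with columns `class`, `length`, `gc`
#' @export
gc_by_feature_class <- function(genome, features, partition = NULL,
                                utr_len = 50L) {
  g <- as_plastome(genome)
  n <- g$length
  ch <- seq_chars(g$seq)
  cls <- rep("intergenic", n)

  mark <- function(cls, start, end, label) {  # 0-based half-open, circular
    if (end <= start) return(cls)
    pos <- (seq.int(start, end - 1L) %% n) + 1L
    cls[pos] <- label
    cls
  }
  if (!is.null(features) && nrow(features)) {
    sp <- gene_spans(features)
    for (i in seq_len(nrow(sp))) {
      cls <- mark(cls, sp$start[i] - utr_len, sp$start[i], "UTR")
      cls <- mark(cls, sp$end[i], sp$end[i] + utr_len, "UTR")
    }
    for (nm in unique(features$name)) {
      ex <- features[features$name == nm, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L) {
        for (i in seq_len(nrow(ex) - 1L))
          cls <- mark(cls, ex$end[i], ex$start[i + 1L], "intron")
      }
    }
    for (i in seq_len(nrow(features)))
      cls <- mark(cls, features$start[i], features$end[i], "exon")
  }

  gcv <- ch %in% c("G", "C")
  lvl <- c("exon", "intron", "UTR", "intergenic")
  out <- do.call(rbind, lapply(lvl, function(l) {
    sel <- cls == l
    data.frame(class = l, length = sum(sel),
               gc = if (any(sel)) mean(gcv[sel]) else NA_real_)
  }))
  out <- rbind(out, data.frame(class = "whole", length = n, gc = mean(gcv)))
  if (!is.null(partition)) {
    for (r in c("lsc", "ira", "ssc", "irb")) {
      iv <- partition[[r]]
      pos <- (seq.int(iv[1], iv[1] + iv[2] - 1L) %% n) + 1L
      out <- rbind(out, data.frame(class = toupper(r), length = iv[2],
                                   gc = mean(gcv[pos])))
    }
  }
  rownames(out) <- NULL
  out
}
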