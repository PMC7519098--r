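## Indel cladistics over a labelled multiple alignment: shared-gap indel
## events, group (genus) specificity, and group-specific SNPs.

#' Construct a labelled multiple alignment
#'
#' @param seqs named character vector of equal-length gapped sequences
#' @param labels named character vector: group (e.g. genus) per sequence
#'   id; ids absent from `labels` (e.g. an outgroup) are allowed
#' @param outgroup optional sequence id used to polarise events
#' @return a `labeled_alignment` object
#' @export
labeled_alignment <- function(seqs, labels, outgroup = NULL) {
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L) stop("gapped lengths differ")
  if (!is.null(outgroup) && !outgroup %in% names(seqs))
    stop("outgroup not among sequences")
  ingroup <- setdiff(names(seqs), outgroup)
  miss <- setdiff(ingroup, names(labels))
  if (length(miss)) stop("no group label for: ", paste(miss, collapse = ", "))
  if (length(unique(labels[ingroup])) < 2L) stop("need at least two groups")
  structure(list(seqs = seqs, labels = labels[ingroup],
                 outgroup = outgroup, width = nchar(seqs[[1L]])),
            class = "labeled_alignment")
}

#' @keywords internal
aln_char_matrix <- function(msa) {
  do.call(rbind, lapply(msa$seqs, seq_chars))
}

#' Extract shared-indel events from a labelled alignment
#'
#' An event is a maximal gap block with identical start and end columns
#' across all its gap carriers; overlapping blocks with different extents
#' are distinct events. Polarity is assigned against the outgroup when
#' given (gap where the outgroup has bases = deletion; bases where the
#' outgroup has a gap = insertion), else against the majority state. The
#' event's carrier set is the set of sequences in the derived state.
#'
#' @param msa a [labeled_alignment()]
#' @return data.frame `start`, `end` (0-based half-open columns),
#'   `polarity`, `carriers` (comma-joined ids, outgroup excluded),
#'   `specific_to` (filled by [group_specific_events()], NA here)
#' @export
extract_indel_events <- function(msa) {
  M <- aln_char_matrix(msa)
  if (any(colSums(M != "-") == 0L)) stop("alignment has an all-gap column")
  ids <- rownames(M)
  blocks <- NULL
  for (i in seq_len(nrow(M))) {
    rl <- rle(M[i, ] == "-")
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    for (j in which(rl$values)) {
      blocks <- rbind(blocks, data.frame(id = ids[i],
                                         start = starts[j] - 1L,
                                         end = ends[j]))
    }
  }
  if (is.null(blocks)) {
    return(data.frame(start = integer(), end = integer(),
                      polarity = character(), carriers = character(),
                      specific_to = character()))
  }
  out <- NULL
  for (key in unique(paste(blocks$start, blocks$end))) {
    b <- blocks[paste(blocks$start, blocks$end) == key, , drop = FALSE]
    s <- b$start[1L]; e <- b$end[1L]
    gap_set <- b$id
    ## sequences with no gap anywhere in the block
    base_set <- ids[apply(M[, (s + 1L):e, drop = FALSE] != "-", 1L, all)]
    ref_state <- if (!is.null(msa$outgroup)) {
      if (msa$outgroup %in% gap_set) "gap"
      else if (msa$outgroup %in% base_set) "base"
      else "mixed"
    } else if (length(gap_set) > length(base_set)) "gap" else "base"
    if (ref_state == "mixed") next      # outgroup partially gapped: unpolarised
    if (ref_state == "base") {
      polarity <- "deletion"; carriers <- setdiff(gap_set, msa$outgroup)
    } else {
      polarity <- "insertion"; carriers <- setdiff(base_set, msa$outgroup)
    }
    if (!length(carriers)) next
    out <- rbind(out, data.frame(start = s, end = e, polarity = polarity,
                                 carriers = paste(sort(carriers), collapse = ","),
                                 specific_to = NA_character_))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-specific indel events
#'
#' An event is specific to a group when its carrier set equals exactly
#' that group's full member set (strict definition: an event carried by a
#' subset of a group, or shared across groups, is specific to none).
#'
#' @param events output of [extract_indel_events()]
#' @param msa the [labeled_alignment()] the events came from
#' @return list with `events` (the input with `specific_to` filled) and
#'   `table` (per-group insertion/deletion counts)
#' @export
group_specific_events <- function(events, msa) {
  groups <- split(names(msa$labels), msa$labels)
  for (i in seq_len(nrow(events))) {
    carriers <- sort(strsplit(events$carriers[i], ",")[[1L]])
    for (gname in names(groups)) {
      if (identical(carriers, sort(groups[[gname]]))) {
        events$specific_to[i] <- gname
        break
      }
    }
  }
  tab <- do.call(rbind, lapply(names(groups), function(gname) {
    sel <- !is.na(events$specific_to) & events$specific_to == gname
    data.frame(group = gname,
               insertions = sum(sel & events$polarity == "insertion"),
               deletions = sum(sel & events$polarity == "deletion"))
  }))
  list(events = events, table = tab)
}

#' Group-specific SNPs
#'
#' Substitution columns whose derived base is carried by exactly one full
#' group. The derived state is the base differing from the outgroup when
#' one is given, else any minority base. Columns with gaps are the domain
#' of the indel analysis and are skipped here.
#'
#' @param msa a [labeled_alignment()]
#' @return data.frame `column` (0-based), `base`, `group`
#' @export
group_specific_snps <- function(msa) {
  M <- aln_char_matrix(msa)
  ingroup <- names(msa$labels)
  groups <- split(ingroup, msa$labels)
  out <- NULL
  for (cc in seq_len(ncol(M))) {
    col <- M[, cc]
    if (any(col == "-") || any(!col %in% DNA_BASES)) next
    states <- unique(col[ingroup])
    if (length(states) < 2L) next
    derived <- if (!is.null(msa$outgroup)) {
      setdiff(states, col[msa$outgroup])
    } else {
      tb <- table(col[ingroup])
      names(tb)[tb < max(tb)]
    }
    for (st in derived) {
      carriers <- sort(ingroup[col[ingroup] == st])
      for (gname in names(groups)) {
        if (identical(carriers, sort(groups[[gname]]))) {
          out <- rbind(out, data.frame(column = cc - 1L, base = st,
                                       group = gname))
        }
      }
    }
  }
  if (is.null(out)) data.frame(column = integer(), base = character(),
                               group = character())
  else out
}

#' Terminal conservation of an alignment
#'
#' Mean pairwise identity (gaps count as mismatches) in the 5-prime and
#' 3-prime terminal column windows, the regions conserved enough for
#' cross-species primer design.
#'
#' @param msa a [labeled_alignment()]
#' @param five_prime number of leading columns
#' @param three_prime number of trailing columns
#' @return named numeric vector `c(five_prime, three_prime)`
#' @export
terminal_conservation <- function(msa, five_prime = 605L, three_prime = 100L) {
  M <- aln_char_matrix(msa)
  pid <- function(cols) {
    sub <- M[, cols, drop = FALSE]
    pr <- utils::combn(nrow(sub), 2L)
    mean(vapply(seq_len(ncol(pr)), function(i) {
      a <- sub[pr[1L, i], ]; b <- sub[pr[2L, i], ]
      mean(a == b & a != "-")
    }, numeric(1)))
  }
  w <- ncol(M)
  c(five_prime = pid(seq_len(min(five_prime, w))),
    three_prime = pid(seq.int(max(1L, w - three_prime + 1L), w)))
}
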