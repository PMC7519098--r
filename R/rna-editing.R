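## C-to-U RNA editing: hard-filter candidate evidence, consensus across
## replicates, per-site efficiency from DP4 counts, and codon-effect
## annotation.
##
## Site evidence is a data.frame with one row per (position, replicate):
## position (0-based), ref, alt, replicate, quality, depth, and the DP4
## counts ref_fwd, ref_rev, alt_fwd, alt_rev.

#' Filter candidate editing evidence
#'
#' Retains single-nucleotide records with `quality >= min_quality`, depth
#' strictly greater than `min_depth` (the conventional variant-calling
#' filters; set `strict_depth = FALSE` for an inclusive depth cut), and a
#' C-to-T change on the forward strand or G-to-A on the reverse, both of
#' which encode C-to-U in transcript orientation. Non-SNV records are
#' dropped with a message.
#'
#' @param evidence site-evidence data.frame
#' @param min_quality minimum phred quality (inclusive)
#' @param min_depth depth cut (exclusive by default)
#' @param strict_depth if TRUE keep `depth > min_depth`, else `>=`
#' @return the filtered evidence data.frame
#' @export
filter_candidates <- function(evidence, min_quality = 20, min_depth = 10,
                              strict_depth = TRUE) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(evidence)
  snv <- nchar(evidence$ref) == 1L & nchar(evidence$alt) == 1L &
         evidence$ref %in% DNA_BASES & evidence$alt %in% DNA_BASES
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) dropped")
  ev <- evidence[snv, , drop = FALSE]
  deep <- if (strict_depth) ev$depth > min_depth else ev$depth >= min_depth
  ctu <- (ev$ref == "C" & ev$alt == "T") | (ev$ref == "G" & ev$alt == "A")
  ev[ev$quality >= min_quality & deep & ctu, , drop = FALSE]
}

#' Editing efficiency from DP4 counts
#'
#' Edited reads divided by total mapped reads at the site:
#' `(alt_fwd + alt_rev) / (ref_fwd + ref_rev + alt_fwd + alt_rev)`.
#'
#' @param dp4 numeric vector `c(ref_fwd, ref_rev, alt_fwd, alt_rev)` or a
#'   4-column matrix of such rows
#' @return efficiency in \[0,1\] (NA with a warning for zero totals)
#' @export
editing_efficiency <- function(dp4) {
  if (is.matrix(dp4) || is.data.frame(dp4)) {
    dp4 <- as.matrix(dp4)
    tot <- rowSums(dp4)
    out <- ifelse(tot > 0, (dp4[, 3L] + dp4[, 4L]) / tot, NA_real_)
    if (anyNA(out)) warning("zero-depth site(s): efficiency undefined")
    return(unname(out))
  }
  tot <- sum(dp4)
  if (tot == 0) { warning("zero-depth site: efficiency undefined"); return(NA_real_) }
  (dp4[3L] + dp4[4L]) / tot
}

#' Consensus editing sites across replicates
#'
#' A site becomes an editing call when it passes the filters in at least
#' `min_replicates` replicates. Efficiency is aggregated both as the
#' unweighted mean of per-replicate efficiencies (the primary value) and
#' as the depth-weighted pooled ratio.
#'
#' @param evidence filtered site-evidence data.frame (see
#'   [filter_candidates()])
#' @param min_replicates minimum number of supporting replicates
#' @return data.frame with `position`, `ref`, `alt`,
#'   `supporting_replicates`, `mean_efficiency`, `weighted_efficiency`;
#'   per-replicate efficiencies are attached as the `per_replicate`
#'   attribute
#' @export
consensus_sites <- function(evidence, min_replicates = 2L) {
  empty <- data.frame(position = integer(), ref = character(),
                      alt = character(), supporting_replicates = integer(),
                      mean_efficiency = numeric(),
                      weighted_efficiency = numeric())
  if (is.null(evidence) || nrow(evidence) == 0L) return(empty)
  key <- paste(evidence$position, evidence$replicate)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate evidence for (position, replicate) = (", d, ")")
  }
  per <- list()
  rows <- NULL
  for (pos in sort(unique(evidence$position))) {
    ev <- evidence[evidence$position == pos, , drop = FALSE]
    if (nrow(ev) < min_replicates) next
    effs <- editing_efficiency(ev[, c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")])
    rows <- rbind(rows, data.frame(
      position = pos, ref = ev$ref[1L], alt = ev$alt[1L],
      supporting_replicates = nrow(ev),
      mean_efficiency = mean(effs),
      weighted_efficiency = sum(ev$alt_fwd + ev$alt_rev) /
        sum(ev$ref_fwd + ev$ref_rev + ev$alt_fwd + ev$alt_rev)))
    per[[as.character(pos)]] <- setNames(effs, ev$replicate)
  }
  out <- if (is.null(rows)) empty else rows
  attr(out, "per_replicate") <- per
  out
}

#' Annotate codon effects of editing sites
#'
#' Each genic site is labelled with its codon position (strand-aware), the
#' reference and edited codons and amino acids, a synonymous flag, and a
#' polarity-change flag (polar to nonpolar); intergenic sites are labelled
#' as such. Sites in overlapping genes yield one row per gene.
#'
#' @param sites consensus site data.frame (needs a `position` column)
#' @param genome a [plastome()] or DNA string
#' @param features feature table of CDS genes (exon rows)
#' @return data.frame: one row per (site, overlapping gene or intergenic)
#' @export
annotate_codon_effect <- function(sites, genome, features) {
  g <- as_plastome(genome)
  n <- g$length
  code <- plastid_code()
  nonpolar <- c("A", "V", "L", "I", "P", "F", "W", "M", "G")
  sp <- if (!is.null(features) && nrow(features)) unique(features$name) else character()
  out <- NULL
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    hit <- FALSE
    for (nm in sp) {
      ex <- features[features$name == nm & features$type == "CDS", , drop = FALSE]
      if (!nrow(ex)) next
      ex <- ex[order(ex$start), , drop = FALSE]
      contains <- (pos >= ex$start & pos < ex$end) |
                  (pos + n >= ex$start & pos + n < ex$end)
      if (!any(contains)) next
      hit <- TRUE
      strand <- ex$strand[1L]
      ## CDS nucleotides in transcription order
      coords <- unlist(lapply(seq_len(nrow(ex)), function(j) {
        seq.int(ex$start[j], ex$end[j] - 1L) %% n
      }))
      if (strand == "-") coords <- rev(coords)
      cds_chars <- seq_chars(g$seq)[coords + 1L]
      if (strand == "-") cds_chars <- dna_complement(cds_chars)
      off <- which(coords == pos %% n) - 1L
      off <- off[1L]
      cp <- off %% 3L + 1L
      ci <- off %/% 3L
      cod_idx <- (ci * 3L + 1L):(ci * 3L + 3L)
      if (max(cod_idx) > length(cds_chars)) next
      ref_codon <- paste(cds_chars[cod_idx], collapse = "")
      edited <- cds_chars
      ## C-to-U reads as C>T on the gene's sense strand
      edited[off + 1L] <- "T"
      alt_codon <- paste(edited[cod_idx], collapse = "")
      aa_ref <- code[[ref_codon]] %||% NA_character_
      aa_alt <- code[[alt_codon]] %||% NA_character_
      out <- rbind(out, data.frame(
        position = pos, region = nm, strand = strand,
        codon_position = cp, ref_codon = ref_codon, alt_codon = alt_codon,
        aa_ref = aa_ref, aa_alt = aa_alt,
        synonymous = identical(aa_ref, aa_alt),
        aa_change = if (identical(aa_ref, aa_alt)) "none"
                    else paste0(aa_ref, ">", aa_alt),
        polarity_change = !identical(aa_ref, aa_alt) &&
          !(aa_ref %in% nonpolar) && (aa_alt %in% nonpolar)))
    }
    if (!hit) {
      out <- rbind(out, data.frame(
        position = pos, region = "intergenic", strand = NA_character_,
        codon_position = NA_integer_, ref_codon = NA_character_,
        alt_codon = NA_character_, aa_ref = NA_character_,
        aa_alt = NA_character_, synonymous = NA,
        aa_change = NA_character_, polarity_change = NA))
    }
  }
  if (is.null(out)) out <- data.frame()
  out
}

#' Summary of annotated editing sites
#'
#' @param annotated output of [annotate_codon_effect()]
#' @return list with the codon-position spectrum, the fraction of genic
#'   sites on serine codons, and the fraction of events producing leucine
#' @export
editing_summary <- function(annotated) {
  genic <- annotated[annotated$region != "intergenic", , drop = FALSE]
  spectrum <- table(factor(genic$codon_position, levels = 1:3))
  list(codon_position_spectrum = spectrum,
       frac_serine_codon = if (nrow(genic)) mean(genic$aa_ref == "S") else NA,
       frac_to_leucine = if (nrow(genic)) mean(genic$aa_alt == "L") else NA,
       n_genic = nrow(genic),
       n_intergenic = sum(annotated$region == "intergenic"))
}
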