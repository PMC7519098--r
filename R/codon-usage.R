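## Codon-usage statistics: RSCU, CAI, Wright's ENC, GC by codon position
## and the GC12-on-GC3 neutrality regression. Plastid genes are translated
## with the bacterial/plastid genetic code (translation table 11).

#' @keywords internal
plastid_code <- function() Biostrings::getGeneticCode("11")

## synonymous families: stops and single-codon families (Met, Trp) excluded
#' @keywords internal
syn_families <- function() {
  code <- plastid_code()
  fam <- split(names(code), code)
  fam <- fam[names(fam) != "*"]
  fam[lengths(fam) >= 2L]
}

#' @keywords internal
informative_codons <- function() sort(unlist(syn_families(), use.names = FALSE))

#' Count codons in coding sequences
#'
#' Counts are taken over complete in-frame CDS; a terminal stop codon is
#' removed before counting, and codons containing non-ACGT characters are
#' dropped. Sequences whose length is not a multiple of three are skipped
#' with a warning.
#'
#' @param cds named character vector of CDS DNA strings
#' @return integer matrix, genes x 64 codons
#' @export
codon_counts <- function(cds) {
  code <- plastid_code()
  codons <- sort(names(code))
  out <- matrix(0L, nrow = length(cds), ncol = length(codons),
                dimnames = list(names(cds), codons))
  keep <- logical(length(cds))
  for (i in seq_along(cds)) {
    s <- toupper(cds[[i]])
    if (nchar(s) %% 3L != 0L) {
      warning("CDS length of ", names(cds)[i] %||% i,
              " not divisible by 3; skipped")
      next
    }
    keep[i] <- TRUE
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cod) && code[[cod[length(cod)]]] %||% "" == "*")
      cod <- cod[-length(cod)]
    cod <- cod[cod %in% codons]
    if (length(cod)) {
      tb <- table(cod)
      out[i, names(tb)] <- out[i, names(tb)] + as.integer(tb)
    }
  }
  out[keep, , drop = FALSE]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !length(a)) b else a

#' @keywords internal
as_count_vector <- function(counts) {
  if (is.matrix(counts)) colSums(counts) else counts
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its
#' synonymous family; values average 1 within each fully observed family.
#' Met, Trp and stop codons carry no synonymous information and are
#' excluded. Families with zero total count are omitted (returned as NA)
#' with a warning.
#'
#' @param counts named codon count vector (or a gene x codon matrix,
#'   summed over genes)
#' @return named numeric vector over the 59 informative codons
#' @export
rscu <- function(counts) {
  cnt <- as_count_vector(counts)
  fam <- syn_families()
  out <- setNames(rep(NA_real_, length(informative_codons())),
                  informative_codons())
  for (aa in names(fam)) {
    members <- fam[[aa]]
    x <- cnt[members]
    if (sum(x) == 0) {
      warning("family ", aa, " has zero counts; omitted from RSCU")
      next
    }
    out[members] <- x / mean(x)
  }
  out
}

#' Codon adaptation index
#'
#' CAI is the geometric mean of relative adaptiveness weights
#' `w = RSCU / max RSCU in family` taken from a reference codon-count set,
#' over the gene's codons (Met, Trp and stops excluded). Codons absent
#' from the reference set receive a pseudo-count of `pseudo` before the
#' reference RSCU is computed.
#'
#' @param gene_counts named codon count vector for the gene
#' @param reference_counts named codon count vector for the reference set
#' @param pseudo pseudo-count for reference codons with zero count
#' @return CAI in (0, 1]
#' @export
cai <- function(gene_counts, reference_counts, pseudo = 0.5) {
  gcnt <- as_count_vector(gene_counts)
  rcnt <- as_count_vector(reference_counts)
  info <- informative_codons()
  rcnt <- rcnt[info]
  rcnt[rcnt == 0] <- pseudo
  fam <- syn_families()
  w <- setNames(rep(NA_real_, length(info)), info)
  for (aa in names(fam)) {
    members <- fam[[aa]]
    r <- rcnt[members] / mean(rcnt[members])
    w[members] <- r / max(r)
  }
  gx <- gcnt[info]
  use <- gx > 0
  if (!any(use)) stop("gene has no informative codons")
  exp(sum(gx[use] * log(w[use])) / sum(gx[use]))
}

#' Wright's ENC from class-average homozygosities
#'
#' Closed form `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to
#' \[20, 61\]: 61 at uniform usage (`Fk = 1/k`), 20 at maximal bias
#' (`Fk = 1`).
#'
#' @param F2,F3,F4,F6 average codon homozygosity of the 2-, 3-, 4- and
#'   6-fold degenerate families
#' @return the effective number of codons
#' @export
enc_wright <- function(F2, F3, F4, F6) {
  v <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(61, max(20, v))
}

#' Effective number of codons of a gene
#'
#' Wright's ENC: per-family codon homozygosity is estimated as
#' `F = (n * sum(p^2) - 1) / (n - 1)` over families with at least two
#' codons observed, averaged within each degeneracy class (2-, 3-, 4- and
#' 6-fold). A missing 3-fold class (no Ile observed) is interpolated as
#' the mean of the 2- and 4-fold class averages, the usual codonW
#' behaviour; if the 2-, 4- or 6-fold class is entirely missing the ENC is
#' undefined (NA). The result is clamped to \[20, 61\].
#'
#' @param counts named codon count vector (or gene x codon matrix)
#' @return ENC value, or NA when undefined
#' @export
enc <- function(counts) {
  cnt <- as_count_vector(counts)
  fam <- syn_families()
  deg <- lengths(fam)
  Fhat <- vapply(names(fam), function(aa) {
    x <- cnt[fam[[aa]]]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classF <- function(k) {
    v <- Fhat[deg == k]
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) NA_real_ else mean(v)
  }
  F2 <- classF(2L); F3 <- classF(3L); F4 <- classF(4L); F6 <- classF(6L)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  enc_wright(F2, F3, F4, F6)
}

#' GC content by codon position
#'
#' Per-gene GC fractions at the three codon positions, GC12 (mean of the
#' first two) and GC over all positions, for genes longer than `min_len`
#' nucleotides, plus a pooled row over all retained genes. Genes whose
#' length is not a multiple of three are skipped with a warning.
#'
#' @param cds named character vector of CDS DNA strings
#' @param min_len genes must be strictly longer than this (bp)
#' @return data.frame with columns `gene`, `gc1`, `gc2`, `gc3`, `gc12`,
#'   `gc_all`; the final row (`gene == "pooled"`) pools the base counts
#' @export
gc_by_codon_position <- function(cds, min_len = 300L) {
  rows <- NULL
  pool <- matrix(0L, nrow = 2L, ncol = 3L)  # row 1: GC count, row 2: total
  for (i in seq_along(cds)) {
    s <- toupper(cds[[i]])
    if (nchar(s) <= min_len) next
    if (nchar(s) %% 3L != 0L) {
      warning("CDS length of ", names(cds)[i] %||% i,
              " not divisible by 3; skipped")
      next
    }
    ch <- seq_chars(s)
    keep <- ch %in% DNA_BASES
    posn <- rep_len(1:3, length(ch))
    gcp <- vapply(1:3, function(p) {
      sel <- posn == p & keep
      c(sum(ch[sel] %in% c("G", "C")), sum(sel))
    }, numeric(2))
    pool <- pool + gcp
    gc123 <- gcp[1, ] / gcp[2, ]
    rows <- rbind(rows, data.frame(
      gene = names(cds)[i] %||% sprintf("gene%d", i),
      gc1 = gc123[1], gc2 = gc123[2], gc3 = gc123[3],
      gc12 = mean(gc123[1:2]), gc_all = sum(gcp[1, ]) / sum(gcp[2, ])))
  }
  if (is.null(rows)) stop("no gene passed the length filter")
  gc123 <- pool[1, ] / pool[2, ]
  rbind(rows, data.frame(gene = "pooled", gc1 = gc123[1], gc2 = gc123[2],
                         gc3 = gc123[3], gc12 = mean(gc123[1:2]),
                         gc_all = sum(pool[1, ]) / sum(pool[2, ])))
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 against GC3 across genes; a slope near 1
#' indicates mutational pressure dominating, a flat slope indicates
#' selection/drift shaping codon usage independently of GC3.
#'
#' @param gc12,gc3 numeric vectors per gene (at least 3 genes), or a
#'   data.frame with `gc12` and `gc3` columns as the first argument
#' @return list with `slope`, `intercept`, `r_squared`, `n`, `undefined`
#' @export
neutrality_regression <- function(gc12, gc3 = NULL) {
  if (is.data.frame(gc12)) {
    d <- gc12[gc12$gene != "pooled", , drop = FALSE]
    gc3 <- d$gc3; gc12 <- d$gc12
  }
  stopifnot(length(gc12) == length(gc3), length(gc12) >= 3L)
  if (var(gc3) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = length(gc3), undefined = TRUE))
  }
  if (var(gc12) == 0) {
    return(list(slope = 0, intercept = gc12[1L], r_squared = 0,
                n = length(gc3), undefined = FALSE))
  }
  fit <- lm(gc12 ~ gc3)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, n = length(gc3),
       undefined = FALSE)
}

#' Default gene functional classes
#'
#' Prefix map assigning plastid genes to photosynthesis-related (photo),
#' genetic-system (genet) or other classes; editable and passed through
#' [codon_usage_stats()].
#'
#' @return named list of name prefixes per class
#' @export
default_gene_classes <- function() {
  list(photo = c("psa", "psb", "pet", "atp", "ndh", "rbc"),
       genet = c("rpl", "rps", "rpo", "inf", "mat", "rrn", "trn"))
}

#' @keywords internal
gene_class <- function(names, class_map = default_gene_classes()) {
  vapply(tolower(names), function(nm) {
    for (cl in names(class_map)) {
      if (any(startsWith(nm, class_map[[cl]]))) return(cl)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Per-gene codon-usage statistics
#'
#' Computes, for every CDS passing the length filter, its functional
#' class, ENC, CAI (against a reference set defaulting to the pooled
#' counts of the photo-gene class), and GC by codon position; also returns
#' the pooled RSCU vector and the neutrality regression.
#'
#' @param cds named character vector of CDS DNA strings
#' @param min_len genes must be strictly longer than this (bp)
#' @param cai_ref "photo" (pooled photo-class counts) or a named codon
#'   count vector
#' @param class_map see [default_gene_classes()]
#' @return list with `stats` (per-gene data.frame), `rscu_pooled`,
#'   `gc` (output of [gc_by_codon_position()]) and `neutrality`
#' @export
codon_usage_stats <- function(cds, min_len = 300L, cai_ref = "photo",
                              class_map = default_gene_classes()) {
  keep <- nchar(cds) > min_len & nchar(cds) %% 3L == 0L
  cds <- cds[keep]
  if (!length(cds)) stop("no CDS passed the filters")
  cnt <- codon_counts(cds)
  cls <- gene_class(rownames(cnt), class_map)
  ref <- if (is.character(cai_ref) && identical(cai_ref, "photo")) {
    if (!any(cls == "photo")) colSums(cnt) else colSums(cnt[cls == "photo", , drop = FALSE])
  } else as_count_vector(cai_ref)
  gc <- gc_by_codon_position(cds, min_len = min_len)
  per <- gc[gc$gene != "pooled", , drop = FALSE]
  stats <- data.frame(
    gene = rownames(cnt),
    gene_class = cls,
    enc = vapply(seq_len(nrow(cnt)), function(i) enc(cnt[i, ]), numeric(1)),
    cai = vapply(seq_len(nrow(cnt)), function(i) cai(cnt[i, ], ref), numeric(1)))
  stats <- merge(stats, per, by = "gene", sort = FALSE)
  list(stats = stats,
       rscu_pooled = suppressWarnings(rscu(cnt)),
       gc = gc,
       neutrality = neutrality_regression(stats$gc12, stats$gc3))
}
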