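## Core sequence helpers. Sequences are plain uppercase character scalars
## over {A,C,G,T,N}; Biostrings is used at the file-format boundary only.

DNA_BASES <- c("A", "C", "G", "T")

#' Complement of a DNA string
#' @param x character vector of DNA strings
#' @return character vector of complemented strings
#' @export
dna_complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse of a DNA string
#' @param x character vector of DNA strings
#' @return character vector with each string reversed
#' @export
dna_reverse <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) dna_reverse(dna_complement(x))

#' @keywords internal
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Random i.i.d. DNA sequence at a given GC fraction
#'
#' @param n sequence length in bp
#' @param gc_fraction expected fraction of G+C bases in \[0,1\]
#' @return a DNA string of length `n`
#' @export
random_dna <- function(n, gc_fraction = 0.37) {
  stopifnot(n >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' GC fraction of a DNA string
#' @param x a DNA string
#' @return fraction of G/C among A/C/G/T characters (NA if none)
#' @export
gc_fraction <- function(x) {
  ch <- seq_chars(toupper(x))
  acgt <- ch %in% DNA_BASES
  if (!any(acgt)) return(NA_real_)
  mean(ch[acgt] %in% c("G", "C"))
}

## Circular substring: 0-based start, length len, wraps past the origin.
#' @keywords internal
circ_substr <- function(seq, start0, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  start0 <- start0 %% n
  if (start0 + len <= n) {
    substr(seq, start0 + 1, start0 + len)
  } else {
    paste0(substr(seq, start0 + 1, n), substr(seq, 1, start0 + len - n))
  }
}

#' Construct a plastome sequence record
#'
#' A plastome is modelled as a circular DNA molecule; all coordinates used
#' by the package are 0-based half-open and interpreted modulo the length.
#'
#' @param seq DNA string over A/C/G/T/N
#' @param id sequence identifier
#' @return an object of class `plastome`
#' @export
plastome <- function(seq, id = "plastome") {
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  structure(list(id = id, seq = seq, length = nchar(seq)), class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %d bp circular, GC %.3f\n",
              x$id, x$length, gc_fraction(x$seq)))
  invisible(x)
}

#' @keywords internal
as_plastome <- function(x, id = "plastome") {
  if (inherits(x, "plastome")) x else plastome(x, id = id)
}

#' Read sequences from a FASTA/FASTQ file
#'
#' @param path input file
#' @param format "fasta" or "fastq"
#' @return named character vector of sequences
#' @export
read_seqs <- function(path, format = "fasta") {
  x <- Biostrings::readDNAStringSet(path, format = format)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA strings
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ with uniform base quality
#'
#' @param seqs named character vector of read sequences
#' @param path output file
#' @param quality single phred quality applied to every base
#' @return `path`, invisibly
#' @export
write_fastq <- function(seqs, path, quality = 30L) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::PhredQuality(vapply(nchar(seqs), function(n) {
    paste(rep(rawToChar(as.raw(quality + 33L)), n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

## ---- feature tables -------------------------------------------------------

## Features are data.frames with columns: name, type, strand, start, end
## (0-based half-open, end may exceed the genome length for features that
## wrap the circular origin).

#' Build a feature table
#'
#' @param name gene names (one row per exon)
#' @param type feature type, one of CDS/tRNA/rRNA/pseudo
#' @param strand "+" or "-"
#' @param start,end 0-based half-open interval; `end` may exceed the genome
#'   length for a feature wrapping the circular origin
#' @return a `data.frame` feature table
#' @export
feature_table <- function(name = character(), type = character(),
                          strand = character(), start = integer(),
                          end = integer()) {
  stopifnot(all(end > start), all(strand %in% c("+", "-")))
  data.frame(name = name, type = type, strand = strand,
             start = as.integer(start), end = as.integer(end))
}

#' Write a feature table as GFF3
#'
#' Wrapping features are split at the origin into two exon records.
#'
#' @param features feature table (see [feature_table()])
#' @param genome_length length of the circular genome in bp
#' @param path output file
#' @param seqid sequence identifier used in column 1
#' @return `path`, invisibly
#' @export
write_features_gff3 <- function(features, genome_length, path,
                                seqid = "plastome") {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$end <= genome_length) {
      rows[[length(rows) + 1L]] <- data.frame(start = f$start, end = f$end,
                                              name = f$name, type = f$type,
                                              strand = f$strand)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(start = f$start,
                                              end = genome_length,
                                              name = f$name, type = f$type,
                                              strand = f$strand)
      rows[[length(rows) + 1L]] <- data.frame(start = 0L,
                                              end = f$end - genome_length,
                                              name = f$name, type = f$type,
                                              strand = f$strand)
    }
  }
  rows <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand)
  gr$type <- rows$type
  gr$ID <- rows$name
  gr$Name <- rows$name
  gr$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' @param path GFF3 file
#' @return a feature table with 0-based half-open coordinates
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  feature_table(name = nm,
                type = as.character(gr$type),
                strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
}

#' Extract spliced CDS sequences from a genome and feature table
#'
#' Concatenates CDS exons per gene in transcription order; minus-strand
#' genes are reverse complemented. Coordinates may wrap the circular
#' origin (end greater than the genome length).
#'
#' @param genome a [plastome()] or DNA string
#' @param features a feature table (see [feature_table()])
#' @return named character vector of CDS sequences
#' @export
extract_cds <- function(genome, features) {
  g <- as_plastome(genome)
  n <- g$length
  feats <- features[features$type == "CDS", , drop = FALSE]
  out <- character(0)
  for (nm in unique(feats$name)) {
    ex <- feats[feats$name == nm, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(ex)), function(i) {
      circ_substr(g$seq, ex$start[i], ex$end[i] - ex$start[i])
    }, character(1)), collapse = "")
    if (ex$strand[1L] == "-") s <- revcomp(s)
    out[nm] <- s
  }
  out
}

## span of a (possibly multi-exon) gene: one row per gene, min start/max end
#' @keywords internal
gene_spans <- function(features) {
  if (nrow(features) == 0)
    return(data.frame(name = character(), strand = character(),
                      start = integer(), end = integer()))
  sp <- do.call(rbind, lapply(split(features, features$name), function(d) {
    data.frame(name = d$name[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end))
  }))
  rownames(sp) <- NULL
  sp[order(sp$start), , drop = FALSE]
}
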