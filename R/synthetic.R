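## Synthetic-data generators: quadripartite plastomes with planted features,
## diverged sister genomes with truth tables, long reads from the two
## SSC-orientation haplotypes, and per-replicate editing pileups.
##
## All generators take an explicit seed and restore the caller's RNG state,
## so identical specs give byte-identical output.

#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic quadripartite plastome
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp; `lsc_len > ssc_len`
#' @param gc_fraction background GC fraction of the i.i.d. nucleotide model
#' @param planted_ssrs list of `list(motif=, count=, region=)` entries;
#'   `region` is one of "lsc", "ira", "ssc"
#' @param planted_repeats list of `list(length=, kind=, pos1=, pos2=)`
#'   entries with `kind` in direct/inverted/complement/palindromic and
#'   0-based genome positions within LSC + IRa + SSC
#' @param n_genes number of background CDS genes to annotate
#' @param seed integer RNG seed
#' @return a `plastome_spec` list
#' @export
plastome_spec <- function(lsc_len, ir_len, ssc_len, gc_fraction = 0.37,
                          planted_ssrs = list(), planted_repeats = list(),
                          n_genes = 4L, seed = 1L) {
  stopifnot(lsc_len > ssc_len, ir_len >= 1L, ssc_len >= 1L,
            gc_fraction >= 0, gc_fraction <= 1)
  structure(list(lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
                 ssc_len = as.integer(ssc_len), gc_fraction = gc_fraction,
                 planted_ssrs = planted_ssrs,
                 planted_repeats = planted_repeats,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "plastome_spec")
}

## region offsets within the core (LSC + IRa + SSC) for a spec
#' @keywords internal
spec_region_bounds <- function(spec) {
  L <- spec$lsc_len; I <- spec$ir_len; S <- spec$ssc_len
  list(lsc = c(0L, L), ira = c(L, L + I), ssc = c(L + I, L + I + S))
}

#' Generate a synthetic quadripartite plastome
#'
#' Builds the circle LSC + IRa + SSC + revcomp(IRa) from i.i.d. nucleotides
#' at the requested GC, plants the requested SSRs and repeat pairs, and
#' adjusts the two single-base IR flanks so the planted IR pair is exactly
#' maximal (no single-base extension preserves the reverse-complement
#' relation). A small annotation is emitted: background CDS genes in the
#' single-copy regions plus one gene spanning the IRb/LSC junction.
#'
#' @param spec a [plastome_spec()]
#' @return list with `genome` (a [plastome()]), `features` (feature table),
#'   `truth` (planted SSR/repeat coordinate tables) and `spec`
#' @export
generate_plastome <- function(spec) {
  stopifnot(inherits(spec, "plastome_spec"))
  with_seed(spec$seed, {
    L <- spec$lsc_len; I <- spec$ir_len; S <- spec$ssc_len
    n <- L + 2L * I + S
    core_len <- L + I + S
    core <- seq_chars(random_dna(core_len, spec$gc_fraction))
    bounds <- spec_region_bounds(spec)

    occupied <- matrix(integer(), ncol = 2)  # planted intervals [start, end)
    claim <- function(start, end, what) {
      if (start < 0 || end > core_len)
        stop(sprintf("planted %s [%d, %d) does not fit in the genome", what, start, end))
      if (nrow(occupied) &&
          any(pmax(occupied[, 1], start) < pmin(occupied[, 2], end)))
        stop(sprintf("planted %s [%d, %d) overlaps another planted feature",
                     what, start, end))
      occupied <<- rbind(occupied, c(start, end))
    }
    place_random <- function(len, region, what) {
      b <- bounds[[region]]
      if (b[2] - b[1] < len)
        stop(sprintf("planted %s (%d bp) does not fit in region %s [%d, %d)",
                     what, len, region, b[1], b[2]))
      for (try in 1:200) {
        s0 <- b[1] + sample.int(b[2] - b[1] - len + 1L, 1L) - 1L
        free <- !nrow(occupied) ||
          !any(pmax(occupied[, 1], s0 - 1L) < pmin(occupied[, 2], s0 + len + 1L))
        if (free) { claim(s0, s0 + len, what); return(s0) }
      }
      stop(sprintf("could not place planted %s (%d bp) in region %s", what, len, region))
    }

    ## fixed-position repeats claim their intervals first so that randomly
    ## placed SSRs are drawn around them
    rep_truth <- NULL
    for (pr in spec$planted_repeats) {
      len <- pr$length
      x <- random_dna(len, spec$gc_fraction)
      y <- switch(pr$kind,
                  direct = x, inverted = dna_reverse(x),
                  complement = dna_complement(x), palindromic = revcomp(x),
                  stop("unknown repeat kind: ", pr$kind))
      claim(pr$pos1, pr$pos1 + len, sprintf("%s repeat copy 1", pr$kind))
      claim(pr$pos2, pr$pos2 + len, sprintf("%s repeat copy 2", pr$kind))
      core[(pr$pos1 + 1L):(pr$pos1 + len)] <- seq_chars(x)
      core[(pr$pos2 + 1L):(pr$pos2 + len)] <- seq_chars(y)
      rep_truth <- rbind(rep_truth,
                         data.frame(kind = pr$kind, length = len,
                                    pos1 = pr$pos1, pos2 = pr$pos2))
    }

    ssr_truth <- NULL
    for (ps in spec$planted_ssrs) {
      run <- strrep(ps$motif, ps$count)
      s0 <- place_random(nchar(run), ps$region, sprintf("SSR (%s)x%d", ps$motif, ps$count))
      core[(s0 + 1L):(s0 + nchar(run))] <- seq_chars(run)
      ssr_truth <- rbind(ssr_truth,
                         data.frame(motif = ps$motif, repeat_count = ps$count,
                                    start = s0, end = s0 + nchar(run),
                                    region = ps$region))
    }
    ## make the planted IR exactly maximal:
    ## outward extension needs seq[0] == comp(seq[L-1]); inward extension
    ## needs last SSC base == comp(first SSC base)
    while (core[1L] == dna_complement(core[L])) {
      core[1L] <- sample(DNA_BASES, 1L)
    }
    while (core[core_len] == dna_complement(core[L + I + 1L])) {
      core[core_len] <- sample(DNA_BASES, 1L)
    }

    core_str <- paste(core, collapse = "")
    ira_str <- substr(core_str, L + 1L, L + I)
    genome <- plastome(paste0(core_str, revcomp(ira_str)), id = "synthetic")

    ## annotation: background CDS genes plus an IRb/LSC junction spanner
    glen <- max(6L, 3L * ((min(300L, L %/% (spec$n_genes + 2L))) %/% 3L))
    feats <- NULL
    if (spec$n_genes > 0L && L > (glen + 20L) * spec$n_genes) {
      starts <- round(seq(10L, L - glen - 10L, length.out = spec$n_genes))
      feats <- feature_table(name = sprintf("gene%02d", seq_len(spec$n_genes)),
                             type = rep("CDS", spec$n_genes),
                             strand = rep(c("+", "-"), length.out = spec$n_genes),
                             start = as.integer(starts),
                             end = as.integer(starts + glen))
    }
    j_irb <- min(60L, I)
    j_lsc <- min(90L, max(6L, L %/% 4L))
    junc <- feature_table(name = "rps19", type = "CDS", strand = "-",
                          start = n - j_irb, end = n + j_lsc)
    feats <- if (is.null(feats)) junc else rbind(feats, junc)

    list(genome = genome, features = feats,
         truth = list(ssrs = ssr_truth, repeats = rep_truth),
         spec = spec)
  })
}

#' Specification of pairwise divergence events
#'
#' @param snp_count number of substituted positions in the truth alignment
#' @param indel_events data.frame with columns `position` (0-based ref
#'   coordinate), `length` (bp) and `type` ("ins" or "del"); events must
#'   not touch (at least one unchanged base between any two events), so
#'   each event is one maximal gap run in the truth alignment
#' @param seed integer RNG seed
#' @return a `divergence_spec` list
#' @export
divergence_spec <- function(snp_count = 0L, indel_events = NULL, seed = 1L) {
  if (is.null(indel_events))
    indel_events <- data.frame(position = integer(), length = integer(),
                               type = character())
  stopifnot(all(indel_events$type %in% c("ins", "del")),
            all(indel_events$length >= 1L), snp_count >= 0L)
  if (nrow(indel_events) > 1L) {
    ev <- indel_events[order(indel_events$position), , drop = FALSE]
    foot <- ifelse(ev$type == "del", ev$length, 0L)
    if (any(ev$position[-1L] <= ev$position[-nrow(ev)] + foot[-nrow(ev)]))
      stop("indel events overlap or touch; separate them by at least one base")
    indel_events <- ev
  }
  structure(list(snp_count = as.integer(snp_count),
                 indel_events = indel_events, seed = as.integer(seed)),
            class = "divergence_spec")
}

#' Draw a random, valid divergence specification
#'
#' Convenience generator for randomized round-trip tests: indel events are
#' placed with enough separation that each stays a distinct alignment gap
#' run, and SNP positions are drawn by [mutate_genome()] away from them.
#'
#' @param genome_len reference genome length in bp
#' @param n_snps,n_indels event counts
#' @param max_indel_len maximum indel length in bp
#' @param seed integer RNG seed
#' @return a `divergence_spec`
#' @export
random_divergence_spec <- function(genome_len, n_snps, n_indels,
                                   max_indel_len = 6L, seed = 1L) {
  with_seed(seed, {
    ev <- NULL
    if (n_indels > 0L) {
      gap <- max_indel_len + 2L
      stopifnot(genome_len > n_indels * 3L * gap + 20L)
      repeat {
        pos <- sort(sample.int(genome_len - 2L * gap, n_indels) + gap)
        if (n_indels == 1L || all(diff(pos) > gap)) break
      }
      ev <- data.frame(position = pos,
                       length = sample.int(max_indel_len, n_indels, replace = TRUE),
                       type = sample(c("ins", "del"), n_indels, replace = TRUE))
    }
    divergence_spec(snp_count = n_snps, indel_events = ev, seed = seed)
  })
}

#' Mutate a genome according to a divergence specification
#'
#' Applies the requested number of substitutions and the given indel events
#' to a copy of the genome and returns the mutated sequence together with a
#' truth table and the implied true pairwise alignment, so downstream
#' variant calling can be checked by exact round trip.
#'
#' SNP positions are drawn uniformly outside indel footprints. With a
#' partition and `ir_policy = "mirror"` (the default when a partition is
#' given), substitutions are drawn in LSC + IRa + SSC only and any hit in
#' IRa is mirrored into IRb, preserving the quadripartite invariant; each
#' mirrored hit consumes two units of `snp_count`, so the truth table always
#' holds exactly `snp_count` substitution rows. Indel events are applied at
#' their stated positions and are never mirrored.
#'
#' @param genome a [plastome()] or DNA string
#' @param spec a [divergence_spec()]
#' @param partition optional `quadripartite_partition` of `genome`
#' @param ir_policy "mirror" or "independent"
#' @return list with `genome` (mutated [plastome()]), `truth`
#'   (data.frame type/ref_pos/ref_allele/alt_allele) and `alignment`
#'   (a [pairwise_alignment()])
#' @export
mutate_genome <- function(genome, spec, partition = NULL,
                          ir_policy = c("mirror", "independent")) {
  g <- as_plastome(genome)
  ir_policy <- match.arg(ir_policy)
  n <- g$length
  ev <- spec$indel_events
  stopifnot(all(ev$position >= 0L), all(ev$position < n),
            all(ev$position + ifelse(ev$type == "del", ev$length, 0L) <= n))

  with_seed(spec$seed, {
    ref <- seq_chars(g$seq)
    qry <- ref

    blocked <- rep(FALSE, n)                       # positions unavailable to SNPs
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "del") {
        blocked[(ev$position[i] + 1L):(ev$position[i] + ev$length[i])] <- TRUE
      }
    }

    truth <- NULL
    mirror <- !is.null(partition) && ir_policy == "mirror"
    pool <- which(!blocked) - 1L                   # 0-based
    if (mirror) {
      irb0 <- partition$irb[1]; irbL <- partition$irb[2]
      in_irb <- ((pool - irb0) %% n) < irbL
      pool <- pool[!in_irb]
      ira0 <- partition$ira[1]; iraL <- partition$ira[2]
    }
    remaining <- spec$snp_count
    while (remaining > 0L) {
      if (!length(pool)) stop("not enough free positions for requested SNPs")
      if (mirror) {
        in_ira <- ((pool - ira0) %% n) < iraL
        p <- if (remaining == 1L) {
          if (!any(!in_ira)) stop("cannot place a final unmirrored SNP")
          sample(pool[!in_ira], 1L)
        } else sample(pool, 1L)
      } else {
        p <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
      alt <- sample(setdiff(DNA_BASES, qry[p + 1L]), 1L)
      qry[p + 1L] <- alt
      truth <- rbind(truth, data.frame(type = "SNP", ref_pos = p,
                                       ref_allele = ref[p + 1L], alt_allele = alt))
      pool <- pool[pool != p]
      remaining <- remaining - 1L
      if (mirror && ((p - ira0) %% n) < iraL) {
        q <- (irb0 + (iraL - 1L - ((p - ira0) %% n))) %% n
        alt_m <- dna_complement(alt)
        truth <- rbind(truth, data.frame(type = "SNP", ref_pos = q,
                                         ref_allele = ref[q + 1L],
                                         alt_allele = alt_m))
        qry[q + 1L] <- alt_m
        pool <- pool[pool != q]
        remaining <- remaining - 1L
      }
    }

    ## assemble the truth alignment: per ref position one column, plus
    ## inserted columns (ref gap) before their anchor position
    ins_at <- rep("", n + 1L)
    del <- rep(FALSE, n)
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "ins") {
        insseq <- random_dna(ev$length[i], 0.5)
        ins_at[ev$position[i] + 1L] <- insseq
        truth <- rbind(truth, data.frame(type = "indel", ref_pos = ev$position[i],
                                         ref_allele = "-", alt_allele = insseq))
      } else {
        idx <- (ev$position[i] + 1L):(ev$position[i] + ev$length[i])
        del[idx] <- TRUE
        truth <- rbind(truth,
                       data.frame(type = "indel", ref_pos = ev$position[i],
                                  ref_allele = paste(ref[idx], collapse = ""),
                                  alt_allele = "-"))
      }
    }

    ref_cols <- character(0); qry_cols <- character(0)
    ref_out <- c(vapply(seq_len(n), function(i) {
      paste0(strrep("-", nchar(ins_at[i])), ref[i])
    }, character(1)), strrep("-", nchar(ins_at[n + 1L])))
    qry_out <- c(vapply(seq_len(n), function(i) {
      paste0(ins_at[i], if (del[i]) "-" else qry[i])
    }, character(1)), ins_at[n + 1L])
    aln <- pairwise_alignment(paste(ref_out, collapse = ""),
                              paste(qry_out, collapse = ""),
                              ref_id = g$id, qry_id = paste0(g$id, "_mut"))

    mut <- paste(c(vapply(seq_len(n), function(i) {
      paste0(ins_at[i], if (del[i]) "" else qry[i])
    }, character(1)), ins_at[n + 1L]), collapse = "")
    if (is.null(truth)) {
      truth <- data.frame(type = character(), ref_pos = integer(),
                          ref_allele = character(), alt_allele = character())
    }
    truth <- truth[order(truth$ref_pos, truth$type), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = plastome(mut, id = paste0(g$id, "_mut")),
         truth = truth, alignment = aln)
  })
}

#' Specification for long-read simulation
#'
#' @param n_reads number of reads
#' @param length_range `c(min, max)` read length in bp
#' @param haplotype_mix fraction of reads drawn from the SSC-forward form
#' @param error_rate per-base substitution error rate
#' @param span_junction when TRUE every read is placed to cover the
#'   haplotype-informative span LSC end - IRa - SSC start with at least
#'   `span_flank` bp on each side (requires a partition at simulation time)
#' @param span_flank flank in bp for `span_junction` placement
#' @param seed integer RNG seed
#' @return a `read_sim_spec` list
#' @export
read_sim_spec <- function(n_reads, length_range, haplotype_mix = 0.5,
                          error_rate = 0, span_junction = FALSE,
                          span_flank = 200L, seed = 1L) {
  stopifnot(haplotype_mix >= 0, haplotype_mix <= 1, length_range[1] > 0,
            length_range[2] >= length_range[1], error_rate >= 0, error_rate < 1)
  structure(list(n_reads = as.integer(n_reads),
                 length_range = as.integer(length_range),
                 haplotype_mix = haplotype_mix, error_rate = error_rate,
                 span_junction = span_junction,
                 span_flank = as.integer(span_flank),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate long reads from the two SSC-orientation haplotypes
#'
#' Each read is a circularly wrapped substring of its source haplotype, on
#' a random strand, with i.i.d. substitution errors. Truth labels record
#' the source form, position and strand.
#'
#' @param genomeA,genomeB the two SSC-orientation forms of one plastome
#'   (see [build_structure_pair()]); strings or [plastome()]s
#' @param spec a [read_sim_spec()]
#' @param partition `quadripartite_partition` shared by the forms; required
#'   when `spec$span_junction` is TRUE
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read_id/source/start/length/strand)
#' @export
simulate_long_reads <- function(genomeA, genomeB, spec, partition = NULL) {
  A <- as_plastome(genomeA, "formA")$seq
  B <- as_plastome(genomeB, "formB")$seq
  stopifnot(nchar(A) == nchar(B))
  n <- nchar(A)
  if (spec$length_range[1] > n)
    stop("minimum read length exceeds the genome length")
  with_seed(spec$seed, {
    src <- ifelse(runif(spec$n_reads) < spec$haplotype_mix, "A", "B")
    len <- sample.int(spec$length_range[2] - spec$length_range[1] + 1L,
                      spec$n_reads, replace = TRUE) + spec$length_range[1] - 1L
    if (spec$span_junction) {
      stopifnot(!is.null(partition))
      b1 <- (partition$lsc[1] + partition$lsc[2]) %% n   # LSC/IRa boundary
      ir <- partition$ir_len
      need <- ir + 2L * spec$span_flank
      if (any(len < need))
        stop(sprintf("span_junction reads need length >= IR + 2*flank = %d bp", need))
      lo <- b1 + ir + spec$span_flank - len               # cover [b1-flank, b1+ir+flank)
      hi <- b1 - spec$span_flank
      start <- vapply(seq_len(spec$n_reads), function(i) {
        (sample.int(hi - lo[i] + 1L, 1L) + lo[i] - 1L) %% n
      }, numeric(1))
    } else {
      start <- sample.int(n, spec$n_reads, replace = TRUE) - 1L
    }
    strand <- sample(c("+", "-"), spec$n_reads, replace = TRUE)
    reads <- vapply(seq_len(spec$n_reads), function(i) {
      r <- circ_substr(if (src[i] == "A") A else B, start[i], len[i])
      if (strand[i] == "-") r <- revcomp(r)
      if (spec$error_rate > 0) {
        ch <- seq_chars(r)
        hit <- which(runif(len[i]) < spec$error_rate)
        for (h in hit) ch[h] <- sample(setdiff(DNA_BASES, ch[h]), 1L)
        r <- paste(ch, collapse = "")
      }
      r
    }, character(1))
    ids <- sprintf("read%05d", seq_len(spec$n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, source = src, start = start,
                            length = len, strand = strand))
  })
}

#' Specification for per-replicate editing pileups
#'
#' @param sites data.frame with `position` (0-based) and `efficiency` in
#'   \[0,1\]; every position must carry C (forward) or G (reverse) on the
#'   template
#' @param n_replicates number of RNA-seq replicates
#' @param depth_mean mean per-site read depth (Poisson)
#' @param base_quality phred quality attached to every record
#' @param noise_rate per-read error rate generating alternate reads at
#'   unedited background sites
#' @param n_noise_sites number of unedited background sites to emit
#' @param seed integer RNG seed
#' @return an `editing_sim_spec` list
#' @export
editing_sim_spec <- function(sites, n_replicates = 4L, depth_mean = 100,
                             base_quality = 30L, noise_rate = 0,
                             n_noise_sites = 0L, seed = 1L) {
  stopifnot(all(sites$efficiency >= 0), all(sites$efficiency <= 1))
  structure(list(sites = sites, n_replicates = as.integer(n_replicates),
                 depth_mean = depth_mean, base_quality = as.integer(base_quality),
                 noise_rate = noise_rate, n_noise_sites = as.integer(n_noise_sites),
                 seed = as.integer(seed)),
            class = "editing_sim_spec")
}

#' Pick candidate C-to-U editing site positions on a genome
#'
#' @param genome a [plastome()] or DNA string
#' @param n number of sites
#' @param efficiencies true efficiencies, recycled to length `n`
#' @param seed integer RNG seed
#' @return data.frame `position`, `efficiency`
#' @export
pick_editing_sites <- function(genome, n, efficiencies, seed = 1L) {
  g <- as_plastome(genome)
  with_seed(seed, {
    ch <- seq_chars(g$seq)
    cand <- which(ch %in% c("C", "G")) - 1L
    stopifnot(length(cand) >= n)
    data.frame(position = sort(sample(cand, n)),
               efficiency = rep_len(efficiencies, n))
  })
}

#' Simulate per-replicate variant evidence for C-to-U editing sites
#'
#' At each edited site the alternate-read count is Binomial(depth,
#' efficiency), split across strands; only sites with at least one
#' alternate read in a replicate yield an evidence record, as a variant
#' caller would emit. Unedited background sites carry reference reads plus
#' sequencing noise at `noise_rate`.
#'
#' @param genome a [plastome()] or DNA string
#' @param spec an [editing_sim_spec()]
#' @return list with `evidence` (a site-evidence data.frame, see
#'   [filter_candidates()]) and `truth` (the site table)
#' @export
simulate_pileups <- function(genome, spec) {
  g <- as_plastome(genome)
  ch <- seq_chars(g$seq)
  base <- ch[spec$sites$position + 1L]
  bad <- !(base %in% c("C", "G"))
  if (any(bad))
    stop("site(s) not C/G on the template at position(s): ",
         paste(spec$sites$position[bad], collapse = ", "))
  with_seed(spec$seed, {
    rows <- list()
    emit <- function(pos, refb, altb, rep_id, depth, nalt) {
      af <- rbinom(1L, nalt, 0.5); ar <- nalt - af
      rf <- rbinom(1L, depth - nalt, 0.5); rr <- depth - nalt - rf
      rows[[length(rows) + 1L]] <<- data.frame(
        position = pos, ref = refb, alt = altb, replicate = rep_id,
        quality = spec$base_quality, depth = depth,
        ref_fwd = rf, ref_rev = rr, alt_fwd = af, alt_rev = ar)
    }
    for (r in seq_len(spec$n_replicates)) {
      for (i in seq_len(nrow(spec$sites))) {
        pos <- spec$sites$position[i]
        depth <- max(1L, rpois(1L, spec$depth_mean))
        nalt <- rbinom(1L, depth, spec$sites$efficiency[i])
        if (nalt >= 1L)
          emit(pos, base[i], if (base[i] == "C") "T" else "A", r, depth, nalt)
      }
      if (spec$n_noise_sites > 0L) {
        free <- setdiff(seq_len(g$length) - 1L, spec$sites$position)
        np <- sample(free, spec$n_noise_sites)
        for (pos in np) {
          depth <- max(1L, rpois(1L, spec$depth_mean))
          nalt <- rbinom(1L, depth, spec$noise_rate)
          if (nalt >= 1L) {
            refb <- ch[pos + 1L]
            emit(pos, refb, sample(setdiff(DNA_BASES, refb), 1L), r, depth, nalt)
          }
        }
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else NULL
    list(evidence = ev, truth = spec$sites)
  })
}
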