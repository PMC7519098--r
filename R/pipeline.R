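## Report assembly: run the comparative stages over two genomes and write
## a reproducible bundle of TSV/BED outputs with a manifest.

#' @keywords internal
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 6, format = "fg"))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pairwise comparative pipeline
#'
#' Orchestrates structure detection, SSR and repeat censuses, pairwise
#' divergence (when an alignment is supplied; alignment production itself
#' is delegated to an external aligner), codon-usage statistics and Ka/Ks
#' over shared equal-length CDS, writing one TSV/BED per stage plus a
#' summary table and a manifest. Stages whose inputs are missing are
#' skipped with an explicit notice in the manifest; a stage failure leaves
#' earlier outputs in place.
#'
#' @param genome_a,genome_b the two genomes ([plastome()] or strings)
#' @param outdir output directory (created if needed)
#' @param features_a,features_b optional feature tables
#' @param alignment optional [pairwise_alignment()] of A (reference)
#'   against B
#' @param min_ir_len,ssr_thresholds,repeat_min_len,window,step stage
#'   parameters (defaults are the conventional plastome settings)
#' @return list with `summary` (data.frame), `manifest` (data.frame of
#'   stage status), and the per-stage results
#' @export
run_compare <- function(genome_a, genome_b, outdir,
                        features_a = NULL, features_b = NULL,
                        alignment = NULL,
                        min_ir_len = 1000L,
                        ssr_thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                           `4` = 3L, `5` = 3L, `6` = 3L),
                        repeat_min_len = 18L,
                        window = 600L, step = 200L) {
  ga <- as_plastome(genome_a, "genomeA")
  gb <- as_plastome(genome_b, "genomeB")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  results <- list()
  note <- function(stage, status, detail = "") {
    manifest <<- rbind(manifest, data.frame(stage = stage, status = status,
                                            detail = detail))
  }
  run_stage <- function(stage, expr) {
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) {
      note(stage, "failed", conditionMessage(r))
      NULL
    } else {
      note(stage, "ok")
      r
    }
  }

  results$structure <- run_stage("structure", {
    lapply(list(A = ga, B = gb), function(g) {
      part <- detect_inverted_repeats(g, min_ir_len = min_ir_len)
      write_partition_bed(part, file.path(outdir, paste0("partition_", g$id, ".bed")),
                          seqid = g$id)
      part
    })
  })
  if (!is.null(results$structure)) {
    feats <- list(A = features_a, B = features_b)
    jt <- NULL
    for (nm in c("A", "B")) {
      if (!is.null(feats[[nm]])) {
        j <- junction_spanning_genes(results$structure[[nm]], feats[[nm]])
        if (nrow(j)) jt <- rbind(jt, cbind(genome = nm, j))
      }
    }
    if (!is.null(jt)) write_tsv(jt, file.path(outdir, "junction_genes.tsv"))
    results$junction_genes <- jt
  }

  results$ssr <- run_stage("ssr", {
    lapply(list(A = ga, B = gb), function(g) {
      loci <- scan_ssrs(g, thresholds = ssr_thresholds)
      write_tsv(loci, file.path(outdir, paste0("ssr_", g$id, ".tsv")))
      loci
    })
  })
  results$repeats <- run_stage("repeats", {
    lapply(list(A = ga, B = gb), function(g) {
      rp <- find_maximal_repeats(g, min_len = repeat_min_len)
      write_tsv(rp, file.path(outdir, paste0("repeats_", g$id, ".tsv")))
      rp
    })
  })

  if (is.null(alignment)) {
    note("divergence", "skipped", "no pairwise alignment supplied")
  } else {
    results$divergence <- run_stage("divergence", {
      calls <- call_snps_indels(alignment)
      write_tsv(calls$variants, file.path(outdir, "variants.tsv"))
      wins <- sliding_divergence(alignment, window = window, step = step)
      write_tsv(wins, file.path(outdir, "divergence_windows.tsv"))
      low <- low_identity_regions(alignment, window = window, step = step)
      write_tsv(low, file.path(outdir, "low_identity_regions.tsv"))
      list(calls = calls, windows = wins, low_identity = low)
    })
  }

  cds_a <- if (!is.null(features_a)) extract_cds(ga, features_a) else character()
  if (!length(cds_a)) {
    note("codon_usage", "skipped", "no CDS annotation for genome A")
  } else {
    results$codon_usage <- run_stage("codon_usage", {
      cub <- codon_usage_stats(cds_a, min_len = 0L)
      write_tsv(cub$stats, file.path(outdir, "codon_usage.tsv"))
      cub
    })
  }

  cds_b <- if (!is.null(features_b)) extract_cds(gb, features_b) else character()
  shared <- intersect(names(cds_a), names(cds_b))
  shared <- shared[nchar(cds_a[shared]) == nchar(cds_b[shared]) &
                   nchar(cds_a[shared]) %% 3L == 0L]
  if (!length(shared)) {
    note("kaks", "skipped", "no shared equal-length CDS pairs")
  } else {
    results$kaks <- run_stage("kaks", {
      pairs <- lapply(shared, function(nm) {
        list(ref = cds_a[[nm]], qry = cds_b[[nm]])
      })
      names(pairs) <- shared
      ks <- suppressWarnings(genome_kaks_summary(pairs))
      write_tsv(ks$table, file.path(outdir, "kaks.tsv"))
      ks
    })
  }

  summary <- data.frame(metric = character(), A = numeric(), B = numeric())
  add <- function(metric, a, b) {
    summary <<- rbind(summary, data.frame(metric = metric, A = a, B = b))
  }
  add("genome_length", ga$length, gb$length)
  add("gc_fraction", gc_fraction(ga$seq), gc_fraction(gb$seq))
  if (!is.null(results$structure)) {
    sa <- partition_sizes(results$structure$A)
    sb <- partition_sizes(results$structure$B)
    add("lsc_len", sa["lsc"], sb["lsc"])
    add("ir_len", sa["ira"], sb["ira"])
    add("ssc_len", sa["ssc"], sb["ssc"])
  }
  if (!is.null(results$ssr)) {
    add("n_ssrs", nrow(results$ssr$A), nrow(results$ssr$B))
  }
  if (!is.null(results$repeats)) {
    for (kd in c("direct", "inverted", "complement", "palindromic")) {
      add(paste0("n_repeats_", kd),
          sum(results$repeats$A$kind == kd),
          sum(results$repeats$B$kind == kd))
    }
  }
  if (!is.null(results$divergence)) {
    add("n_snps", results$divergence$calls$n_snps, NA)
    add("n_indels", results$divergence$calls$n_indels, NA)
  }
  if (!is.null(results$kaks)) {
    add("mean_kaks", results$kaks$mean_ratio, NA)
  }
  write_tsv(summary, file.path(outdir, "summary.tsv"))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  results$summary <- summary
  results$manifest <- manifest
  results
}
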