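## Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method with
## Jukes-Cantor correction, over codon-aware CDS alignments.

## Per-codon synonymous site fractions. At each codon position the three
## possible substitutions are classified; substitutions creating a stop
## codon are excluded and the position renormalised, so every ungapped
## codon always contributes exactly 3 sites (S + N = 3 per codon).
.ng86_env <- new.env(parent = emptyenv())

#' @keywords internal
ng86_site_table <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env$sites)
  code <- plastid_code()
  sense <- names(code)[code != "*"]
  s_sites <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    ch <- seq_chars(cod)
    f <- 0
    for (pos in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (b in setdiff(DNA_BASES, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (code[[alt]] == "*") next
        nonstop <- nonstop + 1L
        if (code[[alt]] == code[[cod]]) syn <- syn + 1L
      }
      if (nonstop > 0L) f <- f + syn / nonstop
    }
    s_sites[cod] <- f
  }
  .ng86_env$sites <- s_sites
  s_sites
}

## Synonymous/nonsynonymous differences between two sense codons, averaged
## with equal weight over all minimal mutational pathways. Pathways passing
## through a stop codon are excluded; if every pathway is blocked, all are
## used.
#' @keywords internal
ng86_path_diffs <- function(c1, c2) {
  code <- plastid_code()
  pos <- which(seq_chars(c1) != seq_chars(c2))
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  walk <- function(order) {
    cur <- seq_chars(c1); tgt <- seq_chars(c2)
    sd <- 0; nd <- 0
    for (p in order) {
      aa_from <- code[[paste(cur, collapse = "")]]
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      aa_to <- code[[nxt]]
      if (aa_to == "*") return(NULL)
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  paths <- lapply(perms(pos), walk)
  ok <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(ok)) {
    ## every pathway crosses a stop: fall back to counting with stops allowed
    walk_any <- function(order) {
      cur <- seq_chars(c1); tgt <- seq_chars(c2)
      sd <- 0; nd <- 0
      for (p in order) {
        aa_from <- code[[paste(cur, collapse = "")]]
        cur[p] <- tgt[p]
        aa_to <- code[[paste(cur, collapse = "")]]
        if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
      }
      c(sd = sd, nd = nd)
    }
    ok <- lapply(perms(pos), walk_any)
  }
  Reduce(`+`, ok) / length(ok)
}

#' @keywords internal
jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Counts synonymous and nonsynonymous sites and differences over a
#' codon-aware pairwise alignment (gapped lengths equal and divisible by
#' three). Site counts are averaged over the two sequences; multi-hit
#' codons are resolved by equal-weight averaging over all minimal
#' mutational pathways, excluding pathways through stop codons. Proportions
#' are Jukes-Cantor corrected, `d = -(3/4) log(1 - 4p/3)`. Codons
#' containing gaps or ambiguity, and codons that are stops in either
#' sequence (mid-alignment stops are tolerated with a warning, as in
#' plastid pseudogenes), are skipped.
#'
#' @param ref,qry equal-length gapped in-frame CDS strings; alternatively
#'   `ref` may be a [pairwise_alignment()]
#' @param gene_id identifier carried through to the result
#' @return a `kaks_result`: list with `s_sites`, `n_sites`, `sd`, `nd`,
#'   `ps`, `pn`, `ks`, `ka`, `ratio`, `selection_class`, `codons_used`,
#'   `codons_skipped`
#' @export
ng86_pairwise <- function(ref, qry = NULL, gene_id = NA_character_) {
  if (inherits(ref, "pairwise_alignment")) {
    qry <- ref$qry; ref <- ref$ref
  }
  ref <- toupper(ref); qry <- toupper(qry)
  if (nchar(ref) != nchar(qry)) stop("gapped lengths differ")
  if (nchar(ref) %% 3L != 0L) stop("alignment length not divisible by 3")
  code <- plastid_code()
  stab <- ng86_site_table()
  idx <- seq(1L, nchar(ref), 3L)
  c1 <- substring(ref, idx, idx + 2L)
  c2 <- substring(qry, idx, idx + 2L)
  S1 <- S2 <- Sd <- Nd <- 0
  used <- 0L; skipped <- 0L; stop_warned <- FALSE
  for (i in seq_along(c1)) {
    a <- c1[i]; b <- c2[i]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) { skipped <- skipped + 1L; next }
    if (code[[a]] == "*" || code[[b]] == "*") {
      if (!stop_warned) {
        warning("mid-alignment stop codon(s) skipped")
        stop_warned <- TRUE
      }
      skipped <- skipped + 1L; next
    }
    used <- used + 1L
    S1 <- S1 + stab[[a]]
    S2 <- S2 + stab[[b]]
    d <- ng86_path_diffs(a, b)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  if (used == 0L) stop("no aligned codons usable for Ka/Ks")
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  ratio <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  cls <- if (is.na(ratio)) "undefined"
         else if (ratio < 1) "purifying"
         else if (ratio > 1) "positive"
         else "neutral"
  structure(list(gene_id = gene_id, s_sites = S, n_sites = N,
                 sd = Sd, nd = Nd, ps = ps, pn = pn, ks = ks, ka = ka,
                 ratio = ratio, selection_class = cls,
                 codons_used = used, codons_skipped = skipped),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<Ka/Ks (NG86)> %s: Ka=%.4f Ks=%.4f ratio=%s (%s), %d codons\n",
              x$gene_id %||% "", x$ka %||% NA, x$ks %||% NA,
              ifelse(is.na(x$ratio), "NA", sprintf("%.4f", x$ratio)),
              x$selection_class, x$codons_used))
  invisible(x)
}

#' Genome-wide Ka/Ks summary over ortholog pairs
#'
#' @param pairs named list; each element is `list(ref=, qry=)` with
#'   codon-aware aligned CDS strings, or a [pairwise_alignment()]
#' @return list with `table` (per-gene data.frame including uncorrected
#'   pn/ps for comparability), `mean_ratio` over defined ratios,
#'   `n_defined`, and `excluded` (gene/reason data.frame)
#' @export
genome_kaks_summary <- function(pairs) {
  rows <- NULL; excl <- NULL
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    res <- tryCatch({
      if (inherits(p, "pairwise_alignment")) ng86_pairwise(p, gene_id = nm)
      else ng86_pairwise(p$ref, p$qry, gene_id = nm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl <- rbind(excl, data.frame(gene = nm, reason = conditionMessage(res)))
      next
    }
    rows <- rbind(rows, data.frame(
      gene = nm, s_sites = res$s_sites, n_sites = res$n_sites,
      sd = res$sd, nd = res$nd, ps = res$ps, pn = res$pn,
      ks = res$ks, ka = res$ka, ratio = res$ratio,
      selection_class = res$selection_class))
    if (is.na(res$ratio)) {
      excl <- rbind(excl, data.frame(
        gene = nm,
        reason = if (!is.na(res$ks) && res$ks == 0) "Ks = 0"
                 else "distance correction undefined"))
    }
  }
  defined <- rows$ratio[!is.na(rows$ratio)]
  list(table = rows,
       mean_ratio = if (length(defined)) mean(defined) else NA_real_,
       n_defined = length(defined),
       excluded = excl)
}
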