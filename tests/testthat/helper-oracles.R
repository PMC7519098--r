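## Independent brute-force oracles used to check the scanners. These are
## deliberately written with different machinery from the package
## implementations (explicit character scanning and dense diagonal
## comparison instead of k-mer anchoring and vectorised rle runs).

## --- SSR oracle ------------------------------------------------------------

## All maximal perfect tandem runs found by explicit left-to-right character
## scanning, filtered by threshold and motif primitivity, then passed through
## the documented resolution rule (smaller unit, longer run, leftmost).
oracle_ssrs <- function(seq, thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                            `4` = 3L, `5` = 3L, `6` = 3L)) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  acgt <- x %in% c("A", "C", "G", "T")
  cand <- NULL
  for (m in 1:6) {
    j <- 1L
    while (j + m <= n) {
      if (acgt[j] && acgt[j + m] && x[j] == x[j + m]) {
        a <- j
        while (j + m <= n && acgt[j + m] && x[j] == x[j + m]) j <- j + 1L
        total <- (j - a) + m                     # bp covered by the period
        count <- total %/% m
        if (count >= thresholds[[as.character(m)]]) {
          motif <- paste(x[a:(a + m - 1L)], collapse = "")
          primitive <- TRUE
          if (m > 1L) {
            for (d in 1:(m - 1L)) {
              if (m %% d == 0L &&
                  motif == strrep(substr(motif, 1L, d), m %/% d)) {
                primitive <- FALSE
                break
              }
            }
          }
          if (primitive) {
            cand <- rbind(cand, data.frame(start = a - 1L,
                                           end = a - 1L + m * count,
                                           motif = motif, unit = m,
                                           repeat_count = count))
          }
        }
        j <- j + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit = integer(), repeat_count = integer()))
  }
  cand <- cand[order(cand$unit, -(cand$end - cand$start), cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  taken <- NULL
  for (i in seq_len(nrow(cand))) {
    ok <- is.null(taken) ||
      !any(pmax(taken[, 1], cand$start[i]) < pmin(taken[, 2], cand$end[i]))
    if (ok) {
      sel[i] <- TRUE
      taken <- rbind(taken, c(cand$start[i], cand$end[i]))
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- maximal repeat oracle --------------------------------------------------

## Dense diagonal comparison: for every diagonal offset, compare the two
## character vectors elementwise and read maximal TRUE runs with rle.
oracle_repeats <- function(seq, min_len = 18L,
                           kinds = c("direct", "inverted", "complement",
                                     "palindromic")) {
  comp <- function(v) chartr("ACGTN", "TGCAN", v)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  out <- NULL
  for (kind in kinds) {
    y <- switch(kind,
                direct = x, inverted = rev(x),
                complement = comp(x), palindromic = rev(comp(x)))
    for (d in (-(n - min_len)):(n - min_len)) {
      ii <- max(1L, 1L + d):min(n, n + d)      # x indices on this diagonal
      pp <- ii - d                             # y indices
      eq <- x[ii] == y[pp]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values & r$lengths >= min_len)) {
        i0 <- ii[starts[j]] - 1L               # 0-based start in x
        p0 <- pp[starts[j]] - 1L               # 0-based start in y
        len <- r$lengths[j]
        if (kind == "direct" && i0 == p0) next
        pos2 <- if (kind %in% c("inverted", "palindromic")) n - p0 - len else p0
        out <- rbind(out, data.frame(kind = kind,
                                     pos1 = min(i0, pos2),
                                     pos2 = max(i0, pos2), length = len))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(kind = character(), pos1 = integer(),
                      pos2 = integer(), length = integer()))
  }
  out <- unique(out)
  out <- out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- inverted-repeat oracle (small circular genomes) ------------------------

## Longest circular inverted pair by dense diagonal comparison on the
## doubled sequence; returns the maximal disjoint pair length.
oracle_longest_ir <- function(seq) {
  comp <- function(v) chartr("ACGTN", "TGCAN", v)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  x2 <- c(x, x)
  y2 <- c(rev(comp(x)), rev(comp(x)))
  best <- 0L
  m <- 2L * n
  for (d in (-(m - 1L)):(m - 1L)) {
    ii <- max(1L, 1L + d):min(m, m + d)
    pp <- ii - d
    eq <- x2[ii] == y2[pp]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- (ii[starts[j]] - 1L) %% n
      p0 <- (pp[starts[j]] - 1L) %% n
      len <- min(r$lengths[j], n)
      a2 <- (n - p0 - len) %% n
      disjoint <- ((a2 - i0) %% n) >= len && ((i0 - a2) %% n) >= len
      if (disjoint && i0 != a2 && len > best) best <- len
    }
  }
  best
}

## --- NG86 oracle ------------------------------------------------------------

## Pathway enumeration over explicit permutation matrices (no recursion),
## using the genetic code straight from Biostrings.
oracle_ng86_diffs <- function(c1, c2) {
  code <- Biostrings::getGeneticCode("11")
  perm_tab <- list(matrix(1L, 1, 1),
                   rbind(c(1L, 2L), c(2L, 1L)),
                   rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(0, 0))
  P <- perm_tab[[length(pos)]]
  paths <- matrix(NA_real_, nrow(P), 2)
  for (r in seq_len(nrow(P))) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in pos[P[r, ]]) {
      from <- code[[paste(cur, collapse = "")]]
      cur[p] <- b[p]
      to <- code[[paste(cur, collapse = "")]]
      if (to == "*") { blocked <- TRUE; break }
      if (from == to) sd <- sd + 1 else nd <- nd + 1
    }
    if (!blocked) paths[r, ] <- c(sd, nd)
  }
  ok <- !is.na(paths[, 1])
  if (!any(ok)) {
    ## all pathways blocked by a stop: count through stops
    for (r in seq_len(nrow(P))) {
      cur <- a
      sd <- 0; nd <- 0
      for (p in pos[P[r, ]]) {
        from <- code[[paste(cur, collapse = "")]]
        cur[p] <- b[p]
        to <- code[[paste(cur, collapse = "")]]
        if (from == to) sd <- sd + 1 else nd <- nd + 1
      }
      paths[r, ] <- c(sd, nd)
    }
    ok <- rep(TRUE, nrow(P))
  }
  colMeans(paths[ok, , drop = FALSE])
}

oracle_ng86_sites <- function(codon) {
  code <- Biostrings::getGeneticCode("11")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (bb in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- bb
      aa <- code[[paste(alt, collapse = "")]]
      if (aa == "*") next
      nonstop <- nonstop + 1L
      if (aa == code[[codon]]) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  s
}

## --- misc helpers ------------------------------------------------------------

## Apply a variant table back onto the reference: the patch property.
apply_variants <- function(ref, variants) {
  ch <- as.list(strsplit(ref, "")[[1]])
  ins_tail <- ""
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$type == "SNP") {
      ch[[v$ref_pos + 1L]] <- v$alt_allele
    } else if (v$ref_allele == "-") {           # insertion before ref_pos
      if (v$ref_pos + 1L > length(ch)) {
        ins_tail <- paste0(ins_tail, v$alt_allele)
      } else {
        ch[[v$ref_pos + 1L]] <- paste0(v$alt_allele, ch[[v$ref_pos + 1L]])
      }
    } else {                                     # deletion of ref bases
      for (p in v$ref_pos:(v$ref_pos + nchar(v$ref_allele) - 1L)) {
        stopifnot(ch[[p + 1L]] == substr(v$ref_allele, p - v$ref_pos + 1L,
                                         p - v$ref_pos + 1L))
        ch[[p + 1L]] <- ""
      }
    }
  }
  paste0(paste(unlist(ch), collapse = ""), ins_tail)
}

## Small synthetic plastome shared by several tests.
tiny_plastome <- function(seed = 1L, ...) {
  generate_plastome(plastome_spec(1000, 300, 200, seed = seed, ...))
}
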