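## Exact-match machinery shared by IR detection, maximal-repeat finding and
## long-read classification: maximal common-substring runs between two
## strings found by k-mer anchoring and chaining along diagonals.
##
## An anchor is a k-mer shared by S and T; anchors with equal diagonal
## d = i - p and consecutive i chain into runs. A chained run [i0, i1+k) is a
## *maximal* exact match: the absence of the neighbouring anchor on the same
## diagonal implies a mismatching character just outside the run (given the
## in-run characters all match), so no run can be extended.

#' @keywords internal
diagonal_runs <- function(S, T, k, max_occ = Inf) {
  nS <- nchar(S); nT <- nchar(T)
  if (nS < k || nT < k)
    return(data.frame(i = integer(), p = integer(), len = integer()))
  iS <- seq_len(nS - k + 1L)
  iT <- seq_len(nT - k + 1L)
  kS <- substring(S, iS, iS + k - 1L)
  kT <- substring(T, iT, iT + k - 1L)
  idx <- split(iT - 1L, kT)                       # 0-based positions per k-mer
  if (is.finite(max_occ)) idx <- idx[lengths(idx) <= max_occ]
  hit <- idx[kS]
  nhit <- lengths(hit)
  keep <- nhit > 0L
  if (!any(keep))
    return(data.frame(i = integer(), p = integer(), len = integer()))
  i <- rep.int(iS[keep] - 1L, nhit[keep])         # 0-based S positions
  p <- unlist(hit[keep], use.names = FALSE)
  d <- i - p
  o <- order(d, i)
  i <- i[o]; d <- d[o]
  m <- length(i)
  newrun <- c(TRUE, d[-1L] != d[-m] | i[-1L] != i[-m] + 1L)
  cnt <- diff(c(which(newrun), m + 1L))
  i0 <- i[newrun]
  data.frame(i = i0, p = i0 - d[newrun], len = cnt + k - 1L)
}

## Merge exact runs on a shared diagonal into mismatch-tolerant runs: greedy
## left-to-right chaining while the gap characters spent stay within budget.
#' @keywords internal
merge_runs_with_mismatches <- function(runs, max_mismatch) {
  if (max_mismatch <= 0L || nrow(runs) < 2L) return(runs)
  d <- runs$i - runs$p
  out <- list()
  for (dd in unique(d)) {
    r <- runs[d == dd, , drop = FALSE]
    r <- r[order(r$i), , drop = FALSE]
    cur <- r[1L, ]
    used <- 0L
    for (j in seq_len(nrow(r))[-1L]) {
      gap <- r$i[j] - (cur$i + cur$len)
      if (gap >= 0L && used + gap <= max_mismatch) {
        used <- used + gap
        cur$len <- r$i[j] + r$len[j] - cur$i
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- r[j, ]
        used <- 0L
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

## Hamming mismatches between two equal-length strings.
#' @keywords internal
count_mismatches <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}
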