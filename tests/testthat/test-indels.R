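## A small labelled alignment in the style of a multi-genus gene set:
## two genera with two members each, plus an outgroup.
mk_msa <- function() {
  seqs <- c(
    g1a = "ATGCATGCATGCATGCATGC",
    g1b = "ATGCATGCATGCATGCATGC",
    g2a = "ATGCATGCATGCATGCATGC",
    g2b = "ATGCATGCATGCATGCATGC",
    out = "ATGCATGCATGCATGCATGC")
  labels <- c(g1a = "Alpha", g1b = "Alpha", g2a = "Beta", g2b = "Beta")
  list(seqs = seqs, labels = labels)
}

test_that("indel events are maximal shared gap blocks with polarity", {
  m <- mk_msa()
  ## one 3 bp deletion in a single sequence vs the majority
  m$seqs["g1a"] <- "ATGC---CATGCATGCATGC"
  msa <- labeled_alignment(m$seqs, m$labels, outgroup = "out")
  ev <- extract_indel_events(msa)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "deletion")
  expect_equal(ev$start, 4L)
  expect_equal(ev$end, 7L)
  expect_equal(ev$carriers, "g1a")
  ## no gaps -> no events
  m2 <- mk_msa()
  msa2 <- labeled_alignment(m2$seqs, m2$labels, outgroup = "out")
  expect_equal(nrow(extract_indel_events(msa2)), 0L)
  ## gap in all but one genus incl. outgroup -> insertion carried by the rest
  m3 <- mk_msa()
  m3$seqs["g1a"] <- "ATGCAT--ATGCATGCATGC"
  m3$seqs["g1b"] <- "ATGCAT--ATGCATGCATGC"
  m3$seqs["out"] <- "ATGCAT--ATGCATGCATGC"
  msa3 <- labeled_alignment(m3$seqs, m3$labels, outgroup = "out")
  ev3 <- extract_indel_events(msa3)
  expect_equal(ev3$polarity, "insertion")
  expect_equal(ev3$carriers, "g2a,g2b")
  ## an all-gap column is malformed
  m4 <- mk_msa()
  m4$seqs[] <- sub("^ATGC", "-TGC", m4$seqs)
  expect_error(extract_indel_events(
    labeled_alignment(m4$seqs, m4$labels, outgroup = "out")), "all-gap")
})

test_that("group specificity is strict on the carrier set", {
  m <- mk_msa()
  ## genus-specific insertion: both Alpha members carry bases, others gap
  m$seqs["g2a"] <- "ATGCAT------GCATGC--"
  m$seqs["g2b"] <- "ATGCAT------GCATGC--"
  m$seqs["out"] <- "ATGCAT------GCATGCAT"
  ## pad to equal length
  m$seqs["g1a"] <- "ATGCATGCATGCGCATGCAT"
  m$seqs["g1b"] <- "ATGCATGCATGCGCATGCAT"
  msa <- labeled_alignment(m$seqs, m$labels, outgroup = "out")
  ev <- extract_indel_events(msa)
  res <- group_specific_events(ev, msa)
  ## the 6-column block is an Alpha-specific insertion (outgroup gapped)
  ins <- res$events[res$events$polarity == "insertion", ]
  expect_equal(ins$specific_to, "Alpha")
  ## the trailing 2-column gap is carried by both Beta members only
  del <- res$events[res$events$polarity == "deletion", ]
  expect_equal(del$specific_to, "Beta")
  tab <- res$table
  expect_equal(tab$insertions[tab$group == "Alpha"], 1L)
  expect_equal(tab$deletions[tab$group == "Beta"], 1L)
})

test_that("events shared across groups or partial within a group are specific to none", {
  m <- mk_msa()
  ## carried by one Alpha and one Beta member: crosses groups
  m$seqs["g1a"] <- "ATGC--GCATGCATGCATGC"
  m$seqs["g2a"] <- "ATGC--GCATGCATGCATGC"
  msa <- labeled_alignment(m$seqs, m$labels, outgroup = "out")
  res <- group_specific_events(extract_indel_events(msa), msa)
  expect_true(all(is.na(res$events$specific_to)))
  ## carried by one of two members of a genus: strict rule says none
  m2 <- mk_msa()
  m2$seqs["g1a"] <- "ATGC--GCATGCATGCATGC"
  msa2 <- labeled_alignment(m2$seqs, m2$labels, outgroup = "out")
  res2 <- group_specific_events(extract_indel_events(msa2), msa2)
  expect_true(all(is.na(res2$events$specific_to)))
})

test_that("group-specific SNPs require a full-group derived state", {
  m <- mk_msa()
  ## Alpha-specific substitution at column 0 (A -> T in both Alpha members)
  substr(m$seqs["g1a"], 1, 1) <- "T"
  substr(m$seqs["g1b"], 1, 1) <- "T"
  ## a substitution shared across groups at column 4
  substr(m$seqs["g1a"], 5, 5) <- "G"
  substr(m$seqs["g2a"], 5, 5) <- "G"
  msa <- labeled_alignment(m$seqs, m$labels, outgroup = "out")
  snps <- group_specific_snps(msa)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$column, 0L)
  expect_equal(snps$base, "T")
  expect_equal(snps$group, "Alpha")
})

test_that("event extraction is order-invariant and matches a column-scan oracle", {
  set.seed(111)
  for (rep in 1:5) {
    base <- random_dna(40, 0.5)
    seqs <- setNames(rep(base, 5), c("a1", "a2", "b1", "b2", "out"))
    ## plant two gap blocks
    for (id in sample(setdiff(names(seqs), "out"), 2)) {
      st <- sample(5:30, 1)
      len <- sample(2:4, 1)
      substr(seqs[id], st, st + len - 1L) <- strrep("-", len)
    }
    labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
    msa <- labeled_alignment(seqs, labels, outgroup = "out")
    ev <- extract_indel_events(msa)
    ## oracle: per-sequence gap blocks via explicit column scanning
    blocks <- NULL
    for (id in names(seqs)) {
      ch <- strsplit(seqs[[id]], "")[[1]]
      j <- 1L
      while (j <= length(ch)) {
        if (ch[j] == "-") {
          a <- j
          while (j <= length(ch) && ch[j] == "-") j <- j + 1L
          blocks <- rbind(blocks, data.frame(start = a - 1L, end = j - 1L))
        } else j <- j + 1L
      }
    }
    expect_equal(nrow(ev), nrow(unique(blocks)))
    ## permuting sequence order changes nothing
    perm <- sample(names(seqs))
    msa_p <- labeled_alignment(seqs[perm], labels, outgroup = "out")
    ev_p <- extract_indel_events(msa_p)
    expect_equal(ev_p[order(ev_p$start, ev_p$end), c("start", "end", "polarity")],
                 ev[order(ev$start, ev$end), c("start", "end", "polarity")],
                 ignore_attr = TRUE)
    ## specific-event count never exceeds the total
    res <- group_specific_events(ev, msa)
    expect_lte(sum(!is.na(res$events$specific_to)), nrow(ev))
  }
})

test_that("terminal conservation reflects identical flanks", {
  m <- mk_msa()
  msa <- labeled_alignment(m$seqs, m$labels, outgroup = "out")
  tc <- terminal_conservation(msa, five_prime = 8, three_prime = 8)
  expect_equal(unname(tc), c(1, 1))
})
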