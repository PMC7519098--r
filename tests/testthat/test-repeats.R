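test_that("SSR class thresholds are sharp", {
  pad1 <- "GCTAGCTTGCAGTCCGTAGGCTG"          # SSR-free padding
  pad2 <- "CGATCGGACTGCAAGGCATCCGG"
  mk <- function(core) paste0(pad1, core, pad2)
  expect_equal(nrow(scan_ssrs(mk(strrep("A", 9)))), 0L)
  ten <- scan_ssrs(mk(strrep("A", 10)))
  expect_equal(nrow(ten), 1L)
  expect_equal(ten$unit, 1L)
  expect_equal(ten$repeat_count, 10L)
  expect_equal(nrow(scan_ssrs(mk(strrep("AT", 4)))), 0L)
  di <- scan_ssrs(mk(strrep("AT", 5)))
  expect_equal(di$unit, 1L + 1L)
  expect_equal(di$repeat_count, 5L)
  ## non-primitive motifs report at the smallest unit
  tetra <- scan_ssrs(mk(strrep("ATAT", 4)))
  expect_true(all(tetra$unit == 2L))
  ## N breaks runs
  expect_equal(nrow(scan_ssrs(mk(paste0(strrep("A", 6), "N", strrep("A", 6))))), 0L)
})

test_that("SSR census equals the brute-force oracle on random sequences", {
  for (seed in 1:6) {
    set.seed(seed)
    s <- random_dna(5000, 0.37)
    ## plant a few loci so the comparison is not vacuous
    substr(s, 1200, 1211) <- strrep("A", 12)
    substr(s, 2400, 2409) <- strrep("AT", 5)
    substr(s, 3600, 3611) <- strrep("CAG", 4)
    got <- scan_ssrs(s)
    want <- oracle_ssrs(s)
    expect_equal(got[, c("start", "end", "motif", "unit", "repeat_count")],
                 want, ignore_attr = TRUE)
  }
})

test_that("SSR census is strand-symmetric after canonical-motif mapping", {
  g <- generate_plastome(plastome_spec(
    2000, 300, 400, seed = 31,
    planted_ssrs = list(list(motif = "A", count = 12, region = "lsc"),
                        list(motif = "AT", count = 6, region = "lsc"),
                        list(motif = "AAG", count = 5, region = "ssc"))))
  fwd <- scan_ssrs(g$genome)
  rev <- scan_ssrs(revcomp(g$genome$seq))
  expect_equal(sort(fwd$canonical_motif), sort(rev$canonical_motif))
  expect_equal(sort(fwd$repeat_count), sort(rev$repeat_count))
})

test_that("raising SSR thresholds never adds loci", {
  g <- generate_plastome(plastome_spec(
    2000, 300, 400, seed = 32,
    planted_ssrs = list(list(motif = "A", count = 11, region = "lsc"),
                        list(motif = "CT", count = 7, region = "lsc"))))
  base <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
  n0 <- nrow(scan_ssrs(g$genome, thresholds = base))
  for (u in names(base)) {
    up <- base; up[u] <- up[u] + 1L
    expect_lte(nrow(scan_ssrs(g$genome, thresholds = up)), n0)
  }
})

test_that("compound grouping joins nearby loci", {
  s <- paste0("GCTAGCTTGCAGTCCGTAGGCTAGCAT", strrep("A", 10), "GCTTGCA",
              strrep("TC", 6), "CGATCGGACTGCAAGGCATCCGGAC")
  loci <- scan_ssrs(s, compound_gap = 20)
  expect_equal(nrow(loci), 2L)
  expect_equal(length(unique(loci$compound_group)), 1L)
  loci2 <- scan_ssrs(s, compound_gap = 3)
  expect_equal(length(unique(loci2$compound_group)), 2L)
})

test_that("planted repeat pairs of every kind are found exactly", {
  set.seed(40)
  mkpad <- function(n) random_dna(n, 0.5)
  for (kind in c("direct", "inverted", "complement", "palindromic")) {
    x <- random_dna(20, 0.5)
    y <- switch(kind, direct = x, inverted = dna_reverse(x),
                complement = dna_complement(x), palindromic = revcomp(x))
    s <- paste0(mkpad(300), x, mkpad(200), y, mkpad(300))
    got <- find_maximal_repeats(s, min_len = 18, kinds = kind)
    expect_gte(nrow(got), 1L)
    hit <- got[got$length >= 20, ]
    expect_equal(nrow(hit), 1L)
    expect_lte(hit$pos1, 300); expect_gte(hit$pos1 + hit$length, 320)
  }
})

test_that("maximal repeats equal the dense diagonal oracle", {
  for (seed in 1:4) {
    set.seed(seed + 50)
    s <- random_dna(1500, 0.37)
    x <- random_dna(22, 0.5)
    substr(s, 200, 221) <- x
    substr(s, 700, 721) <- x                       # direct pair
    substr(s, 1000, 1021) <- revcomp(x)            # palindromic partners
    got <- find_maximal_repeats(s, min_len = 18)
    want <- oracle_repeats(s, min_len = 18)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("a strand-symmetric run is reported once at its own location", {
  s <- paste0("GCTAGCTTGCAGTCCGTAGGCTACC", strrep("A", 18),
              "CCGATCGGACTGCAAGGCATCCGG")
  inv <- find_maximal_repeats(s, min_len = 18, kinds = "inverted")
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$pos1, inv$pos2)
})

test_that("the IR pair is the longest palindromic hit on a plastome", {
  g <- tiny_plastome(seed = 33L)
  p <- detect_inverted_repeats(g$genome, min_ir_len = 100)
  reps <- find_maximal_repeats(g$genome, min_len = 18, partition = p)
  pal <- reps[reps$kind == "palindromic", ]
  expect_gte(nrow(pal), 1L)
  top <- pal[which.max(pal$length), ]
  expect_gte(top$length, 300L)
  expect_true(top$in_ir)
})
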