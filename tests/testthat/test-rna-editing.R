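mk_ev <- function(position = 10L, ref = "C", alt = "T", replicate = 1L,
                  quality = 30, depth = 50, dp4 = c(10, 10, 15, 15)) {
  data.frame(position = position, ref = ref, alt = alt, replicate = replicate,
             quality = quality, depth = depth,
             ref_fwd = dp4[1], ref_rev = dp4[2],
             alt_fwd = dp4[3], alt_rev = dp4[4])
}

test_that("candidate filters apply the exact quality/depth/change rules", {
  expect_equal(nrow(filter_candidates(mk_ev(quality = 19))), 0L)
  expect_equal(nrow(filter_candidates(mk_ev(quality = 20))), 1L)
  expect_equal(nrow(filter_candidates(mk_ev(depth = 10))), 0L)
  expect_equal(nrow(filter_candidates(mk_ev(depth = 11))), 1L)
  expect_equal(nrow(filter_candidates(mk_ev(depth = 10), strict_depth = FALSE)), 1L)
  ## only C>T (forward) and G>A (reverse) encode C-to-U
  expect_equal(nrow(filter_candidates(mk_ev(ref = "A", alt = "G"))), 0L)
  expect_equal(nrow(filter_candidates(mk_ev(ref = "G", alt = "A"))), 1L)
  expect_equal(nrow(filter_candidates(mk_ev(ref = "C", alt = "A"))), 0L)
  ## non-SNV records dropped with a message
  expect_message(out <- filter_candidates(mk_ev(alt = "TT")), "non-SNV")
  expect_equal(nrow(out), 0L)
})

test_that("editing efficiency is edited over total reads", {
  expect_equal(editing_efficiency(c(2, 2, 3, 3)), 0.6)
  expect_equal(editing_efficiency(c(0, 0, 5, 5)), 1)
  expect_equal(editing_efficiency(c(5, 5, 0, 0)), 0)
  expect_warning(v <- editing_efficiency(c(0, 0, 0, 0)), "undefined")
  expect_true(is.na(v))
  m <- rbind(c(2, 2, 3, 3), c(0, 0, 5, 5))
  expect_equal(editing_efficiency(m), c(0.6, 1))
})

test_that("consensus requires the replicate threshold and rejects duplicates", {
  ev1 <- mk_ev(replicate = 1L)
  expect_equal(nrow(consensus_sites(ev1, min_replicates = 2)), 0L)
  ev2 <- rbind(mk_ev(replicate = 1L), mk_ev(replicate = 2L, dp4 = c(5, 5, 5, 5)))
  out <- consensus_sites(ev2, min_replicates = 2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$supporting_replicates, 2L)
  expect_equal(out$mean_efficiency, mean(c(0.6, 0.5)))
  expect_equal(out$weighted_efficiency, (30 + 10) / (50 + 20))
  ## raising the threshold never adds sites
  expect_lte(nrow(consensus_sites(ev2, min_replicates = 3)), nrow(out))
  expect_error(consensus_sites(rbind(ev1, ev1)), "duplicate")
})

test_that("planted editing sites round-trip exactly at high depth", {
  g <- generate_plastome(plastome_spec(3000, 400, 600, seed = 91))
  sites <- pick_editing_sites(g$genome, 20, seq(0.3, 0.9, length.out = 20),
                              seed = 92)
  pu <- simulate_pileups(g$genome, editing_sim_spec(sites, n_replicates = 4,
                                                    depth_mean = 100, seed = 93))
  cons <- consensus_sites(filter_candidates(pu$evidence), min_replicates = 2)
  expect_equal(cons$position, sites$position)
  expect_lt(max(abs(cons$mean_efficiency - sites$efficiency)), 0.2)
})

test_that("codon effects are annotated strand-aware, including ACG start repair", {
  ## forward gene: ACG TCA TTA ... an edit at codon position 2 of codon 1
  gseq <- paste0("TTTTTTTTTT", "ACGTCATTAGGG", "TTTTTTTTTT")
  feats <- feature_table("ndhD", "CDS", "+", 10, 22)
  ## the C of the ACG start is genome position 11 (0-based)
  sites <- data.frame(position = 11L)
  ann <- annotate_codon_effect(sites, gseq, feats)
  expect_equal(ann$region, "ndhD")
  expect_equal(ann$codon_position, 2L)
  expect_equal(ann$ref_codon, "ACG")
  expect_equal(ann$alt_codon, "ATG")
  expect_equal(ann$aa_change, "T>M")
  ## the same gene on the minus strand: genome carries revcomp(ACG...)
  gseq2 <- paste0("TTTTTTTTTT", revcomp("ACGTCATTAGGG"), "TTTTTTTTTT")
  feats2 <- feature_table("ndhD", "CDS", "-", 10, 22)
  ## sense position of the edited C maps to genome position 10 + (12 - 1 - 1)
  sites2 <- data.frame(position = 10L + 12L - 2L)
  ann2 <- annotate_codon_effect(sites2, gseq2, feats2)
  expect_equal(ann2$codon_position, 2L)
  expect_equal(ann2$ref_codon, "ACG")
  expect_equal(ann2$alt_codon, "ATG")
  ## a synonymous third-position edit reports no amino-acid change
  gseq3 <- paste0("AAAAAAAAAA", "TTCGGG", "AAAAAAAAAA")
  feats3 <- feature_table("petB", "CDS", "+", 10, 16)
  ann3 <- annotate_codon_effect(data.frame(position = 12L), gseq3, feats3)
  expect_equal(ann3$codon_position, 3L)
  expect_true(ann3$synonymous)
  expect_equal(ann3$aa_change, "none")
  ## intergenic sites are labelled as such
  ann4 <- annotate_codon_effect(data.frame(position = 2L), gseq3, feats3)
  expect_equal(ann4$region, "intergenic")
})

test_that("annotated spectra match planted codon positions", {
  ## build a gene and edit one C at each codon position
  body <- strrep("CCTCCAGCC", 30)               # Pro/Pro/Ala codons, C-rich
  gseq <- paste0("AAAAAAAAAA", body, "AAAAAAAAAA")
  feats <- feature_table("rpoB", "CDS", "+", 10, 10 + nchar(body))
  sites <- data.frame(position = c(10L, 14L, 18L))  # codon pos 1, 2, 3
  ann <- annotate_codon_effect(sites, gseq, feats)
  expect_equal(ann$codon_position, c(1L, 2L, 3L))
  sm <- editing_summary(ann)
  expect_equal(unname(as.integer(sm$codon_position_spectrum)), c(1L, 1L, 1L))
})
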