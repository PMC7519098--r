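test_that("generated plastome has the planted quadripartite construction", {
  g <- tiny_plastome()
  s <- g$genome$seq
  expect_equal(g$genome$length, 1800L)
  ## last 300 bp are the reverse complement of the IRa block
  expect_identical(substr(s, 1501, 1800), revcomp(substr(s, 1001, 1300)))
  ## detection recovers the planted sizes exactly
  p <- detect_inverted_repeats(g$genome, min_ir_len = 100)
  expect_equal(unname(partition_sizes(p)), c(1000, 300, 200, 300))
})

test_that("generation is byte-identical under a fixed seed", {
  g1 <- tiny_plastome(seed = 9L)
  g2 <- tiny_plastome(seed = 9L)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$features, g2$features)
  g3 <- tiny_plastome(seed = 10L)
  expect_false(identical(g1$genome$seq, g3$genome$seq))
})

test_that("planted SSRs and repeats are recovered and validated", {
  g <- generate_plastome(plastome_spec(
    1000, 300, 200, seed = 2,
    planted_ssrs = list(list(motif = "AT", count = 6, region = "lsc")),
    planted_repeats = list(list(length = 25, kind = "direct",
                                pos1 = 50, pos2 = 400))))
  loci <- scan_ssrs(g$genome)
  tr <- g$truth$ssrs
  hit <- loci$unit == 2 & loci$start <= tr$start & loci$end >= tr$start + 2
  expect_true(any(hit))
  reps <- find_maximal_repeats(g$genome, min_len = 20)
  expect_true(any(reps$kind == "direct" & reps$pos1 <= 50 & reps$pos2 <= 400 &
                  reps$length >= 25))
  ## oversized or overlapping features are rejected with coordinates
  expect_error(generate_plastome(plastome_spec(
    1000, 300, 200, planted_ssrs = list(list(motif = "A", count = 300,
                                             region = "ssc")))),
    "does not fit")
  expect_error(generate_plastome(plastome_spec(
    1000, 300, 200,
    planted_repeats = list(list(length = 30, kind = "direct",
                                pos1 = 100, pos2 = 110)))),
    "overlaps")
})

test_that("mutate_genome honours the spec and arithmetic", {
  g <- tiny_plastome(seed = 3L)
  ## zero events -> identical sequence
  m0 <- mutate_genome(g$genome, divergence_spec(0, seed = 1))
  expect_identical(m0$genome$seq, g$genome$seq)
  expect_equal(nrow(m0$truth), 0L)
  ## a single 5 bp deletion shortens the genome by 5
  del <- divergence_spec(0, data.frame(position = 500, length = 5, type = "del"),
                         seed = 2)
  md <- mutate_genome(g$genome, del)
  expect_equal(md$genome$length, g$genome$length - 5L)
  ## snp_count rows appear in the truth table and round-trip through calling
  ds <- divergence_spec(10, seed = 7)
  mm <- mutate_genome(g$genome, ds)
  expect_equal(sum(mm$truth$type == "SNP"), 10L)
  calls <- call_snps_indels(mm$alignment)
  expect_equal(calls$n_snps, 10L)
  expect_equal(calls$n_indels, 0L)
})

test_that("IR-mirrored mutation keeps both copies identical", {
  g <- tiny_plastome(seed = 4L)
  part <- detect_inverted_repeats(g$genome, min_ir_len = 100)
  mm <- mutate_genome(g$genome, divergence_spec(21, seed = 5),
                      partition = part, ir_policy = "mirror")
  expect_equal(sum(mm$truth$type == "SNP"), 21L)
  p2 <- detect_inverted_repeats(mm$genome, min_ir_len = 100)
  expect_equal(partition_sizes(p2), partition_sizes(part))
  expect_equal(p2$mismatch_count, 0L)
})

test_that("simulated reads follow the mixture, wrap the circle, and are exact at zero error", {
  g <- tiny_plastome(seed = 6L)
  part <- detect_inverted_repeats(g$genome, min_ir_len = 100)
  pair <- build_structure_pair(g$genome, part)
  ## mix = 1 -> all labels A
  s1 <- simulate_long_reads(pair$form_A$seq, pair$form_B$seq,
                            read_sim_spec(30, c(200, 400), haplotype_mix = 1,
                                          seed = 1))
  expect_true(all(s1$truth$source == "A"))
  ## mix = 0.5, n = 200: labels inside the exact-binomial 99% interval
  s2 <- simulate_long_reads(pair$form_A$seq, pair$form_B$seq,
                            read_sim_spec(200, c(200, 400), 0.5, seed = 3))
  nA <- sum(s2$truth$source == "A")
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(nA, ci[1]); expect_lte(nA, ci[2])
  ## error-free reads are exact circular substrings of their source
  dbl <- list(A = paste0(pair$form_A$seq, pair$form_A$seq),
              B = paste0(pair$form_B$seq, pair$form_B$seq))
  for (i in seq_len(20)) {
    rd <- s2$reads[[i]]
    src <- dbl[[s2$truth$source[i]]]
    found <- grepl(rd, src, fixed = TRUE) || grepl(revcomp(rd), src, fixed = TRUE)
    expect_true(found)
  }
  ## min length > genome length is rejected
  expect_error(simulate_long_reads(pair$form_A$seq, pair$form_B$seq,
                                   read_sim_spec(5, c(5000, 6000))),
               "exceeds")
})

test_that("simulated pileups obey the DP4 contract", {
  g <- tiny_plastome(seed = 7L)
  ch <- strsplit(g$genome$seq, "")[[1]]
  cpos <- which(ch == "C")[1:3] - 1L
  ## efficiency 1 -> all reads alternate
  full <- simulate_pileups(g$genome, editing_sim_spec(
    data.frame(position = cpos, efficiency = 1), n_replicates = 1,
    depth_mean = 20, seed = 1))
  expect_true(all(full$evidence$ref_fwd + full$evidence$ref_rev == 0))
  expect_true(all(full$evidence$alt_fwd + full$evidence$alt_rev ==
                  full$evidence$depth))
  ## efficiency 0 -> no candidate rows at all
  none <- simulate_pileups(g$genome, editing_sim_spec(
    data.frame(position = cpos, efficiency = 0), n_replicates = 4,
    depth_mean = 50, seed = 2))
  expect_null(none$evidence)
  ## a site that is not C/G on the template is rejected by name
  apos <- which(ch == "A")[1] - 1L
  expect_error(simulate_pileups(g$genome, editing_sim_spec(
    data.frame(position = apos, efficiency = 0.5))),
    as.character(apos))
})
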