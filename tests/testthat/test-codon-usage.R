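code11 <- Biostrings::getGeneticCode("11")
all_codons <- sort(names(code11))
zero_counts <- function() setNames(rep(0, 64), all_codons)
families <- local({
  f <- split(names(code11), code11)
  f <- f[names(f) != "*"]
  f[lengths(f) >= 2]
})

test_that("RSCU follows the family-mean formula", {
  ## uniform usage in every family -> all RSCU 1
  cnt <- zero_counts()
  for (aa in names(families)) cnt[families[[aa]]] <- 7
  r <- rscu(cnt)
  expect_true(all(abs(r - 1) < 1e-12))
  ## the Phe textbook case
  cnt2 <- zero_counts(); cnt2["TTT"] <- 3; cnt2["TTC"] <- 1
  r2 <- suppressWarnings(rscu(cnt2))
  expect_equal(unname(r2["TTT"]), 1.5)
  expect_equal(unname(r2["TTC"]), 0.5)
  ## random tables match a direct per-family oracle, and family means are 1
  set.seed(71)
  for (rep in 1:5) {
    cnt3 <- zero_counts()
    cnt3[] <- rpois(64, 8) + 1
    r3 <- rscu(cnt3)
    for (aa in names(families)) {
      mem <- families[[aa]]
      expect_equal(unname(r3[mem]), unname(cnt3[mem] / mean(cnt3[mem])))
      expect_equal(mean(r3[mem]), 1, tolerance = 1e-12)
    }
  }
  ## zero-count family is omitted with a warning
  cnt4 <- zero_counts()
  cnt4[families[["K"]]] <- 5
  w <- capture_warnings(r4 <- rscu(cnt4))
  expect_true(any(grepl("zero counts", w)))
  expect_true(all(is.na(r4[families[["F"]]])))
})

test_that("CAI equals the log-domain geometric mean of reference weights", {
  ref <- zero_counts()
  for (aa in names(families)) {
    mem <- families[[aa]]
    ref[mem] <- seq(10, 10 + 5 * (length(mem) - 1), by = 5)
  }
  ## a gene using only family-maximal codons scores exactly 1
  gene <- zero_counts()
  for (aa in names(families)) {
    mem <- families[[aa]]
    gene[mem[which.max(ref[mem])]] <- 4
  }
  expect_equal(cai(gene, ref), 1)
  ## duplication invariance
  expect_equal(cai(gene * 2, ref), cai(gene, ref))
  ## log-domain oracle on a random gene
  set.seed(72)
  gene2 <- zero_counts()
  gene2[] <- rpois(64, 3)
  w <- setNames(rep(NA_real_, 64), all_codons)
  for (aa in names(families)) {
    mem <- families[[aa]]
    rr <- ref[mem] / mean(ref[mem])
    w[mem] <- rr / max(rr)
  }
  info <- unlist(families, use.names = FALSE)
  use <- info[gene2[info] > 0]
  oracle <- exp(sum(gene2[use] * log(w[use])) / sum(gene2[use]))
  expect_equal(cai(gene2, ref), oracle)
  expect_error(cai(zero_counts(), ref), "no informative codons")
})

test_that("ENC hits its closed-form extremes and bounds", {
  ## closed form: uniform usage has Fk = 1/k and ENC = 61
  expect_equal(enc_wright(1/2, 1/3, 1/4, 1/6), 61)
  ## one codon per family gives F = 1 exactly and ENC = 20
  cnt <- zero_counts()
  for (aa in names(families)) cnt[families[[aa]][1]] <- 25
  expect_equal(enc(cnt), 20)
  ## large uniform counts converge to 61
  cnt2 <- zero_counts()
  for (aa in names(families)) cnt2[families[[aa]]] <- 5000
  expect_equal(enc(cnt2), 61, tolerance = 1e-3)
  ## a simulated uniform-usage gene approaches 61
  set.seed(73)
  draw <- zero_counts()
  sim <- sample(unlist(families), 20000, replace = TRUE)
  tb <- table(sim); draw[names(tb)] <- as.numeric(tb)
  expect_equal(enc(draw), 61, tolerance = 0.5)
  ## ENC decreases monotonically as usage concentrates
  bias_counts <- function(b) {  # b = 0 uniform, 1 fully biased
    cnt <- zero_counts()
    for (aa in names(families)) {
      mem <- families[[aa]]
      p <- rep((1 - b) / length(mem), length(mem))
      p[1] <- p[1] + b
      cnt[mem] <- round(4000 * p)
    }
    cnt
  }
  encs <- vapply(c(0, 0.25, 0.5, 0.75, 0.95), function(b) enc(bias_counts(b)),
                 numeric(1))
  expect_true(all(diff(encs) < 0))
  expect_true(all(encs >= 20 & encs <= 61))
})

test_that("GC by codon position is computed per frame", {
  g1 <- setNames(strrep("GGCGGC", 60), "allgc")       # 360 bp, all G/C
  out <- gc_by_codon_position(g1, min_len = 300)
  expect_equal(unlist(out[1, c("gc1", "gc2", "gc3", "gc12", "gc_all")]),
               c(gc1 = 1, gc2 = 1, gc3 = 1, gc12 = 1, gc_all = 1))
  g2 <- setNames(strrep("GCA", 120), "gca")           # GC at 1,2; A at 3
  out2 <- gc_by_codon_position(g2, min_len = 300)
  expect_equal(unname(unlist(out2[1, c("gc1", "gc2", "gc3")])), c(1, 1, 0))
  ## genes at or below the length filter are dropped
  expect_error(gc_by_codon_position(setNames(strrep("GCA", 100), "short"),
                                    min_len = 300),
               "no gene passed")
})

test_that("neutrality regression matches the closed-form OLS oracle", {
  gc3 <- c(0.2, 0.3, 0.4, 0.5)
  perfect <- suppressWarnings(neutrality_regression(gc3, gc3))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$r_squared, 1)
  flat <- neutrality_regression(rep(0.4, 4), gc3)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  set.seed(74)
  x <- runif(20, 0.2, 0.4); y <- 0.3 + 0.2 * x + rnorm(20, 0, 0.01)
  fit <- neutrality_regression(y, x)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  r2 <- (cov(x, y) / (sd(x) * sd(y)))^2
  expect_equal(fit$slope, b)
  expect_equal(fit$intercept, a)
  expect_equal(fit$r_squared, r2)
  expect_true(neutrality_regression(y, rep(0.5, 20))$undefined)
})

test_that("codon_usage_stats assembles per-gene records with classes", {
  set.seed(75)
  mk_gene <- function() {
    paste(c("ATG", sample(unlist(families), 150, replace = TRUE), "TAA"),
          collapse = "")
  }
  cds <- setNames(vapply(1:6, function(i) mk_gene(), character(1)),
                  c("psbA", "petB", "rbcL", "rps12", "rpoC1", "ycf1"))
  cub <- codon_usage_stats(cds, min_len = 300)
  expect_equal(cub$stats$gene_class,
               c("photo", "photo", "photo", "genet", "genet", "other"))
  expect_true(all(cub$stats$enc >= 20 & cub$stats$enc <= 61))
  expect_true(all(cub$stats$cai > 0 & cub$stats$cai <= 1))
  expect_equal(nrow(cub$gc), 7L)   # 6 genes + pooled
})
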