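test_that("duplicate agreement counts sites within the inclusive tolerance", {
  a <- c(0.1, 0.5, 0.9)
  expect_equal(duplicate_agreement(a, a)$percent_within, 100)
  r <- duplicate_agreement(c(0.10, 0.10), c(0.15, 0.25))
  expect_equal(r$percent_within, 50)
  expect_equal(r$n_sites, 2L)
  # boundary |delta| = 0.10 counts as agreeing
  expect_equal(duplicate_agreement(0.2, 0.3)$frac_within, 1)
  expect_error(duplicate_agreement(numeric(0), numeric(0)), "empty")
  expect_error(duplicate_agreement(c(0.1, 0.2), 0.1), "length")
})

test_that("duplicate agreement is symmetric and monotone in tolerance", {
  set.seed(61)
  p <- rbeta(400, 0.5, 7)
  a <- rbinom(400, 30, p) / 30
  b <- rbinom(400, 30, p) / 30
  expect_equal(duplicate_agreement(a, b)$frac_within,
               duplicate_agreement(b, a)$frac_within)
  f10 <- duplicate_agreement(a, b, 10)$frac_within
  f5 <- duplicate_agreement(a, b, 5)$frac_within
  expect_true(f5 <= f10)
  # exact brute-force recount
  expect_equal(f10, sum(abs(a - b) <= 0.1 + 1e-12) / 400)
})

test_that("methylation summaries use interpolated percentiles in percent", {
  s <- methylation_summary(0.1)
  expect_equal(s$median_pct, 10)
  expect_equal(s$p5_pct, 10)
  expect_equal(s$p95_pct, 10)
  expect_equal(methylation_summary(c(0, 0.5, 1))$median_pct, 50)
  set.seed(62)
  x <- runif(500)
  s2 <- methylation_summary(x)
  expect_true(s2$p5_pct <= s2$median_pct && s2$median_pct <= s2$p95_pct)
  expect_error(methylation_summary(numeric(0)), "at least one")
})

test_that("the sample median recovers the analytic Beta median at n = 10,000", {
  set.seed(63)
  x <- rbeta(10000, 0.5, 7)
  med <- methylation_summary(x)$median_pct
  expect_lt(abs(med - 100 * qbeta(0.5, 0.5, 7)), 0.5)
})

write_gff <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("promoter windows follow the strand-aware TSS arithmetic", {
  # + strand transcript, 0-based TSS at 5000 -> promoter [3000, 5500)
  f <- write_gff(c(
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t5001\t6000\t.\t+\t.\tParent=t1"))
  fm <- build_feature_map(f)
  prom <- fm[fm$feature_label == "promoter"]
  expect_equal(GenomicRanges::start(prom), 3001L)  # 0-based 3000
  expect_equal(GenomicRanges::end(prom), 5500L)    # half-open end 5500

  # - strand transcript, 0-based TSS at 5000 -> promoter [4501, 7001)
  f2 <- write_gff(c(
    "chr1\tsrc\tmRNA\t4001\t5001\t.\t-\t.\tID=t2",
    "chr1\tsrc\texon\t4001\t5001\t.\t-\t.\tParent=t2"))
  prom2 <- build_feature_map(f2)
  prom2 <- prom2[prom2$feature_label == "promoter"]
  expect_equal(GenomicRanges::start(prom2), 4502L)
  expect_equal(GenomicRanges::end(prom2), 7001L)

  # clamping at the chromosome start: TSS at 100 -> [0, 600)
  f3 <- write_gff(c(
    "chr1\tsrc\tmRNA\t101\t900\t.\t+\t.\tID=t3",
    "chr1\tsrc\texon\t101\t900\t.\t+\t.\tParent=t3"))
  prom3 <- build_feature_map(f3)
  prom3 <- prom3[prom3$feature_label == "promoter"]
  expect_equal(GenomicRanges::start(prom3), 1L)
  expect_equal(GenomicRanges::end(prom3), 600L)
})

test_that("introns are the transcript span minus exons", {
  f <- write_gff(c(
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tParent=t1"))
  fm <- build_feature_map(f)
  intr <- fm[fm$feature_label == "intron"]
  expect_equal(GenomicRanges::start(intr), 1201L)
  expect_equal(GenomicRanges::end(intr), 1800L)
  # transcript with no exon rows: warned, treated as single-exon
  f2 <- write_gff("chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=t9")
  expect_warning(fm2 <- build_feature_map(f2), "no exons")
  expect_equal(sum(fm2$feature_label == "intron"), 0L)
})

test_that("feature distribution assigns one label per site by precedence", {
  f <- write_gff(c(
    "chr1\tsrc\tmRNA\t10001\t12000\t.\t+\t.\tID=t1",
    "chr1\tsrc\texon\t10001\t10500\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t11501\t12000\t.\t+\t.\tParent=t1"))
  fm <- build_feature_map(f)
  sites <- data.frame(chrom = "chr1",
                      pos = c(9000L,    # promoter (TSS0 = 10000)
                              10100L,   # exon ... but inside promoter window
                              11000L,   # intron
                              50000L))  # intergenic
  fd <- feature_distribution(sites, fm)
  expect_equal(fd$percent, c(50, 0, 25, 25))  # site 2 resolves to promoter
  expect_equal(sum(fd$percent), 100)
  expect_equal(sum(fd$n_sites), nrow(sites))
})

test_that("feature distribution matches a brute-force per-site lookup", {
  f <- write_gff(c(
    "chr1\tsrc\tmRNA\t20001\t30000\t.\t+\t.\tID=a",
    "chr1\tsrc\texon\t20001\t21000\t.\t+\t.\tParent=a",
    "chr1\tsrc\texon\t29001\t30000\t.\t+\t.\tParent=a",
    "chr1\tsrc\tmRNA\t40001\t45000\t.\t-\t.\tID=b",
    "chr1\tsrc\texon\t40001\t45000\t.\t-\t.\tParent=b"))
  fm <- build_feature_map(f)
  set.seed(64)
  sites <- data.frame(chrom = "chr1", pos = sample(0:60000, 1000))
  fd <- feature_distribution(sites, fm)
  # oracle: interval containment checks per site, in precedence order
  iv <- data.frame(start0 = GenomicRanges::start(fm) - 1L,
                   end0 = GenomicRanges::end(fm),
                   label = fm$feature_label)
  lab <- vapply(sites$pos, function(p) {
    hit <- iv$label[iv$start0 <= p & p < iv$end0]
    for (l in c("promoter", "exon", "intron")) if (l %in% hit) return(l)
    "intergenic"
  }, character(1))
  expect_equal(fd$n_sites, as.integer(table(factor(lab, levels = fd$feature_label))))
  expect_equal(sum(fd$percent), 100)
})
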