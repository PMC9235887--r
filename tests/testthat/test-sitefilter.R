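mk_calls <- function(pos, total, meth = 0L, chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth_reads = as.integer(meth), total_reads = as.integer(total),
             context3 = "CAC", stringsAsFactors = FALSE)
}

test_that("depth filtering is inclusive at the threshold", {
  calls <- mk_calls(pos = c(1, 2, 3), total = c(30, 29, 31))
  kept <- filter_depth(calls, min_depth = 30)
  expect_equal(kept$pos, c(1L, 3L))
  expect_error(filter_depth(calls, min_depth = 0), "min_depth")
})

test_that("depth filtering matches a brute-force recount at Poisson depth", {
  set.seed(101)
  total <- rpois(1000, 35)
  calls <- mk_calls(pos = seq_len(1000), total = pmax(total, 0))
  kept <- filter_depth(calls, 30)
  expect_equal(nrow(kept), sum(total >= 30))
})

test_that("common_sites is the exact intersection in deterministic order", {
  r <- list(a = mk_calls(c(1, 2), 50)[, 1:3],
            b = mk_calls(c(2, 3), 50)[, 1:3],
            c = mk_calls(2, 50)[, 1:3])
  cs <- common_sites(r)
  expect_equal(cs$pos, 2L)
  expect_equal(common_sites(r["a"])$pos, c(1L, 2L))
  r$d <- mk_calls(99, 50)[, 1:3]
  expect_warning(cs0 <- common_sites(r), "no site")
  expect_equal(nrow(cs0), 0L)
})

test_that("multi-sample intersection equals iterated pairwise intersection", {
  cfg <- simulation_config(seed = 31, n_chrom = 1, chrom_length = 800,
                           design = discovery_design(4), depth_mean = 35)
  st <- simulate_study(cfg)
  calls <- setNames(lapply(st$samples$sample_id, study_calls, study = st),
                    st$samples$sample_id)
  retained <- filter_depth(calls, 30)
  joint <- common_sites(retained)
  # oracle: fold pairwise with plain string sets
  keys <- lapply(retained, function(df) paste(df$chrom, df$pos, df$strand))
  acc <- keys[[1]]
  for (k in keys[-1]) acc <- acc[acc %in% k]
  expect_setequal(paste(joint$chrom, joint$pos, joint$strand), acc)
  # order is (chrom, pos, strand)
  expect_equal(joint, joint[order(joint$chrom, joint$pos, joint$strand), ],
               ignore_attr = TRUE)
})

test_that("the non-zero rule keeps only sites methylated in every sample", {
  sites <- data.frame(chrom = "chr1", pos = 1:3, strand = "+",
                      context3 = "CAC", stringsAsFactors = FALSE)
  samples <- discovery_design(1)
  meth <- rbind(c(1L, 1L, 1L), c(0L, 2L, 5L), c(3L, 3L, 3L))
  dep <- matrix(30L, 3, 3)
  sm <- site_matrix(sites, samples, meth, dep)
  out <- nonzero_common(sm)
  expect_equal(out$sites$pos, c(1L, 3L))

  set.seed(7)
  meth2 <- matrix(rbinom(500 * 3, 30, 0.05), 500, 3)
  sm2 <- site_matrix(data.frame(chrom = "chr1", pos = 1:500, strand = "+",
                                context3 = "CAC"),
                     samples, meth2, matrix(30L, 500, 3))
  expect_equal(nrow(nonzero_common(sm2)$sites),
               sum(apply(meth2 >= 1, 1, all)))
  # idempotence
  once <- nonzero_common(sm2)
  expect_identical(nonzero_common(once)$sites, once$sites)
})

test_that("context stratification partitions the parent matrix", {
  sites <- data.frame(chrom = "chr1", pos = 1:6, strand = "+",
                      context3 = c("CAC", "CAC", "CAC", "CAT", "CAT", "CTC"),
                      stringsAsFactors = FALSE)
  samples <- discovery_design(1)
  sm <- site_matrix(sites, samples, matrix(1L, 6, 3), matrix(30L, 6, 3))
  strat <- stratify_by_context(sm)
  expect_setequal(names(strat), c("CAC", "CAT", "CTC"))
  expect_equal(vapply(strat[c("CAC", "CAT", "CTC")],
                      function(s) nrow(s$sites), integer(1)),
               c(CAC = 3L, CAT = 2L, CTC = 1L))
  expect_equal(sum(vapply(strat, function(s) nrow(s$sites), integer(1))),
               nrow(sm$sites))
  # CpG parents split into the four CpG contexts
  sites$context3 <- rep(c("CGA", "CGC", "CGG", "CGT"), length.out = 6)
  smc <- site_matrix(sites, samples, matrix(1L, 6, 3), matrix(30L, 6, 3))
  expect_setequal(names(stratify_by_context(smc)), c("CGA", "CGC", "CGG", "CGT"))
})

test_that("filters are monotone in threshold and sample set", {
  cfg <- simulation_config(seed = 37, n_chrom = 1, chrom_length = 600,
                           design = discovery_design(3), depth_mean = 35)
  st <- simulate_study(cfg)
  calls <- setNames(lapply(st$samples$sample_id, study_calls, study = st),
                    st$samples$sample_id)
  k30 <- filter_depth(calls, 30)
  k35 <- filter_depth(calls, 35)
  for (s in names(calls)) {
    expect_true(all(paste(k35[[s]]$chrom, k35[[s]]$pos, k35[[s]]$strand) %in%
                      paste(k30[[s]]$chrom, k30[[s]]$pos, k30[[s]]$strand)))
  }
  fewer <- common_sites(k30[1:3])
  more <- common_sites(k30)
  expect_true(nrow(more) <= nrow(fewer))
})

test_that("assemble_matrix logs stage counts that match brute recounts", {
  cfg <- simulation_config(seed = 41, n_chrom = 1, chrom_length = 500,
                           design = discovery_design(3), depth_mean = 40)
  st <- simulate_study(cfg)
  calls <- setNames(lapply(st$samples$sample_id, study_calls, study = st),
                    st$samples$sample_id)
  asm <- assemble_matrix(calls, st$samples, min_depth = 30, nonzero = TRUE)
  # brute recount straight off the simulated matrices
  deep_all <- rowSums(st$depths >= 30) == ncol(st$depths)
  deep_any <- rowSums(st$depths >= 30) >= 1
  nz <- deep_all & rowSums(st$meth >= 1) == ncol(st$meth)
  expect_equal(asm$stages$n_sites,
               c(sum(deep_any), sum(deep_all), sum(nz)))
  expect_equal(nrow(asm$matrix$sites), sum(nz))
  expect_true(all(asm$matrix$fractions > 0))
})
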