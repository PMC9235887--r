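test_that("the constructed 60-leaf tree scores to the narrative composition", {
  fx <- figure_tree_fixture()
  sc <- score_composition(fx$tree, fx$samples, k_tissues = 3)
  expect_equal(sc$n_triad_individuals, 7L)
  expect_equal(sc$n_pair_individuals, 13L)
  expect_equal(sc$n_triad_samples, 21L)
  expect_equal(sc$n_pair_samples, 26L)
  expect_equal(sc$n_tissue_clustered_samples, 10L)
  expect_equal(sc$n_outliers, 3L)
  expect_equal(sc$n_triad_samples + sc$n_pair_samples +
                 sc$n_tissue_clustered_samples + sc$n_outliers, 60L)
  # the tissue-pure cluster and the outliers are all umbilical cord here
  asg <- sc$assignment
  expect_true(all(asg$tissue[asg$category == "tissue"] == "umbilical_cord"))
  expect_true(all(asg$tissue[asg$category == "outlier"] == "umbilical_cord"))
})

test_that("two-leaf trees score as pair or tissue cluster as appropriate", {
  samples <- data.frame(sample_id = c("s1", "s2"),
                        individual_id = c("i1", "i1"),
                        tissue = c("cord_blood", "peripheral_blood"),
                        replicate = "", stringsAsFactors = FALSE)
  tr <- dendrogram_from_nested(list("s1", "s2"))
  sc <- score_composition(tr, samples, k_tissues = 3)
  expect_equal(sc$n_pair_individuals, 1L)
  expect_equal(sc$n_outliers, 0L)

  samples2 <- samples
  samples2$individual_id <- c("i1", "i2")
  samples2$tissue <- "cord_blood"
  sc2 <- score_composition(tr, samples2, k_tissues = 3)
  expect_equal(sc2$n_tissue_clustered_samples, 2L)
  expect_equal(sc2$n_pair_individuals, 0L)
})

test_that("duplicate leaf labels are rejected", {
  samples <- data.frame(sample_id = "s1", individual_id = "i1",
                        tissue = "cord_blood", replicate = "")
  tr <- dendrogram_from_nested(list("s1", "s1"))
  expect_error(score_composition(tr, samples, 3), "duplicate")
})

test_that("count_paired_individuals counts exact two-leaf tissue pairs", {
  design <- discovery_design(20)
  sid <- function(i, t) paste(sprintf("ind%02d", i), t, sep = "_")
  all_paired <- chain(c(
    lapply(1:20, function(i) list(sid(i, "cord_blood"), sid(i, "peripheral_blood"))),
    lapply(1:20, function(i) sid(i, "umbilical_cord"))
  ))
  tr <- dendrogram_from_nested(all_paired)
  expect_equal(count_paired_individuals(tr, design,
                                        c("cord_blood", "peripheral_blood")), 20L)
  # displace one peripheral-blood sample: its individual no longer pairs
  broken <- chain(c(
    lapply(1:19, function(i) list(sid(i, "cord_blood"), sid(i, "peripheral_blood"))),
    list(sid(20, "cord_blood"), sid(20, "peripheral_blood")),
    lapply(1:20, function(i) sid(i, "umbilical_cord"))
  ))
  tr2 <- dendrogram_from_nested(broken)
  expect_equal(count_paired_individuals(tr2, design,
                                        c("cord_blood", "peripheral_blood")), 19L)
  expect_equal(count_paired_individuals(tr, design,
                                        c("muscle", "cord_blood")), 0L)
})

test_that("first_split_purity reports tissue composition of root branches", {
  design <- discovery_design(20)
  sid <- function(i, t) paste(sprintf("ind%02d", i), t, sep = "_")
  topo <- list(chain(lapply(1:20, function(i) sid(i, "umbilical_cord"))),
               chain(c(lapply(1:20, function(i) sid(i, "cord_blood")),
                       lapply(1:20, function(i) sid(i, "peripheral_blood")))))
  fs <- first_split_purity(dendrogram_from_nested(topo), design)
  uc <- fs[fs$dominant_tissue == "umbilical_cord", ]
  expect_equal(uc$purity, 1.0)
  expect_true(uc$pure)
  expect_equal(uc$n_samples, 20L)
  blood <- fs[fs$dominant_tissue != "umbilical_cord", ]
  expect_false(blood$pure)

  mixed <- dendrogram_from_nested(list(
    list(sid(1, "umbilical_cord"), sid(1, "cord_blood")),
    list(sid(2, "umbilical_cord"), sid(2, "cord_blood"))))
  fsm <- first_split_purity(mixed, design)
  expect_true(all(fsm$purity < 1))
})

test_that("scores are invariant to swapping children anywhere in the tree", {
  swap_all <- function(x) if (is.character(x)) x else list(swap_all(x[[2]]),
                                                           swap_all(x[[1]]))
  fx <- figure_tree_fixture()
  inds <- sprintf("ind%02d", 1:20)
  sid <- function(i, t) paste(inds[i], t, sep = "_")
  topo <- list(list(chain(lapply(1:7, function(i) {
    list(list(sid(i, "umbilical_cord"), sid(i, "cord_blood")),
         sid(i, "peripheral_blood"))
  })), chain(lapply(8:20, function(i) {
    list(sid(i, "cord_blood"), sid(i, "peripheral_blood"))
  }))), chain(lapply(8:17, function(i) sid(i, "umbilical_cord"))))
  topo <- Reduce(function(acc, s) list(acc, s),
                 lapply(18:20, function(i) sid(i, "umbilical_cord")), init = topo)
  tr1 <- dendrogram_from_nested(topo)
  tr2 <- dendrogram_from_nested(swap_all(topo))
  s1 <- score_composition(tr1, fx$samples, 3)
  s2 <- score_composition(tr2, fx$samples, 3)
  for (f in c("n_triad_individuals", "n_pair_individuals", "n_triad_samples",
              "n_pair_samples", "n_tissue_clustered_samples", "n_outliers")) {
    expect_equal(s1[[f]], s2[[f]])
  }
})

test_that("permuting individual labels collapses triad counts to chance", {
  design <- discovery_design(20)
  sid <- function(i, t) paste(sprintf("ind%02d", i), t, sep = "_")
  all_triads <- chain(lapply(1:20, function(i) {
    list(list(sid(i, "umbilical_cord"), sid(i, "cord_blood")),
         sid(i, "peripheral_blood"))
  }))
  tr <- dendrogram_from_nested(all_triads)
  expect_equal(score_composition(tr, design, 3)$n_triad_individuals, 20L)
  set.seed(202)
  null_counts <- replicate(50, {
    perm <- design
    perm$individual_id <- sample(perm$individual_id)
    score_composition(tr, perm, 3)$n_triad_individuals
  })
  expect_lt(mean(null_counts), 1)
  expect_true(all(null_counts <= 3))
})
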