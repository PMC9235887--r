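# Independent oracles and fixture builders used across test files.

# random symmetric "distance" matrix with continuous entries (ties have
# probability zero), labelled by letters
rand_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  dimnames(d) <- list(make.unique(rep(LETTERS, length.out = n)),
                      make.unique(rep(LETTERS, length.out = n)))
  d
}

# Brute-force agglomerative clustering by direct definition, independent of
# the Lance-Williams recurrences used by the package:
#   complete - max over cross pairs of the ORIGINAL distances
#   average  - mean over cross pairs of the ORIGINAL distances
#   wpgma    - weighted mean with leaf weights halved at each merge
# Returns merge heights (in merge order) and the cophenetic matrix.
brute_linkage <- function(d, method) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  weights <- lapply(seq_len(n), function(i) 1)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  cdist <- function(a, b) {
    if (method == "complete") max(d[members[[a]], members[[b]]])
    else if (method == "average") mean(d[members[[a]], members[[b]]])
    else {
      wa <- weights[[a]]; wb <- weights[[b]]
      sum(outer(wa, wb) * d[members[[a]], members[[b]], drop = FALSE])
    }
  }
  while (length(members) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (a in seq_along(members)) for (b in seq_len(a - 1L)) {
      v <- cdist(a, b)
      if (v < best) { best <- v; bi <- a; bj <- b }
    }
    coph[members[[bi]], members[[bj]]] <- best
    coph[members[[bj]], members[[bi]]] <- best
    heights <- c(heights, best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    weights[[bi]] <- c(weights[[bi]] / 2, weights[[bj]] / 2)
    members[[bj]] <- NULL
    weights[[bj]] <- NULL
  }
  list(heights = heights, coph = coph)
}

# position-by-position context scan, written deliberately differently from
# the package (explicit per-base loop, complement via lookup table)
oracle_scan_contexts <- function(seqstr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b <- strsplit(seqstr, "")[[1]]
  L <- length(b)
  out <- list()
  for (i in seq_len(L)) {
    if (b[i] == "C") {
      ctx <- if (i + 2 <= L) paste0(b[i], b[i + 1], b[i + 2]) else "UNDEFINED"
      if (grepl("N", ctx)) ctx <- "UNDEFINED"
      out[[length(out) + 1]] <- data.frame(pos = i - 1L, strand = "+",
                                           context3 = ctx)
    }
    if (b[i] == "G") {
      ctx <- if (i - 2 >= 1) {
        paste0(comp[b[i]], comp[b[i - 1]], comp[b[i - 2]])
      } else "UNDEFINED"
      if (grepl("N", ctx)) ctx <- "UNDEFINED"
      out[[length(out) + 1]] <- data.frame(pos = i - 1L, strand = "-",
                                           context3 = ctx)
    }
  }
  if (!length(out)) return(data.frame(pos = integer(0), strand = character(0),
                                      context3 = character(0)))
  do.call(rbind, out)
}

# left-deep chain of a list of subtrees
chain <- function(items) Reduce(function(a, b) list(a, b), items)

# 60-leaf dendrogram realising the narrative composition: 7 individual
# triads, 13 cord-blood/peripheral-blood pairs, one 10-leaf umbilical-cord
# cluster of 10 distinct individuals, and 3 stray umbilical-cord leaves
# attached above everything else. 20 individuals x 3 tissues.
figure_tree_fixture <- function() {
  inds <- sprintf("ind%02d", 1:20)
  samples <- discovery_design(20)
  sid <- function(i, t) paste(inds[i], t, sep = "_")
  triads <- lapply(1:7, function(i) {
    list(list(sid(i, "umbilical_cord"), sid(i, "cord_blood")),
         sid(i, "peripheral_blood"))
  })
  pairs <- lapply(8:20, function(i) {
    list(sid(i, "cord_blood"), sid(i, "peripheral_blood"))
  })
  uc_cluster <- chain(lapply(8:17, function(i) sid(i, "umbilical_cord")))
  strays <- lapply(18:20, function(i) sid(i, "umbilical_cord"))
  core <- list(list(chain(triads), chain(pairs)), uc_cluster)
  topo <- Reduce(function(acc, s) list(acc, s), strays, accumulate = FALSE,
                 init = core)
  list(tree = dendrogram_from_nested(topo), samples = samples)
}

# recovery-regime wrappers (shared by module and acceptance tests)
cac_recovery <- function(seed) run_context_recovery("CAC", tissue_sd = 0.05,
                                                    ind_sd = 0.01,
                                                    n_sites = 2000, seed = seed)
cat_recovery <- function(seed) run_context_recovery("CAT", tissue_sd = 0.005,
                                                    ind_sd = 0.04,
                                                    n_sites = 2000, seed = seed)
ctc_recovery <- function(seed) run_context_recovery("CTC", tissue_sd = 0.03,
                                                    ind_sd = 0.01,
                                                    n_sites = 700, seed = seed)

modal <- function(x) as.integer(names(which.max(table(x))))
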