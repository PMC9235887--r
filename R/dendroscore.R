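# Formalization of narrative dendrogram reading: samples are assigned once,
# greedily and bottom-up, to individual triads, same-individual pairs,
# tissue-pure clusters, or outliers. "Grouped" always means an EXACT node:
# the cluster contains exactly those samples and nothing else. This is the
# strictest computable reading of "clustered together"; looser readings
# (e.g., leaf adjacency) exist and would give higher counts.

match_samples <- function(tree, samples) {
  ix <- match(tree$labels, samples$sample_id)
  if (anyNA(ix)) {
    stop("leaf label(s) not in sample sheet: ",
         paste(tree$labels[is.na(ix)], collapse = ", "))
  }
  if (anyDuplicated(tree$labels)) stop("duplicate leaf labels")
  samples[ix, , drop = FALSE]
}

#' Score the composition of a sample dendrogram
#'
#' Assigns every leaf to exactly one category:
#' \enumerate{
#'   \item \strong{triad}: a node whose leaf set is exactly all
#'     \code{k_tissues} samples of one individual;
#'   \item \strong{pair}: among still-unassigned leaves, a node whose leaf set
#'     is exactly two samples of one individual;
#'   \item \strong{tissue-pure}: among still-unassigned leaves, every
#'     \emph{maximal} node whose leaves all share one tissue and span at
#'     least two distinct individuals;
#'   \item \strong{outlier}: any remaining leaf.
#' }
#'
#' @param tree A \code{noncpg_dendro} whose labels are sample ids.
#' @param samples Sample records data frame.
#' @param k_tissues Number of tissues per individual that constitutes a full
#'   individual cluster (3 for the discovery design).
#' @return An object of class \code{composition_score}: counts of triad/pair
#'   individuals, per-category sample totals, outliers, and the assignment
#'   per sample.
#' @export
score_composition <- function(tree, samples, k_tissues = 3L) {
  sam <- match_samples(tree, samples)
  n <- length(tree$labels)
  sets <- node_leaf_sets(tree)
  assigned <- rep(NA_character_, n)

  ind <- sam$individual_id
  tis <- sam$tissue
  ind_size <- table(ind)

  triad_inds <- character(0)
  for (s in seq_along(sets)) {
    ls <- sets[[s]]
    if (length(ls) != k_tissues) next
    ii <- unique(ind[ls])
    if (length(ii) == 1L && ind_size[[ii]] == k_tissues && all(is.na(assigned[ls]))) {
      assigned[ls] <- "triad"
      triad_inds <- c(triad_inds, ii)
    }
  }

  pair_inds <- character(0)
  for (s in seq_along(sets)) {
    ls <- sets[[s]]
    if (length(ls) != 2L) next
    if (!all(is.na(assigned[ls]))) next
    ii <- unique(ind[ls])
    if (length(ii) == 1L) {
      assigned[ls] <- "pair"
      pair_inds <- c(pair_inds, ii)
    }
  }

  # tissue-pure: maximal nodes, all leaves unassigned, one tissue, >=2 individuals
  is_cand <- vapply(sets, function(ls) {
    all(is.na(assigned[ls])) &&
      length(unique(tis[ls])) == 1L &&
      length(unique(ind[ls])) >= 2L
  }, logical(1))
  cand <- which(is_cand)
  # maximality: drop candidates strictly contained in another candidate
  keep <- vapply(cand, function(s) {
    !any(vapply(cand, function(t2) {
      t2 != s && length(sets[[s]]) < length(sets[[t2]]) && all(sets[[s]] %in% sets[[t2]])
    }, logical(1)))
  }, logical(1))
  for (s in cand[keep]) assigned[sets[[s]]] <- "tissue"

  assigned[is.na(assigned)] <- "outlier"

  out <- list(
    n_triad_individuals = length(unique(triad_inds)),
    n_pair_individuals = length(unique(pair_inds)),
    n_triad_samples = sum(assigned == "triad"),
    n_pair_samples = sum(assigned == "pair"),
    n_tissue_clustered_samples = sum(assigned == "tissue"),
    n_outliers = sum(assigned == "outlier"),
    n_samples = n,
    assignment = data.frame(sample_id = tree$labels,
                            individual_id = ind, tissue = tis,
                            category = assigned, stringsAsFactors = FALSE)
  )
  class(out) <- "composition_score"
  out
}

#' @export
print.composition_score <- function(x, ...) {
  cat("composition of", x$n_samples, "samples:\n")
  cat("  triads :", x$n_triad_samples, "samples /", x$n_triad_individuals, "individuals\n")
  cat("  pairs  :", x$n_pair_samples, "samples /", x$n_pair_individuals, "individuals\n")
  cat("  tissue-pure clusters:", x$n_tissue_clustered_samples, "samples\n")
  cat("  outliers:", x$n_outliers, "\n")
  invisible(x)
}

#' Tissue composition of the root split
#'
#' Reports, for each of the root's two children, the tissue label counts,
#' the dominant tissue, its purity (proportion), and whether the branch is
#' 100\% a single tissue.
#'
#' @param tree A \code{noncpg_dendro} with >= 2 leaves.
#' @param samples Sample records data frame.
#' @return Data frame with one row per root branch: \code{branch},
#'   \code{n_samples}, \code{dominant_tissue}, \code{purity}, \code{pure},
#'   \code{composition} (label=count string).
#' @export
first_split_purity <- function(tree, samples) {
  sam <- match_samples(tree, samples)
  n <- length(tree$labels)
  if (n < 2L) stop("need at least 2 leaves")
  sets <- node_leaf_sets(tree)
  root <- nrow(tree$merge)
  branch_leaves <- lapply(1:2, function(side) {
    id <- tree$merge[root, side]
    if (id < 0L) -id else sets[[id]]
  })
  do.call(rbind, lapply(1:2, function(b) {
    ls <- branch_leaves[[b]]
    tab <- sort(table(sam$tissue[ls]), decreasing = TRUE)
    data.frame(
      branch = b,
      n_samples = length(ls),
      dominant_tissue = names(tab)[1L],
      purity = as.numeric(tab[1L]) / length(ls),
      pure = length(tab) == 1L,
      composition = paste(names(tab), as.integer(tab), sep = "=", collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

#' Count individuals whose two samples of a given tissue pair form an exact
#' cluster
#'
#' @param tree A \code{noncpg_dendro}.
#' @param samples Sample records data frame.
#' @param tissue_pair Character vector of two tissue labels (e.g.,
#'   \code{c("cord_blood", "peripheral_blood")}).
#' @return Integer: the number of individuals for which some node's leaf set
#'   is exactly that individual's two samples of the given tissues.
#' @export
count_paired_individuals <- function(tree, samples, tissue_pair) {
  stopifnot(length(tissue_pair) == 2L)
  sam <- match_samples(tree, samples)
  sets <- node_leaf_sets(tree)
  two_sets <- sets[vapply(sets, length, integer(1)) == 2L]
  count <- 0L
  for (ii in unique(sam$individual_id)) {
    a <- which(sam$individual_id == ii & sam$tissue == tissue_pair[1L])
    b <- which(sam$individual_id == ii & sam$tissue == tissue_pair[2L])
    if (length(a) != 1L || length(b) != 1L) next
    target <- sort(c(a, b))
    if (any(vapply(two_sets, function(s) identical(s, target), logical(1)))) {
      count <- count + 1L
    }
  }
  count
}

#' Build a dendrogram from a nested list of leaf labels
#'
#' Constructs a valid \code{noncpg_dendro} from an explicit topology: each
#' internal node is a length-2 list, each leaf a character scalar. Node
#' heights are assigned as one plus the maximum child height (leaves at 0),
#' which guarantees monotone heights. Intended for constructing reference
#' trees with a prescribed composition (tests, worked examples).
#'
#' @param x Nested list; e.g. \code{list(list("A", "B"), "C")}.
#' @return A \code{noncpg_dendro}.
#' @export
dendrogram_from_nested <- function(x) {
  labels <- character(0)
  merges <- list()
  heights <- numeric(0)
  build <- function(node) {
    if (is.character(node)) {
      stopifnot(length(node) == 1L)
      labels[[length(labels) + 1L]] <<- node
      return(list(id = -length(labels), h = 0))
    }
    stopifnot(is.list(node), length(node) == 2L)
    l <- build(node[[1L]]); r <- build(node[[2L]])
    merges[[length(merges) + 1L]] <<- c(l$id, r$id)
    heights[[length(heights) + 1L]] <<- max(l$h, r$h) + 1
    list(id = length(merges), h = heights[[length(merges)]])
  }
  root <- build(x)
  n <- length(labels)
  stopifnot(length(merges) == n - 1L)
  merge <- do.call(rbind, merges)
  storage.mode(merge) <- "integer"
  tr <- structure(list(merge = merge, height = as.numeric(heights),
                       order = integer(0), labels = labels, method = "manual"),
                  class = "noncpg_dendro")
  ord <- integer(0)
  walk <- function(id) if (id < 0L) -id else c(walk(merge[id, 1L]), walk(merge[id, 2L]))
  tr$order <- walk(n - 1L)
  tr
}
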