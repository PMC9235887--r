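#' Euclidean distances between samples
#'
#' \eqn{d(i,j) = \sqrt{\sum_s (f_{si} - f_{sj})^2}} over methylation fractions.
#' Fractions are used raw; no standardisation is applied (optionally sites can
#' be mean-centred).
#'
#' @param sm A \code{site_matrix} (or a plain sites-x-samples numeric matrix).
#' @param center Per-site mean-centering before distances (default off).
#' @return A symmetric n x n distance matrix with sample ids as dimnames.
#' @export
euclidean_distances <- function(sm, center = FALSE) {
  f <- if (inherits(sm, "site_matrix")) sm$fractions else as.matrix(sm)
  if (ncol(f) < 2L) stop("need at least 2 samples to compute distances")
  if (center) f <- f - rowMeans(f)
  d <- as.matrix(stats::dist(t(f), method = "euclidean"))
  dimnames(d) <- list(colnames(f), colnames(f))
  d
}

#' Agglomerative hierarchical clustering (from scratch)
#'
#' Bottom-up agglomeration under the Lance-Williams recurrences:
#' \describe{
#'   \item{complete}{cluster distance = maximum of the two merged clusters'
#'     distances to each other cluster;}
#'   \item{average}{UPGMA, size-weighted mean;}
#'   \item{wpgma}{unweighted mean of the two merged clusters' distances.}
#' }
#' At each step the minimum-distance active pair merges. Ties are broken by
#' the lexicographically smallest pair of cluster indices, where a cluster's
#' index is the smallest original leaf index it contains. Within each merge
#' the child containing the lowest original leaf index is recorded first,
#' which fixes a deterministic leaf order.
#'
#' @param d Symmetric distance matrix (e.g., from [euclidean_distances()]).
#' @param method One of \code{"complete"}, \code{"average"}, \code{"wpgma"}.
#' @return An object of class \code{noncpg_dendro}: list with \code{merge}
#'   (hclust-style (n-1) x 2 matrix; negative entries are leaves, positive
#'   entries earlier merge steps), \code{height}, \code{order} (leaf
#'   permutation), \code{labels}, \code{method}.
#' @export
meth_linkage <- function(d, method = c("complete", "average", "wpgma")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 1L, ncol(d) == n)
  if (any(is.na(d)) || any(is.nan(d))) stop("NA/NaN in distance matrix")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0L, 2L), height = numeric(0),
                          order = 1L, labels = labels, method = method),
                     class = "noncpg_dendro"))
  }

  active <- seq_len(n)              # active cluster slots
  node <- -seq_len(n)               # hclust encoding of each slot
  size <- rep(1L, n)
  minleaf <- seq_len(n)             # smallest original leaf index per slot
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- 0L
    for (a in seq_along(active)) {
      ia <- active[a]
      for (b in seq_len(a - 1L)) {
        ib <- active[b]
        v <- D[ia, ib]
        take <- if (bi == 0L) TRUE else if (v < best - 1e-15) TRUE else if
          (abs(v - best) <= 1e-15) {
            lo <- min(minleaf[ia], minleaf[ib]); hi <- max(minleaf[ia], minleaf[ib])
            blo <- min(minleaf[bi], minleaf[bj]); bhi <- max(minleaf[bi], minleaf[bj])
            lo < blo || (lo == blo && hi < bhi)
          } else FALSE
        if (take) { best <- v; bi <- ia; bj <- ib }
      }
    }
    # order children: the one containing the lowest original leaf first
    first <- if (minleaf[bi] <= minleaf[bj]) bi else bj
    second <- if (first == bi) bj else bi
    merge[step, ] <- c(node[first], node[second])
    height[step] <- best
    # Lance-Williams update into slot bi; retire slot bj
    for (k in active) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <- switch(
        method,
        complete = max(D[bi, k], D[bj, k]),
        average = (size[bi] * D[bi, k] + size[bj] * D[bj, k]) / (size[bi] + size[bj]),
        wpgma = (D[bi, k] + D[bj, k]) / 2
      )
    }
    node[bi] <- step
    size[bi] <- size[bi] + size[bj]
    minleaf[bi] <- min(minleaf[bi], minleaf[bj])
    active <- active[active != bj]
  }

  ord <- integer(0)
  walk <- function(id) {
    if (id < 0L) return(-id)
    c(walk(merge[id, 1L]), walk(merge[id, 2L]))
  }
  ord <- walk(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = method),
            class = "noncpg_dendro")
}

#' @export
print.noncpg_dendro <- function(x, ...) {
  cat("noncpg_dendro:", length(x$labels), "leaves,", x$method, "linkage\n")
  if (length(x$height)) {
    cat("merge heights:", format(min(x$height), digits = 4), "..",
        format(max(x$height), digits = 4), "\n")
  }
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' @param x A \code{noncpg_dendro}.
#' @param ... Unused.
#' @return An \code{hclust} object (for plotting and interoperability).
#' @export
as.hclust.noncpg_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$method,
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Leaf sets of every internal node
#'
#' @param tree A \code{noncpg_dendro}.
#' @return List of integer vectors of original leaf indices, one per merge
#'   step.
#' @export
node_leaf_sets <- function(tree) {
  k <- nrow(tree$merge)
  sets <- vector("list", k)
  for (s in seq_len(k)) {
    grab <- function(id) if (id < 0L) -id else sets[[id]]
    sets[[s]] <- sort(c(grab(tree$merge[s, 1L]), grab(tree$merge[s, 2L])))
  }
  sets
}

#' Cophenetic distances of a dendrogram
#'
#' \code{c(i, j)} is the height of the lowest merge containing both leaves.
#' For complete linkage \code{c(i, j) >= d(i, j)} holds for every pair.
#'
#' @param tree A \code{noncpg_dendro}.
#' @return A symmetric n x n matrix with the tree's labels as dimnames.
#' @export
cophenetic_heights <- function(tree) {
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  if (n < 2L) return(cm)
  sets <- node_leaf_sets(tree)
  for (s in seq_along(tree$height)) {
    left <- if (tree$merge[s, 1L] < 0L) -tree$merge[s, 1L] else sets[[tree$merge[s, 1L]]]
    right <- if (tree$merge[s, 2L] < 0L) -tree$merge[s, 2L] else sets[[tree$merge[s, 2L]]]
    cm[left, right] <- tree$height[s]
    cm[right, left] <- tree$height[s]
  }
  cm
}
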