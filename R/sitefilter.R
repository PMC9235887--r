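# A site_matrix holds complete-case methylation data:
#   sites    : data.frame(chrom, pos, strand, context3), one row per site
#   samples  : data.frame(sample_id, individual_id, tissue, replicate)
#   fractions: sites x samples matrix of meth_reads / total_reads
#   depths   : sites x samples integer matrix of total_reads
#   meth     : sites x samples integer matrix of meth_reads

site_key <- function(df) paste(df$chrom, df$pos, df$strand, sep = ":")

order_sites <- function(df) df[order(df$chrom, df$pos, df$strand), , drop = FALSE]

#' Construct a site-by-sample methylation matrix
#'
#' @param sites Data frame with \code{chrom}, \code{pos}, \code{strand},
#'   \code{context3}.
#' @param samples Data frame of sample records (\code{sample_id},
#'   \code{individual_id}, \code{tissue}, \code{replicate}).
#' @param meth,depths Integer matrices, sites x samples.
#' @return An object of class \code{site_matrix}.
#' @export
site_matrix <- function(sites, samples, meth, depths) {
  stopifnot(nrow(sites) == nrow(meth), nrow(meth) == nrow(depths),
            nrow(samples) == ncol(meth), ncol(meth) == ncol(depths))
  if (any(meth > depths)) stop("meth_reads exceeds total_reads")
  if (any(depths < 0) || any(meth < 0)) stop("negative read counts")
  fr <- ifelse(depths > 0, meth / depths, 0)
  colnames(fr) <- colnames(meth) <- colnames(depths) <- samples$sample_id
  structure(
    list(sites = sites, samples = samples, fractions = fr,
         depths = depths, meth = meth),
    class = "site_matrix"
  )
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("site_matrix:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n")
  ctx <- table(x$sites$context3)
  cat("contexts:", paste(names(ctx), as.integer(ctx), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Subset a site matrix by site index
#'
#' @param sm A \code{site_matrix}.
#' @param idx Integer or logical index over sites.
#' @return The subset \code{site_matrix}.
#' @export
subset_sites <- function(sm, idx) {
  site_matrix(sm$sites[idx, , drop = FALSE], sm$samples,
              sm$meth[idx, , drop = FALSE], sm$depths[idx, , drop = FALSE])
}

#' Per-sample depth filtering
#'
#' A site is retained for a sample iff its total read count is at least
#' \code{min_depth} (inclusive).
#'
#' @param calls One calls data frame, or a named list of them (one per sample).
#' @param min_depth Minimum total reads, default 30.
#' @return For a single data frame, a data frame of retained site keys
#'   (\code{chrom}, \code{pos}, \code{strand}); for a list, a named list of
#'   such data frames.
#' @export
filter_depth <- function(calls, min_depth = 30L) {
  stopifnot(min_depth >= 1L)
  one <- function(df) {
    keep <- df$total_reads >= min_depth
    order_sites(df[keep, c("chrom", "pos", "strand"), drop = FALSE])
  }
  if (is.data.frame(calls)) one(calls) else lapply(calls, one)
}

#' Sites retained in every sample
#'
#' Exact set intersection of per-sample retained site keys, in deterministic
#' (chrom, pos, strand) order.
#'
#' @param retained List of site-key data frames from [filter_depth()].
#' @return A site-key data frame; empty (with a warning) if the intersection
#'   is empty.
#' @export
common_sites <- function(retained) {
  stopifnot(length(retained) >= 1L)
  keys <- lapply(retained, site_key)
  common <- Reduce(intersect, keys)
  out <- retained[[1L]][match(common, keys[[1L]]), , drop = FALSE]
  out <- order_sites(out)
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no site is retained in every sample")
  out
}

#' Assemble a complete-case site matrix from per-sample calls
#'
#' @param calls_by_sample Named list of calls data frames; names must match
#'   \code{samples$sample_id}.
#' @param samples Sample records data frame.
#' @param sites Site-key data frame (e.g., from [common_sites()]); every site
#'   must be present in every sample's calls.
#' @return A \code{site_matrix}. \code{context3} is taken from the first
#'   sample's annotated calls.
#' @export
build_site_matrix <- function(calls_by_sample, samples, sites) {
  stopifnot(setequal(names(calls_by_sample), samples$sample_id))
  sites <- order_sites(sites)
  rownames(sites) <- NULL
  skey <- site_key(sites)
  n <- nrow(sites); m <- nrow(samples)
  meth <- matrix(NA_integer_, n, m)
  dep <- matrix(NA_integer_, n, m)
  ctx <- NULL
  for (j in seq_len(m)) {
    df <- calls_by_sample[[samples$sample_id[j]]]
    ix <- match(skey, site_key(df))
    if (anyNA(ix)) {
      stop("sample ", samples$sample_id[j], " is missing ",
           sum(is.na(ix)), " requested site(s)")
    }
    meth[, j] <- df$meth_reads[ix]
    dep[, j] <- df$total_reads[ix]
    if (is.null(ctx) && "context3" %in% names(df)) ctx <- df$context3[ix]
  }
  sites$context3 <- if (is.null(ctx)) NA_character_ else ctx
  site_matrix(sites, samples, meth, dep)
}

#' Restrict to sites with non-zero methylation in every sample
#'
#' The "commonly methylated" rule: a site is kept iff it has at least one
#' methylated read in every sample (equivalently, methylation fraction > 0
#' everywhere). Applied to non-CpG matrices by default in the pipeline; CpG
#' matrices skip it.
#'
#' @param sm A \code{site_matrix}.
#' @return The filtered \code{site_matrix}.
#' @export
nonzero_common <- function(sm) {
  keep <- rowSums(sm$meth >= 1L) == ncol(sm$meth)
  subset_sites(sm, keep)
}

#' Restrict to sites meeting a depth threshold in every sample
#'
#' Matrix-level counterpart of [filter_depth()] + [common_sites()] for data
#' already assembled into a \code{site_matrix}.
#'
#' @param sm A \code{site_matrix}.
#' @param min_depth Minimum total reads per site per sample (inclusive).
#' @return The filtered \code{site_matrix}.
#' @export
filter_matrix_depth <- function(sm, min_depth = 30L) {
  stopifnot(min_depth >= 1L)
  keep <- rowSums(sm$depths >= min_depth) == ncol(sm$depths)
  subset_sites(sm, keep)
}

#' Split a site matrix by trinucleotide context
#'
#' @param sm A \code{site_matrix} with annotated contexts.
#' @return Named list of \code{site_matrix} objects, one per defined context
#'   present; sites with UNDEFINED context are excluded.
#' @export
stratify_by_context <- function(sm) {
  ctx <- sm$sites$context3
  defined <- intersect(all_contexts(), unique(ctx))
  out <- lapply(defined, function(c3) subset_sites(sm, which(ctx == c3)))
  names(out) <- defined
  out
}

#' Assemble the analysis matrix with an auditable stage-count log
#'
#' Runs the full site-retention cascade: per-sample depth filter, intersection
#' across samples, matrix assembly, optional non-zero-in-all-samples filter.
#'
#' @param calls_by_sample Named list of annotated calls data frames.
#' @param samples Sample records data frame.
#' @param min_depth Inclusive minimum depth, default 30.
#' @param nonzero Apply the commonly-methylated (non-zero) rule.
#' @return List with \code{matrix} (the final \code{site_matrix}) and
#'   \code{stages} (data frame of stage name and site count).
#' @export
assemble_matrix <- function(calls_by_sample, samples, min_depth = 30L,
                            nonzero = TRUE) {
  retained <- filter_depth(calls_by_sample, min_depth)
  union_n <- length(unique(unlist(lapply(retained, site_key))))
  common <- common_sites(retained)
  sm <- build_site_matrix(calls_by_sample, samples, common)
  stages <- data.frame(
    stage = c(sprintf("depth>=%d in >=1 sample", min_depth),
              sprintf("depth>=%d in all samples", min_depth)),
    n_sites = c(union_n, nrow(common)),
    stringsAsFactors = FALSE
  )
  if (nonzero) {
    sm <- nonzero_common(sm)
    stages <- rbind(stages, data.frame(
      stage = "non-zero methylation in all samples",
      n_sites = nrow(sm$sites)
    ))
  }
  list(matrix = sm, stages = stages)
}
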