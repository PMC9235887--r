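#' Duplicate concordance
#'
#' Fraction of sites on which two aligned duplicate samples agree to within a
#' tolerance, in absolute percentage points of methylation (inclusive).
#'
#' @param a,b Numeric vectors of methylation fractions on the same site set.
#' @param tol_points Tolerance in percentage points (default 10).
#' @return List with \code{n_sites}, \code{frac_within} (in [0,1]),
#'   \code{percent_within} and \code{tol_points}.
#' @export
duplicate_agreement <- function(a, b, tol_points = 10) {
  if (length(a) != length(b)) stop("duplicate fraction vectors differ in length")
  if (length(a) == 0L) stop("empty site set")
  within <- abs(a - b) <= tol_points / 100 + 1e-12
  list(n_sites = length(a), frac_within = mean(within),
       percent_within = 100 * mean(within), tol_points = tol_points)
}

#' Median and 5th/95th percentiles of per-sample methylation
#'
#' Percentiles use linear interpolation between closest ranks
#' (\code{stats::quantile} type 7). Values are reported in percent.
#'
#' @param fractions Numeric vector of methylation fractions in [0,1].
#' @return List with \code{median_pct}, \code{p5_pct}, \code{p95_pct}.
#' @export
methylation_summary <- function(fractions) {
  if (length(fractions) == 0L) stop("need at least one site")
  q <- stats::quantile(fractions, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  list(median_pct = 100 * q[2L], p5_pct = 100 * q[1L], p95_pct = 100 * q[3L])
}

#' Per-sample methylation summary table
#'
#' @param sm A \code{site_matrix}.
#' @return Data frame with one row per sample: median and 5th/95th
#'   percentiles of methylation, in percent.
#' @export
sample_summary_table <- function(sm) {
  do.call(rbind, lapply(seq_len(ncol(sm$fractions)), function(j) {
    s <- methylation_summary(sm$fractions[, j])
    data.frame(sample_id = sm$samples$sample_id[j],
               median_pct = s$median_pct, p5_pct = s$p5_pct,
               p95_pct = s$p95_pct, stringsAsFactors = FALSE)
  }))
}

#' Build a promoter/exon/intron feature map from gene annotation
#'
#' Promoters are strand-aware windows around the transcription start site:
#' on the plus strand \code{[TSS - up, TSS + down)} and on the minus strand
#' \code{[TSS - down + 1, TSS + up + 1)}, in 0-based half-open plus-strand
#' coordinates, clamped at chromosome bounds. Introns are the transcript span
#' minus its exons. Multiple transcripts contribute the union of their
#' promoters.
#'
#' @param annotation Path to a GFF3 (\code{.gff}/\code{.gff3}) or BED
#'   (\code{.bed}) file, or a \code{GRanges} of transcripts (then treated as
#'   single-exon).
#' @param promoter_up Bases upstream of the TSS (default 2000).
#' @param promoter_down Bases downstream of the TSS, TSS included
#'   (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clamping the downstream ends of promoter windows.
#' @return A \code{GRanges} with metadata columns \code{feature_label}
#'   (\code{promoter}, \code{exon}, \code{intron}) and \code{transcript_id}.
#' @export
build_feature_map <- function(annotation, promoter_up = 2000L,
                              promoter_down = 500L, chrom_lengths = NULL) {
  if (is.character(annotation)) {
    ext <- tolower(tools::file_ext(annotation))
    gr <- rtracklayer::import(annotation)
    if (ext == "bed") {
      tx <- gr
      tx$transcript_id <- if (!is.null(tx$name)) tx$name else as.character(seq_along(tx))
      exons <- tx
      exons$Parent <- tx$transcript_id
    } else {
      type <- as.character(gr$type)
      tx <- gr[type %in% c("mRNA", "transcript", "gene") &
                 !(type == "gene" & any(type %in% c("mRNA", "transcript")))]
      tx$transcript_id <- as.character(tx$ID)
      exons <- gr[type == "exon"]
      exons$Parent <- vapply(exons$Parent, function(p) as.character(p)[1L], character(1))
    }
  } else {
    tx <- annotation
    tx$transcript_id <- if (!is.null(tx$transcript_id)) tx$transcript_id else
      as.character(seq_along(tx))
    exons <- tx
    exons$Parent <- tx$transcript_id
  }
  if (length(tx) == 0L) stop("no transcripts in annotation")

  pieces <- list()
  for (k in seq_along(tx)) {
    t1 <- tx[k]
    tid <- t1$transcript_id
    st <- as.character(GenomicRanges::strand(t1))
    if (!st %in% c("+", "-")) st <- "+"
    # 0-based TSS on the plus-strand coordinate
    tss0 <- if (st == "+") GenomicRanges::start(t1) - 1L else GenomicRanges::end(t1) - 1L
    if (st == "+") {
      p_start0 <- tss0 - promoter_up
      p_end0 <- tss0 + promoter_down          # half-open end
    } else {
      p_start0 <- tss0 - promoter_down + 1L
      p_end0 <- tss0 + promoter_up + 1L
    }
    p_start0 <- max(p_start0, 0L)
    chrom <- as.character(GenomicRanges::seqnames(t1))
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      p_end0 <- min(p_end0, chrom_lengths[[chrom]])
    }
    prom <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(p_start0 + 1L, p_end0), strand = st)
    prom$feature_label <- "promoter"
    prom$transcript_id <- tid

    ex <- exons[exons$Parent == tid]
    if (length(ex) == 0L) {
      warning("transcript ", tid, " has no exons; treated as single-exon")
      ex <- t1
    }
    ex2 <- GenomicRanges::granges(ex)
    ex2$feature_label <- "exon"
    ex2$transcript_id <- tid
    intr <- GenomicRanges::setdiff(GenomicRanges::granges(t1),
                                   GenomicRanges::reduce(GenomicRanges::granges(ex)))
    if (length(intr)) {
      intr$feature_label <- "intron"
      intr$transcript_id <- tid
      pieces[[length(pieces) + 1L]] <- intr
    }
    pieces[[length(pieces) + 1L]] <- prom
    pieces[[length(pieces) + 1L]] <- ex2
  }
  out <- suppressWarnings(do.call(c, pieces))
  out <- out[order(as.character(GenomicRanges::seqnames(out)),
                   GenomicRanges::start(out))]
  out
}

#' Genomic-feature distribution of a site set
#'
#' Every site gets exactly one label by precedence (a site inside both a
#' promoter and, say, another gene's intron is a promoter site under the
#' default order). Sites matching nothing get the final label
#' (\code{intergenic}).
#'
#' @param sites Data frame with \code{chrom} and 0-based \code{pos}.
#' @param map Feature \code{GRanges} from [build_feature_map()].
#' @param precedence Ordered labels; the last is the catch-all.
#' @return Data frame with \code{feature_label}, \code{n_sites},
#'   \code{percent}; percentages sum to 100.
#' @export
feature_distribution <- function(sites, map,
                                 precedence = c("promoter", "exon", "intron",
                                                "intergenic")) {
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  label <- rep(NA_character_, nrow(sites))
  for (lab in precedence[-length(precedence)]) {
    sub <- map[map$feature_label == lab]
    if (length(sub) == 0L) next
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(sgr, sub, ignore.strand = TRUE)))
    label[is.na(label) & seq_along(label) %in% hit] <- lab
  }
  label[is.na(label)] <- precedence[length(precedence)]
  counts <- vapply(precedence, function(l) sum(label == l), integer(1))
  data.frame(feature_label = precedence, n_sites = as.integer(counts),
             percent = 100 * counts / nrow(sites),
             stringsAsFactors = FALSE, row.names = NULL)
}
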