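#' Load a reference genome from FASTA
#'
#' Reads a (possibly soft-masked) FASTA file and returns the sequences as a
#' named character vector of uppercase nucleotide strings. Soft-masked
#' (lowercase) bases are uppercased; any character outside \code{A,C,G,T,N}
#' is rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class \code{"noncpg_genome"}; names are
#'   chromosome names (first whitespace-delimited token of each header),
#'   values are uppercase sequences over \code{A,C,G,T,N}.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)),
    warning = function(w) stop("malformed FASTA '", path, "': ", conditionMessage(w))
  )
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- nm
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop("non-ACGTN characters in sequence(s): ", paste(nm[bad], collapse = ", "))
  if (any(nchar(x) == 0L)) stop("empty sequence(s): ", paste(nm[nchar(x) == 0L], collapse = ", "))
  structure(x, class = "noncpg_genome")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector as returned by [load_genome()].
#' @param path Output FASTA path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, \code{path}.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(!is.null(names(genome)), all(nchar(genome) > 0L))
  ss <- Biostrings::DNAStringSet(unclass(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Load per-cytosine methylation calls
#'
#' Supports two on-disk dialects:
#' \describe{
#'   \item{\code{cytosine_report}}{Bismark-style cytosine report: 7 tab-separated
#'     columns \code{chrom, pos (1-based), strand, meth count, unmeth count,
#'     context class, trinucleotide}.}
#'   \item{\code{bedgraph_cov}}{Coverage bedGraph: 6 tab-separated columns
#'     \code{chrom, start (0-based), end, percent methylation, meth count,
#'     unmeth count}. This dialect carries no strand; strand is loaded as
#'     \code{"*"} and inferred from the genome by [annotate_all()].}
#' }
#'
#' Positions are normalised to 0-based internally. Records with zero total
#' reads are retained at load; depth filtering is a separate, auditable stage
#' ([filter_depth()]). The on-disk trinucleotide column is kept as a
#' provisional \code{context3} but is recomputed from the genome by the
#' context module unless explicitly trusted.
#'
#' @param path Path to the calls file.
#' @param dialect One of \code{"cytosine_report"}, \code{"bedgraph_cov"}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos} (0-based),
#'   \code{strand}, \code{meth_reads}, \code{total_reads}, \code{context3}.
#' @export
load_calls <- function(path, dialect = c("cytosine_report", "bedgraph_cov")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("calls file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (dialect == "cytosine_report") {
    if (ncol(dt) < 7L) stop("cytosine_report needs 7 columns, got ", ncol(dt), ": ", path)
    out <- data.frame(
      chrom = as.character(dt[[1]]),
      pos = as.integer(dt[[2]]) - 1L,
      strand = as.character(dt[[3]]),
      meth_reads = as.integer(dt[[4]]),
      total_reads = as.integer(dt[[4]]) + as.integer(dt[[5]]),
      context3 = as.character(dt[[7]]),
      stringsAsFactors = FALSE
    )
    if (any(!out$strand %in% c("+", "-"))) {
      stop("unknown strand symbol in ", path, ": ",
           paste(unique(setdiff(out$strand, c("+", "-"))), collapse = ", "))
    }
    if (any(dt[[4]] < 0L) || any(dt[[5]] < 0L)) stop("negative read count in ", path)
  } else {
    if (ncol(dt) < 6L) stop("bedgraph_cov needs 6 columns, got ", ncol(dt), ": ", path)
    if (any(dt[[5]] < 0L) || any(dt[[6]] < 0L)) stop("negative read count in ", path)
    if (any(dt[[3]] - dt[[2]] != 1L)) stop("bedgraph_cov intervals must be single-base: ", path)
    out <- data.frame(
      chrom = as.character(dt[[1]]),
      pos = as.integer(dt[[2]]),
      strand = "*",
      meth_reads = as.integer(dt[[5]]),
      total_reads = as.integer(dt[[5]]) + as.integer(dt[[6]]),
      context3 = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (any(out$pos < 0L)) stop("non-positive coordinate in ", path)
  out
}

#' Write methylation calls in a chosen dialect
#'
#' Inverse of [load_calls()]; used by the synthetic generator and for
#' round-trip testing. \code{cytosine_report} writes the Bismark-style context
#' class column (CpG/CHG/CHH/Unknown) derived from \code{context3}.
#'
#' @param calls Data frame as returned by [load_calls()].
#' @param path Output path.
#' @param dialect Target dialect.
#' @return Invisibly, \code{path}.
#' @export
write_calls <- function(calls, path, dialect = c("cytosine_report", "bedgraph_cov")) {
  dialect <- match.arg(dialect)
  if (dialect == "cytosine_report") {
    ctx <- ifelse(is.na(calls$context3), "CNN", calls$context3)
    dt <- data.frame(
      calls$chrom, calls$pos + 1L, calls$strand, calls$meth_reads,
      calls$total_reads - calls$meth_reads,
      vapply(ctx, function(c3) {
        h <- h_class(c3)
        if (h == "UNDEFINED") "Unknown" else h
      }, character(1), USE.NAMES = FALSE),
      ctx
    )
  } else {
    pct <- ifelse(calls$total_reads > 0, 100 * calls$meth_reads / calls$total_reads, 0)
    dt <- data.frame(
      calls$chrom, calls$pos, calls$pos + 1L, pct, calls$meth_reads,
      calls$total_reads - calls$meth_reads
    )
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Load a sample sheet
#'
#' The sheet is a CSV with header columns \code{sample_id}, \code{individual_id},
#' \code{tissue}, \code{replicate}, \code{calls_path}. \code{sample_id} and the
#' combination \code{(individual_id, tissue, replicate)} must be unique;
#' every \code{calls_path} must exist (checked relative to the sheet's
#' directory when not absolute, unless \code{check_paths = FALSE}).
#'
#' @param path CSV path.
#' @param check_paths Verify that each \code{calls_path} exists.
#' @return A \code{data.frame} of sample records.
#' @export
load_sample_sheet <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "individual_id", "tissue", "replicate", "calls_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  key <- paste(df$individual_id, df$tissue, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, tissue, replicate) combination in sample sheet")
  }
  if (check_paths) {
    p <- df$calls_path
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(dirname(path), p[rel])
    ok <- file.exists(p)
    if (!all(ok)) stop("calls_path missing for sample(s): ",
                       paste(df$sample_id[!ok], collapse = ", "))
    df$calls_path <- p
  }
  df
}

#' Export a dendrogram to Newick
#'
#' Branch lengths are parent height minus child height (leaves sit at height
#' zero), so cophenetic distances are preserved. Leaf order follows the
#' dendrogram's deterministic order. Labels containing Newick-reserved
#' characters are quoted.
#'
#' @param tree A \code{noncpg_dendro} object from [meth_linkage()].
#' @param labels Optional per-leaf labels overriding \code{tree$labels}.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by \code{";"}.
#' @export
export_newick <- function(tree, labels = NULL, digits = 10L) {
  stopifnot(inherits(tree, "noncpg_dendro"))
  if (is.null(labels)) labels <- tree$labels
  n <- length(labels)
  quote_lab <- function(x) {
    if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  if (n == 1L) return(paste0(quote_lab(labels[1L]), ":0.0;"))
  heights <- tree$height
  node_str <- character(n - 1L)
  child <- function(id, parent_h) {
    if (id < 0L) {
      paste0(quote_lab(labels[-id]), ":", fmt(parent_h))
    } else {
      if (heights[id] > parent_h + 1e-12) {
        stop("height inversion: child node above its parent")
      }
      paste0(node_str[id], ":", fmt(parent_h - heights[id]))
    }
  }
  for (k in seq_len(n - 1L)) {
    l <- tree$merge[k, 1L]; r <- tree$merge[k, 2L]
    node_str[k] <- paste0("(", child(l, heights[k]), ",", child(r, heights[k]), ")")
  }
  paste0(node_str[n - 1L], ";")
}

#' Write a dendrogram merge table as TSV
#'
#' One row per merge: step, left child, right child, height. Children are
#' encoded hclust-style (negative = leaf index, positive = earlier merge step).
#'
#' @param tree A \code{noncpg_dendro}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_merge_table <- function(tree, path) {
  df <- data.frame(
    step = seq_along(tree$height),
    left = tree$merge[, 1L],
    right = tree$merge[, 2L],
    height = tree$height
  )
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
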