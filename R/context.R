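#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' The sixteen defined trinucleotide contexts
#'
#' Four CpG contexts (CGA, CGC, CGG, CGT) and twelve non-CpG contexts,
#' read 5'-to-3' on the cytosine's own strand.
#'
#' @return Character vector of the 16 context labels.
#' @export
all_contexts <- function() {
  c("CGA", "CGC", "CGG", "CGT",
    "CAA", "CAC", "CAG", "CAT",
    "CCA", "CCC", "CCG", "CCT",
    "CTA", "CTC", "CTG", "CTT")
}

#' Dinucleotide class of a trinucleotide context
#'
#' @param context3 Character vector of 3-letter contexts (or "UNDEFINED"/NA).
#' @return One of \code{"CpG"}, \code{"CpA"}, \code{"CpC"}, \code{"CpT"},
#'   \code{"UNDEFINED"} per element.
#' @export
dinuc_class <- function(context3) {
  second <- substr(context3, 2L, 2L)
  out <- ifelse(is.na(context3) | context3 == "UNDEFINED", "UNDEFINED",
                paste0("Cp", second))
  out[!out %in% c("CpG", "CpA", "CpC", "CpT", "UNDEFINED")] <- "UNDEFINED"
  out
}

#' CpG/CHG/CHH class of a trinucleotide context
#'
#' Position 2 = G gives CpG; otherwise position 3 = G gives CHG; otherwise
#' CHH (H = A, C or T), reading 5'-to-3' on the cytosine's strand.
#'
#' @param context3 Character vector of 3-letter contexts (or "UNDEFINED"/NA).
#' @return One of \code{"CpG"}, \code{"CHG"}, \code{"CHH"}, \code{"UNDEFINED"}
#'   per element.
#' @export
h_class <- function(context3) {
  ok <- !is.na(context3) & context3 %in% all_contexts()
  p2 <- substr(context3, 2L, 2L)
  p3 <- substr(context3, 3L, 3L)
  out <- rep("UNDEFINED", length(context3))
  out[ok & p2 == "G"] <- "CpG"
  out[ok & p2 != "G" & p3 == "G"] <- "CHG"
  out[ok & p2 != "G" & p3 != "G"] <- "CHH"
  out
}

#' Strand-aware trinucleotide context of one cytosine
#'
#' For a plus-strand cytosine the context is the plus-strand bases at
#' \code{[pos, pos+2]}; for a minus-strand cytosine (plus-strand base G) it is
#' the reverse complement of the plus-strand bases at \code{[pos-2, pos]}, so
#' the context always reads 5'-to-3' starting at the C on its own strand.
#' Windows that run off the chromosome or contain N yield \code{"UNDEFINED"}.
#'
#' @param genome A genome from [load_genome()] or [simulate_genome()].
#' @param chrom Chromosome name.
#' @param pos 0-based position of the cytosine (on the plus-strand coordinate).
#' @param strand \code{"+"} or \code{"-"}.
#' @return A list with \code{context3}, \code{dinuc} and \code{hclass}.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  seq <- unclass(genome)[[chrom]]
  L <- nchar(seq)
  if (pos < 0L || pos >= L) stop("position out of bounds: ", chrom, ":", pos)
  base <- substr(seq, pos + 1L, pos + 1L)
  if (strand == "+") {
    if (base != "C") stop("base at ", chrom, ":", pos, " (+) is ", base, ", not C")
    ctx <- if (pos + 2L < L) substr(seq, pos + 1L, pos + 3L) else "UNDEFINED"
  } else if (strand == "-") {
    if (base != "G") stop("base at ", chrom, ":", pos, " (-) is ", base,
                          ", not C on the minus strand")
    ctx <- if (pos - 2L >= 0L) revcomp(substr(seq, pos - 1L, pos + 1L)) else "UNDEFINED"
  } else stop("strand must be '+' or '-'")
  if (grepl("N", ctx)) ctx <- "UNDEFINED"
  list(context3 = ctx, dinuc = dinuc_class(ctx), hclass = h_class(ctx))
}

# Vectorised context extraction for many positions on one chromosome.
# Returns "UNDEFINED" for out-of-window or N-containing contexts.
contexts_at <- function(seq, pos, strand) {
  L <- nchar(seq)
  ctx <- rep("UNDEFINED", length(pos))
  plus <- strand == "+"
  okp <- plus & pos + 2L < L
  if (any(okp)) {
    ctx[okp] <- substring(seq, pos[okp] + 1L, pos[okp] + 3L)
  }
  okm <- !plus & pos - 2L >= 0L
  if (any(okm)) {
    ctx[okm] <- revcomp(substring(seq, pos[okm] - 1L, pos[okm] + 1L))
  }
  ctx[grepl("N", ctx)] <- "UNDEFINED"
  ctx
}

#' Enumerate every cytosine in a genome with its context
#'
#' Scans both strands: plus-strand cytosines are C bases, minus-strand
#' cytosines are plus-strand G bases.
#'
#' @param genome A genome object.
#' @return Data frame with \code{chrom}, \code{pos} (0-based), \code{strand},
#'   \code{context3}, sorted by (chrom, pos, strand).
#' @export
genome_cytosines <- function(genome) {
  res <- lapply(names(genome), function(chrom) {
    seq <- unclass(genome)[[chrom]]
    b <- strsplit(seq, "", fixed = TRUE)[[1L]]
    pp <- which(b == "C") - 1L
    pm <- which(b == "G") - 1L
    df <- data.frame(
      chrom = rep(chrom, length(pp) + length(pm)),
      pos = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))),
      stringsAsFactors = FALSE
    )
    df$context3 <- contexts_at(seq, df$pos, df$strand)
    df
  })
  out <- do.call(rbind, res)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Annotate calls with genome-derived contexts
#'
#' Recomputes every call's trinucleotide context from the genome (the genome
#' is the source of truth; a mismatching on-disk context column indicates a
#' genome/calls mismatch). Calls loaded from a strand-less dialect
#' (\code{strand == "*"}) get their strand inferred from the genome base
#' (plus-strand C is a + call, plus-strand G a - call).
#'
#' @param genome A genome object.
#' @param calls Calls data frame from [load_calls()].
#' @param trust_file_context If TRUE, keep the on-disk \code{context3} for
#'   records that already have one and only fill missing values.
#' @return The calls data frame with \code{strand} resolved and
#'   \code{context3} filled.
#' @export
annotate_all <- function(genome, calls, trust_file_context = FALSE) {
  out <- calls
  for (chrom in unique(out$chrom)) {
    if (!chrom %in% names(genome)) stop("unknown chromosome in calls: ", chrom)
    idx <- which(out$chrom == chrom)
    seq <- unclass(genome)[[chrom]]
    L <- nchar(seq)
    if (any(out$pos[idx] >= L)) {
      bad <- idx[which(out$pos[idx] >= L)[1L]]
      stop("call position beyond chromosome end: ", chrom, ":", out$pos[bad])
    }
    base <- substring(seq, out$pos[idx] + 1L, out$pos[idx] + 1L)
    star <- out$strand[idx] == "*"
    if (any(star)) {
      inferred <- ifelse(base[star] == "C", "+", ifelse(base[star] == "G", "-", "?"))
      if (any(inferred == "?")) {
        bad <- idx[star][which(inferred == "?")[1L]]
        stop("cannot infer strand: base at ", chrom, ":", out$pos[bad],
             " is neither C nor G")
      }
      out$strand[idx[star]] <- inferred
    }
    expect <- ifelse(out$strand[idx] == "+", "C", "G")
    if (any(base != expect)) {
      bad <- idx[which(base != expect)[1L]]
      stop("genome/calls mismatch: base at ", chrom, ":", out$pos[bad], " (",
           out$strand[bad], ") is ", base[which(base != expect)[1L]],
           ", not a cytosine on that strand")
    }
    ctx <- contexts_at(seq, out$pos[idx], out$strand[idx])
    if (trust_file_context) {
      keep <- !is.na(out$context3[idx]) & out$context3[idx] %in% all_contexts()
      ctx[keep] <- out$context3[idx][keep]
    }
    out$context3[idx] <- ctx
  }
  out
}

#' Tabulate site counts per context
#'
#' @param context3 Character vector of context labels.
#' @return Data frame with \code{context3} and \code{n_sites}, one row per
#'   observed label (UNDEFINED included if present).
#' @export
context_site_counts <- function(context3) {
  tab <- table(context3)
  data.frame(context3 = names(tab), n_sites = as.integer(tab),
             stringsAsFactors = FALSE)
}
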