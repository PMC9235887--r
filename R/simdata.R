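# Synthetic multi-tissue / multi-individual methylome generator.
#
# Latent model, per cytosine site s with context c, tissue t, individual i:
#   p(s,t,i) = inv-logit( logit(b_s) + [L(s, lineage(t)) + r(s,t) + u(s,i)] / g0 )
# with b_s a per-site baseline (Beta for non-CpG, a bimodal Beta mixture for
# CpG), L a per-(site, lineage) tissue-lineage effect, r a small per-(site,
# tissue) residual within a lineage, and u a per-(site, individual) effect.
# Effect standard deviations are specified in methylation-fraction units:
# g0 = E[b(1-b)] is the mean logistic derivative of the baseline
# distribution (analytic, per regime), so a shift e moves the methylation
# fraction by about e * b(1-b)/g0 -- e fraction units at a typical site,
# proportionally less at weakly methylated sites -- while the logit
# application keeps probabilities inside (0,1) without hard truncation
# dominating. Reads: total ~ floor + Poisson(depth - floor),
# meth ~ Binomial(total, p). No noise beyond binomial sampling is added for
# replicates.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Default per-context effect regimes
#'
#' Tissue-lineage, within-lineage residual, and individual effect standard
#' deviations (methylation-fraction units) per trinucleotide context.
#' CAC and CTC are tissue-lineage dominated, CAT individual dominated,
#' remaining non-CpG contexts intermediate, CpG contexts tissue dominated.
#'
#' @return Data frame with \code{context3}, \code{tissue_sd}, \code{resid_sd},
#'   \code{ind_sd}.
#' @export
default_context_effects <- function() {
  ctx <- all_contexts()
  df <- data.frame(context3 = ctx,
                   tissue_sd = 0.02, resid_sd = 0.005, ind_sd = 0.02,
                   stringsAsFactors = FALSE)
  set_row <- function(df, c3, t, r, i) {
    df[df$context3 == c3, c("tissue_sd", "resid_sd", "ind_sd")] <- list(t, r, i)
    df
  }
  df <- set_row(df, "CAC", 0.05, 0.005, 0.01)
  df <- set_row(df, "CTC", 0.03, 0.005, 0.01)
  df <- set_row(df, "CAT", 0.005, 0.005, 0.04)
  for (c3 in c("CGA", "CGC", "CGG", "CGT")) df <- set_row(df, c3, 0.05, 0.005, 0.01)
  df
}

#' Discovery-style study design
#'
#' @param n_individuals Number of individuals (default 20).
#' @param tissues Tissue labels (default umbilical cord, cord blood,
#'   peripheral blood).
#' @return Sample-record data frame: one sample per individual per tissue.
#' @export
discovery_design <- function(n_individuals = 20L,
                             tissues = c("umbilical_cord", "cord_blood",
                                         "peripheral_blood")) {
  g <- expand.grid(tissue = tissues,
                   individual_id = sprintf("ind%02d", seq_len(n_individuals)),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$individual_id, g$tissue, sep = "_"),
             individual_id = g$individual_id, tissue = g$tissue,
             replicate = "", stringsAsFactors = FALSE)
}

#' Validation-style study design
#'
#' Four individuals assayed in duplicate in muscle, plus one pooled
#' cord-blood sample assayed as two duplicate pairs (A/B and C/D): 12 samples
#' across 5 individual labels.
#'
#' @return Sample-record data frame.
#' @export
validation_design <- function() {
  muscle <- expand.grid(replicate = c("A", "B"),
                        individual_id = sprintf("ind%02d", 1:4),
                        stringsAsFactors = FALSE)
  muscle$tissue <- "muscle"
  cb <- data.frame(replicate = c("A", "B", "C", "D"),
                   individual_id = "ind05", tissue = "cord_blood",
                   stringsAsFactors = FALSE)
  d <- rbind(muscle[, c("individual_id", "tissue", "replicate")],
             cb[, c("individual_id", "tissue", "replicate")])
  data.frame(sample_id = paste(d$individual_id, d$tissue, d$replicate, sep = "_"),
             d, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed Integer seed; fixes every random draw of the generator.
#' @param n_chrom,chrom_length Genome dimensions.
#' @param gc GC content of the simulated genome.
#' @param design Sample-record data frame ([discovery_design()] by default).
#' @param lineages Named character vector mapping tissue to lineage; cord
#'   blood and peripheral blood share the \code{"blood"} lineage.
#' @param depth_mean Mean sequencing depth per site (default 50).
#' @param depth_floor Minimum depth draw (default 1; depth =
#'   floor + Poisson(mean - floor)).
#' @param baseline_shape Beta shape parameters of the non-CpG per-site
#'   baseline (default c(0.5, 7), a low-methylation regime).
#' @param cpg_mix CpG baseline mixture: list of weight of the
#'   high-methylation component and the two Beta shapes.
#' @param context_effects Per-context effect table
#'   ([default_context_effects()]).
#' @param clip Latent probabilities are clipped to \code{[clip, 1 - clip]}.
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 5000L,
                              gc = 0.5, design = discovery_design(),
                              lineages = c(umbilical_cord = "umbilical_cord",
                                           cord_blood = "blood",
                                           peripheral_blood = "blood",
                                           muscle = "muscle"),
                              depth_mean = 50, depth_floor = 1L,
                              baseline_shape = c(0.5, 7),
                              cpg_mix = list(w_high = 0.5,
                                             high = c(8, 2), low = c(0.5, 10)),
                              context_effects = default_context_effects(),
                              clip = 0.001) {
  stopifnot(chrom_length >= 100L, depth_mean > depth_floor,
            all(c("tissue_sd", "resid_sd", "ind_sd") %in% names(context_effects)))
  if (any(context_effects$tissue_sd < 0) || any(context_effects$ind_sd < 0) ||
      any(context_effects$resid_sd < 0)) stop("negative effect sd")
  if (nrow(design) == 0L || any(!nzchar(design$tissue))) stop("empty tissue in design")
  miss <- setdiff(unique(design$tissue), names(lineages))
  if (length(miss)) stop("no lineage for tissue(s): ", paste(miss, collapse = ", "))
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length), gc = gc,
                 design = design, lineages = lineages,
                 depth_mean = depth_mean, depth_floor = as.integer(depth_floor),
                 baseline_shape = baseline_shape, cpg_mix = cpg_mix,
                 context_effects = context_effects, clip = clip),
            class = "sim_config")
}

#' Simulate a random genome
#'
#' I.i.d. bases with a GC-content knob; deterministic under the config seed.
#'
#' @param config A \code{sim_config}.
#' @return A genome object (named character vector).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- vapply(seq_len(config$n_chrom), function(k) {
    paste(sample(names(p), config$chrom_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(config$n_chrom))
  structure(seqs, class = "noncpg_genome")
}

#' Simulate a methylation study over a genome
#'
#' Draws per-site baselines, context-specific tissue-lineage and individual
#' effects, depths and methylated read counts for every sample in the
#' design. The latent probability table is retained for parameter-recovery
#' checks.
#'
#' @param config A \code{sim_config}.
#' @param genome A genome object (defaults to [simulate_genome()] under the
#'   same config).
#' @param contexts Optional character vector restricting simulation to sites
#'   of these trinucleotide contexts (all defined contexts by default).
#' @return A list of class \code{meth_study}: \code{sites}, \code{samples},
#'   \code{meth}, \code{depths}, \code{truth} (latent p, sites x samples),
#'   \code{genome}, \code{config}.
#' @export
simulate_study <- function(config, genome = simulate_genome(config),
                           contexts = NULL) {
  cy <- genome_cytosines(genome)
  cy <- cy[cy$context3 != "UNDEFINED", , drop = FALSE]
  if (!is.null(contexts)) cy <- cy[cy$context3 %in% contexts, , drop = FALSE]
  if (nrow(cy) == 0L) stop("no eligible cytosine sites in genome")
  rownames(cy) <- NULL

  design <- config$design
  n_sites <- nrow(cy); n_samp <- nrow(design)
  eff <- config$context_effects
  ei <- match(cy$context3, eff$context3)
  if (anyNA(ei)) stop("context_effects table missing context(s): ",
                      paste(setdiff(unique(cy$context3), eff$context3), collapse = ", "))

  set.seed(config$seed + 1L)

  # per-site baseline: CpG contexts from the bimodal mixture, others Beta
  is_cpg <- substr(cy$context3, 2L, 2L) == "G"
  base <- numeric(n_sites)
  base[!is_cpg] <- stats::rbeta(sum(!is_cpg), config$baseline_shape[1L],
                                config$baseline_shape[2L])
  if (any(is_cpg)) {
    hi <- stats::runif(sum(is_cpg)) < config$cpg_mix$w_high
    b <- numeric(sum(is_cpg))
    b[hi] <- stats::rbeta(sum(hi), config$cpg_mix$high[1L], config$cpg_mix$high[2L])
    b[!hi] <- stats::rbeta(sum(!hi), config$cpg_mix$low[1L], config$cpg_mix$low[2L])
    base[is_cpg] <- b
  }
  base <- pmin(pmax(base, config$clip), 1 - config$clip)

  lineages <- unique(config$lineages[design$tissue])
  tissues <- unique(design$tissue)
  individuals <- unique(design$individual_id)
  L <- matrix(stats::rnorm(n_sites * length(lineages), 0, eff$tissue_sd[ei]),
              n_sites, length(lineages), dimnames = list(NULL, lineages))
  r <- matrix(stats::rnorm(n_sites * length(tissues), 0, eff$resid_sd[ei]),
              n_sites, length(tissues), dimnames = list(NULL, tissues))
  u <- matrix(stats::rnorm(n_sites * length(individuals), 0, eff$ind_sd[ei]),
              n_sites, length(individuals), dimnames = list(NULL, individuals))

  beta_mean_deriv <- function(a, b) a * b / ((a + b) * (a + b + 1))
  g0_noncpg <- beta_mean_deriv(config$baseline_shape[1L], config$baseline_shape[2L])
  g0_cpg <- config$cpg_mix$w_high *
    beta_mean_deriv(config$cpg_mix$high[1L], config$cpg_mix$high[2L]) +
    (1 - config$cpg_mix$w_high) *
    beta_mean_deriv(config$cpg_mix$low[1L], config$cpg_mix$low[2L])
  scale <- ifelse(is_cpg, g0_cpg, g0_noncpg)
  lg <- logit(base)
  meth <- matrix(0L, n_sites, n_samp)
  dep <- matrix(0L, n_sites, n_samp)
  truth <- matrix(0, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    t <- design$tissue[j]; i <- design$individual_id[j]
    e <- L[, config$lineages[[t]]] + r[, t] + u[, i]
    p <- inv_logit(lg + e / scale)
    p <- pmin(pmax(p, config$clip), 1 - config$clip)
    d <- config$depth_floor +
      stats::rpois(n_sites, config$depth_mean - config$depth_floor)
    meth[, j] <- stats::rbinom(n_sites, d, p)
    dep[, j] <- d
    truth[, j] <- p
  }
  colnames(meth) <- colnames(dep) <- colnames(truth) <- design$sample_id

  structure(list(sites = cy, samples = design, meth = meth, depths = dep,
                 truth = truth, genome = genome, config = config),
            class = "meth_study")
}

#' @export
print.meth_study <- function(x, ...) {
  cat("meth_study:", nrow(x$sites), "sites x", nrow(x$samples), "samples;",
      "seed", x$config$seed, "\n")
  invisible(x)
}

#' Site matrix of a simulated study
#'
#' @param study A \code{meth_study}.
#' @return A \code{site_matrix} over all simulated sites (unfiltered).
#' @export
study_matrix <- function(study) {
  site_matrix(study$sites, study$samples, study$meth, study$depths)
}

#' Calls data frame for one simulated sample
#'
#' @param study A \code{meth_study}.
#' @param sample_id Sample identifier.
#' @return A calls data frame in the internal layout of [load_calls()].
#' @export
study_calls <- function(study, sample_id) {
  j <- match(sample_id, study$samples$sample_id)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  data.frame(chrom = study$sites$chrom, pos = study$sites$pos,
             strand = study$sites$strand,
             meth_reads = study$meth[, j],
             total_reads = study$depths[, j],
             context3 = study$sites$context3,
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Emits the genome FASTA, one cytosine-report TSV per sample, the sample
#' sheet CSV (with calls paths), the latent truth table TSV, the
#' configuration JSON and a run-info sidecar recording the seed and the
#' config file's MD5 hash.
#'
#' @param study A \code{meth_study}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(study$genome, file.path(dir, "genome.fa"))
  paths <- character(nrow(study$samples))
  for (j in seq_len(nrow(study$samples))) {
    sid <- study$samples$sample_id[j]
    paths[j] <- paste0(sid, ".cytosine_report.tsv")
    write_calls(study_calls(study, sid), file.path(dir, paths[j]),
                dialect = "cytosine_report")
  }
  sheet <- cbind(study$samples, calls_path = paths)
  utils::write.csv(sheet, file.path(dir, "samples.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- cbind(study$sites, as.data.frame(study$truth))
  data.table::fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- study$config
  cfg_json <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(seed = cfg$seed, n_chrom = cfg$n_chrom, chrom_length = cfg$chrom_length,
         gc = cfg$gc, depth_mean = cfg$depth_mean, depth_floor = cfg$depth_floor,
         baseline_shape = cfg$baseline_shape, clip = cfg$clip,
         lineages = as.list(cfg$lineages),
         context_effects = cfg$context_effects,
         design = cfg$design),
    cfg_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_hash = unname(tools::md5sum(cfg_json))),
    file.path(dir, "run_info.json"), auto_unbox = TRUE)
  invisible(dir)
}
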