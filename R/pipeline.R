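#' Run the full analysis pipeline
#'
#' Orchestrates: load genome + sample sheet + per-sample calls, annotate
#' contexts from the genome, apply the depth and commonly-methylated filters,
#' stratify by trinucleotide context, cluster each context sub-matrix
#' (Euclidean distance, chosen linkage), score dendrogram composition, and
#' write a report bundle (Newick trees, merge tables, composition scores,
#' stage counts, per-sample summaries, duplicate concordance, optional
#' feature distribution). Outputs are deterministic for identical inputs.
#'
#' @param genome Genome object or FASTA path.
#' @param sample_sheet Sample-sheet CSV path, or a data frame that already
#'   carries a \code{calls} list-column of calls data frames.
#' @param out_dir Output directory.
#' @param annotation Optional GFF3/BED path for the feature distribution.
#' @param dialect Calls dialect for files referenced by the sheet.
#' @param min_depth Inclusive depth threshold (default 30).
#' @param nonzero Apply the non-zero-in-all-samples rule to non-CpG contexts
#'   (CpG contexts are never subjected to it).
#' @param contexts Contexts to analyse (default: all present).
#' @param linkage Linkage method.
#' @param k_tissues Tissues per individual for triad scoring.
#' @param tol_points Duplicate-agreement tolerance in percentage points.
#' @param promoter_up,promoter_down Promoter window around the TSS.
#' @param trust_file_context Keep on-disk contexts instead of recomputing.
#' @return Invisibly, a list with the assembled matrices, dendrograms and
#'   report tables.
#' @export
run_pipeline <- function(genome, sample_sheet, out_dir,
                         annotation = NULL,
                         dialect = "cytosine_report",
                         min_depth = 30L, nonzero = TRUE,
                         contexts = NULL, linkage = "complete",
                         k_tissues = 3L, tol_points = 10,
                         promoter_up = 2000L, promoter_down = 500L,
                         trust_file_context = FALSE) {
  if (is.character(genome)) genome <- load_genome(genome)
  if (is.character(sample_sheet)) sample_sheet <- load_sample_sheet(sample_sheet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- sample_sheet[, c("sample_id", "individual_id", "tissue", "replicate")]
  calls_by_sample <- if (!is.null(sample_sheet[["calls"]])) {
    stats::setNames(sample_sheet[["calls"]], sample_sheet$sample_id)
  } else {
    stats::setNames(lapply(sample_sheet$calls_path, load_calls, dialect = dialect),
                    sample_sheet$sample_id)
  }
  calls_by_sample <- lapply(calls_by_sample, function(df) {
    annotate_all(genome, df, trust_file_context = trust_file_context)
  })

  asm <- assemble_matrix(calls_by_sample, samples, min_depth = min_depth,
                         nonzero = FALSE)
  sm_depth <- asm$matrix
  stages <- asm$stages
  is_cpg <- substr(sm_depth$sites$context3, 2L, 2L) == "G"
  sm_noncpg <- subset_sites(sm_depth, which(!is_cpg &
                                              sm_depth$sites$context3 != "UNDEFINED"))
  sm_cpg <- subset_sites(sm_depth, which(is_cpg))
  if (nonzero) {
    sm_noncpg <- nonzero_common(sm_noncpg)
    stages <- rbind(stages, data.frame(
      stage = "non-CpG, non-zero methylation in all samples",
      n_sites = nrow(sm_noncpg$sites)))
  }
  data.table::fwrite(stages, file.path(out_dir, "stage_counts.tsv"), sep = "\t")

  strata <- c(stratify_by_context(sm_noncpg), stratify_by_context(sm_cpg))
  if (!is.null(contexts)) strata <- strata[intersect(contexts, names(strata))]
  strata <- strata[vapply(strata, function(s) nrow(s$sites) >= 1L, logical(1))]

  trees <- list(); scores <- list(); purity <- list()
  for (c3 in names(strata)) {
    sm <- strata[[c3]]
    if (ncol(sm$fractions) < 2L) next
    tr <- meth_linkage(euclidean_distances(sm), method = linkage)
    trees[[c3]] <- tr
    writeLines(export_newick(tr), file.path(out_dir, paste0(c3, ".nwk")))
    write_merge_table(tr, file.path(out_dir, paste0(c3, ".merges.tsv")))
    scores[[c3]] <- score_composition(tr, samples, k_tissues = k_tissues)
    purity[[c3]] <- cbind(context3 = c3, first_split_purity(tr, samples))
  }
  score_tab <- do.call(rbind, lapply(names(scores), function(c3) {
    s <- scores[[c3]]
    data.frame(context3 = c3, n_sites = nrow(strata[[c3]]$sites),
               n_triad_individuals = s$n_triad_individuals,
               n_pair_individuals = s$n_pair_individuals,
               n_triad_samples = s$n_triad_samples,
               n_pair_samples = s$n_pair_samples,
               n_tissue_clustered_samples = s$n_tissue_clustered_samples,
               n_outliers = s$n_outliers, stringsAsFactors = FALSE)
  }))
  if (!is.null(score_tab)) {
    data.table::fwrite(score_tab, file.path(out_dir, "composition_scores.tsv"),
                       sep = "\t")
    jsonlite::write_json(score_tab, file.path(out_dir, "composition_scores.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (length(purity)) {
    data.table::fwrite(do.call(rbind, purity),
                       file.path(out_dir, "first_split_purity.tsv"), sep = "\t")
  }

  summary_tab <- sample_summary_table(
    if (nrow(sm_noncpg$sites)) sm_noncpg else sm_depth)
  data.table::fwrite(summary_tab, file.path(out_dir, "sample_summaries.tsv"),
                     sep = "\t")

  # duplicate concordance: samples sharing (individual, tissue), differing replicate
  conc <- NULL
  key <- paste(samples$individual_id, samples$tissue)
  for (k in unique(key[duplicated(key)])) {
    js <- which(key == k)
    f <- (if (nrow(sm_noncpg$sites)) sm_noncpg else sm_depth)$fractions
    for (a in seq_along(js)) for (b in seq_len(a - 1L)) {
      ag <- duplicate_agreement(f[, js[a]], f[, js[b]], tol_points = tol_points)
      conc <- rbind(conc, data.frame(
        sample_a = samples$sample_id[js[a]], sample_b = samples$sample_id[js[b]],
        n_sites = ag$n_sites, percent_within = ag$percent_within,
        tol_points = tol_points, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(conc)) {
    data.table::fwrite(conc, file.path(out_dir, "duplicate_concordance.tsv"),
                       sep = "\t")
  }

  featdist <- NULL
  if (!is.null(annotation)) {
    fm <- build_feature_map(annotation, promoter_up = promoter_up,
                            promoter_down = promoter_down,
                            chrom_lengths = stats::setNames(nchar(genome),
                                                            names(genome)))
    featdist <- feature_distribution(sm_noncpg$sites, fm)
    data.table::fwrite(featdist, file.path(out_dir, "feature_distribution.tsv"),
                       sep = "\t")
  }

  invisible(list(matrix_noncpg = sm_noncpg, matrix_cpg = sm_cpg,
                 strata = strata, trees = trees, scores = scores,
                 score_table = score_tab, stages = stages,
                 first_split = purity, summaries = summary_tab,
                 concordance = conc, feature_distribution = featdist))
}

#' Single-context parameter-recovery experiment
#'
#' Simulates a discovery-design study restricted to one trinucleotide
#' context, applies the depth and commonly-methylated filters, truncates the
#' filtered sub-matrix to \code{n_sites} sites (deterministic site order),
#' clusters it (Euclidean, chosen linkage), and scores the dendrogram. The
#' genome is sized so the filtered matrix comfortably reaches \code{n_sites}.
#'
#' @param context Trinucleotide context to simulate (e.g. \code{"CAC"}).
#' @param tissue_sd,ind_sd,resid_sd Effect standard deviations
#'   (methylation-fraction units) for that context.
#' @param n_sites Number of filtered sites entering the clustering.
#' @param depth_mean Mean sequencing depth.
#' @param seed Simulation seed.
#' @param n_individuals Number of individuals in the discovery design.
#' @param min_depth Depth filter threshold.
#' @param linkage Linkage method.
#' @return List with \code{paired} (cord-blood/peripheral-blood paired
#'   individual count), \code{triads} (triad individual count),
#'   \code{first_split} (purity table), \code{score} (full composition
#'   score), \code{n_sites_used}.
#' @export
run_context_recovery <- function(context, tissue_sd, ind_sd, n_sites,
                                 depth_mean = 50, seed = 1L,
                                 resid_sd = 0.005, n_individuals = 20L,
                                 min_depth = 30L, linkage = "complete") {
  eff <- default_context_effects()
  eff[eff$context3 == context, c("tissue_sd", "resid_sd", "ind_sd")] <-
    list(tissue_sd, resid_sd, ind_sd)
  # expected context sites per bp on two strands is ~1/32; the depth+nonzero
  # cascade under the default baseline keeps roughly a quarter of raw sites
  chrom_length <- as.integer(n_sites * 5L * 33L)
  cfg <- simulation_config(seed = seed, n_chrom = 1L,
                           chrom_length = chrom_length,
                           design = discovery_design(n_individuals),
                           depth_mean = depth_mean,
                           context_effects = eff)
  study <- simulate_study(cfg, contexts = context)
  sm <- filter_matrix_depth(study_matrix(study), min_depth)
  sm <- nonzero_common(sm)
  if (nrow(sm$sites) > n_sites) sm <- subset_sites(sm, seq_len(n_sites))
  tr <- meth_linkage(euclidean_distances(sm), method = linkage)
  list(paired = count_paired_individuals(tr, study$samples,
                                         c("cord_blood", "peripheral_blood")),
       triads = score_composition(tr, study$samples,
                                  k_tissues = 3L)$n_triad_individuals,
       first_split = first_split_purity(tr, study$samples),
       score = score_composition(tr, study$samples, k_tissues = 3L),
       n_sites_used = nrow(sm$sites))
}
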