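# noncpg

Context-stratified clustering of non-CpG DNA methylomes.

## The problem

Mammalian DNA methylation outside CpG dinucleotides (CpA/CpC/CpT, often
written CHG/CHH with H ∈ {A, C, T}) is sparse, strand-asymmetric and easy to
dismiss as noise. Yet when per-cytosine bisulfite calls are restricted to
*commonly methylated* sites — covered by ≥ 30 reads **and** carrying at least
one methylated read in every sample of a study — and then split by the
trinucleotide (CNN) context of each cytosine, hierarchical clustering of
samples becomes strikingly context dependent: methylation at CAC (and, more
weakly, CTC) sites groups samples by **tissue**, with haematopoietic tissues
from the same person pairing inside the blood branch, while methylation at
CAT sites groups samples by **individual**, joining all of a person's tissues
into a triad. `noncpg` implements that entire analysis as a reusable,
testable pipeline for epigenomics researchers working with cytosine-level
methylation calls (Bismark-style cytosine reports or coverage bedGraphs).

## What the package computes

- **Context annotation** — every cytosine on both strands gets its 5'→3'
  trinucleotide context from the reference genome (plus strand: bases
  `[pos, pos+2]`; minus strand: reverse complement of `[pos−2, pos]`),
  partitioned into 4 CpG contexts (CGA/CGC/CGG/CGT) and 12 non-CpG contexts,
  with CpG/CHG/CHH classes derived from it.
- **Site filtering** — inclusive depth threshold (≥ 30× in every sample by
  default) and the non-zero rule (≥ 1 methylated read in every sample),
  logged stage by stage.
- **Clustering** — Euclidean distances between samples over methylation
  fractions, d(i,j) = √Σₛ(fₛᵢ − fₛⱼ)², and from-scratch agglomerative
  clustering via the Lance–Williams recurrences with complete, average
  (UPGMA) and WPGMA linkage, with deterministic tie-breaking and leaf order,
  Newick export and cophenetic distances.
- **Dendrogram composition score** — a formalization of "how did the samples
  cluster": counts of exact individual triads, exact same-individual tissue
  pairs, maximal tissue-pure clusters spanning ≥ 2 individuals, and leftover
  outliers (categories partition the samples), plus first-split tissue
  purity and paired-individual counts.
- **Summaries** — duplicate concordance (fraction of sites agreeing within
  10 percentage points), per-sample median / 5th–95th percentile methylation,
  and promoter/exon/intron/intergenic distributions of site sets (promoter =
  2 kb upstream to 500 bp downstream of the TSS, strand-aware).
- **Synthetic methylomes** — a seeded generator producing genomes, sample
  sheets and cytosine reports for a 20-individual × 3-tissue discovery-style
  design (umbilical cord + a cord-blood/peripheral-blood lineage) or a
  duplicate-based validation-style design, with per-context tissue-lineage
  and individual effects on a Beta-distributed baseline and binomial read
  sampling.

## Worked example

Simulate a 10-individual discovery-style study, write it to disk in standard
formats, and run the pipeline on three contexts:

```r
library(noncpg)

cfg <- simulation_config(seed = 1, n_chrom = 1, chrom_length = 60000,
                         design = discovery_design(10))
study <- simulate_study(cfg)
write_study(study, "example_study")

res <- run_pipeline("example_study/genome.fa", "example_study/samples.csv",
                    out_dir = "example_out", contexts = c("CAC", "CAT", "CTC"))
res$stages
res$score_table
res$first_split[["CAC"]]
```

which prints:

```
                                         stage n_sites
1                      depth>=30 in >=1 sample   29949
2                     depth>=30 in all samples   29256
3 non-CpG, non-zero methylation in all samples    5327

  context3 n_sites n_triad_individuals n_pair_individuals n_triad_samples
1      CAC     444                   0                 10               0
2      CAT     360                  10                  0              30
3      CTC     475                   0                  8               0
  n_pair_samples n_tissue_clustered_samples n_outliers
1             20                         10            0
2              0                          0            0
3             16                         12            2

  context3 branch n_samples dominant_tissue purity  pure          composition
1      CAC      1        10  umbilical_cord    1.0  TRUE    umbilical_cord=10
2      CAC      2        20      cord_blood    0.5 FALSE cord_blood=10,peripheral_blood=10
```

Reading it: of 29,256 sites with ≥ 30× depth in all 30 samples, 5,327 non-CpG
sites are methylated in every sample. Clustering the CAC sub-matrix pairs
all 10 individuals' cord-blood + peripheral-blood samples (20 samples in
pairs) and collects the 10 umbilical-cord samples into one tissue-pure
cluster — the root split is 100% umbilical cord on one side. The CAT
sub-matrix instead joins each individual's three tissues into a triad (30
samples in 10 triads). CTC is intermediate: 8 of 10 individuals pair. The
output directory also contains Newick dendrograms, merge tables, the
composition-score tables (TSV/JSON) and per-sample summaries.

A thin command-line wrapper is included at
`inst/scripts/noncpg-pipeline.R`.

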