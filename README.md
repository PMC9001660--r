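# tcrdrive

Antigen-drive analysis of T cell receptor (TCR) repertoires, built for
clonal T cell proliferations such as T cell large granular lymphocytic
leukemia (T-LGLL). The package is for immunogenomics analysts who have
bulk TCRβ rearrangement tables (AIRR-C or immunoSEQ-style exports),
single-cell V(D)J contig tables, or expression matrices, and want to ask:
**does the expanded leukemic clonotype share TCR sequence features with the
patient's non-leukemic repertoire — i.e., does it look antigen-driven?**

## The method

A clonotype is a set of T cells with an identical CDR3 amino-acid
sequence (optionally paired α/β, optionally V-gene qualified). Per
sample:

1. Non-functional clonotypes are removed; the repertoire is rarefied to a
   fixed depth of 30,000 reads without replacement (multivariate
   hypergeometric); shallower samples are excluded.
2. Clonotypes explaining > 5% of the repertoire (or an externally curated
   list) are flagged *leukemic*.
3. Clonotypes are linked into **specificity groups** (GLIPH-style):
   - *local*: a shared k-mer (k ∈ {3,4}) of the trimmed CDR3 core that is
     enriched against a reference repertoire — one-sided Fisher exact
     p < 10⁻³ and fold ≥ 10, counted over distinct CDR3s, support ≥ 2;
   - *global*: equal-length CDR3s with Hamming distance ≤ 1 over trimmed
     cores, significant when the shared pattern passes the same test.
4. A leukemic clone is **antigen-driven** when its group is significant,
   has ≥ 2 distinct TCRs, and contains ≥ 1 non-leukemic partner.

Cohorts are compared with one-sided Fisher exact tests on driven
proportions; clone sizes by drive status with a two-sided Mann-Whitney
test (exact for small groups, including ties). The package also computes
repertoire clonality (Gini index G = Σᵢⱼ|xᵢ−xⱼ|/(2n²μ), Shannon entropy
in bits with Pielou evenness), expansion classes (singleton / expanded
≥ 2 / hyperexpanded ≥ 10), occurrence of query clonotypes across control
cohorts, and gene-set expression scores (expression-matched module score;
geometric-mean bulk score; Welch-t differential expression with
Bonferroni or BH adjustment).

A synthetic-data module generates repertoires, cohorts, reference sets
and expression matrices with planted ground truth (power-law clone sizes,
an immunodominant clone at 7–50%, a planted motif linking it to partner
clones), so the whole pipeline is testable without restricted patient
data.

## Worked example

```r
library(tcrdrive)

cfg <- pipeline_config()                  # 30,000 depth; >5% rule; k {3,4}
ref <- generate_reference_repertoire(10000, seed = 1)

# a synthetic patient-style sample: leukemic clone at 20% of 60,000 reads,
# planted motif shared with 4 non-leukemic partner clones
sim  <- generate_sample_repertoire(leukemic_freq = 0.20, driven = TRUE, seed = 3)
rep  <- sim$repertoire
rep
#> TCR repertoire 'sim_seed3' (synthetic, CD8): 2005 clonotypes, 60000 reads
#>   top clone: CAVNYQRSTYHNYLF (20.0%)

leuk <- identify_leukemic_clones(rep, cfg)
dc   <- classify_drive(rep, ref, leuk, cfg, seed = 11)
dc$calls[, c("leukemic_key", "driven", "n_nonleukemic_partners")]
#>      leukemic_key driven n_nonleukemic_partners
#> 1 CAVNYQRSTYHNYLF   TRUE                      4
```

The call says the 20% leukemic clone sits in a significant specificity
group with 4 distinct non-leukemic clonotypes — the planted antigen-drive
structure, recovered from sequence alone. Diversity metrics for the same
sample:

```r
diversity_record(subsample_repertoire(rep, 30000, seed = 11))
#>   sample_id      gini shannon_bits shannon_normalized n_clonotypes top_clone_frequency
#> 1 sim_seed3 0.6195365      8.71585          0.7946134         2004              0.2009
```

Cohort-scale runs go through `run_drive_analysis()` (list of repertoires
or a sample-manifest TSV), which writes `drive_calls.tsv`,
`cohort_summary.tsv`, `diversity.tsv` and a JSON run manifest. A thin CLI
over the same functions is installed at `inst/scripts/tcrdrive`
(`run`, `simulate`, `diversity`, `scores` subcommands).

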