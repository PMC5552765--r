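# tvinet

Analysis of tissue-infiltrating TCRβ repertoires across the stages of
gastric carcinogenesis — low-grade intraepithelial neoplasia (LGIN),
high-grade intraepithelial neoplasia (HGIN) and early gastric cancer (EGC)
versus matched adjacent mucosa — and network-based discovery of prognostic
gene modules tied to repertoire change.

The package is aimed at immunogenomics analysts who already have
post-alignment clonotype tables (one tab-delimited table per sample with
read count, frequency, CDR3 nucleotide/amino-acid sequence and V/D/J
assignments) plus a normalized expression matrix, and want a reproducible,
tested implementation of the downstream statistics.

## What it computes

**Repertoire descriptives.** TOP-N subsets, cumulative frequency curves,
Shannon–Wiener diversity H = −Σᵢ pᵢ ln pᵢ, and frequency-bin summaries,
where pᵢ is the read frequency of clonotype i.

**Paired overlap and the repertoire variation index.** For a matched
lesion/adjacent pair: the clone overlap ratio (shared unique clonotypes /
lesion unique clonotypes), cumulative frequencies of common clones, and the
TCR repertoire variation index

```
TVI = 2 − F · (1 + C),      TVI ∈ [0, 2]
```

where *F* is the cumulative frequency of lesion-TOP100 clones also found in
the adjacent repertoire (renormalized within the TOP100) and *C* is the
Spearman correlation between the lesion and adjacent frequencies of the
"top common clones" (shared clones ranking in the TOP100 of either sample).
TVI = 0 means identical repertoires; TVI = 2 maximal divergence.

**Expression integration.** A Spearman screen of per-sample TVI against
every gene's expression, two-sided t-approximation p-values, and
Benjamini–Hochberg FDR control, partitioning genes into positively and
negatively TVI-correlated sets.

**Network module detection.** STRING-style edge filtering (text-mining
score > 200 and combined score > 400), co-expression filtering on |ρ|,
largest connected component, a scale-free topology check (R² of the
log–log degree-distribution fit), top-5% degree hubs with their first
neighbours, and k-clique percolation (CPM) communities, selecting the
module at the highest percolating stringency k.

**Survival validation.** Unsupervised two-group hierarchical clustering on
the module signature, Kaplan–Meier curves, and the two-group log-rank test
— all implemented from first principles and cross-checked against the
`survival` package in the test suite.

**Synthetic data.** Generators for every input with known ground truth:
Zipf-distributed clone abundances (TOP100 coverage ≈ 50%), stage presets
whose shared fractions mirror observed stage-wise overlap ratios, planted
TVI-correlated genes, a planted k-clique-chain module, and two-group
exponential survival.

## Worked example

```r
library(tvinet)

pair <- simulate_paired_repertoires(stage_preset("EGC"),
                                    patient_id = "P01", seed = 42)
pair
#> Lesion/adjacent pair 'P01': EGC lesion (15923 clones) vs adjacent (16491 clones)

shannon_diversity(pair$adjacent)
#> Shannon diversity 6.8720 (normalized 0.7077), richness 16491

sum(top_clones(pair$adjacent, 100)$freq)   # TOP100 cumulative frequency
#> [1] 0.508

overlap_ratio(pair)
#> Overlap: 1157 shared clones, ratio 0.0727, common cum. freq 0.2082 (lesion_denominator_lesion_frequencies)

compute_tvi(pair)
#> TVI P01 (EGC): F=0.6295 C=0.3522 n_common_top=109 tvi=1.1488
```

Reading: the adjacent mucosa holds 16,491 distinct clonotypes whose top 100
cover 50.8% of reads (the skewed distribution typical of tissue TCRβ
repertoires). Only 7.3% of the EGC lesion's clonotypes are shared with the
adjacent tissue; 63% of the lesion's TOP100 mass survives in the adjacent
sample and the shared top clones correlate weakly (C = 0.35), giving a high
divergence score TVI = 1.15 — EGC-like pairs score far above LGIN-like ones
(≈ 0.18 on average).

The full pipeline (simulation → repertoire stats → TVI → expression screen
→ network module → survival) runs from one config:

```r
report <- run_pipeline(pipeline_config(seed = 1, outdir = "run1"))
```

or from the command line:

```sh
Rscript -e 'tvinet::pipeline_cli()' run-all --seed 1 --outdir run1
```

Artifacts (clonotype tables, `tvi_table.tsv`, `gene_screen.tsv`,
`network_report.json`, `km_curves.tsv`, `logrank.json`, a full run report)
are written under the output directory; identical config + seed gives
byte-identical tables.

## Documentation

`vignettes/tvinet-methods.Rmd` describes the statistical model, every
tunable threshold with its default and rationale, what the synthetic
generators do and do not emulate, and known limitations.
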