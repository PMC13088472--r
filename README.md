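# vhrep — immunoglobulin heavy-chain repertoire analysis with a synthetic ground truth

`vhrep` is an R package for analysing peripheral B-cell receptor
heavy-chain (VH) repertoires sequenced from sorted B-cell subsets — naive
(N), double-negative (DN), memory (M) and plasmablasts (P) — at a baseline
(BL) and a six-month follow-up (FUP6) timepoint. It is aimed at
immunologists and bioinformaticians who want the complete analysis chain
from UMI-tagged amplicon reads to repertoire statistics to be testable
end-to-end: a seeded synthetic repertoire generator with known ground
truth drives every stage, so no patient data are needed to validate the
pipeline.

## What it computes

* **UMI consensus** — reads filtered at mean Phred ≥ 20; per-UMI
  quality-weighted majority consensus, admitted with ≥ 5 reads and mean
  group mismatch rate ≤ 0.1; identical sequences under different UMIs
  collapse into unique sequences with copy counts.
* **Annotation** — germline V/J calls, junction (conserved Cys …
  conserved Trp/Phe, anchors included), SHM frequency over the aligned V
  region, productivity.
* **Clones** — sequences sharing V gene, J gene and junction length,
  clustered by single linkage on the length-normalized junction Hamming
  distance *d* with cut *d* ≤ 0.1.
* **Diversity** — Hill numbers
  `D_q = (Σᵢ pᵢ^q)^(1/(1−q))` over clone proportions `pᵢ`
  (q = 0 richness, q = 1 `exp(−Σ pᵢ ln pᵢ)`), on bootstrap subsamples of
  n = 126 unique sequences × 200 repetitions (samples with < 100 unique
  sequences excluded); % clones with > 50 members; SHM, V-family and
  isotype usage; bootstrap clonal overlap between timepoints.
* **Proteome matching** — translated VH sequences of both timepoints
  combined into one patient database; tryptic peptides passing the FDR
  cutoff (DDA 0.1, DIA 0.01) mapped exactly; an entry matches when unique
  peptides cover ≥ 30% of its CDR3.
* **Statistics** — paired Wilcoxon signed-rank, Mann-Whitney,
  Kruskal-Wallis + Dunn, Benjamini-Hochberg.

## Worked example

```r
library(vhrep)

cfg <- pipeline_config(seed = 42)
res <- run_pipeline(cfg, out_dir = "demo_out")

subset(res$metrics, cell_subset == "DN" & timepoint == "BL" & metric %in%
       c("diversity_q0", "diversity_q1", "pct_large_clones_gt50", "mean_shm_freq"))
```

```
subject  timepoint  cell_subset  metric                 value
S1       BL         DN           diversity_q0           55.5700000
S1       BL         DN           diversity_q1           36.0306283
S1       BL         DN           pct_large_clones_gt50   0.6944444
S1       BL         DN           mean_shm_freq           0.0293879
```

Read: in the double-negative subset at baseline, a bootstrap draw of 126
unique sequences contains on average 55.6 distinct clones (q = 0); the
size-weighted effective clone number is 36.0 (q = 1), so abundance is
concentrated in expanded clones; 0.69% of clones hold more than 50 unique
sequences; and the mean somatic hypermutation frequency is 2.9% of
V-region sites, recovering the generator's DN rate of 0.03. The whole run
takes about two minutes on one CPU.

```r
res$overlap
```

```
   mean_overlap  sd_overlap n_reps definition_tag subject cell_subset
N   0.011822285 0.007190148    200        jaccard      S1           N
DN  0.005754079 0.006049801    200        jaccard      S1          DN
M   0.004066013 0.006520791    200        jaccard      S1           M
P   0.013856546 0.011088949    200        jaccard      S1           P
```

With the default clone retention of 2% between timepoints, the bootstrap
clonal overlap stays below 2% in every subset — the low-overlap regime in
which the repertoire turns over almost completely between baseline and
six months.

## Layout

```
R/                 implementation (generator, consensus, annotation,
                   clones, metrics, proteome, statistics, I/O, pipeline)
inst/extdata/      packaged toy germline reference (synthetic, FASTA)
tests/testthat/    unit, property and end-to-end acceptance tests
vignettes/         methods vignette: models, parameters, design choices
scripts/           acceptance script
```
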