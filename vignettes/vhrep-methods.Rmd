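---
title: "VH repertoire analysis with vhrep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VH repertoire analysis with vhrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

`vhrep` analyses peripheral B-cell receptor heavy-chain (VH) repertoires
sequenced from sorted B-cell subsets — naive (N), double-negative (DN),
memory (M) and plasmablasts (P) — at two timepoints (baseline BL, six-month
follow-up FUP6). The pipeline is:

1. **UMI consensus** — amplicon reads carry a 6-nt subset index tag and an
   8- or 12-nt unique molecular identifier (UMI). Reads with mean Phred
   below 20 are discarded; reads sharing a UMI are collapsed into a
   consensus sequence, admitted only with at least 5 supporting reads and a
   mean within-group mismatch rate of at most 0.1. Identical consensus
   sequences under different UMIs are *copies* of one unique sequence.
2. **Annotation** — germline V/J assignment by best ungapped identity
   against a packaged reference, junction extraction (conserved Cys through
   conserved Trp/Phe, anchors included), somatic hypermutation (SHM)
   counted as mismatches over the germline-alignable V region, and a
   productivity flag (in-frame, stop-free).
3. **Clone definition** — sequences sharing the IGHV gene, IGHJ gene and
   junction length are clustered by single linkage on the
   length-normalized junction Hamming distance with a 0.1 cut. Single
   linkage at a fixed cut equals connected components of the threshold
   graph; the dendrogram above the cut is never consulted, so we compute
   components directly with union-find.
4. **Metrics** — Hill-number diversity of order q (q = 0 clone richness,
   q = 1 the exponential of Shannon entropy), computed on bootstrap
   subsamples of n = 126 unique sequences with 200 repetitions, with
   samples under 100 unique sequences excluded; percentage of clones with
   more than 50 members (strict inequality); mean SHM frequency; V-family
   and isotype usage fractions over fixed category universes; and
   longitudinal clonal overlap under the same bootstrap scheme.
5. **Proteome matching** — translated VH sequences from both timepoints
   are combined into one patient database; tryptic peptides passing a
   mode-specific FDR cutoff (0.1 for DDA, 0.01 for DIA) are
   exact-substring-mapped; an entry is *matched* when uniquely mapping
   peptides cover at least 30% of its CDR3.
6. **Statistics** — paired Wilcoxon signed-rank for longitudinal contrasts,
   Mann-Whitney for two independent groups, Kruskal-Wallis with Dunn's post
   hoc for multiple groups, Benjamini-Hochberg for the overlap grid.

Every stage is driven and validated by a synthetic repertoire generator
with known ground truth, so the package needs no access to patient data.

## The synthetic generator: what it emulates

The generator draws, per subset, `n_clones` founders by V(D)J
recombination from a packaged toy germline set (ten V segments across
families IGHV1–IGHV5, four J segments), clone sizes from a truncated zeta
(power) law, and clone members as independent SHM draws from each founder.
Defaults encode the standard subset phenotypes: naive cells essentially
unmutated (per-site SHM rate 0.001), IgD/IgM-dominated and diverse
(300 clones, sizes almost all 1–3); DN, memory and plasmablasts
progressively more mutated (0.03 / 0.05 / 0.06), class-switched and
expanded (zeta exponents 2 / 1.8 / 1.5 with size caps 100 / 150 / 200, so
both singletons and >50-member clones occur). V-family sampling defaults
to (0.15, 0.10, 0.35, 0.25, 0.15) over IGHV1–IGHV5, reflecting the usual
dominance of IGHV3/IGHV4 in human repertoires. Longitudinally, each
baseline clone re-seeds the follow-up with probability
`retention_fraction` (default 0.02, the low-overlap regime in which
repertoire turnover between timepoints is nearly complete); retained
clones keep their junction lineage but redraw SHM and size. Reads default
to a Poisson(8) coverage per molecule, per-base substitution error 0.001,
constant Phred 30 with a 5% fraction of Phred-15 reads so the quality
filter is exercised.

Three deliberate simplifications keep the ground truth interpretable:

* **SHM spares the junction** by default. All members of a simulated clone
  then share the founder junction exactly, so the true partition always
  satisfies the 0.1 clustering cut and recovery can be asserted as an
  exact partition identity. Real SHM does hit CDR3; a `mutate_junction`
  flag enables that regime for stress tests, at the cost of an exact
  truth.
* **Founders are kept identifiable.** A fresh founder whose junction lies
  within 0.2 normalized Hamming (twice the clustering cut) of an existing
  same-V/J/length founder is redrawn, otherwise "distinct" true clones
  could merge under single linkage and the true partition would be
  ill-defined.
* **Members are under productive selection.** An SHM draw that introduces
  a stop codon is redrawn, mirroring the biological fact that circulating
  B cells express a productive receptor; without this, heavily mutated
  clones would lose ~40% of members to the productivity filter and clone
  sizes would be systematically distorted relative to the configured law.

The generator does *not* model SHM hotspot motifs, lineage-tree topology,
indels, UMI errors, chimeras or paired light chains. Passing tests
therefore demonstrate correctness of the analysis logic under a clean
substitution-only error model, not robustness to every artefact of real
libraries; the annotation stage in particular assumes ungapped alignment
and will not handle indel-bearing reads (externally annotated AIRR tables
can be supplied instead).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `qmin` | 20 | mean-Phred read admission threshold |
| `min_reads` | 5 | reads per UMI required for a consensus |
| `max_group_error` | 0.1 | mean per-read mismatch rate allowed per UMI group |
| `clone_threshold` | 0.1 | normalized junction Hamming cut for clones |
| `min_unique` | 100 | unique sequences required per analysed sample |
| `subsample_n` / `reps` | 126 / 200 | bootstrap depth and repetitions |
| `large_clone_min` | 50 | strict size threshold for "large" clones |
| `cdr3_match` | 0.30 | CDR3 coverage required for a proteome match |
| FDR cutoffs | 0.1 DDA / 0.01 DIA | peptide q-value admission |

Bootstrap draws are *with replacement*: with an admission floor of 100 and
a depth of 126, admissible samples of 100–125 sequences could not be drawn
without replacement. The sampling unit is the unique sequence, not the
read copy, because all repertoire metrics are defined on unique sequences.

## Numerical and interpretation choices

Several rules in the underlying protocol admit more than one reading; the
choices here are fixed, documented, and where sensible exposed as options:

* **Quality threshold semantics.** "Quality score threshold of 20" is
  applied as a mean-read Phred filter (the FilterSeq-quality convention),
  not per-base trimming.
* **Consensus ties** in the quality-weighted majority vote become `N` and
  are excluded from the group-error computation — deterministic and
  conservative. UMI groups with unequal read lengths are rejected
  (`length_conflict`) rather than aligned, consistent with the
  substitution-only error model.
* **Junction flanks.** The junction is taken as CDR3 plus one conserved
  anchor residue per side (the IMGT junction convention); the alternative
  reading (two residues per side) is not implemented as a default because
  anchors are what the packaged reference defines.
* **Clustering strata.** Within-sample metrics cluster clones per
  (subject, timepoint, subset). Overlap analyses cluster the pooled
  BL+FUP6 sequences per (subject, subset), since a clone must have a
  single identity across timepoints for "shared clones" to be
  well-defined.
* **Overlap denominator.** "Proportion of shared clones" defaults to the
  Jaccard form (shared / union of clones seen in the two draws);
  BL-referenced and mean-directional denominators are available via
  `definition`, and the choice is recorded in the output
  (`definition_tag`).
* **"≥30% identity to the CDR3".** Peptides are exact-matched against the
  patient's own translated sequences, so identity within a mapped peptide
  is always 100%; the only free quantity is positional coverage. The rule
  is therefore implemented as ≥30% coverage of the CDR3 span by uniquely
  mapping peptides. Peptide uniqueness is resolved at the CDR3-group
  level (entries with identical CDR3 strings pooled), because clonally
  related entries share frameworks and sequence-level uniqueness would
  void nearly every peptide. I/L ambiguity is ignored by default
  (`il_equivalent = FALSE`).
* **Exact vs approximate tests.** The longitudinal "paired rank" test is
  the Wilcoxon signed-rank test (the paired test consistent with its
  usage); exact p-values are used for tie-free samples up to n = 25
  (signed-rank) or n_a + n_b = 12 (Mann-Whitney), tie-corrected normal
  approximations without continuity correction otherwise — fixed
  switchovers so results are reproducible. Dunn's post hoc uses
  Bonferroni-style multiplication, the convention of the common
  implementations.
* **Degenerate inputs.** Empty abundance vectors, empty samples and
  all-zero paired differences raise typed errors or return the degenerate
  p = 1 rather than NA; empty repertoires produce empty clone tables.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated data at
deliberately modest scales — tens of clones per subset and hundreds to a
few thousand molecules per run, 200-replicate bootstraps, 1,000-replicate
null calibrations — sizes at which every closed-form expectation and
brute-force oracle is computable while the statistical checks (binomial
99% confidence intervals, 3-standard-error recovery bounds) retain power.
The generator scales to larger repertoires by setting `n_clones` and the
size laws.

## Known limitations

* Germline assignment is ungapped best-identity against a small synthetic
  reference; it is a stand-in for full IgBLAST/IMGT annotation and not
  suitable for real reads with indels or novel alleles.
* The translation table is the standard genetic code only.
* Isotype is taken from the library annotation (primer-derived), not from
  constant-region alignment; conflicting isotypes among copies of one
  unique sequence resolve to the most frequent.
* D-segment calling, allele-level genotyping, lineage trees,
  Chao/rarefaction estimators and physicochemical CDR3 properties are out
  of scope.
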