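---
title: "Consensus-phenotype inter-omic pathway analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-phenotype inter-omic pathway analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusOR)
```

This vignette is the package's account of the statistical machinery: what
each stage assumes, which parameters matter, how the synthetic generator is
built and what its tests do and do not demonstrate about real panel data.

## The pipeline

The analysis treats a drug-sensitivity screen as three layers:

1. **Feature association.** Each measured feature (probeset or metabolite)
   is correlated with a drug's per-sample −log(GI50) by the Pearson
   coefficient over pairwise-complete observations; significance comes from
   the usual t transform, $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
   freedom, two-sided. Features are selected at a Benjamini–Hochberg FDR of
   `fdr_q = 0.60`. Sixty percent is intentionally permissive: the object of
   inference is the pathway, not the feature, and over-representation tests
   lose power rapidly when panels shrink toward zero. Each selected feature
   carries the sign of its correlation for the later direction-consistency
   checks.

2. **Pathway over-representation.** For a panel of size $K$ drawn from a
   measured background of size $m$, the count $k$ of panel members inside a
   pathway of effective size $N$ is scored by the hypergeometric upper tail
   $P(X \ge k)$, inclusive of the observed count — the standard
   over-representation convention. The *effective size* is what makes the
   two namespaces commensurate: pathway proteins are expanded through an ID
   map to the probesets actually measured (a protein with several measured
   probesets contributes all of them, as a set union across the pathway so a
   shared probe counts once; an unmappable protein contributes nothing), and
   currency metabolites — ubiquitous compounds that occur in many pathways
   without conferring specificity, by default phosphate, diphosphate and
   NADP+ — are removed both from pathways and from the metabolite
   background. Backgrounds are the full measured feature lists supplied by
   the user, not only pathway-annotated features; the choice is recorded in
   the run manifest.

3. **Inter-omic combination and consensus.** The gene and metabolite
   pathway p-values combine as the plain product $p_J = p_G\,p_M$, with
   $p = 1$ for a namespace with nothing measured. The product rests on an
   independence assumption justified by the separate measurement platforms.
   A product of two uniforms is *not* uniform, so $p_J$ is not a calibrated
   p-value; `combine_joint(method = "fisher")` provides the calibrated
   chi-squared combination of the same two values for comparison, but the
   product is the default because it is the quantity the downstream
   consensus counts are built on. Significance is strict: $p < 0.05$, with
   values exactly at the threshold excluded. No multiple-testing correction
   is applied across pathways at this stage — deliberately, since the
   consensus step and the null models, not a per-pathway correction, carry
   the error control. A pathway enters the consensus set when it is
   significant for at least `floor(D/2) + 1` of the $D$ class drugs (3 of 4
   by default).

## Null models and the permutation test

**Null model I** replaces each drug's panels with uniform draws of matched
size from the backgrounds and reruns the *entire* joint pipeline per
replicate (default $R = 100$); it is therefore a null of the joint
analysis, and its replicate-level counts expose Monte-Carlo error.
**Null model II** assumes each drug selects its observed number $S_d$ of
pathways uniformly from the $M$ eligible pathways, so the per-pathway count
of selecting drugs is Poisson-binomial with $q_d = S_d/M$; the package
computes it exactly by polynomial convolution. $M$ defaults to the pathways
with at least one measured entity in either namespace (`eligible_universe()`),
configurable.

Cumulative FDR at threshold $n$ is
$100\cdot\sum_{j\ge n} E_j / \sum_{j\ge n} O_j$, reported to one decimal
(ties rounded away from zero) and capped at 100; a threshold with zero
observed cumulative count is undefined and reported missing. Applied to the
published four-platinum consensus table's printed inputs this reproduces
36.4% (model I, $n\ge1$), 0.2% ($n\ge3$) and 40.7% (model II, $n\ge2$)
exactly. Two printed entries are not derivable from the table's own rounded
inputs — model I at $n\ge2$ evaluates to 3.1% against a printed 3.2%, and
model II at $n\ge3$ to 17.0% against a printed 16.9% — presumably because
the original arithmetic used unrounded expectations. The package reports
its computed values and makes no attempt to guess the unrounded inputs.

The **permutation test** for the joint-analysis gain shuffles the
metabolite p-value list across pathways (default $P = 100$), recomputes the
joint significant count, and reports the number of permutations *strictly*
exceeding the real count, with the empirical p as `exceedance / P` to match
how such results are conventionally phrased; the $(x+1)/(P+1)$ corrected
variant is also returned.

## The synthetic panel generator

The generator emulates the *shape* of an NCI60-style study — 58 samples,
154 metabolites (three of them currency compounds, so 151 remain in the
background), 2000 probesets partitioned among proteins in blocks of 1–3
(exercising probe expansion), 200 pathways of mixed namespace composition,
and one class of 4 drugs — not the distributional detail of real
abundances. The signal model is additive Gaussian: each class has a latent
per-sample sensitivity $L$; drugs observe $L + 0.5\,\varepsilon$; a planted
feature is $\rho L + \eta$ with unit noise, giving feature–latent
correlation $\rho/\sqrt{1+\rho^2}$ (checked empirically at $n = 500$).
Gaussianity suffices because the pipeline consumes only correlations and
set memberships.

Planted labels: *gene-signal* and *metabolite-signal* pathways load 60% of
their measured members in one namespace at $\rho = 0.5$; *split-signal*
pathways load both namespaces weakly. The split loadings are calibrated at
generation time by a pilot simulation — one loading **per namespace**,
because pathway gene membership (tens of probesets) yields far more
powerful enrichment than metabolite membership (a few compounds), and no
single shared loading can put both sides of the same pathway into the
target band. The pilot scans a grid and picks the loading whose median
split-pathway enrichment p is nearest 0.12, the geometric centre of
$(0.05, 0.3)$: single-omic evidence unremarkable, joint product below 0.05.
Calibrated loadings are recorded in the truth table. Split pathways are
drawn from those with at least 15 measured probes and 5 measured
metabolites so their p-values are stable enough to calibrate.

What the generator does **not** emulate: tissue-of-origin structure,
probe-level noise models, replicate counts of GI50 assays, heavy-tailed or
compositional abundance distributions, and realistic pathway overlap
topology (membership is sampled independently per pathway, though overlaps
do occur and are the hard case for over-representation). Passing tests on
synthetic data therefore demonstrate the pipeline's *statistical logic* —
selection, counting, combination, null calibration — not robustness to
real-data artefacts.

A consequence worth stating: drugs of one class share a latent, so a
feature that correlates with the latent by chance is selected *coherently*
across drugs. Chance consensus in such data exceeds what null model I
(independent panels per drug) predicts whenever feature panels are
non-trivial, exactly the regime the cumulative-FDR machinery is there to
flag. With no planted signal the panels are essentially empty and both
observed and expected consensus vanish — the package's null-calibration
test checks that agreement. Under the calibrated band the joint product
sits only a few-fold below the 0.05 threshold, and realised pathway
strength varies more than that between pathways (and is shared across the
correlated drugs), so a *fraction* of each seed's split pathways — rather
than all of them — is recovered by the joint analysis exclusively; the
recovery test asserts the event (at least one joint-exclusive split
recovery) in a majority of seeds and a positive mean fraction.

## Numerical and interface choices

- **Rounding** of reported percentages is half-away-from-zero
  (`round_half_up()`), matching how the published figures (43%, 31%, 23%,
  +76%) fall out of their printed numerators and denominators; base R's
  banker's rounding would differ at exact halves.
- **p-value floors**: correlation p-values and hypergeometric tails are
  floored at the smallest positive double so that joint products never hit
  exact zero; $|r| = 1$ therefore yields the floor, not 0.
- **Degenerate inputs**: zero-variance features and features with fewer
  than 3 complete pairs are flagged and excluded from selection (never
  assigned $r = 0$); empty panels give all-ones enrichment; an empty
  overlap union is defined as 0% with a warning; a zero single-omic
  consensus base makes the gain percentage undefined (NA), not infinite.
- **Clustering** of the drug × pathway binary matrix uses complete linkage
  on Hamming distances normalised by column count after dropping pathways
  associated with no drug (the unnormalised count is an option). The
  agglomeration is implemented in-package with a documented deterministic
  tie-break — among minimum-distance pairs, the lowest positions in the
  current cluster list merge first, the merged cluster inheriting the
  earlier position — so merge order and leaf order are reproducible;
  `stats::hclust` agrees on tie-free distances and serves as a
  cross-check. Drugs with no significant pathway are excluded from
  clustering but reported.
- **BH selection** is `stats::p.adjust(method = "BH") <= q`, verified
  against the exhaustive maximal-rank step-up definition in tests. The
  selection reading (BH on two-sided p-values rather than a raw
  $|r|$-ranked cut) is the documented interpretation of the procedure.
- **Seeds**: every stochastic routine (generation, null model I,
  permutations, pilot calibration) derives a stream-specific 31-bit seed
  from the master seed, saves and restores the caller's RNG state, and
  records seed and replicate counts in its report, so any reported number
  is reproducible from the manifest alone.
- **File dialects**: matrices and phenotypes are TSV with an ID column and
  sample-ID header; pathway membership is standard GMT, one file per
  namespace joined on pathway ID (a pathway absent from one file has empty
  membership there); ID maps are two-column TSVs; measured-feature lists
  are one ID per line. The staged runner `run_pipeline()` is re-entrant
  over these files and writes a JSON manifest with MD5 checksums.

## Problem sizes used in the test suite

Structural tests run a reduced panel (40 samples, 400 probesets, 60
metabolites, 60 pathways). The calibration, recovery and null-calibration
studies use the full default configuration (58 samples, 2000 probesets,
154 metabolites, 200 pathways) over 20 and 12 seeds respectively; oracle
sweeps cover every hypergeometric urn with $m \le 25$, step-up lists up to
length 20, Poisson-binomial enumeration up to 5 drugs with $10^5$
Monte-Carlo draws, and naive-oracle clustering on random 8 × 12 matrices.
These sizes were chosen so each property is exercised well past its edge
cases while the whole suite stays interactive.

## Known limitations

- The joint product is conservative as a p-value yet can be
  anti-conservative as a selection statistic relative to a calibrated
  combination; consumers who need calibrated joint p-values should use the
  Fisher option and recalibrate thresholds accordingly.
- Null model II's uniform-selection assumption ignores pathway size:
  large pathways are more often selected in real data, so model II is the
  more extreme null and its FDRs the more pessimistic.
- Consensus counting treats drugs symmetrically; unequal replicate quality
  or potency ranges across a class are not modelled.
- The pipeline performs no identifier translation beyond the supplied
  maps and no retrieval from pathway web services; the database is
  whatever GMT files the user provides.
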