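---
title: "Intragenic codon usage bias and local folding landscapes with cubscape"
author: "cubscape maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intragenic codon usage bias and local folding landscapes with cubscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubscape)
```

# The problem

Synonymous codons are not used at equal frequency, and the bias varies
*within* a gene as well as between genes. In gene families, domain-wise
differences in codon usage — a rare-codon "ramp" in the first tens of
codons, a GC3-elevated amino-terminal domain, stronger- or
weaker-than-predicted mRNA secondary structure near the start codon — are
candidate mechanisms for differential expression of otherwise similar
paralogs. cubscape computes the standard descriptive statistics of this
intragenic codon landscape, domain by domain, for a cohort of homologous
coding sequences from many species, each judged against its own species'
codon usage table:

* the effective number of codons (Nc), per domain, and the percent
  difference of each domain's Nc against its whole gene;
* the Codon Adaptation Index (CAI) with an expected-CAI (eCAI) null, and
  the CAI-vs-eCAI percent difference, including a first-ten-codon analysis;
* GC3% and GC%, again normalized against the whole gene to control for
  isochore-scale composition;
* sliding-window local folding energy differences (deltaLFE) between the
  native mRNA and synonymous-codon permutations of it, with x-intercepts
  and a ramp length per sequence;
* synonymous / missense abundance summaries for coding variant lists.

Everything runs on synthetic multi-species homolog sets produced by the
package's own generator, so the full analysis is testable end to end
without any database access.

# Models and estimators

## Effective number of codons

`effectiveCodonNumber()` implements Wright's estimator. For amino acid
$a$ with degeneracy $k \ge 2$, observed $n_a \ge 2$ times with synonymous
proportions $p_i$, the codon homozygosity is

$$\hat F_a = \frac{n_a \sum_i p_i^2 - 1}{n_a - 1},$$

and with $\bar F_k$ the mean over the degeneracy-$k$ class and $N_k$ the
number of degeneracy-$k$ amino acids observed,

$$N_c = N_1 + \frac{N_2}{\bar F_2} + \frac{N_3}{\bar F_3} +
        \frac{N_4}{\bar F_4} + \frac{N_6}{\bar F_6}.$$

Nc runs from 20 (one codon per amino acid — maximal bias) to 61 (uniform
usage of all sense codons). Numerical conventions, all flagged in output
where they fire:

* $\hat F_a \le 0$ (possible at small $n_a$) is treated as missing for
  that family rather than entering the class mean;
* if Ile (the only 3-fold amino acid) yields no valid $\hat F$,
  $\bar F_3 = (\bar F_2 + \bar F_4)/2$ is substituted;
* if a degeneracy class has observed amino acids but no valid $\hat F$ at
  all, those amino acids are omitted from the sum with a warning (this
  only happens in very short regions);
* because the finite-sample correction can push the estimate above the
  theoretical maximum, the result is truncated at 61 and the truncation
  is recorded in an attribute;
* a sequence with no degenerate family at $n_a \ge 2$ has no defined Nc
  and is reported as missing, never as zero.

A pseudocounted variant (`variant = "ncw"`, with
$p_i = (n_i + 1)/(n_a + k)$ and $\hat F_a = \sum_i p_i^2$) reproduces the
weighted flavour of Nc used by the CAIcal web service; Wright's form is
the default because it is the verifiable reference against hand
computation. Sequences with Nc $\le$ 35 are flagged as possessing codon
usage bias (`classifyCUB()`, cutoff adjustable).

## CAI and its expected value

Relative adaptiveness weights are $w_c = f_c / \max_{c'} f_{c'}$ within
each synonymous family, from the species' per-thousand codon frequencies;
codons with zero reference frequency receive a pseudo-frequency of 0.5
(per-thousand units) so CAI is always defined. CAI is the geometric mean
of $w_c$ over a region's codons, excluding ATG, TGG and stop codons,
which carry no synonymous choice.

A raw CAI is not interpretable across regions of different amino-acid and
GC composition, so `expectedCAI()` builds the null: `nReplicates`
(default 500) random synonymous sequences of the same protein, each
residue's codon drawn from $q_c \propto \theta^{gc(c)}$, with the tilt
$\theta$ calibrated by bisection (tolerance $10^{-6}$) so the expected
replicate GC equals the query's GC. When the query GC is outside the
achievable synonymous range the tilt is clamped to the bracket end with a
warning. eCAI is the one-sided upper normal tolerance bound $m + k s$
covering 90% of the replicate CAI distribution with 90% confidence (both
defaults; $k$ from the noncentral-$t$ factor, stable to at least four
decimals at $n = 500$), clamped at CAI's own upper bound of 1. The
replicate generator is an interpretation of "random synonymous sequences
of similar GC content": it reproduces the tolerance-interval semantics,
not any particular server's sampling scheme bit for bit.

The sign of `percentDifference(cai, ecai)` is the readout: positive means
more frequently used codons than expected, negative means rare codons.
The same percent difference, $100\,(x_{domain} - x_{whole})/x_{whole}$,
normalizes Nc, GC3% and GC% against the whole gene.

## deltaLFE profiles

mRNA folds locally and cotranscriptionally; a 40-nt window slid in 10-nt
steps (both adjustable) mimics that. For each window, `deltaLFEProfile()`
computes the native minimum folding energy minus the mean energy of the
same window taken from 20 whole-sequence synonymous-codon permutations —
shuffles among positions encoding the same amino acid, which preserve the
protein and the codon multiset exactly. Negative deltaLFE means stronger
than predicted structure. Conventions:

* windows are anchored at their start coordinate (0-based nt from the CDS
  start), matching a "distance from CDS start" axis and keeping the ramp
  definition simple;
* permutations are whole-sequence shuffles evaluated per window, not
  per-window shuffles, so long-range codon exchanges contribute;
* no partial tail window is emitted — fixed-width windows keep native and
  permuted energies commensurate — and the profile covers the entire CDS
  rather than a fixed 5' prefix;
* windows containing an ambiguous base are reported missing and excluded
  from aggregation rather than imputed;
* x-intercepts are found by linear interpolation between consecutive
  window anchors, with exact zeros reported at their window start;
* the ramp length is the length in codons of the 5' prefix with
  deltaLFE > 0 (weaker than predicted structure):
  `floor(x/3)` at the first downward crossing $x$, 0 if the profile
  starts at or below zero, and the full profile length in codons if it
  never crosses.

The default folding backend is a built-in nested-structure dynamic
program (pairs GC/AU/GU scored 3/2/1, minimum hairpin loop of three
unpaired bases, no pseudoknots), chosen because it is exactly testable
against exhaustive enumeration and adds no external dependency; its
energies are in arbitrary units. An `RNAfold` (ViennaRNA) backend is
provided behind the same contract for thermodynamic energies in
kcal/mol. Absolute window energies are backend-dependent; the sign and
zero structure of deltaLFE is the portable quantity, which is why
x-intercepts and ramp lengths, not raw energies, are the cross-backend
outputs. Cross-species aggregation is the unweighted mean per window
start over the species possessing that window (medians are available in
the metrics summary), with per-position species counts retained.

# The synthetic cohort

`generateHomologSet()` draws one protein and emits one CDS per species,
each residue's codon sampled per the region's bias profile against that
species' own usage table (`makeCodonTable()`: Dirichlet-style family
draws, concentration $1/(1+\mathrm{skew})$, skew 0 giving the exactly
uniform table; default skew 2 gives moderately biased, species-distinct
tables). Sampling rules: *frequent* draws the most-adapted codon with
probability 0.9 and the rest uniformly; *rare* draws inversely
proportional to weight; *gc3_tilted* tilts the third position with a
bisection-calibrated $\theta$ to hit a target GC3. A designed hairpin —
codon-aligned `(GGC)^k (AAA)^m (GCC)^k`, whose arms are exact reverse
complements — can be planted near the 5' end; it is shared across species
and is broken by synonymous permutation whenever the rest of the gene
codes Gly/Ala with other codons, which is what makes native deltaLFE
negative over it.

The cohort emulates the statistical structure the analysis assumes — one
shared protein, species-specific usage, region-wise contrasts — and
deliberately not amino-acid divergence, phylogenetic correlation between
species, splice-variant structure, or real vertebrate usage tables.
Passing tests therefore demonstrate that the estimators recover planted
synonymous-level signal; they do not validate conclusions about any real
gene family.

The packaged study-scale preset (`writeB56LikePreset()`) writes five
genes over a 28-species cohort (the cohort size of the motivating
analyses) at 500 codons: one gene with a 5' hairpin plus GC3-elevated
N-terminal domain, one with a rare-codon first-ten ramp, one all-frequent,
one uniform, one GC3-depleted N-terminus, plus per-species Kazusa-format
tables, a three-domain partition (N-terminus / core / C-terminus), a
variant list, and a ready-to-run config.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window`, `step` | 40 nt, 10 nt | local folding window and stride |
| `nPermutations` | 20 | synonymous permutations per profile |
| `ecaiReplicates` | 500 | random synonymous sequences per eCAI |
| `population`, `confidence` | 0.90, 0.90 | eCAI tolerance-interval levels |
| `firstN` | 10 | 5' prefix analysed separately |
| `cubCutoff` | 35 | Nc at or below flags CUB |
| `maxGapRun` | 60 | alignment rows with a gap run this long are excluded |
| `seed` | 20231227 | every stochastic step takes an explicit seed |

Domain boundaries are user input: they are biological knowledge about a
family, not something inferable from a single CDS, so the partition is an
explicit YAML file (0-based, half-open codon coordinates everywhere;
nucleotide coordinates appear only inside the folding module). The
terminal stop codon is stripped before every metric, and codons
containing N are excluded from counts and folding windows.

# Design choices and open points

* **Per-species metrics, then unweighted mean.** Whether cross-species
  figures should average per-species metrics or compute metrics of
  concatenated sequences is genuinely open; cubscape computes per-species
  values and summarizes with the unweighted mean (medians reported
  alongside), which keeps every row traceable to one (gene, species,
  region) triple.
* **GC3 excludes stop codons.** The alternative (including them) changes
  values negligibly for real genes but makes the GC3-of-third-positions
  identity with GC% fail; exclusion keeps the two metrics consistent.
* **No significance machinery.** The analysis is descriptive percent
  differences by design; no tests, no multiple-testing correction.
* **Problem sizes in the test suite.** The suite exercises the full
  preset (5 genes × 28 species × 500 codons) once for the end-to-end and
  determinism checks, and uses 100-seed batches of 300-codon
  single-species sets for the parameter-recovery properties; these sizes
  give stable pass/fail behaviour for the planted effects while keeping a
  complete run in the minutes range on one core.

# A worked example

```{r example, eval = FALSE}
dir <- tempfile("b56like-")
cfg <- writeB56LikePreset(dir, nSpecies = 28, proteinLen = 500)
res <- runCub(cfg)     # metrics.tsv, metrics_means.tsv
lfe <- runLfe(cfg)     # lfe_profiles.tsv, lfe_intercepts.tsv, lfe_aggregate.tsv

subset(res$means, region == "first_10", c(gene, cai, ecai, cai_vs_ecai_pct))
plot(lfe$aggregates$alphaLike)
```

# Limitations

The built-in energy model ranks structures by weighted base-pair count;
it has no stacking, dangles or temperature, so its energies are not
kcal/mol and ramp-length estimates near zero deltaLFE are sensitive to
the backend. eCAI assumes the replicate CAI distribution is approximately
normal for the tolerance bound; at very short regions (a few codons) the
bound is conservative. Nc on regions of a few dozen codons is noisy and
is reported missing rather than guessed when families are too sparse —
the motivating analyses themselves treat ~30-codon domains with caution.
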