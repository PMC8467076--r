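---
title: "Analysing EMS mutagenesis screens with emscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing EMS mutagenesis screens with emscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emscreen)
```

## The screen this package analyses

Ethyl methanesulfonate (EMS) is an alkylating mutagen that produces almost
exclusively G:C→A:T transition mutations. In a forward-genetics screen, a
haploid bacterial reporter strain is mutagenised, colonies with a
dysregulated reporter phenotype are isolated, and the genomes of the
selected mutants are sequenced and variant-called against the parental
reference. Because each selected mutant carries only a handful of point
mutations (the mutagen dose is tuned to roughly one stable transition per
3 × 10^5 bp), causative loci reveal themselves as *clusters*: genomic
regions mutated independently in many selected mutants, far more often than
the background rate allows.

`emscreen` implements the computational side of such a screen:

1. **Input** — per-mutant variant tables (Snippy-style TSV or VCF) merged
   into one *mutant set* against a single reference.
2. **Spectrum** — transition/transversion classification, the G:C→A:T
   signature fraction, per-mutant burden, and the mutagenesis-efficiency
   fold change from resistance plating.
3. **Hotspots** — a proximity-weighted sliding-window clustering score,
   single-linkage cluster calling, ranking, and gene/intergenic annotation.
4. **Effects** — strand-aware codon changes and amino-acid substitution
   labels.
5. **Assays** — four-parameter-logistic (4PL) reporter kinetics with
   maximal-slope extraction, genetic-linkage filtering, and transformation
   frequencies with detection-limit semantics.
6. **Simulation** — a generator for every input the pipeline consumes, so
   the whole analysis is testable without external data.

The package also ships the curated main-cluster SNP tables of a published
*Micrococcus luteus* trpE16 screen (21 positions across 22 M-mutants with
up-regulated *com* promoter activity; 25 positions across R-mutants with
repressed activity) as plain-text fixtures, loadable with
`load_screen_fixture()`.

## The clustering score

The core statistic is the window score. A window of length $W$ (default
5000 bp) slides along the genome in steps of $s$ (default 500 bp). Within a
window, every (mutant, position) pair is one *occurrence*; with occurrences
at sorted positions $q_1 \le \dots \le q_k$ the score is

$$\mathrm{score} = \sum_{i<j} \left(1 - \frac{|q_i - q_j|}{W}\right).$$

This is the simplest statistic with the two properties a hotspot score
needs: it strictly increases when an occurrence is added, and at fixed
count it strictly increases as the occurrences pack more tightly. Two
windows holding the same number of SNPs therefore score differently when
their spacings differ. A window with at most one occurrence scores zero —
a lone SNP is never evidence of clustering. The score is computed in
$O(k)$ per window from the sorted prefix sums, and an exponential-decay
kernel $\sum_{i<j} e^{-|q_i-q_j|/\lambda}$ is available via the `kernel`
argument for sensitivity analysis.

**Occurrence weighting.** By default a position mutated in ten mutants
contributes ten occurrences, because independent recurrence is exactly the
signal a selection screen produces. A `"unique"` mode counting distinct
positions once is provided for comparison.

**Terminal window.** The last window may be shorter than $W$; it is scored
with the same $W$ in the denominator so scores stay comparable across the
track.

## Cluster calling and ranking

Cluster membership is deliberately decoupled from the score. Distinct
mutated positions are grouped by single linkage: two positions share a
cluster when their gap is at most `max_gap` (default $W$). This partitions
the positions — every position belongs to exactly one cluster, and clusters
are separated by gaps larger than `max_gap`. A density threshold would
silently discard single-SNP entries, which in a small screen can still be
the causative locus; instead, *every* position is assigned and the score
only ranks. Clusters are ordered by the peak window score overlapping them,
with ties broken by occurrence count and then by leftmost start.

```{r clusters}
m <- load_screen_fixture("M")
clusters <- call_clusters(m, max_gap = 5000, W = 5000)
clusters
```

The top-ranked cluster of the packaged M-mutant screen contains six
positions within 504 bp — the promoter region between a pilus-assembly gene
and a small DNA-binding-protein gene, recovered purely from position
geometry (the curated tables' own cluster labels are carried only as
provenance and never read by the algorithm; the tests verify that the
algorithmic partition reproduces them exactly).

Annotation labels every member position with the enclosing gene or with
`intergenic(left,right)`:

```{r annotate}
genes <- gene_models(c("Mlut_14650", "Mlut_14660"),
                     c(1605900, 1607150), c(1607000, 1607500), c("-", "+"))
annotate_clusters(clusters, genes)[1, c("start", "end", "n_genic", "n_intergenic")]
```

## Mutation spectrum and mutagenesis efficiency

`classify_substitution()` calls transitions ({A,G} or {C,T} exchanges) and
the EMS signature (G→A or C→T *on the reference strand* — both readings of
G:C→A:T, so the classification is invariant under complementing both
bases). `summarize_spectrum()` reports raw counts: whether a screen's
published per-genome burden refers to pre- or post-filter calls is often
ambiguous, so the summary makes no filtering of its own, and the
per-mutant burden uses the arithmetic mean by default (median optional).

```{r spectrum}
summarize_spectrum(m)
```

Mutagenesis efficiency is the ratio of resistant-colony frequencies in
treated versus untreated cultures. An untreated control with zero resistant
colonies yields a *lower bound* (at the one-colony detection limit), never
an infinite fold change:

```{r efficiency}
mutagenesis_efficiency(2.8e3, 3, 1e8)
```

## Strand-aware codon changes

`codon_change()` walks from genomic to coding coordinates: for a `+` gene
the coding offset is `position - start`; for a `-` gene it is
`end - position` and the coding base is the complement of the
reference-strand base. Translation uses the bacterial genetic code
(table 11); the alternative initiators GTG and TTG — frequent in
actinobacterial CDSs — are rendered as M at codon 1 only. The reference
base is verified against the genome and a mismatch is an error, never a
silent correction. Substitution labels use the compact `X<index>Y` field
convention (`parse_label()`, `residue_distance()`).

The package follows this one convention consistently; labels published
from other pipelines with different strand bookkeeping may disagree for
`-`-strand genes, and no attempt is made to reproduce any particular
external label. Overlapping genes are annotated against all hits with the
first-by-start gene primary (with a warning). Positions inside no gene are
labelled intergenic only — assigning 5′UTRs would require an experimentally
determined TSS table, which is outside this package's scope.

## Reporter kinetics

Reporter output is measured as fluorescence kinetics (default grid: every
10 min over 10 h, 61 points). `fit_4pl()` fits

$$F(t) = d + \frac{a - d}{1 + (t/c)^b}$$

by Levenberg–Marquardt least squares with data-driven starts
($a_0 = \min$, $d_0 = \max$, $c_0$ = half-range crossing time, $b_0 = 1$)
and flags non-convergence (relative RSS change $< 10^{-10}$, 500
iterations) instead of raising. Background (mean of no-cell and
no-substrate controls) is subtracted pointwise before fitting, flooring at
zero (`subtract_background()`).

The promoter-activity readout is the steepest slope of the fitted curve.
Substituting $u = (t/c)^b$ into the derivative shows $|F'|$ is maximal at
$u^* = (b-1)/(b+1)$, i.e. in closed form at
$t^* = c\,((b-1)/(b+1))^{1/b}$ for $b > 1$; for $b \le 1$ the supremum lies
at $t \to 0^+$ and the slope is evaluated at the start of the observed time
range instead (`max_slope()`). `relative_activity()` averages per-replicate
maxima and flags strains strictly below half the reference activity — the
boundary is strict ("less than half"), so exactly 0.5 is kept. Group
comparisons use the classical pooled-variance two-tailed t-test (Welch as
option).

## Linkage and transformation frequency

The linkage degree divides mutant-phenotype colonies by reporter-phenotype
colonies, as the assay is conventionally scored; this can exceed 100%, and
a `"total"`-denominator mode is exposed for users who prefer a bounded
fraction. The screening filter keeps strains strictly below 3% linkage;
undefined degrees (zero denominator) are never kept.

Transformation frequency is transformant CFU/mL over viable CFU/mL, both
volume- and dilution-corrected, in exact rational arithmetic on the integer
counts. The detection limit is the spontaneous-reversion frequency from the
no-DNA control (with zero revertants read as "< 1 colony"). Zero-transformant
reactions are *censored* — reported as `< detection_limit` and excluded
from the across-strain ANOVA rather than imputed, because a censored bound
carries no usable magnitude. The omnibus test is an ordinary fixed-effects
one-way ANOVA on log10 frequencies; no post-hoc procedure is implemented.

## What the simulator does and does not emulate

`sim_config()` defaults encode the study conditions: a 2.5 Mb chromosome at
GC fraction 0.73, 22 mutants, background mutation counts
Binomial($L$, $1/(3\times10^5)$) per mutant (mean ≈ 8.3 SNPs/genome), and a
95% G:C→A:T spectrum with signature mutations placed only at G/C sites.
Hotspots are planted as intervals each mutant hits independently with a
configured probability, the hit landing uniformly on a G/C site within the
interval — phenotypic selection is represented by this elevated hit
probability, not modelled mechanistically. Plate counts follow the standard
Poisson plating model; kinetic curves are the 4PL truth plus i.i.d.
Gaussian noise. All generators are deterministic under `seed`.

The simulator does **not** emulate sequencing or variant-calling error,
mutation context effects beyond G/C targeting, selection-induced linkage
between background mutations, or replicate-level correlation in the assays.
Passing tests on simulated data therefore demonstrate the *algorithms*
recover what the generative model plants, not that real screens are free of
those complications.

## Numerical choices and test problem sizes

* Window scores use exact prefix-sum arithmetic; ties in cluster ranking
  break by occurrence count then leftmost start, so output order is total
  and reproducible.
* Circular chromosomes are treated as linear; a hotspot spanning the origin
  would be split in two. This matches how screen data are usually plotted
  and is a documented limitation.
* The recovery power analysis uses 200 simulated screens at the default
  study conditions with a 550 bp hotspot hit by 60% of mutants per screen;
  the planted interval is the top-ranked cluster in ≥ 95% of runs (in
  practice 100%).
* 4PL recovery is checked on a noiseless curve (relative error < 10⁻⁶ per
  parameter) and at 25 RFU noise on a 4950 RFU amplitude over 100
  replicates. Asymptote errors are judged on the amplitude scale — with
  25 RFU noise, no estimator can pin a 50 RFU baseline to 5% of *itself*,
  and the amplitude is the scale on which the asymptotes act.
* The analytic maximal slope is verified against two-stage dense-grid
  numeric maximization on hundreds of random parameter sets
  (relative error ≤ 10⁻⁵ demanded, ~10⁻¹⁰ observed).
* One record of the packaged R-mutant table is printed in its source
  without an explicit alternate allele; it is transcribed as the C→T
  transition its annotation implies.

## Limitations

No statistical significance is attached to clusters — the screen design
ranks by score and validates candidates experimentally, and a calibrated
null would require the full (unpublished) per-mutant call sets rather than
curated cluster tables. Mixed-effects modelling of technical versus
biological kinetic replicates, instrument raw-file parsing, RNA-structure
or RBS-strength prediction, and read-level simulation are all out of scope.
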