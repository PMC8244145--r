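---
title: "Calling XCI status from allelic expression, DNA methylation and chromatin marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling XCI status from allelic expression, DNA methylation and chromatin marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcistate)
```

# The biological setting

X-chromosome inactivation (XCI) silences one X in XX cells, but many genes
keep expressing from the inactive X (Xi) — constitutively ("escape") or in
only some samples, tissues or transcription start sites ("variable
escape"). `xcistate` calls XCI status per gene per sample by three
independent routes — allelic expression, promoter CpG-island DNA
methylation (DNAme), and a multi-mark ensemble predictor — reconciles them,
and tests for genetic association with variable escape. This vignette is
the package's account of the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

# The allelic-expression model

In a sample with fully skewed XCI the same parental X is inactive in every
cell, so reads over a heterozygous exonic SNP split into Xi and Xa counts.
We model the Xi read count as binomial with proportion
$p = \mathrm{Xi}/(\mathrm{Xi}+\mathrm{Xa})$ and form the Wald interval

$$\hat p \pm z \sqrt{\frac{\hat p (1-\hat p)}{\mathrm{Xi}+\mathrm{Xa}}},
\qquad z = 1.96.$$

A gene escapes when the whole interval lies above
$p^\* = r/(1+r)$ with $r = 0.10$ — the conventional "at least 10%
expression from the Xi relative to the Xa" — is subject when the interval
lies below, and is otherwise **uninformative**: a call is made only when
the 95% CI resolves the threshold, never from the point estimate alone.
Numerical notes:

* The threshold is a **ratio** (Xi/Xa = 0.10) converted to the proportion
  scale ($p^\* = 1/11 \approx 0.0909$); the binomial variance with
  denominator Xi+Xa is only well defined on the proportion scale.
* At $\hat p \in \{0, 1\}$ the Wald half-width is zero, so boundary counts
  are called directly from $\hat p$. No continuity correction is applied.
* `min_total_reads` (default 10) guards against vacuous zero-width
  intervals at tiny depth.

**Orientation and skew.** Allele counts carry no Xi label. The haplotype
silenced (minor allele) at the majority of known-subject genes is taken as
the sample's Xi (`infer_xi_haplotype()`); an exact tie leaves the sample
unoriented. Samples without skewed XCI mimic escape everywhere (allelic
balance at silenced genes), so a sample is dropped when **more than** 25%
of its informative known-subject genes are called escaping — strictly more;
exactly 25% is retained. A gene is variably escaping by expression when at
least two samples escape and at least two are subject; with fewer than two
on one side the gene takes the majority constitutive status.

# The DNAme models

Promoter CpG islands are unmethylated on the Xa; subject genes methylate
the Xi copy, so female bulk means sit near half the Xi level. The bulk
caller uses fixed bands on the female mean: below 10% escape, strictly
between 15% and 60% subject, above 60% hypermethylated. Two deliberate
gaps remain — 10–15% and the exact 60% boundary — and values there map to
an explicit **intermediate** status rather than being snapped to the
nearest band: the band edges were calibrated with a buffer, and snapping
would manufacture confident calls out of ambiguous means. A TSS whose
*male* mean is at or above 15% is methylated on the Xa itself and is
uninformative for this analysis.

**Per-read resolution.** Each bisulfite read's methylation is its
methylated CG dinucleotides over the CGs it covers (read-local counts, not
the island CpG total). Islands are binned by `floor(10 × mean)` with the
top bin closed ([0.9, 1] → bin 9), and reads are classified below 25%,
between 33% and 66%, or above 75% — deliberately disjoint categories, so
their fractions need not sum to 1.

**Allele resolution.** Bisulfite conversion turns unmethylated C to T (and
G to A on the opposite strand), so SNPs whose allele pair is C/T or G/A
cannot be phased from converted reads and are excluded. Remaining reads
are pooled into a C-or-T group and a G-or-A group; with at least 5 reads
per group, both allele means below 0.25 call escape, one below 0.25 with
the other above 0.75 calls subject, both above 0.75 hypermethylated,
anything else uninformative. For binned displays the gene bin uses the
mean of the two per-allele means, so unequal read depth between alleles
does not drag the bin toward the deeper allele; equal allele means
tie-break deterministically (CT group reported as the low allele —
display-only, never affecting calls).

**Variable escape by DNAme** uses the 33% rule: a transcript is variable
when at least a third of its samples escape and at least a third are
subject. The denominator counts **informative** samples only (escape +
subject): the fractions are computed after the informativeness filter, and
counting uninformative samples would make variability a function of
coverage. A gene whose transcripts reach opposite constitutive statuses is
flagged variable *between TSSs*.

# Chromatin marks and the Xi:Xa fold change

Marks are quantified as length-weighted means over 500 bp windows
immediately upstream of each TSS — **strand-aware**, since TSS-proximal
marks are strand-asymmetric — except H3K36me3 (gene bodies: exons,
aggregated length-weighted per transcript) and H3K4me1 (annotated
enhancers). Uncovered positions are *missing, not zero*: a bigWig/bedGraph
gap is absence of evidence, and a region under 50% covered returns NA.
Samples are scaled to a common total depth (the maximum total).

With depth-normalized signal, a male value estimates the single-Xa
contribution and the female−male difference the Xi contribution, so
$(f-m)/m$ estimates the Xi:Xa signal ratio: 0 means no Xi signal, 1 means
Xi ≈ Xa. Its log2 is defined only for $f > m$; negative differences keep
the linear value and a sign flag rather than a pseudocount shift (no
principled pseudocount exists on this scale). Group comparisons use
Welch's t test (no equal-variance assumption across sex/status groups)
with Benjamini–Hochberg correction within one mark × comparison family at
adjusted p < 0.01; one deliberate exception is the expression-based
variable-gene analysis, which is so small (2–3 samples per side) that it
uses uncorrected p < 0.05. Metagene profiles length-scale gene bodies to
100 bins with 50 fixed-width bins per 50 kb flank (the resolution is a
display choice) and strand-flip so profiles read 5′→3′.

# The ensemble predictor

Where no SNP or CpG island is available, XCI status is still predicted
from the marks. Because female signal mixes Xi and Xa, each female sample
is paired with a male reference: k-means (k = 3) on standardized
per-sample *autosomal* mark means, each female paired with the mean of the
males in her cluster (a male-free cluster falls back to all males,
flagged). Features per transcript are the 7 female marks plus the 7 paired
male means — 14 features; missing values are imputed with the sample-wide
feature median and flagged.

Per sample, 20 random-forest models (1500 trees) are trained on labeled
genes (literature-consensus escape/subject meta-status): a global holdout
of 3 genes per class is removed first, then each model draws, fresh and
without replacement, ⌊0.75 × remaining escape genes⌋ escape genes and
twice that many subject genes (2:1 reflects the chromosome's class
imbalance without letting the majority class swamp the trees). The mtry
hyperparameter is tuned over 5 evenly spaced values in [1, 14] by
out-of-bag AUC — the grid size follows the original tuning budget; the
grid itself is this package's choice. Per-model accuracy is measured on
the labeled genes that model did not draw.

**Votes.** A transcript's per-sample status needs 15+ of 20 models (firm);
12–14 on the larger side is a *leaning* call, anything else inconsistent.
**Aggregation across samples**: one status in ≥66% of samples is
constitutive; both firm statuses in ≥33% each is variable; failing both,
leaning votes join their side and the 66% rule is retried, giving a
leaning overall call. The denominator is all samples with a vote result —
including inconsistent ones — which is the only reading consistent with
the rule's worked arithmetic (6 escape + 1 leaning of 10 samples is 60%
firm, 70% with leaning). Feature importance is the within-model rank of
impurity importance (most important = 14), averaged over models; the
simple 2-SD baseline classifier (class mean ± 2 SD bands, midpoint
threshold when the bands overlap, midpoint ties to the lower-mean class)
is included for comparison.

# Genotype association

At variable-escape genes, genotype vs status uses a Pearson chi-square on
the 2×2 homozygote × status table. Heterozygotes are excluded: a cis test
cannot know which allele sits on the Xi. No continuity correction is
applied, and tables with under 5 samples in a homozygote class are skipped
(not replaced by an exact test). BH correction spans all gene × locus
pairs in the run, with an X-only family as a second mode. For large
cohorts the variable set can be defined by absolute counts (strictly more
than 100 samples of each status) instead of the 33% rule.

**Attributable risk** is reported as population attributable risk for
escape, $(P(E) - P(E \mid \text{non-carrier}))/P(E)$ over the two
homozygote classes with the higher-escape-rate genotype as carrier,
clipped to [0, 1]; the estimator is not uniquely pinned down by the name
alone, so the formula is fixed here and labeled in the output.
**Methylation QTLs** are ordinary least squares of island DNAme on dosage
(0/1/2), fitted per sex and BH-corrected within sex at adjusted p < 0.01
(the package-wide convention; no test-specific threshold is inherited). A
QTL *spans a status change* when one homozygote median lies in the escape
band and the other strictly inside the subject band.

# The synthetic-data generator

The generator plants every structure the callers consume, under one seed
(bit-identical regeneration):

* **Cohort**: 250 genes (16% escape, 64% subject, 12% variable, 8%
  unlabeled), 8 females + 5 males over three tissues, 75% of females with
  fully skewed XCI. These are the package's defaults for a desk-scale
  cohort that still trains a 20-model ensemble (200 labeled genes).
* **Allelic counts**: totals Poisson(depth); Xi reads binomial with the
  Xi/Xa ratio drawn per gene — escape in [0.2, 1.0], subject in [0, 0.05].
  Unskewed samples are 50:50 mixtures of the two Xi choices, so their
  allelic imbalance vanishes in expectation — giving the skew filter
  something real to reject.
* **Bisulfite reads**: per-CpG methylation probability = allele-state mean
  (Xa 0.05; Xi 0.75 at subject genes, 0.05 at escape genes) plus a
  per-CpG offset Normal(0, 0.2) clipped to [0, 1]. The offsets are
  **per CpG, not per read**: intermediate island means arise from
  CpG-to-CpG inconsistency on the Xi, not from a mixture of fully
  methylated and unmethylated cells, matching how intermediate reads
  behave in real WGBS. Reads cover contiguous CpG runs and carry the SNP
  base of their chromosome of origin; some SNPs are deliberately C/T or
  G/A to exercise the exclusion rule.
* **Marks**: female value = Xa baseline + status-dependent Xi component +
  Gaussian noise; male = baseline + noise. Heterochromatic marks
  (H3K9me3, H3K27me3) have larger Xi components at subject genes,
  euchromatic marks (H3K4me3, H3K27ac, H3K36me3, H3K4me1) at escape
  genes, and DNAme carries the largest standardized separation — the
  ordering observed across real epigenomes, with magnitudes chosen so a
  single mark is informative but imperfect. `mark_effect_scale`
  multiplies every Xi component for sensitivity analyses.
* **Genotypes**: Hardy–Weinberg at uniform allele frequencies; planted
  loci shift the per-genotype escape probability of a named variable gene.

What the generator does **not** emulate: alignment artifacts and reference
bias, copy-number changes, linkage disequilibrium, tissue-specific mark
baselines at individual genes, and cell-mixture heterogeneity. Passing
tests therefore demonstrate that the statistical machinery is correct and
well calibrated under the stated generative model — not that any
particular real cohort meets those assumptions.

# Test and problem sizes

The test suite verifies the callers against independent oracles
(closed-form recomputation on 10^4-point grids; exhaustive enumeration of
all allelic-call boundaries for totals ≤ 500, all 21 vote counts, and all
status compositions over ≤ 12 samples; 0.001-resolution rule-table grids
for the DNAme bands) and the statistical behaviour by simulation: ≥ 99%
constitutive-status recovery at depth 500, ≥ 95%/≤ 5% skew-filter
retention at 40 samples × depth 200, ensemble balanced accuracy ≥ 85% on
genes withheld from every training draw with AUC degrading monotonically
as the Xi effect is scaled to zero, chi-square null calibration ≤ 2%
discoveries over 20 replicate cohorts of 400 samples, planted-locus power
≥ 90% over 50 replicates, and QTL slope recovery within ±20% in ≥ 95% of
50 replicates at n = 300. The end-to-end pipeline is checked to be
bit-identical across reruns of one seed. These sizes keep the full suite
in the minutes range on one CPU while leaving the statistical margins
wide.

# Known limitations

* The Wald interval is anti-conservative at extreme proportions and low
  depth; the `min_total_reads` guard mitigates but does not remove this.
  A score or exact interval would change boundary behaviour and was not
  adopted, to keep the printed formula.
* The skew filter assumes known-subject genes dominate a sample's
  informative set; cohorts with pervasive misannotation would defeat it.
* The ensemble's training labels are literature meta-status calls; label
  noise propagates into the model, and per-sample ensembles share no
  information across samples by design.
* Attributable risk and the QTL significance threshold are this package's
  documented choices (see above) and are surfaced in output headers rather
  than inherited from a single canonical definition.
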