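---
title: "Quantifying intratumor heterogeneity in single-cell NSCLC cohorts"
author: "scITH authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity in single-cell NSCLC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scITH)
```

# Scope and model

scITH implements an analysis chain for multi-patient non-small cell lung
cancer (NSCLC) single-cell RNA-seq cohorts: cell calling and quality
control, marker-based cell typing with malignant-cluster identification,
LUAD/LUSC patient classification, expression-inferred relative copy-number
(CNA) profiles, intratumor heterogeneity (ITH) scores, and ligand–receptor
interaction networks. Clustering, embedding, batch correction and
trajectory inference are deliberately *not* implemented: cluster labels are
an input, so any external clustering (graph-based, k-means, or ground truth
from the bundled simulator) plugs in.

Every stage is exercised end to end on synthetic cohorts with known ground
truth, so the statistical behavior of the chain — not just its arithmetic —
is tested without any external download.

# Quality control

A cell (barcode) passes QC when all of the following hold:

* number of expressed genes (count > 0) between 200 and 5000 — cells with
  *fewer than* 200 or *more than* 5000 are removed;
* total UMI count at most 30,000 — cells with *more than* 30,000 are
  removed;
* mitochondrial UMI fraction (genes matching `^MT-`, case-insensitive) at
  most 30% — cells *above* 30% are removed.

All exclusion rules are read strictly, so a cell sitting exactly on a
boundary (200 genes, 30,000 UMIs, 30.0% mitochondrial content) survives.
Whether boundary cells were kept in the original analyses is not
documented anywhere we know of; the strict reading is the literal one, and
`qc_thresholds()` makes the bounds configurable for sensitivity analysis.
An all-zero cell has mitochondrial fraction 0 by convention; it is removed
by the gene filter regardless.

Cell calling from raw barcode totals uses the knee of the descending
log–log barcode-rank curve: the point of maximum perpendicular distance to
the chord joining the curve's endpoints, ties broken toward higher totals.
Every barcode with a total at least that of the knee point is kept, so the
retained set is always a prefix of the rank-sorted barcodes. A flat curve
(all totals equal) has no knee and all positive barcodes are kept.

Normalization is the conventional library-size log-normalization:
`log(1 + count * 10000 / cell_total)` with the natural log. It is
re-implemented (three lines) rather than delegated so the pipeline has no
heavyweight dependency for a closed-form transform.

# Cell typing and patient classification

Each cluster is scored against canonical marker sets (endothelial,
epithelial/ciliated, alveolar, fibroblast, T, B, myeloid, neutrophil,
follicular dendritic, mast). The score of cluster *c* for type *t* is the
mean, over *t*'s markers, of the marker's z-score (computed across all
cells on the normalized matrix) averaged over the cells of *c*; the
highest-scoring type wins. Z-scoring before averaging puts genes with very
different expression scales on equal footing; the winning type is
invariant to cluster relabeling, and exact ties fall back to the
definition order of the marker list (deterministic, with a warning).

Two marker symbols required interpretation: the alveolar folate receptor
is taken as FOLR1 and the squamous desmoglein as DSG3; TTF-1 is the
protein name of NKX2-1. All are ordinary list entries and can be replaced.

Malignant (cancer) clusters are EPCAM-positive clusters lacking normal
lung epithelial programs: at least 30% of cells with an EPCAM count > 0,
and Epithelial and Alveolar marker scores both below 0.5 on the z-score
scale. The 30%/0.5 thresholds operationalize a qualitative rule
("EPCAM-positive, negative for normal epithelial markers"); both are
arguments of `identify_cancer_clusters()`.

Patients are classified from their malignant cells: the LUAD score is the
mean fraction of malignant cells expressing NAPSA and NKX2-1, the LUSC
score likewise for KRT5, DSG3 and TP63. Both scores below 0.05 — fewer
than 5% of cells expressing the markers — yields the unclassified label
NSCLC; otherwise the larger score wins, with ties going to the
first-defined subtype under a warning.

# Copy-number inference from expression

Relative CNA profiles are inferred from expression dosage, using all
non-malignant cells as the baseline:

1. genes ordered by chromosome (1..22, X, Y) and start coordinate;
   mitochondrial genes are excluded;
2. genes expressed in fewer than 20 cells filtered (strictly fewer: a
   gene seen in exactly 20 cells stays);
3. per-gene subtraction of the mean over reference (non-malignant) cells,
   on the log-normalized matrix — the pipeline operates in log space
   throughout;
4. smoothing with a 101-gene window along each chromosome, truncated at
   chromosome ends (never mirrored, never spanning a boundary), which
   removes gene-specific expression effects while preserving the
   gene-axis alignment across cells;
5. per-cell centering so the cell's median sits at 1, then clipping to
   1 ± 1.5σ, where σ is the standard deviation of the centered residuals
   over the whole matrix.

The centering statistic is the median: the modal copy state of a tumor
cell should map to 1 even when true CNAs occupy part of the genome, which
a mean would not guarantee. Clipping bounds the influence of extreme
windows; σ is computed once over the whole matrix by default (a per-patient
recomputation would decouple patients' color scales, and the clipped matrix
feeds the heterogeneity scores below, where a shared scale is what makes
patients comparable). The clipped matrix is the default input to ITH_CNA;
`cna_params(clip = FALSE)` switches to the centered, unclipped matrix for
sensitivity analysis. With zero variance the matrix is returned centered
and unclipped. For heatmaps, `subsample_for_viz()` keeps at most 100
malignant cells per patient, sampled without replacement under a seed.

# Intratumor heterogeneity scores

For each patient, all pairwise Pearson correlation coefficients between
malignant cells are computed on two feature sets: the relative CNA matrix
(giving ITH_CNA) and the log-normalized expression matrix (giving
ITH_GEX). The heterogeneity score is the interquartile range (IQR) of the
correlation distribution. A homogeneous tumor — every pair of cells highly
correlated — concentrates the distribution and scores near 0; divergent
clones produce a mixture of high within-clone and low between-clone
correlations, widening the IQR.

Numerical choices: quantiles use linear interpolation between order
statistics (`stats::quantile` type 7), recorded as a configuration choice
since other quantile rules shift the IQR slightly; constant cell profiles
have undefined correlations and are excluded with a warning; scores are
undefined (NA) below 3 malignant cells. ITH_GEX uses all genes surviving
QC, without highly-variable-gene selection — the expression profile is
taken as-is; restricting to variable genes is possible upstream by
subsetting the matrix. Because Pearson correlation is invariant to
per-cell affine transforms, the scores do not depend on per-cell scaling
of the profiles — a property asserted numerically in the tests.

Group comparisons (e.g. LUSCn vs LUADm vs LUADn) use two-sided unpaired
Wilcoxon rank-sum tests via `stats::wilcox.test`: exact p-values for small
tie-free samples, normal approximation with tie correction otherwise.
Fully tied comparisons (zero variance) report p = 1. Correlations between
ITH and cell-type composition use Pearson's r with two-sided t-based
p-values on n − 2 degrees of freedom (`stats::cor.test`), with
significance flagged at p < 0.05.

# Ligand–receptor interaction analysis

Within each patient, for every ligand–receptor pair and every ordered
(sender, receiver) cell-type pair, the statistic is the mean of the
ligand's mean normalized expression in the sender and the receptor's in
the receiver. The null distribution comes from 1000 random permutations of
the cell-type labels, and `p = (1 + #(null ≥ observed)) / (N + 1)`, so p
is never smaller than 1/(N+1). Pairs in which the ligand is expressed in
fewer than 10% of sender cells (or the receptor in fewer than 10% of
receiver cells) are non-specific by construction and are assigned p = 1.
These defaults — the statistic, the 10% floor, the pseudocount — follow
the standard permutation-testing convention for this analysis; only simple
one-to-one pairs are handled (no multi-subunit complexes).

Specificity filtering proceeds per patient and then across patients:

* the *rank* of a pair within a patient is the fraction of type-pairs in
  which it is significant (α = 0.05; configurable, as the significance
  level is a convention); pairs with rank > 0.1 are discarded — an
  interaction significant in many type-pairs is not specific;
* a (pair, sender, receiver) triple is retained when it survives rank
  filtering and is significant in strictly more than five patients.

The rank filter is applied before cross-patient aggregation; the ordering
maximizes specificity since a pair that is promiscuous in one patient
cannot contribute recurrence evidence from that patient. Recurrence counts
significance, not mere expression, since it follows a significance
pipeline.

The cell-type network has cell types as nodes and the number of retained
interactions between two types (both directions summed) as undirected edge
weights; types with total incident interactions below a floor (500 in a
42-patient cohort; scaled down for small synthetic cohorts through
`min_interactions`) are removed from the report. The gene-only network is
built by constructing the master graph with both cell-type–gene expression
edges and gene–gene ligand–receptor edges, deleting the cell-type nodes,
and reporting the four largest connected components (ranked by node count,
ties by edge count, then by lexicographically smallest member). Note that
after deleting cell-type nodes only the ligand–receptor edges can carry
connectivity, so the components are ultimately determined by the retained
pair list.

# The synthetic cohort generator

`generate_cohort()` draws UMI counts from a negative binomial model.
The mean for gene *g* in cell *i* of type *t* is

```
mu[g,i] = base[g] * marker[g,t] * clone_fold[g, clone(i)] * lr[g,t] * lib[i]
```

with variance `mu + dispersion * mu^2`. Defaults, chosen once as realistic
for this kind of data and then left alone:

* `nb_dispersion = 0.5` — moderate overdispersion, in the range typically
  estimated for UMI counts;
* gene baselines Gamma(shape 2, scale 0.5), giving a dynamic range of
  per-gene means around 1 and, at the default 1500-gene universe, roughly
  500–900 expressed genes and 1000–3000 UMIs per cell — the same order as
  real cells against the default QC thresholds;
* `marker_effect = 8` fold upregulation of a type's markers in that type
  (baseline 0.1 elsewhere): strong but not deterministic marker programs;
* copy number acts multiplicatively on the mean (`clone_fold`), the same
  expression-dosage assumption the CNA inference relies on; clone
  profiles are contiguous per-chromosome segments validated against the
  gene ranges, with overlapping segments within a clone rejected;
* per-cell library factors are log-normal with `sdlog = 0.35` and mean 1,
  so QC thresholds bite realistically;
* 13 mitochondrial genes ("MT-" prefixed) tuned to a 5% baseline UMI
  fraction, with a random 5% of cells scaled ×10 to push them past the
  30% QC cutoff;
* ligand–receptor genes default to a baseline mean of 0.05 (≈5% of cells
  expressing, below the 10% expression floor of the interaction test), so
  a planted signal is type-specific rather than ambient. For calibration
  studies of the permutation test the baseline is raised above the floor
  instead (`lr_baseline_mean = 1`), since floor-failing pairs receive
  p = 1 by construction and carry no calibration information.

Determinism: all randomness derives from one integer seed; gene baselines
use the stream seeded with the seed itself, and patient *p* uses the
stream seeded with `(seed + 9973 p) mod 2^31`, so a patient's data do not
depend on how many patients follow it.

What the generator does *not* emulate: doublets, ambient RNA,
batch/chemistry effects, gene–gene correlation beyond the clone and
marker structure, zero inflation beyond the negative binomial, and
read-level artifacts. Tests passing on this generator therefore
demonstrate that the statistical machinery behaves as intended under a
faithful dosage model — not that any particular biological conclusion
transfers to a given real data set.

# Problem sizes used in the checks

The test-suite and acceptance-script simulations use deliberately scaled
cohorts, chosen so each check has clear statistical margin:

* ITH contrast: 16 two-clone vs 12 one-clone patients, 300 malignant +
  100 stromal/immune cells each, 3 chromosomes × 150 genes, segment folds
  2.0 and 0.5 on disjoint chromosomes;
* CNA recovery: a 150-gene fold-2 gain on a 2000-gene axis, 500 malignant
  vs 500 reference cells, scored by inside-vs-outside AUROC of per-gene
  malignant means; the neutral null uses 100 + 100 cells with all folds 1
  and marker effects off, compared by a two-sample KS test on one smoothed
  value per cell and chromosome (window smoothing autocorrelates values
  within a chromosome, so KS is run on independent draws);
* interaction calibration: 4 types × 100 cells, 50 pairs above the
  expression floor, 1000 permutations, 10 seeds; planted recovery:
  4 types × 200 cells, effect 8, 20 seeds.

# Known limitations

* CNA profiles are relative expression dosage: no HMM state calling, no
  allele-specific events, no subclone tree reconstruction.
* The malignant/reference split drives both CNA inference and ITH; a
  misidentified cancer cluster propagates. The pipeline takes cluster
  labels as input and flags EPCAM-based calls, but does not second-guess
  the clustering.
* Interaction analysis handles one-to-one pairs only and treats patients
  independently; p-values are permutation-resolution bounded at 1/(N+1).
* The LUAD/LUSC classifier is a two-score marker rule; it reports NSCLC
  when evidence is weak rather than forcing a call, and expert review
  can override it downstream (a manual column, not an algorithm).
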