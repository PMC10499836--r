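---
title: "Rescoring antibody-antigen docking decoys with structure-conditioned confidence metrics"
author: "AbAgRescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring antibody-antigen docking decoys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbAgRescore)
```

## The problem

Physics-based rigid-body docking of an antibody onto its antigen is good at
*sampling*: among the top 100 low-energy poses there is often at least one
that is geometrically close to the native complex. It is poor at *scoring*:
the native-like poses are rarely ranked near the top, and for
antibody-antigen pairs no co-evolutionary signal exists that
sequence-based complex predictors could exploit (antibody binding arises
from somatic hypermutation, not co-evolution). A practical remedy is to
re-assess each docked pose with a structure-conditioned inference engine:
the pose, stripped to a poly-alanine backbone template and presented as a
single merged chain with a blanked (single-row) MSA, is rebuilt by the
engine, and the confidence the engine reports in its own reconstruction is
used as a new score. This package implements the full surrounding
machinery -- template preparation, model-quality evaluation, the composite
confidence score, and the enrichment analytics -- with a deterministic
synthetic decoy generator standing in for the docking programs and for the
inference engine itself, so every stage is testable on a laptop.

## The composite score

For the ensemble of docked models of one system scored by one method, let
$\mathrm{pLDDT}_i$ and $\mathrm{pTM}_i$ be the per-model confidence
metrics averaged over all positions (both in $[0,1]$; pLDDT is a local
error estimate, pTM a global fold-confidence). Each metric is standardized
*within the ensemble*,

$$z_i = \frac{x_i - \bar{x}}{s_x},$$

with $s_x$ the sample standard deviation (denominator $n-1$; the choice is
exposed through `ddof` but is immaterial for ranking), and the composite
score is the unweighted sum

$$\mathrm{AF2}_{\mathrm{Composite},i} = z_{\mathrm{pLDDT},i} + z_{\mathrm{pTM},i}.$$

No weights are fitted, which avoids any calibration step. The sum rewards
models on which the two metrics *agree*: if
$z_{\mathrm{pLDDT}} = z_{\mathrm{pTM}}$ for every model, the composite has
four times the variance of either component, while disagreement cancels.
Standardization makes the score system-independent but also
size-sensitive: `compositeScores()` refuses ensembles of fewer than 2
models and warns below 25, where the standardized values carry errors of
the order of one composite unit.

Raw docking scores are first oriented so that higher is always better
(`orientDockingScores()`): energies (ProPOSE, PIPER) are sign-flipped,
ZDOCK scores kept, and cluster sizes (ClusPro) used as-is, with ties kept
in original output order by the stable sort in `rankModels()`. To pool
models across methods, every method's oriented scores must first be
standardized within its own (system, method) ensemble; `poolMethods()`
enforces this.

## Model quality: CAPRI metrics

Quality of a pose against the reference (crystal) complex is measured by
three standard quantities, all computed on heavy atoms with residues
matched by (chain, residue number, insertion code):

* **fnat** -- the fraction of native cross-partner residue contacts
  (any heavy-atom pair within 5 Å, closed interval) preserved in the
  model;
* **iRMSD** -- RMSD of the backbone (N, CA, C, O; or CA-only) atoms of
  the interface residues, after least-squares superposition of those same
  atoms. The interface is defined on the *reference only*: residues of
  either partner with a cross-partner heavy atom within 10 Å. The fit is
  joint over both partners by default; an antigen-side-only fit is
  available via `fit = "antigen"`;
* **lRMSD** -- the model's antigen is superposed onto the reference
  antigen, and the RMSD of the antibody atoms is reported in that frame
  without refitting.

The superposition engine (`kabschSuperpose()`) returns the proper rotation
minimizing the RMSD (SVD construction with determinant correction) and
rejects fewer than three or collinear points. Classification
(`classifyCapri()`) uses the standard CAPRI thresholds -- High:
fnat $\ge 0.5$ and (lRMSD $\le 1$ or iRMSD $\le 1$); Medium: fnat
$\ge 0.3$ and (lRMSD $\le 5$ or iRMSD $\le 2$); Acceptable: fnat $\ge 0.1$
and (lRMSD $\le 10$ or iRMSD $\le 4$); otherwise Incorrect -- and a
*positive* is any model of Acceptable or better quality. The thresholds
are not tunable: they are the community convention, and the classification
is monotone in each metric.

`conservedContactFraction()` reuses the identical contact engine with the
docked template as the reference set, to quantify how much a rebuilt model
drifted from the template it was given.

## Template preparation

`mergeChains()` joins the chains of a pose into one chain, antibody chains
first (heavy then light, configurable), antigen last:

* **linker** strategy -- consecutive chains are bridged by 50 unknown
  (X) residues carrying no coordinates; everything is renumbered
  sequentially from 1. Sequential renumbering also closes the two ends of
  any unsolved loop inside a chain; the function reports such junctions.
* **gap** strategy -- no placeholder residues; the numbering jumps by
  200 at every chain boundary (the gap is applied per boundary, which is
  the natural reading when more than two chains are merged).

`toPolyAlanine()` strips each real residue to {N, CA, C, O, CB} and
relabels it alanine. A residue without a C$\beta$ (glycine, or an
incomplete side chain) gets one constructed from N, CA, C by the fixed
local-frame linear combination in `idealCB()`, which yields the ideal
tetrahedral geometry (|CA--CB| $\approx$ 1.52 Å) and is exactly
equivariant under rigid motions. Backbone coordinates are never moved;
the operation is idempotent.

`buildTemplateFeatures()` assembles the feature bundle: the all-alanine
template sequence and per-position labels, a positions $\times$ 5 atom
mask over the N/CA/C/O/CB slots with matching coordinates, the
none-marker for template domain names, and the query side -- the *original*
merged sequence with X at linker positions, plus an MSA containing exactly
that one sequence. The single-row MSA encodes the deliberate absence of
co-evolutionary information: confidence then reflects the structure
module's opinion of the template alone. The bundle is serialized to a
versioned JSON schema owned by this package
(`exportFeatures()`/`importFeatures()`); running the inference engine
itself is outside the package boundary.

## Enrichment analytics

One convention matters throughout: when models are ranked by docking
scores, success is judged on the docking-generated variants; when they are
ranked by the composite score, success is judged on the rebuilt variants.
The labeled decoy table carries both quality labels per model, and
`successCurve()`/`perSystemAUC()` select the pair dictated by the scheme.

* `rocAuc()` is the rank-based (Mann-Whitney) AUC with half-credit ties;
  a system with an empty class yields NA ("system excluded") rather than
  an error. Systems without positives are excluded from AUC comparisons
  but *retained* in success curves, which is precisely where rescoring
  can rescue a failed docking run.
* `successCurve()` reports, per depth N, the fraction of systems with at
  least one model at or above the quality floor (Acceptable by default,
  Medium optionally) among the top N.
* `separationSd()` measures the distance between the medians of the
  positive and negative score distributions in units of the pooled SD of
  all scores (the denominator is configurable to negatives-only; pooled
  is the default because it is symmetric in the two classes).
* `precisionCurve()` estimates $P(\text{positive} \mid \text{score} > t)$
  from Gaussian kernel density estimates rather than raw counts, to avoid
  outlier bias: class densities use Silverman's rule-of-thumb bandwidth
  and a common 512-point grid spanning the data range extended by three
  bandwidths; survival masses are rectangle-rule tail sums; the
  uncertainty band is the binomial standard error at the effective count
  above the threshold.
* `summarizeDecoySet()` produces the composition table (systems, models,
  positives with percentage, negatives, positives-per-system mean ± SD,
  per method and variant, plus totals), and `compositionSummary()`
  re-derives the same statistics from bare counts, which is how the
  bundled reference composition table is checked arithmetically.

## The synthetic generator

`makeToyComplex()` builds two ideal poly-alanine $\alpha$-helices
(NeRF construction from ideal bond lengths/angles, $\phi=-57^\circ$,
$\psi=-47^\circ$), packs them side by side with a seed-determined spin and
axial slide, and closes the gap until the nearest heavy-atom approach is
4 Å -- tightening further, never below a 2.6 Å clash floor, until at least
3 native contact pairs exist. `makeDecoys()` perturbs the antibody
rigidly (the antigen frame stays fixed, mirroring the lRMSD convention)
by a ladder of (rotation, translation) magnitudes with random axis and
direction, and evaluates every decoy against the reference, so
ground-truth labels come from the package's own CAPRI engine. The default
ladder was calibrated once on the toy complex so that all four quality
classes occur and positives form a minority (roughly a quarter of models,
concentrated in the small-perturbation rungs), then frozen; translation
rungs of 50 Å and beyond guarantee fnat = 0.

`mockConfidences()` emulates the confidence output: the latent true
quality $-\log(1+\mathrm{lRMSD})$ is standardized within the ensemble, and
each metric is `signalStrength` times that quality plus bivariate Gaussian
noise with cross-correlation `agreement` and SD `noiseSd`, squashed into
$[0,1]$ by the logistic function. `signalStrength = 0` gives a pure-noise
null. The default `agreement = 0.9` reflects that the two confidence
metrics largely agree on good models; the mock docking score in
`makeBenchmark()` is deliberately signal-free, so the benchmark isolates
the question "does confidence-based reranking beat an uninformative
ranking?".

What the generator does *not* emulate: backbone flexibility (CDR-H3
loops), side-chain packing, the energy landscape of real docking scores
(which carry some signal), sequence diversity, and any actual inference
engine. Passing tests therefore demonstrate the correctness of the
machinery and the internal consistency of the claim -- signal in, better
ranking out -- not performance on experimental complexes.

## Numerical choices and degenerate inputs

* Distances in Å; residue indices 1-based; all cutoffs are closed
  intervals (a pair exactly at 5 Å is a contact).
* Alternate locations resolve to the highest occupancy, ties to the
  alphabetically first label; hydrogens are dropped on read by default.
* Constant score ensembles standardize to all zeros with a warning, so a
  degenerate system never aborts a pooled analysis.
* Sorting is stable everywhere ties can occur; ranks are 1..n.
* `kabschSuperpose()` errors on $n<3$ or collinear input rather than
  returning an unstable fit.
* Generators are deterministic under a fixed seed; per-system seeds are
  derived from the master seed arithmetically.

## Problem sizes

The bundled analyses and tests run the synthetic benchmark at 20 systems
of 50 decoys each (12 + 12 residue toy complexes), which gives stable
AUC/success estimates while keeping a full run in tens of seconds;
oracle-equivalence checks use fixtures of at most 50 residues or 50
scores, where brute-force enumeration is exact and fast. These sizes are
the package's defaults and are stated here so results are reproducible
as-is.

## Limitations

The composite score inherits the weaknesses discussed for per-ensemble
standardization: it is relative, so an ensemble consisting solely of
incorrect poses still has top-ranked members, and absolute thresholds on
the composite are only meaningful because agreement between the two
metrics skews the distribution when genuinely good models are present.
The ligand-RMSD implementation assumes a unique antigen chain
correspondence (no symmetry correction for homo-oligomeric antigens), and
residue correspondence is by numbering, not alignment -- adequate for
docking decoys generated from a common input, not for cross-crystal
comparisons.
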