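---
title: "Rescuing no-call SNP genotypes: models, parameters and design notes"
author: "GenoRescue authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescuing no-call SNP genotypes: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenoRescue)
```

## The statistical problem

An Illumina SNP array reduces each sample × SNP assay to two numbers: the
normalized total intensity $R \ge 0$ and the allelic ratio
$\theta \in [0, 1]$. For a well-behaved SNP the $(\theta, R)$ points form
three clusters — AA near $\theta = 0$, AB near the middle, BB near
$\theta = 1$ — and the production caller assigns genotypes by cluster
membership, emitting a no-call (NC) when the point is ambiguous. GenoRescue
treats no-call recovery as supervised classification: learn the cluster
structure from the valid calls, then classify the no-calls.

Two features make this more than a generic 2-feature classifier. First,
cluster positions vary by SNP (allele chemistry, probe behavior, copy
effects), so the model receives the SNP identity through a learned
embedding rather than pooling all SNPs. Second, the label source is the
caller itself, so recovered genotypes must be validated against independent
technologies (imputation, WGS) before they are trusted; that validation
layer is as much a part of the method as the classifier.

## The genotyping network

For a record $(s, R, \theta)$ with SNP index $s$:

$$ x = [\,E_s \,\|\, R \,\|\, \theta\,] \in \mathbb{R}^{52}, \quad
   h_1 = \max(W_1^\top x + b_1, 0) \in \mathbb{R}^{64}, \quad
   h_2 = \max(W_2^\top h_1 + b_2, 0) \in \mathbb{R}^{160}, $$
$$ p = \operatorname{softmax}(W_3^\top h_2 + b_3) \in \Delta^2 . $$

$E$ is the $V \times 50$ embedding table ($V$ = vocabulary size). The
rectifier is applied to both hidden layers and softmax only to the output:
the output must be a 3-class probability simplex, and a softmax on a
160-unit hidden layer would serve no purpose.

Training minimizes the mean **focal cross-entropy**
$L = -\alpha (1 - p_t)^\gamma \log p_t$ with $p_t$ the probability assigned
to the true class, clipped to $[10^{-7}, 1 - 10^{-7}]$ before the log. With
$\gamma = 0, \alpha = 1$ this is ordinary cross-entropy; $\gamma > 0$
down-weights well-classified examples, which matters here because the
class mix is dominated by easy homozygote calls while the informative
examples sit near cluster boundaries. The gradient at the output logits is
$\partial L / \partial z_j = (\mathrm{d}L/\mathrm{d}p_t)\, p_t (t_j - p_j)$,
which reduces to the familiar $p - t$ at $\gamma = 0, \alpha = 1$.

### Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `embeddingDim` | 50 | dimensions | per-SNP capacity; the production recipe |
| `hiddenUnits` | 64, 160 | units | production recipe; grid-searchable 32–160 by 32 |
| `learningRate` | 1e-4 | — | production recipe (Adam) |
| `maxEpochs` | 11 | epochs | production recipe |
| `earlyStopPatience` | 5 | epochs | stop after this many non-improving validation epochs; best weights restored |
| `focalGamma` | 2 | — | conventional focusing default |
| `focalAlpha` | 0.25 | (0, 1] | conventional scale default |
| `batchSize` | 512 | records | unstated upstream; a standard mini-batch size for ~10⁵-record tables |

The optimizer is Adam with moment decays 0.9/0.999 and epsilon $10^{-7}$,
fixed (not exposed) for reproducibility. Weight initialization is
Glorot-uniform for dense layers and uniform $\pm 0.05$ for the embedding —
the defaults of the framework family this recipe originates from — seeded
from `ModelConfig@seed` together with the batch shuffling, so training is
bit-reproducible on identical input.

### Numerical choices and edge cases

- Softmax is computed with row-max subtraction; outputs sum to 1 within
  $10^{-6}$ and are validated as such in the `PredictionResult` class.
- Argmax ties break toward the earlier class in the fixed order
  AA < AB < BB.
- With patience $k \ge 1$ training stops after $k$ consecutive epochs
  without validation-loss improvement; patience 0 stops at the first
  non-improving epoch. In both cases the best-validation-loss weights are
  restored.
- A record whose snpID is absent from the model vocabulary is *refused*
  (excluded and counted), not approximated: its embedding row was never
  trained, so any output would be noise. NC is never emitted; instead the
  winning probability is reported so callers can threshold downstream.
- An empty training set is an error; an empty prediction input yields an
  empty result.

## Preprocessing contract

Records missing any of {GenTrain, R, $\theta$, genotype} are dropped first;
NC records are then split off for later prediction; the remaining valid
records are randomly divided 90/5/5 into train/validation/test. Two points
deserve emphasis:

- **The split is by record** (sample × SNP observation), not by sample or
  SNP. The same sample can appear in train and test at different SNPs, and
  every SNP is (with near certainty) represented in training — intentional,
  since the model must learn every SNP's embedding. Held-out accuracy
  therefore measures generalization to unseen *measurements*, not unseen
  SNPs. The 80-10-10 alternative sometimes quoted for this design is
  supported via the `fractions` argument; 90/5/5 is the normative default.
- The encoding vocabulary is built from sorted distinct snpIDs, so it is
  deterministic for a given record set; targets are one-hot over (AA, AB,
  BB).

## Concordance conventions

- Calls are matched on exact sample ID and the exact four-field variant key
  (chromosome, 1-based position, ref, alt); no strand or allele flipping is
  attempted, and a ref/alt swap is reported as an allele mismatch, not
  silently harmonized.
- Array genotypes live in Illumina A/B space; `a_is_ref` states whether
  allele A is the reference allele. All dosages are re-expressed as
  alternate-allele counts before comparison. When `a_is_ref` is absent it
  defaults to true with a warning and results are marked
  allele-convention-unverified.
- Concordance is discrete dosage equality in {0, 1, 2}. NC array calls and
  missing reference dosages are excluded from denominators; each
  technology uses its own denominator (calls where *that* technology has a
  dosage), and a rate with an empty denominator is reported missing, never
  0. The summary rate counts a call concordant if it matches at least one
  available reference.
- A SNP is high-performing when every *available* technology rate is ≥ the
  threshold (default 0.90); an unavailable technology does not veto, but a
  SNP with no available rate at all is not classified high-performing.
- Call-rate recalculation adds concordant recoveries to the original call
  count: $(c + r)/n$, constrained so the result can only rise and never
  exceeds 1.
- The GenTrain correlation is the plain Pearson coefficient over complete
  (GenTrain, imputed-concordance) pairs, undefined below 3 pairs or at zero
  variance.
- The Mann–Whitney comparison reports the first group's midrank U. With
  both groups ≤ 8 the two-sided p comes from full enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments (exact even under ties, doubling the
  smaller tail, capped at 1); otherwise the normal approximation with tie
  correction and no continuity correction is used. Raw p-values are
  reported; multiplicity correction is left to the caller.

## Cluster-geometry QC

For each genotype class present, the geometry is the mean centroid in
$(\theta, R)$ and the RMS width
$w_g = \sqrt{\tfrac{1}{n_g}\sum_i \|x_i - \bar{x}_g\|^2}$; a single point
has width 0 and the centroid always lies in its class's bounding box. A SNP
is flagged when any width exceeds `wMax`, any pair of centroids is closer
than `dMin` along $\theta$ (the allelic axis; joint $(\theta, R)$ distance
is available by option), or the lowest centroid R falls below `rMin`.
Classes with fewer than `nMin` points everywhere yield an informational
`insufficient_data` flag that does not by itself condemn the SNP.

Thresholds are openly heuristic — the upstream method leaves them
unresolved — and the defaults (`wMax` 0.10, `dMin` 0.10 in $\theta$ units,
`rMin` 0.20, `nMin` 3) are read off the geometry of well-behaved SNPs:
homozygote centroids near 0 and 1 give pairwise separations ~0.45, an
order of magnitude above `dMin`, and a healthy cluster's spread
(θ sd ~0.03, R CV ~7 %) gives widths ~0.08, safely under `wMax`. All
flagging tests in the package use planted-truth simulations rather than
these constants, so the thresholds can be retuned without invalidating the
test suite.

## What the simulator does and does not emulate

`simulatePanel()` generates, per SNP: an alternate-allele frequency uniform
on `mafRange` (default [0.05, 0.5]); Hardy–Weinberg genotype draws
($p^2, 2pq, q^2$); a per-class $\theta$ cluster centered on the jittered
template 0.05/0.50/0.95 with Gaussian noise (sd 0.03) clamped to $[0, 1]$;
gamma-distributed R with per-class mean 1 and shape 200 (~7 % coefficient
of variation — a tight, well-behaved intensity cluster consistent with the
QC width defaults above); and a per-SNP random A/B↔ref/alt orientation.
Samples are laid out in 11 ancestry strata of 44 (484 samples by default),
with an optional per-stratum $\theta$ offset (off by default). The
GenTrain-like score is $1 - e^{-s/4\sigma}$ in the adjacent-centroid
separation $s$ and noise $\sigma$, plus small noise — high for separated
clusters, near 0 for planted non-clustering SNPs.

No-calls fire with marginal probability `ncProbability` (default 0.03), but
the per-record risk is reweighted by a logistic function of the distance
from the assigned centroid (in $\theta$ sds) and of low R, then normalized
to preserve the marginal rate — so no-calls concentrate on exactly the
ambiguous points the production caller declines, without changing the
overall rate a test asserts on. Planted non-clustering SNPs draw all
genotypes from one overlapping cloud ($\theta \sim N(0.5, 0.15)$, reduced
R). Field missingness knocks out one of the four required fields per
affected record, so `missingness` is directly the expected dropped-record
fraction.

Deliberately *not* modeled: linkage disequilibrium between SNPs, real
probe chemistry or batch effects, fractional imputed dosages (references
are hard 0/1/2 calls with a uniform flip error), genome-realistic positions
(keys are arbitrary unique coordinates), and ancestry-specific allele
frequencies (strata shift cluster positions, not MAFs). Consequently a
passing test suite demonstrates that the algorithms are correct under
their stated model — Hardy–Weinberg sampling, Gaussian/gamma clusters,
independent errors — not that the network will reach any particular
accuracy on a real cohort, where cluster shapes are messier and label
errors are correlated. Boundary clamping of $\theta$ slightly censors
clusters jittered near 0 or 1; the geometry tests account for this by
comparing against the censored-normal mean.

## Problem sizes

The test suite runs panels up to 200 SNPs × 500 samples (the accuracy
surrogate, trained with the full production recipe in well under a minute
on one CPU) and otherwise keeps fixtures at 2–100 SNPs and tens to
hundreds of samples — large enough for the binomial 99 % interval checks
on rates (10⁴–10⁵ records) while keeping the whole suite fast. The
acceptance script uses the 200 × 500 panel. These sizes are the package's
own choices for fast, convincing verification; nothing in the
implementation depends on them.

## Known limitations

- Genotype recovery inherits the label quality of the production caller it
  is trained on; systematically mis-clustered SNPs yield confidently wrong
  recoveries. This is why the concordance layer and the geometry flags are
  part of the pipeline, and why SNPs failing them should be left to
  imputation or sequencing.
- The embedding is strictly per-SNP: the model cannot predict for SNPs
  absent from training, by design.
- Probabilities are raw softmax outputs, not calibrated confidences; the
  reported maximum probability supports thresholding but not probabilistic
  interpretation.
- Multi-allelic sites are representable only as separate biallelic keys;
  haplotype-aware comparisons (e.g. two-SNP diplotypes) are out of scope.
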