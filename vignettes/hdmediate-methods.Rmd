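---
title: "Kernelized high-dimensional mediation: model, algorithm and design choices"
author: "hdmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernelized high-dimensional mediation: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmediate)
```

## The scientific problem

In a genetically diverse population measured on three omic layers —
genome-wide genotypes, transcriptomes, and a panel of physiological
traits — most heritable trait variation is believed to flow through gene
regulation. `hdmediate` asks whether a *single composite axis* of the
transcriptome can account for the genetic signal in the traits: it
searches for one composite genome score $G_C$, one composite transcriptome
score $T_C$, and one composite phenome score $P_C$ whose joint correlation
structure is as consistent as possible with *perfect mediation*,

$$ m = \alpha x + \epsilon_m, \qquad y = \beta m + \epsilon_y, $$

for unit-variance latents $x, m, y$. Perfect mediation pins the implied
covariance of $(x, m, y)$: the $x$–$y$ covariance must equal
$\alpha\beta$, and — equivalently — the partial correlation of $x$ and $y$
given $m$ must be zero. The product $\alpha\beta$ is the **path
coefficient**, the strength of the mediated genome → transcriptome →
phenome pathway.

## From likelihood to a weighted sum of correlations

Writing the structural-equation likelihood for the sample covariance $S$
of $(x, m, y)$ and substituting linear projections $l_X = Xa$, $l_M = Mb$,
$l_Y = Yc$ of column-centered data blocks, the terms involving the
loadings reduce to

$$ L_{red}(a, b, c) =
   \tfrac{2\alpha}{1-\alpha^2}\,\mathrm{corr}(Xa, Mb) +
   \tfrac{2\beta}{1-\beta^2}\,\mathrm{corr}(Mb, Yc), $$

a *weighted sum of correlations* over the chain $X$–$M$–$Y$ (a wSUMCOR
problem). The fitting algorithm alternates two easy updates until the
structural parameters move by less than `tol` (default $10^{-6}$):

1. given $(\alpha, \beta)$, normalize the two coefficients above to
   weights $w_1, w_2$ summing to one and maximize the weighted correlation
   sum over $(a, b, c)$ ([wsumcor()]);
2. given scores, set $\alpha = \mathrm{corr}(l_X, l_M)$ and
   $\beta = \mathrm{corr}(l_M, l_Y)$ (their regression coefficients on
   unit-variance latents).

Both structural parameters start at $0.5$. Weight magnitudes use
$|\alpha|, |\beta|$; a negative interim value is a sign flip of the
corresponding latent and is resolved at exit so that the reported
$\alpha, \beta \ge 0$ (optionally the score triple is flipped jointly so
$P_C$ correlates positively with an anchor trait, which makes "positive
loading = higher disease index" stable).

## Kernelization

With $\sim$20k transcripts against a handful of traits, raw blocks would
let the transcriptome dominate. Each block is therefore reduced to its
$n \times n$ Gram kernel $K = XX^\top$ over individuals
(`gram_kernel()`), and loadings are restricted to the span of the
observed individuals: $a = X^\top \tilde a$, so
$l_X = XX^\top\tilde a = K \tilde a$. All three omic layers then enter
with the same dimension $n$. Per-feature loadings are recovered by
back-projection, $a = X^\top \tilde a$ (`feature_loadings()`), which is
exact: $X(X^\top\tilde a) = (XX^\top)\tilde a$. Multiple tissues are
combined by trace-normalizing each tissue's kernel and summing
(`combine_tissue_kernels()`), which preserves per-tissue back-projected
loadings from the single shared transcriptome loading and is scale-fair
across tissues with different transcript counts.

## The SUMCOR optimizer and its normalization constraint

`wsumcor()` performs block-coordinate ascent: for each block in turn, the
loading is set to the constrained maximizer of its linear term against the
weighted sum of the neighbouring scores. With constraint matrix $C_j$ the
maximizer of $v^\top g$ under $v^\top C_j v = 1$ is $C_j^{-1} g$
renormalized. Because each score's scale is pinned by its constraint, this
is the exact correlation-form update, the recorded objective (the
constrained covariance form, which coincides with the correlation form
when the constraint is the plain covariance) is non-decreasing at every
step, and the iteration converges to a stationary point. Multiple random
initializations (`init = "random"`) are available; the deterministic
default starts each loading at the block's dominant right singular vector.

The constraint matrix interpolates between the sample covariance of the
block's columns and a scaled identity,
$C = (1-\lambda) S + \lambda \bar\nu I$ with $\bar\nu$ the mean diagonal
of $S$:

* `shrink_covariance()` provides the analytic (Schäfer–Strimmer-type)
  intensity — the ratio of the summed sampling variances of the
  off-diagonal covariances to their summed squares — appropriate when the
  blocks are genuinely low-dimensional feature matrices. We verified the
  estimate against independent implementations of closed-form shrinkage
  (it agrees with Ledoit–Wolf to three decimals on our kernels).
* For **kernelized** runs, `run_hdma()` defaults to the covariance-form
  limit $\lambda = 1$ ("mode A" in the multiblock-CCA literature). This
  is a deliberate design choice, made after measurement: on $n \times n$
  Gram blocks the analytic intensity comes out near zero (kernel columns
  are highly structured, so their covariance is "well estimated"), which
  leaves the optimizer essentially an unregularized kernel CCA. Sample
  CCA between two $n$-dimensional spans is dominated by chance subspace
  alignment — on label-permuted data we observe genome–transcriptome
  correlations of 0.85–0.97 — and the structural-likelihood landscape
  actually prefers that corner. Under the covariance-form constraint the
  optimizer instead tracks dominant shared structure, null correlations
  fall to moderate values, and generative structural parameters are
  recovered (see the recovery tests). The feature-space covariance this
  limit corresponds to is also the regime a transcriptome-scale feature
  count forces on the analytic estimate. `lambda` remains user-settable
  everywhere, including per block.

Numerical details: constraint factorizations are Cholesky with a
$10^{-10}$-scaled jitter fallback; the per-block shrinkage is estimated
once per fit, not per iteration; degenerate blocks (zero neighbour
direction with a positive weight, zero-trace kernels) are hard errors;
non-convergence returns the last iterate flagged `converged = FALSE` so
permutation batches never abort. The inner optimizer stops on objective
improvements below $10^{-8}$, distinct from the outer $10^{-6}$ tolerance
on $\alpha, \beta$.

## Inference

Permutation nulls (`permute_path_null()`) permute the individual labels of
the transcriptome kernel only, preserving the genome–phenome relationship
while severing both links through the transcriptome; the full fit is
re-run per permutation. P-values use the add-one counting estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, which is never
zero and remains valid under any amount of optimizer overfitting because
observed and null fits overfit identically. Loading nulls pool
back-projected loadings across permuted fits per tissue
(`loading_null()`); gene-set (cell-type) tests compare a set's mean
loading with equal-size draws from the complement, two-sided, with Holm
adjustment across sets (`gene_set_loading_test()`, `holm_adjust()` — a
named wrapper over `stats::p.adjust`).

## Local and distal heritability

Per transcript (variance-scaled to 1, covariate-adjusted), the founder
haplotype dosages at the marker nearest its transcription start site are
fit by least squares; the variance of the haplotype-fitted values is the
transcript's **local heritability**, and the residual variance times the
kinship-based REML heritability of the residual is its **distal
heritability** (`local_distal_decomposition()`). The REML estimate uses a
single eigendecomposition of the kinship matrix and scalar profile
likelihood on $[0, 1]$ (`estimate_h2()`); kinship is the founder-dosage
cross-product averaged over markers with unit mean diagonal
(`kinship_matrix()`). Dosages sum to 2 per marker, so the last founder
column is dropped as the reference in local fits. `fit_local_model()`
optionally controls for relatedness as a random effect (generalized least
squares at the transcript's REML heritability); we recommend this when
building local-only/distal-only kernel variants, since at modest $n$
ordinary least squares lets polygenic distal signal leak into the "local"
fitted values through chance projections onto the haplotype design.

TWAS-style analysis imputes expression in a new cohort as the product of
the local haplotype design with the training coefficients — genetics
only, no intercept or covariates (`impute_expression()`) — and flags a
transcript–trait correlation as significant only when it exceeds the most
extreme value across all label permutations (`twas()`). Trait relevance
is the maximum absolute Spearman correlation of a transcript across
covariate-adjusted traits (`trait_relevance()`); rank-based inverse
normal scores use the Blom offset $(r - 3/8)/(n + 1/4)$
(`rank_normal()`).

## Translation to new cohorts

Loadings learned in the training population are transferred by
(optionally ortholog-mapped, `map_orthologs()`: one-to-many mappings
propagate, many-to-one average) re-keying, and a predicted metabolic
disease index is the mean of loading-weighted, per-cohort standardized
expression (`predict_mdi()`; standardization is always internal to the
new cohort). Evaluation is simple linear regression of the observed trait
on the prediction, with optional per-group (per-strain) averaging
(`evaluate_prediction()`), or Welch's $t$ between two clinical groups
with subject-level averaging for technical replicates
(`group_comparison()`; a random-intercept model is the natural
alternative for replicated designs but is not implemented).

## What the synthetic populations emulate

`simulate_genomes()` builds founder mosaics: two gametes per chromosome,
each a first-order Markov chain over 8 founders with per-step switch
probability `switch_prob`, yielding diploid founder dosages that sum to 2
at every marker. The default panel is deliberately small — 4 chromosomes
of 5 markers with long founder blocks (`switch_prob = 0.02`) — so that
the genome's effective dimension stays well below the simulated
population sizes, as linkage disequilibrium makes it in a dense real
panel.

`simulate_transcriptome()` emulates the structure the mediation model
assumes and that motivates it empirically: trait-relevant transcripts
are *distally* heritable and *highly correlated*. The first
`module_size` transcripts form a module sharing (i) a distal polygenic
factor — concentrated on a dedicated "driver" chromosome that hosts no
transcript TSS, emulating a trans-band hotspot and guaranteeing distal
regulation never aliases into local fits through marker reuse — and (ii)
a common environmental factor (diet-like shared physiology). Distal and
environmental components are residualized in-sample against each
transcript's own local design so the local/distal decomposition is
exactly orthogonal per transcript. Background transcripts carry low,
independent heritability. Given a target $\alpha$,
the module's environmental fraction is solved numerically so that the
correlation between the module composite and its genetic part equals
$\alpha$ *exactly in the generated sample*; infeasible targets error
with the achievable range.

`simulate_phenome()` builds the latent outcome
$y = \beta m + \sqrt{1-\beta^2}\,\epsilon_y + \delta\, g$ with
$\epsilon_y$ constructed orthogonal to $m$ and $g$ in-sample, so
$\delta = 0$ reproduces perfect mediation exactly and $\delta > 0$
("direct_effect") violates it on purpose. Traits are noisy scalings of
$y$ with communality `trait_communality`.

Default study conditions (chosen once, for realism at desk scale): 60
transcripts with a 30-transcript module (local fraction 0.05, distal 0.35
of which 60% shared), background heritability $\approx 0.1$, 15 traits at
communality 0.5. Under these conditions a population of 400–500 yields a
composite phenome score capturing roughly half of the trait variance and
recovered structural parameters within a few hundredths of the generative
values.

What the generator does **not** emulate: read counts and library-size
effects, tissue-specific co-expression differences, inbreeding structure,
dominance or epistasis, linkage between the driver region and trait loci,
and real-data missingness. Passing recovery tests on these populations
demonstrates correctness of the estimator under its own assumptions, not
robustness to those complications.

## Known limitations

* All reported correlations are in-sample; with weak constraint shrinkage
  they are inflated by chance kernel alignment (see above). Significance
  should always be judged against the permutation null, never against
  zero.
* A single latent triple is extracted; secondary mediation axes are out
  of scope.
* The structural parameters carry no analytic standard errors; inference
  is permutation-only.
* The one-component REML heritability has no leave-one-chromosome-out
  variant, so local signal contributes to kinship.

## Problem sizes used by the test suite

Unit tests run on populations of 40–150 individuals. The end-to-end
checks use $n = 500$ (20 seeds) for parameter recovery, $100 \times 200$
permutations at $n = 60$ for null calibration, $n = 400$ for the
heritability grid and kernel-variant dissociation, and a 300/150
two-population transfer — sizes at which every targeted property is
measurable with comfortable Monte-Carlo margins.
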