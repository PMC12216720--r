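# hdmediate

High-dimensional mediation analysis for multi-omic population studies:
finds one composite genome score (G_C), one composite transcriptome score
(T_C) and one composite phenome score (P_C) whose correlation structure is
maximally consistent with *perfect mediation* — the transcriptome composite
fully transmitting the genetic signal to the traits.

It is written for quantitative geneticists working with genetically
diverse populations (multiparent crosses, outbred stocks, human cohorts)
who measure genome-wide genotypes, transcriptomes and trait panels on the
same individuals and want to ask: is there a single regulated
transcriptional program that mediates the genetic control of these traits,
which transcripts carry it, and does it transfer to new cohorts?

## The model

For unit-variance latents `x` (genome), `m` (transcriptome), `y` (phenome),
perfect mediation is the structural equation model

    m = alpha * x + e_m
    y = beta  * m + e_y

which forces cov(x, y) = alpha * beta and a zero partial correlation of
`x` and `y` given `m`. Substituting linear projections of column-centered
data blocks, the structural likelihood reduces (up to a function of
alpha, beta) to a weighted sum of correlations

    L = [2a/(1-a^2)] corr(Xa, Mb) + [2b/(1-b^2)] corr(Mb, Yc)

The fit alternates (i) a weighted SUMCOR optimization of the loadings
`a, b, c` under shrunk-covariance normalization constraints with
(ii) closed-form structural updates `alpha = corr(l_X, l_M)`,
`beta = corr(l_M, l_Y)`, starting from alpha = beta = 0.5, until both
change by less than 1e-6. Each omics block enters as its n x n Gram
kernel `K = X X'` so that genome, transcriptome and phenome carry equal
dimension, and per-feature loadings are recovered exactly by
back-projection `a = X' a~`. The product `alpha * beta` is the **path
coefficient**; its significance comes from permutation of the
transcriptome kernel's individual labels. Supporting machinery covers
local/distal transcript heritability decomposition (nearest-marker
haplotype fit + kinship REML of the residual), TWAS-style local
imputation, gene-set loading tests with Holm adjustment, loading-based
disease-index prediction in new cohorts, and a founder-mosaic synthetic
population generator with full ground truth.

## Worked example

```r
library(hdmediate)

## a synthetic population with a distally-regulated, trait-relevant
## transcript module: generative alpha = 0.6, beta = 0.8
pop <- simulate_mediation_population(n = 400, seed = 42)

fit <- run_hdma(pop$G_K, pop$T_K, pop$P_K)
print(fit)
#> High-dimensional mediation result
#>   n = 400 individuals, 3 iterations (converged)
#>   alpha (G_C~T_C) = 0.5383, beta (T_C~P_C) = 0.7823
#>   path coefficient = 0.4211
#>   partial cor G_C,P_C | T_C = -0.0074

mediation_summary(fit, pop$phenome)
#> Mediation summary
#>   path coefficient = 0.4211
#>   % phenome variance captured by P_C = 53.8

null <- permute_path_null(pop$G_K, pop$T_K, pop$P_K, n_perm = 200, seed = 1)
empirical_p(fit$path_coefficient, null$path_coefficients, "greater")
#> [1] 0.004975124
```

Reading the output: the fitted genome-transcriptome and
transcriptome-phenome correlations (0.54, 0.78) recover the generative
(0.6, 0.8) up to finite-sample attenuation; the near-zero partial
correlation of G_C and P_C given T_C is the signature of perfect
mediation (conditioning on the transcriptome composite leaves no direct
genome-phenome association); and the observed path coefficient 0.42 is
larger than all 200 label-permuted refits, so the mediated pathway is not
an artifact of optimizer flexibility. Transcript loadings
(`feature_loadings(fit$kernel_loadings$b, pop$expr)`) rank the module
transcripts far above background, and their correlation with the true
generative weights exceeds 0.95 at these settings.

A thin command-line front end over the same functions is installed at
`inst/cli/hdma` (subcommands `simulate`, `run`, `permute`, `herit`).

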