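---
title: "Models and methods in gsrice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gsrice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

gsrice implements a complete genomic-selection workflow for a rice
diversity panel phenotyped under several managed environments. This
vignette is the package's account of the science: the models, the
assumptions behind them, the knobs that matter, what the synthetic-data
generator does and does not emulate, and the numerical decisions that make
the pipeline deterministic and testable.

## The setting

A reference panel of a few hundred inbred accessions is genotyped at
thousands of SNP loci and phenotyped in field trials under contrasting
water regimes: a favourable lowland trial and one or two reproductive-stage
drought trials. Traits such as days to flowering and plant height keep high
genetic correlations between regimes, while grain yield under stress is
nearly uncorrelated with yield under favourable conditions — which is
exactly why models that carry genetic signal *across* environments, and
cross-validation designs that exploit partial phenotyping, matter for
drought breeding.

## Phenotype adjustment

Plot-level records are adjusted per environment and trait with

$$Y_{ijk} = \mu + C_j + \beta_k + N_i\,\alpha_i + \varepsilon_{ijk},$$

where $C_j$ are fixed effects of the replicated checks, $\beta_k$ random
block effects, $\alpha_i \sim N(0, \sigma^2_g)$ random accession effects,
and $N_i$ is 1 for test accessions and 0 for checks, so check plots inform
the mean, the check contrasts and the blocks but carry no accession effect.
Blocks are therefore anchored by the checks present in every block — the
property that makes unreplicated augmented designs adjustable at all. With
one or two replicates an accession-within-block interaction is not
separable from the residual, so $\alpha$ enters as an accession main
effect.

Estimation is EM-REML. The EM update
$\sigma^2_k \leftarrow \sigma^2_k + (\sigma^2_k^2/q_k)\,(y'PA_kPy - \mathrm{tr}(PA_k))$
is monotone in the restricted likelihood — the test suite asserts the trace
is non-decreasing on every fit — and is solved through the Woodbury
identity so cost scales with the number of random levels, not plots.
Convergence is declared at $|\Delta \ell_R| < 10^{-8}$ (cap 1000
iterations); variance iterates are floored at $10^{-10}$ to keep the
boundary reachable but the algebra finite. In the noise-free limit the
likelihood diverges as $\sigma^2_e \to 0$, so the fit is flagged
non-converged there while the estimates still land on the floor — the
degenerate behaviour one should expect.

Adjusted means default to $\hat\mu + \mathrm{BLUP}(\alpha_i)$, the value
consistent with the mixed model. Because "adjusted value" is also commonly
read as a de-blocked raw mean, `adjusted_means(fit, "block_corrected")`
provides that alternative; the two differ only by shrinkage.

Broad-sense heritability is $H^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ —
the phenotypic variance of the single-environment analysis counts only the
genotypic and residual components, not block or fixed-effect variance.

## Genotype QC and the LD machinery

Dosages count the alternate allele (0/1/2, VCF coordinates, 1-based).
Default filters are the standard ones for an inbred rice panel: missing
rate ≤ 20%, MAF ≥ 2%, heterozygosity ≤ 5% per locus (all inclusive bounds;
per-accession heterozygosity is reported by `locus_stats` users but not
filtered on). Imputation is per-locus mean (default) or mode — adequate at
these marker densities for kernel methods, and it keeps the pipeline free
of external phasing tools. Downstream analyses that need frequencies after
imputation recompute them; pruning deliberately uses the *pre-imputation*
missing rates to pick representatives.

LD is the squared Pearson correlation of dosage columns (the composite
estimator appropriate for unphased, essentially inbred data), computed
within chromosomes only. "Clusters of loci" are the connected components of
the graph whose edges join pairs with $r^2$ above the threshold: this is
the only clustering under which keeping one representative per cluster
*guarantees* that every retained pair is at or below the threshold, a
guarantee the tests verify by brute force. Representatives minimise
pre-imputation missingness, then maximise MAF, then are drawn uniformly
under the caller's seed. The threshold grid (`threshold_grid`) accepts
arbitrary $r^2$ and MAF levels; the conventional grid is
$r^2 \le \{0.25, 0.5, 0.75, 0.9, 1\}$ by MAF $\ge \{2, 5, 25\}\%$.

## Marker selection by association

`mlm_gwas` is a single-marker mixed-linear-model scan with kinship $K$ and
principal-component structure covariates $Q$ (for $K$ assumed
subpopulations, $K-1$ components; PCA replaces ancestry-coefficient
estimation because it is the standard, assumption-light structure
correction and the two span nearly the same space for well-separated
subpopulations). Variance components are estimated once under the
marker-free null on the eigendecomposition of $K$ and then held fixed for
every marker (P3D/EMMAX); each marker is tested by GLS with the residual
*scale* re-estimated per marker, so with $K = I$ and no covariates the test
reduces exactly to per-marker OLS — an identity the tests check to
$10^{-10}$, alongside an exact small-instance GLS oracle and a type-I
calibration study on null phenotypes.

`select_top_k` keeps the k smallest p-values with ties broken by genomic
order, making selection deterministic. Inside cross-validation the scan is
re-run on every training fold — kinship and covariates recomputed from the
training accessions only — so trait-specific selection can never touch a
validation phenotype; a poisoning test asserts this end to end.

## Kernel prediction models

Single-environment GBLUP uses $y = \mu + u + e$, $u \sim N(0, \sigma^2_u
K)$ with the VanRaden relationship matrix (columns centred by $2\hat p$,
scaled by $2\sum \hat p(1-\hat p)$; a raw $MM'$ option exists). RKHS is the
same solver with the Gaussian kernel $K_{ij} = \exp(-h\,d^2_{ij})$, $d^2$
the squared Euclidean distance between dosage rows divided by locus count,
and default bandwidth $h = 1/\mathrm{median}(d^2_{offdiag})$ — a common
single-kernel default that keeps the kernel informative at any marker
density (multi-kernel averaging is out of scope). Genetic values extend to
unphenotyped accessions by the conditional expectation
$u_{target} = \sigma^2_u K_{target,train} V^{-1}(y - \hat\mu)$. GBLUP with
the cross-product kernel is algebraically ridge regression on centred
markers with $\lambda = \hat\sigma^2_e/\hat\sigma^2_u$; the tests assert
agreement with an independently coded ridge solution to $10^{-6}$.

The multi-environment models are fitted by Gibbs sampling, written for this
package:

* **M×E decomposition** (`fit_mxe_gblup`, `fit_gxe_rkhs`): stacked records
  $y = \mu_{env} + u_0 + u_{env} + e$ with a genetic main effect
  $u_0 \sim N(0, \sigma^2_0 K)$ shared across environments and deviations
  $u_j \sim N(0, \sigma^2_j K)$. The implied genetic correlation between
  environments $j,k$ is
  $\sigma^2_0/\sqrt{(\sigma^2_0+\sigma^2_j)(\sigma^2_0+\sigma^2_k)}$. The
  Gaussian-kernel version is the empirical-Bayes G×E RKHS formulation.
* **Kronecker multi-trait** (`fit_kron_multitrait`): environments as
  correlated traits, $\mathrm{vec}(U) \sim N(0, \Sigma_G \otimes K)$ with
  unstructured $\Sigma_G$ (inverse-Wishart, df $J+2$,
  identity-proportional scale) and per-environment residual variances;
  missing cells, including fully unphenotyped accessions, are handled by
  data augmentation.

Two G×E RKHS-style formulations are deliberately exposed side by side —
the kernel-decomposition model and the Kronecker model — because both are
defensible readings of "extended RKHS" in this literature; their
predictions agree closely when $\Sigma_G$ is close to compound-symmetric.

Priors follow the common defaults of Bayesian genomic-prediction software:
scaled-inverse-$\chi^2$ with df 5 and scales set from the sample variance
with an even genetic/residual split ($R^2 = 0.5$), genetic scale divided by
the mean kernel diagonal. Residual covariance across environments is fixed
diagonal: the trials are physically separate experiments, so information in
CV2 should flow through genetics only.

Numerically, every kernel term is reparameterised through the truncated
eigendecomposition $K = \Gamma \Lambda \Gamma'$ and a one-time SVD of
$Z\Gamma\Lambda^{1/2}$, which makes the full conditional of the
coefficients diagonal; prior-only directions contribute their
$\chi^2$ sum of squares analytically. The Kronecker sampler simultaneously
diagonalises the residual and genetic precisions each iteration, so a full
row update is a vectorised scalar draw. One 5,000-iteration chain on 300
records therefore costs seconds, which is what makes chain-based models
usable inside replicated cross-validation. Default chains are 25,000
iterations with 5,000 burn-in, the convention for these samplers;
parameter-recovery tests use 5,000/1,000 and the replicated CV comparisons
1,500/500, chosen once as the package's reduced-chain settings — at those
lengths the posterior-mean genetic correlations are still recovered within
±0.15 of truth over repeated simulation, which the acceptance tests verify.
Chains are seeded, so fits are bit-reproducible.

## Cross-validation and inference on predictive ability

`make_partitions` draws 80/20 splits with the training size
`round(0.8 n)` (224/56 at n = 280; 163/41 at n = 204); replicate-level
randomness derives from `seed + replicate`, so the same plan is reusable
across traits and models, which is what makes paired comparisons valid.
Conventional replicate counts are 100 for fixed marker panels and 20 when
GWAS re-selection runs inside each fold.

CV1 masks every phenotype of the validation accessions. CV2 additionally
appends their helper-environment records to the training data — with two
helpers, both are appended. Single-environment models train on the target
environment only. Predictive ability is the Pearson correlation between
predictions and adjusted means over the validation set, per replicate, per
environment; replicates with fewer than three phenotyped validation
accessions are skipped with a warning.

Because the sampling variance of a correlation depends on its value,
comparisons run on the Fisher scale $Z = \tfrac12 \ln[(1+r)/(1-r)]$.
`anova_z` fits a fixed-effects linear model on $Z$ with *sequential*
(Type I) sums of squares in the caller's factor order — in balanced designs
main-effect sums of squares are then identical with and without the
first-order interactions, a property the tests verify — and `glance` on a
CV result reports both the raw mean predictive ability and the
back-transformed mean of $Z$, since either summary convention is found in
practice.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the package targets: 280 inbred accessions in 5 subpopulations,
12 chromosomes × 250 loci at 13.7 kb spacing (a ~3,000 SNP panel — the
density at which LD-selected panels already achieve most of the attainable
predictive ability), ~4% missing calls, ~1% residual heterozygosity, three
environments with genetic correlations following the flowering-time
pattern (0.71/0.58/0.68) and heritability targets 0.75/0.76/0.84.

Genotypes: ancestral allele frequencies are drawn from a clamped
Beta(0.5, 0.5) (rare-skewed MAF spectrum), differentiated across
subpopulations by Balding–Nichols drift with $F_{st} = 0.1$ — enough for
PCA-detectable structure comparable to *indica*/*aus* subgroups. Each
subpopulation carries a pool of 24 founder haplotypes whose alleles along a
chromosome come from a latent AR(1) Gaussian (coefficient `ld_copy_prob`)
thresholded at the subpopulation frequency: a Gaussian copula that
preserves every per-locus marginal exactly while correlating nearby loci
across the pool. Accession haplotypes are Markov mosaics over the pool
(continue the current founder with probability `ld_copy_prob`, else redraw
by the accession's ancestry), and accessions are fully inbred — dosage is
twice the haplotype allele — with heterozygous and missing calls injected
completely at random afterwards. Two free haplotypes per accession would
put per-locus heterozygosity near $2p(1-p)$ and the standard ≤ 5%
heterozygosity filter would then discard most common loci, which is why the
inbred-with-injected-heterozygotes design was chosen. At the default
`ld_copy_prob = 0.99` the realized panel shows mean $r^2 \approx 0.12$ at
short range, decaying to half by ≈ 240 kb; at 0 the founder pool and the
mosaics are both memoryless and inter-locus $r^2$ collapses exactly to the
$1/n$ sampling floor — both regimes are tested. Ancestry proportions are
symmetric-Dirichlet (`admixture_conc`, default 0.2: mostly assignable
accessions with a visible admixed fringe).

Phenotypes: `n_qtl` causal loci receive effects drawn multivariate-normal
across environments and then recalibrated so the in-sample covariance of
the true breeding values matches the target genetic correlations and
variances *exactly* (the recolouring stays inside the column space of the
QTL dosages, so true breeding values still factor exactly through the
stored QTL effects). Residual variance per environment is
$\sigma^2_g(1-H^2)/H^2$; block effects are drawn at the configured
variance; checks are fixed genotypes with their own drawn values,
replicated in every block, never part of the prediction set. Field layouts
are a 1-replicate augmented design and a 2-replicate alpha-lattice.

What the generator does *not* emulate: coalescent genealogies or a
recombination map (LD structure is tunable but stylised — short-range $r^2$
variance is smaller than in real panels), selection or pedigree structure,
non-additive genetic effects (tests that need epistasis construct it
explicitly), spatial field trends beyond block effects, and
missingness that is informative rather than completely at random. Passing
tests on this generator therefore demonstrate correctness of the
estimators and the qualitative behaviours — trait-specific selection helps
under sparse architectures; CV2 multi-environment prediction beats CV1 when
genetic correlation is high — not the absolute predictive abilities of any
particular real panel, which depend on LD and structure details no
simulator of this kind reproduces.

## Problem sizes in the test suite

Unit tests run on panels of 12–200 accessions and tens to hundreds of
loci. The acceptance-style checks use the sizes at which their statistical
claims are stable: ridge equivalence at 30 × 100; pruning guarantees on a
250-locus chromosome; GWAS calibration over 30 null panels of ~250 tested
loci; EM-REML heritability recovery at n = 300 over 30 seeds; Gibbs
genetic-correlation recovery at n = 150 over 10 seeds at chains of
5,000/1,000; the two directional cross-validation findings at n = 300 with
a 3,000-marker panel and 20 replicates. These sizes are the package's
choices for stable, repeatable statistical assertions.

## Known limitations

* EM-REML converges slowly near variance boundaries (it flags rather than
  accelerates); AI-REML would be faster but is not monotone.
* The LD-pruning representative rule can, in contrived cases, make kept-set
  size non-monotone in the threshold when a MAF filter follows (a
  representative chosen for low missingness may fall below the MAF cut);
  with realistic data the grid is monotone, as the tests exercise.
* P3D/EMMAX holds variance components fixed across markers; for markers of
  very large effect exact per-marker REML would give slightly different
  p-values. This matches the behaviour of the standard MLM tools it
  mirrors.
* The Kronecker sampler assumes a shared kernel across environments and
  diagonal residual covariance; environment-specific kernels are out of
  scope.
* `run_pipeline` orchestrates one trait per field-book `trait` label and
  runs scenarios sequentially; there is no built-in parallelism.
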