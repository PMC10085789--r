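---
title: "Models and methods for tester-by-line hybrid genomic prediction"
author: "hybridGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tester-by-line hybrid genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGP)
```

# The setting

Hybrid breeding under cytoplasmic-nuclear male sterility (CMS) crosses
male-sterile female (A) testers to fertility-restoring male (R) lines. A
tester-by-line factorial — every male crossed to the same small set of
female testers — produces half-sib hybrid families and supports the
classical decomposition of hybrid performance into general combining
ability (GCA, the parent's average contribution, largely additive) and
specific combining ability (SCA, the cross-specific deviation, dominance
and epistasis in origin). With dense markers on the inbred parents, hybrid
genotypes follow deterministically (each F1 dosage is the mean of its
parents' dosages) and genomic BLUP can predict the value of crosses that
were never made.

hybridGP implements that workflow end to end: marker QC, F1 construction,
VanRaden relationship matrices, a REML engine for the mixed models, the
derived genetic statistics (heterosis, heritability, variance shares,
hybrid genetic values), and cross-validation schemes that vary how much of
a validation hybrid's parentage is phenotyped in training.

# The mixed models

All analyses reduce to Gaussian mixed models
$y = X\beta + \sum_k Z_k u_k + e$, $u_k \sim N(0, \sigma^2_k K_k)$,
$e \sim N(0, \sigma^2_e I)$, with $K_k$ an identity, a supplied
relationship matrix, or a Kronecker product of structures.

* **Within-year spatial adjustment.** Per year:
  $y = \mu + \text{rep (fixed)} + g\,(\text{random, } I) +
  \text{block-in-rep}\,(\text{random, } I) + e$. The adjusted value is
  $\hat\mu + \mathrm{BLUP}(g)$; parents and hybrids enter one fit so their
  adjusted values are comparable.
* **Hybrid phenotypic model** (hybrids only): year fixed; hybrid ($I$ or
  $G_H$), hybrid-by-year ($I_E \otimes G_H$ in the genomic variant, with
  the year block an unscaled identity) and block random. It supplies the
  variance components for the heritabilities.
* **GCA model**: tester and year fixed; male GCA with $G_M$, male-by-year
  with $I_E \otimes G_M$, block random. The **GCA+SCA model** adds the
  tester-by-male SCA with $G_F \otimes G_M$ and its year interaction with
  $I_E \otimes G_F \otimes G_M$. Identity twins of both models replace all
  relationship matrices by identities; they define the "observed" BLUP
  values used in validation.

Hybrid genetic values are reconstructed as
$\hat y_{ij} = \hat\mu + \hat f_i + \hat m_j (+ \hat s_{ij})$. Because the
fixed effects use treatment contrasts (first level as reference), $\hat
f_i$ is the tester contrast — zero for the reference tester — and
$\hat\mu$ absorbs the reference tester and reference year. The
reconstruction is coding-dependent and therefore documented; values are
invariant to the choice within a fit.

## Heritabilities

With $n_E$ years and $n_R$ replications,
$$H^2 = \frac{\sigma^2_H}{\sigma^2_H + \sigma^2_{HE}/n_E +
\sigma^2_e/(n_E n_R)},\qquad
h^2 = \frac{\sigma^2_{Ha}}{\sigma^2_H + \sigma^2_{HE} + \sigma^2_e},$$
where $\sigma^2_H, \sigma^2_{HE}, \sigma^2_e$ come from the identity fit
and $\sigma^2_{Ha}$ from the genomic refit. The $h^2$ denominator
deliberately uses the identity-fit components without the $1/n_E$
scalings — the convention of the trial design this package follows — and
we do not substitute a plot-basis variant under the same name. Note the
two formulas are therefore not on the same denominator scale. A further
caveat: $\sigma^2_{Ha}$ comes from a model whose covariance is an
unstandardized VanRaden matrix, and variance components are only
comparable across relationship matrices of compatible scale. On strongly
structured panels the hybrid GRM's scale can drift far enough from the
identity's that $h^2$ computed this way exceeds $H^2$; the package
reports the formula as defined rather than silently rescaling $G_H$.

## The REML engine

The engine works in Henderson's mixed-model equations with
variance-ratio-scaled covariances, which keeps the factorized system at
the size of the random-effect dimension rather than the number of plots.
Updates are average-information (AI) steps with step halving; when an AI
step fails to increase the restricted likelihood, an
expectation-maximization step (guaranteed ascent) is taken instead.
Numerical choices that matter:

* **Non-negativity** is enforced by projecting proposals onto a floor of
  $10^{-10}\,\mathrm{var}(y)$ (scaled so the floor is meaningful on any
  trait scale). A component pinned at the floor whose score points further
  downward is dropped from the AI system for that iteration (an active-set
  step); without this, boundary components force every AI proposal to be
  rejected and the fit crawls under EM. Components that finish on the
  floor are reported as 0.
* **Convergence** when the largest relative component change falls below
  1e-8 or the likelihood change below 1e-10, with a 200-iteration cap;
  non-converged fits return the best point with `converged = FALSE`.
* **Stabilization**: a supplied covariance with minimum eigenvalue below
  1e-8 gets $\max(0, -\lambda_{\min}) + 10^{-8}$ added to its diagonal at
  construction. This matters concretely: the VanRaden matrix of two
  opposite-homozygote inbred testers is exactly singular
  ($[[2,-2],[-2,2]]$), and the SCA Kronecker structures inherit the ridge.
* **AIC/BIC** are $-2\ell_R$ penalized by the number of *variance*
  parameters (BIC with $\log n$); fixed effects are identical across the
  GCA and GCA+SCA models, so within-engine comparisons are valid, and no
  cross-software comparability is claimed.
* **Level matching** between a supplied structure and the data is by id
  string, never by position; unmatched levels are an error, not a silent
  reorder.
* Kronecker level ordering: the left factor varies slowest, ids are
  `left:right`, and the factor-encoding step uses the same convention.

Two independent checks back the engine in the test suite: identity-structure
fits reproduce `lme4` (components, BLUPs and the log-likelihood including
constants), and on random small instances the log-likelihood at the
solution matches a Nelder-Mead search over a direct dense evaluation of
the restricted likelihood.

# The synthetic trial generator

`simulateParents()` and `simulateTrial()` generate the study the analysis
modules expect: 2 female testers crossed to `nMales` males (default 301),
evaluated over 2 years and 2 replications with blocks of about 30 plots
nested in replications, plus parent plots in the same trial so heterosis
is estimable. The generative phenotype model mirrors the GCA+SCA analysis
model: fixed tester and year shifts; male GCA; tester-by-male SCA;
male-by-year interaction (the single G-by-E variance is realised at the
male-by-year level, so the SCA-by-year truth is zero); block effects; and
plot error.

Defaults were chosen once to resemble a moderately heritable yield-like
trait and are not revisited: `varGcaMale = 1`, `varSca = 0.15` (a small
but nonzero SCA share, as factorial trials typically show), `varGxe =
0.4`, `varBlock = 0.3`, `varError = 1`, tester and year shifts of one
residual SD. `mu = 10` with `heterosisShift = 2.5` places the parental
per-se mean 25% below the hybrid mean, which yields mid-parent heterosis
in the 30–40% range typical of grain yield in CMS cereal hybrids.

Male GCA is marker-determined by default (`gcaMode = "marker"`): a random
linear combination of centered male dosages, recentered and rescaled so
its sample variance equals `varGcaMale` *exactly* (this makes
variance-recovery tests sharp). Genomic prediction would be meaningless if
the truths were orthogonal to the markers.

Parents are fully inbred (dosages 0/2); `residualHet` flips a fraction of
calls to dosage 1 purely to exercise the F1-construction policy (expected
fractional dosage by default, or marker dropping in strict mode).

**Population structure.** Loci are drawn via a Balding-Nichols model:
ancestral frequencies from `mafRange`, subpopulation frequencies (default
5 subpopulations, `fst = 0.3`) diverged around them, parents assigned
round-robin. A panel with independent, structure-free loci makes all males
mutually unrelated, and then any scenario that relies on relationship
propagation to unphenotyped males (T1F, male-GCA masking) is trivially
uninformative; diversity panels of the kind this generator emulates are in
reality strongly structured, and the default `fst` is at the scale of
divergence between cereal races. Set `fst = 0` to study the unstructured
limit.

What the generator does *not* emulate: linkage and recombination (loci are
exchangeable given subpopulation frequencies), pedigree depth beyond
parents-to-F1, epistasis, multi-trait correlations, and the
maturity/height-informed blocking of real trials (blocks are random
partitions; the blocking covariate does not exist before phenotypes do).
Passing tests on synthetic data therefore demonstrate correctness of the
estimation machinery under the stated generative model, not performance on
any real panel.

# Cross-validation design

* **T2**: 20% of hybrids to validation, constrained so every validation
  hybrid's male keeps at least one hybrid (the other tester) in training.
  Hybrids whose male has a single cross are ineligible and logged.
  Sampling is unstratified by tester (the constraint, not stratification,
  is the defining feature).
* **T1F**: 20% of *males* to validation with all their hybrids — sampling
  at the male level is what guarantees that only the female testers are
  shared with training. For a balanced factorial this moves 20% of
  hybrids.
* **maleGCA**: a fixed number of males (60 at the full design size; scaled
  as ~20% of males in the demo) masked entirely; their GCA BLUPs are
  predicted through the relationship matrix.

Fold membership is a pure function of the iteration seed and the
lexicographically sorted hybrid list; iteration seeds run from
`seedStart` (default 123) upward, one per iteration. Predictive ability is
the Pearson correlation between predictions and full-data identity-model
BLUP values of the validation individuals; reliability is computed once
per trait and model from complete data as the squared correlation between
the genomic and identity hybrid values (or male GCAs), and prediction
accuracy is predictive ability divided by the square root of reliability.
Note that both predicted and observed hybrid values contain the tester
fixed effect, so between-tester separation contributes to the correlation
— which is why the package's null-case tests switch tester effects off.
Iterations whose REML fit neither converges nor ends at an interior point
are skipped and counted, never silently reused.

# Variance-share reporting

Proportion tables report each component over the sum of *all* estimated
components including the residual, so shares are internally comparable
across models. When shares are compared against generative truths (as the
test suite does at 2 testers x 200 males), the identity twins of the
models are used: under VanRaden scaling an inbred panel has mean diagonal
near 2, so genomic-fit variance components live on a different scale than
the generative variances and only the identity parametrization makes
"share recovered within 0.15" a well-posed statement.

# Problem sizes used by the checks

The packaged checks run at deliberately reduced sizes chosen to exercise
every code path at desk scale: oracle comparisons at up to 200
observations, share-recovery at 2 testers x 200 males x 1,000 markers
over 10 seeds x 3 settings, and scenario-ordering runs at 80 males x
2,000 markers with 20 CV iterations. The full-design defaults (301 males,
5,000 markers, 100 iterations) run unchanged — only longer.

# A short tour

```{r demo, eval = FALSE}
set.seed(1)
manifest <- runDemo(seed = 1)        # 80 males, 2000 markers, full pipeline
```

The demo writes every stage table (adjusted values, MPH/IMPH,
heritabilities, variance proportions, genetic values, per-iteration CV
results) under an output directory and prints the headline summaries; the
manifest records config hash, seeds, row counts and an md5 for every file.
Step-by-step use of the same machinery:

```{r steps, eval = FALSE}
cfg     <- simConfig(nMales = 80, nMarkers = 2000, seed = 1)
parents <- simulateParents(cfg)
trial   <- simulateTrial(parents, cfg)
crosses <- crossingTable(trial$design)

gM <- additiveGRM(parents[sprintf("M%03d", 1:80), ])
gF <- additiveGRM(parents[c("T1", "T2"), ])
gH <- additiveGRM(buildHybridGenotypes(parents, crosses))

heritabilities(trial$design, "Y", gH)[c("H2", "h2")]
ca <- combiningAbility(trial$design, gM, gF, "Y", includeSca = TRUE)
head(hybridGeneticValues(ca, crosses))
summarizeAccuracy(runCV(trial$design, gM, gF,
                        cvScheme("T2", nIterations = 20, model = "GCA")))
```

# Known limitations

* Residual variance is homogeneous across years; no spatial row/column
  models beyond block nesting; no multi-trait models; no Bayesian
  alternatives to REML.
* The grain-yield moisture standardization (fixed 14% basis before area
  conversion) is an industry-standard stand-in; field pipelines with a
  different bushel convention should derive GY upstream and pass it in.
* Female testers are mapped to their phenotyped isogenic maintainer lines
  through an explicit alias table; no attempt is made to model
  cytoplasm effects.
* With only two testers the female GCA is not estimable as a variance
  component; testers are fixed effects throughout, and the SCA structure
  over two inbred testers is rank-deficient by construction (handled by
  the documented stabilization, but SCA shares for such designs should be
  read with that in mind).
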