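---
title: "Models and methods behind stabQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stabQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stabQTL)
```

stabQTL implements a complete analysis chain for multi-environment trials
run under two nitrogen (N) fertilization levels: variance components and
heritability, Wricke ecovalence as a mappable stability trait, kinship-based
association scans, doubled-haploid (DH) interval mapping, QTL interval
construction from local LD decay, locus-stability classification, and
environment clustering. This vignette records the models, the parameters
that matter, and the design decisions taken where the methodology left
genuine choices open.

## The trial models

Four nested linear mixed models cover the designs that occur in such trial
series. In all of them the genotype terms are random and the N condition is
fixed (two levels, N1 = limiting, N2 = optimal):

* **multi-environment** (`multi_env_1`): trait = mean + genotype + N +
  trial + replicate-within-trial + G×N + G×T + G×N×T + residual. Fitted on
  all trials at once.
* **per-trial split plot** (`split_plot_3`): genotype + N + replicate + G×N.
* **per-trial alpha plan** (`alpha_plan_4`): adds block-within-replicate for
  incomplete-block layouts.
* **single environment** (`single_env_6`): genotype + replicate within one
  trial × N cell.

The matching heritabilities on the genotype-mean basis are

* multi-environment: $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times N}/n
  + \sigma^2_{G\times T}/t + \sigma^2_e/(t\,n\,r))$,
* per trial: $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times N}/n +
  \sigma^2_e/(n\,r))$,
* single environment: $h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e/r)$,

with $n$ N conditions, $t$ trials and $r$ replicates. Two deliberate
choices here. First, the multi-environment formula omits the three-way
$\sigma^2_{G\times N\times T}$ even though the model estimates it; the
component is reported separately rather than folded in. Second, when
replicate numbers differ across trials, $r$ is the harmonic mean of the
per-cell replicate counts, which is the value that keeps
$\sigma^2_e/(t\,n\,r)$ the right variance of a genotype mean.

### Estimation engines

The default engine is method-of-moments on the Henderson-III
expected-mean-squares equations: the analysis-of-variance mean squares (via
`aov`) are equated to their expectations under the unrestricted mixed-model
convention, where the coefficient of $\sigma^2_u$ in $E[MS_v]$ is
$N/\mathrm{levels}(u)$ whenever the factors of $v$ are a subset of those of
$u$. This is exact on the balanced layouts these designs describe, and the
balance is checked. One subtlety: the model contains no N×T term, so the
N×T stratum of the cell means belongs to the three-way interaction stratum
— this is also what REML estimates under the stated model, and the two
engines agree to numerical precision on balanced data with interior
solutions.

For unbalanced data (alpha plans, missing plots) the package re-estimates
by EM-REML on the mixed-model equations (tolerance 1e-8 on the components,
at most 500 iterations, dense algebra sized for single-trial problems).
Negative moment estimates are clamped to zero and the pre-clamp value is
kept for diagnostics. The fixed N contrast is reported from generalized
least squares, which in balanced layouts is the N-level mean difference.

Genotype estimates for mapping come in two kinds: least-squares adjusted
means (genotype predictions averaged over the observed design cells; equal
to raw means when balanced) and BLUPs, obtained by shrinking the adjusted
means towards the population mean with the genotype-mean reliability
implied by the fitted components. Shrinkage is monotone, so orderings are
preserved. Genetic correlations between traits are method-of-moments ratios
of between/within-genotype mean cross-products; as moment ratios they can
exceed 1 in magnitude and are intentionally not clamped.

## Ecovalence as a trait

For the genotype × treatment mean table $Y$, Wricke's ecovalence
$W_i = \sum_j (Y_{ij} - Y_{i\cdot} - Y_{\cdot j} + Y_{\cdot\cdot})^2$ is the
genotype's share of the double-centred interaction sum of squares; the
treatment axis is either the two N levels (G×N model) or the trials (G×T
model). Cells are built by averaging replicates first, then trials — the
averaging order is fixed and documented because it matters for unbalanced
data. Genotypes with an empty cell are dropped by default
(complete-case); column-mean imputation is available. $W$ is invariant to
adding constants to any row or column, and $\sum_i W_i$ equals the total
interaction sum of squares exactly — both are enforced by tests.

A coding fact worth knowing when simulating: for a biallelic locus,
$W_i$ responds to the *squared deviation* of the allele dosage from its
mean, $(x_i - \bar x)^2$. At allele frequency exactly 0.5 in a fully
homozygous population this is constant, making a crossover interaction QTL
invisible to ecovalence mapping; at intermediate but asymmetric frequencies
the signal is strong. The reference simulation therefore places interactive
QTL at MAF 0.15–0.35.

Nitrogen stress is classified from the N nutrition index at bolting:
below 0.90 = stressed, below 0.75 = intensely stressed, boundaries strict
("below"), so exactly 0.90 is no stress and exactly 0.75 is moderate.
Composite traits are derived as SN = SY × 100000 / TSW (seeds/m², SY in
t/ha, TSW in g) and O/Pr = O / Pr, with zero denominators propagating to
missing values rather than errors.

## Association and linkage scans

The association scan fits $y = \mu + x\beta + u + e$ with
$u \sim N(0, \sigma^2_g K)$, $K$ an identity-by-state kinship (sharing
scores 1 / 0.5 / 0 per marker; the methodology names IBS without a formula,
so this standard scoring is used). The variance ratio is profiled exactly
by REML over the spectral decomposition of $K$ and, by default, estimated
once on the null model and reused for all markers (the P3D shortcut);
per-marker re-estimation is available. Each marker then gets a
generalized-least-squares effect, a Wald test, and the share of variance it
explains on the decorrelated scale (stated explicitly because "marker R²"
has no unique definition). With $K = I$ the scan reduces exactly to
ordinary regression — a tested invariant. FDR control is
Benjamini–Hochberg at a configurable threshold defaulting to 0.15; grouping
of individuals (compression) is deliberately not implemented since the
stated model is the plain random-kinship MLM.

Significant SNPs are grown into QTL intervals in two steps. SNPs on a
linkage group are joined by single linkage when their pairwise $r^2 \ge
0.2$ *or* their cM gap is within the linkage-group-wide LD extent; the
cited clustering procedure defines the "local" LD window by the cluster
midpoint, which is circular at clustering time, so the group-wide extent
drives the joining and the local extent only the boundary extension. Each
cluster is then extended on both sides by the local LD-decay extent at
$r^2 = 0.2$, fitted on all markers inside a window covering 5 % of the
linkage-group length centred at the cluster midpoint (falling back to the
genome-wide extent, with a warning, when the window holds fewer than 10
pairs). LD decay follows the Sved curve $E[r^2] = 1/(1 + 4 N_e c)$ with $c$
in morgans, fitted by bounded least squares with multi-starts at
$N_e \in \{50, 500, 5000\}$, ties towards the smaller $N_e$; the extent at
threshold $\theta$ is $c = (1/\theta - 1)/(4 N_e)$. The peak of a cluster
is the lowest-q SNP, ties broken by larger |effect| then lower cM.

For DH populations the scan is Haley–Knott regression on expected
genotypes at a 1-cM grid (conditional carrier probabilities from flanking
markers under the Haldane map function — chosen because no interference
model is stated and it matches the independence assumptions of the
simulator), with forward-selected marker cofactors entering at the
genome-wide permutation threshold (default 1000 permutations, level 0.05,
at most 10 cofactors) and a rescan that drops cofactors within 10 cM of
the test position. Confidence intervals are 1.5-LOD supports — an
assumption, since the original interval rule is unstated. The reported
effect is the additivity (half the parental class difference, which is the
regression coefficient on ±1 coding) and the favorable parent is the
class with the higher trait value.

## Locus stability classification

After projection onto a common map (piecewise-linear interpolation between
shared anchor markers; positions outside the anchor span are flagged
unprojectable and excluded from overlap analysis), intervals from the three
mapping datasets are overlaid. An additive QTL overlapping nothing is a
stable additive locus; overlap with only G×N (G×T) intervals marks
N-modulated (trial-modulated) additive loci, with both marks modulation by
both; interaction intervals that touch no additive QTL merge transitively
into interaction-specific loci. Two boundary rules the classes need:
an interaction QTL overlapping several additive QTL contributes to each
one's class but becomes a member of the additive locus it overlaps most
(so membership is a partition); a merged interaction-only locus containing
both G×N and G×T members takes its majority type, ties going to G×N.
These are the package's own tie-breaks; the class definitions do not
determine them.

Environment clustering works on genotype × environment trait-mean vectors
(environments = trial × N combinations), traits centred and scaled
(standardization is a choice; the source names only "hierarchical
clustering"), PCA, then Ward clustering (`ward.D2`) of the first five
component scores, cut at a configurable k defaulting to 3. Clustering is
observation-level with environments assigned by plurality, because the
alternative (clustering environment centroids) discards the within-
environment spread that the plurality rule exploits. Environments missing
a requested trait are excluded and reported. QTL-by-cluster consistency
merges per-environment intervals transitively and histograms the number of
distinct clusters per merged locus.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions everything else is validated under:

* **Maps**: uniform or random marker spacing; 19 linkage groups get the
  A1–A10/C1–C9 naming of the *B. napus* subgenomes; physical positions at
  a constant 10⁵ bp/cM (a typical plant genome-wide average), made strictly
  increasing.
* **DH lines**: one recombinant gamete doubled; crossovers between adjacent
  markers with Haldane probability; linkage groups independent.
* **Panels**: founder haplotypes with per-marker frequencies uniform on
  (0.1, 0.9); individuals are founder mosaics with an expected
  `admixture_alpha` switches per morgan (default 2), which yields LD that
  decays with map distance and non-trivial kinship. This mosaic is a
  pragmatic stand-in: it does not reproduce coalescent LD spectra,
  selection, or pedigree structure, so passing tests demonstrate correct
  *method* behaviour, not realism of any particular germplasm panel.
* **Phenotypes**: plot values follow the multi-environment model exactly;
  background G×N, G×T and G×N×T deviations are i.i.d. normal at their
  target variances, and QTL-driven effects (additive, N-conditional,
  trial-specific) add on top, counting toward the same components — which
  is what lets tests separate background from mappable interaction. N is a
  fixed shift (as in the models); NNI values are design metadata only. A
  configurable fraction of records can be masked to exercise missing-data
  paths (default 0).

The reference scenario (`simulate_stability_scenario`) packs 200 inbred
panel lines on five 90-cM groups of 45 markers, five trials × two N levels
× two replicates, a purely additive QTL, a crossover N-interactive QTL
(opposite allelic effects under N1/N2, zero marginal effect) and a
crossover trial-interactive QTL (trial effects summing to zero), each
explaining roughly 15–40 % of its own mapping dataset's variance over a
polygenic background (σ²_G = 0.4, σ²_G×N = σ²_G×T = 0.05, σ²_G×N×T = 0.02,
σ²_e = 0.2). Crossover interactions are used because a locus whose effect
merely switches on under N1 also carries a marginal effect and is then
*correctly* classified as N-modulated additive rather than
interaction-specific.

## Numerical choices and problem sizes

Tolerances: EM-REML 1e-8 on components; the Sved fit polishes the best
multi-start to ~1e-9 relative; ecovalence identities are asserted at 1e-9
relative. Degenerate inputs are contracts, not crashes: monomorphic
markers are skipped with a reason, zero-variance phenotypes yield an empty
scan, a single treatment column gives all-zero ecovalence with a warning,
and a kinship matrix that is not positive semi-definite after a 1e-8
jitter is an error. Seeds are threaded explicitly into every stochastic
function, and identical inputs with identical seeds give bit-identical
outputs.

The shipped tests and the acceptance script run everything at sizes chosen
to make sampling error small relative to the asserted tolerances while
staying desk-scale: 2000 gametes for recombination-fraction checks,
200 genotypes × 5 trials × 2 N × 2 replicates for variance-component and
heritability recovery, 10 000 independent markers for scan calibration,
150–250 individuals for power and interval oracles, and 10 seeds for every
rate-style claim. These are the package's own validation conditions, stated
here so that rerunning them reproduces the same regime.

## Known limitations

* No spatial field-trend modelling, heterogeneous residual variances, or
  average-information REML; the EM-REML fallback is sized for single-trial
  problems, not genome-scale random regressions.
* Ecovalence is computed from raw genotype × treatment means, not
  model-adjusted means (the alternative is one line of code away via
  `genotype_estimates`, but raw means are the default and the documented
  behaviour).
* The association model carries kinship only — no fixed structure
  covariates, no multi-locus models.
* Haplotype-phase r² is not implemented; LD is dosage (composite) r²,
  which is what the downstream Sved fit consumes.
* Finlay–Wilkinson slopes, Shukla variance and rank-based stability
  statistics are out of scope; ecovalence is the single stability measure.
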