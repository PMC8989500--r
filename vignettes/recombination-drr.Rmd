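---
title: "Estimating and predicting recombination rate variation in a double round-robin design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and predicting recombination rate variation in a double round-robin design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombkit)
```

## The problem

Meiotic recombination reshuffles alleles; its rate varies among genotypes
of the same species, and that variation is itself heritable. A double
round-robin (DRR) crossing design — every parent mated to several ring
neighbours — produces a set of biparental populations in which each parent
occurs repeatedly with different partners. That repetition is what lets the
cross-level recombination rate $c_{ij}$ of a population from parents $i$
and $j$ be decomposed as

$$ c_{ij} = \mu + \mathrm{GRE}_i + \mathrm{GRE}_j + \mathrm{SRE}_{ij}, $$

a general recombination effect (GRE) per parent and a specific
recombination effect (SRE) per parental combination. recombkit implements
the whole chain: a meiosis-level simulator of such an experiment with known
GRE/SRE ground truth, genotype cleaning and anchored linkage maps for each
recombinant inbred line (RIL) population, Marey-map spline estimation of
windowed recombination rates, REML/BLUP estimation of the decomposition,
genomic prediction (GBLUP/RR-BLUP) of rates and GREs with two
cross-validation designs, and crossover-count QTL scanning.

## The simulator: what it emulates and what it does not

`simulate_drr_experiment()` emulates a barley-like experiment: 23 fully
homozygous parents, 45 DRR crosses, seven 600 Mbp chromosomes with markers
on a regular grid (0.4 Mbp spacing by default, about 1,500 per
chromosome), and populations of 35–146 RILs (or a fixed size) selfed by
single-seed descent to S4.

**Landscape.** The per-cross landscape is multiplicative on a shared
baseline, $L_{ij}(w) = L_0(w)\,e^{g_i + g_j + s_{ij}}$, over 10 Mbp
windows. The log-additive form keeps rates non-negative while the
analysis-side model stays additive; at the simulated effect sizes
($\tau_g \approx 0.106$ on the log scale) the distinction is second-order.
The baseline is U-shaped along each chromosome
(`distance-from-centromere^3.5 + 0.002`, rescaled), which gives a broad
pericentromeric plateau more than 20-fold below the genome mean — the
defining property of a suppressed pericentromere in a large-genome cereal —
and a genome-wide mean of 0.45 cM/Mbp, the magnitude reported for
cultivated barley.

**Effect sizes.** `tau2_g = 0.0113` makes the cross-level GRE variance on
the rate scale $\approx (0.45)^2 \tau_g^2 \approx 0.0023\,$ (cM/Mbp)$^2$,
the magnitude of the published genome-wide GRE variance, and
`tau2_s = tau2_g / 8` fixes the 8:1 GRE:SRE variance ratio. Both draws are
rescaled to their nominal variances exactly, so the ratio is a controlled
condition of every simulated experiment rather than a random draw.

**Genetic basis.** By default the per-parent effects are polygenic: a sum
of small independent effects of every founder marker allele
(`gre_basis = "markers"`). This reflects the premise that variation in the
recombination machinery is allelic and spread over the genome, and it is
what makes genomic prediction of parents without phenotyped crosses a
meaningful exercise. With unrelated founders and dense markers, the
theoretical accuracy of predicting a completely untested parent from ~20
training parents is modest — real germplasm adds population structure and
long-range LD that the simulator deliberately does not model. SRE effects
are drawn independently of the genotypes (non-additive by construction).

**Meiosis.** Crossovers per gamete are Poisson with mean equal to the
cross landscape's genetic length in Morgans and positions drawn
proportionally to the landscape (Haldane model, no interference, matching
the Haldane map function used on the analysis side). Single-seed descent
runs `generations = 5` meiosis rounds (F2 plus four selfings, residual
heterozygosity $2^{-5} \approx 3.1\%$). The simulator records, per RIL and
chromosome, the number of crossovers observable at marker resolution
(transitions between opposite homozygous founder-origin states), the
oracle used by the crossover-counting tests.

**What passing tests do not show.** The simulator has no genotyping-error
model beyond missingness and quality scores, no segregation distortion
mechanism, no crossover interference, no structural variants, and no
environment. Results on it validate the estimation chain's correctness and
calibration, not robustness to those real-data features.

## Rate estimation: maps, Marey splines, windows

Within each population, markers are recoded to parental origin (markers
with identical or non-homozygous parent calls are dropped), cleaned
(quality < 0.7; marker missingness > 10%; RIL missingness or
heterozygosity > 10% — all strict inequalities on the removal side), and
anchored to the physical order. Adjacent-marker recombinant fractions $R$
on fully informative pairs are corrected for the map expansion of selfed
RILs, $r = R / (2 - 2R)$, and accumulated with the Haldane map function.
Two numerical points deserve notice:

* *Finite-generation contraction.* The $R_\infty = 2r/(1+2r)$ relation is
  the fixed point of the selfing recurrence. At S4 roughly 14% of the
  asymptotic junction density is still hidden in unresolved heterozygous
  regions, so estimated maps (and therefore rates) are contracted by a
  common factor relative to the per-meiosis truth. Because the factor is
  shared across populations it cancels from variance ratios, rankings and
  prediction abilities; absolute simulated rates read about 15% below the
  generating landscape. The same convention (and the same contraction) is
  inherent in any S4-genotyped RIL analysis corrected with the
  fully-inbred formula.
* *Gap chaining.* Adjacent pairs with fewer than 10 informative RILs get
  their distance from the nearest flanking informative pair, distributed
  over the gap proportionally to physical length; a chromosome with no
  such bridge raises an error naming the gap.

The Marey map (genetic versus physical position of the map bins) is
filtered with a running-maximum rule: a point more than 2 cM below the
running maximum of retained points is removed; smaller diversions are
tolerated. A cubic smoothing spline of cM on Mbp is then fitted per
chromosome with the smoothing parameter chosen by generalized
cross-validation, with two automated adjustments where a manual analyst
would intervene:

* *Equivalent-df band.* GCV on noisy Marey maps is erratic — it
  near-interpolates one chromosome (df ≈ 100) and over-smooths the next.
  The boundary behaviour of the spline then varies by population, which
  injects population-specific error into genome-wide rates. The chosen df
  is clamped into `[8, 25]` when GCV leaves that band; within the band the
  fit is insensitive to the exact value.
* *Monotonicity by clipped integration.* The evaluated curve is the
  integral of the fitted derivative clipped at zero, which is monotone by
  construction and leaves window rates non-negative. Escalating the
  smoothing until the raw spline is exactly monotone is deliberately *not*
  done: monotonicity is not monotone in the smoothing parameter, and the
  first exactly-monotone fit typically loses 20–25% of the chromosome's
  genetic length at the ends, which we measured to destroy the GRE/SRE
  variance decomposition. Smoothing is escalated only when clipping would
  remove more than `max_clip_cm = 2` cM — the same scale as the Marey
  tolerance, i.e. the size of diversion the pipeline already accepts.

Window rates on the half-open 10 Mbp grid are mean slopes
$(\hat f(\text{end}) - \hat f(\text{start}))/\text{width}$, evaluated
within the spline's support — mean slopes are exactly additive, so window
rates times widths telescope to the chromosome's fitted genetic length
(the conservation property tested at 2%). A pointwise-derivative variant
(`method = "midpoint"`) is exposed. A terminal window with no Marey points
takes the derivative at the mean position of the five nearest points; the
last partial window is normalized by its true width. Chromosome rates are
plain means of window rates and the genome-wide rate is the unweighted
mean of chromosome means.

The consensus map integrates the cross-population mean window rates to
give every marker a consensus cM position; the pericentromere of a
chromosome is the maximal contiguous window run containing the centromere
at or below 1/20 of the genome-wide mean.

## The GRE/SRE model and its identifiability

`fit_gre_sre()` fits
$c = 1\mu + Z_{\mathrm{GRE}} u_{\mathrm{GRE}} + Z_{\mathrm{SRE}} u_{\mathrm{SRE}} + e$
with $u_{\mathrm{GRE}} \sim N(0, A\sigma_a^2)$,
$u_{\mathrm{SRE}} \sim N(0, D\sigma_d^2)$, $e \sim N(0, I\sigma_e^2)$, by
average-information REML with an EM fallback, non-negativity by projection
(components within $10^{-5}$ of zero relative to the phenotypic variance
are tested against the boundary and pinned when the likelihood does not
object), a convergence tolerance of $10^{-8}$ on relative component
changes, and — for ridge-shaped likelihoods such as a cross relationship
matrix close to the identity — a derivative-free polish on the log scale.
BLUPs come from $\hat u_k = \sigma_k^2 G_k Z_k' P y$, which the tests
verify against an independently assembled dense mixed-model-equation
solve.

**A structural fact about the identity-mode fit.** With one phenotyped
observation per cross and $D = I$, the SRE covariance equals the residual
covariance: the restricted likelihood is exactly flat along
$\sigma_d^2 + \sigma_e^2 = \text{const}$, and no algorithm can separate
them — any reported split is an artefact of starting values. recombkit
detects this case, fits the two-variance model, and attributes the entire
cross-level variance to the SRE (`sigma2_e = NA`, `confounded = TRUE`).
The scientific reading: a cross-level rate estimated from a finite RIL
population carries estimation error that is indistinguishable from a
specific parental-combination effect, so the reported
$\hat\sigma^2_{\mathrm{SRE}}$ is an upper bound inflated by that error
(about 20% under the default simulation conditions). Broad-sense
heritability $H^2 = (\sigma^2_{\mathrm{GRE}} + \sigma^2_{\mathrm{SRE}}) /
(\sigma^2_{\mathrm{GRE}} + \sigma^2_{\mathrm{SRE}} + \sigma^2_e)$ is
therefore not informative from a confounded fit and is returned as `NA`
there; on explicitly supplied components it is plain arithmetic. In
genomic mode ($A$, $D$ from markers) all three components are estimable,
though the $D$-versus-$I$ contrast is weak for unrelated founders and
boundary fits do occur.

## Genomic prediction

The additive genomic relationship matrix follows VanRaden's first method
with allele frequencies from the supplied (training) individuals; for
fully homozygous inbreds its diagonal sits near 2 under this centring. The
cross-level dominance-type matrix is built from parental additive
relationships, $D_{(ij),(kl)} = (A_{ik}A_{jl} + A_{il}A_{jk})/4$, rescaled
to unit mean diagonal — a construction we validate only through its
self-consistency (it reduces to the identity for unrelated parents) and
simulation behaviour. RR-BLUP solves the marker-effect mixed-model
equations with ridge $\lambda = \sigma_e^2 / \sigma_m^2$ and is the exact
dual of GBLUP at matching variance components (tested to $10^{-6}$).
BLUPs extend to unphenotyped individuals (RILs, a diversity panel) through
$u_{\text{new}} = A_{\text{cross}} A^{-1}_{\text{train}} u_{\text{train}}$,
and cross GEBVs are $\hat\mu + \mathrm{GRE}_i + \mathrm{GRE}_j$ over all
$n(n+1)/2$ unordered pairs with self-pairs.

Two cross-validation designs mirror the two practical questions. Fivefold
CV (populations split into five subsets, each once the validation set,
with 4, 3 or 2 of the remaining subsets as training — 36/27/18 populations
at the 45-cross scale) asks how well rates of *new crosses among tested
parents* are predicted. Leave-parents-out (all populations of 3 or 5
randomly chosen parents held out) asks about *untested parents*; the
held-out parents appear in no training population, and their `r_GRE` is
computed over exactly those parents. Medians across runs are the headline
statistic. Marker thinning (one random SNP per 1/5/10 Mbp bin, re-drawn
per run) is available in both designs. On the default simulated preset the
fivefold medians decrease as the training set shrinks and leave-parents-out
sits roughly 0.1 below fivefold at comparable training size.

Zou's modified-asymptotic confidence interval for a difference of two
correlations (independent and overlapping-dependent variants) supports
comparing prediction abilities between scenarios.

## Crossover counts and the QTL scan

`count_crossovers()` counts transitions between opposite homozygous states
in physical order, skipping missing and heterozygous calls — at S4 a
residual heterozygote is ambiguous between zero and one extra crossover,
so the minimal-transition convention is used and is tested against both a
brute-force enumeration and the simulator's recorded truth. The outlier
rule builds a unit-width histogram from the minimum count, takes the last
bin `K` of the first maximal run of consecutive occupied bins, and flags
counts exceeding `K + 2`; reading "last consecutive bin" as the end of the
first occupied run is an interpretation, and the slack is configurable.

The multi-population scan is a simplified cross-specific model, not a
re-implementation of any particular mapping package: at each position,
`CO ~ population + population:dose` against `CO ~ population` by F test
(doses from the nearest marker per population; populations monomorphic at
the position drop their interaction column), with the genome-wide
threshold at the 0.95 quantile of the permutation-maximum null under
within-population phenotype permutations (1,000 permutations at full
scale; tests use 80–150). Its type-I behaviour and power are exercised at
reduced scale in the test suite (4–5 populations of 40–60 RILs, 10–15
positions), sizes chosen to keep the default test run fast.

## Problem sizes used by tests and the acceptance script

The parameter-recovery study runs the full chain on 30 replicate
experiments at the study scale (23 parents, 45 crosses, 100 RILs per
population, 7 × 600 Mbp chromosomes, 1,501 markers each); the replicate
2.5% and 97.5% quantiles of the estimated variance ratio bracket the
simulated 8. The identity-mode ratio estimate is attenuated (typical
medians 5–6.5 rather than 8) because the SRE component absorbs the
crossover-sampling error of rates estimated from 100 RILs; the replicate
distribution is wide and its upper tail extends well past 8. Cross-validation summaries use 10 repeats (fivefold) and 50
repeats (leave-parents-out) on one replicate experiment; most unit tests
run on two-chromosome genomes of 60–150 Mbp. These sizes are the package's
choices for a reproducible desk-scale analysis; all are parameters, and
the full-scale settings (100 and 1,000 repeats) are one argument away.

## Known limitations

* Absolute rate levels from S4 genotypes are contracted ~15% relative to
  per-meiosis truth (see above); comparisons and ratios are unaffected.
* The identity-mode SRE variance includes rate-estimation error
  (confounding is structural, not numerical).
* The simulator's unrelated founders make untested-parent genomic
  prediction conservative relative to structured germplasm.
* No crossover interference; map functions other than Haldane/Kosambi are
  not provided.
* De novo marker ordering is out of scope — maps are anchored to the
  physical order, which is the regime where genetic/physical collinearity
  is already high.
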