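---
title: "Methods: population genomics along an aridity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics along an aridity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aridgen` analyses how genetic diversity and population structure relate to
a climatic aridity gradient. The sampling design it assumes is
hierarchical: sites (populations) along the gradient, social colonies
within sites, diploid individuals within colonies, genotyped at biallelic
SNPs and sequenced for one mitochondrial gene. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The Aridity Index

Sites are characterised by the ratio of water supply to atmospheric
demand. For each month we compute Magnus-form relative humidity from dew
point and air temperature,

$$\mathrm{RH} = 100 \cdot 10^{\,7.591386\left(\frac{d2m}{d2m + 240.7263} -
\frac{T_{air}}{T_{air} + 240.7263}\right)},$$

then Romanenko potential evapotranspiration
$\mathrm{PET} = 0.00006\,(100-\mathrm{RH})\,(25+T_{air})^2$, and finally
$\mathrm{AI} = \sum t_p / \sum \mathrm{PET}$ over complete calendar years.

Three points deserve care:

* **Units.** The Romanenko constant does not pin PET to a depth unit. The
  package therefore treats PET and precipitation in one common depth unit
  and regards AI as meaningful only as a ratio; `aridity_index()` is
  invariant to a common rescaling of both.
* **Aggregation.** "Annual AI" over a multi-decade series is ambiguous.
  The default computes one AI per calendar year and averages
  (`aggregation = "annual_mean"`); pooled multi-year sums
  (`"pooled"`) and a `years =` restriction (e.g. the most recent year) are
  provided because published site tables sometimes report a single recent
  year.
* **Supersaturation.** Gridded reanalysis products occasionally report dew
  point above air temperature; RH is clamped at 100 with a warning rather
  than propagated past 100 into a negative PET.

Classification thresholds are configurable; the defaults (arid < 0.10 ≤
semi-arid < 0.25 ≤ mesic) are chosen to reproduce the transect labels that
motivated the package (AI 0.04 and 0.07 arid, 0.11 semi-arid, 0.42 and
0.86 mesic). They are deliberately *not* the UNEP bins, which would place
0.11 in "arid"; the boundary behaviour (half-open intervals) is tested
explicitly.

## Mitochondrial haplotypes

Sequences identical over their mutually comparable sites share a
haplotype; sites with `N` or a gap in either sequence are skipped
(pairwise deletion, the default) so partially ambiguous Sanger reads do
not inflate the haplotype count. Complete deletion is available by flag.
Haplotype ids are assigned by first appearance, so numbering is stable.

Nucleotide diversity is the mean over unordered pairs of per-site
differences, each pair divided by its own comparable length. Tajima's D
uses the mean pairwise *count* $\hat k$ against $S/a_1$ with the standard
coefficient chain $(a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2)$; it is
undefined at $S = 0$ and the implementation refuses rather than returning
0.

The minimum spanning network is the union of **all** minimum spanning
trees of the haplotype distance matrix (the ε = 0 network). An edge of
weight $w$ is kept exactly when its endpoints lie in different components
of the graph restricted to edges of weight < $w$ — the cycle property —
so ties are resolved by inclusion, never dropped. Tests compare this
against exhaustive enumeration of every spanning tree for up to seven
haplotypes.

Non-synonymous annotation translates haplotypes and a reference under the
vertebrate mitochondrial code (NCBI table 2, via Biostrings); codons
containing `N` or a gap are skipped, and an internal stop in the reference
only warns (partial gene fragments are common).

## Nested AMOVA

`nested_amova()` partitions a matrix of squared molecular distances across
sample → population (→ group) levels by the sums-of-squared-distances
decomposition with unequal-group-size coefficients, yielding variance
components $\sigma_a^2, \sigma_b^2, \sigma_c^2$ and
$\Phi_{CT}, \Phi_{SC}, \Phi_{ST}$. Design choices:

* Negative components are reported as computed and percentages use the raw
  components (an optional truncate-at-zero mode exists, off by default):
  transparency beats cosmetic non-negativity, and published tables do
  print negative entries. The column some tables label "standard
  deviation" is not defined in any methods text we know; the package
  reports the standard deviation of each index's permutation distribution
  (`perm_sd`) and says so.
* Permutation schemes are level-appropriate: Φ_ST permutes individuals
  across the whole data set (hierarchy labels move together so nesting is
  preserved), Φ_SC permutes individuals among populations within their
  group, Φ_CT permutes whole populations among groups. P-values use the +1
  correction, so 999 permutations can return exactly 0.001. With few
  top-level units the number of distinct population-to-group assignments
  is computed and a warning states the attainable minimum p.
* A 3-level call whose top level holds a single group reduces to the
  2-level analysis (with a message) instead of failing: the two must agree
  in that limit, and the tests assert they do.
* Distances are injectable: SNP analyses use squared Euclidean dosage
  distance on pairwise-complete loci (rescaled to the full locus count);
  mtDNA analyses use pairwise difference counts.

## The diversity panel

Per locus, $H_o$ is the called heterozygote fraction, $H_e = 2p(1-p)$, and
$uH_e = H_e \cdot 2N/(2N-1)$ with $N$ that locus's called sample size —
the factor is exact at every locus and the panel checks
$uH_e \ge H_e$. $F_{is} = 1 - \overline{H_o}/\overline{uH_e}$ with means
across loci. Loci monomorphic across the full data set are excluded by
default (configurable); the choice changes absolute values and is recorded
in the panel's provenance attribute.

Rarefied allelic richness uses hypergeometric rarefaction,
$A_r = \sum_a \left(1 - \binom{N-N_a}{g}/\binom{N}{g}\right)$, with $g$
defaulting to the locus-wise minimum copy count across populations
(maximises retained loci); a fixed global $g$ is available and refuses
when it exceeds the available copies. Private alleles count an allele for
a population when observed there and nowhere else, summed over loci.

Hardy–Weinberg: a 1-df chi-square against $p^2, 2pq, q^2$ expectations,
and a Monte-Carlo test that re-pairs the observed alleles into genotypes.
Rather than shuffling allele vectors in a loop, the heterozygote count is
sampled from its exact re-pairing distribution
$P(h) \propto \binom{n}{a}\binom{n-a}{h}2^h$ (with $a = (m-h)/2$ homozygous
carriers of the $m$ alternate alleles) — the same null, verified against
exhaustive enumeration in the tests, and fast enough for thousands of
loci. Published per-population "HWE" summary numbers are typically
undefined (mean p? proportion significant?), so the panel reports both the
mean per-locus p and the fraction significant at 0.05, labelled as such,
and does not claim to reproduce any particular printed column.

Multilocus linkage disequilibrium uses the index of association on
per-locus dosage distances: $I_a = V_O/V_E - 1$ and the standardised
$\bar r_d = (V_O - V_E)\,/\,2\sum_{l<m}\sqrt{v_l v_m}$, whose maximum 1 is
attained by duplicated loci. Significance shuffles each locus's genotypes
independently across individuals, destroying between-locus association
while preserving per-locus frequencies.

## Differentiation and isolation by environment

Nei Fst is computed from sample-size-corrected gene diversities
(Nei–Chesser), with the correction for the number of populations:
$D'_{st} = \frac{r}{r-1}(H_t - H_s)$, $H'_t = H_s + D'_{st}$,
$F_{st} = \overline{D'_{st}}/\overline{H'_t}$ (components averaged over
loci before the ratio). The $r/(r-1)$ factor matters: it makes a pairwise
Fst an unbiased estimate of the generating Balding–Nichols $F$ — under
that model $E[H_s] = h_0(1-F)$ and $E[D'_{st}] = h_0 F$, so
$F_{st} \to F$ for any number of populations — whereas the uncorrected
ratio converges to $\frac{F/2}{1 - F/2}$ for pairs. The recovery tests
(±0.02 of F = 0.1 at 2,000 loci, 30 diploids per population) rely on this.

Geographic distances are haversine great circles on a 6371-km sphere;
environmental distance is |ΔAI|. Isolation models are ordinary least
squares on pairwise distances:

1. joint model: genetic ~ geographic + environmental;
2. residual model: residuals of genetic ~ geographic regressed on the
   environmental predictor.

Two open choices were settled as follows. **Pair set:** unordered pairs by
default (10 pairs for five sites); an `ordered` flag duplicates each pair
to mirror analyses whose degrees of freedom imply directed pairs (df =
2, 17 from five sites). **Residual predictor:** by default the
environmental distances are themselves residualized on geography
(Frisch–Waugh), which makes the residual slope algebraically identical to
the joint model's environmental coefficient and hence unbiased; regressing
the residuals on *raw* environmental distance — the more literal reading
of some methods texts — attenuates the slope by the geography–environment
collinearity (on a linear transect, substantially) and is available via
`residual_predictor = "raw"`. Distance pairs are not independent
observations; parametric p-values are reported but a Mantel-style
permutation of site identities (`n_perm`) is the recommended inference.
The original analyses used spatial mixed models for this step; plain least
squares with permutation is used here deliberately — the estimand is the
same and the inference is permutation-based rather than
likelihood-asymptotic.

Gradient fits regress each diversity statistic on AI (linear), with an
added quadratic term for private-allele counts, whose accumulation at both
environmental extremes is the pattern of interest.

## Clustering

* **PCA** on mean-imputed, centred dosages (deterministic up to sign).
* **Admixture**: the binomial mixture $g_{il} \sim
  \mathrm{Bin}(2, \sum_k q_{ik}p_{kl})$ fitted by EM with seeded random
  starts. This is a maximum-likelihood stand-in for Bayesian MCMC
  admixture programs: the decision surface (the Q matrix and the choice of
  K) is the same, runs are deterministic per seed, and replicate spread
  comes from the random starts. The log-likelihood is non-decreasing by
  construction and the tests assert it. Evanno's
  $\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
  uses replicate means/SDs; zero-SD entries (all replicates in the same
  optimum) are flagged and excluded from the argmax, and a weak peak sets
  a low-confidence flag. The default K grid is 1…min(10, n−1): with a few
  dozen individuals, large K is uninformative.
* **DAPC-style clustering**: k-means over retained principal components,
  scored by $\mathrm{BIC}(K) = n\log(\mathrm{WSS}/n) + K\log(n)$, then
  linear discriminant axes on the winning K. The default retains
  min(n − 1, 40) axes: truncating the PCA discards within-cluster
  variance and makes this BIC decrease monotonically in K, so "keep most
  axes" is a correctness requirement here, not a tuning knob.
* **Spatial PCA**: eigen-decomposition of
  $\frac{1}{2n}X^\top(W + W^\top)X$ with $W$ a row-standardised
  k-nearest-neighbour graph (k = 5 by default; the original analyses do
  not name their graph). Positive eigenvalues capture global structure
  (clines, patches), negative ones local structure. Duplicate coordinates
  (individuals sharing a colony) are broken by a seeded jitter of 1e-4
  degrees — invisible at map scale. The global (local) Monte-Carlo test
  permutes genotype rows against coordinates and compares the largest
  (most negative) eigenvalue, with the +1 correction. For wide matrices
  the decomposition runs in the sample space via SVD
  ($X^\top M X$ and $S^\top M S$ share non-zero eigenvalues), so cost is
  O(n³), not O(L³).

## The synthetic-data generator

`synthetic_design()` mirrors the motivating study: 39 individuals across
five sites (8/10/7/7/7 individuals from 7/6/6/6/4 colonies), 3,540
biallelic loci, site coordinates along a ~500-km coastal transect, target
AI values 0.04–0.86. Genotypes follow a nested Balding–Nichols model:
ancestral frequencies uniform on (0.1, 0.9), population frequencies
Beta-distributed around them with differentiation `f_pop`, colony
frequencies nested likewise with `f_col`, and a configurable fraction of
each colony drawn as full sibs of one shared parent pair (Mendelian
gamete draws), which depresses effective within-colony diversity the way
social family groups do. Defaults chosen once: `f_pop = 0.15`,
`f_col = 0.05`, `sib_fraction = 0.5`, `missing_rate = 0.02` — population
differentiation strong enough to produce the observed order of global Fst
with a visible colony signal, and missingness typical of reduced-
representation SNP panels. Estimator-recovery tests use the flatter
conditions stated with them (F = 0.1, no colony structure) so that the
target of the recovery is unambiguous.

mtDNA alignments are generated from an explicit haplotype tree whose
branch mutations occupy globally distinct sites, so mutational distances
equal tree path lengths and the generating tree is recoverable as the MSN
whenever path lengths are unique. Climate series are sinusoidal seasonal
cycles with Gaussian noise; monthly precipitation is the site's target AI
times that month's realised PET with log-normal noise, so realised AI
fluctuates around the target (a closed-loop construction — the ±20%
check in the tests is a property of the noise, not a calibration).
Gradient-coupled genetic distances are a linear function of km and |ΔAI|
plus pair-level Gaussian noise with recorded truth.

What the generator does **not** emulate: linkage between loci (loci are
independent given the frequency hierarchy), mutation or drift through
time (no coalescent), selection, range edges, or spatially autocorrelated
noise in the isolation-model errors. Passing tests therefore demonstrate
that the estimators recover their estimands under the stated sampling
model — not that real mole-rat data satisfy that model. In particular the
IBE null calibration holds because the generator draws independent pair
noise; on real distance matrices only the permutation p-values are
trustworthy.

## Problem sizes and numerical choices

The test suite runs desk-scale versions of every stochastic claim: 2,000
loci × 120 individuals for Fst/Fis recovery; 1,000 loci × 40 individuals ×
10 replicate data sets for K selection; 200 null replicates × 199
permutations for the calibration of the AMOVA, Fst, Hardy–Weinberg and
sPCA tests (the +1-corrected p-values are exactly uniform on the
attainable grid, so the nominal 5% level is hit by construction and the
binomial band is the sampling noise of 200 replicates); 100 replicates
for the residual-IBE coverage chain. Tolerances: oracle-equivalence
comparisons at 1e-10 or tighter; EM convergence at relative log-likelihood
change < 1e-6 with a 500-iteration cap (non-convergence is returned
flagged, not hidden); allele-frequency clamps at 1e-9 keep the binomial
log-likelihood finite without breaking monotonicity beyond 1e-6.

## Limitations

* Fst here is Nei's gene-diversity formulation; variance-components
  (Weir–Cockerham) estimators will differ on unbalanced data.
* The EM admixture surrogate has no admixture priors, no location prior
  and no MCMC uncertainty; Q matrices are point estimates.
* Ordinary least squares on distance matrices understates uncertainty
  when pair errors are correlated; prefer the Mantel permutation output.
* The chi-square HWE test is unreliable at very small expected counts;
  use the Monte-Carlo variant (both are reported).
* The one-individual-per-colony sensitivity subset picks the first sample
  by id order — deterministic, but not a random subsample.
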