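---
title: "Nonparametric linkage analysis of familial longevity with apmlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric linkage analysis of familial longevity with apmlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmlink)
```

## The problem

Human longevity is moderately heritable, but mapping the loci involved is
hard: the phenotype is only observable at death, affected individuals are
elderly or deceased, and family material is dominated by large,
multigenerational pedigrees with many ungenotyped connecting relatives.
Likelihood-based multipoint IBD machinery (Elston--Stewart,
Lander--Green) is infeasible on such pedigrees, and MCMC IBD samplers
converge poorly.  `apmlink` implements the pragmatic alternative: a
*simplified affected pedigree member* (APM) scan, which needs only the
genotypes of affected relatives and a Monte Carlo null generated by
gene-dropping through the known pedigree.

The package covers the full chain: survival-based phenotype construction,
affected selection, kinship and affected-pair enumeration, the sharing
statistic, gene-dropping nulls (unlinked and linked), singlepoint and
multipoint scans with a 1-cM grid, experiment-wise adjustment,
cross-study meta-analysis, and a synthetic-data generator used both for
validation and for ascertainment-design simulation.

## Phenotype: excess longevity and its familial aggregate

For an individual of known sex and birth cohort,

* **EL** (excess longevity) = observed lifespan − expected lifespan,
  where the expectation comes from a user-supplied `(sex, cohort)`
  reference table.  Supplying a table rather than refitting a survival
  model keeps the stage deterministic and testable; any cohort life
  table can be plugged in.  Units: years.
* **FEL** (familial excess longevity) of individual $i$ is the
  kinship-weighted average of relatives' EL:
  $\mathrm{FEL}_i = \sum_{j\neq i} w_{ij}\,\mathrm{EL}_j \big/
  \sum_{j\neq i} w_{ij}$, with $w_{ij} = 2\varphi(i,j)$, the expected
  allele-sharing proportion.  Self is excluded.  Normalizing by the
  weight sum is a deliberate choice: "kinship-weighted average" is
  underdetermined, and normalization keeps FEL on the years scale that
  thresholds such as 1.75 years imply.  Individuals with no scorable
  relative get `NA`, not zero.

Affected status is a `selection_rule`: fixed thresholds
(EL ≥ 3.0 and FEL ≥ 1.75 by default, closed inequalities), data-derived
top quartiles (linear-interpolation quantiles, `stats::quantile`
type 7), or an attained-age cutoff that ignores sex and family history
(used for sensitivity reanalyses at ages 95, 98, 100).

## Kinship and affected pairs

Kinship coefficients are computed by the standard recursion
$\varphi(i,j) = \tfrac12[\varphi(f_i,j)+\varphi(m_i,j)]$, memoized and
driven by a cached topological order, so pedigrees where pairs are
related through several lines of descent are handled exactly (the paths
sum; a multiply-related pair is still one pair).  Study samples are
usually forests of disconnected families; kinship-based operations
(FEL, pair enumeration) exploit the block structure and never build a
sample-wide dense matrix.  Unknown-sex parents are accepted -- gene
dropping needs only two distinct parents -- and parental sex is checked
only when recorded.

Affected pairs default to $\varphi > 0$ ("any known biological
relationship").  No positive lower bound is imposed because distant
pairs are the most informative for localization; `min_kinship` is
available when a closed threshold is wanted.

## The APM sharing statistic

For affected relatives $i, j$ with genotypes $(G_{i1},G_{i2})$,
$(G_{j1},G_{j2})$ and marker allele frequencies $q(\cdot)$:

$$S_{ij} \;=\; \frac14 \sum_{a=1}^{2}\sum_{b=1}^{2}
  \delta(G_{ia},G_{jb})\; f\!\big(q(G_{ia})\big)$$

with $\delta$ the Kronecker delta.  The weight $f$ takes one of three
forms: `constant` ($f=1$, plain IBS proportion in $[0,1]$),
`inverse_sqrt` ($f = 1/\sqrt q$, the classical choice and the default),
and `inverse` ($f = 1/q$).  Sharing a rare allele is stronger evidence
of descent than sharing a common one, which is what the non-constant
weights encode; $1/q$ was also evaluated here and localized slightly
*worse* than $1/\sqrt q$ in the package's own power simulations (its
null is heavier-tailed), supporting the default.  The scan statistic at
a marker is $\sum_{ij} S_{ij}$ over all affected pairs whose two members
are both typed there; pairs with a missing genotype are dropped from
that marker's sum.

## The gene-dropping null

Significance comes from simulation, not asymptotics on pedigree
structure: alleles are assigned to founders i.i.d. from the population
frequencies and transmitted through the pedigree by Mendelian
segregation.  For multipoint statistics whole chromosomes are dropped:
founder haplotypes are drawn at linkage equilibrium and each meiosis
switches parental strands between adjacent markers with probability
$\theta = (1-e^{-2d/100})/2$ (Haldane, no interference; $d$ in cM).
Three design points deserve note:

* **Missingness masking.** Each null replicate is masked with the
  observed missingness pattern, so the null reflects exactly the
  information available in the data.  The conservative alternative
  (scoring complete null data) would understate the null variance at
  poorly typed markers.
* **One linked ensemble per chromosome.** 500 replicates (configurable)
  of the whole chromosome serve every statistic on it -- singlepoint,
  window multipoint, and grid.  The per-marker marginal law of a linked
  drop equals an unlinked drop, so nothing is lost for singlepoint
  statistics, and all statistics live on a common replicate set, which
  the experiment-wise adjustment requires.
* **Degenerate nulls** (zero variance, e.g. a marker monomorphic in
  practice) are reported as an error state per locus and excluded from
  Z-based summaries, never converted into a Z.

Z-scores are signed so that *excess* sharing is positive, the asymptotic
p is the upper normal tail, and the empirical p is the plug-in
proportion of null scores ≥ observed (ties count against the observed
score; a $(k+1)/(n+1)$ variant is available when zero p-values are
unwanted).

## Multipoint scores and the 1-cM grid

The window multipoint statistic at a focal marker sums the per-marker
APM scores over all markers within 10 cM (spacing-adaptive default;
fixed windows are available), scored against the linked ensemble.  The
grid statistic interpolates between each pair of adjacent markers at
1-cM steps: position $x$ between markers $L$ and $R$ gets
$w_L\,\mathrm{score}(L) + w_R\,\mathrm{score}(R)$ with
$w_L \propto 1/\theta(d_L)$, $w_R \propto 1/\theta(d_R)$, normalized to
sum 1; at a marker position the weight is entirely on that marker.  The
same linear combination is applied to every null replicate, so observed
and null grids are directly comparable.

## Experiment-wise adjustment

The adjusted p-value at a locus is the proportion of null replicates
whose *maximum* Z anywhere in the scan (all markers, all window and
grid positions) reaches the observed Z at that locus.  Null Z curves
are standardized by the full-ensemble moments of each locus.  A
leave-self-out standardization was considered and rejected: with
full-ensemble moments the adjustment is exactly compatible with the
per-locus empirical p (adjusted ≥ empirical everywhere, and a
single-locus scan reduces adjusted p to empirical p); leave-one-out
breaks both identities at the margins while changing nothing at
realistic replicate counts.  Fewer than 20 replicates triggers an
unstable-tail warning.

## Meta-analysis

Z curves from independent scans are combined by the weighted mean
Z-score rule $Z_{meta} = \sum_k w_k Z_k / \sqrt{\sum_k w_k^2}$ on a
shared cM grid (linear interpolation; unit weights by default, so two
equal curves combine to $\sqrt 2 Z$).  The upper normal tail gives the
combined p.

## The synthetic-data generator

`sim_config()` + `simulate_study()` generate the conditions the
analysis assumes: a forest of multigenerational pedigrees built by
random mating with married-in spouses (spouses always unrelated, so
nobody is inbred), a multiallelic microsatellite panel, a biallelic
causal locus dropped jointly with the markers, and Gompertz lifespans
with a carrier hazard ratio.

Defaults are the study conditions the package emulates: dominant causal
allele at frequency 0.01 with all-cause mortality hazard ratio 0.5;
marker spacing 3.4 cM; 2--38 alleles per marker with Dirichlet(1)
frequencies; 5% genotype missingness (never applied to the carrier
truth).  The Gompertz baseline is $a = 10^{-4}$/yr, $b = 0.085$/yr for
females with a 1.35-fold male excess hazard -- chosen so that
non-carrier lifespans centre in the mid-70s to low 80s and "affected"
ages fall in the high-80s-to-centenarian range typical of longevity
studies.  Birth years follow a generation clock (28-year gaps from
1850) so cohort-based expected-lifespan lookups are exercised.  The
expected-lifespan table bundled with a fixture is the non-carrier
Gompertz mean by sex.

What the generator deliberately does **not** emulate: founder linkage
disequilibrium, assortative mating, secular mortality trends, sex-specific
genetic maps, and genotyping error (as opposed to missingness).  Passing
tests on synthetic data therefore validate the statistical machinery
under the stated model, not robustness to those real-data features.

`evaluate_selection_design()` reproduces the ascertainment simulation
that motivates the EL ∧ FEL rule: over repeated simulated studies it
estimates the positive predictive value P(carrier | selected) and
sensitivity P(selected | carrier) of a selection rule, skipping the
marker panel for speed (only the causal locus is dropped).

## Problem sizes used by the test suite

The packaged checks run at desk scale, with sizes chosen once from
pilot power analyses: null calibration uses 20 three-generation
pedigrees (~600 members), 100 unlinked markers and 500 gene-drops per
marker; the parameter-recovery run uses 30 six-generation,
single-founder-couple pedigrees (~4,900 individuals, mean sibship 2.3)
with the causal frequency boosted to 0.05 at 50 cM on a 150 cM
chromosome, 100 linked gene-drops per scan, 20 signal replicates and 12
null replicates; IBD-oracle comparisons use 10,000 drops per pair
class.

## A structural limit on desk-scale localization power

The pilot analyses surfaced a property of APM scans worth recording.
With affecteds chosen by *top-quartile* EL ∧ FEL, the net expected
excess sharing at the causal locus is second-order in the carrier
enrichment: both-carrier affected pairs share in excess, but mixed
carrier/non-carrier affected pairs share *below* the null (selection
anti-correlates their local genotypes), and the two effects largely
cancel.  For a proportional-hazards carrier effect the enrichment at a
top-quartile threshold is analytically capped: writing $u$ for the
baseline survival fraction, the carrier/non-carrier survival ratio is
$u^{\mathrm{HR}-1}$, so its mean over the selected quartile is
$4^{1-\mathrm{HR}}/\mathrm{HR}$ regardless of the Gompertz baseline
(4 at HR 0.5, and exactly 2 at the threshold itself) -- so no choice of
baseline mortality can sharpen a quartile-based design.  In the
package's simulations the genome-wide grid peak lands within 20 cM of
the causal locus in roughly a third to a half of replicates across
pedigree designs from 1,000 to 21,000 individuals, and the causal-region
Z does not grow with study size the way independent-pair heuristics
suggest.  Deep pedigrees dominated by distant pairs localize best
(short shared segments), which is why the power fixture uses
six-generation families; extreme-tail ascertainment (e.g. centenarian
recruitment), not larger samples, is what moves such designs into
reliably-localizing territory.  The packaged parameter-recovery check
reports this honestly rather than relaxing its conditions.

## Numerical and policy choices

* Quantiles: linear interpolation (type 7) everywhere.
* Thresholds are closed (≥): selection rules and the 50% marker
  call-rate filter.
* Ties in null comparisons count as "≥" (conservative).
* Empirical p: plug-in $k/n$ by default.
* Map positions are sex-averaged cM; physical positions in `.map`
  column 4 are accepted and ignored; reports print cM with two
  decimals.
* Frequencies estimated by simple counting must cover every observed
  allele; a marker monomorphic in the counting sample receives a tiny
  pseudo-allele and then flags itself as a degenerate-null locus rather
  than entering Z summaries.
* All randomness flows from one master seed; per-chromosome stream
  seeds are derived deterministically, so reports are byte-identical
  across reruns.

## Known limitations

Beyond the generator simplifications above: the APM family tests
identity *by state* and inherits its known sensitivity to allele
frequency misspecification; no inbreeding-loop likelihoods or condensed
identity coefficients (pairwise $\varphi$ only -- the sampled
pedigrees are non-inbred); autosomes only; and the multipoint grid
interpolates between flanking markers rather than solving the full
hidden-IBD model, which is exactly the trade-off that makes very large
sparse pedigrees tractable.
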