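---
title: "Multilocus phylogeography with seqpopgen: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus phylogeography with seqpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpopgen)
```

## Scope

`seqpopgen` implements the statistical core of a multilocus Sanger-era
phylogeographic analysis of hierarchically structured populations, of the
kind applied to seabird species complexes sampled across ocean basins:
a handful of mitochondrial markers (maternally inherited, effectively one
non-recombining locus) and several phased nuclear introns/exons, a few
hundred individuals in 10–15 breeding colonies nested in nominal lineages
and oceans. The package covers:

* within-population diversity (segregating sites `S`, haplotype count `K`,
  haplotype diversity `hd`, nucleotide diversity `π`) and the neutrality
  statistics Tajima's `D` and Fu's `Fs` with coalescent-simulation
  p-values;
* hierarchical AMOVA (`Φ`-statistics on molecular distances,
  `F`-statistics on haplotype identity), pairwise differentiation
  matrices, `D_XY`, and Mantel isolation-by-distance tests on linearized
  `F_ST`;
* sex-biased dispersal inference from nuclear data: per-sex
  Weir–Cockerham `F_IS`, maximum-likelihood pairwise relatedness and a
  resampling test for the between-sex difference in mean relatedness;
* ABC model choice among population-divergence scenarios: structured
  coalescent simulation, summary statistics, rejection, LDA projection
  and weighted multinomial logistic regression, with the hierarchical
  "winner constrains the next round" comparison strategy;
* a synthetic-data generator that emulates the study design with known
  truth, so every stage is testable without any external data.

## Diversity and neutrality statistics

All per-site quantities use, by default, *complete deletion*: every
alignment column containing a gap, `N`, or a partial IUPAC ambiguity in
any sequence is removed before computation (the common default of
DnaSP-style software); pairwise deletion is available via
`site_policy = "pairwise_ignore_missing"`. Partial ambiguity codes are
treated as missing rather than as their nucleotide sets — phased input
should not contain them, and a defensive default is preferable to
guessing.

Nucleotide diversity is the mean per-site p-distance over all unordered
sequence pairs; `k_bar = π·L` is the mean number of pairwise differences.
Tajima's `D` uses the standard variance coefficients and requires
`n ≥ 4` (reported `NA` below; the coefficients are undefined otherwise).

Fu's `Fs` is computed from the Ewens sampling distribution of the number
of alleles: `S' = P(K ≥ K_obs | θ, n)` with `θ` taken as `k_bar` (the
convention of the original definition and of Arlequin), and
`Fs = ln(S'/(1−S'))`. The unsigned Stirling numbers of the first kind
that enter the Ewens formula are computed by their triangular recurrence
*in log space* with log-sum-exp; this is numerically stable far beyond
`n = 255` (the largest sample size in the motivating design), and is
verified in the test suite against exact enumeration of Ewens partition
probabilities up to `n = 8` and against the closed form at `n = 2`.

Neutrality p-values follow the conditional-on-`S` convention: neutral
constant-size coalescent genealogies are simulated, exactly `S` mutations
are placed on branches with probability proportional to branch length,
and the lower tail `P(statistic ≤ observed)` is reported with `+1`
smoothing, i.e. `(count+1)/(n_sim+1)`. Significance of both `D` and `Fs`
is conventionally an excess of *negative* values; for `Fs` the customary
threshold is 0.02 rather than 0.05 — the package reports p-values and
leaves thresholds to the analyst. No multiple-testing correction is
applied across locus × locality cells, and the documentation of
`diversity_table()` says so explicitly.

## AMOVA and differentiation

The AMOVA decomposes squared inter-haplotype distances. For the two-level
design the implementation follows the standard sums
`SSD_total = Σ_{i<j} d²_ij / N` and `SSD_within = Σ_p Σ_{i<j∈p} d²_ij /
n_p`, with variance components from the usual expected-mean-square
coefficients; the three-level design adds the among-groups /
among-populations-within-groups split with the nested coefficients.
Negative variance components are *retained* (Arlequin's behaviour), so
percentages can be negative; they still sum to 100.

Permutation schemes follow the stratum being tested: copies among
populations for `Φ_ST`, whole populations among groups for `Φ_CT`, copies
among populations within their group for `Φ_SC`. Ties count as "at least
as extreme" and p-values carry `+1` smoothing — with heavily tied
statistics (few segregating sites) this makes the test conservative,
visible as an excess of p-values near 1; with continuous distances the
null p distribution is uniform, which is what the test suite checks.

With unit distances between distinct haplotypes the same computation
yields conventional `F`-statistics. On *concatenated* phased nuclear
sequences, however, virtually every copy is a unique haplotype, and the
identity-based `F_ST` degenerates to ~0 regardless of structure. The
pipeline therefore defaults to molecular-distance weighting for both
marker classes (K2P for mtDNA, TN93 for nuclear concatenates, matching
the substitution models a model-selection step would pick for such data);
identity-based `F_ST` remains available (`statistic = "FST"`) and is the
natural choice for per-locus allele data. `D_XY` is the mean per-site
difference between cross-population sequence pairs and carries no
permutation test.

The Mantel test correlates off-diagonal entries of a genetic and a
geographic matrix, permuting rows and columns of the geographic matrix
jointly. `F_ST`-type inputs are linearized as `x/(1−x)` by default;
pairs at fixation (`F_ST = 1`) are excluded with a warning rather than
clipped. Because isolation by distance is a directional hypothesis, the
default p-value is one-tailed for positive association; a two-tailed
variant is a flag away.

## Sex-biased dispersal

The logic: if one sex disperses more, its sample at a breeding site is a
mixture of residents and immigrants, hence (i) a heterozygote deficit
(Wahlund effect) inflating that sex's `F_IS`, (ii) lower mean relatedness
within that sex, and (iii) weaker between-population structure for that
sex.

`F_IS` is the Weir–Cockerham estimator: per-allele between- and
within-individual components summed over alleles and loci,
`f̂ = 1 − Σc/Σ(b+c)`. Confidence intervals bootstrap loci; the
permutation p-value re-pairs alleles at random within the group, which
destroys within-individual allele correlation — exactly the `F_IS` null.
The reported tail is the heterozygote-deficit direction.

Pairwise relatedness is the dyadic maximum-likelihood estimator: the
genotype pair probability is a mixture over IBD-sharing states
`k = (k0, k1, k2)` on the simplex (no inbreeding), maximized by EM from
multiple starts (including the exact unrelated corner, so the optimum can
never fall below it); `r̂ = k2 + k1/2`. Allele frequencies come from the
population sample including the dyad, the default of the widely used
implementations. A triadic (reference-individual) refinement exists in
the literature; it primarily buys robustness to genotyping error, which
this package does not model, so the dyadic core is the sole estimator
here — its calibration is established directly by the recovery tests
(full-sib dyads average `r̂ ≈ 0.5`, unrelated dyads a small positive value
reflecting the truncation of a noisy estimator at 0).

The between-sex difference test computes the observed difference in mean
within-sex dyadic relatedness, then builds a null by re-assigning
individuals at random to two pseudo-sex groups of the original sizes and
re-averaging the (precomputed) dyad matrix; the observed difference is
significant when outside the null central 95% interval. Re-assignment
without replacement (label permutation) is the default because label
exchangeability is the hypothesis actually tested; a with-replacement
variant is behind `replace = TRUE`. Resampling is at the individual
level, never the dyad level — dyads sharing an individual are dependent,
and resampling them independently would fake precision. Groups with
fewer than five individuals of either sex are skipped, following the
usual practice for this test family.

## Coalescent simulator and ABC

The simulator is a backwards-in-time structured Kingman coalescent in
units of generations: within a population of size `N` and ploidy
multiplier `m`, lineage pairs coalesce at rate `1/(2Nm)`; divergence
events merge populations (looking backwards), size changes reset `N`,
admixture events move lineages with a given probability. `m = 1` for
autosomal nuclear loci and `m = 0.25` for mtDNA (haploid, uniparental).
Mitochondrial loci share one linked genealogy — no recombination is
expected on the mitochondrion at these time scales — while nuclear loci
get independent genealogies with two copies per individual;
within-locus recombination is ignored (the loci are short).

Mutation is finite-sites Jukes–Cantor: per-branch Poisson counts with
rate `μ·L·t`, uniform site choice, uniform change to one of the three
other bases. Finite sites (rather than infinite sites) is deliberate:
the observed data are sequences with possible recurrent substitution,
notably in fast control-region-like markers. Scenario structure is
validated before any simulation: the divergence events must merge all
populations into a single root.

Summary statistics per marker class: per population `K`, `S`, `k̄`,
Tajima's `D`; per population pair `F_ST` (unit-distance AMOVA on
haplotype identity — adequate here because each class is summarized at
the haplotype level within the simulation) and per-site `D_XY`.
Undefined entries (monomorphic samples) are imputed 0, with the
imputation pattern kept as an attribute so the vector's dimension is
fixed by the design. Summaries are normalized by the reference table's
standard deviation; the `ceil(tolerance·n)` simulations nearest in
Euclidean distance are retained (default tolerance 1%).

Posterior scenario probabilities: the default projects retained
summaries onto linear discriminant axes (at most `#scenarios − 1`), fits
a multinomial logistic regression of scenario on the axes with
Epanechnikov weights in the rejection distance, and evaluates it at the
observed point; confidence intervals come from the fit covariance by the
delta method. Complete separation (every retained point classified with
certainty) falls back to the scenario frequencies in the retained set
with binomial CIs. A scenario is *selected* when its posterior is
highest with a non-overlapping 95% CI; otherwise the round is
"undecided". `hierarchical_compare()` chains rounds, passing previous
winners to rounds given as functions.

Numerical scale: the reference table defaults to desk scale (10^3–10^4
simulations per scenario; the motivating study ran 10^6). One reference
table is shared across replicate pseudo-observed datasets in the
recovery experiments — the table is an estimate of the model's summary
distribution and is independent of any particular observation.

## The synthetic-data generator

`synth_preset("study_mimic")` emulates the motivating design: 13
populations in 5 groups and 2 oceans, 9 loci (3 mitochondrial including
a fast control-region-like marker, 6 nuclear with the empirical lengths),
10 individuals per population. Sizes and times: `N = 10^5` per
population, within-group splits at 2,000 generations, group splits at
70–138 thousand, the ocean split at 176 thousand generations (about 1.76
My at a 10-year generation time, matching the reported divergence-time
scale). Mutation rates (`1.5×10⁻⁷`/site/generation for the slower mtDNA
markers, `6×10⁻⁷` for the control-region-like marker, `2–4×10⁻⁹` for
nuclear loci) were chosen once so that per-population diversities fall in
the empirical ranges (mtDNA `π` ≈ 0.01–0.06, nuclear `π` ≈ 0.0008–0.002)
— the generator's role is to reproduce the *statistical regime* of the
study, and these are the regime's sufficient knobs. The bundled
geographic matrix is deterministic and consistent with the nesting
(within-group 150–800 km, within-ocean 1,800–5,500 km, between-ocean
~10⁴ km), so isolation-by-distance signal at the among-lineage scale is
built in.

What the generator does *not* emulate: sequencing artifacts (numts,
heteroplasmy, chromatogram double peaks), phasing error, selection,
within-locus recombination, and continuous (rather than event-like)
migration. Sex labels are assigned after the fact except in the
migration overlay, where each sampled individual is, with a per-sex
probability, replaced by an individual simulated in another deme — a
forward-time island approximation layered on the coalescent, adequate
for the power and type-I experiments it serves, and documented as an
approximation rather than an exact sex-structured coalescent. Sibling
families replace chosen individuals' nuclear gametes with random gametes
of two simulated parents (maternal mtDNA), giving known-truth related
dyads. Consequently, passing tests demonstrate correct behaviour of the
estimators under a clean coalescent regime; they do not certify
robustness to laboratory artifacts.

The genotype arm (`sim_genotypes()`, used by `sexbias_power`) skips
sequence evolution entirely and draws Hardy–Weinberg biallelic panels
with optional full-sib families — relatedness and `F_IS` calibration
need many unlinked loci, not realistic sequences, and the genotype arm
is orders of magnitude faster at equal statistical content.

## Numerical and design choices worth knowing

* **Problem sizes in the tests.** The suites run at desk scale chosen to
  keep the full test run in tens of minutes: neutrality calibration with
  1,000 coalescent replicates (`n = 20`, `θ = 5`) and 200 p-value
  uniformity replicates; relatedness recovery with 500 full-sib and 500
  unrelated dyads at 100 biallelic loci; sex-bias size with 200 null
  panels of 15+15 individuals × 30 loci and power with 50 preset
  replicates; ABC recovery with 10^4 simulations per scenario, 1%
  tolerance and 50 pseudo-observed replicates.
* **Tie and tail conventions.** Permutation p-values count ties as
  exceedances and use `+1` smoothing; neutrality p-values are lower-tail;
  Mantel is one-tailed by default; the `F_IS` permutation p is the
  deficit tail.
* **Saturated distances** (log argument ≤ 0 in K2P/TN93) propagate as
  `NaN` and are never silently clipped; the pipeline replaces them by the
  maximum observed distance, with a warning, only where a complete matrix
  is structurally required.
* **Seeds.** Every stochastic stage derives its seed from one master
  integer via `spawn_seed(master, tag)`; rerunning a pipeline with the
  same seed reproduces every output file byte for byte (`run.log`, which
  records wall-clock times, is excluded from that contract).
* **`Fs` at `K = 1`**, `D` at `S = 0`, monomorphic AMOVA input, and
  groups below the per-sex minimum all return `NA`/skip-with-reason
  rather than fabricated zeros.
* **Known limitations.** The ABC posterior's delta-method CIs understate
  uncertainty when the logistic fit is nearly separated; the
  conservative CI-based selection rule compensates by declaring such
  rounds "undecided". The sequence-level permutation tests are
  conservative under heavy ties. The migration overlay is an
  approximation (above). The triadic relatedness refinement and
  genotyping-error models are out of scope.
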