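# seqpopgen

Multilocus population genetics for phylogeography: diversity and
neutrality statistics, hierarchical AMOVA and pairwise differentiation,
isolation-by-distance Mantel tests, sex-biased dispersal inference, and
ABC scenario choice for colonization histories — with a coalescent
synthetic-data generator so that every stage is testable end to end
without external data.

## The problem and who this is for

Highly dispersive but philopatric organisms — seabirds are the canonical
case — often show strong genetic structure at mitochondrial markers and
much weaker structure at nuclear markers (mitonuclear discordance).
Disentangling drift, incomplete lineage sorting, introgression and
sex-biased dispersal in such systems rests on a standard battery of
statistics applied to a few mitochondrial and a handful of phased
nuclear Sanger markers sampled from breeding colonies nested within
lineages and ocean basins. `seqpopgen` packages that battery as tested,
scriptable R functions for anyone analysing multilocus alignment data
from hierarchically structured populations.

## What it computes

* **Diversity / neutrality** — per locus × population: segregating sites
  `S`, haplotype count `K`, haplotype diversity
  `hd = n(1 − Σ p_i²)/(n − 1)`, nucleotide diversity `π`; Tajima's
  `D = (k̄ − S/a₁)/√(e₁S + e₂S(S−1))`; Fu's
  `Fs = ln(S′/(1 − S′))` with `S′ = P(K ≥ K_obs | θ = k̄)` from the Ewens
  sampling formula via log-space Stirling numbers; p-values by neutral
  coalescent simulation conditioned on `S`.
* **Differentiation** — two- and three-level AMOVA on squared molecular
  distances (`Φ_CT`, `Φ_SC`, `Φ_ST`; `F`-statistics under unit
  distances), stratum-appropriate permutation tests, pairwise
  `Φ_ST`/`F_ST`/`D_XY` matrices, and Mantel tests of `F_ST/(1 − F_ST)`
  against geographic distance.
* **Sex-biased dispersal** — per-sex Weir–Cockerham `F_IS` (bootstrap CI
  over loci, allele-permutation p), dyadic maximum-likelihood
  relatedness `r̂ = k₂ + k₁/2` over the IBD simplex, and a
  label-resampling test of the between-sex difference in mean
  relatedness.
* **ABC scenario choice** — structured Kingman coalescent (linked mtDNA
  genealogy at effective size ratio 0.25, independent nuclear loci),
  finite-sites Jukes–Cantor mutation, summary statistics, 1% rejection,
  LDA projection + distance-weighted multinomial logistic posterior, and
  the hierarchical comparison strategy with the
  highest-posterior/non-overlapping-CI selection rule.
* **Pipeline** — `run_all()` chains the stages into a byte-reproducible
  report bundle; `inst/scripts/seqpopgen.R` is a thin command-line front
  end (`simulate | stats | structure | sexbias | abc | report`).

## Worked example

Simulate two undifferentiated demes (a null preset of the bundled
generator), then run diversity statistics and an AMOVA:

```r
library(seqpopgen)
gen <- synth_generate(synth_preset("two_pop_null", seed = 42))
ds  <- gen$dataset
ds
#> pop_dataset: 5 loci, 40 individuals, 2 populations in 1 groups / 1 oceans

dv <- diversity_table(ds, n_sim = 0)
head(dv[dv$population == "ALL", c("locus","n","L","S","K","hd","pi","D","Fs")], 3)
#>   locus  n   L  S  K    hd      pi      D    Fs
#> 1   mt1 40 600 63 24 0.960 0.01838 -0.919 -4.14
#> 4   nu1 80 450 30 14 0.829 0.01767  0.978  3.35
#> 7   nu2 80 450 18 11 0.861 0.00881  0.265  1.17

aln <- concatenate_loci(Filter(function(l) l$mode == "mitochondrial", ds$loci))
pop <- ds$meta$population[match(aln$individual, ds$meta$individual)]
amova(pairwise_distance(aln, "K2P"), pop, n_perm = 999, seed = 1)
#> AMOVA (two_level)
#>        df    SSD sigma2     pct
#> among   1 0.0001  0e+00  -2.861
#> within 38 0.0091  2e-04 102.861
#> total  NA 0.0092  2e-04 100.000
#> phi_st = -0.0286 (p = 0.772)
```

Read it as: 40 mtDNA copies over 600 sites carry 63 segregating sites in
24 haplotypes with high haplotype diversity; the two demes share one
panmictic history, so the among-population variance component is
(slightly negative) noise around zero and `Φ_ST` is not significant —
exactly what the null preset should produce. Negative components are
reported as estimated, never truncated.

Real data enter through per-locus FASTA alignments plus a metadata TSV
(`read_locus_fasta()`, `read_metadata()`, `pop_dataset()`), or a whole
directory via `read_dataset()`; `run_all(run_config(...))` then writes
the full report bundle (diversity table, AMOVA tables, pairwise
matrices, Mantel JSON, sex-bias table, manifest).

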