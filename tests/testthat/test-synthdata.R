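test_that("presets echo their advertised configurations", {
  sm <- synth_preset("study_mimic", seed = 1)
  expect_equal(length(sm$samples), 13L)
  expect_equal(length(sm$loci), 9L)
  expect_equal(sum(vapply(sm$loci, function(l)
    l$mode == "mitochondrial", TRUE)), 3L)
  expect_equal(length(unique(sm$populations$group)), 5L)
  expect_equal(length(unique(sm$populations$ocean)), 2L)

  tp <- synth_preset("two_pop_null", seed = 1)
  expect_equal(unname(tp$sizes["d1"]), unname(tp$sizes["d2"]))
  expect_equal(tp$events[[1]]$time, 1)

  sp <- synth_preset("sexbias_power", seed = 1)
  expect_equal(sp$migration$F, 10 * sp$migration$M)
  expect_equal(sp$genotype_panel$families$sex, "M")

  ar <- synth_preset("abc_recovery", seed = 1)
  N <- unname(ar$sizes["p1"])
  tms <- sort(vapply(ar$events, `[[`, 0, "time"))
  expect_equal(tms, c(0.2 * N, 0.6 * N))

  expect_error(synth_preset("nope"), "study_mimic")
  expect_error(synth_config(), "mandatory")
})

test_that("generation is byte-identical under a fixed seed", {
  g1 <- synth_generate(synth_preset("two_pop_null", seed = 5))
  g2 <- synth_generate(synth_preset("two_pop_null", seed = 5))
  expect_identical(g1$dataset$loci[[1]]$seq, g2$dataset$loci[[1]]$seq)
  expect_identical(g1$dataset$meta, g2$dataset$meta)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_dataset(g1$dataset, d1); write_dataset(g2$dataset, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  g3 <- synth_generate(synth_preset("two_pop_null", seed = 6))
  expect_false(identical(g1$dataset$loci[[1]]$seq,
                         g3$dataset$loci[[1]]$seq))
})

test_that("study mimic hits the intended diversity ranges and hierarchy", {
  ## per-population nucleotide diversities bracket the empirical marker
  ## panel: mtDNA within [0.005, 0.1], nuclear within [0.00005, 0.02]
  n_ok_mt <- 0; n_ok_nu <- 0; tot <- 0
  for (s in 1:6) {
    gen <- synth_generate(synth_preset("study_mimic", seed = 400 + s))
    ds <- gen$dataset
    for (mode in c("mitochondrial", "nuclear")) {
      aln <- concatenate_loci(Filter(function(l) l$mode == mode, ds$loci))
      pop <- ds$meta$population[match(aln$individual, ds$meta$individual)]
      pis <- vapply(unique(pop), function(p) {
        sub <- locus_alignment("s", mode, aln$seq[pop == p, , drop = FALSE],
                               aln$individual[pop == p], aln$copy[pop == p],
                               aln$copies_per_individual)
        nucleotide_diversity(sub)$pi
      }, 0)
      if (mode == "mitochondrial")
        n_ok_mt <- n_ok_mt + sum(pis >= 0.005 & pis <= 0.1)
      else n_ok_nu <- n_ok_nu + sum(pis >= 0.00005 & pis <= 0.02)
    }
    tot <- tot + 13
  }
  expect_gte(n_ok_mt / tot, 0.9)
  expect_gte(n_ok_nu / tot, 0.9)
})

test_that("deep splits without migration put most variance among groups", {
  gen <- synth_generate(synth_preset("study_mimic", seed = 19))
  ds <- gen$dataset
  aln <- concatenate_loci(Filter(function(l) l$mode == "mitochondrial",
                                 ds$loci))
  pop <- ds$meta$population[match(aln$individual, ds$meta$individual)]
  grp <- ds$meta$group[match(aln$individual, ds$meta$individual)]
  d <- pairwise_distance(aln, "K2P")
  d[is.na(d)] <- max(d, na.rm = TRUE)
  f <- amova(d, pop, grp, n_perm = 0)
  expect_gt(unname(f$pct["a"]), 50)
  expect_gt(unname(f$pct["a"]), unname(f$pct["c"]))
})

test_that("a mitochondrial mutation-rate excess shows up in every population", {
  ## the mimic's mtDNA mu is an order of magnitude above nuclear: pi_mt
  ## must exceed pi_nu in every population (sign test)
  gen <- synth_generate(synth_preset("study_mimic", seed = 23))
  ds <- gen$dataset
  wins <- 0; tot <- 0
  for (mode in c("mitochondrial", "nuclear")) {
    aln <- concatenate_loci(Filter(function(l) l$mode == mode, ds$loci))
    pop <- ds$meta$population[match(aln$individual, ds$meta$individual)]
    pis <- vapply(sort(unique(pop)), function(p) {
      sub <- locus_alignment("s", mode, aln$seq[pop == p, , drop = FALSE],
                             aln$individual[pop == p], aln$copy[pop == p],
                             aln$copies_per_individual)
      nucleotide_diversity(sub)$pi
    }, 0)
    if (mode == "mitochondrial") mt <- pis else nu <- pis
  }
  expect_true(all(mt > nu))
})

test_that("genotype panels embed the requested family structure", {
  out <- sim_genotypes(6, 12, n_loci = 30, p = 0.5,
                       families = list(sex = "M", n_families = 3,
                                       family_size = 4), seed = 2)
  expect_equal(dim(out$genotypes$a1), c(18L, 30L))
  expect_equal(nrow(out$truth$sib_dyads), 3 * choose(4, 2))
  ## sibs share more alleles than non-sibs on average
  gt <- out$genotypes
  share <- function(i, j) mean((gt$a1[i, ] == gt$a1[j, ]) +
                                 (gt$a2[i, ] == gt$a2[j, ]))
  sib_share <- mean(apply(out$truth$sib_dyads, 1,
                          function(x) share(x[1], x[2])))
  unrel <- t(combn(which(gt$sex == "F"), 2))
  un_share <- mean(apply(unrel, 1, function(x) share(x[1], x[2])))
  expect_gt(sib_share, un_share)
})

test_that("the migration overlay records migrants and respects sex rates", {
  cfg <- synth_preset("two_pop_null", seed = 61)
  cfg$migration <- list(F = 0.8, M = 0)
  gen <- synth_generate(cfg)
  expect_true(!is.null(gen$truth$migrants))
  expect_true(all(gen$truth$migrants$sex == "F"))
  expect_gt(nrow(gen$truth$migrants), 0)
})
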