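test_that("complete fixation gives Phi_ST = 1 and shared composition <= 0", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0
  f <- amova(d, c("A", "A", "B", "B"), n_perm = 0)
  expect_equal(unname(f$phi["phi_st"]), 1)

  ## identical haplotype composition in both pops: no among-pop variance
  d2 <- matrix(1, 4, 4); diag(d2) <- 0
  d2[1, 3] <- d2[3, 1] <- d2[2, 4] <- d2[4, 2] <- 0
  f2 <- amova(d2, c("A", "A", "B", "B"), n_perm = 0)
  expect_lte(unname(f2$phi["phi_st"]), 0)

  ## monomorphic total sample: statistic undefined
  f3 <- amova(matrix(0, 4, 4), c("A", "A", "B", "B"), n_perm = 0)
  expect_true(is.na(f3$phi["phi_st"]))
})

test_that("variance components match the brute-force oracle", {
  set.seed(11)
  for (s in 1:12) {
    n <- sample(9:15, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    pop <- sample(c("a", "b", "c"), n, replace = TRUE,
                  prob = c(0.4, 0.3, 0.3))
    while (min(table(pop)) < 2) pop <- sample(c("a", "b", "c"), n, TRUE)
    f <- amova(d, pop, n_perm = 0)
    o <- amova_oracle(d, pop)
    expect_equal(unname(f$sigma), unname(o$sigma), tolerance = 1e-10)
    expect_equal(unname(f$phi["phi_st"]), o$phi_st, tolerance = 1e-10)
    ## three-level with two groups
    grp <- ifelse(pop == "a", "g1", "g2")
    f3 <- amova(d, pop, grp, n_perm = 0)
    o3 <- amova_oracle(d, pop, grp)
    expect_equal(unname(f3$sigma), unname(o3$sigma), tolerance = 1e-10)
    expect_equal(unname(f3$phi["phi_ct"]), o3$phi_ct, tolerance = 1e-10)
    expect_equal(unname(f3$phi["phi_sc"]), o3$phi_sc, tolerance = 1e-10)
    expect_equal(sum(f3$pct), 100, tolerance = 1e-6)
  }
})

test_that("degenerate nesting (one population per group) zeroes the middle stratum", {
  set.seed(3)
  d <- as.matrix(dist(matrix(rnorm(36), 12)))
  pop <- rep(c("a", "b", "c"), each = 4)
  f <- amova(d, pop, groups = pop, n_perm = 0)
  expect_equal(unname(f$sigma["b"]), 0)
  expect_equal(unname(f$phi["phi_ct"]),
               unname(amova(d, pop, n_perm = 0)$phi["phi_st"]),
               tolerance = 1e-10)
})

test_that("Phi statistics are scale invariant; unit distances give F_ST", {
  set.seed(4)
  d <- as.matrix(dist(matrix(rnorm(30), 10)))
  pop <- rep(c("a", "b"), each = 5)
  f1 <- amova(d, pop, n_perm = 0)
  f2 <- amova(3.7 * d, pop, n_perm = 0)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-10)

  aln <- rand_aln(10, 40, seed = 9)
  du <- amova_fst_distances(aln)
  expect_true(all(du %in% c(0, 1)))
  ## unit-distance AMOVA equals the haplotype-frequency computation by
  ## construction; assert numerically against the oracle
  fu <- amova(du, pop, n_perm = 0)
  expect_equal(unname(fu$phi["phi_st"]), amova_oracle(du, pop)$phi_st,
               tolerance = 1e-10)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(5)
  d <- as.matrix(dist(matrix(rnorm(8 * 2), 8)))
  pop <- rep(c("A", "B"), each = 4)
  exact <- phi_exact_perm_p(d, pop)
  f <- amova(d, pop, n_perm = 999, seed = 10)
  mc <- unname(f$p["phi_st"])
  se <- sqrt(exact * (1 - exact) / 999)
  expect_lt(abs(mc - exact), 4 * se + 2 / 999)
})

test_that("permutation p-values are reproducible and bounded", {
  set.seed(6)
  d <- as.matrix(dist(matrix(rnorm(24), 12)))
  pop <- rep(c("a", "b"), each = 6)
  p1 <- amova(d, pop, n_perm = 199, seed = 3)$p["phi_st"]
  p2 <- amova(d, pop, n_perm = 199, seed = 3)$p["phi_st"]
  expect_equal(p1, p2)
  expect_gt(p1, 0); expect_lte(p1, 1)
})

test_that("null permutation p-values are approximately uniform", {
  ## continuous distances: no ties, so the permutation p is exactly
  ## discrete-uniform under random labels (sequence data with few
  ## segregating sites is conservative instead; see the vignette)
  set.seed(12)
  ps <- vapply(1:200, function(i) {
    d <- as.matrix(dist(matrix(rnorm(14 * 3), 14)))
    pop <- sample(rep(c("a", "b"), each = 7))
    amova(d, pop, n_perm = 199, seed = i)$p["phi_st"]
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pairwise matrices are consistent with per-pair AMOVAs and D_XY sums", {
  gen <- synth_generate(synth_preset("two_pop_null", seed = 21))
  ds <- gen$dataset
  pw <- pairwise_diff(ds, "nuclear", "PhiST", n_perm = 49, seed = 2)
  expect_equal(pw$values, t(pw$values))
  expect_equal(diag(pw$values), c(d1 = 0, d2 = 0))
  ## equals a direct two-level AMOVA on the same distances
  aln <- concatenate_loci(Filter(function(l) l$mode == "nuclear", ds$loci))
  pop <- ds$meta$population[match(aln$individual, ds$meta$individual)]
  d <- pairwise_distance(aln, "TN93")
  f <- amova(d, pop, n_perm = 0)
  expect_equal(pw$values["d1", "d2"], unname(f$phi["phi_st"]),
               tolerance = 1e-10)

  ## D_XY: two fixed haplotypes 3 differences apart over L = 100
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  aln2 <- locus_alignment("dx", "nuclear", c(s1, s1, s2, s2),
                          paste0("i", 1:4))
  meta <- data.frame(individual = paste0("i", 1:4),
                     population = rep(c("X", "Y"), each = 2),
                     group = "g", ocean = "o", sex = "unknown")
  ds2 <- pop_dataset(list(aln2), meta)
  dxy <- pairwise_diff(ds2, "nuclear", "DXY")
  expect_equal(dxy$values["X", "Y"], 0.03, tolerance = 1e-9)
})

test_that("Mantel recovers exact correlations and agrees with vegan", {
  g <- as.matrix(dist(c(1, 3, 4, 8, 9, 13)))
  rownames(g) <- colnames(g) <- paste0("p", 1:6)
  m <- mantel_test(g, g, transform = "none", n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p, 0.01)
  h <- max(g) - g; diag(h) <- 0
  rownames(h) <- colnames(h) <- rownames(g)
  m2 <- mantel_test(h, g, transform = "none", n_perm = 99, seed = 1)
  expect_equal(m2$r, -1)

  set.seed(8)
  a <- as.matrix(dist(rnorm(8))); b <- as.matrix(dist(rnorm(8)))
  rownames(a) <- colnames(a) <- rownames(b) <- colnames(b) <- paste0("q", 1:8)
  mine <- mantel_test(a, b, transform = "none", n_perm = 999, seed = 2)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(abs(mine$p - ref$signif), 0.12)

  ## determinism and transform flagging
  expect_equal(mantel_test(a, b, "none", 99, seed = 4)$r,
               mantel_test(a, b, "none", 99, seed = 4)$r)
  sat <- a / max(a); sat[1, 2] <- sat[2, 1] <- 1
  expect_warning(mantel_test(sat, b, "linearize", 49, seed = 1),
                 "F_ST = 1")
})
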