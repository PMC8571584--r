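test_that("FASTA reading assigns copies and rejects ragged alignments", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">ind1_a", "ACGTACGTAC", ">ind1_b", "ACGTACGTAG",
               ">ind2_a", "ACGTACGTAC", ">ind2_b", "ACGTACGTAC"), f)
  aln <- read_locus_fasta(f, mode = "nuclear", copies_per_individual = 2)
  expect_s3_class(aln, "locus_alignment")
  expect_equal(nrow(aln$seq), 4L)
  expect_equal(sort(unique(aln$individual)), c("ind1", "ind2"))
  expect_equal(aln$copy[aln$individual == "ind1"], 1:2)
  expect_equal(aln$L, 10L)

  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f2)
  expect_error(read_locus_fasta(f2, mode = "mitochondrial"), "ragged.*'b'")

  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGG"), f3)
  expect_error(read_locus_fasta(f3, mode = "mitochondrial"), "duplicate")
})

test_that("metadata parsing normalizes sex and enforces nesting", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("individual\tpopulation\tgroup\tocean\tsex",
               "i1\tRaso\tboydi\tatl\tfemale",
               "i2\tRaso\tboydi\tatl\tM",
               "i3\tCima\tboydi\tatl\tnd"), f)
  md <- read_metadata(f)
  expect_equal(nrow(md), 3L)
  expect_equal(md$sex, c("F", "M", "unknown"))

  bad <- data.frame(individual = c("i1", "i2"),
                    population = c("Raso", "Raso"),
                    group = c("boydi", "baroli"),
                    ocean = c("atl", "atl"), sex = c("F", "M"))
  expect_error(validate_metadata(bad), "nesting")
})

test_that("haplotype collapsing conserves counts and honours the site policy", {
  aln <- locus_alignment("x", "nuclear",
                         c("ACGT", "ACGT", "ATGT", "ATGT"),
                         paste0("i", 1:4))
  ht <- collapse_haplotypes(aln)
  expect_equal(nrow(ht$haplotypes), 2L)
  expect_equal(sort(ht$counts), c(2L, 2L))
  expect_equal(sum(ht$counts), 4L)

  same <- locus_alignment("y", "nuclear", rep("ACGT", 3), paste0("i", 1:3))
  expect_equal(nrow(collapse_haplotypes(same)$haplotypes), 1L)

  ## sequences differing only at an N-bearing column merge under
  ## complete deletion
  aln2 <- locus_alignment("z", "nuclear", c("ACGT", "ANGT"), c("i1", "i2"))
  expect_equal(nrow(collapse_haplotypes(aln2,
                                        "complete_deletion")$haplotypes), 1L)

  ## expanding counts by index reproduces the original multiset
  key_orig <- apply(aln$seq, 1, paste, collapse = "")
  key_back <- apply(ht$haplotypes[ht$index, , drop = FALSE], 1, paste,
                    collapse = "")
  expect_equal(sort(unname(key_orig)), sort(unname(key_back)))
})

test_that("pairwise distances match closed forms and stay symmetric", {
  same <- locus_alignment("a", "nuclear", rep("ACGTACGTAA", 2), c("i1", "i2"))
  for (m in c("p", "JC", "K2P", "TN93"))
    expect_equal(pairwise_distance(same, m)[1, 2], 0)

  ## one transition among four sites: K2P = -log(0.5)/2
  a <- locus_alignment("b", "mitochondrial", c("AAAA", "AAAG"),
                       c("i1", "i2"))
  expect_equal(pairwise_distance(a, "K2P")[1, 2], -0.5 * log(0.5),
               tolerance = 1e-6)

  a2 <- locus_alignment("c", "nuclear", c("AAAAAAAAAA", "AAAAAAAAGG"),
                        c("i1", "i2"))
  expect_equal(pairwise_distance(a2, "p")[1, 2], 0.2)

  for (s in 1:5) {
    r <- rand_aln(6, 60, seed = s)
    for (m in c("p", "JC", "K2P", "TN93")) {
      d <- pairwise_distance(r, m)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
    }
  }
})

test_that("K2P approaches JC when transitions and transversions are pooled", {
  ## low divergence, random substitution classes: expected ts/tv ratio 1/2
  set.seed(42)
  diffs <- sapply(1:20, function(i) {
    r <- rand_aln(8, 400, seed = 100 + i)
    dk <- pairwise_distance(r, "K2P")
    dj <- pairwise_distance(r, "JC")
    mean(abs(dk - dj), na.rm = TRUE)
  })
  expect_lt(median(diffs, na.rm = TRUE), 0.05)
})

test_that("locus concatenation sums lengths and enforces ploidy pairing", {
  mk <- function(name, L, ids = paste0("i", 1:3))
    locus_alignment(name, "mitochondrial",
                    replicate(length(ids),
                              paste(sample(c("A", "C", "G", "T"), L,
                                           TRUE), collapse = "")),
                    ids)
  set.seed(1)
  loci <- list(mk("cox1like", 577), mk("cytblike", 877), mk("crlike", 307))
  cc <- concatenate_loci(loci)
  expect_equal(cc$L, 1761L)          # 577 + 877 + 307
  expect_equal(nrow(cc$seq), 3L)

  single <- concatenate_loci(loci[1])
  expect_identical(single, loci[[1]])

  dip <- locus_alignment("nuc", "nuclear",
                         c("ACGT", "ACGT"), c("i1", "i1"), copy = 1:2,
                         copies_per_individual = 2)
  expect_error(concatenate_loci(list(loci[[1]], dip)), "copies|modes")

  ## individuals missing a locus are dropped and reported
  l2 <- mk("partial", 100, ids = paste0("i", 1:2))
  cc2 <- concatenate_loci(list(loci[[1]], l2))
  expect_equal(sort(unique(cc2$individual)), c("i1", "i2"))
  expect_equal(attr(cc2, "dropped"), "i3")
})

test_that("dataset round-trips through the on-disk layout byte-identically", {
  gen <- synth_generate(synth_preset("two_pop_null", seed = 3))
  d1 <- file.path(tempfile(), "ds")
  write_dataset(gen$dataset, d1)
  back <- read_dataset(d1)
  expect_equal(length(back$loci), length(gen$dataset$loci))
  expect_equal(back$meta$population, gen$dataset$meta$population)
  expect_equal(back$loci[[1]]$seq, gen$dataset$loci[[1]]$seq)
})
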