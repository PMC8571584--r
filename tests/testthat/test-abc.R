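test_that("scenario validation catches non-coalescing histories", {
  expect_error(scenario("bad", sizes = c(a = 100, b = 100), events = list()),
               "does not coalesce")
  sc <- scenario("ok", sizes = c(a = 100, b = 100),
                 events = list(list(time = 50, type = "divergence",
                                    from = "b", to = "a")))
  expect_s3_class(sc, "scenario")
})

test_that("priors honour bounds, log scale and ordering constraints", {
  pr <- prior_spec(bounds = list(x = c(1, 2), t1 = c(0, 10), t2 = c(0, 10),
                                 mu = c(1e-9, 1e-7)),
                   log_scale = "mu", order = list(c("t1", "t2")))
  set.seed(1)
  for (i in 1:50) {
    p <- draw_params(pr)
    expect_true(p["x"] >= 1 && p["x"] <= 2)
    expect_lte(p["t1"], p["t2"])
    expect_true(p["mu"] >= 1e-9 && p["mu"] <= 1e-7)
  }
  expect_error(prior_spec(bounds = list(x = c(2, 1))), "lower")
})

test_that("the simulator matches neutral coalescent expectations", {
  sc <- scenario("one", sizes = c(A = 1e4), events = list())
  design1 <- list(samples = c(A = 2L),
                  loci = list(list(name = "l1", mode = "mitochondrial",
                                   L = 1000, mu = 8e-8)))
  ## E[kbar] = theta = 2 * (2 N m) * mu * L with m = 0.25
  th <- 2 * (2 * 1e4 * 0.25) * 8e-8 * 1000
  set.seed(2)
  kb <- vapply(1:2000, function(i) {
    st <- seqpopgen:::sim_states(sc, c(x = 1), design1)
    seqpopgen:::kbar_from_states(st$l1$states)
  }, 0)
  expect_lt(abs(mean(kb) - th) / th, 0.05)

  ## E[S] = theta * a1 at n = 10 (nuclear mode, 5 individuals x 2 copies)
  design2 <- list(samples = c(A = 5L),
                  loci = list(list(name = "l1", mode = "nuclear",
                                   L = 1000, mu = 5e-8)))
  thn <- 4 * 1e4 * 5e-8 * 1000
  set.seed(3)
  S <- vapply(1:2000, function(i)
    ncol(seqpopgen:::sim_states(sc, c(x = 1), design2)$l1$states), 0)
  expect_lt(abs(mean(S) - thn * sum(1 / (1:9))) / (thn * sum(1 / (1:9))),
            0.05)
})

test_that("a zero-aged split yields no differentiation; mtDNA is scaled down", {
  sc <- scenario("split0", sizes = c(A = 5e3, B = 5e3),
                 events = list(list(time = 0.001, type = "divergence",
                                    from = "B", to = "A")))
  design <- list(samples = c(A = 8L, B = 8L),
                 loci = list(list(name = "mt", mode = "mitochondrial",
                                  L = 800, mu = 3e-7),
                             list(name = "nu", mode = "nuclear",
                                  L = 800, mu = 3e-7)))
  set.seed(4)
  fst <- replicate(60, {
    st <- seqpopgen:::sim_states(sc, c(x = 1), design)
    v <- seqpopgen:::summarize_states(st, c("A", "B"))
    c(v["mt_A_B_FST"], v["nu_A_B_FST"], v["mt_kbar_A"], v["nu_kbar_A"])
  })
  expect_lt(abs(mean(fst[1, ])), 0.05)
  expect_lt(abs(mean(fst[2, ])), 0.05)
  ## quarter effective size: mtDNA within-pop diversity below nuclear
  expect_gt(mean(fst[4, ] > fst[3, ]), 0.8)
})

test_that("dataset materialization agrees with the fast summary path", {
  setup <- abc_recovery_setup()
  sc <- setup$rounds$topology[[2]]
  set.seed(9)
  params <- draw_params(setup$priors)
  set.seed(101)
  st <- seqpopgen:::sim_states(sc, params, setup$design)
  v_fast <- seqpopgen:::summarize_states(st, c("p1", "p2", "p3"))
  ds <- seqpopgen:::states_to_dataset(st, setup$design)
  v_full <- summarize_dataset(ds)
  expect_equal(v_fast[names(v_full)], v_full, tolerance = 1e-9,
               ignore_attr = TRUE)
  ## summary invariance to individual order
  ids <- sample(ds$meta$individual)
  ds2 <- subset_individuals(ds, ids)
  expect_equal(summarize_dataset(ds2), v_full, ignore_attr = TRUE)
})

test_that("rejection keeps the nearest rows and the requested fraction", {
  set.seed(7)
  tab <- data.frame(s1 = rnorm(400), s2 = rnorm(400),
                    scenario = rep(c("A", "B"), each = 200))
  attr(tab, "stat_names") <- c("s1", "s2")
  obs <- c(s1 = tab$s1[17], s2 = tab$s2[17])
  ret <- abc_reject(obs, tab, tolerance = 0.05)
  expect_equal(nrow(ret$rows), 20L)          # ceil(0.05 * 400)
  expect_equal(ret$distance[1], 0)
  expect_equal(rownames(ret$rows)[1], "17")
  retall <- abc_reject(obs, tab, tolerance = 1)
  expect_equal(nrow(retall$rows), 400L)
  ## zero-variance summary dropped with warning
  tab$s3 <- 1; attr(tab, "stat_names") <- c("s1", "s2", "s3")
  expect_warning(abc_reject(c(obs, s3 = 1), tab, 0.05), "zero-variance")
})

test_that("posterior probabilities are coherent in symmetric and extreme cases", {
  set.seed(8)
  ## balanced retained set, observed at the centroid
  tab <- data.frame(s1 = c(rnorm(100, -1), rnorm(100, 1)),
                    s2 = rnorm(200),
                    scenario = rep(c("A", "B"), each = 100))
  attr(tab, "stat_names") <- c("s1", "s2")
  ret <- abc_reject(c(s1 = 0, s2 = 0), tab, tolerance = 1)
  pp <- posterior_probability(ret)
  expect_equal(sum(pp$posterior$posterior), 1, tolerance = 1e-6)
  expect_lt(abs(pp$posterior$posterior[1] - 0.5), 0.15)

  ## single-scenario retained set
  tabA <- tab[tab$scenario == "A", ]
  attr(tabA, "stat_names") <- c("s1", "s2")
  retA <- abc_reject(c(s1 = -1, s2 = 0), tabA, tolerance = 0.5)
  ppA <- suppressWarnings(posterior_probability(retA, "direct"))
  expect_gte(ppA$posterior$posterior[ppA$posterior$scenario == "A"], 0.99)

  ## direct and lda_logit agree on well-separated scenarios
  ppd <- posterior_probability(ret, "direct")
  expect_lt(abs(ppd$posterior$posterior[1] -
                  pp$posterior$posterior[1]), 0.2)
})

test_that("two identical scenarios are undecided; the chain is deterministic", {
  sizes <- c(a = 5e3, b = 5e3)
  ev <- list(list(time = 2000, type = "divergence", from = "b", to = "a"))
  twins <- list(scenario("s1", sizes, ev), scenario("s2", sizes, ev))
  pr <- prior_spec(bounds = list(dummy = c(0, 1)))
  design <- list(samples = c(a = 6L, b = 6L),
                 loci = list(list(name = "mt", mode = "mitochondrial",
                                  L = 500, mu = 4e-7)))
  set.seed(30)
  gen_obs <- seqpopgen:::sim_states(twins[[1]], c(dummy = 0.5), design)
  obs <- seqpopgen:::summarize_states(gen_obs, c("a", "b"))
  t1 <- hierarchical_compare(list(r1 = twins), obs, pr, design,
                             n_sim = 400, tolerance = 0.25, seed = 5)
  expect_equal(t1$winners, "undecided")
  t2 <- hierarchical_compare(list(r1 = twins), obs, pr, design,
                             n_sim = 400, tolerance = 0.25, seed = 5)
  expect_equal(t1$results$r1$posterior, t2$results$r1$posterior)
  expect_error(hierarchical_compare(list(), obs, pr, design), "empty")
})

test_that("admixture moves lineages and size changes apply", {
  sc <- scenario("adm", sizes = c(a = 5e3, b = 5e3),
                 events = list(
                   list(time = 100, type = "admixture", from = "a",
                        to = "b", prob = 1),
                   list(time = 500, type = "size_change", pop = "b",
                        size = 100),
                   list(time = 2000, type = "divergence", from = "b",
                        to = "a")))
  set.seed(31)
  design <- list(samples = c(a = 5L, b = 5L),
                 loci = list(list(name = "mt", mode = "mitochondrial",
                                  L = 400, mu = 3e-7)))
  st <- seqpopgen:::sim_states(sc, c(x = 1), design)
  expect_equal(nrow(st$mt$states), 10L)
  v <- seqpopgen:::summarize_states(st, c("a", "b"))
  expect_true(is.finite(v[["mt_a_b_FST"]]))
})
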