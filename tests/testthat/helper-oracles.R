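## Independent oracles used across the suite. These re-derive quantities
## from first principles (explicit loops, exhaustive enumeration) and must
## stay independent of the package's computational paths.

## random alignment fixture
rand_aln <- function(n, L, seed, mode = "nuclear", miss = 0) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  ## anchor some shared ancestry so sites are not all singletons
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  keepvar <- runif(L) < 0.3
  for (i in seq_len(n)) m[i, !keepvar] <- base[!keepvar]
  if (miss > 0) m[sample(length(m), miss)] <- "N"
  locus_alignment(paste0("rnd", seed), mode, m, paste0("i", seq_len(n)))
}

## brute-force AMOVA: explicit pair loops for every SSD term, components
## from the definitional expected-mean-square equations
amova_oracle <- function(d, pop, group = NULL) {
  D2 <- d^2
  N <- nrow(D2)
  ssd_pairs <- function(idx) {
    s <- 0
    if (length(idx) < 2) return(0)
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) s <- s + D2[idx[a], idx[b]]
    s / length(idx)
  }
  ssd_total <- 0
  for (a in 1:N) for (b in 1:N) if (a < b) ssd_total <- ssd_total + D2[a, b]
  ssd_total <- ssd_total / N
  pops <- unique(pop)
  ssd_wp <- sum(vapply(pops, function(p) ssd_pairs(which(pop == p)), 0))
  np <- vapply(pops, function(p) sum(pop == p), 0)
  if (is.null(group)) {
    P <- length(pops)
    sb <- ssd_wp / (N - P)
    nprime <- (N - sum(np^2) / N) / (P - 1)
    sa <- ((ssd_total - ssd_wp) / (P - 1) - sb) / nprime
    list(sigma = c(a = sa, b = sb), phi_st = sa / (sa + sb),
         ssd = c(among = ssd_total - ssd_wp, within = ssd_wp,
                 total = ssd_total))
  } else {
    groups <- unique(group)
    G <- length(groups)
    P <- length(pops)
    ssd_wg <- sum(vapply(groups, function(g) ssd_pairs(which(group == g)), 0))
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    gof <- vapply(pops, function(p) group[which(pop == p)[1]], "")
    ng <- vapply(groups, function(g) sum(group == g), 0)
    sc <- ssd_wp / (N - P)
    sumg <- vapply(groups, function(g) sum(np[gof == g]^2) / ng[groups == g], 0)
    nc <- (N - sum(sumg)) / (P - G)
    nc1 <- (sum(sumg) - sum(np^2) / N) / (G - 1)
    nc2 <- (N - sum(ng^2) / N) / (G - 1)
    sb <- (ssd_ap / (P - G) - sc) / nc
    sa <- (ssd_ag / (G - 1) - sc - nc1 * sb) / nc2
    list(sigma = c(a = sa, b = sb, c = sc),
         phi_ct = sa / (sa + sb + sc), phi_sc = sb / (sb + sc),
         phi_st = (sa + sb) / (sa + sb + sc))
  }
}

## exhaustive two-population permutation distribution of Phi_ST
phi_exact_perm_p <- function(d, pop) {
  obs <- amova_oracle(d, pop)$phi_st
  N <- nrow(d)
  n1 <- sum(pop == pop[1])
  combs <- combn(N, n1)
  stats <- apply(combs, 2, function(ix) {
    pp <- rep("B", N)
    pp[ix] <- "A"
    amova_oracle(d, pp)$phi_st
  })
  mean(stats >= obs - 1e-12)
}

## exact Ewens distribution of the allele count by partition enumeration
ewens_enum <- function(n, theta) {
  parts <- function(n, mx = n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (k in min(n, mx):1)
      for (p in parts(n - k, k)) out <- c(out, list(c(k, p)))
    out
  }
  rf <- prod(theta + 0:(n - 1))
  pk <- numeric(n)
  for (lam in parts(n)) {
    k <- length(lam)
    a <- tabulate(lam, n)
    pk[k] <- pk[k] + factorial(n) / rf * prod((theta / (1:n))^a /
                                                factorial(a))
  }
  pk
}

## neutral single-population dataset at scaled mutation rate theta,
## via the package simulator (N and mu*L chosen so 4*N*mu*L = theta)
sim_neutral_states <- function(n, theta, L = 1000, N = 1e4) {
  mu <- theta / (4 * N * L)
  tr <- seqpopgen:::sim_structured_tree(setNames(n, "A"), c(A = N), mult = 1)
  seqpopgen:::sim_locus_states(tr, mu, L)$states
}
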