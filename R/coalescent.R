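## Backwards-in-time Kingman coalescent with population structure.
##
## Trees are stored as parent pointers: tips are nodes 1..n, internal nodes
## n+1..2n-1, `time[node]` increases into the past. Within a population of
## (census) size N and ploidy multiplier m, each lineage pair coalesces at
## rate 1/(2*N*m) per generation (m = 1 for autosomal nuclear loci, 0.25
## for matrilineally inherited haploid mtDNA).

## single panmictic population, time in units of 2N generations
sim_single_tree <- function(n) {
  ntot <- 2L * n - 1L
  parent <- integer(ntot)
  time <- numeric(ntot)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1L, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n = n, root = ntot)
}

## structured coalescent with divergence / size-change / admixture events.
## samples: integer vector of lineage counts named by population.
## sizes:   numeric vector of population sizes named by population
##          (ancestral-only populations included).
## events:  list of lists, each with $time (generations, increasing),
##          $type in {"divergence","size_change","admixture"} and fields
##          from/to/pop/size/prob.
sim_structured_tree <- function(samples, sizes, mult = 1, events = list()) {
  pops <- names(samples)
  n <- sum(samples)
  ntot <- 2L * n - 1L
  parent <- integer(ntot)
  time <- numeric(ntot)
  tip_pop <- rep(pops, samples)
  act <- split(seq_len(n), factor(tip_pop, levels = names(sizes)))
  sizes <- sizes
  ev <- events[order(vapply(events, `[[`, 0, "time"))]
  ei <- 1L
  t <- 0
  nxt <- n + 1L
  repeat {
    k <- lengths(act)
    if (sum(k) <= 1L) break
    rate <- k * (k - 1) / 2 / (2 * sizes[names(act)] * mult)
    rate[is.na(rate) | !is.finite(rate)] <- 0
    total <- sum(rate)
    tc <- if (total > 0) t + rexp(1L, total) else Inf
    te <- if (ei <= length(ev)) ev[[ei]]$time else Inf
    if (te <= tc) {
      if (!is.finite(te))
        stop("non-coalescing scenario: lineages remain in ",
             sum(k > 0), " populations with no further divergence event")
      e <- ev[[ei]]; ei <- ei + 1L; t <- te
      if (e$type == "divergence") {
        act[[e$to]] <- c(act[[e$to]], act[[e$from]])
        act[[e$from]] <- integer(0)
        sizes[e$from] <- NA_real_          # population no longer exists
      } else if (e$type == "size_change") {
        sizes[e$pop] <- e$size
      } else if (e$type == "admixture") {
        mv <- runif(length(act[[e$from]])) < e$prob
        act[[e$to]] <- c(act[[e$to]], act[[e$from]][mv])
        act[[e$from]] <- act[[e$from]][!mv]
      } else stop("unknown event type: ", e$type)
    } else {
      t <- tc
      p <- sample.int(length(rate), 1L, prob = rate / total)
      pick <- sample.int(k[p], 2L)
      ids <- act[[p]][pick]
      parent[ids] <- nxt
      time[nxt] <- t
      act[[p]] <- c(act[[p]][-pick], nxt)
      nxt <- nxt + 1L
    }
  }
  list(parent = parent, time = time, n = n, root = ntot, tip_pop = tip_pop)
}

## per-edge lengths; edge i is (node i -> parent[i]) for i != root
edge_lengths <- function(tree) {
  len <- numeric(length(tree$parent))
  nz <- tree$parent > 0L
  len[nz] <- tree$time[tree$parent[nz]] - tree$time[nz]
  len
}

## number of descendant tips under each node
descendant_counts <- function(tree) {
  cnt <- c(rep(1L, tree$n), integer(tree$n - 1L))
  for (i in order(tree$time[seq_along(tree$parent)])) {
    p <- tree$parent[i]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[i]
  }
  ## order(time) works because parents are strictly older than children
  cnt
}

## logical tips-x-nodes membership for the nodes in `nodes`
descendant_sets <- function(tree, nodes) {
  n <- tree$n
  memb <- matrix(FALSE, n, length(nodes))
  for (j in seq_along(nodes)) {
    stack <- nodes[j]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) memb[v, j] <- TRUE
      else stack <- c(stack, which(tree$parent == v))
    }
  }
  memb
}

## place exactly S infinite-sites mutations on the tree, branch-length
## weighted (the standard fixed-S conditional simulation); returns the
## tips-x-S derived-state membership matrix
place_mutations_fixed_s <- function(tree, S) {
  len <- edge_lengths(tree)
  nodes <- sample.int(length(len), S, replace = TRUE, prob = len)
  descendant_sets(tree, nodes)
}

## finite-sites Jukes-Cantor mutation; returns variable sites only:
## list(sites, states [tips x length(sites)] with bases in 1..4, L)
sim_locus_states <- function(tree, mu, L) {
  len <- edge_lengths(tree)
  nmut <- rpois(length(len), mu * L * len)
  M <- sum(nmut)
  if (M == 0L)
    return(list(sites = integer(0),
                states = matrix(integer(0), tree$n, 0), L = L))
  site <- sample.int(L, M, replace = TRUE)
  step <- sample.int(3L, M, replace = TRUE)
  edge_of <- rep(seq_along(len), nmut)
  vs <- sort(unique(site))
  scol <- match(site, vs)
  nV <- length(vs)
  ntot <- length(tree$parent)
  states <- matrix(0L, ntot, nV)
  states[tree$root, ] <- sample.int(4L, nV, replace = TRUE)
  ## process nodes parent-before-child (decreasing age; tips last)
  ord <- order(-tree$time[seq_len(ntot)])
  mut_by_edge <- split(seq_len(M), edge_of)
  for (v in ord) {
    if (v == tree$root) next
    st <- states[tree$parent[v], ]
    mm <- mut_by_edge[[as.character(v)]]
    if (!is.null(mm)) {
      for (m in mm[sample.int(length(mm))]) {  # random within-edge order
        j <- scol[m]
        st[j] <- ((st[j] - 1L + step[m]) %% 4L) + 1L
      }
    }
    states[v, ] <- st
  }
  tipstates <- states[seq_len(tree$n), , drop = FALSE]
  ## drop sites that ended up monomorphic (back-mutation)
  poly <- apply(tipstates, 2, function(x) length(unique(x)) > 1L)
  list(sites = vs[poly], states = tipstates[, poly, drop = FALSE], L = L)
}

## mean pairwise differences per sequence (absolute) from a variable-site
## state matrix
kbar_from_states <- function(states) {
  n <- nrow(states)
  if (n < 2L) return(NA_real_)
  if (ncol(states) == 0L) return(0)
  tot <- 0
  for (j in seq_len(ncol(states))) {
    cnt <- tabulate(states[, j], 4L)
    tot <- tot + (choose(n, 2) - sum(choose(cnt, 2)))
  }
  tot / choose(n, 2)
}

## pairwise difference matrix (absolute counts) from variable-site states
diff_matrix_from_states <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  if (ncol(states)) {
    for (b in 1:4) {
      ind <- states == b
      d <- d + tcrossprod(ind * 1)
    }
    d <- ncol(states) - d
    diag(d) <- 0
  }
  d
}
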