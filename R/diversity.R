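## Within-population diversity and neutrality statistics.

#' Number of segregating (polymorphic) sites
#'
#' A retained column is segregating when it carries at least two distinct
#' non-missing states.
#'
#' @param aln a [locus_alignment()] (>= 2 sequence copies).
#' @param site_policy missing-site policy; under `complete_deletion` columns
#'   with any missing character are removed before counting.
#' @return integer count.
#' @export
segregating_sites <- function(aln, site_policy = c("complete_deletion",
                                                   "pairwise_ignore_missing")) {
  site_policy <- match.arg(site_policy)
  if (nrow(aln$seq) < 2L) stop("need at least 2 sequence copies")
  s <- aln$seq[, retained_sites(aln$seq, site_policy), drop = FALSE]
  if (!ncol(s)) return(0L)
  sum(apply(s, 2, function(col) {
    length(unique(col[!(col %in% MISSING_CHARS)])) >= 2L
  }))
}

#' Haplotype (gene) diversity
#'
#' `hd = n (1 - sum p_i^2) / (n - 1)` with `p_i` the haplotype relative
#' frequencies.
#'
#' @param table a [collapse_haplotypes()] result, or an integer vector of
#'   haplotype counts.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(table) {
  counts <- if (inherits(table, "haplotype_table")) {
    if (is.matrix(table$counts)) rowSums(table$counts) else table$counts
  } else as.numeric(table)
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequence copies")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Per-site nucleotide diversity and companion statistics
#'
#' `pi` is the mean over all unordered sequence pairs of the per-site
#' p-distance on retained sites; `k_bar = pi * L` is the mean number of
#' pairwise differences.
#'
#' @inheritParams segregating_sites
#' @return class `diversity_result` with fields `n`, `L`, `S`, `K`, `hd`,
#'   `pi`, `k_bar`.
#' @export
nucleotide_diversity <- function(aln, site_policy = c("complete_deletion",
                                                      "pairwise_ignore_missing")) {
  site_policy <- match.arg(site_policy)
  n <- nrow(aln$seq)
  if (n < 2L) stop("need at least 2 sequence copies")
  keep <- retained_sites(aln$seq, site_policy)
  if (!length(keep)) stop("no sites retained after deletion of missing data")
  d <- pairwise_distance(aln, model = "p", site_policy = site_policy)
  pi <- mean(d[upper.tri(d)], na.rm = TRUE)
  ht <- collapse_haplotypes(aln, site_policy)
  structure(list(n = n, L = length(keep),
                 S = segregating_sites(aln, site_policy),
                 K = nrow(ht$haplotypes),
                 hd = haplotype_diversity(ht),
                 pi = pi, k_bar = pi * length(keep)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("n=%d  L=%d  S=%d  K=%d  hd=%.4f  pi=%.5f  k_bar=%.3f\n",
              x$n, x$L, x$S, x$K, x$hd, x$pi, x$k_bar))
  invisible(x)
}

#' Tajima's D
#'
#' Contrasts the mean number of pairwise differences with the scaled number
#' of segregating sites under the standard variance coefficients.
#'
#' @param S segregating sites (>= 0).
#' @param n number of sequences (>= 4; the variance coefficients are not
#'   defined below that).
#' @param k_bar mean pairwise differences (absolute).
#' @return the statistic, or `NA` when `S = 0`.
#' @export
tajima_d <- function(S, n, k_bar) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## log unsigned Stirling numbers of the first kind, row n (k = 1..n),
## computed once per n via the triangular recurrence in log space
.stirling_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- 0                                   # n = 1: |s(1,1)| = 1
  if (n > 1) for (m in 1:(n - 1)) {
    ## |s(m+1,k)| = m |s(m,k)| + |s(m,k-1)|
    up <- c(-Inf, row)                       # shift: |s(m, k-1)|
    same <- c(row, -Inf) + log(m)
    row <- pmax(up, same) + log1p(exp(-abs(up - same)))
    row[is.nan(row)] <- -Inf
  }
  .stirling_cache[[key]] <- row
  row
}

#' Ewens sampling distribution of the number of alleles
#'
#' `P(K = k | n, theta)` via unsigned Stirling numbers of the first kind.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @return numeric vector of log-probabilities for `k = 1..n`.
#' @export
ewens_log_probs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  log_stirling_row(n) + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1)))
}

#' Fu's Fs
#'
#' `S'` is the Ewens probability of observing at least the sampled number of
#' alleles given `theta`; `Fs = ln(S' / (1 - S'))`. Strongly negative values
#' indicate an excess of alleles, as after demographic expansion.
#'
#' @param K_obs observed number of haplotypes/alleles.
#' @param n number of sequences.
#' @param theta scaled mutation parameter; conventionally the mean pairwise
#'   differences `k_bar`.
#' @return the statistic, or `NA` when `K_obs = 1` or `theta <= 0`.
#' @export
fu_fs <- function(K_obs, n, theta) {
  if (n < 2) stop("need n >= 2")
  if (is.na(theta) || theta <= 0 || K_obs <= 1) return(NA_real_)
  lp <- ewens_log_probs(n, theta)
  logS <- logsumexp(lp[K_obs:n])
  log1mS <- logsumexp(lp[seq_len(K_obs - 1)])
  logS - log1mS
}

#' Coalescent-simulation p-values for Tajima's D and Fu's Fs
#'
#' Simulates neutral constant-size coalescent samples conditioned on the
#' observed number of segregating sites (mutations placed on the simulated
#' genealogy proportionally to branch length) and reports lower-tail
#' p-values `(count + 1) / (n_sim + 1)`, following the convention that
#' significance is an excess of negative values.
#'
#' @param n number of sequences.
#' @param S observed segregating sites.
#' @param D_obs,Fs_obs observed statistics (either may be `NA`).
#' @param n_sim number of simulated samples (>= 100).
#' @param seed integer RNG seed.
#' @return class `neutrality_result`: `D`, `Fs`, `p_D`, `p_Fs`, `n_sim`.
#' @export
neutrality_pvalues <- function(n, S, D_obs, Fs_obs, n_sim = 1000, seed = 1L) {
  stopifnot(n_sim >= 100)
  if (S == 0 || n < 4)
    return(structure(list(D = D_obs, Fs = Fs_obs, p_D = NA_real_,
                          p_Fs = NA_real_, n_sim = n_sim),
                     class = "neutrality_result"))
  set.seed(seed)
  Ds <- Fss <- rep(NA_real_, n_sim)
  for (r in seq_len(n_sim)) {
    tree <- sim_single_tree(n)
    memb <- place_mutations_fixed_s(tree, S)
    cnt <- colSums(memb)
    kb <- sum(cnt * (n - cnt)) / choose(n, 2)
    Ds[r] <- tajima_d(S, n, kb)
    K <- nrow(unique(memb))
    Fss[r] <- fu_fs(K, n, kb)
  }
  p_D <- if (is.na(D_obs)) NA_real_ else
    (sum(Ds <= D_obs + 1e-12, na.rm = TRUE) + 1) / (sum(!is.na(Ds)) + 1)
  p_Fs <- if (is.na(Fs_obs)) NA_real_ else
    (sum(Fss <= Fs_obs + 1e-12, na.rm = TRUE) + 1) / (sum(!is.na(Fss)) + 1)
  structure(list(D = D_obs, Fs = Fs_obs, p_D = p_D, p_Fs = p_Fs,
                 n_sim = n_sim), class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Tajima's D = %.4f (p = %s)   Fu's Fs = %.4f (p = %s)  [%d sims]\n",
              x$D, format(x$p_D, digits = 3), x$Fs,
              format(x$p_Fs, digits = 3), x$n_sim))
  invisible(x)
}

#' Neutrality tests for one alignment
#'
#' Computes `S`, `k_bar` and the haplotype count from the alignment, then
#' Tajima's D, Fu's Fs (with `theta = k_bar`) and their simulation p-values.
#'
#' @inheritParams segregating_sites
#' @inheritParams neutrality_pvalues
#' @export
neutrality_test <- function(aln, n_sim = 1000, seed = 1L,
                            site_policy = "complete_deletion") {
  dv <- nucleotide_diversity(aln, site_policy)
  D <- if (dv$n >= 4 && dv$S > 0) tajima_d(dv$S, dv$n, dv$k_bar) else NA_real_
  Fs <- fu_fs(dv$K, dv$n, dv$k_bar)
  neutrality_pvalues(dv$n, dv$S, D, Fs, n_sim = n_sim, seed = seed)
}

#' Per-locus, per-population diversity and neutrality table
#'
#' One row per locus x population (plus a pooled `ALL` row per locus),
#' mirroring the usual marker summary tables. No multiple-testing
#' correction is applied to the neutrality p-values; with many
#' locus-by-locality cells some significant values are expected by chance.
#'
#' @param dataset a [pop_dataset()].
#' @param n_sim coalescent replicates for neutrality p-values; `0` skips
#'   the p-values (statistics are still reported).
#' @param seed master seed; each cell derives its own seed.
#' @param min_n minimum copies per cell (smaller cells are skipped).
#' @return data.frame with columns locus, population, n, L, S, K, hd, pi,
#'   D, p_D, Fs, p_Fs.
#' @export
diversity_table <- function(dataset, n_sim = 1000, seed = 1L, min_n = 4L) {
  rows <- list()
  for (lc in dataset$loci) {
    popof <- dataset$meta$population[match(lc$individual,
                                           dataset$meta$individual)]
    for (pop in c("ALL", sort(unique(popof)))) {
      sel <- if (pop == "ALL") rep(TRUE, nrow(lc$seq)) else popof == pop
      if (sum(sel) < max(2L, min_n)) next
      sub <- locus_alignment(lc$name, lc$mode, lc$seq[sel, , drop = FALSE],
                             lc$individual[sel], lc$copy[sel],
                             lc$copies_per_individual, lc$model)
      dv <- nucleotide_diversity(sub)
      D <- if (dv$n >= 4 && dv$S > 0) tajima_d(dv$S, dv$n, dv$k_bar) else NA
      Fs <- fu_fs(dv$K, dv$n, dv$k_bar)
      if (n_sim > 0) {
        nt <- neutrality_pvalues(dv$n, dv$S, D, Fs, n_sim = max(100, n_sim),
                                 seed = spawn_seed(seed,
                                                   paste(lc$name, pop)))
        pD <- nt$p_D; pFs <- nt$p_Fs
      } else pD <- pFs <- NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(locus = lc$name, population = pop, n = dv$n, L = dv$L,
                   S = dv$S, K = dv$K, hd = dv$hd, pi = dv$pi,
                   D = D, p_D = pD, Fs = Fs, p_Fs = pFs)
    }
  }
  do.call(rbind, rows)
}
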