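## Sex-biased dispersal inference from phased nuclear loci: per-sex F_IS
## (Weir-Cockerham), maximum-likelihood pairwise relatedness (dyadic IBD
## mixture, projected EM) and the bootstrap difference-of-means test.

#' Build a genotype table from phased nuclear loci
#'
#' Each nuclear locus' sequence copies are collapsed to haplotypes; the two
#' haplotype indices of an individual form its genotype (alleles =
#' haplotypes). Individuals missing a copy at a locus get a missing
#' genotype there.
#'
#' @param dataset a [pop_dataset()].
#' @param loci names of the nuclear loci to use (default: all with
#'   `copies_per_individual == 2`).
#' @param site_policy haplotype-collapsing policy.
#' @return class `genotype_table`: `a1`, `a2` (individual x locus allele
#'   index matrices, `NA` = missing), `individuals`, `population`, `sex`,
#'   `loci`.
#' @export
genotypes_from_phased <- function(dataset, loci = NULL,
                                  site_policy = "complete_deletion") {
  cand <- Filter(function(l) l$mode == "nuclear" &&
                   l$copies_per_individual == 2L, dataset$loci)
  if (!is.null(loci)) cand <- cand[vapply(cand, `[[`, "", "name") %in% loci]
  if (!length(cand)) stop("no phased nuclear loci available")
  inds <- dataset$meta$individual
  nL <- length(cand)
  a1 <- a2 <- matrix(NA_integer_, length(inds), nL,
                     dimnames = list(inds, vapply(cand, `[[`, "", "name")))
  for (j in seq_len(nL)) {
    lc <- cand[[j]]
    ht <- collapse_haplotypes(lc, site_policy)
    for (id in unique(lc$individual)) {
      rows <- which(lc$individual == id)
      if (length(rows) != 2L) next               # missing one copy
      i <- match(id, inds)
      if (is.na(i)) next
      al <- sort(ht$index[rows])
      a1[i, j] <- al[1]; a2[i, j] <- al[2]
    }
  }
  structure(list(a1 = a1, a2 = a2, individuals = inds,
                 population = dataset$meta$population,
                 sex = dataset$meta$sex,
                 loci = colnames(a1)),
            class = "genotype_table")
}

#' Construct a genotype table directly from allele matrices
#' @param a1,a2 individual x locus allele-index matrices.
#' @param population,sex per-individual labels.
#' @return a `genotype_table`.
#' @export
genotype_table <- function(a1, a2, population,
                           sex = rep("unknown", nrow(a1))) {
  stopifnot(identical(dim(a1), dim(a2)), nrow(a1) == length(population))
  ids <- rownames(a1) %||% paste0("ind", seq_len(nrow(a1)))
  rownames(a1) <- rownames(a2) <- ids
  structure(list(a1 = a1, a2 = a2, individuals = ids,
                 population = as.character(population),
                 sex = as.character(sex),
                 loci = colnames(a1) %||% paste0("L", seq_len(ncol(a1)))),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals x",
      length(x$loci), "loci;",
      sum(is.na(x$a1)), "missing genotype cells\n")
  invisible(x)
}

subset_genotypes <- function(gt, sel) {
  genotype_table(gt$a1[sel, , drop = FALSE], gt$a2[sel, , drop = FALSE],
                 gt$population[sel], gt$sex[sel])
}

## Weir-Cockerham (1984) within-population components for one locus in one
## sample: per allele, b (between-individual) and c (within-individual);
## f-hat = 1 - sum(c) / sum(b + c) over alleles and loci.
wc_bc_locus <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2L) return(NULL)
  alleles <- unique(c(g1, g2))
  if (length(alleles) < 2L) return(NULL)          # monomorphic
  b <- c <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    A <- alleles[k]
    dose <- (g1 == A) + (g2 == A)
    p <- mean(dose) / 2
    hbar <- mean(dose == 1L)                       # observed heterozygosity
    b[k] <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    c[k] <- hbar / 2
  }
  cbind(b = b, c = c)
}

fis_point <- function(gt) {
  comp <- lapply(seq_along(gt$loci), function(j)
    wc_bc_locus(gt$a1[, j], gt$a2[, j]))
  comp <- Filter(Negate(is.null), comp)
  if (!length(comp)) return(list(f = NA_real_, per_locus = NULL))
  all <- do.call(rbind, comp)
  denom <- sum(all[, "b"] + all[, "c"])
  f <- if (abs(denom) < 1e-30) NA_real_ else 1 - sum(all[, "c"]) / denom
  list(f = f, per_locus = comp)
}

#' Weir-Cockerham inbreeding coefficient F_IS for one group
#'
#' Point estimate over loci and alleles, bootstrap confidence interval over
#' loci, and a permutation p-value obtained by re-pairing alleles at random
#' among the group's individuals (which destroys within-individual allele
#' correlation, the F_IS null).
#'
#' @param gt a `genotype_table` already restricted to the group
#'   (population, or population x sex).
#' @param n_boot bootstrap replicates over loci for the CI.
#' @param n_perm allele permutations for the p-value; the reported p is the
#'   upper tail (heterozygote deficit, the Wahlund-effect direction).
#' @param seed integer seed.
#' @return class `fis_result`: `f`, `ci`, `p`, `n`.
#' @export
fis_weir_cockerham <- function(gt, n_boot = 1000, n_perm = 1000, seed = 1L) {
  if (length(gt$individuals) < 2L)
    stop("need >= 2 individuals in the group")
  set.seed(seed)
  est <- fis_point(gt)
  nL <- length(gt$loci)
  ci <- c(NA_real_, NA_real_)
  if (!is.na(est$f) && n_boot > 0 && nL > 1) {
    bf <- vapply(seq_len(n_boot), function(i) {
      jj <- sample.int(nL, replace = TRUE)
      sub <- genotype_table(gt$a1[, jj, drop = FALSE],
                            gt$a2[, jj, drop = FALSE],
                            gt$population, gt$sex)
      fis_point(sub)$f
    }, 0)
    ci <- unname(quantile(bf, c(0.025, 0.975), na.rm = TRUE))
  }
  p <- NA_real_
  if (!is.na(est$f) && n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(i) {
      A1 <- gt$a1; A2 <- gt$a2
      for (j in seq_len(nL)) {
        pool <- c(gt$a1[, j], gt$a2[, j])
        ok <- !is.na(pool)
        pool[ok] <- sample(pool[ok])
        A1[, j] <- pool[seq_len(nrow(A1))]
        A2[, j] <- pool[nrow(A1) + seq_len(nrow(A1))]
      }
      fis_point(genotype_table(A1, A2, gt$population, gt$sex))$f
    }, 0)
    p <- perm_pvalue(perm, est$f)
  }
  structure(list(f = est$f, ci = ci, p = p, n = length(gt$individuals),
                 n_boot = n_boot, n_perm = n_perm), class = "fis_result")
}

#' @export
print.fis_result <- function(x, ...) {
  cat(sprintf("F_IS = %.3f [%.3f-%.3f], permutation p = %s (n = %d)\n",
              x$f, x$ci[1], x$ci[2], format(x$p, digits = 3), x$n))
  invisible(x)
}

## per-locus allele frequency list from a genotype table
allele_freqs <- function(gt) {
  lapply(seq_along(gt$loci), function(j) {
    al <- c(gt$a1[, j], gt$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al)) return(numeric(0))
    tb <- table(al)
    setNames(as.numeric(tb) / sum(tb), names(tb))
  })
}

## P(G2 | G1, m IBD alleles shared): the 3-component dyadic mixture.
## Returns c(P0, P1, P2) for one locus; NULL when a genotype is missing or
## the locus is uninformative.
dyad_mixture_probs <- function(g1a, g1b, g2a, g2b, freqs) {
  if (anyNA(c(g1a, g1b, g2a, g2b))) return(NULL)
  ## genotypes are unordered
  if (g1a > g1b) { tmp <- g1a; g1a <- g1b; g1b <- tmp }
  if (g2a > g2b) { tmp <- g2a; g2a <- g2b; g2b <- tmp }
  pf <- function(a) {
    v <- freqs[as.character(a)]
    ifelse(is.na(v), 1e-12, v)
  }
  hwe <- function(a, b) if (a == b) pf(a)^2 else 2 * pf(a) * pf(b)
  P0 <- hwe(g2a, g2b)
  ## one allele of G2 copied IBD from a uniformly chosen allele of G1
  p1_given <- function(src) {
    ## G2 = {g2a, g2b}; the IBD copy must match one of them
    tot <- 0
    if (src == g2a) tot <- tot + pf(g2b)
    if (src == g2b && g2a != g2b) tot <- tot + pf(g2a)
    if (g2a == g2b && src == g2a) tot <- pf(g2a)   # homozygote: single path
    tot
  }
  P1 <- (p1_given(g1a) + p1_given(g1b)) / 2
  P2 <- as.numeric(g1a == g2a && g1b == g2b)
  c(unname(P0), unname(P1), unname(P2))
}

## stacked mixture components for a set of dyads: list of three
## (dyads x loci) matrices; vectorized over dyads per locus
dyad_components <- function(gt, pairs, freqs) {
  nD <- nrow(pairs)
  nL <- length(gt$loci)
  C0 <- C1 <- C2 <- matrix(NA_real_, nD, nL)
  i <- pairs[, 1]; j <- pairs[, 2]
  for (l in seq_len(nL)) {
    fr <- freqs[[l]]
    if (!length(fr)) next
    fv <- numeric(max(as.integer(names(fr))))
    fv[as.integer(names(fr))] <- fr
    fv[fv == 0] <- 1e-12
    g1a <- pmin(gt$a1[i, l], gt$a2[i, l]); g1b <- pmax(gt$a1[i, l], gt$a2[i, l])
    g2a <- pmin(gt$a1[j, l], gt$a2[j, l]); g2b <- pmax(gt$a1[j, l], gt$a2[j, l])
    ok <- !(is.na(g1a) | is.na(g2a))
    if (!any(ok)) next
    pa <- fv[g2a]; pb <- fv[g2b]
    het2 <- g2a != g2b
    C0[ok, l] <- (pa * pb * ifelse(het2, 2, 1))[ok]
    p1_given <- function(src)
      ifelse(het2, (src == g2a) * pb + (src == g2b) * pa,
             (src == g2a) * pa)
    C1[ok, l] <- ((p1_given(g1a) + p1_given(g1b)) / 2)[ok]
    C2[ok, l] <- ((g1a == g2a) & (g1b == g2b))[ok] * 1
  }
  list(C0 = C0, C1 = C1, C2 = C2)
}

## EM over the IBD-coefficient simplex for many dyads at once.
## comps: list(C0, C1, C2), each dyads x loci (NA = missing locus).
## Returns dyads x 3 matrix of (k0, k1, k2).
em_dyads <- function(comps, max_iter = 200, tol = 1e-7,
                     starts = list(c(1, 0, 0),     # exact unrelated corner
                                   c(1, 0, 0) + 1e-3,
                                   c(0.25, 0.5, 0.25),
                                   c(0.05, 0.15, 0.80))) {
  C0 <- comps$C0; C1 <- comps$C1; C2 <- comps$C2
  miss <- is.na(C0)
  C0[miss] <- C1[miss] <- C2[miss] <- 0
  nD <- nrow(C0)
  nl <- rowSums(!miss)
  eps <- 1e-300
  best_ll <- rep(-Inf, nD)
  best_k <- matrix(NA_real_, nD, 3)
  for (s in starts) {
    s <- s / sum(s)
    k0 <- rep(s[1], nD); k1 <- rep(s[2], nD); k2 <- rep(s[3], nD)
    ll_old <- rep(-Inf, nD)
    for (it in seq_len(max_iter)) {
      T0 <- C0 * k0; T1 <- C1 * k1; T2 <- C2 * k2
      den <- T0 + T1 + T2
      den[miss] <- 1                      # missing loci contribute nothing
      ll <- rowSums(log(den + eps) * !miss)
      k0 <- rowSums(T0 / (den + eps) * !miss) / pmax(nl, 1)
      k1 <- rowSums(T1 / (den + eps) * !miss) / pmax(nl, 1)
      k2 <- pmax(1 - k0 - k1, 0)
      if (max(abs(ll - ll_old), na.rm = TRUE) < tol) break
      ll_old <- ll
    }
    upd <- ll > best_ll
    best_k[upd, ] <- cbind(k0, k1, k2)[upd, , drop = FALSE]
    best_ll[upd] <- ll[upd]
  }
  best_k[nl == 0, ] <- NA_real_
  attr(best_k, "loglik") <- best_ll
  best_k
}

#' Maximum-likelihood pairwise relatedness
#'
#' Dyadic likelihood over the IBD coefficients `(k0, k1, k2)` on the
#' simplex (no-inbreeding model), maximized by multi-start EM;
#' `r = k2 + k1/2`. Allele frequencies default to the sample including the
#' dyad.
#'
#' @param gt a `genotype_table` (typically one population).
#' @param pairs 2-column integer matrix of dyad row indices; default all
#'   unordered pairs.
#' @param freqs optional per-locus allele-frequency list (named numeric
#'   vectors); default computed from `gt`.
#' @return data.frame with columns `i`, `j`, `k0`, `k1`, `k2`, `r`.
#' @export
relatedness_ml <- function(gt, pairs = NULL, freqs = NULL) {
  n <- length(gt$individuals)
  if (is.null(pairs)) {
    if (n < 2L) stop("need >= 2 individuals")
    pairs <- t(combn(n, 2))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  freqs <- freqs %||% allele_freqs(gt)
  comps <- dyad_components(gt, pairs, freqs)
  k <- em_dyads(comps)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             k0 = k[, 1], k1 = k[, 2], k2 = k[, 3],
             r = k[, 3] + k[, 2] / 2)
}

#' Sex difference in mean within-group relatedness
#'
#' Computes mean dyadic relatedness within females and within males of one
#' group, then builds a null distribution for the difference by repeatedly
#' re-assigning individuals at random to two pseudo-sex groups of the
#' original sizes (label randomization; a with-replacement bootstrap of
#' individuals is available via `replace = TRUE`). The observed difference
#' is significant when it falls outside the null central 95% interval.
#'
#' @param gt a `genotype_table` for one population (with `sex` labels).
#' @param n_boot resampling replicates.
#' @param seed integer seed.
#' @param min_per_sex groups with fewer individuals of either sex are
#'   rejected (the analysis convention excludes them).
#' @param replace use with-replacement resampling of individuals instead of
#'   label permutation.
#' @return class `sexdiff_result`: per-sex means, `diff_obs`, `ci_null`,
#'   `significant`.
#' @export
sex_difference_test <- function(gt, n_boot = 1000, seed = 1L,
                                min_per_sex = 5L, replace = FALSE) {
  sex <- gt$sex
  nf <- sum(sex == "F"); nm <- sum(sex == "M")
  if (nf < min_per_sex || nm < min_per_sex)
    stop("fewer than ", min_per_sex, " individuals of each sex (F=", nf,
         ", M=", nm, ")")
  keep <- sex %in% c("F", "M")
  gt <- subset_genotypes(gt, keep)
  sex <- gt$sex
  n <- length(gt$individuals)
  ## full dyad matrix once; resampling only re-averages entries
  rel <- relatedness_ml(gt)
  R <- matrix(NA_real_, n, n)
  R[cbind(rel$i, rel$j)] <- rel$r
  R[cbind(rel$j, rel$i)] <- rel$r
  group_mean <- function(idx) {
    sub <- R[idx, idx]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  mean_f <- group_mean(which(sex == "F"))
  mean_m <- group_mean(which(sex == "M"))
  diff_obs <- mean_f - mean_m
  set.seed(seed)
  nulls <- vapply(seq_len(n_boot), function(b) {
    ids <- if (replace) sample.int(n, n, replace = TRUE) else sample.int(n)
    group_mean(ids[seq_len(nf)]) - group_mean(ids[nf + seq_len(nm)])
  }, 0)
  ci <- unname(quantile(nulls, c(0.025, 0.975), na.rm = TRUE))
  structure(list(mean_f = mean_f, mean_m = mean_m, diff_obs = diff_obs,
                 ci_null = ci,
                 significant = diff_obs < ci[1] || diff_obs > ci[2],
                 n_f = nf, n_m = nm, n_boot = n_boot,
                 dyads = rel), class = "sexdiff_result")
}

#' @export
print.sexdiff_result <- function(x, ...) {
  cat(sprintf(
    "mean r: F = %.3f (n=%d), M = %.3f (n=%d); diff = %.3f, null 95%% [%.3f, %.3f]%s\n",
    x$mean_f, x$n_f, x$mean_m, x$n_m, x$diff_obs, x$ci_null[1], x$ci_null[2],
    if (x$significant) "  *significant*" else ""))
  invisible(x)
}

#' Per-sex pairwise population structure
#'
#' Restricts the dataset to one sex and delegates to [pairwise_diff()] on
#' the nuclear markers.
#'
#' @param dataset a [pop_dataset()].
#' @param sex `"F"` or `"M"`.
#' @inheritParams pairwise_diff
#' @export
per_sex_structure <- function(dataset, sex, statistic = "PhiST",
                              n_perm = 999, seed = 1L, min_copies = 4L) {
  ids <- dataset$meta$individual[dataset$meta$sex == sex]
  if (!length(ids)) stop("no individuals of sex ", sex)
  sub <- subset_individuals(dataset, ids)
  pairwise_diff(sub, marker = "nuclear", statistic = statistic,
                n_perm = n_perm, seed = seed, min_copies = min_copies)
}

#' Sex-biased dispersal summary table
#'
#' Per population: sample sizes, per-sex F_IS with CI and permutation p,
#' per-sex mean relatedness, the observed difference and the null 95%
#' interval of [sex_difference_test()]. Populations with fewer than
#' `min_per_sex` individuals of either sex are skipped with a report entry.
#'
#' @param dataset a [pop_dataset()].
#' @param n_boot,n_perm resampling counts.
#' @param seed master seed.
#' @param min_per_sex minimum individuals per sex.
#' @return data.frame; skipped populations carry `NA` and a `note`.
#' @export
sexbias_table <- function(dataset, n_boot = 1000, n_perm = 1000, seed = 1L,
                          min_per_sex = 5L) {
  gt <- genotypes_from_phased(dataset)
  rows <- list()
  for (pop in sort(unique(gt$population))) {
    sel <- gt$population == pop
    sub <- subset_genotypes(gt, sel)
    nf <- sum(sub$sex == "F"); nm <- sum(sub$sex == "M")
    base <- data.frame(population = pop, n_f = nf, n_m = nm,
                       fis_f = NA, fis_f_lo = NA, fis_f_hi = NA, p_fis_f = NA,
                       fis_m = NA, fis_m_lo = NA, fis_m_hi = NA, p_fis_m = NA,
                       rel_f = NA, rel_m = NA, rel_diff = NA,
                       ci_lo = NA, ci_hi = NA, significant = NA,
                       note = "")
    if (nf < min_per_sex || nm < min_per_sex) {
      base$note <- sprintf("skipped: fewer than %d individuals per sex",
                           min_per_sex)
      rows[[length(rows) + 1L]] <- base
      next
    }
    ff <- fis_weir_cockerham(subset_genotypes(sub, sub$sex == "F"),
                             n_boot, n_perm, spawn_seed(seed, paste(pop, "F")))
    fm <- fis_weir_cockerham(subset_genotypes(sub, sub$sex == "M"),
                             n_boot, n_perm, spawn_seed(seed, paste(pop, "M")))
    sd <- sex_difference_test(sub, n_boot = n_boot,
                              seed = spawn_seed(seed, paste(pop, "rel")),
                              min_per_sex = min_per_sex)
    base[c("fis_f", "fis_f_lo", "fis_f_hi", "p_fis_f")] <-
      c(ff$f, ff$ci, ff$p)
    base[c("fis_m", "fis_m_lo", "fis_m_hi", "p_fis_m")] <-
      c(fm$f, fm$ci, fm$p)
    base[c("rel_f", "rel_m", "rel_diff", "ci_lo", "ci_hi")] <-
      c(sd$mean_f, sd$mean_m, sd$diff_obs, sd$ci_null)
    base$significant <- sd$significant
    rows[[length(rows) + 1L]] <- base
  }
  do.call(rbind, rows)
}
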