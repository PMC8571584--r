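## AMOVA, pairwise differentiation and Mantel isolation-by-distance.
##
## The AMOVA decomposes squared inter-haplotype distances over hierarchical
## strata (Excoffier-Smouse-Quattro framework). With molecular distances
## the fixation indices are Phi-statistics; with unit distances between
## distinct haplotypes the same computation yields F-statistics.

## pop x pop block sums of a square matrix under a grouping factor
block_sums <- function(M, f) {
  b <- rowsum(M, f)
  t(rowsum(t(b), f))
}

ssd_decomposition <- function(D2, pop, group = NULL) {
  N <- nrow(D2)
  fp <- factor(pop)
  np <- tabulate(fp)
  Bp <- block_sums(D2, fp)
  ssd_total <- sum(D2) / (2 * N)
  ssd_wp <- sum(diag(Bp) / (2 * np))
  if (is.null(group)) {
    list(total = ssd_total, within = ssd_wp,
         among = ssd_total - ssd_wp, N = N, np = np)
  } else {
    fg <- factor(group)
    ng <- tabulate(fg)
    Bg <- block_sums(D2, fg)
    ssd_g <- sum(diag(Bg) / (2 * ng))    # within-group total SSD
    list(total = ssd_total, wp = ssd_wp, ap_wg = ssd_g - ssd_wp,
         ag = ssd_total - ssd_g, N = N, np = np, ng = ng)
  }
}

phi_two_level <- function(D2, pop) {
  s <- ssd_decomposition(D2, pop)
  P <- length(s$np)
  N <- s$N
  sig_b <- s$within / (N - P)
  nprime <- (N - sum(s$np^2) / N) / (P - 1)
  sig_a <- (s$among / (P - 1) - sig_b) / nprime
  tot <- sig_a + sig_b
  phi <- if (abs(tot) < 1e-30) NA_real_ else sig_a / tot
  list(ssd = c(among = s$among, within = s$within, total = s$total),
       df = c(among = P - 1, within = N - P),
       sigma = c(a = sig_a, b = sig_b), phi_st = phi, n_coef = nprime)
}

phi_three_level <- function(D2, pop, group) {
  ## population -> group map must be well defined
  map <- unique(data.frame(pop = as.character(pop),
                           group = as.character(group)))
  if (anyDuplicated(map$pop))
    stop("a population appears in more than one group")
  G <- length(unique(map$group))
  if (G < 2) stop("a single group: use the two-level design")
  s <- ssd_decomposition(D2, pop, group)
  P <- length(s$np)
  N <- s$N
  ## nested sample-size coefficients
  popg <- map$group[match(levels(factor(pop)), map$pop)]
  npop2_by_g <- tapply(s$np^2, popg, sum)
  ng <- tapply(s$np, popg, sum)
  n_c1 <- (sum(npop2_by_g / ng) - sum(s$np^2) / N) / (G - 1)
  n_c2 <- (N - sum(ng^2) / N) / (G - 1)
  sig_c <- s$wp / (N - P)
  sig_b <- if (P == G) 0 else {          # degenerate nesting: one pop/group
    n_c <- (N - sum(npop2_by_g / ng)) / (P - G)
    (s$ap_wg / (P - G) - sig_c) / n_c
  }
  sig_a <- (s$ag / (G - 1) - sig_c - n_c1 * sig_b) / n_c2
  tot <- sig_a + sig_b + sig_c
  if (is.na(tot)) tot <- 0
  list(ssd = c(among_groups = s$ag, among_pops_within = s$ap_wg,
               within_pops = s$wp, total = s$total),
       df = c(among_groups = G - 1, among_pops_within = P - G,
              within_pops = N - P),
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       phi_ct = if (abs(tot) < 1e-30) NA_real_ else sig_a / tot,
       phi_sc = if (abs(sig_b + sig_c) < 1e-30) NA_real_ else
         sig_b / (sig_b + sig_c),
       phi_st = if (abs(tot) < 1e-30) NA_real_ else (sig_a + sig_b) / tot)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Two-level (populations) or three-level (groups / populations within
#' groups / within populations) decomposition of squared inter-haplotype
#' distances, with permutation p-values. Negative variance components are
#' retained, not truncated; percentages are computed from the components as
#' estimated and may be negative.
#'
#' @param d symmetric distance matrix between sequence copies (molecular
#'   distances for Phi-statistics; see [amova_fst_distances()] for the
#'   unit-distance F-statistic version). Distances are squared internally.
#' @param populations population label per row of `d`.
#' @param groups optional group label per row (three-level design).
#' @param n_perm permutations per statistic (default 999; `0` skips tests).
#' @param seed integer seed.
#' @return class `amova_result`.
#' @export
amova <- function(d, populations, groups = NULL, n_perm = 999, seed = 1L) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            length(populations) == nrow(d))
  if (any(is.na(d)))
    stop("distance matrix contains undefined entries (saturated pairs?)")
  D2 <- d^2
  set.seed(seed)
  if (is.null(groups)) {
    fit <- phi_two_level(D2, populations)
    p <- NA_real_
    if (n_perm > 0 && !is.na(fit$phi_st)) {
      stat <- vapply(seq_len(n_perm), function(i)
        phi_two_level(D2, sample(populations))$phi_st, 0)
      p <- perm_pvalue(stat, fit$phi_st)
    }
    sig <- fit$sigma
    res <- list(design = "two_level", ssd = fit$ssd, df = fit$df,
                sigma = sig, pct = 100 * sig / sum(sig),
                phi = c(phi_st = fit$phi_st),
                p = c(phi_st = p), n_perm = n_perm)
  } else {
    fit <- phi_three_level(D2, populations, groups)
    p <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
    if (n_perm > 0) {
      pops <- unique(as.character(populations))
      g_of_pop <- as.character(groups)[match(pops, as.character(populations))]
      ## phi_st: copies among populations (structure of sizes kept)
      st <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(populations))
        phi_three_level(D2, populations[idx], groups[idx])$phi_st
      }, 0)
      p["phi_st"] <- perm_pvalue(st, fit$phi_st)
      ## phi_ct: whole populations among groups
      ct <- vapply(seq_len(n_perm), function(i) {
        gp <- sample(g_of_pop)
        phi_three_level(D2, populations,
                        gp[match(populations, pops)])$phi_ct
      }, 0)
      p["phi_ct"] <- perm_pvalue(ct, fit$phi_ct)
      ## phi_sc: copies among populations within their group
      sc <- vapply(seq_len(n_perm), function(i) {
        newpop <- as.character(populations)
        for (g in unique(as.character(groups))) {
          sel <- groups == g
          newpop[sel] <- newpop[sel][sample.int(sum(sel))]
        }
        phi_three_level(D2, newpop, groups)$phi_sc
      }, 0)
      p["phi_sc"] <- perm_pvalue(sc, fit$phi_sc)
    }
    sig <- fit$sigma
    res <- list(design = "three_level", ssd = fit$ssd, df = fit$df,
                sigma = sig, pct = 100 * sig / sum(sig),
                phi = c(phi_ct = fit$phi_ct, phi_sc = fit$phi_sc,
                        phi_st = fit$phi_st),
                p = p, n_perm = n_perm)
  }
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$design, ")\n", sep = "")
  tab <- data.frame(df = c(x$df, NA), SSD = x$ssd,
                    sigma2 = c(x$sigma, sum(x$sigma)),
                    pct = c(x$pct, 100))
  rownames(tab) <- c(names(x$df), "total")
  print(round(tab, 4))
  for (nm in names(x$phi))
    cat(sprintf("%s = %.4f (p = %s)\n", nm, x$phi[nm],
                format(x$p[nm], digits = 3)))
  invisible(x)
}

#' Unit distances between distinct haplotypes
#'
#' Builds the 0/1 distance matrix that turns the AMOVA Phi computation into
#' conventional F-statistics.
#'
#' @param aln a [locus_alignment()].
#' @param site_policy missing-site policy for haplotype collapsing.
#' @return symmetric 0/1 matrix over sequence copies.
#' @export
amova_fst_distances <- function(aln, site_policy = "pairwise_ignore_missing") {
  ht <- collapse_haplotypes(aln, site_policy)
  d <- 1 * outer(ht$index, ht$index, "!=")
  rownames(d) <- colnames(d) <- rownames(aln$seq)
  d
}

#' Pairwise population differentiation matrix
#'
#' For every population pair computes `F_ST` (haplotype identity),
#' `Phi_ST` (molecular distances) via the two-level AMOVA, or `D_XY`
#' (mean between-population per-site difference; no permutation test).
#'
#' @param dataset a [pop_dataset()].
#' @param marker `"mitochondrial"` or `"nuclear"`: loci of that mode are
#'   concatenated first.
#' @param statistic `"FST"`, `"PhiST"` or `"DXY"`.
#' @param n_perm permutations for the test.
#' @param seed integer seed.
#' @param model substitution model for `PhiST` distances (default: the
#'   concatenated alignment's tag).
#' @param min_copies populations with fewer copies are excluded (warning).
#' @return class `pairwise_diff`: `statistic`, `values`, `p`, `n_perm`.
#' @export
pairwise_diff <- function(dataset, marker = c("mitochondrial", "nuclear"),
                          statistic = c("FST", "PhiST", "DXY"),
                          n_perm = 999, seed = 1L, model = NULL,
                          min_copies = 2L) {
  marker <- match.arg(marker)
  statistic <- match.arg(statistic)
  loci <- Filter(function(l) l$mode == marker, dataset$loci)
  if (!length(loci)) stop("no loci of mode ", marker)
  aln <- concatenate_loci(loci, name = paste0(marker, "_concat"),
                          model = model)
  pop <- dataset$meta$population[match(aln$individual,
                                       dataset$meta$individual)]
  sizes <- table(pop)
  small <- names(sizes)[sizes < min_copies]
  if (length(small)) {
    warning("excluding populations with < ", min_copies, " copies: ",
            paste(small, collapse = ", "))
    keep <- !(pop %in% small)
    aln <- locus_alignment(aln$name, aln$mode, aln$seq[keep, , drop = FALSE],
                           aln$individual[keep], aln$copy[keep],
                           aln$copies_per_individual, aln$model)
    pop <- pop[keep]
  }
  d <- switch(statistic,
              FST = amova_fst_distances(aln),
              PhiST = pairwise_distance(aln, model = model %||% aln$model),
              DXY = pairwise_distance(aln, model = "p"))
  if (any(is.na(d))) {
    warning("undefined (saturated) distances set to the maximum observed")
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  pops <- sort(unique(pop))
  P <- length(pops)
  vals <- pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(vals) <- 0
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    sel <- pop %in% c(pops[i], pops[j])
    if (statistic == "DXY") {
      cross <- d[pop == pops[i], pop == pops[j], drop = FALSE]
      vals[i, j] <- vals[j, i] <- mean(cross)
    } else {
      fit <- amova(d[sel, sel], pop[sel], n_perm = n_perm,
                   seed = spawn_seed(seed, paste(pops[i], pops[j])))
      vals[i, j] <- vals[j, i] <- fit$phi["phi_st"]
      pv[i, j] <- pv[j, i] <- fit$p["phi_st"]
    }
  }
  structure(list(statistic = statistic, marker = marker, values = vals,
                 p = pv, n_perm = n_perm), class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, digits = 4, ...) {
  cat("Pairwise ", x$statistic, " (", x$marker, " markers)\n", sep = "")
  m <- round(x$values, digits)
  starred <- matrix(paste0(format(m), sig_stars(x$p)), nrow(m),
                    dimnames = dimnames(m))
  print(starred, quote = FALSE)
  invisible(x)
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and a
#' geographic distance matrix, with significance from joint row+column
#' permutations of the geographic matrix. `F_ST`-type inputs are
#' linearized as `x / (1 - x)` by default; entries with `F_ST = 1`
#' (transform undefined) are excluded with a warning.
#'
#' @param genetic,geographic symmetric matrices with identical labels.
#' @param transform `"linearize"` (`x/(1-x)`) or `"none"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"one"` (positive association; default, the
#'   isolation-by-distance hypothesis is directional) or `"two"`.
#' @return class `mantel_result`: `r`, `p`, `n_perm`, `transform`, `tail`.
#' @export
mantel_test <- function(genetic, geographic,
                        transform = c("linearize", "none"),
                        n_perm = 999, seed = 1L, tail = c("one", "two")) {
  transform <- match.arg(transform)
  tail <- match.arg(tail)
  stopifnot(is.matrix(genetic), is.matrix(geographic))
  if (!identical(dim(genetic), dim(geographic)))
    stop("matrices must have identical dimensions")
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic)) &&
      !identical(rownames(genetic), rownames(geographic)))
    stop("matrices must have identical labels in identical order")
  g <- genetic
  if (transform == "linearize") {
    sat <- abs(g - 1) < 1e-12 & row(g) != col(g)
    if (any(sat)) {
      warning(sum(sat) / 2, " pair(s) with F_ST = 1 excluded ",
              "(linearization undefined)")
      g[sat] <- NA
    }
    g <- g / (1 - g)
  }
  ut <- upper.tri(g)
  stat <- function(geo) {
    ok <- ut & !is.na(g) & !is.na(geo)
    cor(g[ok], geo[ok])
  }
  r_obs <- stat(geographic)
  set.seed(seed)
  n <- nrow(g)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(n)
    stat(geographic[ix, ix])
  }, 0)
  p <- if (tail == "one") perm_pvalue(r_perm, r_obs)
       else perm_pvalue(abs(r_perm), abs(r_obs))
  structure(list(r = r_obs, p = p, n_perm = n_perm, transform = transform,
                 tail = tail), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %s (%d permutations, %s-tailed, %s)\n",
              x$r, format(x$p, digits = 3), x$n_perm, x$tail,
              if (x$transform == "linearize") "x/(1-x) transform"
              else "untransformed"))
  invisible(x)
}
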