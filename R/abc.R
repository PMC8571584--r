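## Coalescent simulation of colonization scenarios and ABC scenario choice
## (rejection + LDA projection + weighted multinomial logistic regression).

#' Define a divergence scenario
#'
#' A scenario lists populations (sampled and ancestral), their sizes
#' (numbers, or names of prior parameters) and an event list ordered
#' forwards in coalescent time (backwards from the present): divergence
#' events merge a population into an ancestral one, size changes reset a
#' size, admixture moves lineages with a given probability. Times and
#' rates may reference prior parameters by name.
#'
#' @param name scenario label.
#' @param sizes named vector/list: population sizes (numeric or parameter
#'   name).
#' @param events list of `list(time=, type=, ...)` with `type` one of
#'   `"divergence"` (`from`, `to`), `"size_change"` (`pop`, `size`),
#'   `"admixture"` (`from`, `to`, `prob`).
#' @return class `scenario`.
#' @export
scenario <- function(name, sizes, events) {
  sc <- structure(list(name = name, sizes = sizes, events = events),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario '", x$name, "': ", length(x$sizes), " populations, ",
      length(x$events), " events\n", sep = "")
  invisible(x)
}

## structural check: divergence events must merge all populations into a
## single root lineage
validate_scenario <- function(sc) {
  pops <- names(sc$sizes)
  comp <- setNames(pops, pops)
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  for (e in sc$events) if (identical(e$type, "divergence")) {
    if (!all(c(e$from, e$to) %in% pops))
      stop("divergence references unknown population")
    comp[[find(e$from)]] <- find(e$to)
  }
  roots <- unique(vapply(pops, find, ""))
  if (length(roots) != 1L)
    stop("scenario '", sc$name, "' does not coalesce: populations {",
         paste(roots, collapse = ", "), "} never merge")
  invisible(sc)
}

#' Uniform prior specification
#'
#' Independent uniform (or log-uniform) bounds per parameter, with optional
#' ordering constraints: for each group in `order`, the drawn values are
#' sorted and reassigned so the listed parameters are increasing
#' (conditional sampling of ordered divergence times).
#'
#' @param bounds named list of `c(lower, upper)`.
#' @param log_scale character vector of parameters drawn log-uniformly
#'   (e.g. per-locus mutation rates).
#' @param order list of character vectors that must be increasing.
#' @return class `prior_spec`.
#' @export
prior_spec <- function(bounds, log_scale = character(0), order = list()) {
  for (nm in names(bounds))
    if (bounds[[nm]][1] >= bounds[[nm]][2])
      stop("prior '", nm, "': lower must be < upper")
  structure(list(bounds = bounds, log_scale = log_scale, order = order),
            class = "prior_spec")
}

#' Draw one parameter vector from a prior specification
#' @param priors a [prior_spec()].
#' @return named numeric vector.
#' @export
draw_params <- function(priors) {
  p <- vapply(names(priors$bounds), function(nm) {
    b <- priors$bounds[[nm]]
    if (nm %in% priors$log_scale) exp(runif(1, log(b[1]), log(b[2])))
    else runif(1, b[1], b[2])
  }, 0)
  for (grp in priors$order) p[grp] <- sort(p[grp])
  p
}

## resolve a number-or-parameter-name field
resolve <- function(x, params) {
  if (is.character(x)) {
    if (!x %in% names(params)) stop("unknown parameter: ", x)
    unname(params[[x]])
  } else as.numeric(x)
}

instantiate_scenario <- function(sc, params) {
  sizes <- vapply(sc$sizes, resolve, 0, params = params)
  events <- lapply(sc$events, function(e) {
    e$time <- resolve(e$time, params)
    if (!is.null(e$size)) e$size <- resolve(e$size, params)
    if (!is.null(e$prob)) e$prob <- resolve(e$prob, params)
    e
  })
  list(sizes = sizes, events = events)
}

## ---- locus simulation ------------------------------------------------

## simulate per-locus variable-site states for a sampling design.
## design: list(samples = named individuals per population,
##              loci = list(list(name, mode, L, copies, mu)))
## Returns list(loci = list of list(states, pop, L, mode, name), params).
sim_states <- function(sc, params, design) {
  inst <- instantiate_scenario(sc, params)
  samples <- design$samples
  out <- list()
  mt <- Filter(function(l) l$mode == "mitochondrial", design$loci)
  nuc <- Filter(function(l) l$mode == "nuclear", design$loci)
  ## mtDNA loci share one linked genealogy (no recombination)
  if (length(mt)) {
    tree <- sim_structured_tree(samples, inst$sizes, mult = 0.25,
                                events = inst$events)
    for (l in mt) {
      st <- sim_locus_states(tree, resolve(l$mu, params), l$L)
      out[[l$name]] <- list(states = st$states, sites = st$sites,
                            pop = tree$tip_pop,
                            L = l$L, mode = l$mode, name = l$name,
                            copies = 1L)
    }
  }
  ## nuclear loci: independent genealogies, two copies per individual
  for (l in nuc) {
    cp <- l$copies %||% 2L
    tree <- sim_structured_tree(samples * cp, inst$sizes, mult = 1,
                                events = inst$events)
    st <- sim_locus_states(tree, resolve(l$mu, params), l$L)
    out[[l$name]] <- list(states = st$states, sites = st$sites,
                          pop = tree$tip_pop,
                          L = l$L, mode = l$mode, name = l$name,
                          copies = cp)
  }
  out
}

## materialize simulated states into a full pop_dataset with sequences
states_to_dataset <- function(states, design, meta_extra = NULL) {
  samples <- design$samples
  pops <- names(samples)
  ids <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(samples[[p]]))))
  meta <- data.frame(individual = ids,
                     population = rep(pops, samples),
                     group = meta_extra$group[rep(pops, samples)] %||%
                       rep(pops, samples),
                     ocean = meta_extra$ocean[rep(pops, samples)] %||%
                       rep("ocean1", length(ids)),
                     sex = meta_extra$sex %||% rep("unknown", length(ids)))
  loci <- lapply(states, function(st) {
    cp <- st$copies
    n <- nrow(st$states)
    seqs <- matrix(rep(sample(c("A", "C", "G", "T"), st$L, replace = TRUE),
                       each = n), n, st$L)
    if (ncol(st$states))
      seqs[, st$sites] <- c("A", "C", "G", "T")[st$states]
    ind <- rep(ids, each = cp)
    locus_alignment(st$name, st$mode, seqs, ind,
                    copy = rep(seq_len(cp), length(ids)),
                    copies_per_individual = cp,
                    model = if (st$mode == "mitochondrial") "K2P" else "TN93")
  })
  pop_dataset(loci, meta, geo = meta_extra$geo)
}

#' Simulate a dataset under a scenario
#'
#' Draws parameters from the priors, runs the structured coalescent
#' (mitochondrial loci on one linked genealogy with ploidy multiplier
#' 0.25; nuclear loci independent with two copies per individual), places
#' finite-sites Jukes-Cantor mutations and returns aligned sequences.
#'
#' @param sc a [scenario()].
#' @param priors a [prior_spec()].
#' @param design `list(samples = named individuals per population, loci =
#'   list(list(name, mode, L, copies, mu)))`; `mu` may name a prior
#'   parameter.
#' @param seed integer seed.
#' @return `list(dataset, params)`.
#' @export
simulate_dataset <- function(sc, priors, design, seed = 1L) {
  set.seed(seed)
  params <- draw_params(priors)
  st <- sim_states(sc, params, design)
  list(dataset = states_to_dataset(st, design), params = params)
}

## ---- summary statistics ----------------------------------------------

## per marker class: per-pop {K, S, kbar, D} and per-pair {FST, DXY}.
## states: integer matrix (copies x variable sites); pop: label per row;
## L: total class length in sites. Undefined entries are imputed 0 (the
## imputation pattern is attached as an attribute).
summary_core <- function(states, pop, L, pops, prefix) {
  vals <- c(); imput <- c()
  note <- function(nm, v) {
    vals[[nm]] <<- if (is.na(v)) 0 else v
    imput[[nm]] <<- is.na(v)
  }
  nS <- ncol(states)
  ## one pass: pairwise difference matrix and haplotype index for all rows
  dm <- diff_matrix_from_states(states)
  key <- if (nS) apply(states, 1, paste, collapse = "")
         else rep("", nrow(states))
  hap <- match(key, unique(key))
  for (p in pops) {
    idx <- which(pop == p)
    n <- length(idx)
    if (n < 2L) {
      for (comp in c("K", "S", "kbar", "D"))
        note(paste0(prefix, "_", comp, "_", p), NA_real_)
      next
    }
    S <- if (nS) {
      m <- states[idx, , drop = FALSE]
      sum(colSums(m != matrix(m[1L, ], n, nS, byrow = TRUE)) > 0L)
    } else 0L
    K <- length(unique(hap[idx]))
    kb <- mean(dm[idx, idx][upper.tri(diag(n))])
    D <- if (n >= 4 && S > 0) tajima_d(S, n, kb) else NA_real_
    note(paste0(prefix, "_K_", p), K)
    note(paste0(prefix, "_S_", p), S)
    note(paste0(prefix, "_kbar_", p), kb)
    note(paste0(prefix, "_D_", p), D)
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      si <- pop == pops[i]; sj <- pop == pops[j]
      sel <- si | sj
      ## F_ST: unit-distance two-level AMOVA on haplotype identity
      D2 <- 1 * outer(hap[sel], hap[sel], "!=")
      fst <- phi_two_level(D2, pop[sel])$phi_st
      dxy <- mean(dm[si, sj]) / L
      pr <- paste0(prefix, "_", pops[i], "_", pops[j])
      note(paste0(pr, "_FST"), fst)
      note(paste0(pr, "_DXY"), dxy)
    }
  }
  out <- unlist(vals)
  attr(out, "imputed") <- unlist(imput)
  out
}

## states representation of one marker class of a pop_dataset
class_states <- function(dataset, mode) {
  loci <- Filter(function(l) l$mode == mode, dataset$loci)
  if (!length(loci)) return(NULL)
  aln <- concatenate_loci(loci, name = paste0(mode, "_concat"))
  keep <- retained_sites(aln$seq, "complete_deletion")
  s <- aln$seq[, keep, drop = FALSE]
  ints <- matrix(match(s, c("A", "C", "G", "T")), nrow(s))
  poly <- apply(ints, 2, function(x) length(unique(x)) > 1)
  pop <- dataset$meta$population[match(aln$individual,
                                       dataset$meta$individual)]
  list(states = ints[, poly, drop = FALSE], pop = pop, L = length(keep))
}

#' Summary-statistic vector of a dataset
#'
#' Per marker class (mitochondrial / nuclear): per-population haplotype
#' count, segregating sites, mean pairwise differences and Tajima's D;
#' per population pair F_ST and per-site D_XY. Undefined components
#' (monomorphic samples) are imputed 0, recorded in the `"imputed"`
#' attribute. The vector is deterministic and invariant to individual
#' order.
#'
#' @param dataset a [pop_dataset()].
#' @return named numeric vector.
#' @export
summarize_dataset <- function(dataset) {
  pops <- sort(unique(dataset$meta$population))
  out <- c()
  for (mode in c("mitochondrial", "nuclear")) {
    cs <- class_states(dataset, mode)
    if (is.null(cs)) next
    prefix <- if (mode == "mitochondrial") "mt" else "nu"
    out <- c(out, summary_core(cs$states[order(cs$pop), , drop = FALSE],
                               sort(cs$pop), cs$L, pops, prefix))
  }
  out
}

## summary vector straight from simulated states (same components/naming)
summarize_states <- function(st_list, pops) {
  out <- c()
  for (mode in c("mitochondrial", "nuclear")) {
    cls <- Filter(function(x) x$mode == mode, st_list)
    if (!length(cls)) next
    L <- sum(vapply(cls, `[[`, 0, "L"))
    states <- do.call(cbind, lapply(cls, `[[`, "states"))
    pop <- cls[[1]]$pop
    prefix <- if (mode == "mitochondrial") "mt" else "nu"
    out <- c(out, summary_core(states, pop, L, pops, prefix))
  }
  out
}

#' Simulate an ABC reference table
#'
#' @param scenarios list of [scenario()] objects.
#' @param priors a [prior_spec()] (shared across scenarios).
#' @param design sampling design (see [simulate_dataset()]).
#' @param n_sim simulations per scenario.
#' @param seed integer seed.
#' @return data.frame: `scenario`, drawn parameters, summary columns.
#' @export
abc_table <- function(scenarios, priors, design, n_sim = 1000, seed = 1L) {
  pops <- sort(names(design$samples))
  rows <- vector("list", length(scenarios) * n_sim)
  k <- 0L
  for (sc in scenarios) {
    set.seed(spawn_seed(seed, paste0("abc_", sc$name)))
    for (r in seq_len(n_sim)) {
      params <- draw_params(priors)
      st <- sim_states(sc, params, design)
      k <- k + 1L
      rows[[k]] <- c(summarize_states(st, pops), params)
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  df$scenario <- rep(vapply(scenarios, `[[`, "", "name"), each = n_sim)
  attr(df, "param_names") <- names(priors$bounds)
  attr(df, "stat_names") <- setdiff(names(df),
                                    c("scenario", names(priors$bounds)))
  df
}

#' Rejection step: retain the simulations closest to the observation
#'
#' Summaries are normalized by the training-set standard deviation;
#' zero-variance summaries are dropped with a warning. The
#' `ceil(tolerance * n)` rows with smallest Euclidean distance are kept.
#'
#' @param observed named summary vector.
#' @param table reference table from [abc_table()].
#' @param tolerance retained fraction in `(0, 1]` (default 0.01).
#' @return class `abc_retained`: retained rows, distances, scales.
#' @export
abc_reject <- function(observed, table, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  stats <- attr(table, "stat_names") %||%
    setdiff(names(table), c("scenario", attr(table, "param_names")))
  stats <- intersect(stats, names(observed))
  if (!length(stats)) stop("no shared summary statistics")
  X <- as.matrix(table[stats])
  sds <- apply(X, 2, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    warning("dropping zero-variance summaries: ",
            paste(stats[drop], collapse = ", "))
    stats <- stats[!drop]
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  Z <- sweep(X, 2, sds, "/")
  z_obs <- observed[stats] / sds
  d <- sqrt(colSums((t(Z) - z_obs)^2))
  keep <- order(d)[seq_len(ceiling(tolerance * nrow(table)))]
  structure(list(rows = table[keep, , drop = FALSE], distance = d[keep],
                 stats = stats, sds = sds, observed = observed[stats],
                 n_table = nrow(table), tolerance = tolerance),
            class = "abc_retained")
}

#' Posterior scenario probabilities from a retained set
#'
#' `method = "direct"`: scenario frequencies among retained simulations
#' with binomial 95% CIs. `method = "lda_logit"` (default): project the
#' retained summaries on linear discriminant axes (classes = scenarios),
#' fit an Epanechnikov-distance-weighted multinomial logistic regression on
#' the axes and evaluate it at the observed point; CIs by the delta method
#' on the fit covariance. Perfect separation falls back to `"direct"` with
#' a warning.
#'
#' @param retained an [abc_reject()] result.
#' @param method `"lda_logit"` or `"direct"`.
#' @return class `abc_result`: `posterior` (per scenario, with `lo`/`hi`),
#'   `chosen` (highest posterior with non-overlapping 95% CI, else
#'   `"undecided"`), `method`, `n_retained`.
#' @export
posterior_probability <- function(retained, method = c("lda_logit", "direct")) {
  method <- match.arg(method)
  rows <- retained$rows
  scen <- factor(rows$scenario)
  all_scen <- levels(scen)
  nR <- nrow(rows)
  direct <- function() {
    k <- table(scen)
    p <- as.numeric(k) / nR
    se <- sqrt(pmax(p * (1 - p), 0) / nR)
    data.frame(scenario = names(k), posterior = p,
               lo = pmax(0, p - 1.96 * se), hi = pmin(1, p + 1.96 * se))
  }
  if (length(all_scen) < 2L) {
    warning("a single scenario among retained simulations")
    post <- direct()
    post$posterior <- 1; post$lo <- post$hi <- 1
  } else if (method == "direct") {
    post <- direct()
  } else {
    post <- tryCatch({
      Z <- sweep(as.matrix(rows[retained$stats]), 2, retained$sds, "/")
      keepcol <- apply(Z, 2, sd) > 1e-12
      ld <- MASS::lda(Z[, keepcol, drop = FALSE], grouping = scen)
      A <- Z[, keepcol, drop = FALSE] %*% ld$scaling
      a_obs <- matrix((retained$observed / retained$sds)[keepcol],
                      1) %*% ld$scaling
      dmax <- max(retained$distance) * 1.0000001
      w <- 1 - (retained$distance / dmax)^2
      df <- data.frame(scenario = scen, A)
      fit <- nnet::multinom(scenario ~ ., data = df, weights = w,
                            trace = FALSE, maxit = 500)
      cf <- coef(fit)
      ## complete separation: every retained point classified with
      ## certainty -> logistic surface is degenerate at the observation
      fitted_p <- fit$fitted.values
      if (all(pmax(fitted_p, 1 - fitted_p) > 1 - 1e-10))
        stop("complete separation of scenarios on the discriminant axes")
      newd <- as.data.frame(a_obs)
      names(newd) <- colnames(A)
      pr <- predict(fit, newdata = newd, type = "probs")
      if (length(fit$lev) == 2L && length(pr) == 1L)
        pr <- setNames(c(1 - pr, pr), fit$lev)
      ## delta-method CI on each probability
      th <- as.vector(t(cf))
      probfun <- function(theta) {
        cm <- matrix(theta, nrow = nrow(rbind(cf)), byrow = TRUE)
        eta <- c(0, cm %*% c(1, as.numeric(a_obs)))
        exp(eta) / sum(exp(eta))
      }
      V <- vcov(fit)
      J <- matrix(0, length(all_scen), length(th))
      h <- 1e-5
      for (q in seq_along(th)) {
        tp <- th; tp[q] <- tp[q] + h
        tm <- th; tm[q] <- tm[q] - h
        J[, q] <- (probfun(tp) - probfun(tm)) / (2 * h)
      }
      se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
      data.frame(scenario = all_scen, posterior = as.numeric(pr[all_scen]),
                 lo = pmax(0, as.numeric(pr[all_scen]) - 1.96 * se),
                 hi = pmin(1, as.numeric(pr[all_scen]) + 1.96 * se))
    }, error = function(e) {
      warning("lda_logit failed (", conditionMessage(e),
              "); falling back to direct posterior")
      direct()
    })
  }
  post$posterior <- post$posterior / sum(post$posterior)
  ord <- order(-post$posterior)
  chosen <- "undecided"
  if (length(ord) == 1L) chosen <- post$scenario[1]
  else if (post$lo[ord[1]] > post$hi[ord[2]]) chosen <- post$scenario[ord[1]]
  structure(list(posterior = post, chosen = chosen, method = method,
                 n_retained = nR), class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("ABC posterior (", x$method, ", ", x$n_retained, " retained)\n",
      sep = "")
  print(transform(x$posterior, posterior = round(posterior, 4),
                  lo = round(lo, 4), hi = round(hi, 4)), row.names = FALSE)
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Hierarchical scenario comparison
#'
#' Runs ordered comparison rounds: per round, simulate a reference table
#' for the round's scenarios, reject against the observed summaries and
#' compute posteriors; the winner (highest posterior with non-overlapping
#' 95% CI) is recorded and passed to the next round when that round is a
#' function of previous winners.
#'
#' @param rounds named list; each element is a list of [scenario()]s or a
#'   `function(winners)` returning one.
#' @param observed named summary vector of the observed dataset
#'   ([summarize_dataset()]).
#' @param priors,design as in [abc_table()].
#' @param n_sim simulations per scenario per round.
#' @param tolerance retained fraction.
#' @param seed integer seed.
#' @param method posterior method.
#' @return class `abc_tree`: per-round `abc_result`s plus the decision path.
#' @export
hierarchical_compare <- function(rounds, observed, priors, design,
                                 n_sim = 1000, tolerance = 0.01, seed = 1L,
                                 method = "lda_logit") {
  if (!length(rounds)) stop("empty round list")
  winners <- character(0)
  results <- list()
  for (rn in seq_along(rounds)) {
    rd <- rounds[[rn]]
    if (is.function(rd)) rd <- rd(winners)
    if (!length(rd)) stop("empty round: ", rn)
    tab <- abc_table(rd, priors, design, n_sim = n_sim,
                     seed = spawn_seed(seed, paste0("round", rn)))
    ret <- abc_reject(observed, tab, tolerance)
    res <- posterior_probability(ret, method)
    results[[names(rounds)[rn] %||% paste0("round", rn)]] <- res
    winners <- c(winners, res$chosen)
  }
  structure(list(results = results, winners = winners),
            class = "abc_tree")
}

#' @export
print.abc_tree <- function(x, ...) {
  for (nm in names(x$results)) {
    cat("--", nm, "--\n")
    print(x$results[[nm]])
  }
  cat("decision path:", paste(x$winners, collapse = " -> "), "\n")
  invisible(x)
}
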