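## Study-mimicking synthetic data with known truth. The sequence arm
## delegates to the structured-coalescent simulator; a genotype arm
## produces multilocus genotype panels (optionally with sibling families
## and two-deme mixing) for relatedness and F_IS calibration, where
## sequence-level realism is irrelevant and speed matters.

#' Build a synthetic-data configuration
#'
#' @param populations data.frame with columns `population`, `group`,
#'   `ocean`.
#' @param sizes named numeric: effective size per population (ancestral
#'   populations included).
#' @param events coalescent event list (see [scenario()]).
#' @param samples named integer: sampled individuals per population.
#' @param loci list of `list(name, mode, L, mu, copies)`.
#' @param sex_ratio probability that an individual is female.
#' @param migration `list(F =, M =)`: per-individual probability of being
#'   an immigrant from another deme, per sex (forward-time overlay).
#' @param sib_pairs `NULL`, or `list(sex =, n_families =, family_size =)`:
#'   individuals of that sex are replaced by sibling families whose gametes
#'   are drawn from simulated parent individuals.
#' @param genotype_panel `NULL`, or `list(n_f =, n_m =, n_loci =, p =,
#'   families =)` to use the genotype arm instead of sequences.
#' @param geo optional population distance matrix (km).
#' @param seed mandatory integer seed.
#' @return class `synth_config`.
#' @export
synth_config <- function(populations = NULL, sizes = NULL, events = NULL,
                         samples = NULL, loci = NULL, sex_ratio = 0.5,
                         migration = list(F = 0, M = 0), sib_pairs = NULL,
                         genotype_panel = NULL, geo = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(populations = populations, sizes = sizes, events = events,
                 samples = samples, loci = loci, sex_ratio = sex_ratio,
                 migration = migration, sib_pairs = sib_pairs,
                 genotype_panel = genotype_panel, geo = geo,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Named synthetic-data presets
#'
#' * `study_mimic`: 13 populations in 5 groups and 2 oceans, 3
#'   mitochondrial + 6 nuclear loci, hierarchical divergence (deep ocean
#'   split, intermediate group splits, shallow within-group splits) and a
#'   geographic distance matrix consistent with the nesting.
#' * `two_pop_null`: two identical demes with no divergence, for type-I
#'   error suites.
#' * `sexbias_power`: genotype panel with male sibling families and
#'   unrelated females; female migration 10x male.
#' * `abc_recovery`: three populations with sequential splits at `0.2N`
#'   and `0.6N` generations (truth: `p3` splits from `p2` after `p2` split
#'   from `p1`).
#'
#' @param name preset name.
#' @param seed integer seed stored in the config.
#' @return a [synth_config()].
#' @export
synth_preset <- function(name = c("study_mimic", "two_pop_null",
                                  "sexbias_power", "abc_recovery"),
                         seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("study_mimic", "two_pop_null",
                                             "sexbias_power", "abc_recovery"))
    stop("unknown preset '", name[1], "'; available: study_mimic, ",
         "two_pop_null, sexbias_power, abc_recovery")
  name <- match.arg(name)
  if (name == "study_mimic") {
    groups <- list(carib = 4, cvrd = 2, macar = 4, reun = 2, seych = 1)
    ocean <- c(carib = "atlantic", cvrd = "atlantic", macar = "atlantic",
               reun = "indian", seych = "indian")
    pops <- unlist(lapply(names(groups), function(g)
      paste0(g, seq_len(groups[[g]]))))
    pdf <- data.frame(population = pops,
                      group = rep(names(groups), unlist(groups)),
                      ocean = ocean[rep(names(groups), unlist(groups))])
    N <- 1e5
    sizes <- setNames(rep(N, length(pops)), pops)
    first <- function(g) paste0(g, 1)
    ev <- list()
    ## shallow splits within groups (2k generations)
    for (g in names(groups)) if (groups[[g]] > 1)
      for (i in 2:groups[[g]])
        ev <- c(ev, list(list(time = 2000, type = "divergence",
                              from = paste0(g, i), to = first(g))))
    ## group and ocean splits (generation time ~10 y for reporting)
    ev <- c(ev,
            list(list(time = 70000, type = "divergence",
                      from = first("reun"), to = first("seych")),
                 list(time = 85000, type = "divergence",
                      from = first("macar"), to = first("cvrd")),
                 list(time = 138000, type = "divergence",
                      from = first("cvrd"), to = first("carib")),
                 list(time = 176000, type = "divergence",
                      from = first("seych"), to = first("carib"))))
    loci <- list(
      list(name = "mt1", mode = "mitochondrial", L = 577, mu = 1.5e-7),
      list(name = "mt2", mode = "mitochondrial", L = 877, mu = 1.5e-7),
      list(name = "mtcr", mode = "mitochondrial", L = 307, mu = 6e-7),
      list(name = "nucA", mode = "nuclear", L = 427, mu = 2e-9),
      list(name = "nucB", mode = "nuclear", L = 542, mu = 2e-9),
      list(name = "nucC", mode = "nuclear", L = 542, mu = 2e-9),
      list(name = "nucD", mode = "nuclear", L = 515, mu = 3e-9),
      list(name = "nucE", mode = "nuclear", L = 1323, mu = 3e-9),
      list(name = "nucF", mode = "nuclear", L = 1067, mu = 4e-9))
    ## geographic distances (km) consistent with the nesting
    gd <- matrix(c(0, 4500, 5500, 11000, 10500,
                   4500, 0, 1800, 9500, 9000,
                   5500, 1800, 0, 9800, 9200,
                   11000, 9500, 9800, 0, 1800,
                   10500, 9000, 9200, 1800, 0), 5, 5,
                 dimnames = list(names(groups), names(groups)))
    geo <- matrix(0, length(pops), length(pops),
                  dimnames = list(pops, pops))
    off <- setNames((seq_along(pops) - 1) * 60, pops)  # within-group spread
    for (a in pops) for (b in pops) if (a != b) {
      ga <- pdf$group[pdf$population == a]
      gb <- pdf$group[pdf$population == b]
      geo[a, b] <- if (ga == gb) 150 + abs(off[a] - off[b])
                   else gd[ga, gb] + abs(off[a] - off[b])
    }
    geo <- (geo + t(geo)) / 2
    synth_config(populations = pdf, sizes = sizes, events = ev,
                 samples = setNames(rep(10L, length(pops)), pops),
                 loci = loci, geo = geo, seed = seed)
  } else if (name == "two_pop_null") {
    pdf <- data.frame(population = c("d1", "d2"),
                      group = c("g1", "g1"), ocean = c("o1", "o1"))
    synth_config(populations = pdf,
                 sizes = c(d1 = 1e5, d2 = 1e5),
                 events = list(list(time = 1, type = "divergence",
                                    from = "d2", to = "d1")),
                 samples = c(d1 = 20L, d2 = 20L),
                 loci = list(
                   list(name = "mt1", mode = "mitochondrial", L = 600,
                        mu = 3e-7),
                   list(name = "nu1", mode = "nuclear", L = 450, mu = 2e-8),
                   list(name = "nu2", mode = "nuclear", L = 450, mu = 2e-8),
                   list(name = "nu3", mode = "nuclear", L = 450, mu = 2e-8),
                   list(name = "nu4", mode = "nuclear", L = 450, mu = 2e-8)),
                 seed = seed)
  } else if (name == "sexbias_power") {
    synth_config(genotype_panel = list(n_f = 20L, n_m = 20L, n_loci = 100L,
                                       p = 0.5,
                                       families = list(sex = "M",
                                                       n_families = 5L,
                                                       family_size = 4L)),
                 migration = list(F = 0.1, M = 0.01),
                 seed = seed)
  } else {  # abc_recovery
    pdf <- data.frame(population = c("p1", "p2", "p3"),
                      group = c("g1", "g1", "g1"),
                      ocean = c("o1", "o1", "o1"))
    N <- 1e4
    synth_config(populations = pdf,
                 sizes = c(p1 = N, p2 = N, p3 = N),
                 events = list(
                   list(time = 0.2 * N, type = "divergence",
                        from = "p3", to = "p2"),
                   list(time = 0.6 * N, type = "divergence",
                        from = "p2", to = "p1")),
                 samples = c(p1 = 15L, p2 = 15L, p3 = 15L),
                 loci = c(list(list(name = "mt1", mode = "mitochondrial",
                                    L = 600, mu = 5e-7)),
                          lapply(1:4, function(i)
                            list(name = paste0("nu", i), mode = "nuclear",
                                 L = 500, mu = 1.5e-7))),
                 seed = seed)
  }
}

## Hardy-Weinberg genotype panel with optional sibling families and
## two-deme mixing; biallelic loci with allele frequency p (deme 1) and
## p2 (deme 2, for Wahlund-type constructions).
#' Simulate a multilocus genotype panel
#'
#' @param n_f,n_m females and males.
#' @param n_loci biallelic loci.
#' @param p reference allele frequency.
#' @param families `NULL` or `list(sex, n_families, family_size)`:
#'   individuals of that sex are organized into full-sib families (parents
#'   drawn from the same Hardy-Weinberg pool).
#' @param seed integer seed.
#' @return `list(genotypes, truth)`; `truth$sib_dyads` lists the related
#'   pairs.
#' @export
sim_genotypes <- function(n_f, n_m, n_loci = 100, p = 0.5, families = NULL,
                          seed = 1L) {
  set.seed(seed)
  n <- n_f + n_m
  sex <- c(rep("F", n_f), rep("M", n_m))
  draw <- function(k) matrix(rbinom(k * n_loci, 1, p) + 1L, k, n_loci)
  a1 <- draw(n); a2 <- draw(n)
  sib_dyads <- NULL
  if (!is.null(families)) {
    idx <- which(sex == families$sex)
    need <- families$n_families * families$family_size
    if (need > length(idx))
      stop("not enough individuals of sex ", families$sex,
           " for the requested families")
    slots <- idx[seq_len(need)]
    fam_of <- rep(seq_len(families$n_families), each = families$family_size)
    for (f in seq_len(families$n_families)) {
      mom1 <- draw(1); mom2 <- draw(1)
      dad1 <- draw(1); dad2 <- draw(1)
      for (i in slots[fam_of == f]) {
        frommom <- runif(n_loci) < 0.5
        fromdad <- runif(n_loci) < 0.5
        a1[i, ] <- ifelse(frommom, mom1, mom2)
        a2[i, ] <- ifelse(fromdad, dad1, dad2)
      }
    }
    sib_dyads <- do.call(rbind, lapply(seq_len(families$n_families),
      function(f) t(combn(slots[fam_of == f], 2))))
  }
  ids <- sprintf("ind%03d", seq_len(n))
  rownames(a1) <- rownames(a2) <- ids
  gt <- genotype_table(a1, a2, population = rep("pop1", n), sex = sex)
  list(genotypes = gt, truth = list(sib_dyads = sib_dyads, p = p,
                                    seed = seed))
}

#' Generate a synthetic dataset with known truth
#'
#' Sequence-arm configs run the structured coalescent, materialize
#' FASTA-ready alignments, overlay sexes and (optionally) apply the
#' forward-time migration overlay: each sampled individual is, with its
#' sex's migration probability, replaced by an individual simulated in a
#' random other deme. Sibling families replace chosen individuals' nuclear
#' gametes by random gametes of two simulated parents (and the maternal
#' mtDNA). Genotype-arm configs delegate to [sim_genotypes()].
#'
#' @param config a [synth_config()].
#' @return `list(dataset, genotypes, truth)`; `dataset` is a
#'   [pop_dataset()] (`NULL` for the genotype arm).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$genotype_panel)) {
    gp <- config$genotype_panel
    out <- sim_genotypes(gp$n_f, gp$n_m, gp$n_loci, gp$p, gp$families,
                         seed = config$seed)
    return(list(dataset = NULL, genotypes = out$genotypes,
                truth = c(out$truth, list(migration = config$migration)),
                config = config))
  }
  set.seed(config$seed)
  pops <- config$populations$population
  samples <- config$samples
  migrate <- max(unlist(config$migration)) > 0 && length(pops) > 1
  ## simulate a parallel pool of extra individuals per deme used as
  ## migrant sources and as sibling parents
  pool_extra <- if (migrate || !is.null(config$sib_pairs)) samples else 0L
  sim_samples <- samples + pool_extra
  sc <- scenario("synth", sizes = config$sizes, events = config$events)
  design <- list(samples = sim_samples, loci = config$loci)
  params <- setNames(numeric(0), character(0))
  st <- sim_states(sc, params, design)
  meta_extra <- list(
    group = setNames(config$populations$group, pops),
    ocean = setNames(config$populations$ocean, pops),
    geo = config$geo)
  full <- states_to_dataset(st, design, meta_extra)
  ## split real individuals from the pool
  real_ids <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(samples[[p]]))))
  pool_ids <- setdiff(full$meta$individual, real_ids)
  sexes <- ifelse(runif(length(real_ids)) < config$sex_ratio, "F", "M")
  migrants <- NULL
  swap_individual <- function(loci, id_to, id_from) {
    for (k in seq_along(loci)) {
      to <- which(loci[[k]]$individual == id_to)
      from <- which(loci[[k]]$individual == id_from)
      if (length(to) == length(from) && length(to))
        loci[[k]]$seq[to, ] <- loci[[k]]$seq[from, , drop = FALSE]
    }
    loci
  }
  loci <- full$loci
  if (migrate) {
    pool_by_pop <- split(pool_ids,
                         sub("_[0-9]+$", "", pool_ids))
    used <- character(0)
    pop_of <- rep(pops, samples)
    for (i in seq_along(real_ids)) {
      rate <- config$migration[[sexes[i]]] %||% 0
      if (runif(1) < rate) {
        src <- sample(setdiff(pops, pop_of[i]), 1)
        avail <- setdiff(pool_by_pop[[src]], used)
        if (!length(avail)) next
        donor <- avail[1]
        used <- c(used, donor)
        loci <- swap_individual(loci, real_ids[i], donor)
        migrants <- rbind(migrants,
                          data.frame(individual = real_ids[i],
                                     source = src, sex = sexes[i]))
      }
    }
  }
  pedigree <- NULL
  if (!is.null(config$sib_pairs)) {
    sp <- config$sib_pairs
    cand <- which(sexes == sp$sex)
    need <- sp$n_families * sp$family_size
    if (need > length(cand))
      stop("not enough individuals of sex ", sp$sex, " for families")
    slots <- real_ids[cand[seq_len(need)]]
    fam <- rep(seq_len(sp$n_families), each = sp$family_size)
    pool_pool <- pool_ids
    for (f in seq_len(sp$n_families)) {
      par <- pool_pool[1:2]; pool_pool <- pool_pool[-(1:2)]
      for (id in slots[fam == f]) {
        for (k in seq_along(loci)) {
          lc <- loci[[k]]
          to <- which(lc$individual == id)
          p1 <- which(lc$individual == par[1])
          p2 <- which(lc$individual == par[2])
          if (lc$mode == "mitochondrial") {
            if (length(to) && length(p1))
              loci[[k]]$seq[to, ] <- lc$seq[rep(p1[1], length(to)), ]
          } else if (length(to) == 2 && length(p1) == 2 && length(p2) == 2) {
            loci[[k]]$seq[to[1], ] <- lc$seq[sample(p1, 1), ]
            loci[[k]]$seq[to[2], ] <- lc$seq[sample(p2, 1), ]
          }
        }
      }
      pedigree <- rbind(pedigree,
                        data.frame(family = f, individual = slots[fam == f]))
    }
  }
  ## final dataset: real individuals only, sexes attached
  meta <- full$meta[match(real_ids, full$meta$individual), ]
  meta$sex <- sexes
  loci <- lapply(loci, function(l) {
    keep <- l$individual %in% real_ids
    locus_alignment(l$name, l$mode, l$seq[keep, , drop = FALSE],
                    l$individual[keep], l$copy[keep],
                    l$copies_per_individual, l$model)
  })
  dataset <- pop_dataset(loci, meta, geo = config$geo)
  list(dataset = dataset, genotypes = NULL,
       truth = list(sizes = config$sizes, events = config$events,
                    migrants = migrants, pedigree = pedigree,
                    seed = config$seed),
       config = config)
}
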