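## End-to-end orchestration: run the diversity, differentiation, sex-bias
## and (optional) ABC stages on one dataset, writing a reproducible report
## bundle. All randomness is spawned from one master seed; stage wall-times
## go to run.log, which is not part of the bundle (the bundle must be
## byte-identical across reruns with the same seed).

#' Sex-ratio test against 1:1
#'
#' Pearson's Chi-squared with Yates' continuity correction on observed
#' female/male counts.
#'
#' @param n_f,n_m observed counts.
#' @return list with `chisq`, `df`, `p`.
#' @export
sex_ratio_test <- function(n_f, n_m) {
  obs <- c(n_f, n_m)
  E <- sum(obs) / 2
  chisq <- sum(pmax(0, abs(obs - E) - 0.5)^2 / E)
  list(chisq = chisq, df = 1L, p = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Write a dataset to a directory (FASTA per locus + TSV tables)
#' @param dataset a [pop_dataset()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(name = character(0), mode = character(0),
                    copies = integer(0), model = character(0),
                    file = character(0))
  for (l in dataset$loci) {
    f <- paste0(l$name, ".fasta")
    write_locus_fasta(l, file.path(dir, f))
    man <- rbind(man, data.frame(name = l$name, mode = l$mode,
                                 copies = l$copies_per_individual,
                                 model = l$model, file = f))
  }
  write.table(man, file.path(dir, "loci.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$geo))
    write_square_tsv(dataset$geo, file.path(dir, "geo.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory.
#' @return a [pop_dataset()].
#' @export
read_dataset <- function(dir) {
  man <- read.delim(file.path(dir, "loci.tsv"), stringsAsFactors = FALSE)
  loci <- lapply(seq_len(nrow(man)), function(i)
    read_locus_fasta(file.path(dir, man$file[i]), mode = man$mode[i],
                     copies_per_individual = man$copies[i],
                     model = man$model[i], name = man$name[i]))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  geo <- if (file.exists(file.path(dir, "geo.tsv")))
    read_geo_distance(file.path(dir, "geo.tsv")) else NULL
  pop_dataset(loci, meta, geo)
}

#' Assemble a run configuration
#'
#' @param dataset a [pop_dataset()], or `NULL` with `preset` given.
#' @param preset a [synth_preset()] name to simulate the input dataset.
#' @param outdir output directory for the report bundle.
#' @param seed master seed: every stochastic step derives its seed from it
#'   via [spawn_seed()].
#' @param n_perm permutations for AMOVA / pairwise tests / Mantel.
#' @param n_boot bootstrap/permutation counts for the sex-bias stage.
#' @param neutrality_nsim coalescent replicates for neutrality p-values
#'   (`0` skips the p-values).
#' @param min_per_sex minimum individuals per sex for the sex-bias stage.
#' @param abc `NULL`, or `list(rounds, priors, design, n_sim, tolerance)`
#'   for the scenario-choice stage.
#' @return class `run_config`.
#' @export
run_config <- function(dataset = NULL, preset = NULL, outdir = tempfile(),
                       seed = 1L, n_perm = 1000, n_boot = 1000,
                       neutrality_nsim = 1000, min_per_sex = 5L,
                       abc = NULL) {
  if (is.null(dataset) && is.null(preset))
    stop("either a dataset or a preset is required")
  stopifnot(n_perm >= 1, n_boot >= 1)
  structure(list(dataset = dataset, preset = preset, outdir = outdir,
                 seed = as.integer(seed), n_perm = n_perm, n_boot = n_boot,
                 neutrality_nsim = neutrality_nsim,
                 min_per_sex = min_per_sex, abc = abc),
            class = "run_config")
}

config_hash <- function(config) {
  strip <- config[setdiff(names(config), c("outdir", "dataset"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(str(strip, give.attr = FALSE)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: data (load or simulate) -> diversity -> differentiation
#' (three-level AMOVA per marker class, pairwise matrices, Mantel when a
#' geographic matrix is present) -> sex-bias (skipped with a logged reason
#' when sexes are unavailable) -> optional ABC. A stage failure produces a
#' partial bundle with the error recorded in the manifest.
#'
#' @param config a [run_config()].
#' @return class `report_bundle`; all tables are also written under
#'   `config$outdir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run.log")
  cat("", file = logf)
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%OS2"), ...,
                              "\n", file = logf, append = TRUE)
  bundle <- list(outdir = config$outdir, errors = list(), skipped = list())
  seed <- config$seed
  t_stage <- function(tag, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      bundle$errors[[tag]] <<- conditionMessage(e)
      logmsg("stage", tag, "FAILED:", conditionMessage(e))
      NULL
    })
    logmsg("stage", tag, "done in",
           sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  ## -- data ------------------------------------------------------------
  dataset <- t_stage("data", {
    if (!is.null(config$dataset)) config$dataset
    else {
      gen <- synth_generate(synth_preset(config$preset,
                                         seed = spawn_seed(seed, "synth")))
      write_dataset(gen$dataset, file.path(config$outdir, "data"))
      gen$dataset
    }
  })
  if (is.null(dataset)) {
    bundle$manifest <- write_manifest(bundle, config)
    class(bundle) <- "report_bundle"
    return(bundle)
  }

  ## -- diversity --------------------------------------------------------
  bundle$diversity <- t_stage("diversity", {
    dv <- diversity_table(dataset, n_sim = config$neutrality_nsim,
                          seed = spawn_seed(seed, "diversity"))
    write.table(format(dv, digits = 6), file.path(config$outdir,
                                                  "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dv
  })

  ## -- differentiation --------------------------------------------------
  has_groups <- length(unique(dataset$meta$group)) > 1
  for (cls in c("mitochondrial", "nuclear")) {
    short <- if (cls == "mitochondrial") "mt" else "nu"
    loci <- Filter(function(l) l$mode == cls, dataset$loci)
    if (!length(loci)) next
    bundle[[paste0("amova_", short)]] <- t_stage(paste0("amova_", short), {
      aln <- concatenate_loci(loci, paste0(cls, "_concat"))
      pop <- dataset$meta$population[match(aln$individual,
                                           dataset$meta$individual)]
      grp <- dataset$meta$group[match(aln$individual,
                                      dataset$meta$individual)]
      ## molecular-distance weighting for both classes: identity-based
      ## F_ST degenerates when nearly every concatenated copy is a unique
      ## haplotype
      d <- pairwise_distance(aln, model = if (cls == "mitochondrial")
        "K2P" else "TN93")
      if (any(is.na(d))) d[is.na(d)] <- max(d, na.rm = TRUE)
      fit <- amova(d, pop, groups = if (has_groups) grp else NULL,
                   n_perm = config$n_perm,
                   seed = spawn_seed(seed, paste0("amova", short)))
      tab <- data.frame(stratum = names(fit$sigma),
                        sigma2 = fit$sigma, pct = fit$pct)
      write.table(format(tab, digits = 6),
                  file.path(config$outdir, paste0("amova_", short, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    })
    bundle[[paste0("pairwise_", short)]] <-
      t_stage(paste0("pairwise_", short), {
        pw <- pairwise_diff(dataset, marker = cls,
                            statistic = "PhiST",
                            n_perm = config$n_perm,
                            seed = spawn_seed(seed, paste0("pw", short)))
        write_square_tsv(pw$values,
                         file.path(config$outdir,
                                   paste0("pairwise_", short, ".tsv")))
        write_square_tsv(pw$p,
                         file.path(config$outdir,
                                   paste0("pairwise_", short, "_p.tsv")))
        pw
      })
    if (!is.null(dataset$geo) && !is.null(bundle[[paste0("pairwise_", short)]]))
      bundle[[paste0("mantel_", short)]] <-
        t_stage(paste0("mantel_", short), {
          pw <- bundle[[paste0("pairwise_", short)]]
          pops <- rownames(pw$values)
          mt <- mantel_test(pw$values, dataset$geo[pops, pops],
                            transform = "linearize",
                            n_perm = config$n_perm,
                            seed = spawn_seed(seed, paste0("mantel", short)))
          mt
        })
  }
  mantel_out <- Filter(Negate(is.null),
                       bundle[grep("^mantel_", names(bundle))])
  if (length(mantel_out))
    jsonlite::write_json(
      lapply(mantel_out, function(m)
        list(r = m$r, p = m$p, n_perm = m$n_perm, transform = m$transform)),
      file.path(config$outdir, "mantel.json"), auto_unbox = TRUE,
      digits = NA)

  ## -- sex bias ---------------------------------------------------------
  sexes <- table(dataset$meta$sex)
  pops_ok <- any(vapply(split(dataset$meta$sex, dataset$meta$population),
                        function(s) sum(s == "F") >= config$min_per_sex &&
                          sum(s == "M") >= config$min_per_sex, TRUE))
  if (!any(c("F", "M") %in% names(sexes)) || !pops_ok) {
    bundle$skipped$sexbias <- "no population with enough sexed individuals"
    logmsg("stage sexbias skipped:", bundle$skipped$sexbias)
  } else {
    bundle$sexbias <- t_stage("sexbias", {
      tb <- sexbias_table(dataset, n_boot = config$n_boot,
                          n_perm = config$n_boot,
                          seed = spawn_seed(seed, "sexbias"),
                          min_per_sex = config$min_per_sex)
      write.table(format(tb, digits = 6),
                  file.path(config$outdir, "sexbias.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tb
    })
    for (sx in c("F", "M"))
      bundle[[paste0("fst_", sx)]] <- t_stage(paste0("fst_", sx), {
        pw <- per_sex_structure(dataset, sx, n_perm = config$n_perm,
                                seed = spawn_seed(seed, paste0("persex", sx)))
        write_square_tsv(pw$values,
                         file.path(config$outdir,
                                   paste0("fst_", tolower(sx), ".tsv")))
        pw
      })
    nf <- sum(dataset$meta$sex == "F"); nm <- sum(dataset$meta$sex == "M")
    bundle$sex_ratio <- sex_ratio_test(nf, nm)
  }

  ## -- ABC (optional) ---------------------------------------------------
  if (!is.null(config$abc)) {
    bundle$abc <- t_stage("abc", {
      ab <- config$abc
      obs_ds <- subset_individuals(
        dataset,
        dataset$meta$individual[dataset$meta$population %in%
                                  names(ab$design$samples)])
      obs <- summarize_dataset(obs_ds)
      tree <- hierarchical_compare(ab$rounds, obs, ab$priors, ab$design,
                                   n_sim = ab$n_sim %||% 1000,
                                   tolerance = ab$tolerance %||% 0.01,
                                   seed = spawn_seed(seed, "abc"))
      jsonlite::write_json(
        list(winners = tree$winners,
             rounds = lapply(tree$results, function(r)
               list(method = r$method, n_retained = r$n_retained,
                    posterior = r$posterior, chosen = r$chosen))),
        file.path(config$outdir, "abc.json"), auto_unbox = TRUE,
        digits = NA)
      tree
    })
  }

  bundle$manifest <- write_manifest(bundle, config)
  class(bundle) <- "report_bundle"
  bundle
}

write_manifest <- function(bundle, config) {
  man <- list(package = "seqpopgen",
              version = as.character(utils::packageVersion("seqpopgen")),
              r_version = R.version.string,
              seed = config$seed,
              config_hash = config_hash(config),
              n_perm = config$n_perm, n_boot = config$n_boot,
              preset = config$preset %||% "user-supplied",
              errors = bundle$errors, skipped = bundle$skipped)
  jsonlite::write_json(man, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle in", x$outdir, "\n")
  parts <- setdiff(names(x), c("outdir", "errors", "skipped", "manifest"))
  cat(" components:", paste(parts, collapse = ", "), "\n")
  if (length(x$skipped))
    cat(" skipped:", paste(names(x$skipped), unlist(x$skipped),
                           sep = ": ", collapse = "; "), "\n")
  if (length(x$errors))
    cat(" ERRORS:", paste(names(x$errors), unlist(x$errors),
                          sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' Bundle files subject to the byte-identity reproducibility contract
#'
#' Everything under the output directory except `run.log` (which records
#' wall-clock timings).
#'
#' @param outdir a bundle directory.
#' @return character vector of file paths.
#' @export
bundle_files <- function(outdir) {
  f <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  f[basename(f) != "run.log"]
}

#' Ready-made ABC comparison for the three-population recovery design
#'
#' Builds the radiation-vs-sequential scenario pair, priors and sampling
#' design matching the `abc_recovery` preset: one round comparing a
#' simultaneous split of the three populations against the sequential
#' (stepping-stone) history, with uniform priors on sizes and ordered
#' split times and log-uniform priors on the per-class mutation rates.
#'
#' @return list with `rounds`, `priors`, `design`, `truth` (name of the
#'   true scenario under the preset).
#' @export
abc_recovery_setup <- function() {
  sizes <- c(p1 = "N", p2 = "N", p3 = "N")
  seq_sc <- scenario("sequential", sizes = sizes, events = list(
    list(time = "t_young", type = "divergence", from = "p3", to = "p2"),
    list(time = "t_old", type = "divergence", from = "p2", to = "p1")))
  rad_sc <- scenario("radiation", sizes = sizes, events = list(
    list(time = "t_old", type = "divergence", from = "p3", to = "p1"),
    list(time = "t_old", type = "divergence", from = "p2", to = "p1")))
  priors <- prior_spec(
    bounds = list(N = c(2000, 30000),
                  t_young = c(500, 4000),
                  t_old = c(3000, 12000),
                  mu_mt = c(2e-7, 1.2e-6),
                  mu_nu = c(6e-8, 4e-7)),
    log_scale = c("mu_mt", "mu_nu"),
    order = list(c("t_young", "t_old")))
  design <- list(samples = c(p1 = 15L, p2 = 15L, p3 = 15L),
                 loci = c(list(list(name = "mt1", mode = "mitochondrial",
                                    L = 600, mu = "mu_mt")),
                          lapply(1:4, function(i)
                            list(name = paste0("nu", i), mode = "nuclear",
                                 L = 500, mu = "mu_nu"))))
  list(rounds = list(topology = list(rad_sc, seq_sc)),
       priors = priors, design = design, truth = "sequential")
}
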