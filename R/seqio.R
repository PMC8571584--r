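## Data model: a locus alignment is a character matrix (sequence copies x
## sites) plus per-row individual/copy labels, an inheritance mode and a
## substitution-model tag. All downstream statistics consume this object.

VALID_CHARS <- c("A", "C", "G", "T", "-", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
## characters treated as missing for distance/diversity work: gaps, N and
## all partial ambiguity codes (phased input should not contain them)
MISSING_CHARS <- setdiff(VALID_CHARS, c("A", "C", "G", "T"))

#' Construct a locus alignment
#'
#' @param name locus label.
#' @param mode `"mitochondrial"` or `"nuclear"`.
#' @param seqs character matrix (one row per sequence copy, one column per
#'   site) or a character vector of equal-length sequence strings.
#' @param individual individual id per row.
#' @param copy integer copy index per row (1 for mtDNA, 1:2 for phased
#'   nuclear loci or a duplicated mitochondrial control region).
#' @param copies_per_individual declared maximum copies per individual.
#' @param model substitution model tag: `"p"`, `"JC"`, `"K2P"` or `"TN93"`.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(name, mode = c("mitochondrial", "nuclear"), seqs,
                            individual, copy = NULL,
                            copies_per_individual = 1L,
                            model = c("p", "JC", "K2P", "TN93")) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  if (is.character(seqs) && is.null(dim(seqs))) {
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
      stop("sequences have unequal lengths: ",
           paste(nchar(seqs), collapse = ","))
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  } else {
    seqs <- toupper(as.matrix(seqs))
  }
  if (is.null(copy)) copy <- rep(1L, nrow(seqs))
  stopifnot(length(individual) == nrow(seqs), length(copy) == nrow(seqs))
  bad <- setdiff(unique(as.vector(seqs)), VALID_CHARS)
  if (length(bad))
    stop("invalid characters in alignment '", name, "': ",
         paste(bad, collapse = " "))
  key <- paste(individual, copy)
  if (anyDuplicated(key))
    stop("duplicate (individual, copy) pair: ", key[duplicated(key)][1])
  if (any(copy > copies_per_individual))
    stop("copy index exceeds declared copies_per_individual")
  rownames(seqs) <- if (copies_per_individual > 1L)
    paste0(individual, "_", letters[copy]) else as.character(individual)
  structure(list(name = name, mode = mode, seq = seqs,
                 individual = as.character(individual),
                 copy = as.integer(copy),
                 copies_per_individual = as.integer(copies_per_individual),
                 L = ncol(seqs), model = model),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus '", x$name, "' (", x$mode, ", model ", x$model, "): ",
      nrow(x$seq), " sequence copies x ", x$L, " sites, ",
      length(unique(x$individual)), " individuals\n", sep = "")
  invisible(x)
}

## default header parser: optional "_a"/"_b" copy suffix
default_id_parser <- function(header) {
  m <- regmatches(header, regexec("^(.*)_(a|b)$", header))[[1]]
  if (length(m) == 3L) list(individual = m[2], copy = match(m[3], c("a", "b")))
  else list(individual = header, copy = 1L)
}

#' Read one locus from a FASTA alignment
#'
#' Headers encode the individual id, with an optional `_a`/`_b` suffix for
#' the two copies of a phased locus. A ragged alignment is an error naming
#' the offending record.
#'
#' @param path FASTA file.
#' @inheritParams locus_alignment
#' @param id_parser function mapping one header string to
#'   `list(individual=, copy=)`; default understands the `_a`/`_b` suffix.
#' @return a [locus_alignment()].
#' @export
read_locus_fasta <- function(path, mode = c("mitochondrial", "nuclear"),
                             copies_per_individual = 1L, id_parser = NULL,
                             model = c("p", "JC", "K2P", "TN93"),
                             name = sub("\\.[^.]*$", "", basename(path))) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  recs <- ape::read.FASTA(path)
  if (!length(recs)) stop("empty FASTA: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    off <- names(recs)[which(lens != lens[1])[1]]
    stop("ragged alignment in ", path, ": record '", off,
         "' has length ", lens[names(recs) == off][1],
         " (first record has ", lens[1], ")")
  }
  ## ape stores DNA in raw bytes; decode via its character representation
  chars <- toupper(do.call(rbind, as.character(recs)))
  parser <- id_parser %||% default_id_parser
  ids <- lapply(names(recs), parser)
  locus_alignment(name = name, mode = mode, seqs = chars,
                  individual = vapply(ids, `[[`, "", "individual"),
                  copy = vapply(ids, function(z) as.integer(z$copy), 1L),
                  copies_per_individual = copies_per_individual,
                  model = model)
}

#' Read the individual metadata table
#'
#' Expects a TSV with columns `individual`, `population`, `group`, `ocean`,
#' `sex`. Sex entries are normalized to `F`/`M`/`unknown`. Populations must
#' nest uniquely within groups and groups within oceans.
#'
#' @param path TSV file.
#' @return a data.frame of class `pop_meta`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "group", "ocean", "sex")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  validate_metadata(df[need])
}

#' @rdname read_metadata
#' @param df a data.frame with the metadata columns already in memory.
#' @export
validate_metadata <- function(df) {
  sx <- tolower(trimws(df$sex))
  df$sex <- ifelse(sx %in% c("f", "female"), "F",
            ifelse(sx %in% c("m", "male"), "M", "unknown"))
  for (pair in list(c("population", "group"), c("group", "ocean"))) {
    tab <- unique(df[pair])
    dup <- tab[[1]][duplicated(tab[[1]])]
    if (length(dup))
      stop("nesting error: ", pair[1], " '", dup[1],
           "' is assigned to more than one ", pair[2])
  }
  if (anyDuplicated(df$individual))
    stop("duplicate individual id: ", df$individual[duplicated(df$individual)][1])
  class(df) <- c("pop_meta", "data.frame")
  df
}

#' Read a labelled square geographic distance matrix (km) from TSV
#' @param path TSV file: first column labels, remaining columns the matrix.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_geo_distance <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
      any(diag(m) != 0) || any(m < 0))
    stop("geographic distance matrix must be symmetric, nonnegative, ",
         "with zero diagonal")
  m
}

#' Bundle loci, metadata and geography into one dataset
#'
#' @param loci list of [locus_alignment()] objects.
#' @param meta metadata data.frame (see [read_metadata()]).
#' @param geo optional symmetric population distance matrix (km).
#' @return an object of class `pop_dataset`.
#' @export
pop_dataset <- function(loci, meta, geo = NULL) {
  stopifnot(is.list(loci), length(loci) > 0)
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, `[[`, "", "name")
  meta <- validate_metadata(as.data.frame(meta))
  for (lc in loci) {
    missing <- setdiff(unique(lc$individual), meta$individual)
    if (length(missing))
      stop("locus '", lc$name, "' has individuals absent from metadata: ",
           paste(head(missing, 3), collapse = ", "))
  }
  if (!is.null(geo)) {
    pops <- sort(unique(meta$population))
    if (!all(pops %in% rownames(geo)))
      stop("geo matrix lacks populations: ",
           paste(setdiff(pops, rownames(geo)), collapse = ", "))
  }
  structure(list(loci = loci, meta = meta, geo = geo), class = "pop_dataset")
}

#' @export
print.pop_dataset <- function(x, ...) {
  cat("pop_dataset:", length(x$loci), "loci,", nrow(x$meta), "individuals,",
      length(unique(x$meta$population)), "populations in",
      length(unique(x$meta$group)), "groups /",
      length(unique(x$meta$ocean)), "oceans\n")
  invisible(x)
}

## columns retained under a site policy; for complete deletion every column
## containing a gap/N/ambiguity anywhere is dropped
retained_sites <- function(seqs, site_policy) {
  if (site_policy == "complete_deletion")
    which(colSums(matrix(seqs %in% MISSING_CHARS, nrow(seqs))) == 0)
  else seq_len(ncol(seqs))
}

#' Collapse aligned sequence copies into haplotypes
#'
#' Under `complete_deletion` (default, mirroring common DnaSP behaviour)
#' all sites with a gap, `N` or ambiguity code in any copy are removed
#' first, then exact sequence identity defines a haplotype. Under
#' `pairwise_ignore_missing` a copy joins the first existing haplotype it is
#' compatible with (agreeing at all mutually non-missing sites).
#'
#' @param aln a [locus_alignment()].
#' @param site_policy `"complete_deletion"` or `"pairwise_ignore_missing"`.
#' @param population optional population label per sequence copy; when given,
#'   counts are a haplotype x population matrix.
#' @return class `haplotype_table`: `haplotypes` (distinct sequences on the
#'   retained sites), `index` (haplotype of each copy), `counts`.
#' @export
collapse_haplotypes <- function(aln, site_policy = c("complete_deletion",
                                                     "pairwise_ignore_missing"),
                                population = NULL) {
  site_policy <- match.arg(site_policy)
  if (!inherits(aln, "locus_alignment")) stop("need a locus_alignment")
  if (nrow(aln$seq) == 0) stop("empty alignment")
  keep <- retained_sites(aln$seq, site_policy)
  s <- aln$seq[, keep, drop = FALSE]
  n <- nrow(s)
  if (site_policy == "complete_deletion") {
    key <- apply(s, 1, paste, collapse = "")
    idx <- match(key, unique(key))
  } else {
    idx <- integer(n)
    reps <- list()                      # representative row of each haplotype
    for (i in seq_len(n)) {
      row <- s[i, ]
      hit <- 0L
      for (h in seq_along(reps)) {
        ok <- !(row %in% MISSING_CHARS) & !(reps[[h]] %in% MISSING_CHARS)
        if (all(row[ok] == reps[[h]][ok])) { hit <- h; break }
      }
      if (hit == 0L) { reps[[length(reps) + 1L]] <- row; hit <- length(reps) }
      else {
        ## refine the representative where it was missing
        fill <- reps[[hit]] %in% MISSING_CHARS & !(row %in% MISSING_CHARS)
        reps[[hit]][fill] <- row[fill]
      }
      idx[i] <- hit
    }
  }
  K <- max(idx)
  haps <- s[match(seq_len(K), idx), , drop = FALSE]
  rownames(haps) <- paste0("H", seq_len(K))
  counts <- if (is.null(population)) {
    tabulate(idx, K)
  } else {
    stopifnot(length(population) == n)
    tb <- table(factor(idx, levels = seq_len(K)), population)
    m <- matrix(as.integer(tb), nrow = K, dimnames = dimnames(tb))
    m
  }
  structure(list(haplotypes = haps, index = idx, counts = counts,
                 n = n, sites = keep, locus = aln$name),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table for '", x$locus, "': ", nrow(x$haplotypes),
      " haplotypes among ", x$n, " copies (", length(x$sites),
      " retained sites)\n", sep = "")
  invisible(x)
}

#' Pairwise genetic distances between sequence copies
#'
#' Distances are computed with `ape::dist.dna` under the requested
#' substitution model. A saturated pair (undefined log) propagates as `NaN`
#' and is never silently clipped.
#'
#' @param aln a [locus_alignment()].
#' @param model `"p"`, `"JC"`, `"K2P"` or `"TN93"`; default the alignment's
#'   model tag.
#' @param site_policy missing-site handling, as in [collapse_haplotypes()].
#' @return symmetric numeric matrix (per-site distances), zero diagonal.
#' @export
pairwise_distance <- function(aln, model = aln$model,
                              site_policy = c("pairwise_ignore_missing",
                                              "complete_deletion")) {
  site_policy <- match.arg(site_policy)
  model <- match.arg(model, c("p", "JC", "K2P", "TN93"))
  keep <- retained_sites(aln$seq, site_policy)
  if (!length(keep)) stop("no sites retained under ", site_policy)
  s <- aln$seq[, keep, drop = FALSE]
  ## partial ambiguity codes count as missing, not as their IUPAC set
  s[s %in% setdiff(MISSING_CHARS, "-")] <- "N"
  dna <- ape::as.DNAbin(tolower(s))
  apemodel <- c(p = "raw", JC = "JC69", K2P = "K80", TN93 = "TN93")[model]
  d <- as.matrix(ape::dist.dna(dna, model = apemodel,
                               pairwise.deletion =
                                 site_policy == "pairwise_ignore_missing"))
  rownames(d) <- colnames(d) <- rownames(aln$seq)
  d
}

#' Concatenate loci into one alignment
#'
#' Loci must share `copies_per_individual`; copies are paired by copy index.
#' Individuals missing any locus are dropped and reported in the
#' `"dropped"` attribute.
#'
#' @param loci list of [locus_alignment()] objects.
#' @param name label for the concatenated locus.
#' @param model substitution model tag for the result.
#' @return a [locus_alignment()] of length `sum(L_i)`.
#' @export
concatenate_loci <- function(loci, name = "concat", model = NULL) {
  if (!length(loci)) stop("empty locus subset")
  cp <- unique(vapply(loci, `[[`, 1L, "copies_per_individual"))
  if (length(cp) != 1L)
    stop("loci mix different copies_per_individual (",
         paste(cp, collapse = " vs "), "); supply a pairing rule by ",
         "reducing loci to a common ploidy first")
  modes <- unique(vapply(loci, `[[`, "", "mode"))
  if (length(modes) != 1L)
    stop("refusing to concatenate across inheritance modes: ",
         paste(modes, collapse = ", "))
  if (length(loci) == 1L) return(loci[[1]])
  common <- Reduce(intersect, lapply(loci, function(l) {
    full <- table(l$individual)
    names(full)[full == cp]
  }))
  all_ind <- unique(unlist(lapply(loci, function(l) unique(l$individual))))
  dropped <- setdiff(all_ind, common)
  if (!length(common)) stop("no individual has complete data at all loci")
  blocks <- lapply(loci, function(l) {
    ord <- order(match(l$individual, common), l$copy)
    ord <- ord[l$individual[ord] %in% common]
    l$seq[ord, , drop = FALSE]
  })
  seqs <- do.call(cbind, blocks)
  ind <- rep(common, each = cp)
  cpy <- rep(seq_len(cp), times = length(common))
  out <- locus_alignment(name = name, mode = modes, seqs = seqs,
                         individual = ind, copy = cpy,
                         copies_per_individual = cp,
                         model = model %||% loci[[1]]$model)
  attr(out, "dropped") <- dropped
  out
}

#' Subset a dataset to selected individuals
#' @param dataset a [pop_dataset()].
#' @param individuals ids to keep.
#' @return a [pop_dataset()].
#' @export
subset_individuals <- function(dataset, individuals) {
  loci <- lapply(dataset$loci, function(l) {
    keep <- l$individual %in% individuals
    if (!any(keep)) stop("no sequences left at locus '", l$name, "'")
    locus_alignment(l$name, l$mode, l$seq[keep, , drop = FALSE],
                    l$individual[keep], l$copy[keep],
                    l$copies_per_individual, l$model)
  })
  pop_dataset(loci, dataset$meta[dataset$meta$individual %in% individuals, ],
              dataset$geo)
}

#' Write a locus alignment to FASTA (deterministic bytes)
#' @param aln a [locus_alignment()].
#' @param path output file.
#' @export
write_locus_fasta <- function(aln, path) {
  con <- file(path, "wb")                # "wb": identical bytes on re-run
  on.exit(close(con))
  txt <- paste0(">", rownames(aln$seq), "\n",
                apply(aln$seq, 1, paste, collapse = ""))
  writeLines(txt, con)
  invisible(path)
}
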