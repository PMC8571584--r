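#' Derive a child seed from a master seed and a stage tag
#'
#' All stochastic stages of the pipeline draw their seed from one master
#' integer through this deterministic rule, so that a single `seed` entry in
#' a run configuration fixes every permutation, bootstrap and simulation.
#'
#' @param master integer master seed.
#' @param tag character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
spawn_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 1013904223
  as.integer((abs(master) %% 65011712 + h * 31) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## permutation p-value with +1 smoothing; ties counted as >= observed
perm_pvalue <- function(perm_stats, observed) {
  perm_stats <- perm_stats[!is.na(perm_stats)]
  if (!length(perm_stats) || is.na(observed)) return(NA_real_)
  (sum(perm_stats >= observed - 1e-12) + 1) / (length(perm_stats) + 1)
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## significance stars per the conventional table footnote
sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", "")))
}

## write a numeric matrix as a labelled square TSV (deterministic bytes)
write_square_tsv <- function(m, path, digits = 6) {
  stopifnot(is.matrix(m))
  df <- as.data.frame(formatC(m, digits = digits, format = "g"))
  df <- cbind(label = rownames(m), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
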