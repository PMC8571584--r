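#' Published per-marker summary table for the little-shearwater panel
#'
#' The per-marker polymorphism summary of the nine-marker Sanger panel
#' (three mitochondrial, six nuclear loci): sequences obtained (`N`),
#' alignment length (`L`), segregating sites (`S`), haplotype or allele
#' count (`h_or_a`), haplotype diversity (`hd`, mitochondrial only) and
#' nucleotide diversity (`pi`). Bundled as a plain-text input for
#' cross-checking class-level totals and as a reference for what the
#' synthetic generator emulates.
#'
#' @return data.frame, one row per marker.
#' @export
marker_summary <- function() {
  read.delim(system.file("extdata", "marker_summary.tsv",
                         package = "seqpopgen"),
             stringsAsFactors = FALSE)
}

#' Class-level totals of a per-marker summary table
#'
#' Sums segregating sites per marker class, haplotype/allele counts and
#' concatenated lengths from the per-marker rows.
#'
#' @param df a per-marker table as returned by [marker_summary()].
#' @return list with `S_mt`, `S_nu`, `alleles_nu`, `haplo_mt`, `L_mt`,
#'   `L_nu`.
#' @export
marker_class_totals <- function(df = marker_summary()) {
  mt <- df$class == "mitochondrial"
  list(S_mt = sum(df$S[mt]), S_nu = sum(df$S[!mt]),
       alleles_nu = sum(df$h_or_a[!mt]), haplo_mt = sum(df$h_or_a[mt]),
       L_mt = sum(df$L[mt]), L_nu = sum(df$L[!mt]))
}
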