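#' Bundled reference tables
#'
#' Small plain-text tables shipped with the package.
#'
#' \code{roccapelago_qc()} returns the qPCR quantification and Yfiler Plus
#' typing-success summary for the 25 ancient males sampled from the
#' Roccapelago crypt strata (SU23/SU26/SU28): per-sample large/small
#' autosomal and Y-target concentrations (ng/ul, \code{NA} = not
#' detected), the reported degradation index, and the number of
#' successfully typed series out of 27 (0 = amplification negative).  This
#' is the input for the missing-locus filtering example: at
#' \code{max_missing = 3}, exactly 13 of the 25 ancient samples survive.
#'
#' \code{roccapelago_gene_diversity()} returns the per-locus gene
#' diversities of the same survey for the combined (\code{rp_t}), modern
#' (\code{rp_m}) and ancient (\code{rp_a}) datasets, used for the
#' core-17 / additional-10 / RM-7 group-mean comparisons.
#'
#' @return A data frame.
#' @name bundled_tables
NULL

#' @rdname bundled_tables
#' @export
roccapelago_qc <- function() {
  utils::read.csv(system.file("extdata", "roccapelago_qc.csv",
                              package = "ylineage"),
                  stringsAsFactors = FALSE)
}

#' @rdname bundled_tables
#' @export
roccapelago_gene_diversity <- function() {
  df <- utils::read.csv(system.file("extdata",
                                    "roccapelago_gene_diversity.csv",
                                    package = "ylineage"),
                        stringsAsFactors = FALSE)
  df
}
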