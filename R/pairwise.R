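#' Per-pair locus difference vector
#'
#' Compares two haplotypes series-by-series on the intersection of their
#' typed series (duplication-flagged loci excluded), producing the two
#' encodings consumed by TMRCA estimation: the infinite-allele (IAM)
#' vector of 0 (match) / 1 (mismatch) indicators, and the stepwise (SMM)
#' vector of signed repeat differences (allele of \code{id_b} minus allele
#' of \code{id_a}).
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param id_a,id_b Sample identifiers of the pair.
#' @return An object of class \code{pair_difference}: list with
#'   \code{id_a}, \code{id_b}, \code{loci} (compared series),
#'   \code{iam_vector}, \code{smm_vector} and \code{n_compared}.
#' @export
difference_vector <- function(haps, id_a, id_b) {
  m <- .calls_matrix(haps)
  for (id in c(id_a, id_b))
    if (!id %in% rownames(m)) stop("unknown sample_id: ", id)
  dups <- duplication_flags(haps)
  if (nrow(dups))
    for (k in seq_len(nrow(dups)))
      if (dups$sample_id[k] %in% c(id_a, id_b))
        m[dups$sample_id[k], dups$series[k]] <- NA_real_
  a <- m[id_a, ]; b <- m[id_b, ]
  both <- !is.na(a) & !is.na(b)
  if (!any(both))
    stop("no series typed in both ", id_a, " and ", id_b)
  loci <- colnames(m)[both]
  smm <- as.numeric(b[both] - a[both])
  structure(list(id_a = id_a, id_b = id_b, loci = loci,
                 iam_vector = as.integer(smm != 0), smm_vector = smm,
                 n_compared = length(loci)),
            class = "pair_difference")
}

#' @export
print.pair_difference <- function(x, ...) {
  cat(sprintf("%s vs %s: %d series compared, %d mismatch(es)\n",
              x$id_a, x$id_b, x$n_compared, sum(x$iam_vector)))
  mm <- x$iam_vector == 1L
  if (any(mm))
    cat("  ", paste(sprintf("%s (%+g)", x$loci[mm], x$smm_vector[mm]),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype sharing report
#'
#' Lists every pair of individuals whose profiles mismatch at no more than
#' \code{max_mismatch} of the series typed in both — the exact and
#' near-match pairs that signal shared or recently diverged paternal
#' lineages.
#'
#' @param haps A \code{ystr_haplotypes} table (at least two individuals).
#' @param max_mismatch Maximum mismatch count reported (default 2).
#' @return Data frame with one row per qualifying pair: \code{id_a},
#'   \code{id_b}, \code{n_compared}, \code{n_mismatch},
#'   \code{mismatch_series} and \code{steps} (signed repeat differences).
#' @export
sharing_report <- function(haps, max_mismatch = 2) {
  if (nrow(haps) < 2) stop("need at least two haplotypes")
  ids <- haps$sample_id
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq((i + 1L), length(ids))) {
      d <- difference_vector(haps, ids[i], ids[j])
      k <- sum(d$iam_vector)
      if (k <= max_mismatch) {
        mm <- d$iam_vector == 1L
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], n_compared = d$n_compared,
          n_mismatch = k,
          mismatch_series = paste(d$loci[mm], collapse = ";"),
          steps = paste(sprintf("%+g", d$smm_vector[mm]), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      n_compared = integer(), n_mismatch = integer(),
                      mismatch_series = character(), steps = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
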