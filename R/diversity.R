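#' Per-locus allele counts
#'
#' Tabulates observed alleles at one allelic series, excluding missing
#' calls (pairwise deletion: the locus sample size is the number of
#' individuals typed there).
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param locus Series name.
#' @return An object of class \code{allele_counts}: list with \code{locus},
#'   \code{counts} (named integer vector, allele -> count) and \code{n}.
#' @export
allele_counts <- function(haps, locus) {
  m <- .calls_matrix(haps)
  if (!locus %in% colnames(m)) stop("unknown series: ", locus)
  x <- m[, locus]
  x <- x[!is.na(x)]
  tab <- table(x)
  structure(list(locus = locus,
                 counts = stats::setNames(as.integer(tab), names(tab)),
                 n = length(x)),
            class = "allele_counts")
}

#' Gene diversity of a locus
#'
#' The unbiased gene diversity \eqn{GD = n(1 - \sum x_i^2)/(n-1)} with
#' \eqn{x_i} the sample frequency of the \eqn{i}th allele and \eqn{n} the
#' number of individuals typed at the locus: the probability that two
#' randomly drawn haplotypes carry different alleles, with the small-sample
#' correction \eqn{n/(n-1)}.
#'
#' @param counts An \code{allele_counts} object, or a bare named/unnamed
#'   integer vector of allele counts.
#' @return Gene diversity in [0, 1]; \code{NA} with a warning when fewer
#'   than two individuals are typed.
#' @examples
#' gene_diversity(c(`14` = 3, `15` = 1))  # 0.5
#' @export
gene_diversity <- function(counts) {
  if (inherits(counts, "allele_counts")) counts <- counts$counts
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < 2) {
    warning("gene diversity undefined for n < 2", call. = FALSE)
    return(NA_real_)
  }
  x <- counts / n
  n * (1 - sum(x^2)) / (n - 1)
}

#' Per-locus gene diversity table
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @return Named numeric vector of gene diversities over the panel series.
#' @export
gene_diversity_table <- function(haps) {
  ser <- panel_series(active_panel(haps))
  stats::setNames(
    vapply(ser, function(s) gene_diversity(allele_counts(haps, s)),
           numeric(1)),
    ser)
}

#' Compatibility clustering of (possibly partial) haplotypes
#'
#' Two profiles are compatible when they carry equal alleles at every
#' series typed in both.  Complete profiles cluster by exact identity;
#' partial profiles are merged greedily in order of decreasing typed-series
#' count: each joins the existing cluster with which it is compatible and
#' shares the largest number of typed-and-equal series (ties go to the
#' earliest-created cluster; an ambiguity between mutually incompatible
#' candidate clusters is resolved to the best match and reported in the
#' \code{ambiguities} field).  This is the rule under which a 25-locus
#' ancient profile identical to a complete modern profile on all shared
#' loci counts as the same haplotype.
#'
#' @param haps A \code{ystr_haplotypes} table (normally already passed
#'   through \code{\link{filter_by_missing}}).
#' @return An object of class \code{haplotype_spectrum}: list with
#'   \code{occurrence_counts} (named integer vector: cluster size ->
#'   number of clusters of that size), \code{n}, \code{n_distinct},
#'   \code{clusters} (list of member sample_id vectors) and
#'   \code{ambiguities}.
#' @export
cluster_haplotypes <- function(haps) {
  m <- .calls_matrix(haps)
  # duplication-flagged single-copy loci are excluded from comparison
  dups <- duplication_flags(haps)
  if (nrow(dups))
    for (k in seq_len(nrow(dups)))
      m[dups$sample_id[k], dups$series[k]] <- NA_real_
  ord <- order(-rowSums(!is.na(m)), seq_len(nrow(m)))
  consensus <- list()   # union profile per cluster
  members <- list()
  ambiguities <- character(0)
  for (i in ord) {
    prof <- m[i, ]
    best <- 0L; best_score <- -1L
    compat_idx <- integer(0)
    for (ci in seq_along(consensus)) {
      cons <- consensus[[ci]]
      both <- !is.na(prof) & !is.na(cons)
      if (any(prof[both] != cons[both])) next
      compat_idx <- c(compat_idx, ci)
      score <- sum(both)
      if (score > best_score) { best_score <- score; best <- ci }
    }
    if (best == 0L) {
      consensus[[length(consensus) + 1L]] <- prof
      members[[length(members) + 1L]] <- rownames(m)[i]
    } else {
      if (length(compat_idx) > 1L)
        ambiguities <- c(ambiguities, sprintf(
          "%s compatible with %d clusters; joined best match",
          rownames(m)[i], length(compat_idx)))
      cons <- consensus[[best]]
      fill <- is.na(cons) & !is.na(prof)
      cons[fill] <- prof[fill]
      consensus[[best]] <- cons
      members[[best]] <- c(members[[best]], rownames(m)[i])
    }
  }
  sizes <- lengths(members)
  haplotype_spectrum(sizes, clusters = members, ambiguities = ambiguities)
}

#' Haplotype occurrence spectrum
#'
#' @param sizes Integer vector of cluster sizes (one entry per distinct
#'   haplotype), or a named vector of occurrence counts (name = cluster
#'   size \code{k}, value = number of clusters observed \code{k} times) when
#'   \code{by_count = TRUE}.
#' @param by_count Interpret \code{sizes} as an occurrence-count map.
#' @param clusters,ambiguities Optional member lists carried through from
#'   \code{\link{cluster_haplotypes}}.
#' @return A \code{haplotype_spectrum} object.
#' @examples
#' # 20 haplotypes seen once, 2 twice, 1 three times (n = 27)
#' haplotype_spectrum(c(`1` = 20, `2` = 2, `3` = 1), by_count = TRUE)
#' @export
haplotype_spectrum <- function(sizes, by_count = FALSE, clusters = NULL,
                               ambiguities = character(0)) {
  if (by_count) {
    k <- as.integer(names(sizes))
    sizes <- rep(k, times = as.integer(sizes))
  }
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1))
  tab <- table(sizes)
  structure(list(
    occurrence_counts = stats::setNames(as.integer(tab), names(tab)),
    sizes = sort(sizes, decreasing = TRUE),
    n = sum(sizes), n_distinct = length(sizes),
    clusters = clusters, ambiguities = ambiguities),
    class = "haplotype_spectrum")
}

#' Haplotype diversity, match probability and discrimination capacity
#'
#' From an occurrence spectrum with cluster frequencies \eqn{p_i}:
#' \eqn{HMP = \sum p_i^2} (probability two random individuals share a
#' haplotype), \eqn{HD = n(1 - HMP)/(n-1)} (unbiased haplotype diversity)
#' and \eqn{DC = } distinct haplotypes / \eqn{n}.
#'
#' @param spectrum A \code{haplotype_spectrum}, or a \code{ystr_haplotypes}
#'   table (clustered first).
#' @return An object of class \code{ystr_diversity}: list with \code{hd},
#'   \code{hmp}, \code{dc}, \code{n}, \code{n_distinct} and the spectrum.
#' @examples
#' s <- haplotype_spectrum(c(`1` = 20, `2` = 2, `3` = 1), by_count = TRUE)
#' haplotype_diversity(s)   # HD 0.9858, HMP 0.0508, DC 0.8519
#' @export
haplotype_diversity <- function(spectrum) {
  if (inherits(spectrum, "ystr_haplotypes"))
    spectrum <- cluster_haplotypes(spectrum)
  stopifnot(inherits(spectrum, "haplotype_spectrum"))
  n <- spectrum$n
  if (n < 2) {
    warning("haplotype diversity undefined for n < 2", call. = FALSE)
    return(structure(list(hd = NA_real_, hmp = NA_real_, dc = NA_real_,
                          n = n, n_distinct = spectrum$n_distinct,
                          spectrum = spectrum),
                     class = "ystr_diversity"))
  }
  p <- spectrum$sizes / n
  hmp <- sum(p^2)
  structure(list(hd = n * (1 - hmp) / (n - 1), hmp = hmp,
                 dc = spectrum$n_distinct / n, n = n,
                 n_distinct = spectrum$n_distinct, spectrum = spectrum),
            class = "ystr_diversity")
}

#' Project a haplotype table onto a sub-panel
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param panel_sub A \code{ystr_panel} whose series are a subset of the
#'   active panel.
#' @return The projected \code{ystr_haplotypes} table.
#' @export
project_panel <- function(haps, panel_sub) {
  panel <- active_panel(haps)
  if (!panel_subset(panel_sub, panel))
    stop("panel ", panel_sub$name, " is not a subset of ", panel$name)
  keep <- c("sample_id", "population", "stratum", panel_series(panel_sub))
  df <- as.data.frame(haps)[, keep]
  dups <- duplication_flags(haps)
  ystr_haplotypes(df, panel_sub,
                  duplications = dups[dups$series %in% panel_series(panel_sub),
                                      , drop = FALSE])
}

#' Compare discrimination between a full panel and a sub-panel
#'
#' Recomputes the haplotype spectrum and HD/HMP/DC after projecting every
#' individual onto the sub-panel, and groups per-locus gene diversities
#' into core-17 / additional-10 / RM-7 with group means — the comparison
#' that quantifies how much discrimination the extra (and especially RM)
#' loci buy.
#'
#' @param haps A \code{ystr_haplotypes} table on the full panel.
#' @param panel_full,panel_sub \code{ystr_panel} objects,
#'   \code{panel_sub} contained in \code{panel_full}.
#' @return List of class \code{panel_comparison} with \code{full} and
#'   \code{subset} \code{ystr_diversity} results, \code{gd} (per-locus GD
#'   on the full panel) and \code{gd_group_means}.
#' @export
panel_comparison <- function(haps, panel_full = active_panel(haps),
                             panel_sub = ystr_panel("YFILER17",
                                                    dys389b = panel_full$dys389b)) {
  if (!panel_subset(panel_sub, panel_full))
    stop("panel ", panel_sub$name, " is not a subset of ", panel_full$name)
  full_div <- haplotype_diversity(cluster_haplotypes(haps))
  sub_div <- haplotype_diversity(cluster_haplotypes(project_panel(haps,
                                                                  panel_sub)))
  gd <- gene_diversity_table(haps)
  structure(list(full = full_div, subset = sub_div, gd = gd,
                 gd_group_means = gd_group_means(gd, panel_full)),
            class = "panel_comparison")
}

#' Group means of per-locus gene diversity
#'
#' Averages per-locus GD values over the core-17, additional-10 and RM-7
#' series groups of the Yfiler Plus panel.
#'
#' @param gd Named numeric vector of per-locus gene diversities.
#' @param panel The \code{ystr_panel} defining the groups (Yfiler Plus).
#' @return Named numeric vector with \code{core17}, \code{additional10} and
#'   \code{rm7} means.
#' @export
gd_group_means <- function(gd, panel = ystr_panel()) {
  g <- panel_groups(panel)
  vapply(g, function(s) mean(gd[s]), numeric(1))
}

#' @export
print.haplotype_spectrum <- function(x, ...) {
  cat(sprintf("haplotype spectrum: n = %d, %d distinct haplotypes\n",
              x$n, x$n_distinct))
  oc <- x$occurrence_counts
  cat(paste(sprintf("  observed %s time(s): %d clusters", names(oc), oc),
            collapse = "\n"), "\n")
  if (length(x$ambiguities))
    cat("  ambiguous partial-profile assignments:\n",
        paste("   ", x$ambiguities, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.ystr_diversity <- function(x, ...) {
  cat(sprintf("HD  = %.4f\nHMP = %.4f\nDC  = %.4f\n(n = %d, %d distinct haplotypes)\n",
              x$hd, x$hmp, x$dc, x$n, x$n_distinct))
  invisible(x)
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat("Full panel:\n"); print(x$full)
  cat("Sub-panel:\n"); print(x$subset)
  cat("Per-locus GD group means:\n")
  print(round(x$gd_group_means, 6))
  invisible(x)
}
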