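# Two-level AMOVA from a matrix of (squared) pairwise distances.
# Partitions the total sum of squared deviations into among- and
# within-population components (Excoffier-style):
#   SSD(T) = sum_ij d2_ij / (2N),  SSD(W) = sum_p sum_{ij in p} d2_ij / (2 n_p)
#   sigma_w = SSD(W)/(N-P),  sigma_a = (SSD(A)/(P-1) - sigma_w)/n',
#   n' = (N - sum n_p^2/N)/(P-1),  Phi = sigma_a/(sigma_a + sigma_w).
# Negative components are reported as computed.
.amova_phi <- function(d2, pops) {
  n <- length(pops)
  ssd_t <- sum(d2) / (2 * n)
  lev <- unique(pops)
  ssd_w <- 0
  for (p in lev) {
    idx <- pops == p
    ssd_w <- ssd_w + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  ssd_a <- ssd_t - ssd_w
  P <- length(lev)
  sigma_w <- ssd_w / (n - P)
  n_prime <- (n - sum(tabulate(factor(pops))^2) / n) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_w) / n_prime
  tot <- sigma_a + sigma_w
  list(phi = if (tot == 0) 0 else sigma_a / tot,
       sigma_among = sigma_a, sigma_within = sigma_w)
}

.amova_permute <- function(d2, pops, n_permutations, seed) {
  obs <- .amova_phi(d2, pops)
  if (!is.null(seed)) set.seed(seed)
  b <- 0L
  for (k in seq_len(n_permutations)) {
    perm <- sample(pops)
    if (.amova_phi(d2, perm)$phi >= obs$phi - 1e-12) b <- b + 1L
  }
  list(obs = obs, p = (b + 1) / (n_permutations + 1))
}

#' Frequency-based FST between two populations
#'
#' Two-level AMOVA on categorical lineage labels (e.g. predicted Y
#' haplogroups, or haplotype-cluster identities) with the trivial distance
#' \eqn{\delta(i,j) = 0} for equal labels and 1 otherwise.  The permutation
#' p-value shuffles individuals between populations and is computed with
#' the observed statistic included, \eqn{p = (b+1)/(m+1)}.
#'
#' @param group_a,group_b Character/factor vectors of labels, one entry
#'   per individual, each group of size at least 2.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return An object of class \code{amova_result} with \code{estimate}
#'   (FST), \code{p_value}, variance components, \code{n_permutations} and
#'   \code{seed}.
#' @export
amova_fst <- function(group_a, group_b, n_permutations = 10000,
                      seed = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each population needs at least 2 individuals")
  labels <- c(as.character(group_a), as.character(group_b))
  pops <- rep(c("A", "B"), c(length(group_a), length(group_b)))
  d2 <- outer(labels, labels, "!=") * 1  # 0/1 distance (== its square)
  res <- .amova_permute(d2, pops, n_permutations, seed)
  structure(list(statistic = "FST", estimate = res$obs$phi,
                 p_value = res$p, sigma_among = res$obs$sigma_among,
                 sigma_within = res$obs$sigma_within,
                 n_permutations = n_permutations, seed = seed),
            class = "amova_result")
}

# squared repeat-distance matrix between haplotype rows; pairwise deletion
# over shared typed series, optionally rescaled by panel/shared size so
# pairs with unequal missingness stay comparable
.rst_distance <- function(m, p_size, rescale = TRUE) {
  n <- nrow(m)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      both <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(both))
        stop("no shared typed series between ", rownames(m)[i], " and ",
             rownames(m)[j])
      d <- sum((m[i, both] - m[j, both])^2)
      if (rescale) d <- d * p_size / sum(both)
      d2[i, j] <- d2[j, i] <- d
    }
  }
  d2
}

#' Repeat-distance RST between two populations
#'
#' Two-level AMOVA with the microsatellite distance
#' \eqn{\delta^2(i,j) = \sum_l (a_{il} - a_{jl})^2} summed over the series
#' typed in both individuals (missing loci pairwise-deleted, distances
#' rescaled by panel size / shared size by default).  Permutation scheme
#' as in \code{\link{amova_fst}}.
#'
#' @param haps_a,haps_b \code{ystr_haplotypes} tables for the two
#'   populations (same panel), each with at least 2 individuals.
#' @param rescale_missing Rescale pairwise distances for unequal
#'   missingness (default \code{TRUE}).
#' @inheritParams amova_fst
#' @return An \code{amova_result} with \code{estimate} (RST).
#' @export
amova_rst <- function(haps_a, haps_b, n_permutations = 10000, seed = NULL,
                      rescale_missing = TRUE) {
  if (nrow(haps_a) < 2 || nrow(haps_b) < 2)
    stop("each population needs at least 2 individuals")
  pa <- active_panel(haps_a)
  stopifnot(identical(panel_series(pa), panel_series(active_panel(haps_b))))
  m <- rbind(.calls_matrix(haps_a), .calls_matrix(haps_b))
  pops <- rep(c("A", "B"), c(nrow(haps_a), nrow(haps_b)))
  d2 <- .rst_distance(m, panel_size(pa), rescale = rescale_missing)
  res <- .amova_permute(d2, pops, n_permutations, seed)
  structure(list(statistic = "RST", estimate = res$obs$phi,
                 p_value = res$p, sigma_among = res$obs$sigma_among,
                 sigma_within = res$obs$sigma_within,
                 n_permutations = n_permutations, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("%s = %.5f, permutation p = %.5f (%d permutations)\n",
              x$statistic, x$estimate, x$p_value, x$n_permutations))
  cat(sprintf("  variance components: among %.5g, within %.5g\n",
              x$sigma_among, x$sigma_within))
  invisible(x)
}
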