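#' Configuration for the pairwise TMRCA estimator
#'
#' @param model Mutation model: \code{"IAM"} (infinite alleles; any
#'   mutation produces a mismatch) or \code{"SMM"} (stepwise; mutations
#'   move the repeat count by one and can re-converge).
#' @param lambda Prior mean of the generations back to the most recent
#'   common paternal ancestor of a random pair (geometric prior
#'   hyper-parameter; default 1000).
#' @param grid_max Largest generation count evaluated; default
#'   \code{max(10 * lambda, 5000)}, covering essentially all prior mass.
#' @param ci_levels Central credible-interval levels (default 0.50 and
#'   0.95).
#' @return A \code{walsh_config} list.
#' @export
walsh_config <- function(model = c("IAM", "SMM"), lambda = 1000,
                         grid_max = NULL, ci_levels = c(0.50, 0.95)) {
  model <- match.arg(model)
  stopifnot(lambda > 0, all(ci_levels > 0 & ci_levels < 1))
  if (is.null(grid_max)) grid_max <- max(10 * lambda, 5000)
  grid_max <- as.integer(grid_max)
  structure(list(model = model, lambda = lambda, grid_max = grid_max,
                 ci_levels = sort(unique(ci_levels))),
            class = "walsh_config")
}

#' Infinite-allele pair likelihood
#'
#' Probability of the observed match/mismatch vector given that the two
#' haplotypes coalesce \code{t} generations ago, i.e. are separated by
#' \code{2t} meioses (\code{t} per branch).  Under the infinite allele
#' model a series matches only if no mutation occurred in any of the
#' \code{2t} meioses:
#' \deqn{L(t) = \prod_{match} (1-\mu_i)^{2t} \prod_{mismatch}
#'   \left(1-(1-\mu_i)^{2t}\right).}
#'
#' @param diff A \code{pair_difference}.
#' @param rates A \code{mutation_rates} table covering all compared series.
#' @param t Generations to the common ancestor (vectorised, non-negative
#'   integers).
#' @return Likelihood value(s), same length as \code{t}.
#' @export
iam_likelihood <- function(diff, rates, t) {
  mu <- .rates_for(rates, diff$loci)
  mm <- diff$iam_vector == 1L
  log_match <- sum(log1p(-mu[!mm]))        # per-meiosis log survival
  vapply(t, function(tt) {
    if (tt == 0) return(if (any(mm)) 0 else 1)
    ll <- 2 * tt * log_match +
      sum(log1p(-(1 - mu[mm])^(2 * tt)))
    exp(ll)
  }, numeric(1))
}

# P(net repeat displacement == d) after n_meioses meioses at rate mu under
# the symmetric single-step model: each meiosis leaves the repeat count
# unchanged w.p. 1-mu or moves it +/-1 w.p. mu/2 each.  Sums the binomial
# mixture over mutation counts m, truncated where the binomial tail
# is < 1e-12; only m >= |d| with m = d (mod 2) contribute (walk parity).
.smm_step_prob <- function(d, mu, n_meioses) {
  d <- abs(d)
  if (n_meioses == 0) return(as.numeric(d == 0))
  m_lo <- stats::qbinom(1e-12, n_meioses, mu)
  m_hi <- stats::qbinom(1e-12, n_meioses, mu, lower.tail = FALSE)
  m <- max(m_lo, d):max(m_hi, d)
  m <- m[(m - d) %% 2 == 0]
  if (!length(m)) return(0)
  terms <- stats::dbinom(m, n_meioses, mu) *
    exp(lchoose(m, (m + d) / 2) - m * log(2))
  sum(terms)
}

#' Stepwise pair likelihood
#'
#' Probability of the observed signed repeat differences given coalescence
#' \code{t} generations ago (\code{2t} meioses).  Per series, the number of
#' mutations is Binomial(\code{2t}, \eqn{\mu_i}) and each mutation steps
#' the repeat count by \eqn{\pm 1} with equal probability, so the net
#' displacement is a binomially-stopped symmetric random walk; the
#' likelihood is the product over series of the displacement probabilities.
#' Non-integer observed differences are rounded to the nearest step with a
#' warning (the model lives on a one-repeat lattice).
#'
#' @inheritParams iam_likelihood
#' @return Likelihood value(s), same length as \code{t}.
#' @export
smm_likelihood <- function(diff, rates, t) {
  mu <- .rates_for(rates, diff$loci)
  d <- diff$smm_vector
  if (any(abs(d - round(d)) > 1e-9)) {
    warning("non-integer repeat differences rounded to the nearest step",
            call. = FALSE)
  }
  d <- round(d)
  vapply(t, function(tt) {
    prod(vapply(seq_along(d),
                function(i) .smm_step_prob(d[i], mu[i], 2 * tt),
                numeric(1)))
  }, numeric(1))
}

#' Bayesian pairwise TMRCA posterior
#'
#' Fits the posterior distribution of the time \code{t} (generations) to
#' the most recent common paternal ancestor of a pair of Y-STR haplotypes:
#' posterior(t) is proportional to prior(t) times the IAM or SMM
#' likelihood of the observed locus difference vector, evaluated on the
#' integer grid 0..\code{grid_max} and normalised.  The prior is geometric
#' with mean \code{lambda}, \eqn{P(t) = (\lambda/(\lambda+1))^t/(\lambda+1)},
#' the discrete analogue of the exponential pairwise coalescence-time
#' prior.  Summaries are the posterior mean, median, mode (smallest
#' \code{t} among ties) and central (equal-tailed) credible intervals with
#' bounds snapped outward to grid points.
#'
#' @param diff A \code{pair_difference}.
#' @param rates A \code{mutation_rates} table.
#' @param config A \code{\link{walsh_config}}.
#' @return An object of class \code{tmrca_posterior}: list with
#'   \code{support}, \code{mass}, \code{mean}, \code{median}, \code{mode},
#'   \code{ci} (list, level -> c(low, high)), \code{unit}, model settings
#'   and pair metadata.
#' @examples
#' h <- data.frame(sample_id = c("a", "b"), DYS19 = c(14, 14),
#'                 DYS393 = c(13, 14))
#' haps <- ystr_haplotypes(h, ystr_panel())
#' d <- difference_vector(haps, "a", "b")
#' fit <- tmrca_walsh(d, default_mutation_rates(), walsh_config(lambda = 50))
#' fit$mode
#' @export
tmrca_walsh <- function(diff, rates, config = walsh_config()) {
  stopifnot(inherits(config, "walsh_config"))
  support <- 0:config$grid_max
  lik <- switch(config$model,
                IAM = iam_likelihood(diff, rates, support),
                SMM = smm_likelihood(diff, rates, support))
  lam <- config$lambda
  log_prior <- support * log(lam / (lam + 1)) - log(lam + 1)
  log_post <- log(lik) + log_prior
  if (all(!is.finite(log_post)))
    stop("likelihood is zero over the whole grid; increase grid_max")
  log_post <- log_post - max(log_post, na.rm = TRUE)
  mass <- exp(log_post)
  mass <- mass / sum(mass)
  tail_mass <- sum(mass[support > config$grid_max - 5])
  if (tail_mass > 1e-4)
    warning(sprintf(
      "posterior mass %.2g within 5 grid points of grid_max; increase grid_max",
      tail_mass), call. = FALSE)
  .tmrca_posterior(support, mass, unit = "generations to MRCA",
                   config = config, diff = diff)
}

# assemble a tmrca_posterior from support/mass (support need not be 0..K)
.tmrca_posterior <- function(support, mass, unit, config = NULL,
                             diff = NULL, meta = NULL) {
  cdf <- cumsum(mass)
  ci <- list()
  levels <- if (is.null(config)) meta$ci_levels else config$ci_levels
  for (lev in levels) {
    a <- (1 - lev) / 2
    lo <- support[which(cdf > a)[1]]
    hi <- support[which(cdf >= 1 - a)[1]]
    ci[[sprintf("%g%%", 100 * lev)]] <- c(lo, hi)
  }
  md <- support[which(cdf >= 0.5)[1]]
  structure(list(
    support = support, mass = mass,
    mean = sum(support * mass), median = md,
    mode = support[which.max(mass)], ci = ci, unit = unit,
    model = if (is.null(config)) meta$model else config$model,
    lambda = if (is.null(config)) meta$lambda else config$lambda,
    ci_levels = levels,
    id_a = if (is.null(diff)) meta$id_a else diff$id_a,
    id_b = if (is.null(diff)) meta$id_b else diff$id_b,
    n_compared = if (is.null(diff)) meta$n_compared else diff$n_compared,
    n_mismatch = if (is.null(diff)) meta$n_mismatch else sum(diff$iam_vector)),
    class = "tmrca_posterior")
}

# carry a posterior through a linear rescaling of its support
.rescale_posterior <- function(post, factor, unit) {
  meta <- list(ci_levels = post$ci_levels, model = post$model,
               lambda = post$lambda, id_a = post$id_a, id_b = post$id_b,
               n_compared = post$n_compared, n_mismatch = post$n_mismatch)
  out <- .tmrca_posterior(post$support * factor, post$mass, unit, meta = meta)
  # exact linear transforms (recomputation from the CDF is identical, but
  # keep summaries exactly factor * original to the last bit)
  out$mean <- post$mean * factor
  out$median <- post$median * factor
  out$mode <- post$mode * factor
  out$ci <- lapply(post$ci, function(x) x * factor)
  out
}

#' Total generations separating a pair
#'
#' The TMRCA posterior counts generations back to the common ancestor
#' along one branch; an ancient and a modern male are separated by the sum
#' of both branches, i.e. twice the TMRCA.  This rescales the posterior
#' support (and all summaries) by 2.
#'
#' @param post A \code{tmrca_posterior} in generations to MRCA.
#' @return A \code{tmrca_posterior} over total separating generations.
#' @export
generations_separating <- function(post) {
  stopifnot(inherits(post, "tmrca_posterior"))
  .rescale_posterior(post, 2, "total generations separating")
}

#' Convert a generations posterior to years
#'
#' @param post A \code{tmrca_posterior} over generations.
#' @param generation_time Years per generation (default 33, a
#'   genealogy-based estimate for the study region).
#' @return A \code{tmrca_posterior} over years.
#' @export
to_years <- function(post, generation_time = 33) {
  stopifnot(inherits(post, "tmrca_posterior"), generation_time > 0)
  .rescale_posterior(post, generation_time, "years")
}

#' TMRCA posteriors for all cross-population pairs
#'
#' Convenience driver: computes, for every pair of one individual from
#' \code{from_pop} and one from \code{to_pop}, the TMRCA posterior, doubles
#' it to total separating generations and converts to years.
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param rates A \code{mutation_rates} table.
#' @param config A \code{\link{walsh_config}}.
#' @param from_pop,to_pop Population labels (e.g. ancient and modern).
#' @param generation_time Years per generation.
#' @return List of class \code{tmrca_pairs}: per-pair list entries with
#'   \code{id_a}, \code{id_b}, \code{generations} / \code{total} /
#'   \code{years} posteriors; plus a \code{summary} data frame.
#' @export
tmrca_pairs <- function(haps, rates, config = walsh_config(),
                        from_pop, to_pop, generation_time = 33) {
  a_ids <- haps$sample_id[haps$population == from_pop]
  b_ids <- haps$sample_id[haps$population == to_pop]
  pairs <- list()
  rows <- list()
  for (ia in a_ids) {
    for (ib in b_ids) {
      d <- difference_vector(haps, ia, ib)
      g <- tmrca_walsh(d, rates, config)
      tot <- generations_separating(g)
      yrs <- to_years(tot, generation_time)
      pairs[[paste(ia, ib, sep = "|")]] <-
        list(id_a = ia, id_b = ib, generations = g, total = tot, years = yrs)
      ci_cols <- unlist(lapply(names(yrs$ci), function(nm)
        stats::setNames(yrs$ci[[nm]],
                        paste0("years_ci", sub("%", "", nm), c("_low", "_high")))))
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ia, id_b = ib, n_compared = d$n_compared,
        n_mismatch = sum(d$iam_vector),
        mode_generations = g$mode, mean_generations = g$mean,
        median_generations = g$median,
        mode_total = tot$mode, mode_years = yrs$mode,
        t(ci_cols), stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = pairs,
                 summary = if (length(rows)) do.call(rbind, rows) else NULL),
            class = "tmrca_pairs")
}

#' @export
print.tmrca_posterior <- function(x, ...) {
  cat(sprintf("TMRCA posterior (%s, %s)", x$model, x$unit))
  if (!is.null(x$id_a)) cat(sprintf(" for %s vs %s", x$id_a, x$id_b))
  cat("\n")
  cat(sprintf("  mean %.1f, median %g, mode %g\n", x$mean, x$median, x$mode))
  for (nm in names(x$ci))
    cat(sprintf("  %s CI: [%g, %g]\n", nm, x$ci[[nm]][1], x$ci[[nm]][2]))
  invisible(x)
}

#' @export
summary.tmrca_posterior <- function(object, ...) {
  ci <- do.call(rbind, object$ci)
  colnames(ci) <- c("low", "high")
  out <- list(pair = c(object$id_a, object$id_b), unit = object$unit,
              model = object$model, lambda = object$lambda,
              n_compared = object$n_compared, n_mismatch = object$n_mismatch,
              mean = object$mean, median = object$median, mode = object$mode,
              ci = ci)
  class(out) <- "summary.tmrca_posterior"
  out
}

#' @export
print.summary.tmrca_posterior <- function(x, ...) {
  cat(sprintf("Pairwise TMRCA fit (%s model, lambda = %g)\n", x$model,
              x$lambda))
  if (length(x$pair))
    cat(sprintf("  pair: %s vs %s (%d series compared, %d mismatches)\n",
                x$pair[1], x$pair[2], x$n_compared, x$n_mismatch))
  cat(sprintf("  %s: mean %.1f, median %g, mode %g\n", x$unit, x$mean,
              x$median, x$mode))
  print(x$ci)
  invisible(x)
}

#' @export
plot.tmrca_posterior <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) {
    hi <- x$ci[[length(x$ci)]][2]
    xlim <- c(0, hi * 1.5)
  }
  keep <- x$support <= xlim[2]
  graphics::plot(x$support[keep], x$mass[keep], type = "h",
                 xlab = x$unit, ylab = "posterior mass",
                 main = if (!is.null(x$id_a))
                   paste(x$id_a, "vs", x$id_b) else "TMRCA posterior", ...)
  for (nm in names(x$ci))
    graphics::segments(x$ci[[nm]][1], 0, x$ci[[nm]][2], 0, lwd = 3,
                       col = grDevices::adjustcolor("red", 0.5))
  invisible(x)
}

#' Draw TMRCA values from a fitted posterior
#'
#' @param object A \code{tmrca_posterior}.
#' @param nsim Number of draws.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Numeric vector of \code{nsim} support values.
#' @export
simulate.tmrca_posterior <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample(object$support, nsim, replace = TRUE, prob = object$mass)
}
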