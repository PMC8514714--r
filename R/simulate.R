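#' Configuration for the forward genealogy simulator
#'
#' The generator emulates the statistical structure the downstream
#' analyses assume: a handful of well-separated founding paternal lineages
#' (the haplogroup-like clusters of a small endogamous village), stepwise
#' locus-specific mutation along each meiosis, "ancient" individuals
#' sampled from early generations in dated strata and "modern" individuals
#' from the final generation, and ancient-DNA style locus dropout
#' concentrated in the older strata.
#'
#' @param panel A \code{ystr_panel} (default Yfiler Plus, DYS389b form).
#' @param rates A \code{mutation_rates} table.
#' @param n_founders Number of founding lineages (default 4).
#' @param generations Number of generations grown after the founders
#'   (default 15, so ancient-modern separations fall around the 9-15
#'   generation scale of a 300-500 year window at 33 years/generation).
#' @param generation_time Years per generation (default 33).
#' @param lineage_size Males per lineage per generation (default 4).
#' @param ancient_generations Generations whose members can be sampled as
#'   ancient (default 0:6).
#' @param n_ancient,n_modern Sample sizes (defaults 13 and 14).
#' @param missingness Named per-stratum locus-dropout probabilities
#'   (default SU28 = 0.45, SU26 = 0.12, SU23 = 0.04, modern = 0 — dropout
#'   graded by age, heaviest in the oldest stratum).
#' @param dropout_weights Optional named per-series multipliers for
#'   length-weighted dropout (larger = more dropout-prone); renormalised
#'   to mean 1.
#' @param seed Integer RNG seed (mandatory: simulated datasets are
#'   reproducible by construction).
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(panel = ystr_panel(),
                              rates = default_mutation_rates(panel),
                              n_founders = 4, generations = 15,
                              generation_time = 33, lineage_size = 4,
                              ancient_generations = 0:6,
                              n_ancient = 13, n_modern = 14,
                              missingness = c(SU28 = 0.45, SU26 = 0.12,
                                              SU23 = 0.04, modern = 0),
                              dropout_weights = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(generations >= 1, all(missingness >= 0), all(missingness < 1),
            max(ancient_generations) < generations)
  structure(list(panel = panel, rates = rates, n_founders = n_founders,
                 generations = generations, generation_time = generation_time,
                 lineage_size = lineage_size,
                 ancient_generations = ancient_generations,
                 n_ancient = n_ancient, n_modern = n_modern,
                 missingness = missingness,
                 dropout_weights = dropout_weights,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# plausible founder allele ranges: integer repeat counts in 10..17 per
# series, no external frequency database involved
.draw_founder <- function(panel) {
  s <- panel_series(panel)
  stats::setNames(as.numeric(sample(10:17, length(s), replace = TRUE)), s)
}

# founders spaced so cross-lineage pairs are unambiguous: lineage f adds
# +2f repeats at 10 fixed series (>= 8 steps apart at >= 6 series for any
# founder pair)
.draw_founders <- function(panel, n_founders) {
  base <- .draw_founder(panel)
  sep_series <- panel_series(panel)[seq_len(min(10, panel_size(panel)))]
  lapply(seq_len(n_founders) - 1L, function(f) {
    h <- base
    h[sep_series] <- h[sep_series] + 2 * f
    h
  })
}

#' Mutate a haplotype along a line of descent
#'
#' Applies \code{n_meioses} meioses: in each, every series mutates
#' independently with its per-generation probability, and a mutation moves
#' the allele by one repeat up or down with equal probability.  The event
#' log permits exact replay.
#'
#' @param h Named numeric vector of alleles (one entry per series).
#' @param n_meioses Number of meioses (non-negative integer).
#' @param rates A \code{mutation_rates} table covering the series of
#'   \code{h}.
#' @param seed Optional RNG seed.
#' @return List with \code{haplotype} (mutated vector) and \code{events}
#'   (data frame \code{meiosis}, \code{series}, \code{step}).
#' @export
mutate_lineage <- function(h, n_meioses, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- .rates_for(rates, names(h))
  events <- list()
  for (g in seq_len(n_meioses)) {
    hit <- which(stats::runif(length(h)) < mu & !is.na(h))
    if (length(hit)) {
      step <- sample(c(-1, 1), length(hit), replace = TRUE)
      h[hit] <- h[hit] + step
      events[[length(events) + 1L]] <- data.frame(
        meiosis = g, series = names(h)[hit], step = step,
        stringsAsFactors = FALSE)
    }
  }
  list(haplotype = h,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(meiosis = integer(), series = character(),
                    step = numeric(), stringsAsFactors = FALSE))
}

#' Simulate a haplotype pair with known TMRCA
#'
#' Draws one founder haplotype and evolves two independent branches of
#' \code{t} meioses each, so the pair is separated by exactly \code{2t}
#' meioses.
#'
#' @param t Generations to the common ancestor of the pair.
#' @param config A \code{\link{simulation_config}} (panel and rates are
#'   used; the seed is NOT reset here so replicates can be drawn in a
#'   loop under one \code{set.seed}).
#' @return An object of class \code{simulated_pair}: list with
#'   \code{haps} (two-row \code{ystr_haplotypes}, ids "A" and "B"),
#'   \code{founder}, \code{true_tmrca}, \code{true_total_generations} and
#'   per-branch event logs.
#' @export
simulate_pair <- function(t, config) {
  founder <- .draw_founder(config$panel)
  a <- mutate_lineage(founder, t, config$rates)
  b <- mutate_lineage(founder, t, config$rates)
  df <- data.frame(sample_id = c("A", "B"), stringsAsFactors = FALSE)
  m <- rbind(a$haplotype, b$haplotype)
  for (s in names(founder)) df[[s]] <- m[, s]
  structure(list(haps = ystr_haplotypes(df, config$panel),
                 founder = founder, true_tmrca = t,
                 true_total_generations = 2L * as.integer(t),
                 events_a = a$events, events_b = b$events),
            class = "simulated_pair")
}

# stratum label for an ancient sampling generation (oldest -> SU28)
.stratum_of <- function(g) {
  if (g <= 1) "SU28" else if (g <= 4) "SU26" else "SU23"
}

#' Simulate a village of paternal lineages
#'
#' Founds \code{n_founders} well-separated lineages, grows each for
#' \code{generations} generations (every male's father drawn uniformly
#' from his lineage's previous generation), samples ancient individuals
#' from the configured early generations (stratum label by age) and
#' modern individuals from the final generation, then applies per-stratum
#' locus dropout.  The full genealogy is retained, so the true total
#' generations separating every sampled pair is known exactly.
#'
#' @param config A \code{\link{simulation_config}}; its seed drives all
#'   randomness.
#' @return An object of class \code{simulated_village}: list with
#'   \code{haplotypes} (a \code{ystr_haplotypes} table, populations RP_A /
#'   RP_M), \code{truth} (symmetric matrix of true total generations
#'   separating each sampled pair, \code{NA} across lineages),
#'   \code{lineages} (data frame sample_id, lineage, generation, stratum)
#'   and the \code{config}.
#' @export
simulate_village <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- config$panel
  founders <- .draw_founders(panel, config$n_founders)

  # genealogy: each lineage starts from a single founder (generation 0)
  # and keeps a cohort of lineage_size males per later generation, every
  # male's father drawn uniformly from the previous cohort
  k <- config$lineage_size
  hap <- list(); father <- list()
  for (f in seq_len(config$n_founders)) {
    cohorts <- vector("list", config$generations + 1L)
    fathers <- vector("list", config$generations + 1L)
    cohorts[[1]] <- list(founders[[f]])
    fathers[[1]] <- NA_integer_
    for (g in seq_len(config$generations)) {
      pa <- sample.int(length(cohorts[[g]]), k, replace = TRUE)
      cohorts[[g + 1L]] <- lapply(pa, function(i)
        mutate_lineage(cohorts[[g]][[i]], 1, config$rates)$haplotype)
      fathers[[g + 1L]] <- pa
    }
    hap[[f]] <- cohorts; father[[f]] <- fathers
  }
  cohort_size <- function(g) if (g == 0) 1L else k

  # ancestor chain of individual (lineage f, generation g, index i):
  # element m is the cohort index of the ancestor at generation m - 1
  chain <- function(f, g, i) {
    idx <- integer(g + 1L); idx[g + 1L] <- i
    if (g > 0)
      for (gg in g:1) idx[gg] <- father[[f]][[gg + 1L]][idx[gg + 1L]]
    idx
  }

  # sampling: ancients from the configured early generations, moderns from
  # the final generation, all without replacement
  anc_pool <- do.call(rbind, lapply(config$ancient_generations, function(g)
    expand.grid(lineage = seq_len(config$n_founders), generation = g,
                index = seq_len(cohort_size(g)))))
  anc_pick <- anc_pool[sample.int(nrow(anc_pool), config$n_ancient), ]
  mod_cells <- expand.grid(lineage = seq_len(config$n_founders),
                           generation = config$generations,
                           index = seq_len(k))
  mod_pick <- mod_cells[sample.int(nrow(mod_cells), config$n_modern), ]

  samples <- rbind(
    data.frame(anc_pick, population = "RP_A",
               stratum = vapply(anc_pick$generation, .stratum_of,
                                character(1)),
               stringsAsFactors = FALSE),
    data.frame(mod_pick, population = "RP_M", stratum = "modern",
               stringsAsFactors = FALSE))
  samples$sample_id <- sprintf("L%dG%02dI%d", samples$lineage,
                               samples$generation, samples$index)
  rownames(samples) <- NULL

  n <- nrow(samples)
  ser <- panel_series(panel)
  calls <- matrix(NA_real_, n, length(ser), dimnames = list(NULL, ser))
  chains <- vector("list", n)
  for (r in seq_len(n)) {
    f <- samples$lineage[r]; g <- samples$generation[r]
    i <- samples$index[r]
    calls[r, ] <- hap[[f]][[g + 1L]][[i]][ser]
    chains[[r]] <- chain(f, g, i)
  }

  # per-stratum locus dropout (optionally length-weighted)
  w <- rep(1, length(ser))
  if (!is.null(config$dropout_weights)) {
    w <- config$dropout_weights[ser]
    w <- w / mean(w)
  }
  for (r in seq_len(n)) {
    p <- config$missingness[[samples$stratum[r]]]
    if (p > 0) {
      drop <- stats::runif(length(ser)) < pmin(p * w, 0.99)
      calls[r, drop] <- NA_real_
    }
  }

  # truth: total generations separating each sampled pair
  truth <- matrix(NA_real_, n, n,
                  dimnames = list(samples$sample_id, samples$sample_id))
  diag(truth) <- 0
  for (r in seq_len(n - 1L)) {
    for (s in (r + 1L):n) {
      if (samples$lineage[r] != samples$lineage[s]) next
      cr <- chains[[r]]; cs <- chains[[s]]
      gmax <- min(length(cr), length(cs))
      # equal cohort index at a generation means the same individual, and
      # shared ancestry is a prefix from the founder, so the deepest
      # shared ancestor is the last index of the common prefix
      gm <- sum(cumprod(cr[seq_len(gmax)] == cs[seq_len(gmax)])) - 1L
      truth[r, s] <- truth[s, r] <-
        (samples$generation[r] - gm) + (samples$generation[s] - gm)
    }
  }

  df <- data.frame(sample_id = samples$sample_id,
                   population = samples$population,
                   stratum = samples$stratum, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(calls))
  structure(list(haplotypes = ystr_haplotypes(df, panel),
                 truth = truth,
                 lineages = data.frame(sample_id = samples$sample_id,
                                       lineage = samples$lineage,
                                       generation = samples$generation,
                                       stratum = samples$stratum,
                                       stringsAsFactors = FALSE),
                 config = config),
            class = "simulated_village")
}

#' @export
print.simulated_village <- function(x, ...) {
  cat(sprintf(
    "simulated village: %d lineages, %d generations, %d ancient + %d modern sampled (seed %d)\n",
    x$config$n_founders, x$config$generations,
    sum(x$haplotypes$population == "RP_A"),
    sum(x$haplotypes$population == "RP_M"), x$config$seed))
  invisible(x)
}
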