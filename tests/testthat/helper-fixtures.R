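# shared builders and independent oracles for the test suite

# a complete haplotype table: each row gets base allele `base` everywhere,
# with named per-sample tweaks applied afterwards
make_haps <- function(ids, base = 14, panel = ystr_panel(),
                      population = "ALL", stratum = NA_character_) {
  df <- data.frame(sample_id = ids, population = population,
                   stratum = stratum, stringsAsFactors = FALSE)
  for (s in panel_series(panel)) df[[s]] <- base
  ystr_haplotypes(df, panel)
}

set_allele <- function(haps, id, series, value) {
  df <- as.data.frame(haps)
  df[df$sample_id == id, series] <- value
  ystr_haplotypes(df, active_panel(haps),
                  duplications = duplication_flags(haps))
}

# haplotypes rebuilt from the published typing-success counts: sample i
# gets its first n_typed series set, the rest missing
haps_from_typed_counts <- function(ids, n_typed, population = "RP_A",
                                   panel = ystr_panel()) {
  ser <- panel_series(panel)
  df <- data.frame(sample_id = ids, population = population,
                   stratum = NA_character_, stringsAsFactors = FALSE)
  m <- matrix(NA_real_, length(ids), length(ser),
              dimnames = list(NULL, ser))
  for (i in seq_along(ids))
    if (n_typed[i] > 0) m[i, seq_len(n_typed[i])] <- 14
  ystr_haplotypes(cbind(df, as.data.frame(m)), panel)
}

# brute-force gene diversity: discordant ordered draws (with replacement)
# over all n^2 ordered pairs, small-sample corrected
gd_oracle <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  disc <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (alleles[i] != alleles[j]) disc <- disc + 1L
  (disc / n^2) * n / (n - 1)
}

# brute-force two-level AMOVA from explicit pairwise-distance loops
amova_oracle <- function(d2, pops) {
  n <- length(pops)
  ssd_t <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) ssd_t <- ssd_t + d2[i, j]
  ssd_t <- ssd_t / (2 * n)
  ssd_w <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    ssd_w <- ssd_w + s / (2 * length(idx))
  }
  P <- length(unique(pops))
  sigma_w <- ssd_w / (n - P)
  sizes <- table(pops)
  n_prime <- (n - sum(sizes^2) / n) / (P - 1)
  sigma_a <- ((ssd_t - ssd_w) / (P - 1) - sigma_w) / n_prime
  sigma_a / (sigma_a + sigma_w)
}

# Monte-Carlo oracles for the mutation models (2t meioses per pair)
mc_iam_mismatch <- function(mu, t, nrep = 1e6) {
  mean(stats::rbinom(nrep, 2 * t, mu) > 0)
}
mc_smm_displacement <- function(mu, t, d, nrep = 1e6) {
  m <- stats::rbinom(nrep, 2 * t, mu)
  disp <- 2 * stats::rbinom(nrep, m, 0.5) - m
  mean(disp == d)
}

# minimal pair_difference for likelihood-level tests
fake_diff <- function(loci, smm) {
  structure(list(id_a = "a", id_b = "b", loci = loci,
                 iam_vector = as.integer(smm != 0), smm_vector = smm,
                 n_compared = length(loci)),
            class = "pair_difference")
}
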