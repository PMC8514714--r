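test_that("gene diversity matches the corrected heterozygosity formula", {
  expect_equal(gene_diversity(c(`15` = 5)), 0)
  expect_equal(gene_diversity(c(`14` = 1, `15` = 1)), 1)
  expect_equal(gene_diversity(c(`14` = 3, `15` = 1)), 0.5)
  expect_warning(g1 <- gene_diversity(c(`14` = 1)), "n < 2")
  expect_true(is.na(g1))
})

test_that("gene diversity equals the brute-force ordered-pair count", {
  set.seed(71)
  for (rep in 1:20) {
    alleles <- sample(10:14, sample(3:12, 1), replace = TRUE)
    counts <- table(alleles)
    expect_equal(gene_diversity(counts), gd_oracle(alleles))
  }
})

test_that("per-locus diversity uses pairwise deletion for missing calls", {
  h <- make_haps(c("a", "b", "c", "d"))
  h <- set_allele(h, "a", "DYS19", 15)
  h <- set_allele(h, "b", "DYS19", NA)
  ac <- allele_counts(h, "DYS19")
  expect_equal(ac$n, 3)                # b excluded at this locus only
  expect_equal(gene_diversity(ac), 3 * (1 - (4 + 1) / 9) / 2)
  # sampling consistency: GD converges to (1 - sum x^2) * n/(n-1)
  set.seed(72)
  freq <- c(`12` = 0.5, `13` = 0.3, `14` = 0.2)
  draws <- sample(names(freq), 4000, replace = TRUE, prob = freq)
  expect_equal(gene_diversity(table(draws)), 1 - sum(freq^2),
               tolerance = 0.02)
})

test_that("compatibility clustering pools partial with complete profiles", {
  # two identical complete profiles -> one cluster of two
  h <- make_haps(c("x", "y", "z"))
  h <- set_allele(h, "z", "DYS19", 16)
  sp <- cluster_haplotypes(h)
  expect_equal(sp$n_distinct, 2)
  expect_equal(unname(sp$occurrence_counts[c("1", "2")]), c(1L, 1L))

  # a 25-series partial equal on shared series joins the complete pair
  h2 <- make_haps(c("anc", "mod1", "mod2"))
  h2 <- set_allele(h2, "anc", c("DYS19", "DYS390"), NA)
  sp2 <- cluster_haplotypes(h2)
  expect_equal(sp2$n_distinct, 1)
  expect_equal(sp2$sizes, 3L)

  # mutually incompatible profiles stay singletons
  h3 <- make_haps(c("p", "q", "r"))
  h3 <- set_allele(h3, "q", "DYS19", 15)
  h3 <- set_allele(h3, "r", "DYS19", 16)
  sp3 <- cluster_haplotypes(h3)
  expect_equal(unname(sp3$occurrence_counts["1"]), 3L)
  expect_equal(sp3$n_distinct, 3)

  # a one-step mismatch never merges (distinctness preserved)
  h4 <- make_haps(c("u", "v"))
  h4 <- set_allele(h4, "v", "DYS570", 15)
  expect_equal(cluster_haplotypes(h4)$n_distinct, 2)
})

test_that("partial profile joins its best-matching cluster, ambiguity logged", {
  h <- make_haps(c("c1", "c2", "part"))
  h <- set_allele(h, "c2", "DYS19", 16)         # c1 and c2 incompatible
  h <- set_allele(h, "part", "DYS19", NA)        # part compatible with both
  h <- set_allele(h, "part", c("DYS390", "DYS391"), NA)
  sp <- cluster_haplotypes(h)
  expect_equal(sp$n_distinct, 2)
  expect_length(sp$ambiguities, 1)
  # ties by typed count go to the first-created (input-order) cluster
  first <- sp$clusters[[1]]
  expect_true("part" %in% first && "c1" %in% first)
})

test_that("duplicated single-copy loci are ignored in clustering", {
  h <- make_haps(c("a", "b"))
  dups <- data.frame(sample_id = "a", series = "DYS19", alleles = "14,15",
                     stringsAsFactors = FALSE)
  df <- as.data.frame(h); df$DYS19[1] <- NA
  h <- ystr_haplotypes(df, active_panel(h), duplications = dups)
  expect_equal(cluster_haplotypes(h)$n_distinct, 1)
})

test_that("diversity indexes reproduce the published occurrence spectra", {
  # columns: list(spectrum counts, n, hd, hmp, dc)
  cases <- list(
    yplus_total = list(c(`1` = 20, `2` = 2, `3` = 1), 27, 0.9858, 0.0508, 0.8519),
    yplus_rpa   = list(c(`1` = 11, `2` = 1),          13, 0.9872, 0.0888, 0.9231),
    yplus_rpm   = list(c(`1` = 12, `2` = 1),          14, 0.9890, 0.0816, 0.9286),
    yfiler_total = list(c(`1` = 9, `2` = 1, `3` = 1, `4` = 2, `5` = 1),
                        27, 0.9259, 0.1084, 0.5185),
    yfiler_rpa  = list(c(`1` = 5, `2` = 1, `3` = 2),  13, 0.9103, 0.1598, 0.6154),
    yfiler_rpm  = list(c(`1` = 7, `2` = 2, `3` = 1),  14, 0.9451, 0.1224, 0.7143))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    sp <- haplotype_spectrum(cs[[1]], by_count = TRUE)
    expect_equal(sp$n, cs[[2]], info = nm)
    d <- haplotype_diversity(sp)
    expect_equal(round(d$hd, 4), cs[[3]], info = nm)
    expect_equal(round(d$hmp, 4), cs[[4]], info = nm)
    expect_equal(round(d$dc, 4), cs[[5]], info = nm)
  }
})

test_that("diversity identities hold on arbitrary spectra", {
  set.seed(73)
  for (rep in 1:25) {
    sizes <- sample(1:5, sample(2:10, 1), replace = TRUE)
    d <- haplotype_diversity(haplotype_spectrum(sizes))
    expect_equal(d$hd, d$n * (1 - d$hmp) / (d$n - 1))
    expect_equal(d$dc * d$n, round(d$dc * d$n))
    expect_true(d$hmp >= 1 / d$n)
  }
  # degenerate: everyone shares one haplotype
  d0 <- haplotype_diversity(haplotype_spectrum(6))
  expect_equal(d0$hd, 0)
  expect_equal(d0$dc, 1 / 6)
})

test_that("panel projection never increases distinct haplotypes", {
  set.seed(74)
  v <- simulate_village(simulation_config(seed = 74))
  haps <- filter_by_missing(v$haplotypes, 3)
  comp <- panel_comparison(haps)
  expect_lte(comp$subset$n_distinct, comp$full$n_distinct)
  expect_lte(round(comp$subset$hd, 6), round(comp$full$hd, 6) + 1e-9)
  # projecting onto the full panel itself is the identity
  same <- panel_comparison(haps, panel_sub = active_panel(haps))
  expect_equal(same$subset$hd, same$full$hd)
  expect_equal(same$subset$spectrum$sizes, same$full$spectrum$sizes)
  expect_error(panel_comparison(project_panel(haps, ystr_panel("YFILER17")),
                                panel_sub = ystr_panel("YFILERPLUS27")),
               "subset")
})

test_that("published per-locus gene diversities average as printed", {
  gd <- roccapelago_gene_diversity()
  v <- stats::setNames(gd$rp_t, gd$series)
  means <- gd_group_means(v)
  expect_equal(round(unname(means["rm7"]), 6), 0.702792)
  expect_equal(round(unname(means["additional10"]), 6), 0.673029)
})
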