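rates1 <- function(mu, locus = "DYS19") mutation_rate_table(setNames(mu, locus))

test_that("likelihoods behave correctly at t = 0", {
  r <- default_mutation_rates()
  match3 <- fake_diff(c("DYS19", "DYS390", "DYS570"), c(0, 0, 0))
  mm3 <- fake_diff(c("DYS19", "DYS390", "DYS570"), c(0, 1, 0))
  expect_equal(iam_likelihood(match3, r, 0), 1)
  expect_equal(iam_likelihood(mm3, r, 0), 0)
  expect_equal(smm_likelihood(match3, r, 0), 1)
  expect_equal(smm_likelihood(mm3, r, 0), 0)
})

test_that("single-locus IAM likelihood matches the closed form and MC", {
  d <- fake_diff("DYS19", 1)
  r <- rates1(0.01)
  expect_equal(iam_likelihood(d, r, 10), 1 - 0.99^20)
  set.seed(91)
  mc <- mc_iam_mismatch(0.01, 10, nrep = 1e6)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(iam_likelihood(d, r, 10) - mc), 3 * se)
  # match probability decays with t; mismatch prob grows
  m0 <- fake_diff("DYS19", 0)
  lm <- iam_likelihood(m0, r, 0:200)
  expect_true(all(diff(lm) < 0))
  expect_error(iam_likelihood(fake_diff("NOSUCH", 0), r, 1), "NOSUCH")
})

test_that("SMM displacement probabilities respect parity and match MC", {
  # odd displacement needs an odd number of steps: P(d=1) at tiny mu ~ 0
  d1 <- fake_diff("DYS19", 1)
  expect_lt(smm_likelihood(d1, rates1(1e-4), 5), 1e-3)
  # no-displacement likelihood tends to 1 as mu -> 0
  d0 <- fake_diff("DYS19", 0)
  expect_gt(smm_likelihood(d0, rates1(1e-6), 50), 0.9999)
  # SMM allows hidden back mutations: never below IAM at d = 0
  r <- rates1(0.01)
  ts <- 0:100
  expect_true(all(smm_likelihood(d0, r, ts) >= iam_likelihood(d0, r, ts) - 1e-12))
  # grid of (mu, t, d) points against the Monte-Carlo mutation-walk oracle
  set.seed(92)
  for (pt in list(c(0.02, 5, 1), c(0.05, 10, 0), c(0.05, 10, 2),
                  c(0.01, 20, -1))) {
    mu <- pt[1]; t <- pt[2]; dd <- pt[3]
    mc <- mc_smm_displacement(mu, t, dd, nrep = 2e5)
    se <- sqrt(max(mc * (1 - mc), 1e-12) / 2e5)
    expect_lt(abs(smm_likelihood(fake_diff("DYS19", dd), rates1(mu), t) - mc),
              3 * se + 1e-12)
  }
  expect_warning(smm_likelihood(fake_diff("DYS19", 0.4), rates1(0.01), 5),
                 "rounded")
})

test_that("posterior is a proper distribution with nested central intervals", {
  r <- default_mutation_rates()
  set.seed(93)
  cfg <- simulation_config(seed = 93)
  for (t_true in c(0, 5, 20)) {
    p <- simulate_pair(t_true, cfg)
    fit <- tmrca_walsh(difference_vector(p$haps, "A", "B"), r)
    expect_lt(abs(sum(fit$mass) - 1), 1e-9)
    ci50 <- fit$ci[["50%"]]; ci95 <- fit$ci[["95%"]]
    expect_gte(ci50[1], ci95[1])
    expect_lte(ci50[2], ci95[2])
    expect_true(fit$mode %in% fit$support)
  }
  # SMM route normalises too
  p <- simulate_pair(5, cfg)
  fit_smm <- tmrca_walsh(difference_vector(p$haps, "A", "B"), r,
                         walsh_config(model = "SMM", lambda = 50,
                                      grid_max = 500))
  expect_lt(abs(sum(fit_smm$mass) - 1), 1e-9)
})

test_that("an all-match pair yields a mode-zero decreasing posterior", {
  h <- make_haps(c("a", "b"))
  fit <- tmrca_walsh(difference_vector(h, "a", "b"),
                     default_mutation_rates())
  expect_equal(fit$mode, 0)
  expect_true(all(diff(fit$mass) <= 0))        # non-increasing everywhere
  expect_true(all(diff(fit$mass[1:100]) < 0))  # strictly so in the bulk
})

test_that("a larger prior mean stochastically increases the posterior", {
  d <- fake_diff(c("DYS19", "DYS570"), c(0, 1))
  r <- mutation_rate_table(c(DYS19 = 0.002, DYS570 = 0.012))
  f1 <- tmrca_walsh(d, r, walsh_config(lambda = 500, grid_max = 20000))
  f2 <- tmrca_walsh(d, r, walsh_config(lambda = 2000, grid_max = 20000))
  expect_true(all(cumsum(f2$mass) <= cumsum(f1$mass) + 1e-12))
})

test_that("removing an informative matched locus widens the interval", {
  set.seed(94)
  cfg <- simulation_config(seed = 94)
  widths_full <- widths_drop <- numeric(10)
  for (i in 1:10) {
    p <- simulate_pair(10, cfg)
    d <- difference_vector(p$haps, "A", "B")
    fit <- tmrca_walsh(d, cfg$rates)
    # drop one matched locus (simulated missingness)
    keep <- which(d$iam_vector == 0)[1]
    d2 <- d
    d2$loci <- d$loci[-keep]
    d2$iam_vector <- d$iam_vector[-keep]
    d2$smm_vector <- d$smm_vector[-keep]
    d2$n_compared <- d$n_compared - 1L
    fit2 <- tmrca_walsh(d2, cfg$rates)
    widths_full[i] <- diff(fit$ci[["95%"]])
    widths_drop[i] <- diff(fit2$ci[["95%"]])
  }
  expect_true(all(widths_drop >= widths_full))
})

test_that("separation doubling and year conversion are exact rescalings", {
  h <- make_haps(c("a", "b"))
  h <- set_allele(h, "b", "DYS570", 15)
  fit <- tmrca_walsh(difference_vector(h, "a", "b"),
                     default_mutation_rates())
  tot <- generations_separating(fit)
  expect_equal(tot$mode, 2 * fit$mode)
  expect_equal(tot$mean, 2 * fit$mean)
  expect_equal(tot$ci[["50%"]], 2 * fit$ci[["50%"]])
  expect_equal(tot$mass, fit$mass)
  yrs <- to_years(tot)
  expect_equal(yrs$mean, 33 * tot$mean)
  expect_equal(yrs$ci[["95%"]], 33 * tot$ci[["95%"]])
  yrs30 <- to_years(tot, generation_time = 30)
  expect_equal(yrs30$support, 30 * tot$support)
  # worked doubling: mode 6 generations -> 12 total -> 396 years
  expect_equal(to_years(generations_separating(
    structure(list(support = 0:10, mass = c(rep(0, 6), 1, rep(0, 4)),
                   mean = 6, median = 6, mode = 6,
                   ci = list(`50%` = c(3, 9)), unit = "generations to MRCA",
                   model = "IAM", lambda = 1000, ci_levels = 0.5,
                   id_a = "x", id_b = "y", n_compared = 27, n_mismatch = 0),
              class = "tmrca_posterior")))$mode, 396)
})

test_that("grid exhaustion is reported rather than silently truncated", {
  d <- fake_diff(rep("DYS19", 1), 1)
  # huge lambda pushes mass to the grid edge for a weakly informed pair
  expect_warning(
    tmrca_walsh(fake_diff("DYS19", 0), rates1(1e-4),
                walsh_config(lambda = 1e6, grid_max = 100)),
    "grid_max")
})
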