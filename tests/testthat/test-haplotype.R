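write_fixture_csv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

test_that("genotype tables parse missing cells, multi-copy and duplications", {
  panel <- ystr_panel(dys389b = FALSE)
  ser <- panel_series(panel)
  hdr <- paste(c("sample_id", "population", "stratum",
                 "DYS19", "DYS385", "DYS391"), collapse = ",")
  tf <- write_fixture_csv(c(
    hdr,
    "s1,RP_A,SU23,15,\"11,14\",10",
    "s2,RP_A,SU23,,37,10",
    "s3,RP_M,,\"14,15\",\"11,14\",10"))
  expect_warning(haps <- read_haplotype_table(tf, panel), regexp = NA)
  expect_equal(nrow(haps), 3)
  # multi-copy split: sorted a/b, homoallelic single value
  expect_equal(haps$DYS385a, c(11, 37, 11))
  expect_equal(haps$DYS385b, c(14, 37, 14))
  # empty cell is missing
  expect_true(is.na(haps$DYS19[2]))
  # duplicated single-copy locus: flagged, missing downstream
  expect_true(is.na(haps$DYS19[3]))
  d <- duplication_flags(haps)
  expect_equal(d$sample_id, "s3")
  expect_equal(d$series, "DYS19")
  expect_equal(d$alleles, "14,15")
  # unlisted loci are missing
  expect_true(all(is.na(haps$DYS390)))
})

test_that("malformed tables fail loudly, bad cells degrade gracefully", {
  panel <- ystr_panel(dys389b = FALSE)
  expect_error(read_haplotype_table(
    write_fixture_csv(c("id,DYS19", "s1,15")), panel), "sample_id")
  expect_error(read_haplotype_table(
    write_fixture_csv(c("sample_id,DYS19", "s1,15", "s1,16")), panel),
    "duplicate")
  expect_error(read_haplotype_table(
    write_fixture_csv(c("sample_id,DYS999", "s1,15")), panel), "DYS999")
  expect_warning(
    h <- read_haplotype_table(
      write_fixture_csv(c("sample_id,DYS19", "s1,xx")), panel),
    "unparseable")
  expect_true(is.na(h$DYS19[1]))
})

test_that("write/read round trip preserves calls, missingness and flags", {
  panel <- ystr_panel(dys389b = FALSE)
  tf <- write_fixture_csv(c(
    "sample_id,population,DYS19,DYS385,DYS391,DYS458",
    "s1,RP_A,15,\"11,14\",10,17.2",
    "s2,RP_M,\"14,15\",12,,16"))
  h1 <- read_haplotype_table(tf, panel)
  tf2 <- tempfile(fileext = ".csv")
  write_haplotype_table(h1, tf2)
  h2 <- read_haplotype_table(tf2, panel)
  expect_equal(.calls_matrix(h1), .calls_matrix(h2))
  expect_equal(duplication_flags(h1), duplication_flags(h2))
  # intermediate allele preserved to one decimal
  expect_equal(h2$DYS458[1], 17.2)
})

test_that("DYS389b conversion subtracts the embedded repeat stretch", {
  expect_equal(convert_dys389(13, 29), 16)
  expect_equal(convert_dys389(14, 30), 16)
  expect_true(is.na(convert_dys389(NA, 30)))
  expect_true(is.na(convert_dys389(13, NA)))
  expect_warning(b <- convert_dys389(30, 13), "inconsisten")
  expect_true(is.na(b))
  # table-wide application renames the series and switches the panel
  h <- make_haps(c("a", "b"), panel = ystr_panel(dys389b = FALSE))
  h <- set_allele(h, "a", "DYS389I", 13)
  h <- set_allele(h, "a", "DYS389II", 29)
  h <- set_allele(h, "b", "DYS389I", 14)
  h <- set_allele(h, "b", "DYS389II", 30)
  hc <- apply_dys389b(h)
  expect_true(active_panel(hc)$dys389b)
  expect_equal(hc$DYS389b[hc$sample_id == "a"], 16)
  expect_null(hc$DYS389II)
  expect_error(apply_dys389b(hc), "already")
})

test_that("multi-copy splitting sorts, duplicates singles, propagates gaps", {
  p <- ystr_panel()
  expect_equal(split_multicopy(list(DYS385 = c(14, 11)), p),
               c(DYS385a = 11, DYS385b = 14))
  expect_equal(split_multicopy(list(DYF387S1 = 37), p),
               c(DYF387S1a = 37, DYF387S1b = 37))
  out <- split_multicopy(list(DYS385 = numeric(0)), p)
  expect_true(all(is.na(out)))
  expect_error(split_multicopy(list(DYS385 = c(10, 11, 12)), p), ">2")
})

test_that("missing-locus filter retains 13 of the 25 ancient profiles", {
  qc <- roccapelago_qc()
  haps <- haps_from_typed_counts(qc$sample_id, qc$n_typed)
  kept <- filter_by_missing(haps, 3)
  expect_equal(nrow(kept), 13)
  expect_setequal(kept$sample_id,
                  c("23-41", "23-12", "23-31", "23-46", "23-06", "23-7",
                    "23-44", "26-05", "26-32", "26-43", "26-42", "26-1",
                    "26-10"))
  # all complete modern profiles pass
  mod <- make_haps(sprintf("m%02d", 1:14), population = "RP_M")
  expect_equal(nrow(filter_by_missing(mod, 3)), 14)
})

test_that("missing-locus filter is idempotent and monotone", {
  qc <- roccapelago_qc()
  haps <- haps_from_typed_counts(qc$sample_id, qc$n_typed)
  k3 <- filter_by_missing(haps, 3)
  expect_equal(as.data.frame(filter_by_missing(k3, 3)), as.data.frame(k3))
  prev <- character(0)
  for (mm in c(0, 2, 3, 10, 27)) {
    cur <- filter_by_missing(haps, mm)$sample_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_equal(filter_by_missing(haps, 27)$sample_id, haps$sample_id)
  expect_equal(nrow(filter_by_missing(haps[0, ], 3)), 0)
})

test_that("degradation index follows the small/large target ratio", {
  q <- compute_qc("23-31", small_target = 0.0226, large_target = 0.0074,
                  y_target = 0.0153)
  expect_equal(q$di_reported, 3L)
  expect_equal(q$degradation_index, 0.0226 / 0.0074)
  # undetected large target -> undefined DI
  q2 <- compute_qc("28-02", small_target = 0.0151, large_target = NA,
                   y_target = 0.0095)
  expect_true(is.na(q2$degradation_index))
  expect_equal(compute_qc("x", 0.05, 0.05, 0.01)$di_reported, 1L)
  expect_error(compute_qc("x", -0.1, 0.2, 0.1), "negative")
  expect_error(compute_qc("x", 0.1, 0.2, 0.1, n_typed = 30), "panel")
})
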