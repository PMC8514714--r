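#' Y-STR haplotype tables
#'
#' The central container of the package: one row per male individual, one
#' numeric column per allelic series of the active panel (allele = repeat
#' count, possibly non-integer for intermediate alleles, \code{NA} for
#' missing), plus \code{sample_id}, \code{population} and optional
#' \code{stratum} metadata columns.  A duplicated single-copy locus (two
#' alleles observed at a one-copy marker) is recorded in the
#' \code{duplications} attribute and treated as missing in every downstream
#' comparison.
#'
#' @param df Data frame with \code{sample_id}, optional \code{population}
#'   and \code{stratum}, and one numeric column per panel series.
#' @param panel A \code{ystr_panel}.
#' @param duplications Optional data frame (\code{sample_id}, \code{series},
#'   \code{alleles}) recording observed duplications at single-copy loci.
#' @return An object of class \code{ystr_haplotypes} (a data frame with
#'   attributes \code{panel} and \code{duplications}).
#' @export
ystr_haplotypes <- function(df, panel, duplications = NULL) {
  stopifnot(inherits(panel, "ystr_panel"))
  df <- as.data.frame(df)
  class(df) <- "data.frame"
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!"population" %in% names(df)) df$population <- "ALL"
  if (!"stratum" %in% names(df)) df$stratum <- NA_character_
  ser <- panel_series(panel)
  for (s in setdiff(ser, names(df))) df[[s]] <- NA_real_
  extra <- setdiff(names(df), c("sample_id", "population", "stratum", ser))
  if (length(extra))
    stop("columns not in panel ", panel$name, ": ",
         paste(extra, collapse = ", "))
  df <- df[, c("sample_id", "population", "stratum", ser)]
  for (s in ser) df[[s]] <- as.numeric(df[[s]])
  if (is.null(duplications))
    duplications <- data.frame(sample_id = character(), series = character(),
                               alleles = character(), stringsAsFactors = FALSE)
  structure(df, panel = panel, duplications = duplications,
            class = c("ystr_haplotypes", "data.frame"))
}

#' @rdname ystr_haplotypes
#' @param haps A \code{ystr_haplotypes} table.
#' @export
active_panel <- function(haps) attr(haps, "panel")

#' @rdname ystr_haplotypes
#' @export
duplication_flags <- function(haps) attr(haps, "duplications")

# numeric allele matrix (rows = sample_id, cols = panel series)
.calls_matrix <- function(haps) {
  ser <- panel_series(active_panel(haps))
  m <- as.matrix(as.data.frame(haps)[, ser, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- haps$sample_id
  m
}

#' Read a delimited Y-STR genotype table
#'
#' Expects a header row naming \code{sample_id}, optionally
#' \code{population} and \code{stratum}, and one column per locus.
#' Multi-copy markers (DYS385, DYF387S1) may appear either as separate
#' "a"/"b" series columns or as a single marker column holding
#' comma-separated alleles; the latter are split with the smaller allele
#' assigned to the "a" series (a single value is taken as homoallelic).
#' Two comma-separated alleles in a single-copy column are recorded as a
#' duplication and the call is set to missing.  Empty cells and \code{NA}
#' are missing; an unparseable cell becomes missing with a warning.
#'
#' @param path File path.
#' @param panel A \code{ystr_panel}; columns must belong to it.
#' @param sep Field delimiter (default \code{","}).
#' @return A \code{ystr_haplotypes} table.
#' @export
read_haplotype_table <- function(path, panel = ystr_panel(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, na.strings = c("", "NA"))
  if (!"sample_id" %in% names(raw)) stop("missing 'sample_id' column")
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
               collapse = ", "))
  meta <- intersect(c("sample_id", "population", "stratum"), names(raw))
  locus_cols <- setdiff(names(raw), meta)
  multi <- panel$markers$marker[panel$markers$copies == 2L]
  known <- c(panel_series(panel), intersect(multi, panel$markers$marker))
  bad <- setdiff(locus_cols, known)
  if (length(bad))
    stop("locus column(s) not in panel ", panel$name, ": ",
         paste(bad, collapse = ", "))

  n <- nrow(raw)
  ser <- panel_series(panel)
  calls <- matrix(NA_real_, n, length(ser), dimnames = list(NULL, ser))
  dups <- list()

  parse_cell <- function(cell, id, col) {
    if (is.na(cell)) return(numeric(0))
    vals <- suppressWarnings(as.numeric(strsplit(cell, ",", fixed = TRUE)[[1]]))
    if (anyNA(vals)) {
      warning(sprintf("unparseable allele cell '%s' at %s/%s set to missing",
                      cell, id, col), call. = FALSE)
      return(NA)  # sentinel: unparseable
    }
    vals
  }

  for (i in seq_len(n)) {
    id <- raw$sample_id[i]
    for (col in locus_cols) {
      vals <- parse_cell(raw[[col]][i], id, col)
      if (length(vals) == 1L && is.na(vals)) next  # unparseable -> missing
      if (col %in% multi) {
        if (length(vals) > 2L)
          stop(sprintf(">2 alleles at multi-copy marker %s for %s", col, id))
        sp <- split_multicopy(stats::setNames(list(vals), col), panel)
        calls[i, names(sp)] <- sp
      } else {
        if (length(vals) == 0L) next
        if (length(vals) > 1L) {
          dups[[length(dups) + 1L]] <- data.frame(
            sample_id = id, series = col,
            alleles = paste(sort(vals), collapse = ","),
            stringsAsFactors = FALSE)
          next  # duplicated single-copy locus: missing downstream
        }
        calls[i, col] <- vals
      }
    }
  }

  df <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  df$population <- if ("population" %in% meta) raw$population else "ALL"
  df$stratum <- if ("stratum" %in% meta) raw$stratum else NA_character_
  df <- cbind(df, as.data.frame(calls))
  ystr_haplotypes(df, panel,
                  duplications = if (length(dups)) do.call(rbind, dups) else NULL)
}

#' Write a Y-STR genotype table
#'
#' Inverse of \code{\link{read_haplotype_table}}: alleles are written with
#' at most one fractional digit, missing calls as empty cells, and recorded
#' duplications as comma-separated allele pairs, so that a read/write
#' round trip reproduces calls, missingness and duplication flags exactly.
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_haplotype_table <- function(haps, path, sep = ",") {
  ser <- panel_series(active_panel(haps))
  out <- as.data.frame(haps)[, c("sample_id", "population", "stratum")]
  m <- .calls_matrix(haps)
  fmt <- function(x) ifelse(is.na(x), "",
                            sub("\\.0$", "", sprintf("%.1f", x)))
  for (s in ser) out[[s]] <- fmt(m[, s])
  dups <- duplication_flags(haps)
  if (nrow(dups)) {
    for (k in seq_len(nrow(dups))) {
      i <- match(dups$sample_id[k], out$sample_id)
      out[i, dups$series[k]] <- dups$alleles[k]
    }
  }
  # duplication cells ("14,15") contain the delimiter: quote text fields
  utils::write.table(out, path, sep = sep, quote = TRUE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Split multi-copy marker calls into sorted allelic series
#'
#' Alleles observed at a copy-2 marker are sorted ascending and assigned to
#' the "a" (smaller) and "b" (larger) series.  A single observed value is
#' taken as homoallelic (both series equal); no value leaves both series
#' missing.
#'
#' @param raw_calls Named list: marker name -> numeric vector of observed
#'   alleles (length 0, 1 or 2 for copy-2 markers).
#' @param panel A \code{ystr_panel}.
#' @return Named numeric vector over the expanded series.
#' @export
split_multicopy <- function(raw_calls, panel = ystr_panel()) {
  out <- numeric(0)
  for (mk in names(raw_calls)) {
    row <- match(mk, panel$markers$marker)
    if (is.na(row)) stop("marker not in panel: ", mk)
    vals <- sort(raw_calls[[mk]])
    if (panel$markers$copies[row] == 2L) {
      if (length(vals) > 2L)
        stop(">2 alleles at multi-copy marker ", mk)
      ab <- paste0(mk, c("a", "b"))
      if (length(vals) == 0L)
        out[ab] <- NA_real_
      else if (length(vals) == 1L)
        out[ab] <- vals
      else
        out[ab] <- vals
    } else {
      out[mk] <- if (length(vals) == 1L) vals else NA_real_
    }
  }
  out
}

#' DYS389b nomenclature conversion
#'
#' DYS389II amplicons contain the DYS389I repeat stretch; the DYS389b
#' nomenclature removes it by subtracting the DYS389I repeat count from the
#' DYS389II allele.  Missingness propagates; a non-positive difference is
#' flagged as an inconsistency and returned missing.
#'
#' @param dys389I,dys389II Numeric allele vectors (recycled to equal
#'   length).
#' @return Numeric vector of DYS389b alleles.
#' @examples
#' convert_dys389(13, 29)  # 16
#' @export
convert_dys389 <- function(dys389I, dys389II) {
  b <- dys389II - dys389I
  bad <- !is.na(b) & b <= 0
  if (any(bad)) {
    warning(sprintf("%d DYS389II <= DYS389I inconsistencies set to missing",
                    sum(bad)), call. = FALSE)
    b[bad] <- NA_real_
  }
  b
}

#' @rdname convert_dys389
#'
#' @details \code{apply_dys389b} applies the conversion table-wide,
#'   replacing the DYS389II series by DYS389b and switching the attached
#'   panel to its DYS389b form.
#'
#' @param haps A \code{ystr_haplotypes} table on a panel carrying raw
#'   DYS389II.
#' @export
apply_dys389b <- function(haps) {
  panel <- active_panel(haps)
  if (panel$dys389b)
    stop("table already uses the DYS389b nomenclature")
  df <- as.data.frame(haps)
  df$DYS389b <- convert_dys389(df$DYS389I, df$DYS389II)
  df$DYS389II <- NULL
  ystr_haplotypes(df, ystr_panel(panel$name, dys389b = TRUE),
                  duplications = duplication_flags(haps))
}

#' Count typed series per individual
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @return Named integer vector of typed (non-missing) series counts.
#' @export
n_typed <- function(haps) {
  m <- .calls_matrix(haps)
  stats::setNames(as.integer(rowSums(!is.na(m))), rownames(m))
}

#' Filter haplotypes by missing-locus count
#'
#' Retains individuals with at most \code{max_missing} missing series out of
#' the active panel, preserving input order.  With the study default of 3
#' this is the rule that keeps partially typed ancient profiles informative
#' while bounding their loss of discrimination.
#'
#' @param haps A \code{ystr_haplotypes} table.
#' @param max_missing Non-negative integer (default 3).
#' @return The filtered \code{ystr_haplotypes} table.
#' @export
filter_by_missing <- function(haps, max_missing = 3) {
  stopifnot(max_missing >= 0)
  keep <- (panel_size(active_panel(haps)) - n_typed(haps)) <= max_missing
  out <- as.data.frame(haps)[keep, , drop = FALSE]
  rownames(out) <- NULL
  dups <- duplication_flags(haps)
  ystr_haplotypes(out, active_panel(haps),
                  duplications = dups[dups$sample_id %in% out$sample_id, ,
                                      drop = FALSE])
}

#' qPCR quantification QC record
#'
#' Computes the degradation index (DI), the ratio of the small to the large
#' autosomal target concentration from a quantification assay: fragmented
#' (ancient) DNA amplifies the small target preferentially, so larger DI
#' means more degradation.  The reported DI is rounded to the nearest
#' integer; the full-precision value is kept alongside.
#'
#' @param sample_id Sample identifiers.
#' @param small_target,large_target,y_target Concentrations (ng/ul);
#'   \code{NA} for not detected.
#' @param n_typed Optional count of successfully typed series.
#' @param panel_size Panel size used to bound \code{n_typed} (default 27).
#' @return A data frame of class \code{qc_record} with columns
#'   \code{degradation_index} (full precision, \code{NA} when the large
#'   target was absent) and \code{di_reported} (integer).
#' @examples
#' compute_qc("23-31", small_target = 0.0226, large_target = 0.0074,
#'            y_target = 0.0153)$di_reported   # 3
#' @export
compute_qc <- function(sample_id, small_target, large_target, y_target = NA,
                       n_typed = NA_integer_, panel_size = 27L) {
  conc <- c(small_target, large_target, y_target)
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentration")
  if (any(!is.na(n_typed) & (n_typed < 0 | n_typed > panel_size)))
    stop("n_typed outside [0, panel size]")
  di <- ifelse(!is.na(large_target) & large_target > 0,
               small_target / large_target, NA_real_)
  structure(
    data.frame(sample_id = as.character(sample_id),
               small_target = small_target, large_target = large_target,
               y_target = y_target, degradation_index = di,
               di_reported = as.integer(round(di)), n_typed = n_typed,
               stringsAsFactors = FALSE),
    class = c("qc_record", "data.frame"))
}

#' @export
`[.ystr_haplotypes` <- function(x, i, j, ...) {
  out <- NextMethod()
  panel <- attr(x, "panel")
  if (is.null(panel)) return(out)
  if (is.data.frame(out) &&
      all(c("sample_id", panel_series(panel)) %in% names(out))) {
    dups <- attr(x, "duplications")
    out <- ystr_haplotypes(
      as.data.frame(out), panel,
      duplications = dups[dups$sample_id %in% out$sample_id, , drop = FALSE])
  }
  out
}

#' @export
print.ystr_haplotypes <- function(x, ...) {
  p <- active_panel(x)
  cat(sprintf("ystr_haplotypes: %d individuals x %d series (panel %s)\n",
              nrow(x), panel_size(p), p$name))
  nt <- n_typed(x)
  cat(sprintf("  typed series per individual: %d-%d (median %g)\n",
              if (nrow(x)) min(nt) else 0L, if (nrow(x)) max(nt) else 0L,
              if (nrow(x)) stats::median(nt) else 0))
  d <- duplication_flags(x)
  if (nrow(d))
    cat(sprintf("  duplications at single-copy loci: %s\n",
                paste(sprintf("%s@%s(%s)", d$sample_id, d$series, d$alleles),
                      collapse = "; ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
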