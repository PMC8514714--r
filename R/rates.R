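#' Per-locus mutation rate tables
#'
#' A mutation rate table maps every allelic series of a panel to a
#' per-generation (per-meiosis) mutation probability.  The package bundles a
#' synthetic default table (see \code{default_mutation_rates}) in which RM
#' series mutate roughly an order of magnitude faster than core series, the
#' structure that motivates RM panels for separating close paternal
#' relatives.
#'
#' @param rates Named numeric vector: series name -> mutation probability in
#'   (0, 0.1].
#' @return An object of class \code{mutation_rates} (a named numeric vector).
#' @export
mutation_rate_table <- function(rates) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("mutation rates must be a named vector (series -> rate)")
  if (any(!is.finite(rates)) || any(rates <= 0) || any(rates > 0.1))
    stop("mutation rates must lie in (0, 0.1]")
  structure(rates, class = c("mutation_rates", "numeric"))
}

#' @rdname mutation_rate_table
#'
#' @details \code{default_mutation_rates} returns the bundled synthetic
#'   defaults: 2e-3 per generation for the 17 core series, 4e-3 for the
#'   additional non-RM Yfiler Plus series, and 1.2e-2 for the 7 RM series.
#'   These are stand-in values with a realistic rate hierarchy, not a
#'   published locus-specific table; substitute a measured table via
#'   \code{read_rate_table} for real casework.
#'
#' @param panel A \code{ystr_panel}.
#' @export
default_mutation_rates <- function(panel = ystr_panel()) {
  s <- panel_series(panel)
  r <- rep(2e-3, length(s))
  names(r) <- s
  if (panel$name == "YFILERPLUS27") {
    g <- panel_groups(panel)
    r[setdiff(g$additional10, g$rm7)] <- 4e-3
    r[g$rm7] <- 1.2e-2
  }
  mutation_rate_table(r)
}

#' @rdname mutation_rate_table
#' @param path Path to a two-column delimited text file (header
#'   \code{series}, \code{rate}).
#' @param sep Field delimiter.
#' @export
read_rate_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("series", "rate") %in% names(df)))
    stop("rate table must have columns 'series' and 'rate'")
  mutation_rate_table(stats::setNames(as.numeric(df$rate), df$series))
}

# Rates restricted to given series; errors naming any uncovered series.
.rates_for <- function(rates, series) {
  miss <- setdiff(series, names(rates))
  if (length(miss))
    stop("no mutation rate for series: ", paste(miss, collapse = ", "))
  as.numeric(rates[series])
}
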