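#' Configuration for chronological continuity verdicts
#'
#' @param window Chronological window of the ancient remains, in years
#'   before present, as \code{c(min_years, max_years)} (default
#'   \code{c(300, 500)}).
#' @param ci_level Credible-interval level used for the verdict (default
#'   0.50, the stringent choice: only pairs whose tight 50\% interval
#'   reaches the window count as continuous).
#' @param generation_time Years per generation (default 33).
#' @return A \code{continuity_config} list.
#' @export
continuity_config <- function(window = c(300, 500), ci_level = 0.50,
                              generation_time = 33) {
  stopifnot(length(window) == 2, window[1] > 0, window[1] < window[2],
            ci_level > 0, ci_level < 1, generation_time > 0)
  structure(list(window = window, ci_level = ci_level,
                 generation_time = generation_time),
            class = "continuity_config")
}

#' Continuity verdict for one pair
#'
#' A pair shows continuity when the decisive credible interval of the
#' years separating the two individuals overlaps the chronological window
#' of the ancient remains.  Intervals are closed: touching endpoints count
#' as overlap.
#'
#' @param years_posterior A \code{tmrca_posterior} in years separating the
#'   pair (see \code{\link{to_years}}), carrying a CI at the decisive
#'   level.
#' @param config A \code{\link{continuity_config}}.
#' @return One-row data frame: pair ids, decisive CI bounds and the
#'   logical \code{verdict}.
#' @export
assess_pair <- function(years_posterior, config = continuity_config()) {
  stopifnot(inherits(years_posterior, "tmrca_posterior"))
  key <- sprintf("%g%%", 100 * config$ci_level)
  if (!key %in% names(years_posterior$ci))
    stop("posterior carries no ", key, " credible interval")
  ci <- years_posterior$ci[[key]]
  verdict <- ci[1] <= config$window[2] && ci[2] >= config$window[1]
  data.frame(id_a = years_posterior$id_a %||% NA_character_,
             id_b = years_posterior$id_b %||% NA_character_,
             ci_low = ci[1], ci_high = ci[2],
             ci_level = config$ci_level,
             window_min = config$window[1], window_max = config$window[2],
             verdict = verdict, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Continuity matrix over ancient x modern pairs
#'
#' Applies \code{\link{assess_pair}} to every ancient-modern pair and
#' summarises per ancient individual: an ancient shows continuity when at
#' least one modern partner yields a positive verdict.
#'
#' @param tmrca A \code{tmrca_pairs} object (see \code{\link{tmrca_pairs}})
#'   whose \code{id_a} side is the ancient individuals, or a bare list of
#'   \code{tmrca_posterior} objects in years.
#' @param config A \code{\link{continuity_config}}.
#' @return An object of class \code{continuity_result}: list with
#'   \code{pairs} (verdict data frame), \code{per_ancient} (data frame of
#'   ancient id, number of flagged partners, flag) and
#'   \code{n_continuous}.
#' @export
continuity_matrix <- function(tmrca, config = continuity_config()) {
  posts <- if (inherits(tmrca, "tmrca_pairs"))
    lapply(tmrca$pairs, `[[`, "years") else tmrca
  pairs <- do.call(rbind, lapply(posts, assess_pair, config = config))
  if (is.null(pairs))
    pairs <- data.frame(id_a = character(), id_b = character(),
                        ci_low = numeric(), ci_high = numeric(),
                        ci_level = numeric(), window_min = numeric(),
                        window_max = numeric(), verdict = logical(),
                        stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  ancients <- unique(pairs$id_a)
  per_ancient <- data.frame(
    id = ancients,
    n_flagged_partners = vapply(ancients, function(a)
      sum(pairs$verdict[pairs$id_a == a]), integer(1)),
    stringsAsFactors = FALSE)
  per_ancient$continuous <- per_ancient$n_flagged_partners > 0L
  rownames(per_ancient) <- NULL
  structure(list(pairs = pairs, per_ancient = per_ancient,
                 n_continuous = sum(per_ancient$continuous),
                 config = config),
            class = "continuity_result")
}

#' @export
print.continuity_result <- function(x, ...) {
  cat(sprintf(
    "Continuity vs window [%g, %g] years (decisive CI %g%%):\n",
    x$config$window[1], x$config$window[2], 100 * x$config$ci_level))
  cat(sprintf("  %d of %d ancient individuals show continuity\n",
              x$n_continuous, nrow(x$per_ancient)))
  print(x$per_ancient)
  invisible(x)
}

#' Plot continuity intervals against the chronological window
#'
#' Horizontal bars of the per-pair credible intervals in years, with the
#' chronological window marked by dashed lines.
#'
#' @param x A \code{continuity_result}.
#' @param ... Passed to \code{plot}.
#' @export
plot.continuity_result <- function(x, ...) {
  p <- x$pairs
  if (!nrow(p)) {
    graphics::plot.new(); return(invisible(x))
  }
  ord <- order(p$ci_low)
  p <- p[ord, ]
  graphics::plot(NA, xlim = c(0, max(p$ci_high, x$config$window[2]) * 1.05),
                 ylim = c(0.5, nrow(p) + 0.5), xlab = "years separating pair",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(p)),
                 labels = paste(p$id_a, p$id_b, sep = " / "), las = 1,
                 cex.axis = 0.6)
  graphics::segments(p$ci_low, seq_len(nrow(p)), p$ci_high,
                     col = ifelse(p$verdict, "black", "grey60"), lwd = 3)
  graphics::abline(v = x$config$window, lty = 2, col = "red")
  invisible(x)
}
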