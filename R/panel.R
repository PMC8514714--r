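#' Y-STR panel definitions
#'
#' A panel is an ordered set of Y-STR markers together with their expected
#' copy number and rapidly-mutating (RM) status.  Two panels are bundled:
#' the 17-marker Yfiler panel (\code{"YFILER17"}) and the 27-series Yfiler
#' Plus panel (\code{"YFILERPLUS27"}), of which Yfiler is a subset.  The
#' multi-copy markers DYS385 and DYF387S1 expand into "a"/"b" allelic
#' series, and DYS389II can be carried either raw or in the DYS389b
#' nomenclature (DYS389II minus DYS389I).
#'
#' @param name Panel name, one of \code{"YFILERPLUS27"} or \code{"YFILER17"}.
#' @param dys389b Logical; if \code{TRUE} the panel carries the derived
#'   DYS389b series in place of raw DYS389II (the convention used for all
#'   statistical comparisons).
#' @return An object of class \code{ystr_panel}: a list with elements
#'   \code{name}, \code{markers} (data frame of marker, copies, rm),
#'   \code{series} (character vector of allelic series after multi-copy
#'   expansion) and \code{rm_series}.
#' @examples
#' p <- ystr_panel("YFILERPLUS27")
#' panel_size(p)            # 27
#' ystr_panel("YFILER17")$series
#' @export
ystr_panel <- function(name = c("YFILERPLUS27", "YFILER17"), dys389b = TRUE) {
  name <- match.arg(name)
  markers <- .yfiler_plus_markers()
  if (name == "YFILER17") {
    markers <- markers[markers$core17, , drop = FALSE]
  }
  series <- .expand_series(markers)
  if (dys389b) series[series == "DYS389II"] <- "DYS389b"
  rm_series <- intersect(series, .rm_series())
  structure(
    list(name = name, markers = markers, series = series,
         rm_series = rm_series, dys389b = dys389b),
    class = "ystr_panel")
}

# Yfiler Plus marker inventory: 23 single-copy + 2 double-copy markers
# -> 27 allelic series.  core17 marks Yfiler membership.
.yfiler_plus_markers <- function() {
  m <- data.frame(
    marker = c("DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390", "DYS391",
               "DYS392", "DYS393", "DYS437", "DYS438", "DYS439", "DYS448",
               "DYS456", "DYS458", "DYS635", "YGATAH4",
               "DYS460", "DYS481", "DYS533",
               "DYF387S1", "DYS449", "DYS518", "DYS570", "DYS576", "DYS627"),
    copies = 1L,
    stringsAsFactors = FALSE)
  m$copies[m$marker %in% c("DYS385", "DYF387S1")] <- 2L
  m$core17 <- m$marker %in% c(
    "DYS19", "DYS385", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456", "DYS458",
    "DYS635", "YGATAH4")
  m$rm <- m$marker %in% c("DYF387S1", "DYS449", "DYS518", "DYS570",
                          "DYS576", "DYS627")
  m
}

.rm_series <- function() {
  c("DYF387S1a", "DYF387S1b", "DYS449", "DYS518", "DYS570", "DYS576",
    "DYS627")
}

.expand_series <- function(markers) {
  unlist(lapply(seq_len(nrow(markers)), function(i) {
    if (markers$copies[i] == 2L)
      paste0(markers$marker[i], c("a", "b"))
    else
      markers$marker[i]
  }), use.names = FALSE)
}

#' @rdname ystr_panel
#' @param panel A \code{ystr_panel}.
#' @export
panel_size <- function(panel) length(panel$series)

#' @rdname ystr_panel
#' @export
panel_series <- function(panel) panel$series

#' Series groups of the Yfiler Plus panel
#'
#' Splits the series of a Yfiler Plus panel into the 17 core Yfiler series,
#' the 10 additional Yfiler Plus series, and the 7 RM series (a subset of
#' the additional ten).
#'
#' @param panel A \code{ystr_panel}; must be the 27-series panel.
#' @return A list with character vectors \code{core17}, \code{additional10}
#'   and \code{rm7}.
#' @export
panel_groups <- function(panel) {
  stopifnot(inherits(panel, "ystr_panel"))
  if (panel$name != "YFILERPLUS27")
    stop("panel_groups() is defined for the YFILERPLUS27 panel")
  core <- panel_series(ystr_panel("YFILER17", dys389b = panel$dys389b))
  list(core17 = core,
       additional10 = setdiff(panel$series, core),
       rm7 = panel$rm_series)
}

#' Test panel containment
#'
#' @param sub,full \code{ystr_panel} objects.
#' @return \code{TRUE} if every series of \code{sub} is a series of
#'   \code{full}.
#' @export
panel_subset <- function(sub, full) {
  all(panel_series(sub) %in% panel_series(full))
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat(sprintf("Y-STR panel %s: %d allelic series (%d markers, %d RM series)\n",
              x$name, length(x$series), nrow(x$markers),
              length(x$rm_series)))
  cat(strwrap(paste(x$series, collapse = ", "), indent = 2, exdent = 2),
      sep = "\n")
  invisible(x)
}
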