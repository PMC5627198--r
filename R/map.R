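#' Construct and validate a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker`, `chr`, `cM` (sex-averaged map position) and `Mb` (physical
#' position).  Markers must be sorted by chromosome and then by cM, with
#' non-decreasing cM within each chromosome, and marker names must be unique.
#' Reported QTL intervals are in Mb, obtained by linear interpolation of the
#' per-marker (cM, Mb) pairs, while all mapping is done on the cM grid.
#'
#' @param marker character vector of unique marker names, or a data frame
#'   with columns `marker`, `chr`, `cM`, `Mb` (other arguments then ignored).
#' @param chr chromosome labels (character or factor; "X" allowed).
#' @param cM map positions in centimorgans, non-negative.
#' @param Mb physical positions in megabases, non-negative.
#' @return A `genetic_map` object (a data frame).
#' @examples
#' genetic_map(c("m1", "m2"), chr = c("1", "1"), cM = c(0, 10), Mb = c(3, 21))
#' @export
genetic_map <- function(marker, chr = NULL, cM = NULL, Mb = NULL) {
  if (is.data.frame(marker)) {
    df <- marker
    need <- c("marker", "chr", "cM", "Mb")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop("genetic map lacks column(s): ", paste(missing_cols, collapse = ", "))
    df <- df[, need]
  } else {
    df <- data.frame(marker = as.character(marker), chr = as.character(chr),
                     cM = as.numeric(cM), Mb = as.numeric(Mb),
                     stringsAsFactors = FALSE)
  }
  df$marker <- as.character(df$marker)
  df$chr <- as.character(df$chr)
  validate_map(df)
  df <- df[order(chr_index(df$chr), df$cM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

validate_map <- function(df) {
  if (anyDuplicated(df$marker))
    stop("duplicate marker names: ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  if (any(!is.finite(df$cM)) || any(df$cM < 0))
    stop("cM positions must be finite and non-negative")
  if (any(!is.finite(df$Mb)) || any(df$Mb < 0))
    stop("Mb positions must be finite and non-negative")
  for (cc in unique(df$chr)) {
    x <- df$cM[df$chr == cc]
    if (is.unsorted(x[order(x)]))  # cannot happen after sort; kept for raw input
      stop("non-monotone cM on chromosome ", cc)
  }
  invisible(df)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x), "markers on",
      length(unique(x$chr)), "chromosome(s)\n")
  NextMethod()
}

# Chromosome ordering: numeric chromosomes first in numeric order, then X.
chr_index <- function(chr) {
  chr <- as.character(chr)
  n <- suppressWarnings(as.numeric(chr))
  n[is.na(n)] <- 1000 + as.numeric(factor(chr[is.na(n)], levels = c("X", "M")))
  n
}

#' Interpolate physical position from map position
#'
#' Linear interpolation of Mb from the (cM, Mb) marker pairs of one
#' chromosome; positions outside the marker range are clamped to the
#' terminal markers.
#'
#' @param map a [genetic_map()].
#' @param chr chromosome label.
#' @param cM map position(s) on that chromosome.
#' @return Mb position(s).
#' @export
interpolate_mb <- function(map, chr, cM) {
  m <- map[map$chr == as.character(chr), , drop = FALSE]
  if (nrow(m) == 0) stop("no markers on chromosome ", chr)
  if (nrow(m) == 1) return(rep(m$Mb, length(cM)))
  stats::approx(m$cM, m$Mb, xout = cM, rule = 2, ties = "ordered")$y
}

#' Default synthetic marker map for an RI panel
#'
#' A mouse-like marker grid: 19 autosomes plus X (no Y, as is usual for an
#' RI panel), with chromosome lengths between roughly 55 and 105 cM, markers
#' every `spacing_cM`, and physical positions at 1.9 Mb per cM.  This is a
#' synthetic stand-in grid for simulation and testing, not a real genotyping
#' platform.
#'
#' @param spacing_cM marker spacing in cM (default 10).
#' @return A [genetic_map()].
#' @export
default_map <- function(spacing_cM = 10) {
  chrs <- c(as.character(1:19), "X")
  len <- c(98, 103, 82, 88, 90, 79, 89, 76, 75, 77,
           88, 64, 67, 66, 59, 57, 61, 64, 56, 79)
  pieces <- lapply(seq_along(chrs), function(i) {
    cm <- seq(0, len[i], by = spacing_cM)
    data.frame(marker = sprintf("m%s_%03.0f", chrs[i], cm),
               chr = chrs[i], cM = cm, Mb = cm * 1.9,
               stringsAsFactors = FALSE)
  })
  genetic_map(do.call(rbind, pieces))
}
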