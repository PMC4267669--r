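#' Construct a chromatogram
#'
#' A chromatogram couples the called base sequence of a capillary read with the
#' four-channel peak heights recorded at each called position. It is the common
#' currency of the package: trace readers produce one, the synthetic generator
#' renders one, and [decompose_trace()] consumes a control/sample pair.
#'
#' IUPAC ambiguity codes other than `N` in the called bases are replaced by
#' `N`; calls are only used for alignment and display, the decomposition runs
#' on peak fractions.
#'
#' @param bases Called bases, a single string (or character vector of single
#'   characters) over `A,C,G,T,N`.
#' @param peaks Numeric `N x 4` matrix of non-negative peak heights, column
#'   order `A,C,G,T` (arbitrary fluorescence units).
#' @param source_id Free-text provenance tag (file name or synthetic seed tag).
#' @return An object of class `chromatogram`: a list with elements `bases`,
#'   `peaks` and `source_id`.
#' @examples
#' chromatogram("ACGT", diag(4) * 100)
#' @export
chromatogram <- function(bases, peaks, source_id = "") {
  if (is.character(bases) && length(bases) > 1L) {
    bases <- paste0(bases, collapse = "")
  }
  if (!is.character(bases) || length(bases) != 1L || is.na(bases) ||
      nchar(bases) < 1L) {
    stop("`bases` must be a non-empty nucleotide string", call. = FALSE)
  }
  bases <- toupper(bases)
  bvec <- strsplit(bases, "", fixed = TRUE)[[1L]]
  bvec[!bvec %in% c(CHANNELS, "N")] <- "N"
  bases <- paste0(bvec, collapse = "")
  peaks <- as.matrix(peaks)
  storage.mode(peaks) <- "double"
  if (ncol(peaks) != 4L) {
    stop("`peaks` must have 4 columns (A,C,G,T)", call. = FALSE)
  }
  if (nrow(peaks) != nchar(bases)) {
    stop(sprintf(
      "integrity error: %d called bases but %d peak rows",
      nchar(bases), nrow(peaks)
    ), call. = FALSE)
  }
  if (anyNA(peaks) || any(peaks < 0)) {
    stop("`peaks` must be non-negative and free of NA", call. = FALSE)
  }
  dimnames(peaks) <- list(NULL, CHANNELS)
  structure(
    list(bases = bases, peaks = peaks, source_id = as.character(source_id)[1L]),
    class = "chromatogram"
  )
}

#' @export
length.chromatogram <- function(x) nchar(x$bases)

#' Called bases of a chromatogram as a character vector
#'
#' @param x A [chromatogram()].
#' @return Character vector of single bases, one per position.
#' @export
base_calls <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  strsplit(x$bases, "", fixed = TRUE)[[1L]]
}

#' @export
print.chromatogram <- function(x, ...) {
  n <- length(x)
  cat(sprintf(
    "<chromatogram> %d positions%s\n", n,
    if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""
  ))
  show <- min(n, 60L)
  cat("  bases: ", substr(x$bases, 1L, show),
      if (n > show) "..." else "", "\n", sep = "")
  cat(sprintf("  peak height range: [%g, %g]\n",
              min(x$peaks), max(x$peaks)))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.chromatogram <- function(target, current, ...) {
  msg <- character(0)
  if (!inherits(current, "chromatogram")) return("current is not a chromatogram")
  if (target$bases != current$bases) msg <- c(msg, "called bases differ")
  pe <- all.equal(unname(target$peaks), unname(current$peaks), ...)
  if (!isTRUE(pe)) msg <- c(msg, pe)
  if (length(msg)) msg else TRUE
}

#' Normalize peak heights into per-position signal fractions
#'
#' Each row of the peak matrix is divided by its channel sum, so that the four
#' entries at a position give the relative abundance of each nucleotide's
#' signal there. Positions whose raw channel sum is zero (late-read signal
#' dropout) are masked and filled with a flat 0.25 per channel; the mask lets
#' downstream window selection and fitting skip those positions.
#'
#' Per-row normalization makes the result invariant to any per-trace or
#' per-row amplitude scaling, so raw and base-caller-rescaled peak heights
#' give the same fractions.
#'
#' @param x A [chromatogram()].
#' @return An object of class `signal_matrix`: list with `fractions`
#'   (`N x 4`, unmasked rows sum to 1) and `mask` (logical, `TRUE` where the
#'   raw row sum was zero).
#' @examples
#' sm <- normalize_peaks(chromatogram("AC", rbind(c(100, 0, 0, 0), c(2, 2, 2, 2))))
#' sm$fractions
#' @export
normalize_peaks <- function(x) {
  stopifnot(inherits(x, "chromatogram"))
  s <- rowSums(x$peaks)
  mask <- s == 0
  s[mask] <- 1
  fr <- x$peaks / s
  fr[mask, ] <- 0.25
  structure(list(fractions = fr, mask = mask), class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d positions, %d masked\n",
              nrow(x$fractions), sum(x$mask)))
  invisible(x)
}
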