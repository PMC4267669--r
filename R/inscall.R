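#' Infer the base composition of +1 insertions
#'
#' The first position 3' of the cut is the only one where the identity of a
#' single inserted base is unambiguous. The expected signal there from every
#' allele with fewer insertions — wild type and all deletions (which present
#' a downstream control base at that position) — is reconstructed from the
#' fitted coefficients and subtracted from the observed sample signal;
#' insertions of two or more bases, whose first inserted base is unknown,
#' contribute an uninformative flat quarter per channel. The residual, clipped
#' at zero and normalized, estimates the relative frequency with which each
#' nucleotide is the +1 insertion. The estimate is only reported as supported
#' when the fitted +1 frequency reaches `min_percentage` (default 1%, the
#' practical detection floor of the method).
#'
#' @param sample_signal,control_signal `signal_matrix` objects for the two
#'   traces.
#' @param result A `decomp_result` from [decompose_signal()].
#' @param site A `break_site`.
#' @param offset An `offset_alignment`.
#' @param min_percentage Minimum fitted +1 percentage for a supported call.
#' @return Object of class `insertion_composition`: list with `fraction`
#'   (named numeric over A,C,G,T summing to 1, or `NA` when unsupported),
#'   `supported`, `plus_one_percentage` and `note`.
#' @export
plus_one_composition <- function(sample_signal, control_signal, result, site,
                                 offset, min_percentage = 1.0) {
  stopifnot(inherits(sample_signal, "signal_matrix"),
            inherits(control_signal, "signal_matrix"),
            inherits(result, "decomp_result"),
            inherits(site, "break_site"),
            inherits(offset, "offset_alignment"))
  cut <- site$cut_index
  spec <- result$spectrum
  plus1 <- spec$percentage[spec$indel == 1]
  if (!length(plus1)) {
    stop("decomposition did not model a +1 insertion", call. = FALSE)
  }
  unsupported <- function(note) {
    structure(list(fraction = setNames(rep(NA_real_, 4L), CHANNELS),
                   supported = FALSE, plus_one_percentage = plus1,
                   note = note),
              class = "insertion_composition")
  }
  if (plus1 < min_percentage) {
    return(unsupported(sprintf(
      "+1 frequency %.2f%% below the %.1f%% support threshold",
      plus1, min_percentage)))
  }
  srow_i <- cut + offset$offset
  if (srow_i < 0L || srow_i >= nrow(sample_signal$fractions) ||
      sample_signal$mask[srow_i + 1L]) {
    return(unsupported("first post-cut position unreadable in the sample trace"))
  }
  observed <- sample_signal$fractions[srow_i + 1L, ]
  expected <- numeric(4L)
  for (j in seq_len(nrow(spec))) {
    k <- spec$indel[j]
    co <- spec$coefficient[j]
    if (co == 0 || k == 1) next
    if (k <= 0) {
      src <- cut + abs(k)                    # deletion -d shows control base cut+d
      if (src < nrow(control_signal$fractions)) {
        expected <- expected + co * control_signal$fractions[src + 1L, ]
      }
    } else {
      expected <- expected + co * rep(0.25, 4L)   # first base of a >= +2 insert unknown
    }
  }
  residual <- pmax(observed - expected, 0)
  if (sum(residual) <= 0) {
    return(unsupported(
      "no residual signal at the first post-cut position despite a fitted +1 component"))
  }
  structure(
    list(fraction = setNames(residual / sum(residual), CHANNELS),
         supported = TRUE, plus_one_percentage = plus1, note = ""),
    class = "insertion_composition"
  )
}

#' @export
print.insertion_composition <- function(x, ...) {
  if (x$supported) {
    cat(sprintf("<insertion_composition> +1 frequency %.1f%%: %s\n",
                x$plus_one_percentage,
                paste(sprintf("%s %.0f%%", names(x$fraction),
                              100 * x$fraction), collapse = ", ")))
  } else {
    cat(sprintf("<insertion_composition> unsupported (%s)\n", x$note))
  }
  invisible(x)
}
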