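# Local-alignment scoring used throughout: match +2, mismatch -1, and a gap
# of length L costs 5 + 2L. Strongly discourages gapped guide matches; an
# exact 20-mer scores 40.
SW_MATCH <- 2
SW_MISMATCH <- -1
SW_GAP_OPEN <- 5
SW_GAP_EXT <- 2

sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = SW_MATCH,
                                           mismatch = SW_MISMATCH,
                                           baseOnly = FALSE)
}

sw_local <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sw_submat(),
    gapOpening = SW_GAP_OPEN, gapExtension = SW_GAP_EXT
  )
}

#' Reverse complement of a nucleotide string
#'
#' @param x Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement as a string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Ungapped sliding scores of `pattern` at every start of `subject` (both
# character vectors of single bases); used to detect ambiguous guide matches
# in repetitive targets.
ungapped_scores <- function(pattern, subject) {
  np <- length(pattern)
  ns <- length(subject)
  if (ns < np) return(numeric(0))
  nstart <- ns - np + 1L
  m <- integer(nstart)
  for (j in seq_len(np)) {
    m <- m + (subject[j:(j + nstart - 1L)] == pattern[j])
  }
  SW_MATCH * m + SW_MISMATCH * (np - m)
}

#' Locate the expected nuclease cut site on the control trace
#'
#' Aligns the 20-nt guide (and its reverse complement) to the control called
#' bases by Smith-Waterman local alignment and places the expected blunt
#' SpCas9 cut 3 bp 5' of the PAM-proximal end of the protospacer, i.e.
#' between protospacer positions 17 and 18, mapped through the matched
#' orientation.
#'
#' A match is only accepted at >= `min_identity` identity over the guide
#' length. If the two orientations score equally, or the best ungapped score
#' is attained at more than one start (a repetitive target), the guide is
#' reported as not located.
#'
#' @param control A [chromatogram()] (the unedited control trace).
#' @param guide 20-nt guide/protospacer sequence over `A,C,G,T`.
#' @param min_identity Minimum fraction of identical bases in the match.
#' @return An object of class `break_site`: list with `cut_index` (0-based,
#'   the gap before this index is the cut), `strand` (`"forward"` or
#'   `"reverse"`), `guide_start` (0-based match start on the control) and
#'   `alignment_score`.
#' @export
locate_guide <- function(control, guide, min_identity = 0.9) {
  stopifnot(inherits(control, "chromatogram"))
  guide <- toupper(guide)
  if (nchar(guide) != 20L || !grepl("^[ACGT]{20}$", guide)) {
    stop("`guide` must be a 20-nt A/C/G/T string", call. = FALSE)
  }
  subject <- control$bases
  guide_rc <- reverse_complement(guide)
  pa_f <- sw_local(guide, subject)
  pa_r <- sw_local(guide_rc, subject)
  sf <- Biostrings::score(pa_f)
  sr <- Biostrings::score(pa_r)
  if (sf == sr) {
    stop(sprintf(
      "guide not found: forward and reverse orientations tie (scores %g, %g)",
      sf, sr
    ), call. = FALSE)
  }
  fwd <- sf > sr
  pa <- if (fwd) pa_f else pa_r
  ident <- Biostrings::nmatch(pa) / nchar(guide)
  if (ident < min_identity) {
    stop(sprintf(
      "guide not found: best match identity %.0f%% < %.0f%% (forward score %g, reverse score %g)",
      100 * ident, 100 * min_identity, sf, sr
    ), call. = FALSE)
  }
  # repetitive-target guard: the top ungapped score must be unique
  sv <- base_calls(control)
  us <- c(ungapped_scores(strsplit(guide, "", fixed = TRUE)[[1L]], sv),
          ungapped_scores(strsplit(guide_rc, "", fixed = TRUE)[[1L]], sv))
  if (sum(us == max(us)) > 1L) {
    stop("guide not found: multiple equally good matches (repetitive target)",
         call. = FALSE)
  }
  # 0-based start of the full matched orientation on the control, assuming the
  # (heavily gap-penalized) alignment is effectively ungapped
  g0 <- (Biostrings::start(Biostrings::subject(pa)) - 1L) -
    (Biostrings::start(Biostrings::pattern(pa)) - 1L)
  cut <- if (fwd) g0 + 17L else g0 + 3L
  if (cut <= 0L || cut >= length(control)) {
    stop("guide match places the cut outside the control read", call. = FALSE)
  }
  structure(
    list(cut_index = cut,
         strand = if (fwd) "forward" else "reverse",
         guide_start = g0,
         alignment_score = if (fwd) sf else sr),
    class = "break_site"
  )
}

#' @export
print.break_site <- function(x, ...) {
  cat(sprintf("<break_site> cut before position %d (1-based %d), %s strand, score %g\n",
              x$cut_index, x$cut_index + 1L, x$strand, x$alignment_score))
  invisible(x)
}

#' Coordinate offset between the control and sample reads
#'
#' Aligns the control region immediately upstream of the break site against
#' the sample called bases (Smith-Waterman local alignment) and reports the
#' shift mapping control coordinates to sample coordinates: a position `i` on
#' the control corresponds to `i + offset` on the sample. Because the probe
#' lies entirely 5' of the cut it is unaffected by editing, so a poor match
#' signals swapped or unrelated samples.
#'
#' @param control,sample [chromatogram()] objects.
#' @param site A `break_site` from [locate_guide()].
#' @param probe_len Length of the upstream probe (capped by the available
#'   upstream sequence).
#' @param min_identity Minimum identity of the probe match.
#' @return An object of class `offset_alignment`: list with `offset` (signed
#'   integer) and `alignment_score`.
#' @export
align_offset <- function(control, sample, site, probe_len = 100,
                         min_identity = 0.9) {
  stopifnot(inherits(control, "chromatogram"),
            inherits(sample, "chromatogram"),
            inherits(site, "break_site"))
  cut <- site$cut_index
  probe_start <- max(0L, cut - as.integer(probe_len))
  probe <- substr(control$bases, probe_start + 1L, cut)
  if (nchar(probe) < 10L) {
    stop("too little sequence upstream of the break to anchor the sample read",
         call. = FALSE)
  }
  pa <- sw_local(probe, sample$bases)
  ident <- Biostrings::nmatch(pa) / nchar(probe)
  if (ident < min_identity) {
    stop(sprintf(
      "sample does not match control upstream of break (identity %.0f%%): check that the traces belong to the same amplicon",
      100 * ident
    ), call. = FALSE)
  }
  offset <- (Biostrings::start(Biostrings::subject(pa)) - 1L) -
    (Biostrings::start(Biostrings::pattern(pa)) - 1L) - probe_start
  if (abs(offset) >= min(length(control), length(sample))) {
    stop("implausible offset between control and sample reads", call. = FALSE)
  }
  structure(list(offset = as.integer(offset),
                 alignment_score = Biostrings::score(pa)),
            class = "offset_alignment")
}

#' @export
print.offset_alignment <- function(x, ...) {
  cat(sprintf("<offset_alignment> control -> sample shift %+d, score %g\n",
              x$offset, x$alignment_score))
  invisible(x)
}
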