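#' Parameters for synthetic trace rendering
#'
#' Controls the statistical structure of synthetic chromatograms: overall
#' amplitude, exponential signal decay along the read, multiplicative
#' lognormal peak noise, and spectral cross-talk between dye channels. The
#' defaults emulate a clean capillary run: with them a pure-control
#' self-decomposition attains an R-squared above 0.99.
#'
#' @param base_amplitude Peak height at the first position, fluorescence
#'   units (> 0).
#' @param decay_rate Per-position exponential decay constant (>= 0); position
#'   `i` (0-based) carries amplitude `base_amplitude * exp(-decay_rate * i)`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied independently per channel per position (>= 0).
#' @param crosstalk Fraction in `[0, 0.3]` of a peak's height leaked uniformly
#'   into the other three channels.
#' @param seed Integer seed; rendering is deterministic given it.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(base_amplitude = 1000, decay_rate = 0.0015,
                         noise_cv = 0.05, crosstalk = 0.02, seed = 1L) {
  stopifnot(
    base_amplitude > 0,
    decay_rate >= 0,
    noise_cv >= 0,
    crosstalk >= 0, crosstalk <= 0.3
  )
  structure(
    list(base_amplitude = base_amplitude, decay_rate = decay_rate,
         noise_cv = noise_cv, crosstalk = crosstalk, seed = as.integer(seed)),
    class = "trace_params"
  )
}

# Evaluate expr under a local RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Describe a single indel
#'
#' @param size Signed integer: negative = deletion, positive = insertion,
#'   0 = wild type.
#' @param position 0-based cut-site coordinate; the gap before this index is
#'   the cut, so the indel acts immediately 3' of `position`.
#' @param inserted_bases For insertions, the inserted nucleotides (length must
#'   equal `size`); ignored for deletions.
#' @return A list of class `indel_spec`.
#' @export
indel_spec <- function(size, position, inserted_bases = "") {
  size <- as.integer(size)
  position <- as.integer(position)
  inserted_bases <- toupper(inserted_bases)
  if (size > 0L) {
    if (nchar(inserted_bases) != size ||
        !grepl("^[ACGT]+$", inserted_bases)) {
      stop("`inserted_bases` must be an A/C/G/T string of length `size`",
           call. = FALSE)
    }
  }
  structure(list(size = size, position = position,
                 inserted_bases = if (size > 0L) inserted_bases else ""),
            class = "indel_spec")
}

#' Apply an indel to a sequence
#'
#' Deletions remove `|size|` bases immediately 3' of the cut; insertions
#' insert `inserted_bases` immediately 3' of the cut; size 0 returns the
#' input unchanged.
#'
#' @param sequence Nucleotide string.
#' @param indel An [indel_spec()].
#' @return The mutated nucleotide string.
#' @examples
#' apply_indel("AACCGGTT", indel_spec(-2, 4))        # "AACCTT"
#' apply_indel("AACCGGTT", indel_spec(+1, 4, "G"))   # "AACCGGGTT"
#' @export
apply_indel <- function(sequence, indel) {
  stopifnot(inherits(indel, "indel_spec"))
  n <- nchar(sequence)
  pos <- indel$position
  if (pos < 0L || pos > n) {
    stop("cut position outside the sequence", call. = FALSE)
  }
  if (indel$size == 0L) return(sequence)
  left <- substr(sequence, 1L, pos)
  if (indel$size < 0L) {
    d <- -indel$size
    if (pos + d > n) {
      stop(sprintf("range error: deletion of %d bases at %d overruns the sequence end",
                   d, pos), call. = FALSE)
    }
    paste0(left, substr(sequence, pos + d + 1L, n))
  } else {
    paste0(left, indel$inserted_bases, substr(sequence, pos + 1L, n))
  }
}

# Deterministic (noise-free) N x 4 peak matrix for one sequence: decayed
# amplitude in the called channel, crosstalk leakage in the other three.
render_noiseless <- function(sequence, params) {
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  col <- match(b, CHANNELS)
  if (anyNA(col)) stop("sequence must be over A/C/G/T", call. = FALSE)
  n <- length(b)
  h <- params$base_amplitude * exp(-params$decay_rate * (seq_len(n) - 1L))
  peaks <- matrix(h * (params$crosstalk / 3), n, 4L)
  peaks[cbind(seq_len(n), col)] <- h * (1 - params$crosstalk)
  peaks
}

# Multiplicative lognormal noise with unit mean and CV = noise_cv, drawn
# independently per channel per position.
apply_peak_noise <- function(peaks, params) {
  if (params$noise_cv == 0) return(peaks)
  sdlog <- sqrt(log(1 + params$noise_cv^2))
  peaks * matrix(rlnorm(length(peaks), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                 nrow(peaks), ncol(peaks))
}

#' Render a synthetic chromatogram for one sequence
#'
#' Position `i` (0-based) carries height
#' `base_amplitude * exp(-decay_rate * i)` times a lognormal noise factor in
#' the called base's channel, with a `crosstalk` fraction leaked uniformly
#' into the other three channels. Deterministic given `params$seed`.
#'
#' @param sequence Non-empty nucleotide string over `A,C,G,T`.
#' @param params A [trace_params()].
#' @return A [chromatogram()].
#' @export
render_trace <- function(sequence, params = trace_params()) {
  mix_traces(sequence, 1, params)
}

#' Render a synthetic composite chromatogram from a mixture of alleles
#'
#' Emulates sequencing a bulk PCR product from an edited cell pool: each
#' component allele contributes its noise-free rendered peak matrix scaled by
#' its weight, the matrices are summed per position, and multiplicative noise
#' is applied once after mixing. Called bases are the per-position channel
#' argmax of the final matrix. Components shorter than the longest contribute
#' nothing past their own end. Component sequences are aligned at their shared
#' 5' end (amplicons share the sequencing primer), so with noise off the peak
#' matrix is exactly linear in the weights.
#'
#' @param sequences Character vector of component allele sequences.
#' @param weights Non-negative weights, one per component, summing to 1
#'   (within 1e-9).
#' @param params A [trace_params()].
#' @return A [chromatogram()] of length `max(nchar(sequences))`.
#' @export
mix_traces <- function(sequences, weights, params = trace_params()) {
  stopifnot(inherits(params, "trace_params"))
  sequences <- toupper(sequences)
  weights <- as.numeric(weights)
  if (length(sequences) != length(weights) || length(sequences) < 1L) {
    stop("`sequences` and `weights` must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("validation error: weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  lens <- nchar(sequences)
  L <- max(lens)
  peaks <- matrix(0, L, 4L)
  for (i in seq_along(sequences)) {
    if (weights[i] == 0) next
    m <- render_noiseless(sequences[i], params)
    peaks[seq_len(lens[i]), ] <- peaks[seq_len(lens[i]), ] + weights[i] * m
  }
  peaks <- with_seed(params$seed, apply_peak_noise(peaks, params))
  called <- CHANNELS[max.col(peaks, ties.method = "first")]
  chromatogram(called, peaks,
               source_id = sprintf("synthetic(seed=%d)", params$seed))
}

#' Random amplicon sequence
#'
#' Uniform i.i.d. bases; a convenience for simulations and tests.
#'
#' @param n Sequence length.
#' @param seed Integer seed.
#' @return A nucleotide string of length `n`.
#' @export
random_sequence <- function(n, seed = 1L) {
  with_seed(seed, paste0(sample(CHANNELS, n, replace = TRUE), collapse = ""))
}

#' Simulate a control/sample trace pair for an editing experiment
#'
#' Builds the full synthetic input to [decompose_trace()]: a control
#' chromatogram of the unedited amplicon and a composite sample chromatogram
#' mixing the wild type with indel alleles at given frequencies, with the cut
#' site derived from a guide embedded in the amplicon.
#'
#' @param amplicon Wild-type amplicon sequence.
#' @param guide_start 0-based start of the 20-nt protospacer on `amplicon`
#'   (forward strand); the cut is placed between protospacer positions 17 and
#'   18.
#' @param spectrum Data frame with columns `size` (signed indel size, 0 = wild
#'   type), `fraction` (allele frequencies, must sum to 1) and optionally
#'   `inserted_bases` for insertions (random bases drawn when absent or empty).
#' @param params A [trace_params()]; the control is rendered with `seed + 1`
#'   so the two traces carry independent noise.
#' @return List with `control` and `sample` chromatograms, the `guide`
#'   sequence, the 0-based `cut` index, and `truth` (the spectrum actually
#'   used, including drawn insertion bases).
#' @export
simulate_editing <- function(amplicon, guide_start, spectrum,
                             params = trace_params()) {
  amplicon <- toupper(amplicon)
  stopifnot(guide_start >= 0, guide_start + 20 <= nchar(amplicon))
  guide <- substr(amplicon, guide_start + 1L, guide_start + 20L)
  cut <- guide_start + 17L
  spectrum <- as.data.frame(spectrum)
  if (is.null(spectrum$inserted_bases)) spectrum$inserted_bases <- ""
  if (abs(sum(spectrum$fraction) - 1) > 1e-9) {
    stop("spectrum fractions must sum to 1", call. = FALSE)
  }
  ins_missing <- spectrum$size > 0 & !nzchar(spectrum$inserted_bases)
  if (any(ins_missing)) {
    spectrum$inserted_bases[ins_missing] <- with_seed(
      params$seed + 2L,
      vapply(spectrum$size[ins_missing],
             function(k) paste0(sample(CHANNELS, k, replace = TRUE),
                                collapse = ""),
             character(1))
    )
  }
  seqs <- vapply(seq_len(nrow(spectrum)), function(i) {
    apply_indel(amplicon, indel_spec(spectrum$size[i], cut,
                                     spectrum$inserted_bases[i]))
  }, character(1))
  control_params <- params
  control_params$seed <- params$seed + 1L
  list(
    control = render_trace(amplicon, control_params),
    sample = mix_traces(seqs, spectrum$fraction, params),
    guide = guide,
    cut = cut,
    truth = spectrum
  )
}
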