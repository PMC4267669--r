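#' Quantify the indel spectrum of an edited cell pool from two Sanger traces
#'
#' The main entry point. Given a control chromatogram (unedited cells), a
#' sample chromatogram (nuclease-treated pool of cells) and the 20-nt guide
#' sequence, it
#'
#' 1. locates the expected cut site by aligning the guide to the control
#'    ([locate_guide()]),
#' 2. determines the coordinate offset between the two reads from the
#'    sequence upstream of the break ([align_offset()]),
#' 3. selects the decomposition window ([default_window()]) and builds one
#'    shifted-control trace model per indel size in `{-n..+n}`
#'    ([build_models()]),
#' 4. fits the sample trace as a non-negative linear combination of the
#'    models ([decompose_signal()]), yielding per-indel frequencies, standard
#'    errors, p-values and R-squared,
#' 5. runs rule-of-thumb quality checks ([quality_check()]) and infers the
#'    base composition of +1 insertions ([plus_one_composition()]).
#'
#' @param control,sample [chromatogram()] objects or paths to trace files
#'   (passed to [read_trace()] with format auto-detection).
#' @param guide 20-nt guide sequence.
#' @param max_indel Largest indel size modelled (`n`); the spectrum covers
#'   `-n..+n`.
#' @param window Optional window override: integer vector `c(left, right)`
#'   in 0-based control-frame coordinates (left inclusive, right exclusive),
#'   e.g. to steer around a locally poor trace region.
#' @param alpha Two-tailed significance threshold for flagging an indel as
#'   detected.
#' @param probe_len Length of the upstream probe used to anchor the sample
#'   read.
#' @return An object of class `trace_decomp`; see [summary.trace_decomp()],
#'   [coef.trace_decomp()], [plot.trace_decomp()] and [write_report()].
#'   Key elements: `spectrum` (per-indel table), `r_squared`,
#'   `total_efficiency` (percentage of edited sequences), `insertion`
#'   (+1 base composition), `profile` (per-position aberrant signal),
#'   `quality` (warnings), `site`, `offset`, `window`.
#' @examples
#' sim <- simulate_editing(random_sequence(700, seed = 7), guide_start = 300,
#'                         spectrum = data.frame(size = c(0, -1),
#'                                               fraction = c(0.7, 0.3)),
#'                         params = trace_params(seed = 7))
#' fit <- decompose_trace(sim$control, sim$sample, sim$guide)
#' summary(fit)
#' @export
decompose_trace <- function(control, sample, guide, max_indel = 10,
                            window = NULL, alpha = 0.001, probe_len = 100) {
  cl <- match.call()
  if (is.character(control)) control <- read_trace(control)
  if (is.character(sample)) sample <- read_trace(sample)
  stopifnot(inherits(control, "chromatogram"), inherits(sample, "chromatogram"))
  n <- as.integer(max_indel)
  if (n < 1L) stop("`max_indel` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)

  site <- locate_guide(control, guide)
  offset <- align_offset(control, sample, site, probe_len = probe_len)

  control_signal <- normalize_peaks(control)
  sample_signal <- normalize_peaks(sample)

  win <- if (is.null(window)) {
    default_window(site, offset, length(control), length(sample), n)
  } else {
    w <- structure(list(left = as.integer(window[1L]),
                        right = as.integer(window[2L])),
                   class = "decomp_window")
    if (w$left <= site$cut_index || w$right <= w$left ||
        w$right + n > length(control)) {
      stop("window override violates the window invariants", call. = FALSE)
    }
    w
  }

  models <- build_models(control_signal, win, n)
  result <- decompose_signal(sample_signal, models, offset, alpha = alpha)

  # aberrant profile in the control frame, over positions covered by both reads
  L <- min(length(control),
           length(sample) - offset$offset,
           length(control) - max(0L, -offset$offset))
  pos <- 0:(L - 1L)
  spos <- pos + offset$offset
  usable <- spos >= 0L & spos < length(sample)
  pos <- pos[usable]
  ctrl_ab <- aberrant_signal(control_signal, control$bases)
  ref <- base_calls(control)[pos + 1L]
  col <- match(ref, CHANNELS)
  samp_ab <- rep(NA_real_, length(pos))
  ok <- !is.na(col) & !sample_signal$mask[pos + offset$offset + 1L]
  samp_ab[ok] <- 1 - sample_signal$fractions[cbind(pos[ok] + offset$offset + 1L,
                                                   col[ok])]
  profile <- data.frame(pos = pos, control = ctrl_ab[pos + 1L],
                        sample = samp_ab)

  quality <- quality_check(profile, result, site$cut_index)
  insertion <- plus_one_composition(sample_signal, control_signal, result,
                                    site, offset)

  structure(
    list(spectrum = result$spectrum,
         r_squared = result$r_squared,
         total_efficiency = result$total_efficiency,
         insertion = insertion,
         profile = profile,
         quality = quality,
         site = site,
         offset = offset,
         window = win,
         max_indel = n,
         alpha = alpha,
         df = result$df,
         observed = result$observed,
         fitted_values = result$fitted,
         residual_values = result$residuals,
         fit_warnings = result$warnings,
         control_id = control$source_id,
         sample_id = sample$source_id,
         call = cl),
    class = "trace_decomp"
  )
}

#' @export
print.trace_decomp <- function(x, ...) {
  cat("Sequence trace decomposition\n")
  cat(sprintf("  cut site: before position %d (1-based %d), %s strand\n",
              x$site$cut_index, x$site$cut_index + 1L, x$site$strand))
  cat(sprintf("  window:   [%d, %d) (0-based, control frame)\n",
              x$window$left, x$window$right))
  cat(sprintf("  R-squared: %.4f   total editing: %.1f%%\n",
              x$r_squared, x$total_efficiency))
  sig <- x$spectrum[x$spectrum$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  %d significant indel(s) at alpha = %g; see summary()\n",
                nrow(sig), x$alpha))
  } else {
    cat("  no significant indels\n")
  }
  if (length(x$quality)) {
    cat("  quality warnings:\n")
    for (w in x$quality) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a trace decomposition
#'
#' @param object A `trace_decomp` fit.
#' @param ... Unused.
#' @return The fit, invisibly, after printing the per-indel table (frequency,
#'   standard error, p-value, significance), goodness of fit, total editing
#'   efficiency, +1 insertion composition and any quality warnings.
#' @export
summary.trace_decomp <- function(object, ...) {
  structure(list(fit = object), class = "summary.trace_decomp")
}

#' @export
print.summary.trace_decomp <- function(x, ...) {
  f <- x$fit
  print(f)
  tab <- f$spectrum
  tab$percentage <- sprintf("%.2f", tab$percentage)
  tab$se <- sprintf("%.4f", tab$se)
  tab$p <- format.pval(tab$p, digits = 3)
  tab$sig <- ifelse(tab$significant, "*", "")
  cat("\nIndel spectrum (percentages rescaled to sum to 100 * R-squared):\n")
  print(tab[, c("indel", "percentage", "se", "p", "sig")], row.names = FALSE)
  cat("\n+1 insertion base composition:\n  ")
  print(f$insertion)
  invisible(x)
}

#' @describeIn decompose_trace Raw non-negative fit coefficients, named by
#'   signed indel size.
#' @param object,x A `trace_decomp` fit.
#' @param ... Unused.
#' @export
coef.trace_decomp <- function(object, ...) {
  setNames(object$spectrum$coefficient, sprintf("%d", object$spectrum$indel))
}

#' @describeIn decompose_trace Fitted values of the concatenated window
#'   signal vector.
#' @export
fitted.trace_decomp <- function(object, ...) object$fitted_values

#' @describeIn decompose_trace Residuals of the fit.
#' @export
residuals.trace_decomp <- function(object, ...) object$residual_values

#' Plot a trace decomposition
#'
#' Draws the three-step output: (1) the aberrant signal along both traces
#' with the expected cut site and the decomposition window; (2) the indel
#' spectrum as a bar chart (significant indels filled); (3) the +1 insertion
#' base composition, when supported.
#'
#' @param x A `trace_decomp` fit.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.trace_decomp <- function(x, ...) {
  op <- par(mfrow = c(1L, if (x$insertion$supported) 3L else 2L),
            mar = c(4.5, 4.5, 2.5, 1))
  on.exit(par(op))
  pr <- x$profile
  plot(pr$pos + 1L, 100 * pr$control, type = "l", col = "black",
       ylim = c(0, 100), xlab = "position (bp)", ylab = "aberrant signal (%)",
       main = "Aberrant sequence signal")
  lines(pr$pos + 1L, 100 * pr$sample, col = "forestgreen")
  rect(x$window$left + 1L, -2, x$window$right, 0,
       col = "grey60", border = NA)
  abline(v = x$site$cut_index + 1L, lty = 3, col = "blue")
  legend("topleft", legend = c("control", "sample"),
         col = c("black", "forestgreen"), lty = 1, bty = "n")
  sp <- x$spectrum
  cols <- ifelse(sp$significant, "firebrick", adjustcolor("grey40", 0.5))
  barplot(sp$percentage, names.arg = sp$indel, col = cols, border = NA,
          xlab = "indel size (bp)", ylab = "frequency (%)",
          main = sprintf("Indel spectrum (R² = %.3f)", x$r_squared))
  if (x$insertion$supported) {
    barplot(100 * x$insertion$fraction, col = "steelblue", border = NA,
            ylim = c(0, 100), xlab = "inserted base", ylab = "frequency (%)",
            main = "+1 insertion composition")
  }
  invisible(x)
}
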