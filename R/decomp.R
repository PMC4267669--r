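#' Per-position aberrant signal fraction
#'
#' At each position, the aberrant signal is the fraction of fluorescence not
#' attributable to the reference (control-called) base: `1 - fraction[i, ref_i]`.
#' In a clean unedited trace it hovers near zero; downstream of an efficient
#' cut it rises, saturating near 75% for a fully frame-shifted pool because a
#' random aberrant base still coincides with the reference one time in four.
#'
#' @param signal A `signal_matrix` from [normalize_peaks()].
#' @param reference_bases Reference base string (typically the control calls);
#'   truncated/recycled to the shorter of the two lengths.
#' @return Numeric vector of aberrant fractions in `[0,1]`; `NA` where the
#'   reference base is `N` or the signal row is masked.
#' @export
aberrant_signal <- function(signal, reference_bases) {
  stopifnot(inherits(signal, "signal_matrix"))
  ref <- strsplit(toupper(reference_bases), "", fixed = TRUE)[[1L]]
  n <- min(nrow(signal$fractions), length(ref))
  ref <- ref[seq_len(n)]
  col <- match(ref, CHANNELS)
  out <- rep(NA_real_, n)
  ok <- !is.na(col) & !signal$mask[seq_len(n)]
  idx <- cbind(seq_len(n)[ok], col[ok])
  out[ok] <- 1 - signal$fractions[idx]
  out
}

#' Default decomposition window
#'
#' The fit runs on a segment downstream of the break: from `n + 5` positions
#' after the cut to `n + 5` positions before the end of the shortest usable
#' read (`n` = maximum modelled indel size). The left margin guarantees that
#' for any insertion up to `+n`, every window position of the shifted model
#' is determined by known control sequence; the right margin keeps every
#' shifted model inside both reads.
#'
#' @param site A `break_site`.
#' @param offset An `offset_alignment` (control -> sample shift).
#' @param control_len,sample_len Read lengths in called bases.
#' @param n Maximum indel size modelled.
#' @return List of class `decomp_window` with `left` (inclusive) and `right`
#'   (exclusive), 0-based control-frame coordinates.
#' @export
default_window <- function(site, offset, control_len, sample_len, n = 10) {
  stopifnot(inherits(site, "break_site"), inherits(offset, "offset_alignment"))
  n <- as.integer(n)
  left <- site$cut_index + n + 5L
  right <- min(control_len, sample_len - offset$offset) - (n + 5L)
  min_width <- 10 * (2 * n + 1) / 4
  if (right <= left || (right - left) < min_width) {
    stop(sprintf(
      "reads too short for requested indel range: window [%d, %d) needs at least %.0f positions",
      left, right, ceiling(min_width)
    ), call. = FALSE)
  }
  structure(list(left = left, right = as.integer(right)),
            class = "decomp_window")
}

#' @export
print.decomp_window <- function(x, ...) {
  cat(sprintf("<decomp_window> [%d, %d) (0-based, control frame), width %d\n",
              x$left, x$right, x$right - x$left))
  invisible(x)
}

#' Build the shifted-trace indel model set
#'
#' One model column per indel size in `{-n..+n}`, constructed from the
#' control signal fractions by shifting all peaks by the indel size: at
#' window position `i`, a deletion of `d` bases reads the control at `i + d`
#' (downstream sequence slides left), an insertion of `k` bases reads
#' `i - k`, and size 0 is the unshifted control. The four per-base vectors
#' over the window are concatenated (block order A,C,G,T) into one column of
#' length `4 * width`.
#'
#' @param control_signal `signal_matrix` of the control trace.
#' @param window A `decomp_window`.
#' @param n Maximum indel size.
#' @return Object of class `indel_models`: list with `M` (`4W x (2n+1)`
#'   matrix, columns named by signed indel size), `labels` (integer sizes
#'   `-n..n`), `window`, `n`, and `control_mask` (logical over window
#'   positions).
#' @export
build_models <- function(control_signal, window, n = 10) {
  stopifnot(inherits(control_signal, "signal_matrix"),
            inherits(window, "decomp_window"))
  n <- as.integer(n)
  L <- nrow(control_signal$fractions)
  if (L < window$right + n) {
    stop(sprintf(
      "range error: control read (%d positions) too short for window right %d with indels up to %d",
      L, window$right, n
    ), call. = FALSE)
  }
  pos <- window$left:(window$right - 1L)      # 0-based control coordinates
  W <- length(pos)
  labels <- (-n):n
  M <- matrix(0, 4L * W, length(labels))
  for (j in seq_along(labels)) {
    src <- pos - labels[j]                    # deletion -d -> i + d; insertion +k -> i - k
    M[, j] <- as.vector(control_signal$fractions[src + 1L, ])
  }
  colnames(M) <- sprintf("%+d", labels)
  colnames(M)[labels == 0] <- "0"
  structure(
    list(M = M, labels = labels, window = window, n = n,
         control_mask = control_signal$mask[pos + 1L]),
    class = "indel_models"
  )
}

#' Decompose a composite sample trace over an indel model set
#'
#' The sample signal over the decomposition window (shifted into the control
#' frame) is modelled as a non-negative linear combination of the indel model
#' columns and resolved by non-negative least squares. Goodness of fit is the
#' ordinary R-squared about the mean of the observed vector. Standard errors
#' and two-tailed t-test p-values come from the unconstrained least-squares
#' variance-covariance matrix `sigma^2 (M'M)^-1` evaluated at the NNLS
#' solution, with `4W - (2n+1)` degrees of freedom; coefficients estimated at
#' the zero boundary are assigned p = 1. Finally the coefficients are
#' multiplied by one constant so their sum equals R-squared — absorbing any
#' systematic intensity difference between the two traces — and reported as
#' percentages.
#'
#' Window positions masked in either trace are dropped from the observation
#' vector and from every model column (consistently across the four base
#' blocks). Duplicate model columns (perfectly periodic control sequence)
#' make `M'M` singular: the affected indels get missing p-values and a
#' warning is recorded on the result.
#'
#' @param sample_signal `signal_matrix` of the sample trace (sample frame).
#' @param models An `indel_models` from [build_models()].
#' @param offset An `offset_alignment`; sample position = control position +
#'   offset.
#' @param alpha Significance threshold used for the `significant` flag.
#' @return Object of class `decomp_result`: list with `spectrum` (data frame:
#'   `indel`, `coefficient`, `percentage`, `se`, `p`, `significant`),
#'   `r_squared`, `total_efficiency` (summed percentage of all indels != 0),
#'   `window`, `df`, `fitted`, `residuals`, `observed` and `warnings`.
#' @export
decompose_signal <- function(sample_signal, models, offset, alpha = 0.001) {
  stopifnot(inherits(sample_signal, "signal_matrix"),
            inherits(models, "indel_models"),
            inherits(offset, "offset_alignment"))
  win <- models$window
  pos <- win$left:(win$right - 1L)
  spos <- pos + offset$offset
  if (min(spos) < 0L || max(spos) >= nrow(sample_signal$fractions)) {
    stop("sample read does not cover the decomposition window", call. = FALSE)
  }
  keep <- !(models$control_mask | sample_signal$mask[spos + 1L])
  if (sum(keep) < 10L) {
    stop("too few unmasked window positions to fit", call. = FALSE)
  }
  W <- length(pos)
  rows <- which(rep(keep, 4L))               # same positions in all 4 blocks
  y <- as.vector(sample_signal$fractions[spos + 1L, ])[rows]
  M <- models$M[rows, , drop = FALSE]

  fit <- pracma::lsqnonneg(M, y)
  coefs <- fit$x
  fitted <- as.vector(M %*% coefs)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else 1
  k <- ncol(M)
  df <- length(y) - k
  sigma2 <- rss / df

  warnings <- character(0)
  se <- rep(NA_real_, k)
  p <- rep(NA_real_, k)
  xtx <- crossprod(M)
  qr_x <- qr(xtx)
  if (qr_x$rank < k) {
    bad <- sort(qr_x$pivot[(qr_x$rank + 1L):k])
    warnings <- c(warnings, sprintf(
      "singular model matrix (repetitive control sequence?): no p-values for indel(s) %s",
      paste(colnames(M)[bad], collapse = ", ")
    ))
    good <- setdiff(seq_len(k), bad)
    if (length(good)) {
      vc_d <- diag(solve(xtx[good, good, drop = FALSE]))
      se[good] <- sqrt(sigma2 * vc_d)
    }
  } else {
    se <- sqrt(sigma2 * diag(solve(xtx)))
  }
  tstat <- coefs / se
  p <- 2 * pt(-abs(tstat), df)
  p[coefs == 0] <- 1                          # active-set boundary: no evidence
  p[is.na(se)] <- NA_real_
  p[se == 0 & coefs > 0] <- 0                 # exact fit

  scale <- if (sum(coefs) > 0) r2 / sum(coefs) else 0
  percentage <- 100 * coefs * scale
  spectrum <- data.frame(
    indel = models$labels,
    coefficient = coefs,
    percentage = percentage,
    se = se,
    p = p,
    significant = !is.na(p) & p < alpha,
    row.names = NULL
  )
  structure(
    list(spectrum = spectrum,
         r_squared = r2,
         total_efficiency = sum(percentage[models$labels != 0]),
         window = win,
         df = df,
         alpha = alpha,
         observed = y,
         fitted = fitted,
         residuals = resid,
         warnings = warnings),
    class = "decomp_result"
  )
}

#' @export
print.decomp_result <- function(x, digits = 3, ...) {
  cat(sprintf("<decomp_result> R-squared %.4f, total editing %.1f%%, window [%d, %d)\n",
              x$r_squared, x$total_efficiency, x$window$left, x$window$right))
  sig <- x$spectrum[x$spectrum$significant, c("indel", "percentage", "p")]
  if (nrow(sig)) {
    cat("significant indels:\n")
    print(format(sig, digits = digits), row.names = FALSE)
  } else {
    cat("no significant indels\n")
  }
  invisible(x)
}

#' Rule-of-thumb quality checks on a decomposition
#'
#' Flags the conditions under which a decomposition should be interpreted
#' with caution: pre-break background aberrant signal of 10% or more in
#' either trace (noisy reads or impure PCR product), R-squared at or below
#' 0.9, and an aberrant signal that fails to rise at the expected cut site
#' while editing is reported (possible misalignment or wrong guide).
#'
#' @param profile Data frame with columns `pos` (0-based control frame),
#'   `control` and `sample` aberrant fractions, as produced by
#'   [decompose_trace()] (`$profile`).
#' @param result A `decomp_result`.
#' @param cut_index 0-based cut coordinate on the control.
#' @return Character vector of warnings (length 0 when all checks pass).
#' @export
quality_check <- function(profile, result, cut_index) {
  stopifnot(inherits(result, "decomp_result"))
  warnings <- character(0)
  pre <- profile$pos < cut_index
  post <- profile$pos >= cut_index
  pre_ctrl <- mean(profile$control[pre], na.rm = TRUE)
  pre_samp <- mean(profile$sample[pre], na.rm = TRUE)
  post_samp <- mean(profile$sample[post], na.rm = TRUE)
  if (!is.nan(pre_ctrl) && pre_ctrl >= 0.10) {
    warnings <- c(warnings, sprintf(
      "high background: mean pre-break aberrant signal %.1f%% in the control trace (aim for < 10%%)",
      100 * pre_ctrl))
  }
  if (!is.nan(pre_samp) && pre_samp >= 0.10) {
    warnings <- c(warnings, sprintf(
      "high background: mean pre-break aberrant signal %.1f%% in the sample trace (aim for < 10%%)",
      100 * pre_samp))
  }
  if (result$r_squared <= 0.9) {
    warnings <- c(warnings, sprintf(
      "poor fit: R-squared %.3f <= 0.9; interpret the spectrum with caution",
      result$r_squared))
  }
  if (!is.nan(post_samp) && !is.nan(pre_samp) &&
      (post_samp - pre_samp) < 0.02 && result$total_efficiency > 5) {
    warnings <- c(warnings,
      "aberrant signal does not rise at the expected cut site despite reported editing: possible misalignment or wrong guide")
  }
  warnings
}
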