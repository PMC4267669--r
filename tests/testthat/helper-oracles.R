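# Independent oracles and small builders shared by the test files. These
# deliberately re-derive results by routes different from the package
# internals (dynamic programming written out by hand, explicit matrix
# arithmetic, exhaustive grid search).

BASES4 <- c("A", "C", "G", "T")

# Smith-Waterman local alignment score by explicit Gotoh dynamic programming:
# match +2, mismatch -1, a gap of length L costs 5 + 2L (same convention as
# the package's aligner).
sw_score_dp <- function(a, b, match = 2, mismatch = -1, open = 5, ext = 2) {
  a <- strsplit(a, "", fixed = TRUE)[[1L]]
  b <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)   # best ending at (i,j)
  E <- matrix(NEG, n + 1L, m + 1L) # gap in a (consuming b)
  F <- matrix(NEG, n + 1L, m + 1L) # gap in b (consuming a)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open - ext, E[i + 1L, j] - ext)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - open - ext, F[i, j + 1L] - ext)
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# Noise-free peak matrix, written out independently of the package renderer.
noiseless_matrix <- function(sequence, amplitude = 1000, decay = 0.0015,
                             crosstalk = 0.02) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(b)
  out <- matrix(0, n, 4L, dimnames = list(NULL, BASES4))
  for (i in seq_len(n)) {
    h <- amplitude * exp(-decay * (i - 1L))
    row <- rep(h * crosstalk / 3, 4L)
    row[match(b[i], BASES4)] <- h * (1 - crosstalk)
    out[i, ] <- row
  }
  out
}

# Exhaustive grid search minimising ||y - M w|| over non-negative w.
# For 2 columns the grid is the full square [0,1]^2; for 3 columns the grid
# is the face w1+w2+w3 = 1 of the simplex (adequate when y is an exact convex
# combination, where the global optimum attains zero residual on that face).
nnls_grid_oracle <- function(M, y, step = 1e-3) {
  k <- ncol(M)
  Q <- crossprod(M)
  b <- crossprod(M, y)
  g <- seq(0, 1, by = step)
  if (k == 2L) {
    obj <- outer(g^2 * Q[1, 1] - 2 * g * b[1],
                 g^2 * Q[2, 2] - 2 * g * b[2], "+") +
      2 * Q[1, 2] * outer(g, g)
    idx <- arrayInd(which.min(obj), dim(obj))
    c(g[idx[1]], g[idx[2]])
  } else if (k == 3L) {
    grid <- expand.grid(w1 = g, w2 = g)
    grid <- grid[grid$w1 + grid$w2 <= 1, ]
    w3 <- 1 - grid$w1 - grid$w2
    W <- cbind(grid$w1, grid$w2, w3)
    obj <- rowSums((W %*% Q) * W) - 2 * as.vector(W %*% b)
    W[which.min(obj), ]
  } else {
    stop("oracle supports 2 or 3 columns")
  }
}

# Evaluate expr under a fixed seed without disturbing the session RNG.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Hand-built break_site / offset_alignment objects for unit tests that do
# not need the aligners.
make_site <- function(cut, strand = "forward") {
  structure(list(cut_index = as.integer(cut), strand = strand,
                 guide_start = as.integer(cut) - 17L, alignment_score = 40),
            class = "break_site")
}

make_offset <- function(k = 0) {
  structure(list(offset = as.integer(k), alignment_score = 0),
            class = "offset_alignment")
}

# Standard synthetic editing experiment used across tests: random amplicon,
# guide embedded mid-read, given allele spectrum.
make_experiment <- function(seed, spectrum, len = 700, guide_start = 300,
                            noise_cv = 0.05, crosstalk = 0.02,
                            decay = 0.0015) {
  simulate_editing(
    random_sequence(len, seed = seed + 1000L),
    guide_start = guide_start,
    spectrum = spectrum,
    params = trace_params(noise_cv = noise_cv, crosstalk = crosstalk,
                          decay_rate = decay, seed = seed)
  )
}

expect_percentages <- function(fit, truth_sizes, truth_pct, tol) {
  for (i in seq_along(truth_sizes)) {
    got <- fit$spectrum$percentage[fit$spectrum$indel == truth_sizes[i]]
    expect_lt(abs(got - truth_pct[i]), tol,
              label = sprintf("|error| of indel %+d percentage", truth_sizes[i]))
  }
}
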