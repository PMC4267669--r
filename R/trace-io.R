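#' Read a capillary sequencing trace
#'
#' Reads a trace file into a [chromatogram()]. Three dialects are supported:
#'
#' * `abif` — Applied Biosystems `.ab1`. Called bases come from the `PBAS2`
#'   tag (fallback `PBAS1`), per-base peak sample indices from `PLOC2`
#'   (fallback `PLOC1`), the channel-to-base mapping from `FWO_1`, and peak
#'   heights are the values of the four analyzed-data channels `DATA9`–`DATA12`
#'   at each base's peak location.
#' * `scf` — SCF version 3.
#' * `fixture` — a plain-text, tab-separated dialect with header
#'   `pos base A C G T` and 1-based `pos`, intended for hand-editable test
#'   fixtures.
#'
#' @param path Path to the trace file.
#' @param format One of `"auto"` (detect from the file's magic bytes),
#'   `"abif"`, `"scf"`, `"fixture"`.
#' @return A [chromatogram()]; `source_id` is set to the file path.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format = c("auto", "abif", "scf", "fixture")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 4L)
    format <- if (length(magic) == 4L && rawToChar(magic) == "ABIF") {
      "abif"
    } else if (length(magic) == 4L && rawToChar(magic) == ".scf") {
      "scf"
    } else {
      "fixture"
    }
  }
  switch(format,
    abif = read_abif(path),
    scf = read_scf(path),
    fixture = read_fixture(path)
  )
}

#' Write a chromatogram to disk
#'
#' The fixture dialect round-trips bit-exactly through [read_trace()]; the
#' ABIF and SCF emitters write the minimal tag/section set the corresponding
#' readers consume, with peak heights rounded to integers (ABIF stores 16-bit
#' channel data).
#'
#' @param x A [chromatogram()].
#' @param path Output file path.
#' @param format One of `"fixture"`, `"abif"`, `"scf"`.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(x, path, format = c("fixture", "abif", "scf")) {
  stopifnot(inherits(x, "chromatogram"))
  format <- match.arg(format)
  switch(format,
    fixture = write_fixture(x, path),
    abif = write_abif(x, path),
    scf = write_scf(x, path)
  )
  invisible(path)
}

## ---- fixture dialect (TSV) -------------------------------------------------

write_fixture <- function(x, path) {
  b <- base_calls(x)
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    "pos\tbase\tA\tC\tG\tT",
    sprintf("%d\t%s\t%s\t%s\t%s\t%s",
            seq_along(b), b,
            num(x$peaks[, 1L]), num(x$peaks[, 2L]),
            num(x$peaks[, 3L]), num(x$peaks[, 4L]))
  )
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

read_fixture <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", quote = "",
               colClasses = c("integer", "character", "numeric", "numeric",
                              "numeric", "numeric"),
               comment.char = ""),
    error = function(e) {
      stop(sprintf("format error in fixture %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (!identical(names(tab), c("pos", "base", "A", "C", "G", "T"))) {
    stop(sprintf("format error in fixture %s: header must be 'pos base A C G T'",
                 path), call. = FALSE)
  }
  if (nrow(tab) < 1L || !identical(tab$pos, seq_len(nrow(tab)))) {
    stop(sprintf("integrity error in fixture %s: pos must run 1..N", path),
         call. = FALSE)
  }
  chromatogram(paste0(tab$base, collapse = ""),
               as.matrix(tab[, c("A", "C", "G", "T")]),
               source_id = path)
}

## ---- ABIF ------------------------------------------------------------------

# Raw-vector integer readers; ABIF is big-endian throughout.
rd_int <- function(raw, off, size, signed = TRUE) {
  if (off + size > length(raw)) {
    stop("integrity error: truncated ABIF record", call. = FALSE)
  }
  readBin(raw[(off + 1L):(off + size)], "integer", n = 1L, size = size,
          endian = "big", signed = signed)
}

rd_ints <- function(raw, off, size, n, signed = TRUE) {
  if (off + size * n > length(raw)) {
    stop("integrity error: truncated ABIF data block", call. = FALSE)
  }
  readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
          endian = "big", signed = signed)
}

parse_abif_entry <- function(raw, off) {
  if (off + 28L > length(raw)) {
    stop("integrity error: truncated ABIF directory", call. = FALSE)
  }
  name <- rawToChar(raw[(off + 1L):(off + 4L)])
  number <- rd_int(raw, off + 4L, 4L)
  type <- rd_int(raw, off + 8L, 2L)
  elsize <- rd_int(raw, off + 10L, 2L)
  nelem <- rd_int(raw, off + 12L, 4L)
  datasize <- rd_int(raw, off + 16L, 4L)
  # data <= 4 bytes is stored inline in the offset field
  data_off <- if (datasize <= 4L) off + 20L else rd_int(raw, off + 20L, 4L)
  if (data_off + datasize > length(raw)) {
    stop(sprintf("integrity error: ABIF tag %s%d points past end of file",
                 name, number), call. = FALSE)
  }
  list(name = name, number = number, type = type, elsize = elsize,
       nelem = nelem, datasize = datasize, data_off = data_off)
}

read_abif <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 34L || rawToChar(raw[1:4]) != "ABIF") {
    stop(sprintf("format error: %s is not an ABIF file", path), call. = FALSE)
  }
  # header: magic(4) version(2) then the 'tdir' entry
  ndir <- rd_int(raw, 18L, 4L)
  dir_off <- rd_int(raw, 26L, 4L)
  if (ndir < 1L) stop("integrity error: empty ABIF directory", call. = FALSE)
  entries <- lapply(seq_len(ndir) - 1L,
                    function(i) parse_abif_entry(raw, dir_off + 28L * i))
  find <- function(name, number) {
    for (e in entries) if (e$name == name && e$number == number) return(e)
    NULL
  }
  need <- function(name, numbers) {
    for (num in numbers) {
      e <- find(name, num)
      if (!is.null(e)) return(e)
    }
    stop(sprintf("format error: ABIF tag %s%s missing in %s",
                 name, paste(numbers, collapse = "/"), path), call. = FALSE)
  }
  pbas_e <- need("PBAS", c(2L, 1L))
  ploc_e <- need("PLOC", c(2L, 1L))
  fwo_e <- need("FWO_", 1L)
  bases <- rawToChar(raw[(pbas_e$data_off + 1L):(pbas_e$data_off + pbas_e$nelem)])
  ploc <- rd_ints(raw, ploc_e$data_off, 2L, ploc_e$nelem, signed = FALSE)
  fwo <- strsplit(rawToChar(raw[(fwo_e$data_off + 1L):(fwo_e$data_off + 4L)]),
                  "", fixed = TRUE)[[1L]]
  if (nchar(bases) != length(ploc)) {
    stop(sprintf(
      "integrity error: %d called bases but %d peak locations in %s",
      nchar(bases), length(ploc), path
    ), call. = FALSE)
  }
  n <- length(ploc)
  peaks <- matrix(0, n, 4L)
  for (ch in 1:4) {
    e <- need("DATA", 8L + ch)
    trace <- rd_ints(raw, e$data_off, 2L, e$nelem, signed = TRUE)
    if (any(ploc + 1L > length(trace))) {
      stop(sprintf("integrity error: peak location beyond DATA%d in %s",
                   8L + ch, path), call. = FALSE)
    }
    col <- match(fwo[ch], CHANNELS)
    if (is.na(col)) {
      stop(sprintf("format error: unexpected FWO_1 '%s' in %s",
                   paste(fwo, collapse = ""), path), call. = FALSE)
    }
    peaks[, col] <- pmax(trace[ploc + 1L], 0)
  }
  chromatogram(bases, peaks, source_id = path)
}

# Minimal ABIF emitter: the tag set read_abif consumes (DATA9-12, FWO_1,
# PLOC2, PBAS2), peaks placed at evenly spaced sample indices.
write_abif <- function(x, path) {
  n <- length(x)
  peaks <- round(x$peaks)
  if (any(peaks > 32767)) {
    stop("peak heights exceed the ABIF 16-bit channel range", call. = FALSE)
  }
  ploc <- as.integer((seq_len(n) - 1L) * 10L + 5L)
  nsamp <- max(ploc) + 6L
  fwo <- c("G", "A", "T", "C")  # conventional 3730 dye order
  channels <- lapply(1:4, function(ch) {
    v <- integer(nsamp)
    v[ploc + 1L] <- as.integer(peaks[, match(fwo[ch], CHANNELS)])
    v
  })

  i16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "big")
  i32 <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "big")
  entry <- function(name, number, type, elsize, nelem, payload) {
    list(name = name, number = number, type = type, elsize = elsize,
         nelem = nelem, payload = payload)
  }
  entries <- c(
    lapply(1:4, function(ch) {
      entry("DATA", 8L + ch, 4L, 2L, nsamp, i16(channels[[ch]]))
    }),
    list(
      entry("FWO_", 1L, 2L, 1L, 4L, charToRaw(paste0(fwo, collapse = ""))),
      entry("PBAS", 2L, 2L, 1L, n, charToRaw(x$bases)),
      entry("PLOC", 2L, 4L, 2L, n, i16(ploc))
    )
  )

  body <- raw(0)
  offs <- integer(length(entries))
  for (i in seq_along(entries)) {
    pl <- entries[[i]]$payload
    if (length(pl) > 4L) {
      offs[i] <- 128L + length(body)
      body <- c(body, pl)
    }
  }
  dir_off <- 128L + length(body)
  dir <- raw(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    sz <- length(e$payload)
    off_field <- if (sz <= 4L) {
      c(e$payload, raw(4L - sz))
    } else {
      i32(offs[i])
    }
    dir <- c(dir, charToRaw(e$name), i32(e$number), i16(e$type), i16(e$elsize),
             i32(e$nelem), i32(sz), off_field, i32(0L))
  }
  tdir <- c(charToRaw("tdir"), i32(1L), i16(1023L), i16(28L),
            i32(length(entries)), i32(length(dir)), i32(dir_off), i32(0L))
  header <- c(charToRaw("ABIF"), i16(101L), tdir)
  header <- c(header, raw(128L - length(header)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(header, body, dir), con)
}

## ---- SCF v3 ----------------------------------------------------------------

# SCF v3 stores each channel's samples double-delta encoded modulo 2^16.
scf_delta_encode <- function(v) {
  for (k in 1:2) v <- (v - c(0, v[-length(v)])) %% 65536
  v
}

scf_delta_decode <- function(v) {
  for (k in 1:2) v <- cumsum(v) %% 65536
  v
}

read_scf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L || rawToChar(raw[1:4]) != ".scf") {
    stop(sprintf("format error: %s is not an SCF file", path), call. = FALSE)
  }
  nsamp <- rd_int(raw, 4L, 4L)
  samp_off <- rd_int(raw, 8L, 4L)
  n <- rd_int(raw, 12L, 4L)
  bases_off <- rd_int(raw, 24L, 4L)
  version <- rawToChar(raw[37:40])
  sample_size <- rd_int(raw, 40L, 4L)
  if (substr(version, 1L, 1L) != "3") {
    stop(sprintf("format error: only SCF v3 is supported (file says '%s')",
                 version), call. = FALSE)
  }
  if (sample_size != 2L) {
    stop("format error: only 2-byte SCF samples are supported", call. = FALSE)
  }
  channels <- lapply(0:3, function(ch) {
    scf_delta_decode(rd_ints(raw, samp_off + 2L * nsamp * ch, 2L, nsamp,
                             signed = FALSE))
  })
  peak_idx <- rd_ints(raw, bases_off, 4L, n)
  base_raw_off <- bases_off + 4L * n + 4L * n  # peak indices + 4 accuracy arrays
  if (base_raw_off + n > length(raw)) {
    stop("integrity error: truncated SCF bases section", call. = FALSE)
  }
  bases <- rawToChar(raw[(base_raw_off + 1L):(base_raw_off + n)])
  if (any(peak_idx + 1L > nsamp)) {
    stop("integrity error: SCF peak index beyond sample array", call. = FALSE)
  }
  peaks <- vapply(1:4, function(ch) channels[[ch]][peak_idx + 1L], numeric(n))
  if (n == 1L) peaks <- matrix(peaks, 1L, 4L)
  chromatogram(bases, peaks, source_id = path)
}

write_scf <- function(x, path) {
  n <- length(x)
  peaks <- round(x$peaks)
  if (any(peaks > 65535)) {
    stop("peak heights exceed the SCF 16-bit sample range", call. = FALSE)
  }
  ploc <- as.integer((seq_len(n) - 1L) * 10L + 5L)
  nsamp <- max(ploc) + 6L
  i32 <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "big")
  i16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "big")
  samples <- raw(0)
  for (ch in 1:4) {  # SCF channel order is A,C,G,T
    v <- integer(nsamp)
    v[ploc + 1L] <- as.integer(peaks[, ch])
    samples <- c(samples, i16(scf_delta_encode(v)))
  }
  bases_sec <- c(i32(ploc), raw(4L * n), charToRaw(x$bases), raw(3L * n))
  bases_off <- 128L + length(samples)
  header <- c(
    charToRaw(".scf"),
    i32(nsamp), i32(128L), i32(n), i32(0L), i32(0L), i32(bases_off),
    i32(0L), i32(bases_off + length(bases_sec)),
    charToRaw("3.00"), i32(2L), i32(0L), i32(0L), i32(0L),
    raw(72L)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(header, samples, bases_sec), con)
}
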