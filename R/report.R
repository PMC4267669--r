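#' Write machine-readable report files for a decomposition
#'
#' Writes four files into `dir`:
#'
#' * `spectrum.tsv` — per-indel table (`indel`, `percentage`, `se`, `p`,
#'   `significant`);
#' * `profile.tsv` — per-position aberrant signal of both traces (`pos`,
#'   1-based, `control`, `sample`);
#' * `composition.tsv` — +1 insertion base fractions plus the `supported`
#'   flag;
#' * `report.json` — everything above bundled with provenance: input file
#'   MD5 hashes (when the inputs were files), all parameters, coordinates
#'   (1-based in user-facing output), quality warnings and the package
#'   version.
#'
#' @param x A `trace_decomp` fit from [decompose_trace()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "trace_decomp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, name) {
    write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  spec <- x$spectrum[, c("indel", "percentage", "se", "p", "significant")]
  tsv(spec, "spectrum.tsv")
  prof <- data.frame(pos = x$profile$pos + 1L,
                     control = x$profile$control,
                     sample = x$profile$sample)
  tsv(prof, "profile.tsv")
  comp <- data.frame(base = CHANNELS,
                     fraction = as.numeric(x$insertion$fraction),
                     supported = x$insertion$supported)
  tsv(comp, "composition.tsv")

  hash_if_file <- function(p) {
    if (is.character(p) && nzchar(p) && file.exists(p)) {
      unname(tools::md5sum(p))
    } else {
      NA_character_
    }
  }
  report <- list(
    tool = list(name = "tracedec",
                version = as.character(packageVersion("tracedec"))),
    inputs = list(
      control = list(id = x$control_id, md5 = hash_if_file(x$control_id)),
      sample = list(id = x$sample_id, md5 = hash_if_file(x$sample_id))
    ),
    parameters = list(max_indel = x$max_indel, alpha = x$alpha),
    cut_site = list(position = x$site$cut_index + 1L, strand = x$site$strand,
                    alignment_score = x$site$alignment_score),
    offset = x$offset$offset,
    window = list(left = x$window$left + 1L, right = x$window$right),
    r_squared = x$r_squared,
    total_efficiency = x$total_efficiency,
    spectrum = spec,
    insertion = list(supported = x$insertion$supported,
                     plus_one_percentage = x$insertion$plus_one_percentage,
                     fraction = as.list(x$insertion$fraction),
                     note = x$insertion$note),
    quality_warnings = as.list(x$quality),
    fit_warnings = as.list(x$fit_warnings)
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
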