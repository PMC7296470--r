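# The "middle file" interchange format and spreadsheet-readable PSD tables.
#
# A middle file is UTF-8 text: four header lines
#   #MIDDLE 1.0
#   #fs <sampling rate Hz>
#   #channels <M>
#   #labels <tab-separated M labels>
# followed by N data rows of M tab-separated decimal floats, sample-major
# (row = one time point across all channels). Numbers are rendered with 17
# significant digits so double-precision values round-trip bit-exactly.

MIDDLE_MAGIC <- "#MIDDLE 1.0"

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("eegwelch_format_error", "error")))
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a middle file
#'
#' Parses the plain-text multi-channel interchange format and returns one
#' [signal_channel()] per column. Any structural defect (missing magic
#' header, ragged row, non-numeric field, duplicate labels) raises a format
#' error of class `eegwelch_format_error` citing the file and, for row
#' defects, the 1-based line number.
#'
#' @param path path to the middle file.
#' @return A list with `fs` (Hz) and `channels` (list of `signal_channel`,
#'   all of equal length).
#' @export
read_middle <- function(path) {
  if (!file.exists(path)) {
    format_error(sprintf("middle file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || lines[1L] != MIDDLE_MAGIC) {
    format_error(sprintf(
      "%s: not a middle file (missing '%s' header)", path, MIDDLE_MAGIC
    ))
  }
  fs <- suppressWarnings(as.numeric(sub("^#fs\\s+", "", lines[2L])))
  if (!startsWith(lines[2L], "#fs ") || is.na(fs) || fs <= 0) {
    format_error(sprintf("%s: line 2 must be '#fs <positive number>'", path))
  }
  m <- suppressWarnings(as.integer(sub("^#channels\\s+", "", lines[3L])))
  if (!startsWith(lines[3L], "#channels ") || is.na(m) || m < 1L) {
    format_error(sprintf(
      "%s: line 3 must be '#channels <positive integer>'", path
    ))
  }
  lab_fields <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  if (lab_fields[1L] != "#labels" || length(lab_fields) != m + 1L) {
    format_error(sprintf(
      "%s: line 4 must be '#labels' followed by %d tab-separated labels",
      path, m
    ))
  }
  labels <- lab_fields[-1L]
  if (anyDuplicated(labels)) {
    format_error(sprintf(
      "%s: duplicate channel label '%s'", path, labels[duplicated(labels)][1L]
    ))
  }
  data_lines <- lines[-(1:4)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) {
    format_error(sprintf("%s: no data rows", path))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != m)) {
    bad <- which(n_fields != m)[1L]
    format_error(sprintf(
      "%s: line %d has %d fields, expected %d", path, bad + 4L,
      n_fields[bad], m
    ))
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(m)))
  vals <- if (m == 1L) matrix(vals, nrow = 1L) else vals # m rows x N cols
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[1L]
    format_error(sprintf(
      "%s: line %d contains a non-numeric field", path, bad + 4L
    ))
  }
  channels <- lapply(seq_len(m), function(j) {
    signal_channel(vals[j, ], fs = fs, label = labels[j])
  })
  list(fs = fs, channels = channels)
}

#' Write a middle file
#'
#' Writes channels column-wise in the middle-file dialect with 17-significant-
#' digit rendering, so `read_middle(write_middle(...))` reproduces every
#' double bit-exactly.
#'
#' @param fs sampling rate in Hz shared by all channels.
#' @param channels non-empty list of [signal_channel()] of equal length.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_middle <- function(fs, channels, path) {
  if (inherits(channels, "signal_channel")) channels <- list(channels)
  if (!length(channels)) stop("'channels' must be a non-empty list")
  if (!all(vapply(channels, inherits, logical(1L), "signal_channel"))) {
    stop("every element of 'channels' must be a signal_channel")
  }
  lens <- vapply(channels, function(ch) length(ch$samples), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop(sprintf(
      "all channels must have equal length; got lengths %s",
      paste(unique(lens), collapse = ", ")
    ))
  }
  labels <- vapply(channels, function(ch) ch$label, character(1L))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  mat <- vapply(channels, function(ch) ch$samples, numeric(lens[1L]))
  mat <- matrix(mat, nrow = lens[1L]) # N rows x M cols
  rows <- apply(mat, 1L, function(r) paste(fmt17(r), collapse = "\t"))
  writeLines(c(
    MIDDLE_MAGIC,
    sprintf("#fs %s", fmt17(fs)),
    sprintf("#channels %d", length(channels)),
    paste(c("#labels", labels), collapse = "\t"),
    rows
  ), path)
  invisible(path)
}

#' Write PSD results as a spreadsheet-readable table
#'
#' One row per frequency bin; first column `freq_hz`, then one column per
#' channel, delimited by tab (default) or comma for direct import into a
#' spreadsheet. All results must share one frequency axis.
#'
#' @param results list of `psd_result` objects (or a single one).
#' @param path output file path.
#' @param delimiter "\t" or ",".
#' @return `path`, invisibly.
#' @export
write_psd_table <- function(results, path, delimiter = "\t") {
  if (inherits(results, "psd_result")) results <- list(results)
  if (!length(results)) stop("'results' must be non-empty")
  if (!delimiter %in% c("\t", ",")) {
    stop("'delimiter' must be tab or comma")
  }
  freqs <- results[[1L]]$freqs
  same <- vapply(results, function(r) identical(r$freqs, freqs), logical(1L))
  if (!all(same)) {
    stop("all PSD results must share one frequency axis")
  }
  labels <- vapply(results, function(r) r$label, character(1L))
  header <- paste(c("freq_hz", labels), collapse = delimiter)
  cols <- c(list(freqs), lapply(results, function(r) r$psd))
  rows <- vapply(seq_along(freqs), function(i) {
    paste(fmt17(vapply(cols, `[`, numeric(1L), i)), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Batch-process a directory of middle files
#'
#' Computes the Welch PSD of every channel of every `*.middle` file in
#' `input_dir` (visited in lexicographic order) and writes one PSD table per
#' file into `output_dir`, named `<basename>.psd.tsv` (or `.psd.csv`). A
#' summary line per file (channels, segments, recording seconds) goes to
#' standard error. Unreadable files are logged and skipped; they are reported
#' in the returned summary. Numeric output is identical for every backend,
#' worker count and granularity.
#'
#' @param input_dir directory containing at least one middle file.
#' @param output_dir directory for the PSD tables (created if needed).
#' @param config a [welch_config()].
#' @param backend scheduler backend for the per-channel estimates.
#' @param n_workers worker count.
#' @param granularity "segment" (parallelize segments within each file, the
#'   framework's native mode) or "file" (one file per worker at a time,
#'   plumbing for very high file counts).
#' @param delimiter "\t" or "," for the output tables.
#' @return Invisibly, a list with `n_files`, `n_ok`, `n_failed`, `failed`
#'   (file names) and `outputs` (paths written).
#' @export
process_dir <- function(input_dir, output_dir, config = welch_config(),
                        backend = "serial", n_workers = 1L,
                        granularity = c("segment", "file"),
                        delimiter = "\t") {
  granularity <- match.arg(granularity)
  backend <- match.arg(backend, backend_names)
  if (!dir.exists(input_dir)) {
    stop(sprintf("input directory not found: %s", input_dir))
  }
  files <- sort(list.files(input_dir, pattern = "\\.middle$",
                           full.names = TRUE))
  if (!length(files)) {
    stop(sprintf("no middle files (*.middle) in %s", input_dir))
  }
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  ext <- if (delimiter == ",") ".psd.csv" else ".psd.tsv"
  process_one <- function(f, bk, w) {
    mf <- read_middle(f)
    res <- lapply(mf$channels, function(ch) {
      parallel_welch(ch, config, backend = bk, n_workers = w)
    })
    out <- file.path(
      output_dir, paste0(sub("\\.middle$", "", basename(f)), ext)
    )
    write_psd_table(res, out, delimiter)
    list(
      out = out, channels = length(mf$channels),
      segments = res[[1L]]$n_segments_used,
      seconds = length(mf$channels[[1L]]$samples) / mf$fs
    )
  }
  # file granularity distributes whole files across worker processes (each
  # file computed serially inside); segment granularity (the native mode)
  # parallelizes segments within each file. Either way every file goes
  # through the same per-channel path, so outputs are identical.
  safe_one <- function(f, bk, w) tryCatch(process_one(f, bk, w),
                                          error = function(e) e)
  infos <- if (granularity == "segment") {
    lapply(files, safe_one, bk = backend, w = n_workers)
  } else if (backend == "process" && n_workers > 1L) {
    parallel::mclapply(files, safe_one, bk = "serial", w = 1L,
                       mc.cores = n_workers)
  } else {
    lapply(files, safe_one, bk = "serial", w = 1L)
  }
  failed <- character(0L)
  outputs <- character(0L)
  for (k in seq_along(files)) {
    f <- files[k]
    info <- infos[[k]]
    if (inherits(info, "error") || inherits(info, "try-error")) {
      message(sprintf("ERROR %s: %s", basename(f), conditionMessage(info)))
      failed <- c(failed, basename(f))
    } else {
      message(sprintf(
        "%s: %d channels, %d segments, %g s", basename(f), info$channels,
        info$segments, info$seconds
      ))
      outputs <- c(outputs, info$out)
    }
  }
  invisible(list(
    n_files = length(files), n_ok = length(outputs),
    n_failed = length(failed), failed = failed, outputs = outputs
  ))
}
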