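#' Read a multi-channel recording from delimited text files
#'
#' Expects the per-channel layout `<subject>_<channel>.txt` (two delimited
#' columns: time in seconds, amplitude; whitespace- or comma-separated,
#' optional header line) plus `<subject>_states.txt` with one
#' `state,start,end` line per behavioural-state interval and an optional
#' `<subject>_meta.json` sidecar with `id`, `genotype`, `age_months`.
#'
#' The sampling rate of each channel is inferred from the median
#' inter-sample interval of its time column; a non-monotone time column is
#' an error, as is irregular sampling (any interval deviating from the
#' median by more than 1%). Non-finite amplitudes are retained and flagged
#' on the [sampled_signal]; cleaning is an explicit later step.
#'
#' @param path Directory containing the recording files.
#' @param subject Subject id (the filename prefix). If `NULL` and the
#'   directory holds exactly one `*_states.txt`, that subject is used.
#' @param channels Channel labels to look for. Missing channels produce a
#'   warning and a partial recording.
#' @return A [recording].
#' @export
read_recording <- function(path, subject = NULL,
                           channels = c("dia", "eic", "ps", "pressure")) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  if (is.null(subject)) {
    st_files <- list.files(path, pattern = "_states\\.txt$")
    if (length(st_files) != 1L)
      stop("subject not given and directory does not contain exactly one *_states.txt")
    subject <- sub("_states\\.txt$", "", st_files)
  }
  st_path <- file.path(path, paste0(subject, "_states.txt"))
  if (!file.exists(st_path)) stop("missing state annotation file: ", st_path)
  st <- utils::read.csv(st_path, header = FALSE,
                        col.names = c("state", "start", "end"),
                        stringsAsFactors = FALSE, strip.white = TRUE)
  states <- state_intervals(st$state, st$start, st$end)

  chans <- list()
  for (lab in channels) {
    f <- file.path(path, paste0(subject, "_", lab, ".txt"))
    if (!file.exists(f)) {
      warning("missing channel file for '", lab, "': ", f)
      next
    }
    chans[[lab]] <- read_signal_file(f, lab)
  }
  if (length(chans) == 0) stop("no channel files found for subject ", subject)

  meta <- list(id = subject, genotype = NA_character_, age_months = NA_real_)
  mf <- file.path(path, paste0(subject, "_meta.json"))
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    meta[names(m)] <- m
    meta$id <- subject
  }
  recording(chans, states, subject_meta = meta)
}

# Two-column (time s, amplitude) text file -> sampled_signal.
# EMG labels are expected in uV, pressure in cmH2O; a header that declares
# the other unit family is treated as a unit mismatch.
read_signal_file <- function(file, label) {
  expected_units <- if (identical(label, "pressure")) "cmH2O" else "uV"
  first <- readLines(file, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  if (has_header) {
    other <- if (identical(expected_units, "uV")) "cmh2o" else "uv|microvolt"
    if (grepl(other, tolower(first)))
      stop("unit mismatch for channel '", label, "' in ", file,
           " (expected ", expected_units, ")")
  }
  dt <- data.table::fread(file, header = has_header, sep = "auto",
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2) stop("expected two columns (time, amplitude) in ", file)
  tm <- as.numeric(dt[[1]]); amp <- as.numeric(dt[[2]])
  if (length(tm) < 2) stop("need at least 2 samples in ", file)
  dts <- diff(tm)
  if (any(dts <= 0)) stop("non-monotone time column in ", file)
  med <- stats::median(dts)
  if (max(abs(dts - med)) > 0.01 * med)
    stop("irregular sampling in ", file,
         " (max deviation exceeds 1% of the median interval)")
  sampled_signal(amp, rate = 1 / med, label = label, units = expected_units,
                 t0 = tm[1])
}

#' Write a recording in the per-channel text layout
#'
#' Emits `<id>_<channel>.txt` (time, amplitude; comma-separated, no
#' header, full double precision so that [read_recording()] round-trips
#' exactly), `<id>_states.txt` and `<id>_meta.json`.
#'
#' @param rec A [recording].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the subject id.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- rec$subject_meta$id
  for (ch in rec$channels) {
    tm <- signal_times(ch)
    f <- file.path(dir, paste0(id, "_", ch$label, ".txt"))
    # %.17g guarantees doubles survive the text round trip bit-exactly
    data.table::fwrite(data.table::data.table(time = sprintf("%.17g", tm),
                                              amplitude = sprintf("%.17g", ch$samples)),
                       f, col.names = FALSE, showProgress = FALSE, quote = FALSE)
  }
  utils::write.table(rec$states, file.path(dir, paste0(id, "_states.txt")),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(rec$subject_meta,
                       file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(id)
}

#' Write a long-format summary table deterministically
#'
#' Rows are sorted by (subject, muscle, state, metric) and written as CSV
#' with `NA` for missing values, so that identical inputs always yield
#' byte-identical files.
#'
#' @param rows A data.frame of result rows; must contain `subject`,
#'   `muscle`, `state`, `metric` columns (others are carried through).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_summary_table <- function(rows, path) {
  need <- c("subject", "muscle", "state", "metric")
  if (nrow(rows) > 0) {
    miss <- setdiff(need, names(rows))
    if (length(miss)) stop("summary rows lack column(s): ",
                           paste(miss, collapse = ", "))
    rows <- rows[order(rows$subject, rows$muscle, rows$state, rows$metric), ,
                 drop = FALSE]
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], function(v) { v[is.nan(v)] <- NA; v })
  }
  data.table::fwrite(rows, path, na = "NA", showProgress = FALSE)
  invisible(path)
}
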