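# I/O layer: recording container, delimited-text readers/writers, cohort
# manifest, long-format metric tables. The reader never filters, detrends
# or rescales: samples come back exactly as stored.

#' sEMG recording container
#'
#' Holds the raw samples of one surface-EMG channel for one
#' subject/muscle/session, together with the sampling rate and labels.
#' Amplitudes are kept in whatever units the instrument exported; every
#' downstream metric is a ratio to the fMVC calibration value, so absolute
#' units cancel.
#'
#' @param samples Numeric vector of amplitude values (zero-mean expected).
#' @param sampling_rate Sampling frequency in Hz (default 1000).
#' @param subject_id,group,muscle Character labels (may be `NA`).
#' @param session_kind One of `"work"`, `"baseline"`, `"fmvc_trial"`.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate = 1000,
                          subject_id = NA_character_, group = NA_character_,
                          muscle = NA_character_,
                          session_kind = c("work", "baseline", "fmvc_trial")) {
  session_kind <- match.arg(session_kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    semg_stop("recording has no samples", "semg_empty_input")
  if (!all(is.finite(samples)))
    semg_stop("recording contains non-finite samples", "semg_invalid_samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    semg_stop("sampling_rate must be a single positive number",
              "semg_invalid_argument")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         subject_id = subject_id, group = group, muscle = muscle,
         session_kind = session_kind),
    class = "emg_recording"
  )
}

#' Duration of a recording in seconds
#'
#' @param rec An [emg_recording()].
#' @return Length of the recording, `length(samples) / sampling_rate`.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  length(rec$samples) / rec$sampling_rate
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s / %s / %s [%s]\n",
              x$subject_id, x$group, x$muscle, x$session_kind))
  cat(sprintf("  %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sampling_rate, recording_duration(x)))
  invisible(x)
}

# Delimiter auto-detection from the header line: tab wins if present,
# otherwise comma, otherwise whitespace.
detect_delim <- function(header_line) {
  if (grepl("\t", header_line)) "\t"
  else if (grepl(",", header_line)) ","
  else ""
}

#' Read an sEMG recording from a delimited text file
#'
#' Reads one channel column from a comma- or tab-delimited text file with
#' a single header line (delimiter auto-detected from the header). The
#' samples are returned in file order with no resampling, filtering, or
#' rescaling. A column whose name matches `time` (case-insensitive) is
#' ignored after checking that it is monotone non-decreasing; sample
#' timing is implicit from `sampling_rate`.
#'
#' @param path Path to the signal file.
#' @param column Channel selector: column name or index. `NULL` (default)
#'   selects the single non-time column, and errors when the choice is
#'   ambiguous.
#' @param sampling_rate Sampling frequency in Hz.
#' @inheritParams emg_recording
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, column = NULL, sampling_rate = 1000,
                           subject_id = NA_character_, group = NA_character_,
                           muscle = NA_character_,
                           session_kind = c("work", "baseline", "fmvc_trial")) {
  session_kind <- match.arg(session_kind)
  if (!file.exists(path))
    semg_stop(sprintf("signal file not found: %s", path), "semg_io_error")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    semg_stop(sprintf("signal file is empty: %s", path), "semg_empty_input")
  sep <- detect_delim(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0L)
    semg_stop(sprintf("signal file has no data rows: %s", path),
              "semg_empty_input")
  time_cols <- grep("^time$", names(df), ignore.case = TRUE)
  if (length(time_cols)) {
    tv <- suppressWarnings(as.numeric(df[[time_cols[1L]]]))
    if (anyNA(tv) || is.unsorted(tv))
      semg_stop("time column is not monotone non-decreasing",
                "semg_parse_error")
  }
  if (is.null(column)) {
    candidates <- setdiff(seq_along(df), time_cols)
    if (length(candidates) != 1L)
      semg_stop(sprintf(
        "file %s has %d channel columns; supply `column` to choose one",
        path, length(candidates)), "semg_invalid_argument")
    column <- candidates
  }
  v <- if (is.character(column)) {
    if (!column %in% names(df))
      semg_stop(sprintf("column '%s' not found in %s", column, path),
                "semg_invalid_argument")
    df[[column]]
  } else df[[as.integer(column)]]
  if (is.null(v) || length(v) == 0L)
    semg_stop("selected column is empty", "semg_empty_input")
  x <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(x))
  if (length(bad))
    semg_stop(sprintf(
      "non-numeric or non-finite value at data row %d of %s ('%s')",
      bad[1L], path, v[bad[1L]]), "semg_parse_error")
  emg_recording(x, sampling_rate = sampling_rate, subject_id = subject_id,
                group = group, muscle = muscle, session_kind = session_kind)
}

#' Write a recording to a delimited text file
#'
#' One header line (`amplitude`) and one sample per row, at full
#' round-trip precision (15 significant digits).
#'
#' @param rec An [emg_recording()].
#' @param path Output path.
#' @param delim Field delimiter (irrelevant for the single-column layout,
#'   kept for symmetry with multi-channel exports).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delim = ",") {
  stopifnot(inherits(rec, "emg_recording"))
  con <- tryCatch(file(path, "w"), error = function(e)
    semg_stop(sprintf("cannot open %s for writing", path), "semg_io_error"))
  on.exit(close(con))
  writeLines("amplitude", con)
  writeLines(formatC(rec$samples, digits = 15, format = "g"), con)
  invisible(path)
}

#' Write a long-format metric table
#'
#' Writes per-subject metrics in the long layout consumed by the group
#' analysis: one header line, then one row per (group, subject, muscle,
#' metric, value) tuple, comma-delimited, in stable column order.
#'
#' @param rows Data frame with columns `group`, `subject_id` (or
#'   `subject`), `muscle`, `metric`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if ("subject_id" %in% names(rows) && !"subject" %in% names(rows))
    names(rows)[names(rows) == "subject_id"] <- "subject"
  need <- c("group", "subject", "muscle", "metric", "value")
  if (!all(need %in% names(rows)))
    semg_stop(sprintf("long table needs columns: %s",
                      paste(need, collapse = ", ")), "semg_invalid_argument")
  bad <- setdiff(unique(rows$metric), .semg_metrics)
  if (length(bad))
    semg_stop(sprintf("unknown metric name(s): %s",
                      paste(bad, collapse = ", ")), "semg_invalid_argument")
  out <- rows[, need]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    semg_stop(sprintf("cannot write %s", path), "semg_io_error")
  invisible(path)
}

#' Read a long-format metric table
#'
#' @param path Path written by [write_long_table()].
#' @return Data frame with columns `group`, `subject`, `muscle`, `metric`,
#'   `value`.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path))
    semg_stop(sprintf("metric table not found: %s", path), "semg_io_error")
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  need <- c("group", "subject", "muscle", "metric", "value")
  if (!all(need %in% names(df)))
    semg_stop("not a long-format metric table", "semg_parse_error")
  df[, need]
}

# --- cohort manifest ---------------------------------------------------

#' Cohort manifest
#'
#' Maps each subject x muscle pair to its work recording, baseline
#' recording and fMVC trial files, plus the subject's group. Paths are
#' interpreted relative to `root` (usually the manifest file's
#' directory).
#'
#' @param entries Data frame with columns `subject_id`, `group`, `muscle`,
#'   `work`, `baseline`, and `fmvc_trials` (a list-column of character
#'   vectors, or a single `;`-separated string per row).
#' @param sampling_rate Sampling frequency shared by the listed files.
#' @param metadata Named list of free-form metadata.
#' @param root Directory against which relative paths resolve.
#' @return An object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(entries, sampling_rate = 1000,
                            metadata = list(), root = ".") {
  entries <- as.data.frame(entries)
  need <- c("subject_id", "group", "muscle", "work", "baseline", "fmvc_trials")
  if (!all(need %in% names(entries)))
    semg_stop(sprintf("manifest entries need columns: %s",
                      paste(need, collapse = ", ")), "semg_invalid_argument")
  if (!is.list(entries$fmvc_trials))
    entries$fmvc_trials <- strsplit(as.character(entries$fmvc_trials), ";",
                                    fixed = TRUE)
  key <- paste(entries$subject_id, entries$muscle)
  if (anyDuplicated(key))
    semg_stop(sprintf("duplicate subject x muscle entry: %s",
                      key[duplicated(key)][1L]), "semg_invalid_argument")
  n_tr <- vapply(entries$fmvc_trials, length, integer(1))
  if (any(n_tr < 1L))
    semg_stop(sprintf("entry %s lists no fMVC trial files",
                      key[n_tr < 1L][1L]), "semg_invalid_argument")
  structure(
    list(entries = entries, sampling_rate = sampling_rate,
         metadata = metadata, root = root),
    class = "cohort_manifest"
  )
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d entries, %d subjects, groups: %s\n",
              nrow(x$entries), length(unique(x$entries$subject_id)),
              paste(unique(x$entries$group), collapse = ", ")))
  invisible(x)
}

#' Read a cohort manifest from YAML
#'
#' The manifest is a YAML file with top-level keys `sampling_rate`,
#' optional `metadata`, and `entries` -- a sequence of maps with keys
#' `subject_id`, `group`, `muscle`, `work`, `baseline`, `fmvc_trials`.
#'
#' @param path Path to the manifest file.
#' @return A [cohort_manifest()] rooted at the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    semg_stop(sprintf("manifest not found: %s", path), "semg_io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$entries) || !length(y$entries))
    semg_stop("manifest has no entries", "semg_parse_error")
  entries <- do.call(rbind, lapply(y$entries, function(e) {
    data.frame(subject_id = e$subject_id, group = e$group, muscle = e$muscle,
               work = e$work, baseline = e$baseline,
               fmvc_trials = I(list(unlist(e$fmvc_trials))),
               stringsAsFactors = FALSE)
  }))
  cohort_manifest(entries,
                  sampling_rate = if (is.null(y$sampling_rate)) 1000
                                  else y$sampling_rate,
                  metadata = if (is.null(y$metadata)) list() else y$metadata,
                  root = dirname(normalizePath(path)))
}

#' Write a cohort manifest to YAML
#'
#' @param manifest A [cohort_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  e <- manifest$entries
  y <- list(
    sampling_rate = manifest$sampling_rate,
    metadata = manifest$metadata,
    entries = lapply(seq_len(nrow(e)), function(i) list(
      subject_id = e$subject_id[i], group = e$group[i], muscle = e$muscle[i],
      work = e$work[i], baseline = e$baseline[i],
      fmvc_trials = as.list(e$fmvc_trials[[i]])
    ))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# Resolve a manifest-relative path.
manifest_path <- function(manifest, p) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(manifest$root, p))
}
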