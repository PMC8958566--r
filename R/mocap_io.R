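#' Marker trajectory tables
#'
#' A marker trajectory set holds the labelled 3D positions of facial markers
#' over the frames of one motion-capture trial. It is stored as a long tibble
#' with one row per (frame, marker):
#'
#' * `frame`: 0-based frame index
#' * `time_s`: time in seconds (strictly increasing across frames)
#' * `marker`: marker label
#' * `x`, `y`, `z`: coordinates in millimetres (`NA` when not reconstructed)
#' * `valid`: `TRUE` only when all three coordinates are present
#'
#' The nominal sample rate (Hz) is carried in the `sample_rate` attribute.
#' Frames where a marker was not reconstructed (gaps) keep their row with
#' `valid = FALSE`; gaps are never interpolated.
#'
#' @param df data frame with the columns above (`valid` optional; it is
#'   derived from missingness when absent).
#' @param sample_rate nominal sampling rate in Hz (default 120).
#' @return A `marker_traj` tibble.
#' @export
marker_traj <- function(df, sample_rate = 120) {
  stopifnot(is.data.frame(df))
  needed <- c("frame", "time_s", "marker", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("marker_traj: missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("marker_traj: sample_rate must be a single positive number")
  }
  out <- as_tibble(df)
  out$valid <- is.finite(out$x) & is.finite(out$y) & is.finite(out$z)
  # a partial coordinate triple has no usable 3D position
  out$x[!out$valid] <- NA_real_
  out$y[!out$valid] <- NA_real_
  out$z[!out$valid] <- NA_real_
  out <- dplyr::arrange(out, .data$frame, .data$marker)
  validate_marker_traj(out)
  structure(out,
            sample_rate = sample_rate,
            class = c("marker_traj", class(as_tibble(out))))
}

validate_marker_traj <- function(df) {
  per_marker <- dplyr::count(df, .data$marker)
  if (nrow(per_marker) > 0 && length(unique(per_marker$n)) > 1) {
    abort("marker_traj: all markers must share one frame count")
  }
  tt <- dplyr::distinct(df, .data$frame, .data$time_s)
  if (anyDuplicated(tt$frame)) {
    abort("marker_traj: frames carry inconsistent time stamps")
  }
  tt <- tt[order(tt$frame), ]
  if (nrow(tt) > 1 && any(diff(tt$time_s) <= 0)) {
    abort("marker_traj: time must be strictly increasing")
  }
  invisible(df)
}

#' @export
#' @rdname marker_traj
#' @param x object to query.
sample_rate <- function(x) attr(x, "sample_rate")

#' @export
#' @rdname marker_traj
marker_labels <- function(x) sort(unique(x$marker))

#' @export
#' @rdname marker_traj
n_frames <- function(x) length(unique(x$frame))

#' Read a marker-trajectory trial file
#'
#' Parses the wide tab-separated trajectory dialect: columns `frame`,
#' `time_s`, then `<label>_X`, `<label>_Y`, `<label>_Z` for each marker.
#' Empty fields or the literal `NaN` mark coordinates that were not
#' reconstructed; a frame with any missing coordinate of a marker's triple is
#' flagged invalid for that marker. No interpolation is performed.
#'
#' @param path path to a TSV trajectory file.
#' @param sample_rate nominal sampling rate in Hz (default 120).
#' @return A [marker_traj] tibble.
#' @export
read_trial <- function(path, sample_rate = 120) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "frame" || header[2] != "time_s") {
    abort(paste0("read_trial: malformed header in ", path,
                 ": expected 'frame\ttime_s' then marker triples"))
  }
  coord_cols <- header[-(1:2)]
  m <- regmatches(coord_cols, regexec("^(.*)_([XYZ])$", coord_cols))
  bad <- coord_cols[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0) {
    abort(paste0("read_trial: coordinate columns must end in _X/_Y/_Z; got: ",
                 paste(bad, collapse = ", ")))
  }
  labels <- vapply(m, `[`, "", 2L)
  axes <- vapply(m, `[`, "", 3L)
  for (lab in unique(labels)) {
    have <- sort(axes[labels == lab])
    if (!identical(have, c("X", "Y", "Z"))) {
      abort(paste0("read_trial: marker '", lab,
                   "' does not have a complete X/Y/Z column triple"))
    }
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                         na = c("", "NA", "NaN"), progress = FALSE)
  if (!identical(names(raw), header)) {
    abort(paste0("read_trial: data rows inconsistent with header in ", path))
  }
  if (nrow(raw) > 1 && any(diff(raw$time_s) <= 0)) {
    bad_line <- which(diff(raw$time_s) <= 0)[1] + 1L
    abort(paste0("read_trial: non-monotonic time at data line ", bad_line,
                 " of ", path))
  }
  if (length(coord_cols) == 0 || nrow(raw) == 0) {
    return(marker_traj(tibble(frame = integer(), time_s = numeric(),
                              marker = character(), x = numeric(),
                              y = numeric(), z = numeric()),
                       sample_rate = sample_rate))
  }
  long <- tidyr::pivot_longer(raw, cols = -c("frame", "time_s"),
                              names_to = c("marker", "axis"),
                              names_pattern = "^(.*)_([XYZ])$",
                              values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "axis", values_from = "value")
  names(wide)[names(wide) %in% c("X", "Y", "Z")] <- c("x", "y", "z")
  marker_traj(wide, sample_rate = sample_rate)
}

#' Write a marker-trajectory trial file
#'
#' Inverse of [read_trial()]: writes the wide TSV dialect. Invalid
#' marker-frames are written as empty fields, so the validity mask round-trips
#' bit-exactly; coordinates round-trip to `digits` decimals.
#'
#' @param set a [marker_traj] tibble.
#' @param path output path.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_trial <- function(set, path, digits = 6) {
  stopifnot(inherits(set, "marker_traj"))
  labs <- marker_labels(set)
  long <- tidyr::pivot_longer(as_tibble(set)[c("frame", "time_s", "marker",
                                               "x", "y", "z")],
                              cols = c("x", "y", "z"),
                              names_to = "axis", values_to = "value")
  long$axis <- toupper(long$axis)
  long$col <- paste(long$marker, long$axis, sep = "_")
  wide <- tidyr::pivot_wider(long[c("frame", "time_s", "col", "value")],
                             names_from = "col", values_from = "value")
  ordered_cols <- c("frame", "time_s",
                    as.vector(t(outer(labs, c("X", "Y", "Z"), paste, sep = "_"))))
  wide <- wide[ordered_cols]
  num_cols <- setdiff(ordered_cols, c("frame"))
  for (cn in num_cols) wide[[cn]] <- round(wide[[cn]], digits)
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write tidy feature / vocal / manifest tables
#'
#' Thin CSV wrappers with schema checks. `read_feature_table()` requires at
#' least `subject_id` and `condition` columns; all other columns are parsed
#' as numeric and a parse failure is reported with its row index.
#' `read_manifest()` additionally requires a `path` column (and keeps it as
#' character).
#'
#' @param path file path.
#' @param required required column names.
#' @return A tibble.
#' @export
read_feature_table <- function(path, required = c("subject_id", "condition")) {
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("read_feature_table: missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  value_cols <- setdiff(names(tbl), c("subject_id", "condition", "path",
                                      "parameter", "segment"))
  for (cn in value_cols) {
    if (is.character(tbl[[cn]])) {
      parsed <- suppressWarnings(as.numeric(tbl[[cn]]))
      bad <- which(!is.na(tbl[[cn]]) & is.na(parsed))
      # a mixed column is a corrupted numeric column; an all-text column is
      # a legitimate label column and is left alone
      if (length(bad) > 0 && length(bad) < sum(!is.na(tbl[[cn]]))) {
        abort(paste0("read_feature_table: column '", cn,
                     "' is not numeric at row(s) ",
                     paste(head(bad, 5), collapse = ", ")))
      }
      if (length(bad) == 0) tbl[[cn]] <- parsed
    }
  }
  tbl
}

#' @rdname read_feature_table
#' @param table tibble to write.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @export
read_manifest <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c("subject_id", "condition", "path"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("read_manifest: missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(tbl[c("subject_id", "condition")])
  if (any(dup)) {
    abort(paste0("read_manifest: duplicated (subject_id, condition) pairs: ",
                 paste(unique(paste(tbl$subject_id[dup], tbl$condition[dup],
                                    sep = "/")), collapse = ", ")))
  }
  tbl
}
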