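#' Read a long-format marker trajectory table
#'
#' Reads a marker CSV with columns `frame,marker,x_mm,y_mm,z_mm` (one row per
#' marker per frame, frame indices 0-based) and attaches the sampling rate.
#' Empty cells and NaN-like tokens (`NA`, `NaN`, `nan`, `""`) in the coordinate
#' columns are normalised to `NA` and kept: missing samples are flagged, never
#' silently dropped.
#'
#' @param path Path to the CSV file.
#' @param fps Sampling rate in frames per second (not inferred from the file).
#' @return A `marker_table`: a data.frame with columns `frame`, `marker`,
#'   `x`, `y`, `z` (millimetres) and attribute `fps`.
#' @export
read_marker_table <- function(path, fps) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  required <- c("frame", "marker", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("marker file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(df$frame) | is.na(df$marker) | df$frame < 0 |
                 df$frame != floor(df$frame))
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L] + 1L, " of ", path,
         " (frame must be a non-negative integer, marker non-missing)")
  }
  marker_table(frame = as.integer(df$frame), marker = as.character(df$marker),
               x = as.numeric(df$x_mm), y = as.numeric(df$y_mm),
               z = as.numeric(df$z_mm), fps = fps)
}

#' Construct a marker table from vectors
#'
#' Validates the duplicate-(frame, marker) integrity rule and sorts rows by
#' marker then frame so per-marker frame indices are strictly increasing.
#'
#' @param frame Integer frame indices (0-based).
#' @param marker Character marker identifiers.
#' @param x,y,z Coordinates in millimetres; `NA` marks missing samples.
#' @param fps Frames per second.
#' @return A `marker_table` data.frame.
#' @export
marker_table <- function(frame, marker, x, y, z, fps) {
  stopifnot(length(frame) == length(marker),
            length(frame) == length(x),
            length(frame) == length(y),
            length(frame) == length(z),
            fps > 0)
  key <- paste(frame, marker, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (frame, marker) pair: ",
         sub("\r", ", ", d, fixed = TRUE))
  }
  df <- data.frame(frame = as.integer(frame), marker = as.character(marker),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  df <- df[order(df$marker, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fps") <- as.numeric(fps)
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Write a marker table to CSV
#'
#' Inverse of [read_marker_table()]: emits `frame,marker,x_mm,y_mm,z_mm` with
#' missing coordinates as empty cells, full double precision.
#'
#' @param tab A `marker_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(tab, path) {
  out <- data.frame(frame = tab$frame, marker = tab$marker,
                    x_mm = tab$x, y_mm = tab$y, z_mm = tab$z)
  utils::write.csv(format_coord_df(out), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

# full-precision text rendering so read-back is bit-identical
format_coord_df <- function(df) {
  for (cl in c("x_mm", "y_mm", "z_mm")) {
    v <- df[[cl]]
    s <- formatC(v, format = "g", digits = 17)
    s[is.na(v)] <- NA_character_
    df[[cl]] <- s
  }
  df
}

#' Read a dyad metadata table
#'
#' Columns: `dyad_id,age_group,condition,climax_time_s,fps`. Age groups and
#' conditions must come from the declared enumerations (`3y`/`6y`,
#' `PAI`/`PII`).
#'
#' @param path CSV path.
#' @return A data.frame of class `dyad_metadata`.
#' @export
read_dyad_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dyad_id", "age_group", "condition", "climax_time_s", "fps")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dyad_metadata(df$dyad_id, df$age_group, df$condition, df$climax_time_s, df$fps)
}

#' Construct dyad metadata
#'
#' @param dyad_id Character dyad identifiers (unique).
#' @param age_group `"3y"` or `"6y"`.
#' @param condition `"PAI"` (predominantly affective) or `"PII"`
#'   (predominantly intellectual).
#' @param climax_time_s Story-climax time in seconds from recording start.
#' @param fps Frames per second of the recording.
#' @return A data.frame of class `dyad_metadata`.
#' @export
dyad_metadata <- function(dyad_id, age_group, condition, climax_time_s, fps) {
  age_group <- as.character(age_group)
  condition <- as.character(condition)
  if (!all(age_group %in% c("3y", "6y"))) {
    stop("age_group must be '3y' or '6y'")
  }
  if (!all(condition %in% c("PAI", "PII"))) {
    stop("condition must be 'PAI' or 'PII'")
  }
  if (anyDuplicated(dyad_id)) stop("dyad_id values must be unique")
  if (any(!is.finite(climax_time_s) | climax_time_s <= 0)) {
    stop("climax_time_s must be positive and finite")
  }
  if (any(!is.finite(fps) | fps <= 0)) stop("fps must be positive")
  df <- data.frame(dyad_id = as.character(dyad_id), age_group = age_group,
                   condition = condition,
                   climax_time_s = as.numeric(climax_time_s),
                   fps = as.numeric(fps), stringsAsFactors = FALSE)
  class(df) <- c("dyad_metadata", "data.frame")
  df
}

#' Write dyad metadata to CSV
#' @param meta A `dyad_metadata` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a marker labeling map
#'
#' Assigns each marker to an interactant (`child` / `storyteller`) and a body
#' region. Back-marker regions feed the analysis; `identifier` markers (the
#' rigid ID constellation on the lab coat) are metadata only and are excluded
#' from analysis streams.
#'
#' @param marker Character marker ids (each mapped at most once).
#' @param interactant `"child"` or `"storyteller"` per marker.
#' @param region One of `upper_back_left`, `upper_back_right`,
#'   `lower_back_left`, `lower_back_right`, `identifier`.
#' @return A data.frame of class `labeling_map`.
#' @export
labeling_map <- function(marker, interactant, region) {
  regions <- c("upper_back_left", "upper_back_right",
               "lower_back_left", "lower_back_right", "identifier")
  interactant <- as.character(interactant)
  region <- as.character(region)
  if (anyDuplicated(marker)) {
    stop("marker mapped twice in labeling map: ",
         marker[duplicated(marker)][1L])
  }
  if (!all(interactant %in% c("child", "storyteller"))) {
    stop("interactant must be 'child' or 'storyteller'")
  }
  if (!all(region %in% regions)) {
    stop("unknown region: ", setdiff(region, regions)[1L])
  }
  back <- region != "identifier"
  for (who in c("child", "storyteller")) {
    if (sum(back & interactant == who) < 1L) {
      stop("interactant '", who, "' has no back markers in the labeling map")
    }
  }
  df <- data.frame(marker = as.character(marker), interactant = interactant,
                   region = region, stringsAsFactors = FALSE)
  class(df) <- c("labeling_map", "data.frame")
  df
}

#' Read a labeling map from CSV (`marker,interactant,region`)
#' @param path CSV path.
#' @return A `labeling_map`.
#' @export
read_labeling_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labeling_map(df$marker, df$interactant, df$region)
}

#' Label a marker table and align it on a common frame range
#'
#' Partitions marker rows by interactant and body region according to the
#' labeling map, drops `identifier` markers from the analysis streams, and
#' completes every remaining marker over the common frame range (frames where
#' a marker has no row become missing samples). Coordinate values are never
#' altered.
#'
#' @param tab A `marker_table`.
#' @param labels A `labeling_map` covering every marker id present in `tab`.
#' @return A `labeled_recording`: list with elements `data` (long data.frame
#'   `frame, marker, interactant, region, x, y, z` on the complete frame
#'   grid), `frames` (common frame range), `fps`, `duration_s`, and
#'   `gap_report` (filled by [fill_gaps()]).
#' @export
apply_labels <- function(tab, labels) {
  stopifnot(inherits(tab, "marker_table"), inherits(labels, "labeling_map"))
  fps <- attr(tab, "fps")
  unlabeled <- setdiff(unique(tab$marker), labels$marker)
  if (length(unlabeled) > 0L) {
    stop("unlabeled marker(s) in table: ", paste(unlabeled, collapse = ", "))
  }
  idx <- match(tab$marker, labels$marker)
  keep <- labels$region[idx] != "identifier"
  df <- data.frame(frame = tab$frame[keep], marker = tab$marker[keep],
                   interactant = labels$interactant[idx][keep],
                   region = labels$region[idx][keep],
                   x = tab$x[keep], y = tab$y[keep], z = tab$z[keep],
                   stringsAsFactors = FALSE)
  for (who in c("child", "storyteller")) {
    if (!any(df$interactant == who)) {
      stop("interactant '", who, "' has zero back markers after labeling")
    }
  }
  frames <- seq(min(df$frame), max(df$frame))
  markers <- unique(df$marker)
  full <- expand.grid(frame = frames, marker = markers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- match(paste(full$frame, full$marker), paste(df$frame, df$marker))
  lab_idx <- match(full$marker, labels$marker)
  out <- data.frame(frame = full$frame, marker = full$marker,
                    interactant = labels$interactant[lab_idx],
                    region = labels$region[lab_idx],
                    x = df$x[m], y = df$y[m], z = df$z[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$marker, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(data = out, frames = frames, fps = fps,
                 duration_s = length(frames) / fps, gap_report = NULL),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  nmk <- length(unique(x$data$marker))
  cat("<labeled_recording> ", nmk, " markers, ",
      length(x$frames), " frames @ ", x$fps, " fps (",
      signif(x$duration_s, 4), " s)\n", sep = "")
  tab <- table(unique(x$data[, c("marker", "interactant")])$interactant)
  for (who in names(tab)) cat("  ", who, ": ", tab[[who]], " markers\n", sep = "")
  gr <- x$gap_report
  if (!is.null(gr)) {
    cat("  gaps remaining after fill: ", nrow(gr), "\n", sep = "")
  }
  invisible(x)
}

#' Fill short occlusion gaps by linear interpolation
#'
#' Missing runs of at most `max_gap_s` seconds are linearly interpolated per
#' marker and coordinate; longer runs (and runs touching the recording edges)
#' are left missing and listed in the gap report. Idempotent.
#'
#' @param rec A `labeled_recording`.
#' @param max_gap_s Maximum gap duration to interpolate, seconds (default
#'   0.25 s).
#' @return The recording with gaps filled; `$gap_report` is a data.frame
#'   (`marker, start_frame, end_frame, n_frames`) of remaining gaps and
#'   attribute-free flag `$any_unfilled`.
#' @export
fill_gaps <- function(rec, max_gap_s = 0.25) {
  stopifnot(inherits(rec, "labeled_recording"), max_gap_s >= 0)
  max_gap_frames <- floor(max_gap_s * rec$fps)
  df <- rec$data
  report <- list()
  for (mk in unique(df$marker)) {
    sel <- which(df$marker == mk)
    for (cl in c("x", "y", "z")) {
      v <- df[[cl]][sel]
      if (anyNA(v) && max_gap_frames > 0L) {
        v <- zoo::na.approx(v, maxgap = max_gap_frames, na.rm = FALSE)
      }
      df[[cl]][sel] <- v
    }
    miss <- is.na(df$x[sel]) | is.na(df$y[sel]) | is.na(df$z[sel])
    if (any(miss)) {
      r <- rle(miss)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gi <- which(r$values)
      report[[mk]] <- data.frame(
        marker = mk,
        start_frame = rec$frames[starts[gi]],
        end_frame = rec$frames[ends[gi]],
        n_frames = r$lengths[gi], stringsAsFactors = FALSE)
    }
  }
  rec$data <- df
  rec$gap_report <- if (length(report) > 0L) {
    out <- do.call(rbind, report)
    rownames(out) <- NULL
    out
  } else {
    data.frame(marker = character(), start_frame = integer(),
               end_frame = integer(), n_frames = integer(),
               stringsAsFactors = FALSE)
  }
  rec$any_unfilled <- nrow(rec$gap_report) > 0L
  rec
}

#' Fraction of frames with any missing back-marker sample
#'
#' Quality-control statistic used to exclude dyads with excessive occlusion
#' after gap filling.
#'
#' @param rec A `labeled_recording` (after [fill_gaps()]).
#' @return Fraction in \[0, 1\] of common-range frames where at least one
#'   analysis marker coordinate is missing.
#' @export
missing_fraction <- function(rec) {
  df <- rec$data
  miss <- is.na(df$x) | is.na(df$y) | is.na(df$z)
  bad_frames <- unique(df$frame[miss])
  length(bad_frames) / length(rec$frames)
}
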