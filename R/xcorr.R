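#' Uncentered cross-correlation coefficient of two speed signals
#'
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))` on Pearson scale, with no mean
#' centering: speed signals are zero-mean around rest, so the raw inner
#' product is used as printed. Pairs where either sample is missing are
#' excluded. Cauchy-Schwarz guarantees `r` in `[-1, 1]`.
#'
#' @param a,b Numeric vectors of equal length (n >= 2 complete pairs).
#' @param center If `TRUE`, subtract means first (sensitivity-analysis flag;
#'   default `FALSE`, the definitional form).
#' @return Correlation in `[-1, 1]`.
#' @export
xcorr_coef <- function(a, b, center = FALSE) {
  if (length(a) != length(b)) stop("signals must have equal length")
  ok <- !(is.na(a) | is.na(b))
  a <- as.numeric(a[ok]); b <- as.numeric(b[ok])
  if (length(a) < 2L) stop("insufficient overlap: fewer than 2 complete pairs")
  if (center) { a <- a - mean(a); b <- b - mean(b) }
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) stop("undefined correlation: a signal is all zero")
  r <- sum(a * b) / den
  min(1, max(-1, r))
}

#' Cross-correlation at a single delay
#'
#' Pairs `(s[t], c[t + lag])` with signal ends that do not overlap trimmed:
#' the storyteller's series is held fixed while the child's is offset, so a
#' positive lag asks whether the child moved as the storyteller had done
#' `lag` frames before. Negative lags (child leads) use the same machinery.
#'
#' @param storyteller,child `speed_signal`s (or numeric vectors) of equal
#'   length, frame-aligned at lag 0.
#' @param lag_frames Integer delay in frames (`abs(lag_frames) < n - 1`).
#' @param center Passed to [xcorr_coef()].
#' @return List with `r` (correlation, `NA` if undefined at this lag) and
#'   `m` (number of complete sample pairs used).
#' @export
xcorr_at_lag <- function(storyteller, child, lag_frames, center = FALSE) {
  s <- as.numeric(storyteller); c_ <- as.numeric(child)
  n <- length(s)
  if (length(c_) != n) stop("signals must have equal length")
  lag_frames <- as.integer(lag_frames)
  if (abs(lag_frames) >= n - 1L) {
    stop("insufficient overlap at lag ", lag_frames, " frames")
  }
  if (lag_frames >= 0L) {
    a <- s[seq_len(n - lag_frames)]
    b <- c_[seq.int(1L + lag_frames, n)]
  } else {
    a <- s[seq.int(1L - lag_frames, n)]
    b <- c_[seq_len(n + lag_frames)]
  }
  ok <- !(is.na(a) | is.na(b))
  m <- sum(ok)
  r <- tryCatch(xcorr_coef(a, b, center = center),
                error = function(e) NA_real_)
  list(r = r, m = m)
}

#' Lag grid for delayed cross-correlations
#'
#' Delays are specified in milliseconds and converted to whole frames by
#' round-to-nearest; the default grid (0 plus 100..1500 ms in 100 ms steps,
#' i.e. one simultaneous and 15 delayed correlations) is exact at 120 fps
#' (100 ms = 12 frames).
#'
#' @param lags_ms Numeric vector of delays in milliseconds (unique; sorted on
#'   construction). Positive delays mean the child trails the storyteller.
#' @param fps Frames per second.
#' @return A `lag_grid` data.frame with `lag_ms` and `lag_frames`.
#' @export
lag_grid <- function(lags_ms = default_lags_ms(), fps = 120) {
  stopifnot(fps > 0)
  lags_ms <- sort(unique(as.numeric(lags_ms)))
  lag_frames <- as.integer(round(lags_ms * fps / 1000))
  if (anyDuplicated(lag_frames)) {
    stop("lag grid collapses at ", fps, " fps: two delays round to the same frame")
  }
  structure(data.frame(lag_ms = lags_ms, lag_frames = lag_frames),
            fps = fps, class = c("lag_grid", "data.frame"))
}

#' Default delay grid: zero-lag plus 100..1500 ms
#' @return Numeric vector of 16 delays in milliseconds.
#' @export
default_lags_ms <- function() c(0, seq(100, 1500, by = 100))

#' Cross-correlation curve of one dyad over a lag grid
#'
#' One `(r, m)` pair per grid delay. Lags where the correlation is undefined
#' (a segment all zero after filtering) are recorded as `NA`, never
#' fabricated, and are excluded later from pooling.
#'
#' @param storyteller,child `speed_signal`s, frame-aligned at lag 0.
#' @param grid A `lag_grid` (defaults to the standard 16-point grid at the
#'   signal's fps).
#' @param dyad_id,segment Identification carried as attributes (`segment` is
#'   `"whole"`, `"pre"` or `"post"`).
#' @param center Passed to [xcorr_coef()].
#' @return An `xcorr_curve` data.frame: `lag_ms, lag_frames, r, m`.
#' @export
xcorr_curve <- function(storyteller, child,
                        grid = lag_grid(fps = attr(storyteller, "fps")),
                        dyad_id = NA_character_, segment = "whole",
                        center = FALSE) {
  res <- lapply(grid$lag_frames, function(L) {
    xcorr_at_lag(storyteller, child, L, center = center)
  })
  out <- data.frame(lag_ms = grid$lag_ms, lag_frames = grid$lag_frames,
                    r = vapply(res, `[[`, numeric(1), "r"),
                    m = vapply(res, function(x) as.numeric(x$m), numeric(1)))
  structure(out, dyad_id = dyad_id, segment = segment, fps = attr(grid, "fps"),
            class = c("xcorr_curve", "data.frame"))
}

#' Split a labeled recording at the story climax
#'
#' Partitions the common frame range at `floor(climax_time_s * fps)` frames
#' from the recording start into disjoint pre and post segments. Downstream
#' preprocessing (axis estimation, filtering) is re-run independently per
#' segment.
#'
#' @param rec A `labeled_recording`.
#' @param climax_time_s Climax time in seconds (strictly inside the
#'   recording); a single-row `dyad_metadata` may be given instead.
#' @return List with `pre` and `post` `labeled_recording`s.
#' @export
split_at_climax <- function(rec, climax_time_s) {
  if (inherits(climax_time_s, "dyad_metadata")) {
    climax_time_s <- climax_time_s$climax_time_s[1L]
  }
  cut_frame <- rec$frames[1L] + floor(climax_time_s * rec$fps)
  if (!(climax_time_s > 0) || cut_frame <= rec$frames[1L] ||
      cut_frame > rec$frames[length(rec$frames)]) {
    stop("climax time ", climax_time_s, " s lies outside the recording")
  }
  subset_rec <- function(frames) {
    structure(list(data = rec$data[rec$data$frame %in% frames, , drop = FALSE],
                   frames = frames, fps = rec$fps,
                   duration_s = length(frames) / rec$fps,
                   gap_report = rec$gap_report),
              class = "labeled_recording")
  }
  list(pre = subset_rec(rec$frames[rec$frames < cut_frame]),
       post = subset_rec(rec$frames[rec$frames >= cut_frame]))
}

#' Export one or more cross-correlation curves to CSV
#' @param curves A single `xcorr_curve` or a list of them.
#' @param path Output CSV path (`dyad_id,segment,lag_ms,r,m`).
#' @return `path`, invisibly.
#' @export
write_xcorr_curves <- function(curves, path) {
  if (inherits(curves, "xcorr_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(dyad_id = attr(cv, "dyad_id"), segment = attr(cv, "segment"),
               lag_ms = cv$lag_ms, r = cv$r, m = cv$m,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
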