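#' Average back markers into a torso centroid trajectory
#'
#' Per-frame unweighted mean of the available back-marker coordinates for one
#' interactant. Frames where some markers are missing use the mean of the
#' remaining ones; frames with no marker at all stay missing.
#'
#' @param rec A `labeled_recording`.
#' @param who `"child"` or `"storyteller"`.
#' @return A `torso_trajectory`: an n x 3 matrix (columns x, y, z, mm) with
#'   attributes `fps` and `who`; rows follow `rec$frames`.
#' @export
average_torso <- function(rec, who = c("child", "storyteller")) {
  who <- match.arg(who)
  df <- rec$data[rec$data$interactant == who & rec$data$region != "identifier", ]
  if (nrow(df) == 0L) stop("no back markers for interactant '", who, "'")
  nf <- length(rec$frames)
  markers <- unique(df$marker)
  acc <- matrix(0, nf, 3L)
  cnt <- matrix(0L, nf, 3L)
  for (mk in markers) {
    sub <- df[df$marker == mk, ]
    m <- cbind(sub$x, sub$y, sub$z)[match(rec$frames, sub$frame), , drop = FALSE]
    ok <- !is.na(m)
    m[!ok] <- 0
    acc <- acc + m
    cnt <- cnt + ok
  }
  out <- acc / cnt          # 0/0 -> NaN where no marker observed
  out[cnt == 0L] <- NA_real_
  colnames(out) <- c("x", "y", "z")
  structure(out, fps = rec$fps, who = who,
            class = c("torso_trajectory", class(out)))
}

#' Estimate the proximity axis between two interactants
#'
#' Unit vector from the time-mean centroid of `traj_a` to that of `traj_b`,
#' estimated once per analysis segment (the seating geometry is quasi-static;
#' a per-frame axis would leak partner motion into one's own projection).
#' Orientation signs are set so that motion toward the partner is positive for
#' both interactants.
#'
#' @param traj_a,traj_b `torso_trajectory` matrices for the two interactants.
#' @return A `proximity_axis`: list with `unit` (unit 3-vector a -> b),
#'   `sign_a` (+1: a approaches along `+unit`) and `sign_b` (-1).
#' @export
estimate_axis <- function(traj_a, traj_b) {
  ca <- colMeans(traj_a, na.rm = TRUE)
  cb <- colMeans(traj_b, na.rm = TRUE)
  d <- cb - ca
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len < 1) {
    stop("degenerate geometry: mean centroids closer than 1 mm")
  }
  structure(list(unit = d / len, sign_a = +1, sign_b = -1),
            class = "proximity_axis")
}

#' Project a torso trajectory onto the oriented proximity axis
#'
#' Scalar per-frame position `sign * (position . unit)`; increasing values
#' mean approaching the partner for both interactants (the sign convention
#' under which positive downstream correlations read as mirror-like, both
#' approach/both retreat, coordination).
#'
#' @param traj A `torso_trajectory`.
#' @param axis A `proximity_axis` from [estimate_axis()].
#' @param role `"a"` if `traj` was the first argument to [estimate_axis()],
#'   `"b"` otherwise.
#' @param shared_frame Debug flag: if `TRUE`, skip the per-interactant
#'   orientation and project both on the shared world axis (inverts the
#'   symmetric/asymmetric reading; for diagnostics only).
#' @return Numeric vector of 1D positions (mm), one per frame.
#' @export
project_axis <- function(traj, axis, role = c("a", "b"), shared_frame = FALSE) {
  role <- match.arg(role)
  s <- if (shared_frame) 1 else if (role == "a") axis$sign_a else axis$sign_b
  as.numeric(traj %*% axis$unit) * s
}

#' Discrete speed from a 1D position series
#'
#' First difference: `s[t] = pos[t] - pos[t-1]`, units mm/frame, length
#' `n - 1`. Speed (unlike position, which has an arbitrary origin) is
#' zero-mean around rest, which is what makes the uncentered correlation of
#' [xcorr_coef()] meaningful.
#'
#' @param pos Numeric 1D position series (length >= 2).
#' @param fps Frames per second (carried as an attribute).
#' @return A `speed_signal`: numeric vector with attribute `fps`.
#' @export
differentiate <- function(pos, fps = attr(pos, "fps")) {
  if (length(pos) < 2L) stop("position series too short to differentiate")
  structure(diff(as.numeric(pos)), fps = fps, class = "speed_signal")
}

#' Smoothing coefficient of the single-pole low-pass filter
#'
#' `alpha = dt / (RC + dt)` with `RC = 1 / (2 pi cutoff_hz)` and
#' `dt = 1 / fps`. At 120 fps and 10 Hz cutoff, `alpha` is approximately
#' 0.3437.
#'
#' @param fps Frames per second.
#' @param cutoff_hz Cutoff frequency, Hz; must lie in (0, fps/2).
#' @return The smoothing coefficient in (0, 1).
#' @export
lowpass_alpha <- function(fps, cutoff_hz) {
  if (!(cutoff_hz > 0 && cutoff_hz < fps / 2)) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  dt <- 1 / fps
  rc <- 1 / (2 * pi * cutoff_hz)
  dt / (rc + dt)
}

#' Single-pole low-pass filter for speed signals
#'
#' Causal first-order recursive smoother
#' `y[t] = y[t-1] + alpha * (s[t] - y[t-1])`, initialised `y[1] = s[1]` to
#' avoid a startup transient; unity DC gain. Single pass only (a "single
#' pole" filter; no zero-phase forward-backward filtering). Used to remove
#' recording artifacts above `cutoff_hz` before correlation.
#'
#' @param speed A `speed_signal` (or plain numeric vector with `fps` given).
#' @param cutoff_hz Cutoff frequency in Hz, default 10.
#' @param fps Frames per second; defaults to the signal's attribute.
#' @return Filtered `speed_signal`, same length and attributes.
#' @export
lowpass <- function(speed, cutoff_hz = 10, fps = attr(speed, "fps")) {
  if (is.null(fps)) stop("fps must be supplied or carried by the signal")
  a <- lowpass_alpha(fps, cutoff_hz)
  s <- as.numeric(speed)
  if (length(s) == 0L) return(speed)
  nas <- is.na(s)
  if (any(nas)) s[nas] <- 0   # residual gaps treated as rest; flagged upstream
  y <- stats::filter(a * s, filter = 1 - a, method = "recursive", init = s[1L])
  out <- as.numeric(y)
  out[nas] <- NA_real_
  structure(out, fps = fps, class = "speed_signal")
}

#' Reduce a labeled recording to one oriented speed signal per interactant
#'
#' The fixed processing order is: average back markers into a torso centroid,
#' project onto the oriented proximity axis (approach-positive), differentiate
#' to discrete speed (mm/frame), and low-pass filter. The axis is estimated
#' from this recording's own time-mean centroids, so pre/post-climax segments
#' get independent axes when processed separately.
#'
#' @param rec A `labeled_recording` (gap-filled).
#' @param cutoff_hz Low-pass cutoff in Hz (default 10); `NULL` skips the
#'   filter.
#' @return List with `storyteller` and `child` `speed_signal`s, plus the
#'   `axis` used.
#' @export
preprocess_dyad <- function(rec, cutoff_hz = 10) {
  tc <- average_torso(rec, "child")
  ts <- average_torso(rec, "storyteller")
  axis <- estimate_axis(tc, ts)
  pc <- project_axis(tc, axis, "a")
  ps <- project_axis(ts, axis, "b")
  sc <- differentiate(pc, rec$fps)
  ss <- differentiate(ps, rec$fps)
  if (!is.null(cutoff_hz)) {
    sc <- lowpass(sc, cutoff_hz)
    ss <- lowpass(ss, cutoff_hz)
  }
  list(storyteller = ss, child = sc, axis = axis)
}
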