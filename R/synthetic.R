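#' Configuration for one simulated dyad
#'
#' Describes a mocap-like recording of two seated interactants facing each
#' other: band-limited base torso motion for the storyteller, the child's
#' speed linearly coupled to the storyteller's at configurable delays (with a
#' possibly different coupling regime after the story climax), integration of
#' speeds to proximity-axis positions with a mild mean reversion (so seated
#' posture does not random-walk away), and embedding into 3D back-marker
#' constellations with measurement jitter.
#'
#' Coupling gains act on approach-axis *speeds*: a positive gain makes the
#' child approach when the storyteller approaches (symmetric, mirror-like
#' coordination, positive downstream correlation); a negative gain gives
#' asymmetric coordination.
#'
#' @param fps Frames per second (default 120).
#' @param duration_s Session length in seconds (default 300 s, a five-minute
#'   storytelling session).
#' @param climax_time_s Story-climax time (default mid-session).
#' @param base_sd Stationary standard deviation of the storyteller's base
#'   speed, mm/frame (default 1).
#' @param base_phi AR(1) smoothness of the base speed in `[0, 1)` (default
#'   0.95, roughly 1 Hz postural-sway bandwidth at 120 fps; 0 gives white
#'   noise).
#' @param coupling_pre,coupling_post Data.frames `lag_ms, gain` (see
#'   [coupling()]); defaults: no coupling before the climax, a single
#'   positive coupling at 500 ms after it.
#' @param noise_sd Standard deviation of the child's own (uncoupled) speed
#'   component, mm/frame (default 1).
#' @param seat_distance_mm Distance between the two torso centroids
#'   (default 1500 mm).
#' @param marker_jitter_sd Per-coordinate Gaussian marker jitter, mm
#'   (default 0.5 mm, just above an optical system's resolution floor).
#' @param drift Mean-reversion coefficient for integrating speed to position
#'   (default 0.999; 1 = pure integration).
#' @param seed RNG seed for this dyad.
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(fps = 120, duration_s = 300,
                            climax_time_s = duration_s / 2,
                            base_sd = 1, base_phi = 0.95,
                            coupling_pre = coupling(),
                            coupling_post = coupling(500, 1),
                            noise_sd = 1, seat_distance_mm = 1500,
                            marker_jitter_sd = 0.5, drift = 0.999,
                            seed = 1L) {
  stopifnot(fps > 0, duration_s > 0,
            climax_time_s > 0, climax_time_s < duration_s,
            base_sd >= 0, base_phi >= 0, base_phi < 1,
            noise_sd >= 0, marker_jitter_sd >= 0,
            drift > 0, drift <= 1)
  if (seat_distance_mm <= 0) stop("invalid geometry: seat distance must be positive")
  for (cp in list(coupling_pre, coupling_post)) {
    if (nrow(cp) > 0L && any(round(cp$lag_ms * fps / 1000) < 0)) {
      stop("coupling lags must be non-negative")
    }
  }
  if (base_sd == 0 && noise_sd == 0 &&
      nrow(coupling_pre) == 0L && nrow(coupling_post) == 0L) {
    stop("degenerate config: no motion source at all")
  }
  structure(list(fps = fps, duration_s = duration_s,
                 climax_time_s = climax_time_s, base_sd = base_sd,
                 base_phi = base_phi, coupling_pre = coupling_pre,
                 coupling_post = coupling_post, noise_sd = noise_sd,
                 seat_distance_mm = seat_distance_mm,
                 marker_jitter_sd = marker_jitter_sd, drift = drift,
                 seed = as.integer(seed)),
            class = "dyad_sim_config")
}

#' Lagged coupling specification
#' @param lag_ms Delay(s) in milliseconds (child trails storyteller).
#' @param gain Signed dimensionless gain(s), one per lag.
#' @return Data.frame `lag_ms, gain`.
#' @export
coupling <- function(lag_ms = numeric(0), gain = numeric(0)) {
  stopifnot(length(lag_ms) == length(gain))
  data.frame(lag_ms = as.numeric(lag_ms), gain = as.numeric(gain))
}

# stationary AR(1): s[t] = phi s[t-1] + eta, eta ~ N(0, sd^2 (1 - phi^2)),
# initialised from the stationary distribution; uses the current RNG stream
ar1 <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  s0 <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive", init = s0))
}

#' Simulate the storyteller's base speed signal
#'
#' Zero-mean stationary AR(1) process with the configured stationary standard
#' deviation and smoothness, reproducible from the config seed.
#'
#' @param cfg A `dyad_sim_config`.
#' @return A `speed_signal` of length `round(duration_s * fps) - 1`.
#' @export
simulate_base_speed <- function(cfg) {
  set.seed(cfg$seed)
  n <- n_speed_samples(cfg)
  structure(ar1(n, cfg$base_sd, cfg$base_phi), fps = cfg$fps,
            class = "speed_signal")
}

n_speed_samples <- function(cfg) round(cfg$duration_s * cfg$fps) - 1L

coupling_frames <- function(cp, fps) {
  if (nrow(cp) == 0L) return(cp)
  cp$lag_frames <- as.integer(round(cp$lag_ms * fps / 1000))
  cp
}

#' Simulate the coupled speed-signal pair of one dyad
#'
#' Storyteller speed is the AR(1) base process; the child's speed is
#' `c[t] = sum_k g_k s[t - L_k] + eps[t]` with the pre-climax couplings
#' applying up to the climax frame and the post-climax couplings after it.
#' This is the ground-truth layer beneath [simulate_dyad()]; it skips marker
#' embedding and is used for statistical calibration studies where only the
#' speed pair matters.
#'
#' @param cfg A `dyad_sim_config`.
#' @return List with `storyteller` and `child` `speed_signal`s and
#'   `climax_frame` (position-frame index of the regime switch).
#' @export
simulate_dyad_signals <- function(cfg) {
  set.seed(cfg$seed)
  n <- n_speed_samples(cfg)
  cpre <- coupling_frames(cfg$coupling_pre, cfg$fps)
  cpost <- coupling_frames(cfg$coupling_post, cfg$fps)
  lmax <- max(0L, cpre$lag_frames, cpost$lag_frames)
  s_full <- ar1(n + lmax, cfg$base_sd, cfg$base_phi)
  s <- s_full[(lmax + 1L):(lmax + n)]
  child <- stats::rnorm(n, 0, cfg$noise_sd)
  cf <- floor(cfg$climax_time_s * cfg$fps)
  pre_idx <- seq_len(min(cf, n))
  post_idx <- if (cf < n) (cf + 1L):n else integer(0)
  add_regime <- function(child, cp, idx) {
    if (nrow(cp) == 0L || length(idx) == 0L) return(child)
    for (k in seq_len(nrow(cp))) {
      shifted <- s_full[(lmax + 1L - cp$lag_frames[k]):(lmax + n - cp$lag_frames[k])]
      child[idx] <- child[idx] + cp$gain[k] * shifted[idx]
    }
    child
  }
  child <- add_regime(child, cpre, pre_idx)
  child <- add_regime(child, cpost, post_idx)
  list(storyteller = structure(s, fps = cfg$fps, class = "speed_signal"),
       child = structure(child, fps = cfg$fps, class = "speed_signal"),
       climax_frame = cf)
}

# integrate speed to a mean-reverting 1D position, p[1] = 0
integrate_speed <- function(speed, drift) {
  as.numeric(stats::filter(c(0, speed), drift, method = "recursive"))
}

# back-marker and identifier-constellation offsets in the local torso frame:
# columns (along-axis toward own back, lateral, vertical), mm
marker_offsets <- function() {
  list(back = rbind(upper_back_left  = c(-50, -80,  150),
                    upper_back_right = c(-50,  80,  150),
                    lower_back_left  = c(-50, -80, -150),
                    lower_back_right = c(-50,  80, -150)),
       ident = rbind(id1 = c(-60, -120, 250),
                     id2 = c(-60,    0, 280),
                     id3 = c(-60,   90, 255)))
}

#' Simulate one dyad as a labeled mocap marker table
#'
#' Runs [simulate_dyad_signals()], integrates the speeds to proximity-axis
#' positions, embeds the two torsos facing each other along the x axis at the
#' configured seat distance, expands each into four back markers plus a
#' three-marker identifier constellation with Gaussian jitter, and emits the
#' standard marker table together with the matching labeling map and
#' metadata row.
#'
#' @param cfg A `dyad_sim_config`.
#' @param dyad_id,age_group,condition Metadata for the emitted dyad.
#' @return List with `table` (a `marker_table`), `labels` (a
#'   `labeling_map`), `meta` (one-row `dyad_metadata`), and `truth` (the
#'   generating speed pair from [simulate_dyad_signals()]).
#' @export
simulate_dyad <- function(cfg, dyad_id = "dyad01", age_group = "3y",
                          condition = "PII") {
  sig <- simulate_dyad_signals(cfg)
  set.seed(cfg$seed + 1000003L)  # jitter stream, distinct from the signal stream
  # child faces +x at the origin; storyteller faces -x at the seat distance;
  # approach-positive speed integrates to motion toward the partner
  pos_c <- integrate_speed(as.numeric(sig$child), cfg$drift)
  pos_s <- integrate_speed(as.numeric(sig$storyteller), cfg$drift)
  x_child <- pos_c
  x_story <- cfg$seat_distance_mm - pos_s
  nf <- length(x_child)
  off <- marker_offsets()
  frames <- 0:(nf - 1L)
  build <- function(prefix, x_centre, facing) {
    # facing = +1 when the interactant faces +x (back offsets point to -x)
    rows <- list()
    all_off <- rbind(off$back, off$ident)
    region <- c(rownames(off$back), rep("identifier", nrow(off$ident)))
    for (i in seq_len(nrow(all_off))) {
      o <- all_off[i, ]
      jit <- if (cfg$marker_jitter_sd > 0) {
        matrix(stats::rnorm(3L * nf, 0, cfg$marker_jitter_sd), nf, 3L)
      } else matrix(0, nf, 3L)
      rows[[i]] <- data.frame(
        frame = frames,
        marker = paste0(prefix, "_", rownames(all_off)[i]),
        x = x_centre + facing * o[1L] + jit[, 1L],
        y = o[2L] + jit[, 2L],
        z = o[3L] + jit[, 3L],
        region = region[i], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  dc <- build("child", x_child, +1)
  ds <- build("storyteller", x_story, -1)
  all <- rbind(dc, ds)
  tab <- marker_table(all$frame, all$marker, all$x, all$y, all$z, cfg$fps)
  lab_df <- unique(all[, c("marker", "region")])
  labels <- labeling_map(
    marker = lab_df$marker,
    interactant = ifelse(startsWith(lab_df$marker, "child"), "child",
                         "storyteller"),
    region = lab_df$region)
  meta <- dyad_metadata(dyad_id, age_group, condition, cfg$climax_time_s,
                        cfg$fps)
  list(table = tab, labels = labels, meta = meta, truth = sig)
}

#' Closed-form expected correlation for a single-coupling dyad
#'
#' For a single lagged coupling with gain `g`, base-speed sd `sigma_s` and
#' child noise sd `sigma_e`, the expected uncentered correlation at the
#' coupling lag is `rho = g sigma_s / sqrt(g^2 sigma_s^2 + sigma_e^2)`
#' (exactly, for any stationary base process). Off-lag values are 0 for a
#' white-noise base (`base_phi = 0`); with a smooth base they decay with the
#' base autocorrelation instead and this closed form does not apply.
#'
#' @param cfg A `dyad_sim_config` whose relevant regime has at most one
#'   coupling.
#' @param lag_ms Delay at which to evaluate.
#' @param segment `"post"` (default) or `"pre"`: which coupling regime.
#' @return The expected correlation.
#' @export
theoretical_rho <- function(cfg, lag_ms, segment = c("post", "pre")) {
  segment <- match.arg(segment)
  cp <- if (segment == "post") cfg$coupling_post else cfg$coupling_pre
  if (nrow(cp) > 1L) {
    stop("closed form unsupported for multiple couplings; use Monte Carlo")
  }
  if (nrow(cp) == 0L || cp$gain[1L] == 0) return(0)
  if (lag_ms != cp$lag_ms[1L]) {
    if (cfg$base_phi > 0) {
      warning("off-lag values are only exact for a white-noise base (base_phi = 0)")
    }
    return(0)
  }
  g <- cp$gain[1L]
  num <- g * cfg$base_sd
  den <- sqrt(g^2 * cfg$base_sd^2 + cfg$noise_sd^2)
  if (den == 0) return(sign(g))
  num / den
}

#' Configuration for a simulated 2 x 2 group study
#'
#' @param n_per_cell Dyads per age-by-condition cell (default 5).
#' @param template A `dyad_sim_config` used for every dyad.
#' @param cell_overrides Named list (names like `"3y.PII"`) of lists of
#'   `dyad_sim_config` fields to override per cell.
#' @param base_seed Base RNG seed; dyad `i` (in generation order) uses
#'   `base_seed + i`, so groups are reproducible dyad by dyad.
#' @return A `group_sim_config` list.
#' @export
group_sim_config <- function(n_per_cell = 5, template = dyad_sim_config(),
                             cell_overrides = list(), base_seed = 20260101L) {
  stopifnot(n_per_cell >= 1)
  structure(list(n_per_cell = as.integer(n_per_cell), template = template,
                 cell_overrides = cell_overrides,
                 base_seed = as.integer(base_seed)),
            class = "group_sim_config")
}

#' Simulate a group study and write it as a mocap dataset
#'
#' Generates `n_per_cell` dyads for each of the four age-by-condition cells
#' and writes, in the dialects [read_marker_table()] and
#' [read_dyad_metadata()] consume: one marker CSV per dyad
#' (`dyad_<id>.csv`), a shared `metadata.csv`, and a shared `labels.csv`.
#' Fully reproducible from `base_seed`.
#'
#' @param gcfg A `group_sim_config`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a manifest list: `dir`, `metadata_path`, `labels_path`,
#'   `marker_paths` (named by dyad id), `metadata`.
#' @export
simulate_group <- function(gcfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- expand.grid(age_group = c("3y", "6y"), condition = c("PAI", "PII"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  metas <- list(); paths <- character(0); labels <- NULL
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cfg <- gcfg$template
    key <- paste(cell$age_group, cell$condition, sep = ".")
    if (!is.null(gcfg$cell_overrides[[key]])) {
      cfg[names(gcfg$cell_overrides[[key]])] <- gcfg$cell_overrides[[key]]
    }
    for (i in seq_len(gcfg$n_per_cell)) {
      idx <- idx + 1L
      cfg$seed <- gcfg$base_seed + idx
      dyad_id <- sprintf("%s_%s_%02d", cell$age_group, cell$condition, i)
      sim <- simulate_dyad(cfg, dyad_id, cell$age_group, cell$condition)
      p <- file.path(dir, paste0("dyad_", dyad_id, ".csv"))
      write_marker_table(sim$table, p)
      paths[dyad_id] <- p
      metas[[dyad_id]] <- sim$meta
      labels <- sim$labels
    }
  }
  meta <- do.call(rbind, metas)
  class(meta) <- c("dyad_metadata", "data.frame")
  rownames(meta) <- NULL
  metadata_path <- file.path(dir, "metadata.csv")
  write_dyad_metadata(meta, metadata_path)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(as.data.frame(labels), labels_path, row.names = FALSE,
                   quote = FALSE)
  invisible(list(dir = dir, metadata_path = metadata_path,
                 labels_path = labels_path, marker_paths = paths,
                 metadata = meta))
}
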