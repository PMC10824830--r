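# independent brute-force evaluation of the uncentered correlation on
# explicitly materialized vectors (the oracle the fast path is checked against)
brute_uncentered_corr <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# materialize the trimmed slices for a delay by hand, then apply the oracle
brute_corr_at_lag <- function(s, c_, lag) {
  n <- length(s)
  if (lag >= 0) {
    a <- s[1:(n - lag)]; b <- c_[(1 + lag):n]
  } else {
    a <- s[(1 - lag):n]; b <- c_[1:(n + lag)]
  }
  list(r = brute_uncentered_corr(a, b), m = length(a))
}

# tiny labeled recording built from explicit marker matrices:
# coords[[interactant]][[marker_name]] is an n x 3 matrix
make_recording <- function(coords, fps = 120,
                           regions = c("upper_back_left", "upper_back_right",
                                       "lower_back_left", "lower_back_right")) {
  rows <- list()
  lab <- list()
  for (who in names(coords)) {
    mks <- coords[[who]]
    for (i in seq_along(mks)) {
      nm <- names(mks)[i]
      m <- mks[[i]]
      rows[[paste(who, nm)]] <- data.frame(
        frame = 0:(nrow(m) - 1L), marker = nm,
        x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
      lab[[paste(who, nm)]] <- data.frame(marker = nm, interactant = who,
                                          region = regions[((i - 1L) %% 4L) + 1L],
                                          stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  lb <- do.call(rbind, lab)
  tab <- marker_table(df$frame, df$marker, df$x, df$y, df$z, fps)
  apply_labels(tab, labeling_map(lb$marker, lb$interactant, lb$region))
}

# single-lag-coupled dyad at the speed-signal level (fast, no marker embedding)
null_dyad_cfg <- function(seed, duration_s = 60) {
  dyad_sim_config(duration_s = duration_s, climax_time_s = duration_s / 2,
                  base_sd = 1, base_phi = 0, noise_sd = 1,
                  coupling_pre = coupling(), coupling_post = coupling(),
                  seed = seed)
}
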