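#' Analysis configuration for an end-to-end run
#'
#' Bundles paths, the lag grid, filter and inference settings, the gap/QC
#' policy and the contrast plan. Defaults encode the standard analysis: 10 Hz
#' single-pole low-pass, 0-1500 ms delay grid, family-wise `alpha = 0.001`
#' with 41 Bonferroni comparisons, within-dyad baseline = pre-climax,
#' between-group baselines = the 3-year-old group (age) and the PII
#' condition.
#'
#' @param marker_dir Directory with per-dyad marker CSVs named
#'   `dyad_<dyad_id>.csv`.
#' @param metadata_path Dyad metadata CSV.
#' @param labels_path Labeling-map CSV.
#' @param output_dir Where result CSVs, figures and the log are written.
#' @param lags_ms Delay grid in milliseconds.
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param alpha Family-wise confidence level.
#' @param n_comparisons Bonferroni divisor.
#' @param max_gap_s Occlusion gaps up to this length are interpolated.
#' @param max_missing_frac Dyads with more than this fraction of frames still
#'   missing after filling are excluded (QC-logged).
#' @param contrast_direction `"post_minus_pre"` (default: the change created
#'   by the climax) or `"pre_minus_post"`.
#' @param age_baseline,condition_baseline Baseline groups subtracted in the
#'   between-group contrasts.
#' @param center,weighted Sensitivity flags passed to [xcorr_coef()] and
#'   [pool_curves()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(marker_dir, metadata_path, labels_path,
                            output_dir,
                            lags_ms = default_lags_ms(), cutoff_hz = 10,
                            alpha = 0.001, n_comparisons = 41,
                            max_gap_s = 0.25, max_missing_frac = 0.10,
                            contrast_direction = c("post_minus_pre",
                                                   "pre_minus_post"),
                            age_baseline = "3y", condition_baseline = "PII",
                            center = FALSE, weighted = FALSE) {
  contrast_direction <- match.arg(contrast_direction)
  structure(list(marker_dir = marker_dir, metadata_path = metadata_path,
                 labels_path = labels_path, output_dir = output_dir,
                 lags_ms = lags_ms, cutoff_hz = cutoff_hz, alpha = alpha,
                 n_comparisons = n_comparisons, max_gap_s = max_gap_s,
                 max_missing_frac = max_missing_frac,
                 contrast_direction = contrast_direction,
                 age_baseline = age_baseline,
                 condition_baseline = condition_baseline,
                 center = center, weighted = weighted),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; relative paths are
#' resolved against the file's directory.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("marker_dir", "metadata_path", "labels_path", "output_dir")) {
    if (!is.null(vals[[k]]) && !startsWith(vals[[k]], "/")) {
      vals[[k]] <- file.path(base, vals[[k]])
    }
  }
  do.call(analysis_config, vals)
}

# per-dyad stage: read -> label -> fill -> QC -> per-segment preprocess+curve
process_dyad <- function(meta_row, config, labels) {
  path <- file.path(config$marker_dir, paste0("dyad_", meta_row$dyad_id, ".csv"))
  tab <- read_marker_table(path, fps = meta_row$fps)
  rec <- fill_gaps(apply_labels(tab, labels), max_gap_s = config$max_gap_s)
  mf <- missing_fraction(rec)
  if (mf > config$max_missing_frac) {
    return(list(ok = FALSE, reason = "excess_missing",
                detail = sprintf("%.1f%% frames missing after filling", 100 * mf)))
  }
  grid <- lag_grid(config$lags_ms, fps = meta_row$fps)
  segs <- c(list(whole = rec),
            split_at_climax(rec, meta_row$climax_time_s))
  curves <- lapply(names(segs), function(sn) {
    sig <- preprocess_dyad(segs[[sn]], cutoff_hz = config$cutoff_hz)
    xcorr_curve(sig$storyteller, sig$child, grid,
                dyad_id = meta_row$dyad_id, segment = sn,
                center = config$center)
  })
  names(curves) <- names(segs)
  list(ok = TRUE, reason = "ok", detail = sprintf("missing %.2f%%", 100 * mf),
       curves = curves)
}

#' Run the full coordination analysis
#'
#' For every dyad in the metadata table: read and label its marker table,
#' fill occlusion gaps, apply the QC rule, preprocess to oriented speed
#' signals (whole recording and pre/post-climax segments independently), and
#' compute its lagged cross-correlation curve. Curves are then pooled in
#' Fisher space per age-by-condition group, corrected confidence bands are
#' attached, and three contrast families are formed: within-dyad
#' (post-climax minus pre-climax baseline, per group), between ages
#' (6-year-olds minus the 3-year-old baseline) and between conditions (PAI
#' minus the PII baseline). All results, peak tables, the QC/exclusion log
#' and figures are written to the output directory.
#'
#' @param config An `analysis_config`.
#' @return Invisibly, a list: `dyad_curves`, `group_curves` (aggregated, per
#'   segment), `contrasts`, `peaks`, `qc`, `paths`.
#' @export
run_analysis <- function(config) {
  meta <- read_dyad_metadata(config$metadata_path)
  labels <- read_labeling_map(config$labels_path)
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  qc <- data.frame(dyad_id = meta$dyad_id, included = FALSE,
                   reason = NA_character_, detail = NA_character_,
                   stringsAsFactors = FALSE)
  dyad_curves <- list()
  for (i in seq_len(nrow(meta))) {
    res <- tryCatch(process_dyad(meta[i, ], config, labels),
                    error = function(e) {
                      list(ok = FALSE, reason = "processing_error",
                           detail = conditionMessage(e))
                    })
    qc$included[i] <- res$ok
    qc$reason[i] <- res$reason
    qc$detail[i] <- res$detail
    if (res$ok) dyad_curves[[meta$dyad_id[i]]] <- res$curves
  }
  if (length(dyad_curves) == 0L) {
    stop("no usable dyads; exclusions: ",
         paste(sprintf("%s (%s)", qc$dyad_id, qc$reason), collapse = "; "))
  }
  used <- meta[meta$dyad_id %in% names(dyad_curves), ]
  used$cell <- paste(used$age_group, used$condition, sep = ".")
  band_of <- function(fc) {
    confidence_band(fc, alpha = config$alpha,
                    n_comparisons = config$n_comparisons)
  }
  pool_ids <- function(ids, segment, label) {
    pool_curves(lapply(dyad_curves[ids], `[[`, segment), label = label,
                weighted = config$weighted)
  }
  # per-cell aggregated curves for each segment
  group_fisher <- list(); group_curves <- list()
  for (cell in unique(used$cell)) {
    ids <- used$dyad_id[used$cell == cell]
    for (seg in c("whole", "pre", "post")) {
      lbl <- paste(cell, seg, sep = ".")
      group_fisher[[lbl]] <- pool_ids(ids, seg, lbl)
      group_curves[[lbl]] <- band_of(group_fisher[[lbl]])
    }
  }
  contrasts <- list()
  # within-dyad climax contrast per cell
  for (cell in unique(used$cell)) {
    post <- group_fisher[[paste(cell, "post", sep = ".")]]
    pre <- group_fisher[[paste(cell, "pre", sep = ".")]]
    fc <- if (config$contrast_direction == "post_minus_pre") {
      subtract_fisher(post, pre, label = paste0(cell, ".post-pre"))
    } else {
      subtract_fisher(pre, post, label = paste0(cell, ".pre-post"))
    }
    contrasts[[attr(fc, "label")]] <- band_of(fc)
  }
  # between-group contrasts on the whole-recording curves
  lvls <- list(age_group = unique(used$age_group),
               condition = unique(used$condition))
  baselines <- c(age_group = config$age_baseline,
                 condition = config$condition_baseline)
  for (fac in names(lvls)) {
    others <- setdiff(lvls[[fac]], baselines[[fac]])
    if (length(others) == 0L || !(baselines[[fac]] %in% lvls[[fac]])) next
    base_ids <- used$dyad_id[used[[fac]] == baselines[[fac]]]
    base_fc <- pool_ids(base_ids, "whole", baselines[[fac]])
    for (lv in others) {
      ids <- used$dyad_id[used[[fac]] == lv]
      fc <- subtract_fisher(pool_ids(ids, "whole", lv), base_fc,
                            label = paste0(lv, "-", baselines[[fac]]))
      contrasts[[attr(fc, "label")]] <- band_of(fc)
    }
  }
  all_agg <- c(group_curves, contrasts)
  peaks <- do.call(rbind, lapply(names(all_agg), function(lbl) {
    cbind(data.frame(label = lbl, stringsAsFactors = FALSE),
          find_peaks(all_agg[[lbl]]))
  }))
  # write the result bundle
  paths <- list(
    dyad_curves = file.path(config$output_dir, "dyad_curves.csv"),
    group_curves = file.path(config$output_dir, "group_curves.csv"),
    contrast_curves = file.path(config$output_dir, "contrast_curves.csv"),
    peaks = file.path(config$output_dir, "peaks.csv"),
    qc = file.path(config$output_dir, "qc_log.csv"),
    figure = file.path(config$output_dir, "contrast_curves.pdf"))
  write_xcorr_curves(unlist(dyad_curves, recursive = FALSE),
                     paths$dyad_curves)
  write_aggregated_curves(group_curves, paths$group_curves)
  write_aggregated_curves(contrasts, paths$contrast_curves)
  utils::write.csv(peaks, paths$peaks, row.names = FALSE, quote = FALSE)
  utils::write.csv(qc, paths$qc, row.names = FALSE)
  fig <- plot_curves(contrasts)
  ggplot2::ggsave(paths$figure, fig, width = 8, height = 5)
  invisible(list(dyad_curves = dyad_curves, group_curves = group_curves,
                 contrasts = contrasts, peaks = peaks, qc = qc,
                 paths = paths))
}

#' Plot aggregated coordination curves with confidence overlays
#'
#' One series per curve: solid line = back-transformed correlation `R`
#' against delay (ms), translucent ribbon = the corrected confidence band, a
#' zero reference line, and the morphology reading annotated on the margins
#' (upper half symmetric, lower half asymmetric). A coordination effect is
#' not attributable to chance wherever the ribbon clears zero.
#'
#' @param curves A single `aggregated_curve` or a (optionally named) list.
#' @param path Optional output path; writes both the given file and a `.png`
#'   sibling.
#' @return The ggplot object, invisibly if `path` was given.
#' @export
plot_curves <- function(curves, path = NULL) {
  if (inherits(curves, "aggregated_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no curves to plot")
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    lbl <- attr(curves[[i]], "label")
    if (is.null(lbl) || is.na(lbl)) lbl <- names(curves)[i]
    cbind(data.frame(label = lbl, stringsAsFactors = FALSE),
          as.data.frame(curves[[i]]))
  }))
  ymax <- max(abs(c(df$ci_low, df$ci_high)), na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$R,
                                        colour = .data$label,
                                        fill = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::annotate("text", x = -Inf, y = ymax, hjust = -0.1, vjust = 1,
                      label = "symmetric", size = 3, colour = "grey30") +
    ggplot2::annotate("text", x = -Inf, y = -ymax, hjust = -0.1, vjust = 0,
                      label = "asymmetric", size = 3, colour = "grey30") +
    ggplot2::labs(x = "delay (ms)", y = "cross-correlation (R)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 5)
    ggplot2::ggsave(sub("\\.[a-zA-Z]+$", ".png", path), p,
                    width = 8, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
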