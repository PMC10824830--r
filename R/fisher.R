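#' Fisher z-transform of a correlation
#'
#' `x = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, mapping a correlation to an
#' approximately normal variable so curves can be averaged across dyads and
#' tested with z statistics.
#'
#' @param r Correlation(s), `|r| < 1`.
#' @return Fisher-transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("|r| >= 1 is outside the Fisher transform domain (clamp first)")
  }
  atanh(r)
}

#' Inverse Fisher transform
#'
#' `tanh(x)`, mapping a pooled Fisher mean back to Pearson scale.
#'
#' @param x Fisher value(s), finite.
#' @return Correlation(s) in `(-1, 1)`.
#' @export
fisher_inv <- function(x) tanh(x)

# correlations numerically at +/-1 (possible on tiny noiseless segments)
# are pulled just inside the open interval so pooling never produces Inf
clamp_r <- function(r, eps = 1e-12) {
  hit <- which(abs(r) >= 1)
  if (length(hit) > 0L) {
    warning("clamped ", length(hit), " correlation(s) at |r| = 1 to 1 - 1e-12")
    r[hit] <- sign(r[hit]) * (1 - eps)
  }
  r
}

#' Pool per-dyad cross-correlation curves in Fisher space
#'
#' Per lag, the pooled value is the unweighted mean of `atanh(r_i)` over
#' dyads with a defined correlation there (the grand average of the
#' transformed values), and the standard error is `1 / sqrt(sum(m_i))` — the
#' standard error of a single Fisher-transformed correlation for a signal as
#' long as all contributing signals combined (which assumes the `m_i` are
#' similar and the samples serially uncorrelated).
#'
#' @param curves List of `xcorr_curve`s sharing one lag grid.
#' @param label Group label carried on the result.
#' @param weighted If `TRUE`, use the inverse-variance (m-weighted) mean of
#'   the `x_i` instead of the unweighted mean (sensitivity-analysis flag;
#'   default `FALSE`, the definitional unweighted average).
#' @return A `fisher_curve` data.frame:
#'   `lag_ms, X, se, m_total, n_dyads`, with attribute `label`.
#' @export
pool_curves <- function(curves, label = NA_character_, weighted = FALSE) {
  if (inherits(curves, "xcorr_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no curves to pool")
  lags <- curves[[1L]]$lag_ms
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$lag_ms, lags))) {
      stop("curves do not share a common lag grid")
    }
  }
  r_mat <- vapply(curves, function(cv) cv$r, numeric(length(lags)))
  m_mat <- vapply(curves, function(cv) cv$m, numeric(length(lags)))
  r_mat <- matrix(r_mat, nrow = length(lags))
  m_mat <- matrix(m_mat, nrow = length(lags))
  X <- se <- m_total <- rep(NA_real_, length(lags))
  n_dyads <- integer(length(lags))
  for (i in seq_along(lags)) {
    ok <- !is.na(r_mat[i, ])
    n_dyads[i] <- sum(ok)
    if (n_dyads[i] == 0L) next
    xi <- fisher_z(clamp_r(r_mat[i, ok]))
    mi <- m_mat[i, ok]
    X[i] <- if (weighted) sum(mi * xi) / sum(mi) else mean(xi)
    m_total[i] <- sum(mi)
    se[i] <- 1 / sqrt(m_total[i])
  }
  structure(data.frame(lag_ms = lags, X = X, se = se, m_total = m_total,
                       n_dyads = n_dyads),
            label = label, class = c("fisher_curve", "data.frame"))
}

#' Subtract one pooled curve from another in Fisher space
#'
#' Per lag, `X = X_minuend - X_subtrahend` with standard errors combined in
#' quadrature. Used for the within-dyad contrast (post-climax minus
#' pre-climax baseline) and for between-group contrasts (e.g. 6-year-olds
#' minus the 3-year-old baseline). The result reads as a comparative, not
#' absolute, level of coordination.
#'
#' @param minuend,subtrahend `fisher_curve`s on the same lag grid.
#' @param label Label for the contrast curve.
#' @return A `fisher_curve` of the difference.
#' @export
subtract_fisher <- function(minuend, subtrahend, label = NA_character_) {
  if (!isTRUE(all.equal(minuend$lag_ms, subtrahend$lag_ms))) {
    stop("curves are on different lag grids; cannot subtract")
  }
  structure(data.frame(lag_ms = minuend$lag_ms,
                       X = minuend$X - subtrahend$X,
                       se = sqrt(minuend$se^2 + subtrahend$se^2),
                       m_total = NA_real_,
                       n_dyads = pmin(minuend$n_dyads, subtrahend$n_dyads)),
            label = label, class = c("fisher_curve", "data.frame"))
}

#' Back-transform a pooled curve and attach corrected confidence bands
#'
#' The Bonferroni-corrected level is `p_c = alpha / n_comparisons`; the
#' two-sided standard-normal cutoff `z* = qnorm(1 - p_c / 2)` scales the
#' Fisher-space standard error, and the interval
#' `[tanh(X - z* se), tanh(X + z* se)]` is mapped back to Pearson scale. A
#' lag is flagged significant when its interval excludes zero, and labeled by
#' morphology: `symmetric` (mirror-like, both-approach/both-retreat
#' coordination) when the whole interval is positive, `asymmetric` (one
#' approaches while the other retreats) when it is negative, `none`
#' otherwise. The printed defaults (`alpha = 0.001`, 41 comparisons) give a
#' corrected level of 2e-5.
#'
#' @param fc A `fisher_curve`.
#' @param alpha Family-wise level (default 0.001).
#' @param n_comparisons Bonferroni divisor (default 41; an explicit
#'   parameter, not derived from the grid length).
#' @param label Optional label override.
#' @return An `aggregated_curve` data.frame:
#'   `lag_ms, R, ci_low, ci_high, X, se, m_total, n_dyads, significant,
#'   morphology`, with attributes `label`, `alpha`, `n_comparisons`,
#'   `p_corrected`, `z_crit`.
#' @export
confidence_band <- function(fc, alpha = 0.001, n_comparisons = 41,
                            label = attr(fc, "label")) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1)
  if (any(fc$se <= 0, na.rm = TRUE)) stop("degenerate standard error <= 0")
  p_c <- alpha / n_comparisons
  z_crit <- stats::qnorm(1 - p_c / 2)
  ci_low <- fisher_inv(fc$X - z_crit * fc$se)
  ci_high <- fisher_inv(fc$X + z_crit * fc$se)
  significant <- !is.na(ci_low) & (ci_low > 0 | ci_high < 0)
  morphology <- ifelse(is.na(ci_low), NA_character_,
                       ifelse(ci_low > 0, "symmetric",
                              ifelse(ci_high < 0, "asymmetric", "none")))
  structure(data.frame(lag_ms = fc$lag_ms, R = fisher_inv(fc$X),
                       ci_low = ci_low, ci_high = ci_high,
                       X = fc$X, se = fc$se, m_total = fc$m_total,
                       n_dyads = fc$n_dyads, significant = significant,
                       morphology = morphology, stringsAsFactors = FALSE),
            label = label, alpha = alpha, n_comparisons = n_comparisons,
            p_corrected = p_c, z_crit = z_crit,
            class = c("aggregated_curve", "data.frame"))
}

#' Locate coordination peaks on an aggregated curve
#'
#' Local extrema of `R` over the lag grid (plateau-tolerant; endpoints
#' count), each labeled by the sign's morphology reading, plus the global
#' maximum and minimum.
#'
#' @param ac An `aggregated_curve`.
#' @return Data.frame `lag_ms, R, type, morphology, global` where `type` is
#'   `"max"` or `"min"` and `global` flags the curve-wide extremes.
#' @export
find_peaks <- function(ac) {
  R <- ac$R
  n <- length(R)
  if (n == 0L) stop("empty curve")
  left <- c(-Inf, R[-n]); right <- c(R[-1L], -Inf)
  is_max <- !is.na(R) & R >= left & R >= right
  left <- c(Inf, R[-n]); right <- c(R[-1L], Inf)
  is_min <- !is.na(R) & R <= left & R <= right
  rows <- list()
  add <- function(idx, type) {
    if (length(idx) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      lag_ms = ac$lag_ms[idx], R = R[idx], type = type,
      morphology = ifelse(R[idx] > 0, "symmetric",
                          ifelse(R[idx] < 0, "asymmetric", "none")),
      global = (type == "max" & idx == which.max(R)) |
               (type == "min" & idx == which.min(R)),
      stringsAsFactors = FALSE)
  }
  add(which(is_max), "max")
  add(which(is_min), "min")
  out <- do.call(rbind, rows)
  out <- out[order(out$lag_ms, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.aggregated_curve <- function(x, ...) {
  if (is.numeric(attr(x, "p_corrected"))) {
    cat("<aggregated_curve> ", attr(x, "label"), ": ", nrow(x), " lags, ",
        "alpha = ", attr(x, "alpha"), " / ", attr(x, "n_comparisons"),
        " comparisons (corrected p = ", signif(attr(x, "p_corrected"), 3),
        ")\n", sep = "")
  } else {
    cat("<aggregated_curve> ", nrow(x), " rows\n", sep = "")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Export aggregated curves to CSV
#' @param curves A single `aggregated_curve` or a list of them.
#' @param path Output path
#'   (`label,lag_ms,R,ci_low,ci_high,X,se,m_total,n_dyads,significant,morphology`).
#' @return `path`, invisibly.
#' @export
write_aggregated_curves <- function(curves, path) {
  if (inherits(curves, "aggregated_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    cbind(data.frame(label = attr(cv, "label"), stringsAsFactors = FALSE),
          as.data.frame(cv))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
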