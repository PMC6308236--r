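#' Time-averaged MSD of a single track
#'
#' For each lag tau = k * dt the mean squared displacement
#' MSD(tau) = <(x_{t+tau} - x_t)^2 + (y_{t+tau} - y_t)^2>, averaged over all
#' ordered position pairs (t, t + tau) within the track (overlapping
#' windows). Lags are reported up to `max_lag_fraction` of the track length,
#' which bounds the variance of the long-lag estimates.
#'
#' @param xy n x 2 matrix of positions (um), row t = frame t; or a
#'   `track_set` subset for a single track (columns `x_um`, `y_um`).
#' @param frame_interval minutes between frames.
#' @param max_lag_fraction largest reported lag as a fraction of track
#'   length (default 1/3).
#' @return list of class `msd_curve`: `lags` (minutes), `values` (um^2),
#'   `n_pairs` (pairs per lag), `level = "track"`, `frame_interval`.
#' @examples
#' xy <- cbind(c(0, 1, 1, 2), c(0, 0, 1, 1))
#' track_msd(xy, frame_interval = 1, max_lag_fraction = 1)$values
#' @export
track_msd <- function(xy, frame_interval = 3, max_lag_fraction = 1 / 3) {
  if (is.data.frame(xy)) xy <- cbind(xy$x_um, xy$y_um)
  n <- nrow(xy)
  if (is.null(n) || n < 2) stop("track must have at least 2 frames")
  kmax <- max(1L, floor((n - 1L) * max_lag_fraction))
  vals <- vapply(seq_len(kmax), function(k) {
    d <- xy[(k + 1):n, , drop = FALSE] - xy[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
  structure(list(lags = seq_len(kmax) * frame_interval, values = vals,
                 n_pairs = n - seq_len(kmax), level = "track",
                 frame_interval = frame_interval),
            class = "msd_curve")
}

#' Exclude outlier tracks by their final-lag MSD
#'
#' A track is an outlier when its MSD at the final (largest reported) lag
#' lies more than 3 sample standard deviations from the across-track mean at
#' that lag. The mean and SD are computed once over all candidate tracks
#' (the candidate included) and the rule is applied in a single pass — it is
#' not iterated, so it is order-invariant. With zero spread nothing is
#' removed.
#'
#' @param track_curves list of track-level [track_msd()] curves sharing a
#'   final lag.
#' @param final_lag lag (minutes) at which the rule is applied; default the
#'   largest lag common to all curves.
#' @param n_sd exclusion threshold in SD units (default 3).
#' @return list: `included`, `excluded` (index vectors), `final_lag`,
#'   `mean`, `sd`.
#' @export
remove_outliers <- function(track_curves, final_lag = NULL, n_sd = 3) {
  if (length(track_curves) < 2) stop("need at least 2 curves")
  if (is.null(final_lag))
    final_lag <- min(vapply(track_curves, function(cv) max(cv$lags), 0))
  v <- vapply(track_curves, function(cv) {
    i <- match(final_lag, cv$lags)
    if (is.na(i)) stop("a curve does not contain the final lag")
    cv$values[i]
  }, 0)
  m <- mean(v); s <- stats::sd(v)
  excluded <- if (s == 0) integer(0) else which(abs(v - m) > n_sd * s)
  list(included = setdiff(seq_along(v), excluded), excluded = excluded,
       final_lag = final_lag, mean = m, sd = s)
}

#' Ensemble MSD over cells with SEM
#'
#' Track curves are first averaged within each cell (one curve per cell),
#' then across cells; the per-lag SEM is the SD over cell curves divided by
#' sqrt(n_cells). n counts cells, not tracks — for single-locus probes the
#' two coincide. Outlier exclusion is expected to have been applied already.
#'
#' @param track_curves list of track-level [track_msd()] curves.
#' @param cell_ids vector assigning each curve to a cell.
#' @return list of class `msd_curve`: `lags`, `values`, `sem`, `n_cells`,
#'   `cell_values` (n_cells x n_lags matrix), `level = "ensemble"`.
#' @export
ensemble_msd <- function(track_curves, cell_ids) {
  stopifnot(length(track_curves) == length(cell_ids))
  cells <- unique(cell_ids)
  if (length(cells) < 2) stop("need at least 2 cells for the SEM")
  kmax <- min(vapply(track_curves, function(cv) length(cv$lags), 0L))
  lags <- track_curves[[1]]$lags[seq_len(kmax)]
  cell_mat <- t(vapply(cells, function(cid) {
    vs <- vapply(track_curves[cell_ids == cid],
                 function(cv) cv$values[seq_len(kmax)], numeric(kmax))
    rowMeans(cbind(vs))
  }, numeric(kmax)))
  structure(list(lags = lags, values = colMeans(cell_mat),
                 sem = apply(cell_mat, 2, stats::sd) / sqrt(length(cells)),
                 n_cells = length(cells), cell_values = cell_mat,
                 level = "ensemble",
                 frame_interval = track_curves[[1]]$frame_interval),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s level), %d lags [%g..%g min]\n",
              x$level, length(x$lags), min(x$lags), max(x$lags)))
  df <- data.frame(lag_min = x$lags, msd_um2 = signif(x$values, 4))
  if (!is.null(x$sem)) df$sem <- signif(x$sem, 3)
  print(utils::head(df, 10), row.names = FALSE)
  if (length(x$lags) > 10) cat("...\n")
  invisible(x)
}

#' Per-lag Student's t comparison of two groups of cell MSDs
#'
#' Two-sample, two-sided, pooled-variance (classical Student) t-test of the
#' per-cell MSD values at each lag, with no multiple-testing correction
#' across lags by default (a Bonferroni option exists). When both groups are
#' constant and equal the statistic is undefined; that lag is reported as
#' t = 0, p = 1 and flagged `degenerate`.
#'
#' @param group_a,group_b matrices of per-cell MSD values (cells x lags),
#'   e.g. the `cell_values` of two ensemble curves, or an `msd_curve`.
#' @param lags lag times (minutes) for labelling; taken from curves if given.
#' @param alpha significance level for flagging (default 0.05).
#' @param bonferroni apply Bonferroni correction across lags (default FALSE).
#' @return data frame of class `msd_comparison`: `lag_min`, `t`, `p`,
#'   `n_a`, `n_b`, `significant`, `degenerate`.
#' @export
compare_msd <- function(group_a, group_b, lags = NULL, alpha = 0.05,
                        bonferroni = FALSE) {
  get_mat <- function(g) if (inherits(g, "msd_curve")) g$cell_values else cbind(g)
  get_lags <- function(g) if (inherits(g, "msd_curve")) g$lags else NULL
  if (is.null(lags)) lags <- get_lags(group_a)
  a <- get_mat(group_a); b <- get_mat(group_b)
  kmax <- min(ncol(a), ncol(b))
  if (is.null(lags)) lags <- seq_len(kmax)
  if (nrow(a) < 2 || nrow(b) < 2) stop("both groups need >= 2 cells")
  out <- do.call(rbind, lapply(seq_len(kmax), function(k) {
    x <- a[, k]; y <- b[, k]
    degen <- stats::var(x) == 0 && stats::var(y) == 0
    if (degen && mean(x) == mean(y)) {
      tt <- 0; p <- 1
    } else if (degen) {
      tt <- sign(mean(x) - mean(y)) * Inf; p <- 0
    } else {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(lag_min = lags[k], t = tt, p = p,
               n_a = length(x), n_b = length(y), degenerate = degen)
  }))
  if (bonferroni) out$p <- pmin(out$p * kmax, 1)
  out$significant <- out$p < alpha
  class(out) <- c("msd_comparison", "data.frame")
  out
}

#' Power-law (anomalous diffusion) fit of an ensemble MSD
#'
#' Least squares on the log-log curve: log MSD = log(4 d) + alpha log(tau),
#' so the slope estimates the anomalous exponent alpha and exp(intercept)/4
#' the generalized diffusion coefficient (um^2/min^alpha).
#'
#' @param curve an [ensemble_msd()] (or any) `msd_curve` with >= 3 strictly
#'   positive values.
#' @param lag_range optional c(min, max) lag window (minutes) to fit.
#' @return list of class `power_law_fit`: `alpha_hat`, `d_hat`,
#'   `fit_lag_range`, `r_squared`.
#' @export
fit_power_law <- function(curve, lag_range = NULL) {
  lags <- curve$lags; vals <- curve$values
  if (!is.null(lag_range)) {
    keep <- lags >= lag_range[1] & lags <= lag_range[2]
    lags <- lags[keep]; vals <- vals[keep]
  }
  if (length(vals) < 3) stop("need >= 3 MSD points to fit")
  if (any(vals <= 0)) stop("nonpositive MSD values in fit range")
  fit <- stats::lm(log(vals) ~ log(lags))
  y <- log(vals)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(alpha_hat = unname(stats::coef(fit)[2]),
                 d_hat = exp(unname(stats::coef(fit)[1])) / 4,
                 fit_lag_range = range(lags),
                 r_squared = r2),
            class = "power_law_fit")
}

#' Rayleigh test of circular uniformity
#'
#' Tests n angles against the uniform circular distribution via the mean
#' resultant length R: Z = n R^2, with the standard finite-n corrected
#' p-value approximation.
#'
#' @param angles numeric vector of angles (radians).
#' @return list: `n`, `R` (mean resultant length in [0,1]), `mean_angle`,
#'   `p_value`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 1) stop("no angles")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(n = n, R = R, mean_angle = atan2(S, C),
       p_value = min(max(p, 0), 1))
}

#' Turning-angle directionality analysis of a track set
#'
#' The turning angle at each interior frame is the signed angle between
#' successive displacement vectors; for isotropic, memoryless motion it is
#' uniform on (-pi, pi]. Persistent directed motion concentrates angles near
#' 0 (or near pi for strictly antipersistent back-and-forth motion). Angles
#' at zero-length displacements are undefined and skipped (counted).
#'
#' @param tracks a `track_set` data frame ([build_track_set()]) or a list of
#'   n x 2 position matrices.
#' @return list of class `directionality_result`: `angles` (pooled,
#'   radians), `R`, `mean_angle`, `p_value` (Rayleigh), `n_angles`,
#'   `n_skipped`.
#' @export
directionality <- function(tracks) {
  mats <- if (is.data.frame(tracks)) {
    lapply(split(tracks, tracks$track_id),
           function(d) cbind(d$x_um[order(d$frame)], d$y_um[order(d$frame)]))
  } else tracks
  angles <- c(); skipped <- 0L
  for (xy in mats) {
    if (nrow(xy) < 3) next
    d <- diff(xy)
    len <- sqrt(rowSums(d^2))
    for (i in seq_len(nrow(d) - 1L)) {
      if (len[i] == 0 || len[i + 1] == 0) { skipped <- skipped + 1L; next }
      cross <- d[i, 1] * d[i + 1, 2] - d[i, 2] * d[i + 1, 1]
      dot <- sum(d[i, ] * d[i + 1, ])
      angles <- c(angles, atan2(cross, dot))
    }
  }
  if (!length(angles)) stop("no turning angles could be computed")
  rt <- rayleigh_test(angles)
  structure(list(angles = angles, R = rt$R, mean_angle = rt$mean_angle,
                 p_value = rt$p_value, n_angles = rt$n,
                 n_skipped = skipped),
            class = "directionality_result")
}

#' Track-set MSD analysis: curves, outlier exclusion, ensemble
#'
#' Convenience wrapper running the full MSD stage on a `track_set`:
#' per-track Eq.-style time-averaged curves, the 3-SD final-lag outlier
#' exclusion, then cell-level and ensemble averaging with SEM over cells.
#'
#' @param tracks a `track_set` ([build_track_set()]).
#' @param probe which probe's tracks to analyse (default all).
#' @param max_lag_fraction see [track_msd()].
#' @return list: `ensemble` (`msd_curve`), `track_curves`, `cell_ids`,
#'   `outliers` ([remove_outliers()] result), `n_tracks_used`.
#' @export
analyze_msd <- function(tracks, probe = NULL, max_lag_fraction = 1 / 3) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is.null(probe)) tracks <- tracks[tracks$probe %in% probe, ]
  if (!nrow(tracks)) stop("no tracks to analyse")
  fi <- attr(tracks, "frame_interval")
  ids <- unique(tracks$track_id)
  curves <- lapply(ids, function(tid) {
    d <- tracks[tracks$track_id == tid, ]
    track_msd(cbind(d$x_um[order(d$frame)], d$y_um[order(d$frame)]),
              frame_interval = fi, max_lag_fraction = max_lag_fraction)
  })
  cell_ids <- vapply(ids, function(tid)
    tracks$cell_id[tracks$track_id == tid][1], 0)
  out <- remove_outliers(curves)
  ens <- ensemble_msd(curves[out$included], cell_ids[out$included])
  list(ensemble = ens, track_curves = curves, cell_ids = cell_ids,
       outliers = out, n_tracks_used = length(out$included))
}
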