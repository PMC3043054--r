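# Mean-square displacement, diffusion coefficients and per-event surface
# mobility.
#
# Unit conventions: positions nm, times ps. 1 nm^2/ps = 1e-2 cm^2/s, so a
# 3-D MSD slope s (nm^2/ps) gives D = s/6 * 1e-2 cm^2/s.

NM2_PER_PS_TO_CM2_PER_S <- 1e-2

#' Time-origin-averaged mean square displacement
#'
#' MSD over all frame pairs separated by each lag that lie inside a single
#' segment (segments never mix, so shell-conditioned curves only average
#' displacement accrued while the ion stayed in the shell).
#'
#' @param x `n x 3` matrix of continuous (unwrapped) positions, nm.
#' @param dt frame spacing, ps.
#' @param max_lag largest lag in frames (default `min(n - 1, 100)`).
#' @param segments optional data.frame with columns `first_frame`,
#'   `last_frame` (and optionally `sim`) delimiting index ranges; default one
#'   segment covering everything.
#' @return data.frame of class `"msd_curve"`: `lag` (ps), `msd` (nm^2),
#'   `n_samples`; attribute `n_contributing_sims`.
#' @export
msd_curve <- function(x, dt = 1, max_lag = NULL, segments = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(segments))
    segments <- data.frame(first_frame = 1L, last_frame = n, sim = 1L)
  if (is.null(segments$sim)) segments$sim <- 1L
  if (any(segments$first_frame < 1L) || any(segments$last_frame > n))
    stop("segment outside position series")
  if (is.null(max_lag))
    max_lag <- min(max(segments$last_frame - segments$first_frame), 100L)
  if (max_lag < 1L) stop("no valid pair at any requested lag")
  sums <- numeric(max_lag)
  cnts <- integer(max_lag)
  contrib <- logical(length(unique(segments$sim)))
  names(contrib) <- as.character(unique(segments$sim))
  for (si in seq_len(nrow(segments))) {
    a <- segments$first_frame[si]; b <- segments$last_frame[si]
    len <- b - a
    if (len < 1L) next
    contrib[as.character(segments$sim[si])] <- TRUE
    xs <- x[a:b, , drop = FALSE]
    for (lag in seq_len(min(len, max_lag))) {
      dxy <- xs[(1L + lag):(len + 1L), , drop = FALSE] -
        xs[1L:(len + 1L - lag), , drop = FALSE]
      sums[lag] <- sums[lag] + sum(dxy * dxy)
      cnts[lag] <- cnts[lag] + (len + 1L - lag)
    }
  }
  ok <- cnts > 0L
  if (!any(ok)) stop("no valid pair at any requested lag")
  out <- data.frame(lag = c(0, seq_len(max_lag)[ok] * dt),
                    msd = c(0, sums[ok] / cnts[ok]),
                    n_samples = c(sum(segments$last_frame -
                                      segments$first_frame + 1L),
                                  cnts[ok]))
  structure(out, class = c("msd_curve", "data.frame"),
            n_contributing_sims = sum(contrib))
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares line on the lag window; `D = slope / 6` for 3-D diffusion,
#' converted to cm^2/s. The fit's R-squared is reported as a linearity
#' diagnostic and a warning is raised when it falls below `r2_warn`, the sign
#' of a ballistic or confined (non-Fickian) window.
#'
#' @param msd an [msd_curve()].
#' @param fit_window `(lo, hi)` lag window in ps (default 10-100 ps).
#' @param r2_warn linearity warning threshold.
#' @return list of class `"diffusion_estimate"`: `D` (cm^2/s), `fit_window`,
#'   `slope_stderr` (cm^2/s), `linearity_r2`, `n_lags`.
#' @export
estimate_D <- function(msd, fit_window = c(10, 100), r2_warn = 0.98) {
  sel <- msd$lag >= fit_window[1] & msd$lag <= fit_window[2] & msd$lag > 0
  if (sum(sel) < 3L) stop("fewer than 3 lags inside the fit window")
  f <- stats::lm(msd ~ lag, data = msd[sel, , drop = FALSE])
  sl <- stats::coef(f)[["lag"]]
  se <- summary(f)$coefficients["lag", "Std. Error"]
  r2 <- summary(f)$r.squared
  if (is.finite(r2) && r2 < r2_warn)
    warning(sprintf("MSD window linearity R^2 = %.4f < %.2f: window may be ",
                    r2, r2_warn), "ballistic or confined", call. = FALSE)
  structure(list(D = max(sl, 0) / 6 * NM2_PER_PS_TO_CM2_PER_S,
                 fit_window = fit_window,
                 slope_stderr = se / 6 * NM2_PER_PS_TO_CM2_PER_S,
                 linearity_r2 = r2, n_lags = sum(sel)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g cm^2/s (slope stderr %.2g), window %g-%g ps, R^2 = %.4f\n",
              x$D, x$slope_stderr, x$fit_window[1], x$fit_window[2],
              x$linearity_r2))
  invisible(x)
}

#' Shell-conditioned MSD over an ensemble
#'
#' Pools residence-event segments of one shell across simulations and
#' averages the MSD over them, requiring contributions from at least
#' `min_sims` distinct simulations (segments shorter than a lag contribute
#' nothing at that lag).
#'
#' @param positions list of `n x 3` unwrapped (or protein-frame) position
#'   matrices, one per simulation.
#' @param shell_series list of integer shell-index vectors matching
#'   `positions`.
#' @param shell which shell index to condition on.
#' @param dt frame spacing (ps).
#' @param grace_time residence bridging time (ps).
#' @param min_sims minimum number of contributing simulations (default 8).
#' @param max_lag largest lag in frames.
#' @return an [msd_curve()].
#' @export
shell_conditioned_msd <- function(positions, shell_series, shell, dt = 1,
                                  grace_time = 2, min_sims = 8L,
                                  max_lag = NULL) {
  stopifnot(length(positions) == length(shell_series))
  segs <- list()
  for (i in seq_along(positions)) {
    sh <- shell_series[[i]]
    times <- (seq_along(sh) - 1) * dt
    ev <- extract_residence_events(sh, times, grace_time, shell_set = shell)
    if (nrow(ev))
      segs[[length(segs) + 1L]] <- data.frame(first_frame = ev$first_frame,
                                              last_frame = ev$last_frame,
                                              sim = i)
  }
  if (!length(segs)) stop("no residence segments in shell ", shell)
  segs <- do.call(rbind, segs)
  usable <- segs$last_frame > segs$first_frame
  if (length(unique(segs$sim[usable])) < min_sims)
    stop("only ", length(unique(segs$sim[usable])),
         " simulations contribute to shell ", shell, " (need >= ", min_sims,
         ")")
  # concatenate per-sim positions so segment indices stay valid per block
  offs <- cumsum(c(0L, vapply(positions, nrow, 1L)))
  allx <- do.call(rbind, positions)
  segs$first_frame <- segs$first_frame + offs[segs$sim]
  segs$last_frame <- segs$last_frame + offs[segs$sim]
  msd_curve(allx, dt = dt, max_lag = max_lag, segments = segs)
}

#' Per-event maximum displacement (surface mobility)
#'
#' For each residence event, the maximum over its frames of the squared
#' displacement from the position at event entry, evaluated in the
#' protein-fitted frame (global protein rotation/translation removed by
#' [superpose_to_reference()] before calling this). The distribution is
#' summarised by the exceedance curve: the fraction of events whose maximum
#' exceeds a displacement-squared threshold.
#'
#' @param events a `residence_events` data.frame (with `first_frame`,
#'   `last_frame`).
#' @param positions `n x 3` protein-frame ion positions (nm).
#' @return data.frame of class `"event_mobility"`: the event columns plus
#'   `max_msd` (nm^2).
#' @export
event_max_msd <- function(events, positions) {
  positions <- as.matrix(positions)
  if (!nrow(events)) stop("no events")
  if (any(events$last_frame > nrow(positions)) || any(events$first_frame < 1L))
    stop("event outside position series")
  mx <- vapply(seq_len(nrow(events)), function(i) {
    a <- events$first_frame[i]; b <- events$last_frame[i]
    dx <- sweep(positions[a:b, , drop = FALSE], 2L, positions[a, ])
    max(rowSums(dx * dx))
  }, numeric(1))
  out <- cbind(as.data.frame(events), max_msd = mx)
  structure(out, class = c("event_mobility", "data.frame"))
}

#' Exceedance curve of event mobilities
#'
#' @param mobility an [event_max_msd()] result (or numeric `max_msd` vector).
#' @param thresholds displacement-squared thresholds (nm^2).
#' @return data.frame with `threshold` and `percent` (share of events with
#'   `max_msd >= threshold`, in percent).
#' @export
exceedance_curve <- function(mobility, thresholds) {
  mm <- if (is.data.frame(mobility)) mobility$max_msd else as.numeric(mobility)
  data.frame(threshold = thresholds,
             percent = vapply(thresholds,
                              function(x) 100 * mean(mm >= x), numeric(1)))
}
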