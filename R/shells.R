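# Solvation-shell assignment, occupancy, residence events, survival curves
# and exponential residence-time fitting.

#' Solvation shell scheme
#'
#' A set of strictly increasing outer boundaries measured from the protein
#' surface. Shell 1 is `[0, b1)`, shell i is `[b(i-1), b(i))` (half-open),
#' and everything at or beyond the last boundary is bulk. The default is the
#' 2.5 Angstrom scheme: first shell below 0.35 nm, then 0.25 nm layers out to
#' 2.1 nm.
#'
#' @param boundaries outer boundaries in nm, strictly increasing.
#' @return object of class `"shell_scheme"`.
#' @export
shell_scheme <- function(boundaries = c(0.35, 0.60, 0.85, 1.10, 1.35, 1.60,
                                        1.85, 2.10)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || any(diff(boundaries) <= 0) ||
      boundaries[1] <= 0)
    stop("boundaries must be positive and strictly increasing")
  structure(list(boundaries = boundaries,
                 n_shells = length(boundaries),
                 bulk_index = length(boundaries) + 1L),
            class = "shell_scheme")
}

#' @export
print.shell_scheme <- function(x, ...) {
  cat("shell_scheme:", x$n_shells, "shells, boundaries (nm):",
      paste(format(x$boundaries), collapse = ", "),
      "| bulk index", x$bulk_index, "\n")
  invisible(x)
}

#' Assign each frame to a solvation shell
#'
#' Half-open intervals: a distance exactly on a boundary belongs to the outer
#' shell. Distances at or beyond the last boundary get the bulk sentinel
#' index `scheme$bulk_index`.
#'
#' @param ds a `distance_series` (or a bare numeric vector of distances, nm).
#' @param scheme a [shell_scheme()].
#' @return integer vector of shell indices (1 = innermost).
#' @export
assign_shells <- function(ds, scheme = shell_scheme()) {
  d <- if (is.data.frame(ds)) ds$d else as.numeric(ds)
  if (any(d < 0)) stop("distances must be non-negative")
  findInterval(d, c(0, scheme$boundaries), left.open = FALSE)
}

#' Distance occupancy histogram
#'
#' Percentage of time the ion spends at each distance from the protein, out
#' of the total time it spends within `d_max`, plus the running cumulative
#' percentage.
#'
#' @param ds a `distance_series` or numeric distance vector (nm).
#' @param bin_width histogram bin width (nm).
#' @param d_max only frames with `d <= d_max` enter the denominator.
#' @return data.frame of class `"occupancy_histogram"` with `d_lo`, `d_hi`,
#'   `d_mid`, `percent`, `cumulative`.
#' @export
occupancy_histogram <- function(ds, bin_width = 0.01, d_max = 1.2) {
  d <- if (is.data.frame(ds)) ds$d else as.numeric(ds)
  d <- d[d <= d_max]
  if (!length(d)) stop("no frames within d_max = ", d_max, " nm")
  breaks <- seq(0, d_max + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(d, breaks, left.open = FALSE),
                  nbins = length(breaks) - 1L)
  pct <- 100 * cnt / sum(cnt)
  structure(data.frame(d_lo = breaks[-length(breaks)], d_hi = breaks[-1],
                       d_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                       percent = pct, cumulative = cumsum(pct)),
            class = c("occupancy_histogram", "data.frame"))
}

# bridge FALSE runs of length <= g frames (not touching either end) in a
# logical vector
bridge_gaps <- function(ind, g) {
  if (g < 1L || !any(ind)) return(ind)
  r <- rle(ind)
  n <- length(r$lengths)
  fix <- which(!r$values & r$lengths <= g & seq_len(n) > 1L & seq_len(n) < n)
  if (length(fix)) {
    r$values[fix] <- TRUE
    ind <- inverse.rle(r)
  }
  ind
}

#' Extract residence events per shell
#'
#' A residence event is a maximal run of frames in one shell, where
#' excursions to other shells lasting no more than `grace_time` are bridged
#' into the run rather than terminating it (implemented as runs of at most
#' `floor(grace_time / dt)` frames, independently per shell). The exit
#' direction records whether the ion left toward the protein (`inward`),
#' away from it (`outward`), or the data ended (`end_of_data`).
#'
#' @param shells integer shell index per frame (bulk = sentinel), as from
#'   [assign_shells()].
#' @param times frame times (ps), uniform grid.
#' @param grace_time bridging time in ps (default 2).
#' @param shell_set which shell indices to extract events for; default all
#'   values present except none.
#' @return data.frame of class `"residence_events"` with columns `shell`,
#'   `t_start`, `t_end`, `duration` (ps), `first_frame`, `last_frame`
#'   (indices into the original series, bridged gaps included) and
#'   `exit_direction`.
#' @export
extract_residence_events <- function(shells, times, grace_time = 2,
                                     shell_set = NULL) {
  n <- length(shells)
  stopifnot(length(times) == n, n >= 1L)
  dt <- if (n > 1L) times[2] - times[1] else 1
  g <- as.integer(floor(grace_time / dt))
  shell_set <- shell_set %||% sort(unique(shells))
  out <- list()
  for (s in shell_set) {
    ind <- bridge_gaps(shells == s, g)
    if (!any(ind)) next
    r <- rle(ind)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      i0 <- starts[k]; i1 <- ends[k]
      nxt <- if (i1 < n) shells[i1 + 1L] else NA_integer_
      dir <- if (is.na(nxt)) "end_of_data"
             else if (nxt < s) "inward" else "outward"
      out[[length(out) + 1L]] <- data.frame(
        shell = s, t_start = times[i0],
        t_end = times[i0] + (i1 - i0 + 1L) * dt,
        duration = (i1 - i0 + 1L) * dt,
        first_frame = i0, last_frame = i1,
        exit_direction = dir, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(shell = integer(0), t_start = numeric(0), t_end = numeric(0),
               duration = numeric(0), first_frame = integer(0),
               last_frame = integer(0), exit_direction = character(0))
  ev <- ev[order(ev$t_start, ev$shell), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("residence_events", "data.frame"))
}

#' Residence survival curve
#'
#' `N(t)` = number of residence occurrences lasting at least `t`, evaluated
#' on the frame-time grid. `N(0)` equals the number of events and the curve
#' is non-increasing.
#'
#' @param durations event durations in ps (a `residence_events` data.frame is
#'   also accepted).
#' @param dt grid spacing in ps.
#' @return data.frame of class `"survival_curve"` with columns `t` and `N`.
#' @export
survival_curve <- function(durations, dt = 1) {
  if (is.data.frame(durations)) durations <- durations$duration
  if (!length(durations)) stop("no events: survival curve undefined")
  tg <- seq(0, max(durations), by = dt)
  # N(t) = #durations >= t via a sorted lookup
  sd <- sort(durations)
  N <- length(sd) - findInterval(tg, sd, left.open = TRUE)
  structure(data.frame(t = tg, N = N),
            class = c("survival_curve", "data.frame"))
}

# log-linear ls fit of log(N) ~ t on a subset; returns c(A, tau)
loglin_guess <- function(t, N) {
  ok <- N > 0
  if (sum(ok) < 2L) return(c(NA, NA))
  f <- stats::lm.fit(cbind(1, t[ok]), log(N[ok]))
  b <- f$coefficients
  if (!is.finite(b[2]) || b[2] >= 0) return(c(exp(b[1]), max(t) + 1))
  c(exp(b[1]), -1 / b[2])
}

#' Fit exponential decays to a survival curve
#'
#' Nonlinear least squares of `N(t) ~ sum_i A_i exp(-t / tau_i)` (order 1 or
#' 2) on the curve points whose count exceeds `min_count`. Start values come
#' from log-linear fits of the tail (slow component) and of the
#' early-time residual (fast component); a deterministic grid of scale
#' perturbations provides multi-start restarts, and the converged fit with
#' the lowest residual sum of squares wins, making the procedure
#' deterministic given the data and configuration. Time constants are
#' reported ascending (`tau1 < tau2`).
#'
#' @param sc a [survival_curve()] (or data.frame with `t`, `N`).
#' @param order 1 or 2 exponential components.
#' @param min_count only points with `N > min_count` are fitted (default 10).
#' @param max_restarts size cap on the restart grid.
#' @return object of class `"exp_decay_fit"`: a classic model object with
#'   `print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods.
#'   Components: `order`, `A`, `tau` (ps), `rel_rms_error`, `data` (retained
#'   points), `fitted`, `converged`, `n_retained`.
#' @export
fit_exponential <- function(sc, order = 2L, min_count = 10L,
                            max_restarts = 20L) {
  stopifnot(order %in% c(1L, 2L))
  t <- sc$t; N <- sc$N
  keep <- N > min_count
  t <- t[keep]; N <- N[keep]
  if (length(t) < 3L * order)
    stop("insufficient points after the count filter (need >= ", 3L * order,
         ", have ", length(t), ")")
  df <- data.frame(t = t, N = N)

  tail_i <- t >= stats::quantile(t, 0.6)
  gs <- loglin_guess(t[tail_i], N[tail_i])
  if (!is.finite(gs[1]) || !is.finite(gs[2]) || gs[2] <= 0)
    gs <- c(N[1] / 2, max(t) / 2)
  if (order == 1L) {
    starts0 <- list(A1 = max(gs[1], N[1]), tau1 = max(gs[2], 1e-6))
    form <- N ~ A1 * exp(-t / tau1)
    lower <- c(A1 = 1e-12, tau1 = 1e-9)
  } else {
    # anchor the slow amplitude on the last retained point, then peel it off
    # and fit the fast component on the positive early-time residual
    tau2g <- gs[2]
    A2g <- N[length(N)] * exp(t[length(t)] / tau2g)
    if (!is.finite(A2g) || A2g <= 0) A2g <- gs[1]
    A2g <- min(A2g, N[1])
    resid_head <- N - A2g * exp(-t / tau2g)
    # e-folding time of the early residual bounds the fast-component window
    efold <- which(resid_head < resid_head[1] / exp(1))[1]
    head_n <- if (is.na(efold)) ceiling(length(t) / 5) else
      min(max(3L * efold, 5L), length(t))
    head_i <- which(resid_head > 0 & seq_along(t) <= head_n)
    gf <- if (length(head_i) >= 2L)
      loglin_guess(t[head_i], resid_head[head_i]) else c(NA, NA)
    if (!is.finite(gf[1]) || !is.finite(gf[2]) || gf[2] <= 0 ||
        gf[2] >= tau2g / 4)
      gf <- c(max(N[1] - A2g, 0.1 * N[1]),
              if (!is.na(efold)) max(t[efold], t[2] - t[1]) else
                max(t[2] - t[1], tau2g / 50))
    starts0 <- list(A1 = max(gf[1], 0.01 * N[1]),
                    tau1 = max(min(gf[2], tau2g / 2), 1e-6),
                    A2 = max(A2g, 0.01 * N[1]), tau2 = max(tau2g, 1e-3))
    form <- N ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    lower <- c(A1 = 1e-12, tau1 = 1e-9, A2 = 1e-12, tau2 = 1e-9)
  }

  # deterministic restart grid: scale factors applied to the tau guesses
  fac <- c(1, 0.3, 3, 0.1, 10)
  grid <- if (order == 1L) data.frame(f1 = fac) else
    expand.grid(f1 = fac, f2 = fac)[seq_len(min(max_restarts, 25L)), ,
                                    drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    st <- starts0
    st$tau1 <- starts0$tau1 * grid$f1[r]
    if (order == 2L) st$tau2 <- starts0$tau2 * grid$f2[r]
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12 * abs(best$rss))
        best <- list(fit = fit, rss = rss)
    }
    if (!is.null(best) && r >= 1L && order == 1L) break
    if (!is.null(best) && order == 2L && r >= 1L) {
      # accept the first converged fit unless it is visibly poor
      if (best$rss <= 1e-3 * sum(N^2)) break
    }
  }
  if (is.null(best))
    stop("exponential fit failed to converge after ", nrow(grid), " restarts")

  cf <- stats::coef(best$fit)
  if (order == 1L) {
    A <- cf[["A1"]]; tau <- cf[["tau1"]]
  } else {
    A <- c(cf[["A1"]], cf[["A2"]]); tau <- c(cf[["tau1"]], cf[["tau2"]])
    o <- order(tau)
    A <- A[o]; tau <- tau[o]
  }
  fitted <- Reduce(`+`, lapply(seq_along(tau),
                               function(i) A[i] * exp(-t / tau[i])))
  res <- N - fitted
  rel_rms <- sqrt(mean(res^2)) / sqrt(mean(N^2))
  structure(list(order = order, A = A, tau = tau,
                 rel_rms_error = rel_rms,
                 data = df, fitted = fitted, converged = TRUE,
                 n_retained = length(t), min_count = min_count),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential residence-decay fit (order ", x$order, ")\n", sep = "")
  for (i in seq_along(x$tau))
    cat(sprintf("  component %d: A = %s, tau = %s ps\n", i,
                format(x$A[i], digits = digits),
                format(x$tau[i], digits = digits)))
  cat("  relative RMS error:", format(x$rel_rms_error, digits = digits),
      "on", x$n_retained, "points (N >", x$min_count, ")\n")
  invisible(x)
}

#' @export
coef.exp_decay_fit <- function(object, ...) {
  stats::setNames(c(object$A, object$tau),
                  c(paste0("A", seq_along(object$A)),
                    paste0("tau", seq_along(object$tau))))
}

#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else
    if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  Reduce(`+`, lapply(seq_along(object$tau),
                     function(i) object$A[i] * exp(-t / object$tau[i])))
}

#' @export
residuals.exp_decay_fit <- function(object, ...) object$data$N - object$fitted

#' @export
summary.exp_decay_fit <- function(object, ...) {
  s <- list(order = object$order,
            coefficients = coef(object),
            rel_rms_error = object$rel_rms_error,
            n_retained = object$n_retained,
            rss = sum(residuals(object)^2))
  class(s) <- "summary.exp_decay_fit"
  s
}

#' @export
print.summary.exp_decay_fit <- function(x, ...) {
  cat("Exponential decay fit, order", x$order, "\n")
  print(x$coefficients)
  cat("relative RMS error:", format(x$rel_rms_error), " RSS:",
      format(x$rss), " points:", x$n_retained, "\n")
  invisible(x)
}

#' @export
plot.exp_decay_fit <- function(x, log = "y", ...) {
  graphics::plot(x$data$t, x$data$N, log = log, xlab = "t (ps)",
                 ylab = "N(t)", pch = 16, cex = 0.4, ...)
  graphics::lines(x$data$t, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Mean residence time split by exit direction
#'
#' @param events a `residence_events` data.frame.
#' @param direction one or more of `"inward"`, `"outward"`, `"end_of_data"`.
#' @return data.frame with `shell`, `direction`, `n_events`, `mean_duration`
#'   (ps).
#' @export
directional_residence <- function(events,
                                  direction = c("inward", "outward")) {
  ev <- events[events$exit_direction %in% direction, , drop = FALSE]
  if (!nrow(ev))
    stop("no events with exit direction ",
         paste(direction, collapse = "/"))
  agg <- do.call(rbind, lapply(split(ev, list(ev$shell, ev$exit_direction),
                                     drop = TRUE), function(g)
    data.frame(shell = g$shell[1], direction = g$exit_direction[1],
               n_events = nrow(g), mean_duration = mean(g$duration),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$shell, agg$direction), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
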