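#' Detect peaks in a time series
#'
#' Local maxima with a prominence floor (default 1% of the window's range)
#' and a minimum separation (default 0.25 h) to suppress solver ripple.
#' Peak positions and heights are refined by a local quadratic fit through
#' the three samples around each discrete maximum.  Ties in height are
#' broken by earliest time.
#'
#' @param times Strictly increasing time grid, hours.
#' @param x Series values at `times`.
#' @param min_prominence Prominence floor as a fraction of `max(x) - min(x)`.
#' @param min_separation Minimum spacing between reported peaks, hours.
#' @return Data frame with columns `time` and `height`, ordered by time.
#' @examples
#' t <- seq(0, 30, 0.01)
#' find_peaks(t, 100 + 50 * sin(2 * pi * t / 6))
#' @export
find_peaks <- function(times, x, min_prominence = 0.01,
                       min_separation = 0.25) {
  stopifnot(length(times) == length(x), length(x) >= 3L)
  rng <- max(x) - min(x)
  if (rng == 0)
    return(data.frame(time = numeric(0), height = numeric(0)))
  n <- length(x)
  d <- diff(x)
  # indices of strict local maxima (plateaus: first index of the plateau)
  s <- sign(d)
  nz <- s != 0
  # collapse zero-slope runs: carry the previous non-zero sign forward
  sf <- s
  for (i in seq_len(n - 1L)[-1L]) if (sf[i] == 0) sf[i] <- sf[i - 1L]
  cand <- which(sf[-1L] < 0 & sf[-(n - 1L)] > 0) + 1L

  if (!length(cand))
    return(data.frame(time = numeric(0), height = numeric(0)))

  # topographic prominence: lowest descent before meeting a higher point
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    hi_l <- which(left > h)
    base_l <- min(left[seq.int(from = if (length(hi_l)) max(hi_l) else 1L,
                               to = i - 1L)])
    right <- x[seq.int(i + 1L, n)]
    hi_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) else n - i)])
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence * rng
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(time = numeric(0), height = numeric(0)))

  # enforce minimum separation, preferring higher peaks (ties: earlier time)
  ord <- order(-x[cand], times[cand])
  sel <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(times[i] - times[sel]) >= min_separation))
      sel <- c(sel, i)
  }
  sel <- sort(sel)

  # quadratic refinement on the three points around each maximum
  ref <- t(vapply(sel, function(i) {
    if (i <= 1L || i >= n) return(c(times[i], x[i]))
    t3 <- times[(i - 1L):(i + 1L)]; x3 <- x[(i - 1L):(i + 1L)]
    fit <- stats::lm.fit(cbind(1, t3 - t3[2L], (t3 - t3[2L])^2), x3)
    b <- fit$coefficients
    if (!is.finite(b[3L]) || b[3L] >= 0) return(c(times[i], x[i]))
    dt <- -b[2L] / (2 * b[3L])
    c(t3[2L] + dt, b[1L] + b[2L] * dt + b[3L] * dt^2)
  }, numeric(2)))
  data.frame(time = ref[, 1L], height = ref[, 2L])
}

#' Summarise the settled oscillatory (or steady) regime of a trajectory
#'
#' Metrics are computed on the settled window: the last `settle_fraction`
#' of the simulated span.  Amplitude is `max - min` over the window; the
#' spikyness of an oscillation is amplitude divided by the time-averaged
#' level.  A tail whose amplitude is below `1e-3` times its average is
#' classified non-oscillatory, with `peak_level` equal to the average.  A
#' window whose amplitude is above that floor but contains fewer than three
#' detected peaks (or fewer than five putative periods) cannot be
#' classified and raises an "unsettled" error.
#'
#' @param traj A `p53_trajectory` (or any data frame with a `time_h` column
#'   and the species columns).
#' @param species One of `"free_p53"`, `"total_p53"`, `"mdm2"`, `"complex"`,
#'   `"mrna"`.
#' @param settle_fraction Fraction of the span (from the end) treated as
#'   settled; default 0.5.
#' @return An object of class `p53_metrics`: list with elements `average`,
#'   `amplitude`, `peak_level` (nM), `period` (h, `NA` with fewer than two
#'   settled peaks), `spikyness`, `oscillatory`, `peaks` (data frame), and
#'   `free_to_bound_ratio` (time-averaged p/c, `NA` if the complex reaches
#'   zero).
#' @examples
#' tr <- p53_simulate(p53_parameters(), duration = 60)
#' oscillation_metrics(tr)$oscillatory    # FALSE at the resting state
#' @export
oscillation_metrics <- function(traj, species = "free_p53",
                                settle_fraction = 0.5) {
  stopifnot(is.data.frame(traj), "time_h" %in% names(traj))
  if (settle_fraction <= 0 || settle_fraction > 1)
    stop("'settle_fraction' must be in (0, 1]", call. = FALSE)
  x_all <- .species_series(traj, species)
  t_all <- traj$time_h
  span <- max(t_all) - min(t_all)
  w <- t_all >= max(t_all) - settle_fraction * span
  tt <- t_all[w]; x <- x_all[w]
  if (length(x) < 10L)
    stop("unsettled: fewer than 10 samples in the settled window",
         call. = FALSE)

  avg <- .time_average(tt, x)
  amp <- max(x) - min(x)
  floor_amp <- 1e-3 * avg
  oscillatory <- amp > floor_amp && amp > 0
  peaks <- find_peaks(tt, x)

  if (oscillatory) {
    if (nrow(peaks) < 3L)
      stop(sprintf(paste0("unsettled: amplitude %.3g nM above the oscillation ",
                          "floor but only %d peak(s) in the settled window; ",
                          "lengthen the trajectory"), amp, nrow(peaks)),
           call. = FALSE)
    period <- mean(diff(peaks$time))
    if ((settle_fraction * span) / period < 5)
      stop("unsettled: settled window shorter than 5 oscillation periods",
           call. = FALSE)
  } else {
    period <- if (nrow(peaks) >= 2L) mean(diff(peaks$time)) else NA_real_
  }

  ratio <- if ("c_nM" %in% names(traj) && all(traj$c_nM[w] > 0))
    .time_average(tt, traj$p_nM[w] / traj$c_nM[w]) else NA_real_

  structure(list(
    average = avg,
    amplitude = amp,
    peak_level = if (oscillatory) max(x) else avg,
    period = if (oscillatory) period else NA_real_,
    spikyness = if (avg > 0) amp / avg else 0,
    peaks = peaks,
    oscillatory = oscillatory,
    free_to_bound_ratio = ratio), class = "p53_metrics")
}

.time_average <- function(tt, x) {
  # trapezoidal time average (robust to non-uniform grids)
  dt <- diff(tt)
  sum((x[-1L] + x[-length(x)]) / 2 * dt) / sum(dt)
}

#' @export
print.p53_metrics <- function(x, ...) {
  cat(sprintf("settled-regime metrics: %s\n",
              if (x$oscillatory) "oscillatory" else "steady"))
  cat(sprintf("  average   %.4g nM\n  amplitude %.4g nM\n  peak      %.4g nM\n",
              x$average, x$amplitude, x$peak_level))
  if (x$oscillatory)
    cat(sprintf("  period    %.4g h\n  spikyness %.4g\n", x$period, x$spikyness))
  invisible(x)
}

#' Classify the long-run response of a parameter set
#'
#' Standardised protocol: start from the resting state when a stable
#' equilibrium exists (otherwise from the final state of a 300 h
#' pre-equilibration run), integrate 200 h, and summarise free p53 on the
#' last half of the span.  The regime is `"oscillatory"` when the settled
#' amplitude exceeds the oscillation floor; oscillations with spikyness of
#' at least 2 (amplitude at least twice the average) are labelled
#' `"spiky"`, others `"smooth"` (the boundary value 2 is spiky).
#'
#' @param params A [p53_parameters()] object.
#' @param duration Length of the standardised run, hours.
#' @param settle_fraction Settled-window fraction passed to
#'   [oscillation_metrics()].
#' @return An object of class `p53_classification`: list with elements
#'   `regime` (`"steady"` or `"oscillatory"`), `shape` (`"spiky"`,
#'   `"smooth"`, or `NA` for steady), `peak_p53` (peak free p53, nM) and
#'   `metrics` (the full [oscillation_metrics()] result).
#' @examples
#' classify_response(p53_parameters())$regime          # "steady"
#' @export
classify_response <- function(params, duration = 200, settle_fraction = 0.5) {
  validate_parameters(params)
  init <- tryCatch(resting_state(params), error = function(e) NULL)
  if (is.null(init)) {
    # no stable equilibrium: pre-equilibrate onto the attractor
    pre <- p53_simulate(params, init = p53_state(1, 1, 1, 1),
                        duration = 300, dt = 0.05)
    last <- pre[nrow(pre), ]
    init <- p53_state(last$p_nM, last$mm_nM, last$m_nM, last$c_nM)
  }
  traj <- p53_simulate(params, init = init, duration = duration, dt = 0.02)
  met <- oscillation_metrics(traj, species = "free_p53",
                             settle_fraction = settle_fraction)
  structure(list(
    regime = if (met$oscillatory) "oscillatory" else "steady",
    shape = if (met$oscillatory) {
      if (met$spikyness >= 2) "spiky" else "smooth"
    } else NA_character_,
    peak_p53 = met$peak_level,
    metrics = met), class = "p53_classification")
}

#' @export
print.p53_classification <- function(x, ...) {
  cat(sprintf("response: %s%s, peak free p53 %.4g nM\n", x$regime,
              if (!is.na(x$shape)) paste0(" (", x$shape, ")") else "",
              x$peak_p53))
  invisible(x)
}
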