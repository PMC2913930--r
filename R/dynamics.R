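#' Deterministic time course with stress events
#'
#' Integrates the feedback-loop ODEs with a stiff-capable solver
#' (`deSolve::ode`, method `lsoda`, relative tolerance `1e-8`, absolute
#' tolerance `1e-6` nM).  Stresses are applied as parameter switches at
#' exact event times: the integration is restarted at each event with the
#' scenario's fold changes applied to the parameter set active on the
#' previous interval.
#'
#' @param params A [p53_parameters()] object, active from time 0.
#' @param init Initial [p53_state()]; defaults to the resting state of
#'   `params` (see [resting_state()]).
#' @param duration Length of the simulated span, hours.
#' @param events Optional list of events, each a list with elements `time`
#'   (hours, within the span) and `scenario` (a [stress_scenario()]).
#' @param dt Output grid spacing in hours; chosen from the duration when
#'   `NULL` (at most 0.02 h, at least 2000 points).
#' @return A `p53_trajectory`: a data frame with columns `time_h`, `p_nM`,
#'   `mm_nM`, `m_nM`, `c_nM`, `total_p53_nM`, carrying the per-interval
#'   parameter timeline in attribute `params_timeline`.
#' @examples
#' tr <- p53_simulate(p53_parameters(), duration = 10)
#' range(tr$total_p53_nM)
#' @export
p53_simulate <- function(params, init = NULL, duration, events = NULL,
                         dt = NULL) {
  validate_parameters(params)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive number of hours", call. = FALSE)
  if (is.null(init)) init <- resting_state(params)
  validate_state(init)
  if (is.null(dt)) dt <- min(0.02, duration / 2000)

  ev_times <- numeric(0)
  if (length(events)) {
    ev_times <- vapply(events, function(e) e$time, numeric(1))
    if (any(ev_times < 0 | ev_times > duration))
      stop("event times must lie within [0, duration]", call. = FALSE)
    o <- order(ev_times)
    events <- events[o]
    ev_times <- ev_times[o]
  }

  bounds <- unique(c(0, ev_times, duration))
  cur <- params
  # apply any events scheduled exactly at t = 0 before the first interval
  for (e in events) if (e$time == 0) cur <- apply_scenario(e$scenario, cur)
  timeline <- list(list(time = 0, params = cur))

  rows <- list()
  y <- unclass(init)
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    if (i > 1L) {
      for (e in events) if (e$time == t0)
        cur <- apply_scenario(e$scenario, cur)
      timeline[[length(timeline) + 1L]] <- list(time = t0, params = cur)
    }
    times <- unique(c(seq(t0, t1, by = dt), t1))
    parms <- c(unlist(cur[.rate_names]), cur$hill,
               as.numeric(cur$variant == "release"))
    out <- tryCatch(
      deSolve::ode(y = y, times = times, func = "p53_derivs", parms = parms,
                   dllname = "p53loop", initfunc = "p53_initparms",
                   method = "lsoda", rtol = 1e-8, atol = 1e-6),
      warning = function(w) stop(sprintf(
        "integration failed on [%g, %g] h: %s", t0, t1, conditionMessage(w)),
        call. = FALSE))
    m <- unclass(out)
    # clamp solver-tolerance negatives
    m[, -1L][m[, -1L] < 0 & m[, -1L] > -1e-5] <- 0
    if (any(m[, -1L] < 0))
      stop(sprintf("integration produced negative concentrations on [%g, %g] h",
                   t0, t1), call. = FALSE)
    rows[[i]] <- if (i == 1L) m else m[-1L, , drop = FALSE]
    y <- m[nrow(m), -1L]
  }
  m <- do.call(rbind, rows)
  traj <- data.frame(time_h = m[, 1L], p_nM = m[, 2L], mm_nM = m[, 3L],
                     m_nM = m[, 4L], c_nM = m[, 5L])
  traj$total_p53_nM <- traj$p_nM + traj$c_nM
  structure(traj, params_timeline = timeline,
            class = c("p53_trajectory", "data.frame"))
}

#' Resting state: the stable equilibrium of a parameter set
#'
#' The canonical initial condition for stress simulations.  Fails with an
#' explicit error when no stable equilibrium exists (e.g. inside the
#' oscillatory regime), in which case a long pre-equilibration run should be
#' used instead (see [classify_response()], which does this automatically).
#'
#' @param params A [p53_parameters()] object.
#' @return The stable equilibrium as a [p53_state()].
#' @examples
#' total_p53(resting_state(p53_parameters()))   # about 100 nM
#' @export
resting_state <- function(params) {
  eq <- p53_steady_states(params)
  stable <- Filter(function(e) e$stable, eq)
  if (length(stable) == 0L)
    stop(paste0("no stable equilibrium for this parameter set (oscillatory ",
                "regime); use a long pre-equilibration run instead"),
         call. = FALSE)
  stable[[1L]]$state
}

#' @export
print.p53_trajectory <- function(x, ...) {
  tl <- attr(x, "params_timeline")
  cat(sprintf("p53 trajectory: %d points over [%g, %g] h, %d parameter interval(s)\n",
              nrow(x), min(x$time_h), max(x$time_h), length(tl)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.p53_trajectory <- function(x, species = "free_p53", ...) {
  graphics::plot(x$time_h, .species_series(x, species), type = "l",
                 xlab = "time (h)", ylab = paste(species, "(nM)"), ...)
  invisible(x)
}

.species_series <- function(traj, species) {
  switch(species,
         free_p53  = traj$p_nM,
         total_p53 = traj$total_p53_nM,
         mdm2      = traj$m_nM,
         mrna      = traj$mm_nM,
         complex   = traj$c_nM,
         stop("unknown species '", species,
              "'; use one of free_p53, total_p53, mdm2, mrna, complex",
              call. = FALSE))
}
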