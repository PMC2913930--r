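#' Two-dimensional phase diagram of the response regime
#'
#' Evaluates the standardised response protocol of [classify_response()]
#' over a grid of two parameters (the cell's own resting state when a
#' stable equilibrium exists, otherwise pre-equilibration; 200 h run;
#' metrics on the last half) and records, per cell, the peak and average
#' free p53, the spikyness, and the oscillatory flag.  `k_D` is handled
#' through `k_f` with `k_b` fixed, as everywhere else.  Cells whose
#' integration fails are recorded with `NA` metrics and the error message;
#' the scan itself never aborts.  The spikyness = 2 level set (the
#' boundary of the spiky-oscillation region) is extracted by linear
#' interpolation on grid edges (marching squares); disconnected contour
#' pieces are allowed.
#'
#' @param params Baseline parameter set.
#' @param axis_x,axis_y Axis definitions: lists with elements `name`,
#'   `lo`, `hi`, `n` and optionally `log` (default `TRUE`, log-spaced grid).
#'   The two names must differ.
#' @param duration,settle_fraction Protocol controls, as in
#'   [classify_response()].
#' @return An object of class `p53_phase_diagram`: list with `grid` (data
#'   frame with columns `axis1_value`, `axis2_value`, `peak_p53_nM`,
#'   `avg_p53_nM`, `spikyness`, `oscillatory`, `error`), `contour` (list of
#'   data frames with columns `x`, `y`), `axes`, and `protocol` metadata.
#' @examples
#' \donttest{
#' pd <- phase_diagram(p53_parameters(),
#'                     axis_x = list(name = "delta", lo = 2, hi = 60, n = 6),
#'                     axis_y = list(name = "gamma", lo = 0.1, hi = 1, n = 6))
#' }
#' @export
phase_diagram <- function(params, axis_x, axis_y, duration = 200,
                          settle_fraction = 0.5) {
  validate_parameters(params)
  ax <- .check_axis(axis_x); ay <- .check_axis(axis_y)
  if (ax$name == ay$name)
    stop("the two axes must name distinct parameters", call. = FALSE)

  cells <- expand.grid(axis1_value = ax$values, axis2_value = ay$values,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    ps <- tryCatch({
      p1 <- .set_scan_parameter(params, ax$name, cells$axis1_value[i])
      .set_scan_parameter(p1, ay$name, cells$axis2_value[i])
    }, error = function(e) e)
    if (inherits(ps, "error"))
      return(list(NA_real_, NA_real_, NA_real_, NA, conditionMessage(ps)))
    cl <- tryCatch(classify_response(ps, duration = duration,
                                     settle_fraction = settle_fraction),
                   error = function(e) e)
    if (inherits(cl, "error"))
      return(list(NA_real_, NA_real_, NA_real_, NA, conditionMessage(cl)))
    list(cl$peak_p53, cl$metrics$average, cl$metrics$spikyness,
         cl$metrics$oscillatory, NA_character_)
  })
  cells$peak_p53_nM <- vapply(res, function(r) r[[1L]], numeric(1))
  cells$avg_p53_nM <- vapply(res, function(r) r[[2L]], numeric(1))
  cells$spikyness <- vapply(res, function(r) r[[3L]], numeric(1))
  cells$oscillatory <- vapply(res, function(r) r[[4L]], logical(1))
  cells$error <- vapply(res, function(r) as.character(r[[5L]]), character(1))
  n_fail <- sum(!is.na(cells$error))
  if (n_fail > 0)
    warning(sprintf("%d of %d cells failed; see the 'error' column",
                    n_fail, nrow(cells)), call. = FALSE)

  z <- matrix(cells$spikyness, nrow = ax$n, ncol = ay$n)
  contour <- .spikyness_contour(ax$values, ay$values, z, level = 2,
                                logx = ax$log, logy = ay$log)

  structure(list(grid = cells, contour = contour,
                 axes = list(x = ax, y = ay),
                 protocol = list(duration_h = duration,
                                 settle_fraction = settle_fraction,
                                 spikyness_level = 2)),
            class = "p53_phase_diagram")
}

.check_axis <- function(axis) {
  stopifnot(is.list(axis), all(c("name", "lo", "hi", "n") %in% names(axis)))
  if (is.null(axis$log)) axis$log <- TRUE
  if (axis$n < 1 || axis$lo <= 0 || axis$hi < axis$lo)
    stop("invalid axis definition", call. = FALSE)
  axis$values <- if (axis$n == 1) axis$lo
  else if (axis$log) exp(seq(log(axis$lo), log(axis$hi), length.out = axis$n))
  else seq(axis$lo, axis$hi, length.out = axis$n)
  axis
}

.scan_parameter_names <- c(.rate_names, "k_D")

.set_scan_parameter <- function(params, name, value) {
  if (!name %in% .scan_parameter_names)
    stop("unknown scan parameter: ", name, call. = FALSE)
  do.call(set_parameters, c(list(params), stats::setNames(list(value), name)))
}

# marching-squares extraction of the z = level set; interpolation is linear
# in the (optionally log-transformed) axis coordinate
.spikyness_contour <- function(xs, ys, z, level = 2, logx = TRUE,
                               logy = TRUE) {
  tx <- if (logx) log(xs) else xs
  ty <- if (logy) log(ys) else ys
  bx <- function(v) if (logx) exp(v) else v
  by <- function(v) if (logy) exp(v) else v
  nx <- length(xs); ny <- length(ys)
  if (nx < 2 || ny < 2 || all(is.na(z))) return(list())
  segs <- list()
  interp <- function(c1, v1, c2, v2) c1 + (level - v1) / (v2 - v1) * (c2 - c1)
  for (i in seq_len(nx - 1L)) for (j in seq_len(ny - 1L)) {
    v <- c(z[i, j], z[i + 1L, j], z[i + 1L, j + 1L], z[i, j + 1L])
    if (any(is.na(v))) next
    above <- v >= level
    if (all(above) || all(!above)) next
    # edge crossings: (bottom, right, top, left)
    pts <- list()
    if (xor(above[1L], above[2L]))
      pts[[length(pts) + 1L]] <- c(interp(tx[i], v[1L], tx[i + 1L], v[2L]),
                                   ty[j])
    if (xor(above[2L], above[3L]))
      pts[[length(pts) + 1L]] <- c(tx[i + 1L],
                                   interp(ty[j], v[2L], ty[j + 1L], v[3L]))
    if (xor(above[4L], above[3L]))
      pts[[length(pts) + 1L]] <- c(interp(tx[i], v[4L], tx[i + 1L], v[3L]),
                                   ty[j + 1L])
    if (xor(above[1L], above[4L]))
      pts[[length(pts) + 1L]] <- c(tx[i],
                                   interp(ty[j], v[1L], ty[j + 1L], v[4L]))
    # pair crossings into segments (saddles: pair in listed order)
    while (length(pts) >= 2L) {
      a <- pts[[1L]]; b <- pts[[2L]]; pts <- pts[-(1:2)]
      segs[[length(segs) + 1L]] <- data.frame(
        x = bx(c(a[1L], b[1L])), y = by(c(a[2L], b[2L])))
    }
  }
  .join_segments(segs)
}

# chain segments sharing endpoints into polylines
.join_segments <- function(segs) {
  if (!length(segs)) return(list())
  eps <- 1e-9
  used <- rep(FALSE, length(segs))
  same <- function(a, b) all(abs(a - b) <= eps * (abs(a) + abs(b) + 1))
  out <- list()
  for (s in seq_along(segs)) {
    if (used[s]) next
    used[s] <- TRUE
    line <- segs[[s]]
    repeat {
      extended <- FALSE
      tail_pt <- unlist(line[nrow(line), ])
      head_pt <- unlist(line[1L, ])
      for (t in which(!used)) {
        a <- unlist(segs[[t]][1L, ]); b <- unlist(segs[[t]][2L, ])
        if (same(tail_pt, a)) {
          line <- rbind(line, segs[[t]][2L, ]); used[t] <- TRUE
        } else if (same(tail_pt, b)) {
          line <- rbind(line, segs[[t]][1L, ]); used[t] <- TRUE
        } else if (same(head_pt, a)) {
          line <- rbind(segs[[t]][2L, ], line); used[t] <- TRUE
        } else if (same(head_pt, b)) {
          line <- rbind(segs[[t]][1L, ], line); used[t] <- TRUE
        } else next
        extended <- TRUE
        break
      }
      if (!extended) break
    }
    rownames(line) <- NULL
    out[[length(out) + 1L]] <- line
  }
  out
}

#' @export
print.p53_phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram: %s x %s, %d x %d cells, %d contour piece(s) at spikyness = %g\n",
              x$axes$x$name, x$axes$y$name, x$axes$x$n, x$axes$y$n,
              length(x$contour), x$protocol$spikyness_level))
  cat(sprintf("  oscillatory cells: %d / %d\n",
              sum(x$grid$oscillatory, na.rm = TRUE), nrow(x$grid)))
  invisible(x)
}

#' Fold-change sensitivity of the average free p53 level
#'
#' Varies one parameter over fold changes spanning `[1/5, 5]` of its
#' default (log-spaced, fold 1 included exactly) while all other parameters
#' stay fixed, and reports the settled average free p53 at each fold
#' divided by its value at fold 1.  Two slope summaries are returned: the
#' maximum absolute log-log finite difference along the curve
#' (`max_slope`) and the curve-wide mean absolute log-log slope
#' (`mean_slope`, the total variation of the log response divided by the
#' log fold span).  Sensitivity rankings between parameters use
#' `mean_slope`: curves that cross the oscillation onset pick up a short,
#' steep kink where the settled average changes regime, so the local
#' maximum reflects proximity to the onset rather than how strongly the
#' parameter moves the p53 level overall.
#'
#' `beta` and `k_tl` are excluded by construction: time and mRNA
#' concentration units can always be rescaled so that both equal 1, so
#' their variation is equivalent to variation of the remaining parameters.
#'
#' @param params Baseline parameter set.
#' @param name One of `sigma`, `alpha`, `delta`, `k_t`, `gamma`, `k_D`.
#' @param n_points Number of folds (odd values place fold 1 exactly).
#' @param duration,settle_fraction Protocol controls, as in
#'   [classify_response()].
#' @return An object of class `p53_sensitivity`: list with `parameter`,
#'   `curve` (data frame: `fold`, `response`, `avg_p53_nM`, `peak_p53_nM`),
#'   `max_slope` and `mean_slope`.
#' @examples
#' \donttest{sensitivity_curve(p53_parameters(), "alpha", n_points = 5)}
#' @export
sensitivity_curve <- function(params, name, n_points = 9, duration = 200,
                              settle_fraction = 0.5) {
  validate_parameters(params)
  if (name %in% c("beta", "k_tl"))
    stop("sensitivity with respect to '", name, "' is excluded: time and ",
         "mRNA-concentration units can be rescaled so that beta = k_tl = 1, ",
         "making its variation equivalent to variation of other parameters",
         call. = FALSE)
  if (!name %in% c("sigma", "alpha", "delta", "k_t", "gamma", "k_D"))
    stop("unknown sensitivity parameter: ", name, call. = FALSE)
  if (n_points %% 2L == 0L) n_points <- n_points + 1L
  folds <- exp(seq(log(1 / 5), log(5), length.out = n_points))
  folds[(n_points + 1L) %/% 2L] <- 1

  base <- if (name == "k_D") k_D(params) else params[[name]]
  run <- function(f) {
    cl <- classify_response(.set_scan_parameter(params, name, base * f),
                            duration = duration,
                            settle_fraction = settle_fraction)
    c(avg = cl$metrics$average, peak = cl$peak_p53)
  }
  vals <- t(vapply(folds, run, numeric(2)))
  ref <- vals[folds == 1, "avg"]
  curve <- data.frame(fold = folds, response = vals[, "avg"] / ref,
                      avg_p53_nM = vals[, "avg"], peak_p53_nM = vals[, "peak"])
  dlr <- diff(log(curve$response))
  dlf <- diff(log(curve$fold))
  structure(list(parameter = name, curve = curve,
                 max_slope = max(abs(dlr / dlf)),
                 mean_slope = sum(abs(dlr)) / sum(dlf)),
            class = "p53_sensitivity")
}

#' @export
print.p53_sensitivity <- function(x, ...) {
  cat(sprintf("sensitivity of average free p53 to '%s': mean |dlog response / dlog fold| = %.3g (max %.3g)\n",
              x$parameter, x$mean_slope, x$max_slope))
  invisible(x)
}
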