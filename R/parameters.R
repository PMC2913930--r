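#' Rate constants of the p53-Mdm2 feedback loop
#'
#' Construct a validated parameter set for the four-species model of the
#' p53-Mdm2 negative feedback loop.  All rates use nanomolar and hour units.
#' The dissociation constant `k_D = k_b / k_f` is a derived quantity: the
#' constructor accepts either `k_D` (the independent pair then being
#' `k_b`/`k_D`, with `k_f` computed) or an explicit `k_f`.
#'
#' @param sigma p53 production rate, nM/h.
#' @param alpha Mdm2-independent p53 removal rate (degradation, nuclear
#'   export, sequestration, inactivating modification), 1/h.
#' @param delta Mdm2-dependent p53 degradation rate; acts on the p53-Mdm2
#'   complex, 1/h.
#' @param k_t mdm2 transcription rate constant, 1/(nM h).  Transcription is
#'   activated by p53 with Hill exponent `hill`.
#' @param k_tl Mdm2 translation rate, 1/h.
#' @param beta Mdm2 mRNA degradation rate, 1/h.
#' @param gamma Mdm2 removal rate, identical for free and complexed Mdm2, 1/h.
#' @param k_b p53-Mdm2 complex dissociation rate, 1/h.
#' @param k_D p53-Mdm2 dissociation constant `k_b/k_f`, nM.  Ignored when
#'   `k_f` is supplied.
#' @param k_f p53-Mdm2 complex formation rate, 1/(nM h), or `NULL` to derive
#'   it from `k_D`.
#' @param hill Hill exponent of mdm2 activation by p53; 2 by default
#'   (a double p53 binding site at the mdm2 promoter).
#' @param variant Convention for degradation of the complexed moieties:
#'   `"release"` (default) lets `delta` destroy the p53 moiety of the complex
#'   and release free Mdm2, and `gamma` destroy the Mdm2 moiety and release
#'   free p53; `"codegrade"` lets `gamma` destroy the entire complex.
#'
#' @return An object of class `p53_params`: a named list with elements
#'   `sigma`, `alpha`, `delta`, `k_t`, `k_tl`, `beta`, `gamma`, `k_b`, `k_f`,
#'   `hill` and `variant`.
#'
#' @examples
#' p <- p53_parameters()
#' p$k_f                 # 5000 = 7200 / 1.44
#' k_D(p)                # 1.44 nM
#' @export
p53_parameters <- function(sigma = 1000, alpha = 0.1, delta = 11,
                           k_t = 0.03, k_tl = 1.4, beta = 0.6, gamma = 0.2,
                           k_b = 7200, k_D = 1.44, k_f = NULL, hill = 2,
                           variant = c("release", "codegrade")) {
  variant <- match.arg(variant)
  if (is.null(k_f)) {
    if (!is.numeric(k_D) || length(k_D) != 1L || !is.finite(k_D) || k_D <= 0)
      stop("'k_D' must be a single positive finite number", call. = FALSE)
    k_f <- k_b / k_D
  }
  obj <- structure(
    list(sigma = sigma, alpha = alpha, delta = delta, k_t = k_t,
         k_tl = k_tl, beta = beta, gamma = gamma, k_b = k_b, k_f = k_f,
         hill = hill, variant = variant),
    class = "p53_params")
  validate_parameters(obj)
  obj
}

#' @rdname p53_parameters
#' @param params A `p53_params` object.
#' @export
k_D <- function(params) {
  stopifnot(inherits(params, "p53_params"))
  params$k_b / params$k_f
}

.rate_names <- c("sigma", "alpha", "delta", "k_t", "k_tl", "beta", "gamma",
                 "k_b", "k_f")

validate_parameters <- function(params) {
  if (!inherits(params, "p53_params"))
    stop("not a 'p53_params' object", call. = FALSE)
  for (nm in c(.rate_names, "hill")) {
    v <- params[[nm]]
    # sigma = 0 (production switched off) is admitted; all other rates must
    # be strictly positive
    lo_ok <- if (nm == "sigma") v >= 0 else v > 0
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || !lo_ok)
      stop(sprintf("parameter '%s' must be a single strictly positive finite number", nm),
           call. = FALSE)
  }
  if (!params$variant %in% c("release", "codegrade"))
    stop("unknown model variant: ", params$variant, call. = FALSE)
  invisible(params)
}

#' Update parameters, keeping the dissociation constant consistent
#'
#' Returns a copy of `params` with the named values replaced.  Assigning
#' `k_D` rewrites `k_f = k_b / k_D` with `k_b` held fixed, so the identity
#' `k_D == k_b / k_f` holds under any update path.  When both `k_b` and
#' `k_D` are given, `k_b` is applied first.
#'
#' @param params A `p53_params` object.
#' @param ... Named scalar values among `sigma`, `alpha`, `delta`, `k_t`,
#'   `k_tl`, `beta`, `gamma`, `k_b`, `k_f`, `k_D`, `hill`.
#' @return A new `p53_params` object.
#' @examples
#' p <- set_parameters(p53_parameters(), k_D = 7.2)
#' p$k_f   # 1000
#' @export
set_parameters <- function(params, ...) {
  stopifnot(inherits(params, "p53_params"))
  upd <- list(...)
  if (length(upd) == 0L) return(params)
  nms <- names(upd)
  if (is.null(nms) || any(nms == ""))
    stop("all updates must be named", call. = FALSE)
  allowed <- c(.rate_names, "k_D", "hill")
  bad <- setdiff(nms, allowed)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # apply k_b before k_D so the derived k_f is computed against the new k_b
  for (nm in intersect(c(setdiff(allowed, "k_D"), "k_D"), nms)) {
    if (nm == "k_D") {
      params$k_f <- params$k_b / upd[[nm]]
    } else {
      params[[nm]] <- upd[[nm]]
    }
  }
  validate_parameters(params)
  params
}

#' @export
print.p53_params <- function(x, ...) {
  cat("p53-Mdm2 feedback loop parameters (nM, h):\n")
  v <- unlist(x[.rate_names])
  lab <- c(sigma = "p53 production (nM/h)",
           alpha = "Mdm2-independent p53 removal (1/h)",
           delta = "Mdm2-dependent p53 degradation (1/h)",
           k_t   = "mdm2 transcription (1/(nM h))",
           k_tl  = "Mdm2 translation (1/h)",
           beta  = "Mdm2 mRNA degradation (1/h)",
           gamma = "Mdm2 removal (1/h)",
           k_b   = "complex dissociation (1/h)",
           k_f   = "complex formation (1/(nM h))")
  for (nm in .rate_names)
    cat(sprintf("  %-6s %-38s %g\n", nm, lab[[nm]], v[[nm]]))
  cat(sprintf("  %-6s %-38s %g\n", "k_D", "dissociation constant k_b/k_f (nM)", k_D(x)))
  cat(sprintf("  %-6s %-38s %g\n", "hill", "Hill exponent (mdm2 activation)", x$hill))
  if (x$variant != "release")
    cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' System state of the four-species model
#'
#' A state holds the concentrations (nM) of free nuclear p53 (`p`), Mdm2
#' mRNA (`mm`), free Mdm2 (`m`) and the p53-Mdm2 complex (`c`).
#'
#' @param p Free nuclear p53, nM.
#' @param mm Mdm2 mRNA, nM.
#' @param m Free Mdm2, nM.
#' @param c p53-Mdm2 complex, nM.
#' @return A named numeric vector of class `p53_state` with components
#'   `p`, `mm`, `m`, `c`.
#' @examples
#' s <- p53_state(10, 5, 1, 90)
#' total_p53(s)   # p + c = 100
#' @export
p53_state <- function(p = 0, mm = 0, m = 0, c = 0) {
  s <- c(p = as.numeric(p), mm = as.numeric(mm),
         m = as.numeric(m), c = as.numeric(c))
  validate_state(s)
  structure(s, class = "p53_state")
}

validate_state <- function(state) {
  if (length(state) != 4L || !is.numeric(state))
    stop("a state has exactly four numeric components (p, mm, m, c)",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("state components must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state components must be non-negative (concentrations)",
         call. = FALSE)
  invisible(state)
}

#' @rdname p53_state
#' @param state A state vector or a trajectory data frame with columns
#'   `p_nM` and `c_nM`.
#' @export
total_p53 <- function(state) {
  if (is.data.frame(state)) return(state$p_nM + state$c_nM)
  unname(state[["p"]] + state[["c"]])
}

#' @rdname p53_state
#' @export
total_mdm2 <- function(state) {
  if (is.data.frame(state)) return(state$m_nM + state$c_nM)
  unname(state[["m"]] + state[["c"]])
}
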