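#' Right-hand side of the feedback-loop ODEs
#'
#' Instantaneous rates of change (nM/h) of the four species.  The model is
#'
#' \deqn{dp/dt = \sigma - \alpha p - k_f p m + k_b c + \gamma c}
#' \deqn{dm_m/dt = k_t p^{h} - \beta m_m}
#' \deqn{dm/dt = k_{tl} m_m - \gamma m - k_f p m + (k_b + \delta) c}
#' \deqn{dc/dt = k_f p m - (k_b + \delta + \gamma) c}
#'
#' with Hill exponent `h = 2` by default.  Mass bookkeeping under the
#' default `"release"` convention: degradation of the p53 moiety of the
#' complex (rate `delta`) returns one free Mdm2; degradation of the Mdm2
#' moiety (rate `gamma`, equal for free and bound Mdm2) returns one free
#' p53.  Under `"codegrade"`, `gamma` acting on the complex destroys both
#' moieties (the `+ gamma c` term is absent from `dp/dt`).
#'
#' @param state Non-negative state vector (see [p53_state()]).
#' @param params A [p53_parameters()] object.
#' @return Named numeric vector of the four rates, order `p`, `mm`, `m`, `c`.
#' @examples
#' p53_rhs(p53_state(), p53_parameters())     # only production survives
#' @export
p53_rhs <- function(state, params) {
  validate_state(state)
  validate_parameters(params)
  .rhs(state, params)
}

# unvalidated core, shared with the ODE driver
.rhs <- function(state, params) {
  p <- state[[1L]]; mm <- state[[2L]]; m <- state[[3L]]; cc <- state[[4L]]
  form <- params$k_f * p * m
  rel <- if (params$variant == "release") params$gamma * cc else 0
  c(p  = params$sigma - params$alpha * p - form + params$k_b * cc + rel,
    mm = params$k_t * p^params$hill - params$beta * mm,
    m  = params$k_tl * mm - params$gamma * m - form +
         (params$k_b + params$delta) * cc,
    c  = form - (params$k_b + params$delta + params$gamma) * cc)
}

#' Jacobian of the feedback-loop ODEs
#'
#' Analytic 4x4 matrix of partial derivatives of [p53_rhs()] with respect to
#' the state, used for linear stability of equilibria and oscillation-onset
#' detection.
#'
#' @inheritParams p53_rhs
#' @return A 4x4 numeric matrix; rows and columns ordered `p`, `mm`, `m`, `c`.
#' @export
p53_jacobian <- function(state, params) {
  validate_state(state)
  validate_parameters(params)
  .jacobian(state, params)
}

.jacobian <- function(state, params) {
  p <- state[[1L]]; m <- state[[3L]]
  h <- params$hill
  rel <- if (params$variant == "release") params$gamma else 0
  J <- rbind(
    c(-params$alpha - params$k_f * m, 0, -params$k_f * p, params$k_b + rel),
    c(h * params$k_t * p^(h - 1), -params$beta, 0, 0),
    c(-params$k_f * m, params$k_tl, -params$gamma - params$k_f * p,
      params$k_b + params$delta),
    c(params$k_f * m, 0, params$k_f * p,
      -(params$k_b + params$delta + params$gamma)))
  dimnames(J) <- list(c("p", "mm", "m", "c"), c("p", "mm", "m", "c"))
  J
}

#' Equilibria of the feedback loop and their stability
#'
#' Solves the steady-state equations by a one-dimensional reduction.  At
#' equilibrium `mm = (k_t/beta) p^h`, total Mdm2 `m + c = (k_tl/gamma) mm`,
#' and `c = k_f p m / (k_b + delta + gamma)`; the remaining scalar equation
#' in `p` (p53 balance `sigma = alpha p + delta c`, plus `gamma c` under the
#' co-degradation variant) is solved by bracketed root finding on
#' `[1e-6, 1e4]` nM and polished by Newton iteration on the full system.
#' Stability is classified from the eigenvalues of the Jacobian (real parts
#' compared to zero with tolerance `1e-8` per hour).
#'
#' @param params A [p53_parameters()] object.
#' @param tol Relative tolerance for the bracketed root search.
#' @return A list of equilibria, each a list with elements `state`
#'   (a [p53_state()]), `stable` (logical) and `eigenvalues` (complex,
#'   ordered by decreasing real part).
#' @examples
#' eq <- p53_steady_states(p53_parameters())[[1]]
#' total_p53(eq$state)    # about 100 nM
#' eq$stable              # TRUE: the resting state
#' @export
p53_steady_states <- function(params, tol = 1e-10) {
  validate_parameters(params)
  if (params$hill != 2)
    stop("equilibrium reduction assumes a Hill exponent of 2", call. = FALSE)
  K <- params$k_b + params$delta + params$gamma
  a <- params$k_tl * params$k_t / (params$gamma * params$beta)
  # effective removal acting on the complex in the p53 balance:
  # sigma = alpha p + delta c (release) / sigma = alpha p + (delta+gamma) c
  drem <- params$delta + if (params$variant == "codegrade") params$gamma else 0
  cfun <- function(p) {
    Tm <- a * p^2
    params$k_f * p * Tm / (K + params$k_f * p)
  }
  resid <- function(p) params$sigma - params$alpha * p - drem * cfun(p)

  state_at <- function(p) {
    cc <- cfun(p)
    p53_state(p = p, mm = params$k_t * p^2 / params$beta,
              m = a * p^2 - cc, c = cc)
  }

  if (params$sigma == 0) {
    # without production every species decays: the origin is the equilibrium
    st <- p53_state()
    ev <- eigen(.jacobian(st, params), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    return(list(list(state = st, stable = all(Re(ev) < 1e-8),
                     eigenvalues = ev)))
  }

  lo <- 1e-6; hi <- 1e4
  if (resid(lo) <= 0 || resid(hi) >= 0)
    stop("no equilibrium found in the search bracket [1e-6, 1e4] nM",
         call. = FALSE)
  root <- stats::uniroot(resid, c(lo, hi), tol = tol * hi)$root
  # Newton polish on the full 4-D system
  y <- unclass(state_at(root))
  for (i in 1:8) {
    f <- .rhs(y, params)
    if (max(abs(f)) < 1e-10) break
    step <- solve(.jacobian(y, params), -f)
    y <- pmax(y + step, 0)
  }
  st <- p53_state(y[["p"]], y[["mm"]], y[["m"]], y[["c"]])
  ev <- eigen(.jacobian(st, params), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(list(state = st, stable = all(Re(ev) < 1e-8), eigenvalues = ev))
}
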