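#' Stress scenarios as per-parameter fold changes
#'
#' A stress is encoded as a named set of multiplicative fold changes of the
#' model's rate constants, together with the direction (sign pattern) each
#' change must respect.  Parameters absent from the map are untouched.
#' Entries for `k_D` act on the formation rate `k_f` with `k_b` held fixed.
#'
#' @param name Scenario identifier.
#' @param fold_changes Named numeric vector of strictly positive
#'   multipliers; names among `sigma`, `alpha`, `delta`, `k_t`, `k_tl`,
#'   `beta`, `gamma`, `k_b`, `k_f`, `k_D`.
#' @param sign_pattern Named character vector over the same names with
#'   values `"increase"` or `"decrease"`; inferred from the multipliers when
#'   `NULL`.
#' @return An object of class `p53_scenario`.
#' @examples
#' stress_scenario("nutlin", c(k_D = 5))
#' @export
stress_scenario <- function(name, fold_changes, sign_pattern = NULL) {
  fold_changes <- unlist(fold_changes)
  nms <- names(fold_changes)
  allowed <- c(.rate_names, "k_D")
  if (length(fold_changes) && (is.null(nms) || any(!nms %in% allowed)))
    stop("fold changes must be named after model parameters (",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  if (any(!is.finite(fold_changes) | fold_changes <= 0))
    stop("all fold changes must be strictly positive and finite",
         call. = FALSE)
  if (is.null(sign_pattern))
    sign_pattern <- ifelse(fold_changes >= 1, "increase", "decrease")
  if (length(fold_changes)) names(sign_pattern) <- nms
  obj <- structure(list(name = name,
                        fold_changes = fold_changes,
                        sign_pattern = sign_pattern),
                   class = "p53_scenario")
  .check_signs(obj)
  obj
}

.check_signs <- function(scenario) {
  fc <- scenario$fold_changes
  sp <- scenario$sign_pattern
  for (nm in names(fc)) {
    dir <- sp[[nm]]
    ok <- switch(dir,
                 increase = fc[[nm]] >= 1,
                 decrease = fc[[nm]] <= 1,
                 stop("sign pattern entries must be 'increase' or 'decrease'",
                      call. = FALSE))
    if (!ok)
      stop(sprintf(paste0("scenario '%s': fold change %.4g for '%s' violates ",
                          "its sign pattern ('%s')"),
                   scenario$name, fc[[nm]], nm, dir), call. = FALSE)
  }
  invisible(scenario)
}

#' @export
print.p53_scenario <- function(x, ...) {
  cat(sprintf("stress scenario '%s':\n", x$name))
  if (!length(x$fold_changes)) cat("  (identity: no parameter changed)\n")
  for (nm in names(x$fold_changes))
    cat(sprintf("  %-6s x %-8.4g (%s)\n", nm, x$fold_changes[[nm]],
                x$sign_pattern[[nm]]))
  invisible(x)
}

# DNA-damage fold changes frozen from calibrate_dna_damage() at the default
# parameter set (grid search + refinement against the published peak
# schedule); regenerate with calibrate_dna_damage(p53_parameters()).
.dna_damage_folds <- c(gamma = 3.1299177, delta = 0.61323756, k_D = 2.65914795)

#' Built-in stress scenarios
#'
#' The packaged stresses touch the parameters indicated by their biology:
#' Nutlin weakens p53-Mdm2 binding (`k_D` up, nothing else); DNA damage
#' increases Mdm2 auto-ubiquitination, decreases p53 ubiquitination by Mdm2
#' and weakens binding (`gamma` up, `delta` down, `k_D` up — magnitudes
#' calibrated to the published peak schedule, see
#' [calibrate_dna_damage()]); hypoxia suppresses p53 transactivation and
#' HIF shields p53 from degradation (`k_t` down, `delta` down); oncogene
#' activation induces ARF, which inhibits Mdm2's ligase activity (`delta`
#' down); nitric oxide phosphorylates p53, blocking Mdm2-mediated
#' degradation (`delta` down); ribonucleotide depletion redistributes p53
#' to the nucleus (`sigma` up).  Uncalibrated magnitudes default to
#' `magnitude`-fold in the indicated direction so stresses are comparable
#' at matched fold changes.
#'
#' @param magnitude Default fold magnitude for the uncalibrated stresses.
#' @param dna_damage_folds Named multipliers for the DNA-damage scenario;
#'   defaults to the packaged calibrated values.
#' @return Named list of [stress_scenario()] objects with entries
#'   `nutlin`, `dna_damage`, `hypoxia`, `oncogene`, `nitric_oxide`,
#'   `ribonucleotide_depletion`.
#' @examples
#' names(builtin_scenarios())
#' builtin_scenarios()$oncogene
#' @export
builtin_scenarios <- function(magnitude = 5,
                              dna_damage_folds = .dna_damage_folds) {
  stopifnot(magnitude > 1)
  list(
    nutlin = stress_scenario("nutlin", c(k_D = magnitude)),
    dna_damage = stress_scenario(
      "dna_damage", dna_damage_folds,
      sign_pattern = c(gamma = "increase", delta = "decrease",
                       k_D = "increase")),
    hypoxia = stress_scenario(
      "hypoxia", c(k_t = 1 / magnitude, delta = 1 / magnitude)),
    oncogene = stress_scenario("oncogene", c(delta = 1 / magnitude)),
    nitric_oxide = stress_scenario("nitric_oxide", c(delta = 1 / magnitude)),
    ribonucleotide_depletion = stress_scenario(
      "ribonucleotide_depletion", c(sigma = magnitude)))
}

#' Apply a stress scenario to a parameter set
#'
#' Returns a new parameter set with each named fold change applied
#' multiplicatively; the input is untouched.  A `k_D` multiplier rewrites
#' `k_f = k_b / (k_D * multiplier)` with `k_b` fixed.  Fold changes that
#' violate the scenario's sign pattern are rejected.
#'
#' @param scenario A [stress_scenario()].
#' @param params A [p53_parameters()] object.
#' @return A new `p53_params` object.
#' @examples
#' p <- apply_scenario(builtin_scenarios()$nutlin, p53_parameters())
#' p$k_f    # 7200 / (1.44 * 5) = 1000
#' @export
apply_scenario <- function(scenario, params) {
  stopifnot(inherits(scenario, "p53_scenario"))
  validate_parameters(params)
  .check_signs(scenario)
  out <- params
  for (nm in names(scenario$fold_changes)) {
    mult <- scenario$fold_changes[[nm]]
    if (nm == "k_D") {
      out$k_f <- out$k_b / (k_D(out) * mult)
    } else {
      out[[nm]] <- out[[nm]] * mult
    }
  }
  validate_parameters(out)
  out
}

#' Calibrate the DNA-damage scenario to the published peak schedule
#'
#' Searches for fold changes restricted to the DNA-damage sign pattern
#' (`gamma` up, `delta` down, `k_D` up) such that, applied at time zero to
#' the resting state, the free-p53 response reproduces the peak schedule
#' measured in single cells after ionizing radiation: first peak near
#' 30 min, second near 6 h, third within 9-13 h, with the second peak about
#' half the height of the first and the third about 2.5-fold lower than the
#' first.
#'
#' The loss is the sum of squared relative errors on (t1, t2, h1/h2, h1/h3)
#' against (0.5 h, 6 h, 2, 2.5) plus a hinge penalty when t3 leaves
#' `[9, 13]` h; candidates with fewer than three detected peaks incur a
#' large penalty.  The search is a coarse log-spaced grid (7 points per
#' axis over multipliers `[1, 50]` for `gamma` and `k_D` and `[1/50, 1]`
#' for `delta`) followed by iterative local log-grid refinement.  The
#' procedure is deterministic (no randomness).
#'
#' @param params Baseline parameters (resting state is computed from them).
#' @param grid_points Points per axis of the coarse grid.
#' @param refine Number of local refinement passes.
#' @param verbose Print the achieved schedule.
#' @return A [stress_scenario()] named `"dna_damage"` with attribute
#'   `achieved`: named vector `t1`, `t2`, `t3` (h), `r12`, `r13`, `loss`.
#' @export
calibrate_dna_damage <- function(params = p53_parameters(), grid_points = 7,
                                 refine = 3, verbose = TRUE) {
  validate_parameters(params)
  rest <- resting_state(params)

  evaluate <- function(g, d, k) {
    ps <- apply_scenario(stress_scenario(
      "cand", c(gamma = g, delta = d, k_D = k),
      sign_pattern = c(gamma = "increase", delta = "decrease",
                       k_D = "increase")), params)
    traj <- p53_simulate(ps, init = rest, duration = 16, dt = 0.005)
    pk <- find_peaks(traj$time_h, traj$p_nM)
    if (nrow(pk) < 3L)
      return(list(loss = 1e6 + (3 - nrow(pk)), sched = NULL))
    t1 <- pk$time[1L]; t2 <- pk$time[2L]; t3 <- pk$time[3L]
    r12 <- pk$height[1L] / pk$height[2L]
    r13 <- pk$height[1L] / pk$height[3L]
    loss <- ((t1 - 0.5) / 0.5)^2 + ((t2 - 6) / 6)^2 +
      ((r12 - 2) / 2)^2 + ((r13 - 2.5) / 2.5)^2 +
      (max(0, 9 - t3) / 9)^2 + (max(0, t3 - 13) / 13)^2
    list(loss = loss,
         sched = c(t1 = t1, t2 = t2, t3 = t3, r12 = r12, r13 = r13))
  }

  search_grid <- function(gs, ds, ks, best) {
    for (g in gs) for (d in ds) for (k in ks) {
      res <- evaluate(g, d, k)
      if (res$loss < best$loss)
        best <- list(loss = res$loss, g = g, d = d, k = k, sched = res$sched)
    }
    best
  }

  lg <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  gs0 <- lg(1, 50, grid_points)
  ds0 <- lg(1 / 50, 1, grid_points)
  ks0 <- lg(1, 50, grid_points)
  coarse <- expand.grid(g = gs0, d = ds0, k = ks0, KEEP.OUT.ATTRS = FALSE)
  coarse$loss <- vapply(seq_len(nrow(coarse)), function(i)
    evaluate(coarse$g[i], coarse$d[i], coarse$k[i])$loss, numeric(1))
  if (min(coarse$loss) >= 1e6)
    stop("calibration failed: no candidate on the coarse grid produced ",
         "three peaks", call. = FALSE)

  # the loss surface is multimodal: refine the best few coarse candidates
  # with a shrinking local log-grid each, clipped to the search bounds,
  # and keep the overall argmin
  starts <- utils::head(order(coarse$loss), 5L)
  width <- (50 / 1)^(1 / (grid_points - 1))   # one coarse-grid spacing
  best <- list(loss = Inf)
  for (s in starts) {
    inc <- list(loss = coarse$loss[s], g = coarse$g[s], d = coarse$d[s],
                k = coarse$k[s],
                sched = evaluate(coarse$g[s], coarse$d[s], coarse$k[s])$sched)
    for (r in seq_len(refine)) {
      span <- width^(1 / r)
      gs <- lg(max(1, inc$g / span), min(50, inc$g * span), 5)
      ds <- lg(max(1 / 50, inc$d / span), min(1, inc$d * span), 5)
      ks <- lg(max(1, inc$k / span), min(50, inc$k * span), 5)
      inc <- search_grid(gs, ds, ks, inc)
    }
    if (inc$loss < best$loss) best <- inc
  }

  sched <- best$sched
  ok <- sched[["t1"]] >= 0.25 && sched[["t1"]] <= 0.75 &&
    sched[["t2"]] >= 5 && sched[["t2"]] <= 7 &&
    sched[["t3"]] >= 9 && sched[["t3"]] <= 13 &&
    sched[["r12"]] >= 1.5 && sched[["r12"]] <= 2.5 &&
    sched[["r13"]] >= 1.8 && sched[["r13"]] <= 3.2
  if (!ok)
    stop(sprintf(paste0("calibration could not meet the target bands; best ",
                        "schedule: t1=%.3g h, t2=%.3g h, t3=%.3g h, ",
                        "h1/h2=%.3g, h1/h3=%.3g"),
                 sched[["t1"]], sched[["t2"]], sched[["t3"]],
                 sched[["r12"]], sched[["r13"]]), call. = FALSE)

  if (verbose)
    message(sprintf(paste0("calibrated dna_damage: gamma x%.4g, delta x%.4g, ",
                           "k_D x%.4g | peaks at %.3g, %.3g, %.3g h; ",
                           "h1/h2=%.3g, h1/h3=%.3g (loss %.3g)"),
                    best$g, best$d, best$k, sched[["t1"]], sched[["t2"]],
                    sched[["t3"]], sched[["r12"]], sched[["r13"]], best$loss))

  out <- stress_scenario(
    "dna_damage", c(gamma = best$g, delta = best$d, k_D = best$k),
    sign_pattern = c(gamma = "increase", delta = "decrease",
                     k_D = "increase"))
  attr(out, "achieved") <- c(sched, loss = best$loss)
  out
}

#' Model the mdm2 SNP309 promoter polymorphism
#'
#' The G allele of SNP309 increases mdm2 transcription; the model encodes a
#' genotype as a shift of the resting parameter set towards higher `k_t`.
#' The TT genotype leaves `k_t` unchanged, GG multiplies it by `g_fold`,
#' and TG uses the geometric mean of the two (no quantitative allele dosage
#' is available).  Downstream stress runs should start from the variant's
#' own resting state.
#'
#' @param params Baseline (TT) parameters.
#' @param genotype `"TT"`, `"TG"` or `"GG"`.
#' @param g_fold Fold increase of `k_t` for the GG genotype; must exceed 1.
#' @return A new `p53_params` object.
#' @examples
#' snp309_variant(p53_parameters(), "GG", g_fold = 2)$k_t    # 0.06
#' @export
snp309_variant <- function(params, genotype = c("TT", "TG", "GG"),
                           g_fold = 2) {
  genotype <- match.arg(genotype)
  validate_parameters(params)
  if (!is.numeric(g_fold) || length(g_fold) != 1L || !is.finite(g_fold) ||
      g_fold <= 1)
    stop("'g_fold' must be a single number > 1", call. = FALSE)
  mult <- switch(genotype, TT = 1, TG = sqrt(g_fold), GG = g_fold)
  set_parameters(params, k_t = params$k_t * mult)
}
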