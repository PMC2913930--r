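# Expensive shared computations, evaluated once per test session.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache))
    assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache)
}

# full DNA-damage calibration (grid search + refinement)
cached_calibration <- function() {
  cached("calibration", calibrate_dna_damage(p53_parameters(),
                                             verbose = FALSE))
}

# sensitivity curves for all six admissible parameters
cached_sensitivity_curves <- function() {
  cached("sensitivity", {
    nms <- c("sigma", "alpha", "delta", "k_t", "gamma", "k_D")
    stats::setNames(
      lapply(nms, function(nm) sensitivity_curve(p53_parameters(), nm,
                                                 n_points = 9)),
      nms)
  })
}

# standardized classification of the packaged stresses at 5-fold magnitude
cached_stress_classification <- function(name) {
  cached(paste0("class_", name), {
    sc <- builtin_scenarios()[[name]]
    classify_response(apply_scenario(sc, p53_parameters()))
  })
}
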