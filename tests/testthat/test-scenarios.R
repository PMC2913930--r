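test_that("built-in scenarios touch exactly the parameters their biology dictates", {
  sc <- builtin_scenarios()
  expect_setequal(names(sc), c("nutlin", "dna_damage", "hypoxia", "oncogene",
                               "nitric_oxide", "ribonucleotide_depletion"))
  expect_equal(names(sc$nutlin$fold_changes), "k_D")
  expect_gt(sc$nutlin$fold_changes[["k_D"]], 1)
  expect_equal(names(sc$oncogene$fold_changes), "delta")
  expect_lt(sc$oncogene$fold_changes[["delta"]], 1)
  expect_setequal(names(sc$hypoxia$fold_changes), c("k_t", "delta"))
  expect_true(all(sc$hypoxia$fold_changes < 1))
  expect_setequal(names(sc$dna_damage$fold_changes),
                  c("gamma", "delta", "k_D"))
  expect_gt(sc$dna_damage$fold_changes[["gamma"]], 1)
  expect_lt(sc$dna_damage$fold_changes[["delta"]], 1)
  expect_gt(sc$dna_damage$fold_changes[["k_D"]], 1)
  expect_equal(names(sc$nitric_oxide$fold_changes), "delta")
  expect_lt(sc$nitric_oxide$fold_changes[["delta"]], 1)
  expect_equal(names(sc$ribonucleotide_depletion$fold_changes), "sigma")
  expect_gt(sc$ribonucleotide_depletion$fold_changes[["sigma"]], 1)
})

test_that("applying scenarios is multiplicative, invertible and side-effect free", {
  p <- p53_parameters()
  # identity
  expect_equal(apply_scenario(stress_scenario("noop", numeric(0)), p), p)
  # nutlin x5 rewrites only k_f
  p5 <- apply_scenario(builtin_scenarios()$nutlin, p)
  expect_equal(p5$k_f, 7200 / (1.44 * 5))
  expect_equal(p5[setdiff(p53loop:::.rate_names, "k_f")],
               p[setdiff(p53loop:::.rate_names, "k_f")])
  expect_equal(p$k_f, 5000)   # original untouched
  # exact group inverse
  scen <- builtin_scenarios()$dna_damage
  inv <- stress_scenario("undo", 1 / scen$fold_changes)
  back <- apply_scenario(inv, apply_scenario(scen, p))
  expect_equal(unlist(back[p53loop:::.rate_names]),
               unlist(p[p53loop:::.rate_names]), tolerance = 1e-12)
})

test_that("fold changes violating the printed sign pattern are rejected", {
  expect_error(stress_scenario("bad", c(delta = 2),
                               sign_pattern = c(delta = "decrease")),
               "delta")
  sc <- stress_scenario("ok", c(gamma = 2))
  sc$fold_changes[["gamma"]] <- 0.5    # tampered after construction
  expect_error(apply_scenario(sc, p53_parameters()), "gamma")
  expect_error(stress_scenario("bad", c(delta = -1)), "positive")
  expect_error(stress_scenario("bad", c(2)), "named")
})

test_that("the packaged DNA-damage scenario reproduces the published schedule", {
  p <- p53_parameters()
  tr <- p53_simulate(apply_scenario(builtin_scenarios()$dna_damage, p),
                     init = resting_state(p), duration = 16, dt = 0.005)
  pk <- find_peaks(tr$time_h, tr$p_nM)
  expect_gte(nrow(pk), 3)
  expect_equal(pk$time[1], 0.5, tolerance = 0.5)       # ~30 min
  expect_equal(pk$time[2], 6, tolerance = 1 / 6)       # ~6 h
  expect_gte(pk$time[3], 9); expect_lte(pk$time[3], 13)
  expect_equal(pk$height[1] / pk$height[2], 2, tolerance = 0.25)
  expect_equal(pk$height[1] / pk$height[3], 2.5, tolerance = 0.28)
})

test_that("hypoxia responds more strongly than oncogene at matched fold changes", {
  hyp <- cached_stress_classification("hypoxia")$metrics
  onc <- cached_stress_classification("oncogene")$metrics
  expect_gt(hyp$amplitude, onc$amplitude)
  expect_gt(hyp$average, onc$average)
})

test_that("weakening p53-Mdm2 binding five-fold raises peak p53 only modestly", {
  base_peak <- classify_response(p53_parameters())$peak_p53
  nut_peak <- cached_stress_classification("nutlin")$peak_p53
  expect_lt(nut_peak / base_peak, 2)
})

test_that("hypoxia oscillates with a longer period than DNA damage", {
  hyp <- cached_stress_classification("hypoxia")
  dna <- cached_stress_classification("dna_damage")
  expect_equal(hyp$regime, "oscillatory")
  expect_equal(dna$regime, "oscillatory")
  expect_gt(hyp$metrics$period, dna$metrics$period)
})

test_that("higher mdm2 transcription at rest weakens the stress response monotonically", {
  p <- p53_parameters()
  scen <- builtin_scenarios()$dna_damage
  peak_after_damage <- function(params) {
    tr <- p53_simulate(apply_scenario(scen, params),
                       init = resting_state(params), duration = 24,
                       dt = 0.01)
    max(tr$p_nM)
  }
  tt_peak <- peak_after_damage(p)
  gg_peaks <- vapply(c(1.5, 2, 3, 5), function(g)
    peak_after_damage(snp309_variant(p, "GG", g)), numeric(1))
  expect_true(all(gg_peaks < tt_peak))
  expect_true(all(diff(c(tt_peak, gg_peaks)) < 0))   # non-increasing ladder
})

test_that("a strong G-allele shift suppresses stress-induced oscillations", {
  p <- snp309_variant(p53_parameters(), "GG", g_fold = 25)
  cl <- classify_response(
    apply_scenario(builtin_scenarios()$dna_damage, p))
  expect_equal(cl$regime, "steady")
})
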