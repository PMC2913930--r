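test_that("simulation from the resting state stays at the resting state", {
  p <- p53_parameters()
  rest <- resting_state(p)
  tr <- p53_simulate(p, init = rest, duration = 50)
  for (col in c("p_nM", "mm_nM", "m_nM", "c_nM")) {
    ref <- switch(col, p_nM = rest[["p"]], mm_nM = rest[["mm"]],
                  m_nM = rest[["m"]], c_nM = rest[["c"]])
    expect_lt(max(abs(tr[[col]] - ref)) / ref, 1e-3)
  }
})

test_that("DNA damage triggers at least three damped free-p53 peaks", {
  p <- p53_parameters()
  tr <- p53_simulate(p, duration = 30, events = list(
    list(time = 0, scenario = builtin_scenarios()$dna_damage)))
  pk <- find_peaks(tr$time_h, tr$p_nM)
  expect_gte(nrow(pk), 3)
  expect_true(all(diff(pk$height[1:3]) < 0))
})

test_that("a stress followed by its inverse relaxes back to rest", {
  p <- p53_parameters()
  rest <- resting_state(p)
  scen <- builtin_scenarios()$dna_damage
  inv <- stress_scenario("undo", 1 / scen$fold_changes)
  tr <- p53_simulate(p, init = rest, duration = 120, events = list(
    list(time = 0, scenario = scen), list(time = 20, scenario = inv)))
  # parameters after both events equal the originals exactly
  tl <- attr(tr, "params_timeline")
  final_pars <- tl[[length(tl)]]$params
  expect_equal(unlist(final_pars[p53loop:::.rate_names]),
               unlist(p[p53loop:::.rate_names]), tolerance = 1e-12)
  last <- tr[nrow(tr), ]
  expect_lt(abs(last$p_nM - rest[["p"]]) / rest[["p"]], 0.01)
  expect_lt(abs(last$total_p53_nM - total_p53(rest)) / total_p53(rest), 0.01)
})

test_that("event times outside the span and negative inputs are rejected", {
  p <- p53_parameters()
  expect_error(p53_simulate(p, duration = -1), "positive")
  expect_error(p53_simulate(p, duration = 10, events = list(
    list(time = 20, scenario = builtin_scenarios()$nutlin))), "within")
  expect_error(p53_simulate(p, init = c(p = -1, mm = 0, m = 0, c = 0),
                            duration = 10), "non-negative")
})

test_that("oscillation metrics recover the closed-form sinusoid", {
  sin_tr <- fixtures()$sinusoid    # 100 + 50 sin(2 pi t / 6) over 60 h
  m <- oscillation_metrics(sin_tr, species = "free_p53")
  expect_equal(m$average, 100, tolerance = 1e-3)
  expect_equal(m$amplitude, 100, tolerance = 1e-3)   # max - min
  expect_equal(m$period, 6, tolerance = 1e-3)
  expect_equal(m$spikyness, 1, tolerance = 1e-2)
  expect_true(m$oscillatory)
  # every detected inter-peak interval matches the analytic period to 1%
  expect_true(all(abs(diff(m$peaks$time) - 6) / 6 < 0.01))
})

test_that("a constant trajectory is steady with zero spikyness", {
  tt <- seq(0, 50, 0.01)
  tr <- structure(data.frame(time_h = tt, p_nM = rep(100, length(tt)),
                             mm_nM = 0, m_nM = 0, c_nM = 0,
                             total_p53_nM = 100),
                  class = c("p53_trajectory", "data.frame"))
  m <- oscillation_metrics(tr)
  expect_equal(m$average, 100)
  expect_equal(m$amplitude, 0)
  expect_equal(m$spikyness, 0)
  expect_equal(m$peak_level, 100)
  expect_false(m$oscillatory)
})

test_that("a window holding too few peaks raises an unsettled error", {
  sin_tr <- fixtures()$sinusoid
  expect_error(oscillation_metrics(sin_tr, settle_fraction = 0.2),
               "unsettled")
})

test_that("the doubled-gamma oscillator settles into a finite-period cycle", {
  cl <- classify_response(set_parameters(p53_parameters(), gamma = 0.4))
  expect_equal(cl$regime, "oscillatory")
  expect_true(is.finite(cl$metrics$period))
  expect_gt(cl$metrics$period, 0)
})

test_that("settled metrics are insensitive to doubling the trajectory span", {
  p <- set_parameters(p53_parameters(), gamma = 0.4)
  pre <- p53_simulate(p, init = p53_state(1, 1, 1, 1), duration = 300,
                      dt = 0.05)
  last <- pre[nrow(pre), ]
  init <- p53_state(last$p_nM, last$mm_nM, last$m_nM, last$c_nM)
  m1 <- oscillation_metrics(p53_simulate(p, init = init, duration = 200,
                                         dt = 0.02))
  m2 <- oscillation_metrics(p53_simulate(p, init = init, duration = 400,
                                         dt = 0.02))
  expect_lt(abs(m1$average - m2$average) / m1$average, 0.01)
  expect_lt(abs(m1$period - m2$period) / m1$period, 0.01)
})

test_that("the default resting response is steady near 100 nM total p53", {
  cl <- classify_response(p53_parameters())
  expect_equal(cl$regime, "steady")
  expect_equal(total_p53(resting_state(p53_parameters())), 100,
               tolerance = 0.15)
})

test_that("peak p53 responds less to weakened binding than to slowed degradation", {
  p <- p53_parameters()
  base_peak <- classify_response(p)$peak_p53
  kd_peak <- cached_stress_classification("nutlin")$peak_p53      # k_D x5
  delta_peak <- cached_stress_classification("oncogene")$peak_p53 # delta /5
  expect_lt(kd_peak / base_peak, delta_peak / base_peak)
})

test_that("snp309 genotypes scale mdm2 transcription geometrically", {
  p <- p53_parameters()
  expect_equal(snp309_variant(p, "TT", 4)$k_t, p$k_t)
  expect_equal(snp309_variant(p, "TG", 4)$k_t, 2 * p$k_t)
  expect_equal(snp309_variant(p, "GG", 4)$k_t, 4 * p$k_t)
  expect_error(snp309_variant(p, "GG", g_fold = 0.5), "> 1")
})
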