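test_that("the reference cell volume maps 100 nM to about 50,000 molecules", {
  vol <- volume_context()
  expect_equal(vol$omega, 544.87, tolerance = 1e-4)
  expect_equal(nM_to_molecules(100, vol), 5.45e4, tolerance = 0.01)
  expect_equal(molecules_to_nM(nM_to_molecules(7, vol), vol), 7)
  v500 <- volume_context(500)
  expect_equal(v500$omega, vol$omega / 500)
})

test_that("reaction propensities vanish whenever a consumed species is absent", {
  ch <- build_reactions(p53_parameters(), volume_context(500))
  expect_length(ch, 10L)
  # empty cell: only the production channel can fire
  n0 <- c(0, 0, 0, 0)
  a0 <- vapply(ch, function(r) r$propensity(n0), numeric(1))
  expect_equal(sum(a0 > 0), 1L)
  expect_equal(a0[[1]], 1000 * volume_context(500)$omega)
  # a single p53 molecule cannot occupy the double promoter site
  a1 <- vapply(ch, function(r) r$propensity(c(1, 0, 0, 0)), numeric(1))
  expect_equal(a1[[7]], 0)
  # no channel can push a zero species negative
  set.seed(3)
  for (i in 1:25) {
    n <- rpois(4, 20) * rbinom(4, 1, 0.6)
    for (r in ch) {
      consumed <- which(r$stoich < 0)
      if (length(consumed) && any(n[consumed] == 0))
        expect_equal(r$propensity(n), 0)
    }
  }
})

test_that("summed channel rates reproduce the deterministic rhs in the mean field", {
  p <- p53_parameters()
  vol <- volume_context()    # large omega: O(1/omega) discrepancy only
  ch <- build_reactions(p, vol)
  set.seed(5)
  for (i in 1:10) {
    conc <- stats::runif(4, 0.5, 150)
    n <- conc * vol$omega
    drift <- rowSums(vapply(ch, function(r) r$stoich * r$propensity(n),
                            numeric(4))) / vol$omega
    ref <- unname(p53_rhs(p53_state(conc[1], conc[2], conc[3], conc[4]), p))
    expect_equal(drift, ref, tolerance = 1e-3)
  }
})

test_that("a system with all rates zero stays frozen until the horizon", {
  rates <- stats::setNames(rep(0, 9), p53loop:::.rate_names)
  res <- p53loop:::.ssa_core(rates, 1, c(5, 4, 3, 2), t_max = 10,
                             record_dt = 0.5, seed = 1)
  expect_true(res$exhausted)
  expect_true(all(res$samples[, 2] == 5 & res$samples[, 5] == 2))
  expect_equal(res$n_events, 0)
})

test_that("a production-dominated system matches the Poisson growth law", {
  # sigma = 10/h at omega = 1, every other rate negligibly small: counts at
  # t = 5 h are Poisson(50)
  p <- p53_parameters(sigma = 10, alpha = 1e-12, delta = 1e-12, k_t = 1e-12,
                      k_tl = 1e-12, beta = 1e-12, gamma = 1e-12, k_b = 1e-12,
                      k_f = 1e-12)
  rates <- unlist(p[p53loop:::.rate_names])
  counts <- vapply(1:200, function(s) {
    res <- p53loop:::.ssa_core(rates, 1, c(0, 0, 0, 0), t_max = 5,
                               record_dt = 5, seed = s)
    res$final[1]
  }, numeric(1))
  se <- sqrt(50 / 200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
  expect_equal(stats::var(counts), 50, tolerance = 0.35)
})

test_that("stochastic runs are reproducible per seed and integral throughout", {
  p <- p53_parameters()
  vol <- volume_context(500)
  ch <- build_reactions(p, vol)
  t1 <- ssa_run(ch, t_max = 4, seed = 9)
  t2 <- ssa_run(ch, t_max = 4, seed = 9)
  t3 <- ssa_run(ch, t_max = 4, seed = 10)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
  counts <- as.matrix(t1[, c("n_p", "n_mm", "n_m", "n_c")])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
})

test_that("an unstressed stochastic cell fluctuates around the deterministic rest", {
  p <- p53_parameters()
  vol <- volume_context(100)
  ch <- build_reactions(p, vol)
  tr <- ssa_run(ch, t_max = 20, seed = 4, record_dt = 0.02)
  ode_rest <- total_p53(resting_state(p))
  expect_equal(mean(tr$total_p53_nM), ode_rest, tolerance = 0.05)
})

test_that("peak-time statistics are deterministic given the seed", {
  p <- p53_parameters()
  scen <- builtin_scenarios()$dna_damage
  vol <- volume_context(2000)
  pv1 <- peak_time_variability(p, scen, n_runs = 30, vol = vol, seed = 7,
                               t_max = 12)
  pv2 <- peak_time_variability(p, scen, n_runs = 30, vol = vol, seed = 7,
                               t_max = 12)
  expect_identical(pv1$stats, pv2$stats)
  expect_error(peak_time_variability(p, scen, n_runs = 10, vol = vol,
                                     seed = 1), "at least 30")
})

test_that("demographic noise in the second peak grows as the volume shrinks", {
  p <- p53_parameters()
  scen <- builtin_scenarios()$dna_damage
  sds <- vapply(c(200, 500, 2000), function(sf) {
    pv <- peak_time_variability(p, scen, n_runs = 30,
                                vol = volume_context(sf), seed = 21,
                                t_max = 9)
    pv$stats$sd_time_h[2]
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})
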