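test_that("default parameters carry the published rates with consistent k_D", {
  p <- p53_parameters()
  expect_equal(p$sigma, 1000)
  expect_equal(p$alpha, 0.1)
  expect_equal(p$delta, 11)
  expect_equal(p$k_t, 0.03)
  expect_equal(p$k_tl, 1.4)
  expect_equal(p$beta, 0.6)
  expect_equal(p$gamma, 0.2)
  expect_equal(p$k_b, 7200)
  expect_equal(p$k_f, 5000)      # k_b / k_D = 7200 / 1.44
  expect_equal(k_D(p), 1.44)
  expect_equal(p$hill, 2)
})

test_that("k_D stays consistent under any parameter-update path", {
  p <- set_parameters(p53_parameters(), k_D = 7.2)
  expect_equal(p$k_f, 1000)
  expect_equal(k_D(p), 7.2)
  # updating k_b together with k_D applies k_b first
  p2 <- set_parameters(p53_parameters(), k_b = 3600, k_D = 1.44)
  expect_equal(p2$k_f, 2500)
  expect_equal(k_D(p2), 1.44)
  expect_error(set_parameters(p53_parameters(), delta = -1), "delta")
  expect_error(set_parameters(p53_parameters(), bogus = 2), "unknown")
})

test_that("rhs reproduces single-term cases and rejects invalid states", {
  p <- p53_parameters()
  expect_equal(unname(p53_rhs(p53_state(), p)), c(1000, 0, 0, 0))
  r <- p53_rhs(p53_state(p = 10), p)
  expect_equal(r[["mm"]], 0.03 * 10^2)
  expect_error(p53_rhs(c(p = -1, mm = 0, m = 0, c = 0), p), "non-negative")
  expect_error(p53_rhs(c(p = Inf, mm = 0, m = 0, c = 0), p), "finite")
})

test_that("rhs never points out of the positive orthant on its boundary", {
  p <- p53_parameters()
  set.seed(11)
  for (i in 1:40) {
    s <- stats::runif(4, 0, 150)
    zero <- sample(4, sample(1:3, 1))
    s[zero] <- 0
    st <- p53_state(s[1], s[2], s[3], s[4])
    r <- p53_rhs(st, p)
    expect_true(all(r[zero] >= 0),
                info = paste("state", paste(signif(s, 3), collapse = ",")))
  }
})

test_that("analytic Jacobian matches central finite differences", {
  p <- p53_parameters()
  fd_jacobian <- function(st, h = 1e-4) {
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      up <- dn <- unclass(st)
      up[j] <- up[j] + h; dn[j] <- max(dn[j] - h, 0)
      J[, j] <- (.rhs_unsafe(up, p) - .rhs_unsafe(dn, p)) / (up[j] - dn[j])
    }
    J
  }
  .rhs_unsafe <- function(y, p) unname(p53loop:::.rhs(y, p))
  rest <- resting_state(p)
  expect_lt(max(abs(p53_jacobian(rest, p) - fd_jacobian(rest))), 1e-4)
  set.seed(7)
  for (i in 1:10) {
    st <- p53_state(stats::runif(1, 1, 100), stats::runif(1, 0, 40),
                    stats::runif(1, 0, 40), stats::runif(1, 0, 100))
    expect_lt(max(abs(p53_jacobian(st, p) - fd_jacobian(st))), 1e-4)
  }
  # structural entries
  J0 <- p53_jacobian(p53_state(), p)
  expect_equal(J0["mm", "p"], 0)                      # 2 k_t p at p = 0
  expect_equal(J0["c", "c"], -(7200 + 11 + 0.2))      # -(k_b + delta + gamma)
})

test_that("resting equilibrium satisfies the reduced-balance identities", {
  p <- p53_parameters()
  eq <- p53_steady_states(p)[[1]]
  st <- eq$state
  expect_lt(max(abs(p53_rhs(st, p))), 1e-6)
  # total Mdm2 balance and p53 balance, exact algebra of the model
  tot_m <- st[["m"]] + st[["c"]]
  expect_equal(tot_m, p$k_tl * p$k_t / (p$gamma * p$beta) * st[["p"]]^2,
               tolerance = 1e-8)
  expect_equal(p$sigma, p$alpha * st[["p"]] + p$delta * st[["c"]],
               tolerance = 1e-8)
  expect_true(eq$stable)
})

test_that("equilibrium agrees with an independent cubic-root oracle", {
  # eliminating mm, m, c from the steady-state equations leaves
  # delta*k_f*a*p^3 + alpha*k_f*p^2 + (alpha*K - sigma*k_f)*p - sigma*K = 0
  # with a = k_tl*k_t/(gamma*beta), K = k_b + delta + gamma
  p <- p53_parameters()
  K <- p$k_b + p$delta + p$gamma
  a <- p$k_tl * p$k_t / (p$gamma * p$beta)
  roots <- polyroot(c(-p$sigma * K, p$alpha * K - p$sigma * p$k_f,
                      p$alpha * p$k_f, p$delta * p$k_f * a))
  real_pos <- Re(roots[abs(Im(roots)) < 1e-6 & Re(roots) > 0])
  expect_length(real_pos, 1L)
  eq <- p53_steady_states(p)[[1]]
  expect_equal(eq$state[["p"]], real_pos, tolerance = 1e-9)
})

test_that("switching off production leaves only the stable origin", {
  eq <- p53_steady_states(set_parameters(p53_parameters(), sigma = 0))
  expect_length(eq, 1L)
  expect_equal(unname(unclass(eq[[1]]$state)), c(0, 0, 0, 0))
  expect_true(eq[[1]]$stable)
})

test_that("doubling Mdm2 removal destabilises the equilibrium via a complex pair", {
  eq <- p53_steady_states(set_parameters(p53_parameters(), gamma = 0.4))[[1]]
  expect_false(eq$stable)
  lead <- eq$eigenvalues[1]
  expect_gt(Re(lead), 0)
  expect_gt(abs(Im(lead)), 0)   # oscillatory instability (Hopf onset)
})

test_that("equilibrium total p53 is monotone in sigma, delta and k_t", {
  tot <- function(...) {
    total_p53(p53_steady_states(set_parameters(p53_parameters(), ...))[[1]]$state)
  }
  folds <- exp(seq(log(1 / sqrt(5)), log(sqrt(5)), length.out = 5))
  t_sigma <- vapply(folds, function(f) tot(sigma = 1000 * f), numeric(1))
  t_delta <- vapply(folds, function(f) tot(delta = 11 * f), numeric(1))
  t_kt <- vapply(folds, function(f) tot(k_t = 0.03 * f), numeric(1))
  expect_true(all(diff(t_sigma) > 0))
  expect_true(all(diff(t_delta) < 0))
  expect_true(all(diff(t_kt) < 0))
})

test_that("the co-degradation variant shifts the resting state by < 5%", {
  ref <- total_p53(p53_steady_states(p53_parameters())[[1]]$state)
  alt <- total_p53(p53_steady_states(
    p53_parameters(variant = "codegrade"))[[1]]$state)
  expect_lt(abs(alt - ref) / ref, 0.05)
})
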