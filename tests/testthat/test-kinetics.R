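test_that("mass-action propensities count source-complex assemblies", {
  p <- mass_action_propensity(2, c(2L, 0L))     # source 2A
  expect_equal(crntrans:::prop_eval(p, matrix(c(5, 0), 1)), 2 * 20)
  expect_equal(crntrans:::prop_eval(p, matrix(c(1, 7), 1)), 0)
  p0 <- mass_action_propensity(3.5, c(0L, 0L))  # source 0
  expect_equal(crntrans:::prop_eval(p0, matrix(c(9, 2), 1)), 3.5)
  pab <- mass_action_propensity(1, c(1L, 1L))   # source A+B
  expect_equal(crntrans:::prop_eval(pab, matrix(c(2, 3), 1)), 6)
})

test_that("generalized mass action reduces to mass action for identity f", {
  src <- c(2L, 1L)
  pma <- mass_action_propensity(1.5, src)
  pg <- gma_propensity(1.5, src, list(NULL, NULL))
  pg$f <- list(function(x) x, function(x) x)
  G <- crntrans:::state_grid(c(0L, 0L), c(20L, 20L))
  expect_equal(crntrans:::prop_eval(pg, G), crntrans:::prop_eval(pma, G))
})

test_that("gma supports dimer-counting and Hill-type per-species functions", {
  ## f_A(n) = n(n-1) with source A gives alpha * n(n-1)
  p <- gma_propensity(0.5, c(1L), list(function(x) x * (x - 1)))
  n <- matrix(0:6, ncol = 1)
  expect_equal(crntrans:::prop_eval(p, n), 0.5 * (0:6) * (-1:5) * (0:6 >= 1))
  ## Hill: alpha * n^2/(K + n^2)
  K <- 4
  ph <- gma_propensity(2, c(1L), list(function(x) x^2 / (K + x^2)))
  expect_equal(crntrans:::prop_eval(ph, matrix(3)), 2 * 9 / (K + 9))
})

test_that("expression kinetics parse and evaluate with parameters", {
  net <- parse_network("A -> 0 : expr(k * n_A^2 / (K + n_A^2))",
                       params = c(k = 2, K = 4))
  expect_equal(crntrans:::prop_eval(net$reactions[[1]]$propensity, matrix(3)),
               2 * 9 / 13)
  expect_error(parse_network("A -> 0 : expr(system(n_A))"), "disallowed")
})

test_that("positivity thresholds locate the factorization base point", {
  d2 <- c(0L, 0L)
  ## affine birth: positive everywhere
  p1 <- crntrans:::prop_sum(mass_action_propensity(10, c(0L, 0L)),
                            mass_action_propensity(2, c(1L, 0L)))
  expect_equal(positivity_threshold(p1, d2), c(0L, 0L))
  ## dimer counting from source A: positive iff n_A >= 2, so b_A = 1
  p2 <- mass_action_propensity(1, c(2L, 0L))
  expect_equal(positivity_threshold(p2, c(1L, 0L)), c(1L, 0L))
  ## linear decay: threshold equals the source complex
  p3 <- mass_action_propensity(1, c(1L, 0L))
  expect_equal(positivity_threshold(p3, c(1L, 0L)), c(0L, 0L))
  ## a propensity whose support is not an upper orthant has no base point
  p4 <- crntrans:::prop_expr(function(N) pmax(N[, 1] * (5 - N[, 1]), 0), "bump")
  expect_null(positivity_threshold(p4, c(1L)))
})

test_that("the CME residual vanishes exactly for detailed-balanced pmfs", {
  net <- birth_death(10, 1)
  n <- 0:60
  pmf <- pmf_table(matrix(n, ncol = 1), dpois(n, 10), "A")
  for (s in c(0L, 3L, 17L, 40L))
    expect_lt(abs(cme_residual(net, pmf, s)), 1e-12)
  ## uniform pmf is not stationary: net outflow at the lower boundary
  ## (birth 10/11 out, death 1/11 in)
  expect_equal(cme_residual(net, pmf_table(matrix(0:10, ncol = 1),
                                           rep(1 / 11, 11), "A"), 0L),
               (1 - 10) / 11, tolerance = 1e-12)
})

test_that("out-of-domain lookups are reported by state", {
  net <- birth_death()
  pmf <- pmf_table(matrix(0:5, ncol = 1), rep(1 / 6, 6), "A",
                   zero_outside = FALSE)
  expect_error(cme_residual(net, pmf, 5L), "missing from pmf")
})

test_that("CME residuals sum to zero over a closed state space", {
  net <- net_ab(2, 3)
  states <- rbind(c(3L, 0L), c(2L, 1L), c(1L, 2L), c(0L, 3L))
  set.seed(4)
  w <- runif(4); w <- w / sum(w)
  pmf <- pmf_table(states, w, net$species)
  tot <- sum(vapply(seq_len(4), function(i) cme_residual(net, pmf, states[i, ]), 0))
  expect_lt(abs(tot), 1e-12)
})

test_that("propensities are non-negative on random states", {
  set.seed(9)
  nets <- lapply(1:5, random_mass_action_net)
  N <- matrix(sample(0:30, 60, replace = TRUE), ncol = 2)
  for (net in nets)
    for (rx in net$reactions)
      expect_true(all(crntrans:::prop_eval(rx$propensity, N) >= 0))
})
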