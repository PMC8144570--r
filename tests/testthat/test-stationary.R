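test_that("the birth-death network normalizes to the Poisson distribution", {
  net <- birth_death(10, 0.3)
  d <- derive(net)
  expect_equal(d$status, "ok")
  m <- dist_marginal(d$dist, "A")
  expect_lt(tv_distance(m, data.frame(count = m$count,
                                      prob = dpois(m$count, 10 / 0.3))), 1e-12)
  ## normalizing constant: M = exp(-c) for the Poisson profile
  expect_equal(d$dist$log_M, -10 / 0.3, tolerance = 1e-10)
})

test_that("two-state conversion gives the Bernoulli distribution", {
  net <- net_ab(2, 3)
  d <- derive(net, totals = 1)
  expect_equal(d$status, "ok")
  expect_equal(nrow(d$dist$states), 2L)
  ## pi(B)/pi(A) = k1/k2
  pA <- d$dist$pmf[d$dist$states[, 1] == 1]
  pB <- d$dist$pmf[d$dist$states[, 2] == 1]
  expect_equal(pB / pA, 2 / 3, tolerance = 1e-10)
})

test_that("irreducible classes honour conservation and base-point constraints", {
  net <- builtin_network("pak1")
  tn <- apply_scheme(net, attr(net, "scheme"))
  b <- crntrans:::factor_base_point(tn)
  expect_equal(b, c(1L, 0L, 0L))
  sp <- irreducible_class(tn, b, totals = 80)
  expect_equal(sp$kind, "finite")
  expect_true(all(rowSums(sp$states) == 80))
  expect_true(all(sp$states[, 1] >= 1))
  expect_true(sp$irreducible)
  ## the merged-production network lives on the full lattice
  net1 <- fig1_net()
  tn1 <- apply_scheme(net1, attr(builtin_network("fig1"), "scheme"))
  sp1 <- irreducible_class(tn1, c(0L, 0L))
  expect_equal(sp1$kind, "lattice")
})

test_that("a state space that a reaction exits is rejected", {
  ## an inflated base point excludes states the dynamics still reach:
  ## from (1, T-1) the trans-autophosphorylation step exits {n_A >= 1}
  net <- builtin_network("aurorab")
  tn <- apply_scheme(net, attr(net, "scheme"))
  expect_error(irreducible_class(tn, c(1L, 0L), totals = 10), "not closed")
})

test_that("autophosphorylation marginals match their closed forms", {
  d <- derive(egfr_net())
  expect_equal(d$status, "ok")
  ## phosphorylated marginal: Poisson(a1/a3)
  m <- dist_marginal(d$dist, "A_P")
  expect_lt(tv_distance(m, data.frame(count = m$count,
                                      prob = dpois(m$count, 10 / 0.3))), 1e-10)
  ## unphosphorylated marginal: r^n/(n!(n-1)!), r = (a1/a2)(1+a4/a3), n >= 1
  r <- (10 / 0.03) * (1 + 2 / 0.3)
  ma <- dist_marginal(d$dist, "A")
  expect_true(all(ma$count >= 1))
  lw <- ma$count * log(r) - lfactorial(ma$count) - lfactorial(ma$count - 1)
  ref <- exp(lw - max(lw)); ref <- ref / sum(ref)
  expect_lt(tv_distance(ma, data.frame(count = ma$count, prob = ref)), 1e-10)
  ## sub-Poissonian
  mo <- dist_moments(d$dist, "A")
  expect_lt(mo$var, mo$mean)
})

test_that("the Bessel-type normalization matches the modified Bessel function", {
  ## sum_{n>=1} r^n/(n!(n-1)!) = sqrt(r) I_1(2 sqrt(r))
  for (r in c(0.5, 1.8, 5)) {
    n <- 1:150
    s <- sum(exp(n * log(r) - lfactorial(n) - lfactorial(n - 1)))
    expect_equal(s, sqrt(r) * besselI(2 * sqrt(r), 1), tolerance = 1e-12)
  }
})

test_that("the coefficient of variation peaks near r = 1.8", {
  res <- bessel_marginal_cv()
  expect_equal(res$r_max, 1.8, tolerance = 0.1)
  expect_true(all(res$cv < 1))  # sub-Poissonian throughout
})

test_that("stationary distributions are invariant to the chosen translation", {
  net <- builtin_network("aurorab")
  schemes <- search_translations(net, max_schemes = 4L)
  dists <- list()
  for (sc in schemes) {
    d <- derive(net, totals = 20, scheme = sc)
    if (d$status == "ok") dists[[length(dists) + 1L]] <- d$dist
  }
  expect_gte(length(dists), 1L)
  if (length(dists) >= 2) {
    expect_lt(tv_distance(crntrans:::as_pmf_table(dists[[1]]),
                          crntrans:::as_pmf_table(dists[[2]])), 1e-10)
  }
})

test_that("the assembled distribution solves the chemical master equation", {
  ## full-pipeline oracle on a small conserved class, against the direct
  ## null-space solution of the CME generator
  net <- builtin_network("pak1")
  d <- derive(net, totals = 12)
  expect_equal(d$status, "ok")
  oracle <- cme_direct_stationary(net, d$dist$states)
  expect_lt(max(abs(d$dist$pmf - oracle)), 1e-12)
})

test_that("divergent measures are reported, not silently truncated", {
  ## autocatalysis faster than removal: the stationary measure is not
  ## summable on the lattice
  net <- fig1_net(10, 3, 1, 1)
  tn <- apply_scheme(net, attr(builtin_network("fig1"), "scheme"))
  fac <- factorize_general(tn, window = 40L)
  eq <- solve_cbe(tn, fac$kappa)
  sp <- irreducible_class(tn, fac)
  expect_error(normalize_measure(stationary_measure(fac, eq), sp,
                                 max_side = 96L),
               "truncation cap|not be summable")
})
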