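test_that("mass-action networks factorize with theta = prod n_i!", {
  net <- net_ab(2, 3)
  fac <- factorize_gma(net)
  expect_equal(fac$kappa, c(2, 3))
  G <- crntrans:::state_grid(c(0L, 0L), c(8L, 8L))
  expect_equal(crntrans:::fac_log_theta(fac, G),
               lfactorial(G[, 1]) + lfactorial(G[, 2]))
  expect_true(verify_factorization(fac, window = 12L))
})

test_that("translated dimer kinetics give theta = n_A!(n_A-1)! n_AP!", {
  net <- egfr_net()
  tn <- apply_scheme(net, translation_scheme(
    rbind(c(0, 0), c(-1, 0), c(0, 0), c(0, 0))))
  f <- list(function(x) x * (x - 1), function(x) x)
  fac <- factorize_gma(tn, f, base = c(1L, 0L))
  expect_equal(fac$kappa, c(10, 0.03, 0.3, 2))
  for (n in list(c(1L, 0L), c(4L, 2L), c(7L, 5L))) {
    expect_equal(crntrans:::fac_log_theta(fac, matrix(n, 1)),
                 lfactorial(n[1]) + lfactorial(n[1] - 1) + lfactorial(n[2]),
                 tolerance = 1e-12)
  }
  expect_true(verify_factorization(fac, window = 15L))
})

test_that("Hill-type f yields the telescoping product theta", {
  net <- parse_network("0 -> A : mass_action(4)\nA -> 0 : gma(1; fA=n/(2+n))")
  f <- list(function(x) x / (2 + x))
  fac <- factorize_gma(net, f)
  n <- 6L
  expect_equal(crntrans:::fac_log_theta(fac, matrix(n, 1)),
               sum(log(seq_len(n) / (2 + seq_len(n)))))
})

test_that("the recurrence solver reproduces the known closed-form factorization", {
  set.seed(31)
  for (rep in 1:3) {
    a1 <- runif(1, 2, 12); a4 <- runif(1, 0.2, 1.5)
    a2 <- a4 + runif(1, 0.5, 2); a3 <- runif(1, 0.5, 2)
    net <- fig1_net(a1, a4, a2, a3)
    tn <- apply_scheme(net, translation_scheme(
      rbind(c(0, 0), c(-1, 0), c(0, 0), c(0, 0))))
    fac <- factorize_general(tn, window = 20L)
    expect_equal(fac$status, "ok")
    expect_true(verify_factorization(fac))
    ## closed form: theta(n) = ((a1+a4 nA)/a1) prod a1 j/(a1+a4 j) * nB!
    th_ref <- function(nA, nB) log((a1 + a4 * nA) / a1) +
      sum(log(a1 * seq_len(nA) / (a1 + a4 * seq_len(nA)))) + lfactorial(nB)
    for (n in list(c(0L, 0L), c(3L, 2L), c(9L, 7L), c(15L, 1L)))
      expect_equal(crntrans:::fac_log_theta(fac, matrix(n, 1)),
                   th_ref(n[1], n[2]), tolerance = 1e-9)
    expect_equal(fac$kappa, c(a1, a2, a3), tolerance = 1e-9)
  }
})

test_that("factorization on a conserved class reproduces all propensities", {
  net <- builtin_network("aurorab")
  tn <- apply_scheme(net, attr(net, "scheme"))
  b <- crntrans:::factor_base_point(tn)
  space <- irreducible_class(tn, b, totals = 60)
  fac <- factorize_general(tn, states = space$states)
  expect_equal(fac$status, "ok")
  ## direct identity check at every class state
  lth <- crntrans:::fac_log_theta(fac, space$states)
  for (k in seq_along(tn$reactions)) {
    rx <- tn$reactions[[k]]
    lam <- crntrans:::prop_eval(rx$propensity, space$states)
    ok <- which(lam > 0)
    M <- sweep(space$states[ok, , drop = FALSE], 2, rx$source)
    lom <- crntrans:::fac_log_omega(fac, M)
    expect_equal(log(fac$kappa[k]) + lth[ok] + lom, log(lam[ok]),
                 tolerance = 1e-9)
  }
})

test_that("non-factorizable extensions fail with a certificate", {
  ## the extended autophosphorylation network translates to a weakly
  ## reversible deficiency-zero network whose propensities cannot be
  ## factorized: two reactions share a translated source with a
  ## non-constant propensity ratio
  ext <- parse_network("
    0 -> A : mass_action(10)
    2A -> A + A_P : mass_action(0.03)
    A + A_P -> 2A_P : mass_action(0.01)
    A_P -> 0 : mass_action(0.3)
    A_P -> A : mass_action(2)")
  sc <- search_translations(ext, max_schemes = 5L)
  found_inconsistent <- FALSE
  for (s in sc) {
    tn <- apply_scheme(ext, s)
    fac <- factorize_general(tn, window = 12L)
    if (fac$status != "ok") {
      found_inconsistent <- TRUE
      if (fac$status == "inconsistent") {
        expect_true(fac$certificate$reaction %in% seq_along(tn$reactions))
        expect_true(all(fac$certificate$state >= 0))
      }
    }
  }
  expect_true(found_inconsistent)
  d <- derive(ext)
  expect_true(d$status %in% c("not_factorizable", "not_translatable"))
})

test_that("verification rejects a perturbed factorization", {
  net <- net_ab()
  fac <- factorize_gma(net)
  expect_true(verify_factorization(fac))
  fac$kappa[1] <- fac$kappa[1] * 2
  expect_false(verify_factorization(fac))
})

test_that("gma and recurrence factorizations agree up to gauge", {
  ## gauge-invariant comparison: both must reproduce every propensity, and
  ## the assembled stationary distributions must coincide
  net <- net_ab(2, 3)
  fg <- factorize_gma(net)
  fr <- factorize_general(net, window = 25L)
  expect_equal(fr$status, "ok")
  eqg <- solve_cbe(net, fg$kappa)
  eqr <- solve_cbe(net, fr$kappa)
  sp <- irreducible_class(net, c(0L, 0L), totals = 6)
  dg <- normalize_measure(stationary_measure(fg, eqg), sp)
  dr <- normalize_measure(stationary_measure(fr, eqr), sp)
  expect_equal(dg$pmf, dr$pmf, tolerance = 1e-10)
})
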