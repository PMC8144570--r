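test_that("merging reactions with a shared stoichiometric vector sums propensities", {
  net <- fig1_net(10, 1, 3, 1)
  sc <- translation_scheme(rbind(c(0, 0), c(-1, 0), c(0, 0), c(0, 0)))
  tn <- apply_scheme(net, sc)
  expect_equal(length(tn$reactions), 3L)
  prod_rx <- tn$reactions[[1]]
  expect_equal(prod_rx$source, c(0L, 0L))
  ## merged production propensity is a1 + a4 * n_A
  N <- matrix(c(0, 0, 5, 2, 12, 7), ncol = 2, byrow = TRUE)
  expect_equal(crntrans:::prop_eval(prod_rx$propensity, N), 10 + 1 * N[, 1])
})

test_that("shifting preserves the propensity function", {
  ## A + B -> 2B shifted by (0, -1) becomes A -> B, propensity untouched
  net <- parse_network("A + B -> 2B : mass_action(2)")
  tn <- apply_scheme(net, translation_scheme(matrix(c(0, -1), 1)))
  expect_equal(tn$reactions[[1]]$source, c(1L, 0L))
  expect_equal(tn$reactions[[1]]$product, c(0L, 1L))
  N <- matrix(c(3, 4), 1)
  expect_equal(crntrans:::prop_eval(tn$reactions[[1]]$propensity, N), 2 * 3 * 4)
})

test_that("identity scheme returns the network unchanged", {
  net <- egfr_net()
  tn <- apply_scheme(net, crntrans:::identity_scheme(net))
  expect_equal(length(tn$reactions), length(net$reactions))
  expect_true(verify_scheme(net, tn))
})

test_that("invalid schemes are rejected", {
  net <- parse_network("0 -> A : mass_action(1)")
  expect_error(apply_scheme(net, translation_scheme(matrix(-1, 1))),
               "negative complex entry")
})

test_that("scheme verification accepts CME-preserving translations only", {
  net <- egfr_net()
  good <- apply_scheme(net, translation_scheme(
    rbind(c(0, 0), c(-1, 0), c(0, 0), c(0, 0))))
  expect_true(verify_scheme(net, good))
  ## wrong: attach the dimer propensity to the opposite stoichiometry
  bad <- crntrans:::new_crn(net$species, list(
    net$reactions[[1]],
    list(source = c(0L, 1L), product = c(1L, 0L),
         propensity = net$reactions[[2]]$propensity, label = "A_P -> A (wrong)"),
    net$reactions[[3]], net$reactions[[4]]))
  expect_false(verify_scheme(net, bad))
})

test_that("search finds the published translated networks", {
  ## merged production cycle 0 -> A -> A+B -> 0
  sc <- search_translations(fig1_net())
  expect_gt(length(sc), 0)
  tn <- apply_scheme(fig1_net(), sc[[1]])
  labs <- vapply(tn$reactions, `[[`, "", "label")
  expect_setequal(labs, c("0 -> A", "A -> A + B", "A + B -> 0"))

  sc2 <- search_translations(egfr_net())
  tn2 <- apply_scheme(egfr_net(), sc2[[1]])
  expect_setequal(vapply(tn2$reactions, `[[`, "", "label"),
                  c("0 -> A", "A -> A_P", "A_P -> 0", "A_P -> A"))

  ## an already weakly reversible deficiency-zero network returns the
  ## identity scheme first
  sc3 <- search_translations(net_ab())
  expect_equal(sc3[[1]]$shifts, matrix(0L, 2, 2), ignore_attr = TRUE)
})

test_that("accepted schemes always yield weak reversibility and deficiency zero", {
  for (nm in c("fig1", "egfr", "pak1", "aurorab")) {
    net <- builtin_network(nm)
    for (sc in search_translations(net, max_schemes = 3L)) {
      tn <- apply_scheme(net, sc)
      expect_equal(deficiency(tn), 0L)
      expect_true(is_weakly_reversible(tn))
      expect_true(verify_scheme(net, tn))
      expect_equal(tn$species, net$species)
    }
  }
})

test_that("original and translated networks produce identical gamma-attributed paths", {
  ## with reactions sorted by stoichiometric vector, the per-gamma propensity
  ## sums coincide, so the same random stream yields the same jump times and
  ## the same state path
  sort_by_gamma <- function(net) {
    keys <- vapply(net$reactions, function(rx)
      paste(rx$product - rx$source, collapse = ","), "")
    crntrans:::new_crn(net$species, net$reactions[order(keys)], net$params)
  }
  net <- egfr_net()
  tn <- apply_scheme(net, translation_scheme(
    rbind(c(0, 0), c(-1, 0), c(0, 0), c(0, 0))))
  t1 <- gillespie(sort_by_gamma(net), c(1L, 0L), 3, seed = 42)
  t2 <- gillespie(sort_by_gamma(tn), c(1L, 0L), 3, seed = 42)
  expect_equal(t1$times, t2$times)
  expect_equal(t1$states, t2$states)
})
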