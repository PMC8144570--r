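toggle_setup <- function(epsilon = 1e-2) {
  net <- builtin_network("toggle", epsilon = epsilon)
  list(net = net, split = timescale_split(net, attr(net, "slow_reactions")))
}

test_that("the timescale split classifies reactions and species correctly", {
  ts <- toggle_setup()
  expect_equal(sort(ts$net$species[ts$split$slow_species]),
               sort(c("Ga_act", "Ga_rep", "Gb_act", "Gb_rep")))
  expect_equal(sort(ts$net$species[ts$split$fast_species]),
               sort(c("A", "A_P", "B", "B_P")))
  expect_equal(length(ts$split$fast) + length(ts$split$slow),
               length(ts$net$reactions))
  ## fast reactions never change slow species
  gam <- crntrans:::stoich_matrix(ts$net)
  expect_true(all(gam[ts$split$fast, ts$split$slow_species] == 0))
})

test_that("gene copies are untouched by the fast reactions", {
  net <- builtin_network("toggle_fast_A")
  W <- conservation_laws(net)
  ## each gene species is individually conserved (two-dimensional basis
  ## supported on the gene coordinates only), so G_act + G_rep is too
  expect_equal(nrow(W), 2L)
  ip <- match(c("A", "A_P"), net$species)
  expect_true(all(W[, ip] == 0))
  ig <- match(c("G_act", "G_rep"), net$species)
  expect_equal(qr(W[, ig])$rank, 2L)
})

test_that("the untranslated fast subnetwork has deficiency three, the translated zero", {
  net <- builtin_network("toggle_fast_A")
  expect_equal(deficiency(net), 3L)
  expect_false(is_weakly_reversible(net))
  tn <- apply_scheme(net, attr(net, "scheme"))
  expect_equal(deficiency(tn), 0L)
  expect_true(is_weakly_reversible(tn))
  ## merged production propensity: a_act n_Gact + a_rep n_Grep
  prod_rx <- tn$reactions[[1]]
  N <- matrix(c(1, 0, 0, 0,  0, 3, 1, 2), ncol = 4, byrow = TRUE)
  expect_equal(crntrans:::prop_eval(prod_rx$propensity, N),
               10 * N[, 1] + 1.5 * N[, 3])
})

test_that("conditional distributions are the expected Poisson laws", {
  ts <- toggle_setup()
  d <- conditional_stationary(ts$net, ts$split,
                              c(Ga_act = 1, Ga_rep = 0, Gb_act = 0, Gb_rep = 1))
  expect_equal(d$status, "ok")
  ## phosphorylated protein given its gene state: Poisson(expr/deg)
  m <- dist_marginal(d, "A_P")
  expect_lt(tv_distance(m, data.frame(count = m$count,
                                      prob = dpois(m$count, 10 / 0.2))), 1e-9)
  mb <- dist_marginal(d, "B_P")
  expect_lt(tv_distance(mb, data.frame(count = mb$count,
                                       prob = dpois(mb$count, 1 / 0.1))), 1e-9)
  ## conditional pi solves the frozen fast subnetwork's CME
  expect_equal(dist_moments(d, "A_P")$mean, 50, tolerance = 1e-8)
})

test_that("mixture approximation behaves like a convex combination", {
  m1 <- data.frame(count = 0:3, prob = c(0.1, 0.2, 0.3, 0.4))
  m2 <- data.frame(count = 2:5, prob = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(mixture_approximation(list(m1, m2), c(1, 0)), m1)
  mix <- mixture_approximation(list(m1, m1), c(0.3, 0.7))
  expect_equal(mix$prob, m1$prob)
  mix2 <- mixture_approximation(list(m1, m2), c(0.5, 0.5))
  expect_equal(sum(mix2$prob), 1)
})

test_that("the slow chain is a proper distribution over joint gene states", {
  ts <- toggle_setup()
  cm <- function(slow) {
    ## closed-form conditional means (Poisson rates), avoiding re-derivation
    names(slow) <- ts$net$species[ts$split$slow_species]
    c(A = 0, A_P = if (slow[["Ga_act"]] == 1) 50 else 7.5,
      B = 0, B_P = if (slow[["Gb_act"]] == 1) 100 else 10)
  }
  ch <- slow_chain(ts$net, ts$split, attr(ts$net, "initial"), cond_means = cm)
  expect_equal(nrow(ch$states), 4L)
  expect_equal(sum(ch$rho), 1, tolerance = 1e-12)
  expect_true(all(ch$rho >= 0))
  ## dominant unbinding drives the gene to the active state
  net_fast_unbind <- builtin_network("toggle", epsilon = 1e-2)
  idx <- attr(net_fast_unbind, "slow_reactions")
  net_fast_unbind$reactions[[idx[2]]]$propensity$rate <- 1e6  # Ga unbinding
  ch2 <- slow_chain(net_fast_unbind,
                    timescale_split(net_fast_unbind, idx),
                    attr(net_fast_unbind, "initial"), cond_means = cm)
  ia <- match("Ga_act", ch2$slow_species)
  expect_gt(sum(ch2$rho[ch2$states[, ia] == 1]), 0.99)
})

test_that("the reduced model contains only slow reactions over slow species", {
  ts <- toggle_setup()
  cm <- function(slow) {
    names(slow) <- ts$net$species[ts$split$slow_species]
    c(A = 0, A_P = if (slow[["Ga_act"]] == 1) 50 else 7.5,
      B = 0, B_P = if (slow[["Gb_act"]] == 1) 100 else 10)
  }
  red <- reduce_model(ts$net, ts$split, cond_means = cm)
  expect_equal(length(red$reactions), 4L)
  expect_equal(sort(red$species), sort(c("Ga_act", "Ga_rep", "Gb_act", "Gb_rep")))
  ## binding propensity uses the conditional repressor mean
  n0 <- c(1L, 0L, 1L, 0L)[match(red$species, c("Ga_act", "Ga_rep", "Gb_act", "Gb_rep"))]
  lam <- crntrans:::prop_eval(red$reactions[[1]]$propensity, matrix(n0, 1))
  expect_equal(lam, 1e-2 * 1 * 100, tolerance = 1e-9)
})

test_that("single-exit residence times are exponential with mean 1/rate", {
  net <- parse_network("A -> B : mass_action(0.5)\nB -> A : mass_action(2)")
  rt <- residence_times(net, "B", c(1L, 0L), 4000, seed = 6)
  expect_gt(length(rt), 300)
  expect_lt(abs(mean(rt) - 1 / 2), 3 * sd(rt) / sqrt(length(rt)))
  ## exponential shape: CV of an exponential is 1
  expect_lt(abs(sd(rt) / mean(rt) - 1), 0.15)
})
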