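test_that("parsing builds species, complexes and reactions from .crn text", {
  net <- parse_network("0 -> A : mass_action(10)")
  expect_equal(net$species, "A")
  expect_equal(length(net$reactions), 1L)
  expect_equal(nrow(crntrans:::complex_matrix(net)), 2L)

  fig1 <- fig1_net()
  expect_equal(fig1$species, c("A", "B"))
  expect_equal(length(fig1$reactions), 4L)
  cx <- crntrans:::complex_matrix(fig1)
  expect_equal(nrow(cx), 4L)  # 0, A, 2A, A+B
  expect_true(all(apply(cx, 1, paste, collapse = ",") %in%
                    c("0,0", "1,0", "2,0", "1,1")))
})

test_that("malformed input is rejected with the offending line", {
  expect_error(parse_network("A + -> B : mass_action(1)"), "line 1")
  expect_error(parse_network("A -> A : mass_action(1)"), "identical source")
  expect_error(parse_network("A -> B"), "KINETICS")
  expect_error(parse_network("A -> B : mass_action(z)"), "neither numeric")
})

test_that("reversible sugar and parallel-edge merging work", {
  net <- parse_network("A <-> B : mass_action(2), mass_action(3)")
  expect_equal(length(net$reactions), 2L)
  dup <- parse_network("A -> B : mass_action(2)\nA -> B : mass_action(3)")
  expect_equal(length(dup$reactions), 1L)
  expect_equal(crntrans:::prop_eval(dup$reactions[[1]]$propensity,
                                    matrix(c(4, 0), 1)), 20)
})

test_that("linkage classes partition the complex graph", {
  egfr <- egfr_net()
  lc <- linkage_classes(egfr)
  expect_equal(length(lc), 2L)
  expect_setequal(lengths(lc), c(3L, 2L))  # {0, A, A_P} and {2A, A+A_P}
  expect_equal(length(linkage_classes(fig1_net())), 1L)
  empty <- crntrans:::new_crn("A", list())
  expect_equal(linkage_classes(empty), list())
})

test_that("deficiency matches hand computations and published indices", {
  expect_equal(deficiency(fig1_net()), 1L)
  expect_equal(deficiency(egfr_net()), 1L)
  expect_equal(deficiency(builtin_network("pak1")), 1L)
  expect_equal(deficiency(builtin_network("aurorab")), 1L)
  expect_equal(deficiency(net_ab()), 0L)
  expect_equal(deficiency(builtin_network("toggle_fast_A")), 3L)
})

test_that("weak reversibility detects strongly connected linkage classes", {
  expect_false(is_weakly_reversible(fig1_net()))
  expect_true(is_weakly_reversible(net_cycle3()))
  expect_true(is_weakly_reversible(crntrans:::new_crn("A", list())))
})

test_that("conservation laws span the left null space of the stoichiometry", {
  W <- conservation_laws(builtin_network("pak1"))
  expect_equal(nrow(W), 1L)
  expect_equal(abs(as.numeric(W)), c(1, 1, 1))
  expect_equal(nrow(conservation_laws(fig1_net())), 0L)
  Wab <- conservation_laws(net_ab())
  expect_equal(nrow(Wab), 1L)
  expect_equal(abs(as.numeric(Wab)), c(1, 1))
})

test_that("deficiency is non-negative and invariant to relabeling", {
  for (s in 1:20) {
    net <- random_mass_action_net(s)
    delta <- deficiency(net)
    expect_gte(delta, 0L)
    ## permute reaction order
    net2 <- crntrans:::new_crn(net$species, rev(net$reactions))
    expect_equal(deficiency(net2), delta)
    ## relabel species (swap coordinates)
    net3 <- crntrans:::new_crn(rev(net$species), lapply(net$reactions, function(rx) {
      rx$source <- rev(rx$source); rx$product <- rev(rx$product)
      rx$propensity$source <- rev(rx$propensity$source)
      rx
    }))
    expect_equal(deficiency(net3), delta)
  }
})

test_that("weak reversibility implies every complex has in- and out-edges", {
  for (s in 1:30) {
    net <- random_mass_action_net(s, n_rx = 3)
    if (!is_weakly_reversible(net) || !length(net$reactions)) next
    ed <- crntrans:::reaction_edges(net)
    cxn <- nrow(crntrans:::complex_matrix(net))
    expect_setequal(unique(ed[, "src"]), seq_len(cxn))
    expect_setequal(unique(ed[, "dst"]), seq_len(cxn))
  }
})

test_that("structure report bundles consistent indices", {
  st <- structure_report(egfr_net())
  expect_equal(st$deficiency,
               st$n_complexes - length(st$linkage_classes) - st$stoich_dim)
  expect_false(st$weakly_reversible)
  gam <- crntrans:::stoich_matrix(egfr_net())
  if (nrow(st$conservation_basis))
    expect_true(all(abs(gam %*% t(st$conservation_basis)) < 1e-12))
})
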