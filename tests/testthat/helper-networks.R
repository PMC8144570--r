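# Shared fixtures and independent oracles.

birth_death <- function(birth = 10, death = 1) {
  parse_network(sprintf(
    "0 -> A : mass_action(%g)\nA -> 0 : mass_action(%g)", birth, death))
}

net_ab <- function(k1 = 2, k2 = 3) {
  parse_network(sprintf(
    "A -> B : mass_action(%g)\nB -> A : mass_action(%g)", k1, k2))
}

net_cycle3 <- function(k = c(1, 2, 3)) {
  parse_network(sprintf(
    "A -> B : mass_action(%g)\nB -> C : mass_action(%g)\nC -> A : mass_action(%g)",
    k[1], k[2], k[3]))
}

fig1_net <- function(a1 = 10, a4 = 1, a2 = 3, a3 = 1) {
  parse_network(sprintf("
    0 -> A : mass_action(%.12g)
    A -> 2A : mass_action(%.12g)
    A -> A + B : mass_action(%.12g)
    A + B -> 0 : mass_action(%.12g)", a1, a4, a2, a3))
}

egfr_net <- function(a1 = 10, a2 = 0.03, a3 = 0.3, a4 = 2) {
  parse_network(sprintf("
    0 -> A : mass_action(%.12g)
    2A -> A + A_P : mass_action(%.12g)
    A_P -> 0 : mass_action(%.12g)
    A_P -> A : mass_action(%.12g)", a1, a2, a3, a4))
}

# Independent oracle: stationary distribution as the null vector of the CME
# generator restricted to an explicit finite state set.
cme_direct_stationary <- function(net, states) {
  m <- nrow(states)
  keys <- apply(states, 1, function(n) paste(n, collapse = ":"))
  Q <- matrix(0, m, m)
  for (rx in net$reactions) {
    gam <- rx$product - rx$source
    lam <- crntrans:::prop_eval(rx$propensity, states)
    for (i in which(lam > 0)) {
      j <- match(paste(states[i, ] + gam, collapse = ":"), keys)
      if (!is.na(j)) Q[i, j] <- Q[i, j] + lam[i]
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  v <- svd(t(Q))$v[, m]
  v <- abs(v)
  v / sum(v)
}

# empirical marginal of one species from a pmf_table of joint end states
empirical_marginal <- function(emp, net, sp) {
  i <- match(sp, net$species)
  tab <- tapply(emp$prob, emp$states[, i], sum)
  data.frame(count = as.integer(names(tab)), prob = as.numeric(tab))
}

random_mass_action_net <- function(seed, d = 2, n_rx = 4, max_order = 2) {
  set.seed(seed)
  species <- LETTERS[seq_len(d)]
  cx <- crntrans:::state_grid(rep(0L, d), rep(max_order, d))
  cx <- cx[rowSums(cx) <= max_order, , drop = FALSE]
  lines <- character(0)
  while (length(lines) < n_rx) {
    ij <- sample(nrow(cx), 2)
    src <- cx[ij[1], ]; dst <- cx[ij[2], ]
    lab <- function(v) if (all(v == 0)) "0" else
      paste(sprintf("%d%s", v[v > 0], species[v > 0]), collapse = " + ")
    lines <- c(lines, sprintf("%s -> %s : mass_action(%g)", lab(src), lab(dst),
                              round(runif(1, 0.5, 3), 3)))
  }
  parse_network(paste(unique(lines), collapse = "\n"))
}
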