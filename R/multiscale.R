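## Fast/slow decomposition of multi-timescale networks (slow promoter
## kinetics): conditional stationary distributions of translated fast
## subnetworks given the slow state, mixture approximation of unconditional
## marginals, quasi-steady-state (QSS) reduced slow model and residence-time
## analysis.

#' Fast/slow timescale split
#'
#' @param net a `crn`.
#' @param slow indices of the slow reactions (e.g. repressor binding and
#'   unbinding, whose rates carry the separation factor epsilon).
#' @return a `timescale_split`: fast/slow reaction indices, slow species
#'   (changed only by slow reactions) and fast species.
#' @export
timescale_split <- function(net, slow) {
  r <- length(net$reactions)
  stopifnot(all(slow %in% seq_len(r)))
  fast <- setdiff(seq_len(r), slow)
  gam <- stoich_matrix(net)
  changed_by_fast <- apply(gam[fast, , drop = FALSE] != 0, 2, any)
  slow_species <- which(!changed_by_fast)
  if (any(gam[fast, slow_species, drop = FALSE] != 0))
    stop("fast reactions change slow species")  # unreachable by construction
  structure(list(fast = fast, slow = slow,
                 slow_species = slow_species,
                 fast_species = which(changed_by_fast),
                 species = net$species),
            class = "timescale_split")
}

## substitute fixed counts for a subset of species, producing a network over
## the remaining species; zero-rate reactions (a frozen gene copy absent from
## the current slow state) are dropped and coinciding pairs are merged
freeze_species <- function(net, frozen, counts) {
  keep <- setdiff(seq_along(net$species), frozen)
  species <- net$species[keep]
  reactions <- list()
  seen <- character(0)
  for (rx in net$reactions) {
    p <- freeze_prop(rx$propensity, frozen, counts, length(keep), keep)
    if (is.null(p)) next
    src <- rx$source[keep]; dst <- rx$product[keep]
    if (all(src == dst)) next
    key <- paste(cx_key(src), cx_key(dst), sep = ">")
    j <- match(key, seen)
    if (is.na(j)) {
      seen <- c(seen, key)
      reactions[[length(reactions) + 1L]] <-
        list(source = src, product = dst, propensity = p,
             label = paste(cx_label(src, species), "->", cx_label(dst, species)))
    } else {
      reactions[[j]]$propensity <- prop_sum(reactions[[j]]$propensity, p)
    }
  }
  new_crn(species, reactions, net$params)
}

freeze_prop <- function(p, frozen, counts, d_new, keep) {
  if (p$kind == "mass_action") {
    rate <- p$rate
    for (i in frozen)
      if (p$source[i] > 0) rate <- rate * falling_factorial(counts[i], p$source[i])
    if (rate <= 0) return(NULL)
    return(mass_action_propensity(rate, p$source[keep]))
  }
  if (p$kind == "sum") {
    parts <- Filter(Negate(is.null),
                    lapply(p$parts, freeze_prop, frozen = frozen,
                           counts = counts, d_new = d_new, keep = keep))
    if (!length(parts)) return(NULL)
    return(Reduce(prop_sum, parts))
  }
  if (p$kind == "gma") {
    rate <- p$rate
    for (i in frozen) {
      if (p$source[i] > 0) {
        fi <- if (is.null(p$f[[i]])) function(x) x else p$f[[i]]
        for (j in 0:(p$source[i] - 1L)) rate <- rate * fi(counts[i] - j)
      }
    }
    if (rate <= 0) return(NULL)
    return(gma_propensity(rate, p$source[keep], p$f[keep], p$f_text[keep]))
  }
  ## expr: wrap with fixed coordinates
  d_old <- length(keep) + length(frozen)
  fun_old <- p$fun
  prop_expr(function(N) {
    M <- matrix(0, nrow(N), d_old)
    M[, keep] <- N
    M[, frozen] <- rep(counts[frozen], each = nrow(N))
    fun_old(M)
  }, paste0("frozen(", p$text, ")"))
}

## connected components of the species-interaction graph (species coupled
## when a reaction's complexes involve both; expression propensities
## conservatively couple everything they might read)
species_components <- function(net) {
  d <- length(net$species)
  g <- igraph::make_empty_graph(n = d, directed = FALSE)
  opaque <- FALSE
  supp_of <- function(p) {
    if (p$kind %in% c("mass_action", "gma")) return(which(p$source > 0L))
    if (p$kind == "sum") return(unique(unlist(lapply(p$parts, supp_of))))
    opaque <<- TRUE
    seq_len(d)
  }
  for (rx in net$reactions) {
    sp <- sort(unique(c(which(rx$source + rx$product > 0L),
                        supp_of(rx$propensity))))
    if (length(sp) > 1)
      g <- igraph::add_edges(g, t(utils::combn(sp, 2)))
  }
  memb <- igraph::components(g)$membership
  lapply(unique(memb), function(m) which(memb == m))
}

#' Conditional stationary distribution of the fast subnetwork
#'
#' Freezes the slow species at `slow_state`, keeps the fast reactions, and
#' runs the full derivation pipeline (translation, factorization, complex
#' balance, normalization). When the frozen fast network decomposes into
#' independent species blocks (e.g. the two protein chains of a toggle
#' switch) each block is derived separately and the conditional distribution
#' is their product; [dist_marginal()] and [dist_moments()] work on the
#' combined object.
#'
#' @param net the full `crn`.
#' @param split a [timescale_split()].
#' @param slow_state named (or positional) counts of the slow species.
#' @param ... passed to [derive()].
#' @return a `crn_derivation`, or a `crn_conditional` bundling one
#'   derivation per independent block (field `status` either way).
#' @export
conditional_stationary <- function(net, split, slow_state, ...) {
  counts <- numeric(length(net$species))
  if (!is.null(names(slow_state))) {
    counts[match(names(slow_state), net$species)] <- slow_state
  } else counts[split$slow_species] <- slow_state
  fast_net <- new_crn(net$species, net$reactions[split$fast], net$params)
  frozen_net <- freeze_species(fast_net, split$slow_species, counts)
  comps <- species_components(frozen_net)
  comps <- comps[vapply(comps, function(cp) {
    any(vapply(frozen_net$reactions, function(rx)
      any((rx$source + rx$product)[cp] > 0L), TRUE))
  }, TRUE)]
  if (length(comps) <= 1) return(derive(frozen_net, ...))
  parts <- lapply(comps, function(cp) {
    keep_rx <- vapply(frozen_net$reactions, function(rx)
      all(which(rx$source + rx$product > 0L) %in% cp), TRUE)
    sub <- new_crn(frozen_net$species, frozen_net$reactions[keep_rx],
                   frozen_net$params)
    derive(freeze_species(sub, setdiff(seq_along(sub$species), cp),
                          numeric(length(sub$species))), ...)
  })
  status <- if (all(vapply(parts, `[[`, "", "status") == "ok")) "ok" else
    parts[[which(vapply(parts, `[[`, "", "status") != "ok")[1]]]$status
  structure(list(status = status, parts = parts,
                 species = frozen_net$species,
                 component_species = lapply(comps, function(cp)
                   frozen_net$species[cp])),
            class = "crn_conditional")
}

## locate the component derivation that owns a species
conditional_part <- function(cond, species) {
  j <- which(vapply(cond$component_species, function(s) species %in% s, TRUE))
  if (!length(j)) stop("species ", species, " not in any derived component")
  cond$parts[[j[1]]]
}

#' Mixture approximation of an unconditional marginal
#'
#' `pi(n) ~= sum_s rho_s pi(n | s)`: the stationary marginal of a fast
#' species is approximated by the conditional stationary marginals weighted
#' by the slow-state probabilities.
#'
#' @param conditionals list of marginal data frames (`count`, `prob`).
#' @param rho slow-state probabilities (summing to 1).
#' @return data frame `count`, `prob`.
#' @export
mixture_approximation <- function(conditionals, rho) {
  stopifnot(length(conditionals) == length(rho),
            abs(sum(rho) - 1) < 1e-9)
  counts <- sort(unique(unlist(lapply(conditionals, `[[`, "count"))))
  prob <- numeric(length(counts))
  for (s in seq_along(rho)) {
    m <- conditionals[[s]]
    prob[match(m$count, counts)] <- prob[match(m$count, counts)] + rho[s] * m$prob
  }
  keep <- prob > 0
  data.frame(count = counts[keep], prob = prob[keep])
}

## enumerate slow states reachable from `init` under the slow reactions
enumerate_slow_states <- function(net, split, init, max_states = 1024L) {
  sl <- split$slow_species
  gam <- stoich_matrix(net)[split$slow, sl, drop = FALSE]
  start <- as.integer(init[sl])
  seen <- list(start)
  keys <- cx_key(start)
  queue <- list(start)
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(gam))) {
      s2 <- s + gam[k, ]
      if (any(s2 < 0)) next
      key <- cx_key(s2)
      if (!(key %in% keys)) {
        keys <- c(keys, key)
        seen[[length(seen) + 1L]] <- s2
        queue[[length(queue) + 1L]] <- s2
        if (length(seen) > max_states) stop("slow state space too large")
      }
    }
  }
  do.call(rbind, seen)
}

#' Quasi-steady-state chain over the slow states
#'
#' Builds the finite CTMC over the joint slow states (e.g. gene
#' activation/repression patterns) whose transition rates are the slow-
#' reaction propensities with each fast species replaced by its conditional
#' stationary mean given the current slow state, and returns its stationary
#' probabilities `rho`.
#'
#' @param net the full `crn`.
#' @param split a [timescale_split()].
#' @param initial full initial state (fixes the reachable slow states).
#' @param cond_means function(slow_counts) returning named conditional means
#'   of the fast species; defaults to deriving them with
#'   [conditional_stationary()] (memoised).
#' @return a `slow_chain` with `states` (slow coordinates), `rho`,
#'   `generator` and the conditional means used.
#' @export
slow_chain <- function(net, split, initial, cond_means = NULL) {
  if (is.null(cond_means)) cond_means <- conditional_mean_fun(net, split)
  sl <- split$slow_species
  states <- enumerate_slow_states(net, split, initial)
  m <- nrow(states)
  keys <- apply(states, 1, cx_key)
  gam <- stoich_matrix(net)[split$slow, sl, drop = FALSE]
  Q <- matrix(0, m, m)
  mus <- vector("list", m)
  for (i in seq_len(m)) {
    full <- numeric(length(net$species))
    full[sl] <- states[i, ]
    mu <- cond_means(states[i, ])
    mus[[i]] <- mu
    full[match(names(mu), net$species)] <- mu
    for (jk in seq_along(split$slow)) {
      rx <- net$reactions[[split$slow[jk]]]
      lam <- prop_eval(rx$propensity, matrix(full, 1))
      if (lam <= 0) next
      s2 <- states[i, ] + gam[jk, ]
      j <- match(cx_key(s2), keys)
      if (is.na(j)) next
      Q[i, j] <- Q[i, j] + lam
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  ns <- svd(t(Q))
  rho <- ns$v[, m]
  if (sum(rho) < 0) rho <- -rho
  if (any(rho < -1e-9)) stop("slow-state generator is not irreducible")
  rho <- pmax(rho, 0); rho <- rho / sum(rho)
  structure(list(states = states, rho = rho, generator = Q,
                 slow_species = net$species[sl], cond_means = mus),
            class = "slow_chain")
}

## memoised conditional means via the derivation pipeline
conditional_mean_fun <- function(net, split, ...) {
  cache <- new.env(parent = emptyenv())
  fast_names <- net$species[split$fast_species]
  function(slow_counts) {
    key <- cx_key(slow_counts)
    if (exists(key, envir = cache, inherits = FALSE)) return(cache[[key]])
    der <- conditional_stationary(net, split,
                                  setNames(slow_counts, net$species[split$slow_species]),
                                  ...)
    if (der$status != "ok")
      stop("conditional derivation failed for slow state (", key, "): ", der$status)
    mu <- vapply(fast_names, function(sp) dist_moments(der, sp)$mean, 0)
    cache[[key]] <- mu
    mu
  }
}

#' QSS-reduced model over the slow species
#'
#' Keeps only the slow reactions, projects their complexes onto the slow
#' species, and replaces every fast species in their propensities by its
#' conditional stationary mean given the current slow state.
#'
#' @param net the full `crn`.
#' @param split a [timescale_split()].
#' @param cond_means as in [slow_chain()] (defaults to pipeline-derived).
#' @return a `crn` over the slow species with state-dependent (expression)
#'   propensities.
#' @export
reduce_model <- function(net, split, cond_means = NULL) {
  if (is.null(cond_means)) cond_means <- conditional_mean_fun(net, split)
  sl <- split$slow_species
  species <- net$species[sl]
  d_full <- length(net$species)
  reactions <- lapply(split$slow, function(k) {
    rx <- net$reactions[[k]]
    p_old <- rx$propensity
    fun <- local({
      p0 <- p_old
      function(N) {
        out <- numeric(nrow(N))
        for (q in seq_len(nrow(N))) {
          full <- numeric(d_full)
          full[sl] <- N[q, ]
          mu <- cond_means(N[q, ])
          full[match(names(mu), net$species)] <- mu
          out[q] <- prop_eval(p0, matrix(full, 1))
        }
        out
      }
    })
    list(source = rx$source[sl], product = rx$product[sl],
         propensity = prop_expr(fun, paste0("qss(", rx$label, ")")),
         label = paste(cx_label(rx$source[sl], species), "->",
                       cx_label(rx$product[sl], species)))
  })
  new_crn(species, reactions, net$params)
}

#' Residence-time samples of a bound (repressed) state
#'
#' Durations of maximal intervals during which the tracked species (e.g. the
#' repressed gene copy) has count at least one, from an SSA trajectory of
#' either the full or the reduced model.
#'
#' @param net a `crn`.
#' @param species tracked species name.
#' @param n0 initial state.
#' @param t_end horizon.
#' @param seed seed.
#' @return numeric vector of completed residence durations.
#' @export
residence_times <- function(net, species, n0, t_end, seed = NULL) {
  tr <- gillespie(net, n0, t_end, seed = seed, record = "track",
                  track = species)
  residence_from_track(tr$times, tr$values)
}
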