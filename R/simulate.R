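## Exact stochastic simulation (direct-method Gillespie). Networks whose
## propensities flatten to sums of mass-action terms run in compiled code;
## arbitrary propensities fall back to an R loop.

## flatten a propensity into mass-action terms (rate, source) or NULL
flatten_terms <- function(p) {
  if (p$kind == "mass_action") return(list(list(rate = p$rate, source = p$source)))
  if (p$kind == "sum") {
    parts <- lapply(p$parts, flatten_terms)
    if (any(vapply(parts, is.null, TRUE))) return(NULL)
    return(do.call(c, parts))
  }
  NULL
}

net_terms <- function(net) {
  term_rate <- numeric(0); term_rxn <- integer(0)
  term_src <- NULL
  for (k in seq_along(net$reactions)) {
    tm <- flatten_terms(net$reactions[[k]]$propensity)
    if (is.null(tm)) return(NULL)
    for (t1 in tm) {
      term_rate <- c(term_rate, t1$rate)
      term_rxn <- c(term_rxn, k - 1L)
      term_src <- rbind(term_src, t1$source)
    }
  }
  list(src = term_src, rate = term_rate, rxn = term_rxn)
}

#' Gillespie stochastic simulation
#'
#' Exact direct-method SSA: exponential waiting times at the total propensity
#' rate, next reaction chosen proportionally to its propensity. Reproducible
#' given a seed. A state where all propensities vanish absorbs the
#' trajectory (recorded, not an error).
#'
#' @param net a `crn` with numeric propensities.
#' @param n0 initial state (integer vector in species order).
#' @param t_end simulation horizon.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param record `"end"` (end state only), `"full"` (jump times, states and
#'   fired reaction indices) or `"track"` (change times of one species).
#' @param track species name used by `record = "track"`.
#' @param max_events event-count guard.
#' @return a `crn_trajectory` list.
#' @export
gillespie <- function(net, n0, t_end, seed = NULL,
                      record = c("full", "end", "track"), track = NULL,
                      max_events = 1e9) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  d <- length(net$species)
  stopifnot(length(n0) == d, all(n0 >= 0))
  gam <- stoich_matrix(net)
  tm <- net_terms(net)
  rec_code <- c(full = 1L, end = 0L, track = 2L)[[record]]
  ti <- if (is.null(track)) 0L else match(track, net$species) - 1L
  if (!is.null(tm)) {
    out <- ssa_cpp(tm$src, tm$rate, tm$rxn, gam, as.integer(n0), t_end,
                   record = rec_code, track = ti, max_events = max_events)
  } else {
    out <- ssa_r(net, n0, t_end, rec_code, ti + 1L, max_events)
  }
  out$species <- net$species
  out$seed <- seed
  class(out) <- "crn_trajectory"
  out
}

## R fallback for general propensities
ssa_r <- function(net, n0, t_end, rec_code, track1, max_events) {
  n <- as.numeric(n0); t <- 0; events <- 0
  gam <- stoich_matrix(net)
  r <- length(net$reactions)
  absorbed <- FALSE; capped <- FALSE
  times <- c(); states <- NULL; rxns <- c(); vals <- c()
  if (rec_code == 1L) { times <- 0; states <- matrix(n, 1); rxns <- NA_integer_ }
  if (rec_code == 2L) { times <- 0; vals <- n[track1] }
  N1 <- matrix(n, 1)
  repeat {
    N1[1, ] <- n
    a <- vapply(net$reactions, function(rx) prop_eval(rx$propensity, N1), 0)
    a0 <- sum(a)
    if (a0 <= 0) { absorbed <- TRUE; break }
    t <- t + rexp(1, a0)
    if (t > t_end) break
    k <- sample.int(r, 1, prob = a)
    n <- n + gam[k, ]
    events <- events + 1
    if (rec_code == 1L) { times <- c(times, t); states <- rbind(states, n); rxns <- c(rxns, k) }
    if (rec_code == 2L && vals[length(vals)] != n[track1]) {
      times <- c(times, t); vals <- c(vals, n[track1])
    }
    if (events >= max_events) { capped <- TRUE; break }
  }
  out <- list(end_state = as.integer(n), t = min(t, t_end), events = events,
              absorbed = absorbed, capped = capped)
  if (rec_code == 1L) { out$times <- times; out$states <- states; out$reaction <- rxns }
  if (rec_code == 2L) { out$times <- times; out$values <- vals }
  out
}

#' Empirical stationary distribution from repeated simulations
#'
#' Runs `n_runs` independent trajectories to `t_end` (per-run streams drawn
#' sequentially from the master seed) and histograms the end states.
#'
#' @param net a `crn`.
#' @param n0 initial state.
#' @param t_end horizon (beyond burn-in; stationarity is the user's judgment).
#' @param n_runs number of independent runs.
#' @param seed master seed.
#' @return a [pmf_table()] of end-state frequencies.
#' @export
empirical_stationary <- function(net, n0, t_end, n_runs, seed = 1L) {
  set.seed(seed)
  d <- length(net$species)
  gam <- stoich_matrix(net)
  tm <- net_terms(net)
  ends <- matrix(0L, n_runs, d)
  for (run in seq_len(n_runs)) {
    if (!is.null(tm)) {
      out <- ssa_cpp(tm$src, tm$rate, tm$rxn, gam, as.integer(n0), t_end,
                     record = 0L)
    } else {
      out <- ssa_r(net, n0, t_end, 0L, 1L, 1e9)
    }
    ends[run, ] <- out$end_state
  }
  keys <- apply(ends, 1, cx_key)
  tab <- table(keys)
  states <- do.call(rbind, lapply(strsplit(names(tab), ":", fixed = TRUE), as.integer))
  pmf_table(states, as.numeric(tab) / n_runs, net$species)
}

#' Time-averaged occupancy distribution of one species
#'
#' Holding-time-weighted histogram of a species' copy number over long
#' trajectories after a burn-in, an ergodic estimate of the stationary
#' marginal with far better per-event efficiency than end-state sampling.
#'
#' @param net a `crn` (mass-action flattenable propensities).
#' @param n0 initial state.
#' @param t_end per-run horizon.
#' @param burn initial time discarded.
#' @param n_runs number of runs averaged.
#' @param species tracked species name.
#' @param seed master seed.
#' @return data frame `count`, `prob`.
#' @export
occupancy_marginal <- function(net, n0, t_end, burn, species, n_runs = 4L,
                               seed = 1L) {
  set.seed(seed)
  tm <- net_terms(net)
  stopifnot(!is.null(tm))
  gam <- stoich_matrix(net)
  ti <- match(species, net$species) - 1L
  occ <- 0
  for (run in seq_len(n_runs)) {
    out <- ssa_cpp(tm$src, tm$rate, tm$rxn, gam, as.integer(n0), t_end,
                   record = 3L, track = ti, burn = burn)
    occ <- occ + out$occupancy
  }
  occ <- occ / sum(occ)
  keep <- which(occ > 0)
  data.frame(count = keep - 1L, prob = occ[keep])
}

#' Total variation distance between two distributions
#'
#' Accepts [pmf_table()]s, `crn_stationary` objects, or data frames with
#' `count`/`prob` columns (compared on the union of supports).
#'
#' @param p,q distributions.
#' @return numeric in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  as_map <- function(x) {
    if (inherits(x, "pmf_table")) return(setNames(x$prob, apply(x$states, 1, cx_key)))
    if (inherits(x, "crn_stationary")) return(setNames(x$pmf, apply(x$states, 1, cx_key)))
    if (is.data.frame(x)) return(setNames(x$prob, as.character(x$count)))
    stop("unsupported distribution object")
  }
  pm <- as_map(p); qm <- as_map(q)
  keys <- union(names(pm), names(qm))
  pv <- ifelse(keys %in% names(pm), pm[keys], 0)
  qv <- ifelse(keys %in% names(qm), qm[keys], 0)
  0.5 * sum(abs(pv - qv))
}

#' Approximation gap of an extended network
#'
#' The stationary distribution of a network extended by an extra reaction is
#' approximated by the core network's analytic distribution when the added
#' rate is small. This measures the total variation distance between the
#' analytic core distribution and the empirical distribution of the extended
#' network across a sequence of rate scales.
#'
#' @param core_dist analytic `crn_stationary` of the core network.
#' @param extended_maker function(rate) returning the extended `crn`.
#' @param rate_scales numeric vector of added-reaction rates.
#' @param n0 initial state.
#' @param t_end horizon per run.
#' @param n_runs runs per scale.
#' @param seed master seed.
#' @return data frame `rate`, `tv`.
#' @export
extension_gap <- function(core_dist, extended_maker, rate_scales, n0, t_end,
                          n_runs, seed = 1L) {
  core_pmf <- as_pmf_table(core_dist)
  tv <- vapply(seq_along(rate_scales), function(i) {
    net_i <- extended_maker(rate_scales[i])
    emp <- empirical_stationary(net_i, n0, t_end, n_runs, seed = seed + i)
    tv_distance(core_pmf, emp)
  }, 0)
  data.frame(rate = rate_scales, tv = tv)
}

## residence durations of maximal intervals with value >= 1 from a tracked
## trajectory (completed intervals only)
residence_from_track <- function(times, values) {
  out <- numeric(0)
  t_on <- NA_real_
  for (i in seq_along(times)) {
    if (values[i] >= 1 && is.na(t_on)) t_on <- times[i]
    if (values[i] < 1 && !is.na(t_on)) {
      out <- c(out, times[i] - t_on)
      t_on <- NA_real_
    }
  }
  out
}
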