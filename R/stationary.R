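## Stationary distribution assembly: pi(n) = M * c^n / theta(n) on the
## irreducible state space (0 outside Gamma = {n >= b}), where c is the CBE
## of the translated network with rates kappa and theta comes from the
## propensity factorization. All mass computations are done in log space
## (theta grows factorially) with log-sum-exp normalization.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Unnormalized stationary measure
#'
#' @param fac a verified `crn_factorization`.
#' @param eq a `crn_equilibrium` with positive `c`.
#' @return object with `log_value(N)` returning `n . log c - log theta(n)`
#'   for states in Gamma and `-Inf` outside.
#' @export
stationary_measure <- function(fac, eq) {
  stopifnot(fac$status == "ok", eq$status == "ok")
  logc <- log(eq$c)
  b <- fac$b
  structure(list(
    fac = fac, eq = eq,
    log_value = function(N) {
      if (is.null(dim(N))) N <- matrix(N, ncol = length(b))
      out <- rep(-Inf, nrow(N))
      ing <- apply(N, 1, function(n) all(n >= b))
      if (any(ing))
        out[ing] <- as.numeric(N[ing, , drop = FALSE] %*% logc) -
          fac_log_theta(fac, N[ing, , drop = FALSE])
      out
    }), class = "crn_measure")
}

#' Irreducible state space
#'
#' Determines the state space on which the stationary measure is normalized:
#' a finite stoichiometric compatibility class
#' `{n >= b, W n = totals}` when the conservation laws bound the state (its
#' closedness under all reactions is verified and its irreducibility is
#' checked by strong connectivity of the reachability graph), otherwise the
#' full lattice domain `Gamma = {n >= b}` (irreducibility then certified only
#' on the truncation used for normalization).
#'
#' @param net `crn` whose dynamics define reachability (original or
#'   translated; they share stoichiometric vectors and propensity sums).
#' @param fac factorization providing the base point `b`.
#' @param initial initial state (used to compute conserved totals), or
#' @param totals conserved totals aligned with rows of [conservation_laws()].
#' @param max_states guard on enumeration size.
#' @return object of class `crn_statespace`.
#' @export
irreducible_class <- function(net, fac, initial = NULL, totals = NULL,
                              max_states = 2e6) {
  d <- length(net$species)
  b <- if (is.numeric(fac)) as.integer(fac) else fac$b
  W <- conservation_laws(net)
  if (!is.null(initial) && is.null(totals) && nrow(W))
    totals <- as.numeric(W %*% initial)
  if (!nrow(W) || is.null(totals))
    return(structure(list(kind = "lattice", base = b, species = net$species),
                     class = "crn_statespace"))
  ## per-species upper bounds from non-negative conservation rows
  U <- rep(Inf, d)
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]; t_i <- totals[i]
    if (all(w <= 0)) { w <- -w; t_i <- -t_i }
    if (any(w < 0)) next
    for (jj in which(w > 0)) U[jj] <- min(U[jj], floor(t_i / w[jj]))
  }
  if (any(!is.finite(U)))
    return(structure(list(kind = "lattice", base = b, species = net$species),
                     class = "crn_statespace"))
  if (prod(U - b + 1) > max_states)
    stop("conserved class too large to enumerate (", prod(U - b + 1), " states)")
  G <- state_grid(b, as.integer(U))
  keep <- rep(TRUE, nrow(G))
  for (i in seq_len(nrow(W)))
    keep <- keep & abs(as.numeric(G %*% W[i, ]) - totals[i]) < 1e-9
  states <- G[keep, , drop = FALSE]
  if (!nrow(states)) stop("conserved class is empty")
  keys <- apply(states, 1, cx_key)
  idx <- setNames(seq_along(keys), keys)
  ## closedness + transition edges
  ei <- integer(0); ej <- integer(0)
  for (rx in net$reactions) {
    gam <- rx$product - rx$source
    lam <- prop_eval(rx$propensity, states)
    act <- which(lam > 0)
    if (!length(act)) next
    nxt <- sweep(states[act, , drop = FALSE], 2, -gam)
    j <- idx[apply(nxt, 1, cx_key)]
    if (anyNA(j)) {
      bad <- act[which(is.na(j))[1]]
      stop("state space not closed: reaction '", rx$label,
           "' exits the class from state (",
           paste(states[bad, ], collapse = ", "), ")")
    }
    ei <- c(ei, act); ej <- c(ej, unname(j))
  }
  g <- igraph::make_empty_graph(n = nrow(states), directed = TRUE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  irr <- igraph::components(g, mode = "strong")$no == 1
  structure(list(kind = "finite", base = b, species = net$species,
                 states = states, totals = totals, W = W,
                 irreducible = irr,
                 warning = if (!irr) "state space is not irreducible"),
            class = "crn_statespace")
}

#' Normalize a stationary measure into a distribution
#'
#' On a finite class the measure is summed exactly. On the infinite lattice
#' an adaptive rectangular truncation is used: the box doubles along every
#' axis whose boundary face still carries relative mass above `tail_tol`
#' (hard cap 8192 per axis; the factorization table is recomputed
#' transparently when the box outgrows it).
#'
#' @param measure a [stationary_measure()].
#' @param space a [irreducible_class()] result.
#' @param tail_tol tail-mass tolerance for infinite spaces.
#' @param max_side truncation cap per axis; reaching it (a non-summable or
#'   extremely spread measure) is an error reporting the partial mass.
#' @return object of class `crn_stationary` with `states`, `pmf`, `log_pmf`,
#'   the normalizing constant `log_M`, and the CBE `c`.
#' @export
normalize_measure <- function(measure, space, tail_tol = 1e-12,
                              max_side = 768L) {
  fac <- measure$fac
  if (space$kind == "finite") {
    states <- space$states
    lv <- measure$log_value(states)
  } else {
    b <- fac$b
    d <- length(b)
    hi <- b + 32L
    repeat {
      fac_use <- measure$fac
      if (fac_use$method != "gma" &&
          (is.null(fac_use$states) || any(apply(fac_use$states, 2, max) < hi))) {
        fac_use <- factorize_general(fac$net, window = max(hi - b) + 2L)
        if (fac_use$status != "ok")
          stop("factorization window extension failed during normalization")
        measure <- stationary_measure(fac_use, measure$eq)
      }
      states <- state_grid(b, hi)
      lv <- measure$log_value(states)
      tot <- logsumexp(lv)
      if (!is.finite(tot)) stop("stationary measure sums to zero on the box")
      grow <- logical(d)
      for (i in seq_len(d)) {
        face <- states[, i] == hi[i]
        grow[i] <- logsumexp(lv[face]) - tot > log(tail_tol)
      }
      if (!any(grow)) break
      if (any(hi[grow] - b[grow] >= max_side))
        stop("truncation cap reached; measure may not be summable ",
             "(partial log-mass ", tot, ")")
      hi[grow] <- b[grow] + 2L * (hi[grow] - b[grow])
    }
    fac <- measure$fac
  }
  logM <- -logsumexp(lv)
  lp <- lv + logM
  structure(list(states = states, log_pmf = lp, pmf = exp(lp),
                 species = space$species, space = space,
                 c = measure$eq$c, log_M = logM, fac = fac),
            class = "crn_stationary")
}

#' @export
print.crn_stationary <- function(x, ...) {
  cat(sprintf("Stationary distribution on %d states (%s space), log M = %.6g\n",
              nrow(x$states),
              if (x$space$kind == "finite") "finite conserved" else "truncated lattice",
              x$log_M))
  for (sp in x$species) {
    mo <- dist_moments(x, sp)
    cat(sprintf("  %s: mean %.4g, var %.4g, CV %.4g\n", sp, mo$mean, mo$var, mo$cv))
  }
  invisible(x)
}

#' Marginal distribution of one species
#'
#' @param dist a `crn_stationary`.
#' @param species species name.
#' @return data frame with columns `count` and `prob`.
#' @export
dist_marginal <- function(dist, species) {
  if (inherits(dist, "crn_derivation")) dist <- dist$dist
  if (inherits(dist, "crn_conditional"))
    return(dist_marginal(conditional_part(dist, species), species))
  i <- match(species, dist$species)
  stopifnot(!is.na(i))
  tab <- tapply(dist$pmf, dist$states[, i], sum)
  data.frame(count = as.integer(names(tab)), prob = as.numeric(tab))
}

#' Moments of one species under a stationary distribution
#'
#' @param dist a `crn_stationary`.
#' @param species species name.
#' @return list with `mean`, `var`, `cv` (sd/mean).
#' @export
dist_moments <- function(dist, species) {
  m <- dist_marginal(dist, species)
  mu <- sum(m$count * m$prob)
  v <- sum(m$count^2 * m$prob) - mu^2
  list(mean = mu, var = v, cv = sqrt(max(v, 0)) / mu)
}

## view a stationary distribution as a pmf table (for cme_residual)
as_pmf_table <- function(dist) {
  pmf_table(dist$states, dist$pmf, dist$species, zero_outside = TRUE)
}

#' Coefficient of variation of the Bessel-type marginal
#'
#' The unphosphorylated-protein marginal of the asymmetric
#' trans-autophosphorylation network has pmf proportional to
#' `r^n / (n! (n-1)!)` for `n >= 1`, where `r` is the composite parameter
#' `(alpha_1/alpha_2)(1 + alpha_4/alpha_3)`; its normalizing constant is
#' `sqrt(r) I_1(2 sqrt(r))` (modified Bessel function). This helper computes
#' the CV on a grid of `r` and locates its maximum.
#'
#' @param r_grid grid of composite-parameter values.
#' @param n_max truncation of the count support.
#' @return list with `r` (grid), `cv` (per grid point), `r_max`, `cv_max`.
#' @export
bessel_marginal_cv <- function(r_grid = seq(0.1, 10, by = 0.01), n_max = 200L) {
  cv <- vapply(r_grid, function(r) {
    n <- seq_len(n_max)
    lw <- n * log(r) - lfactorial(n) - lfactorial(n - 1)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    mu <- sum(n * w)
    sqrt(max(sum(n^2 * w) - mu^2, 0)) / mu
  }, 0)
  j <- which.max(cv)
  list(r = r_grid, cv = cv, r_max = r_grid[j], cv_max = cv[j])
}
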