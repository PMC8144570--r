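## Network translation: shift reactions (add the same vector to source and
## product, leaving the propensity function untouched) and merge reactions
## that land on the same ordered complex pair (summing propensities). Both
## operations preserve all per-stoichiometry propensity sums, hence the
## chemical master equation.

#' Translation scheme
#'
#' @param shifts integer matrix, one row per original reaction: the vector
#'   added to both the source and product complex of that reaction. Reactions
#'   whose shifted (source, product) pairs coincide are merged, so merge
#'   groups are implied by the shifts.
#' @return a `translation_scheme`.
#' @export
translation_scheme <- function(shifts) {
  structure(list(shifts = as.matrix(shifts)), class = "translation_scheme")
}

identity_scheme <- function(net) {
  translation_scheme(matrix(0L, length(net$reactions), length(net$species)))
}

#' Apply a translation scheme
#'
#' Shifts each reaction by its row of `scheme$shifts` and merges reactions
#' with identical translated (source, product) pairs by summing their
#' propensities. The translated propensities are unchanged as functions of
#' the state, so the stochastic dynamics are preserved.
#'
#' @param net a `crn`.
#' @param scheme a [translation_scheme()].
#' @return a `crn` with attributes `scheme` (provenance) and `origin`
#'   (the original network).
#' @export
apply_scheme <- function(net, scheme) {
  sh <- scheme$shifts
  stopifnot(nrow(sh) == length(net$reactions), ncol(sh) == length(net$species))
  reactions <- list()
  seen <- character(0)
  group <- integer(nrow(sh))
  for (k in seq_along(net$reactions)) {
    rx <- net$reactions[[k]]
    src <- as.integer(rx$source + sh[k, ])
    dst <- as.integer(rx$product + sh[k, ])
    if (any(src < 0) || any(dst < 0))
      stop(sprintf("shift of reaction %d produces a negative complex entry", k))
    key <- paste(cx_key(src), cx_key(dst), sep = ">")
    j <- match(key, seen)
    if (is.na(j)) {
      seen <- c(seen, key)
      j <- length(seen)
      reactions[[j]] <- list(source = src, product = dst,
                             propensity = rx$propensity,
                             label = paste(cx_label(src, net$species), "->",
                                           cx_label(dst, net$species)))
    } else {
      reactions[[j]]$propensity <- prop_sum(reactions[[j]]$propensity, rx$propensity)
    }
    group[k] <- j
  }
  out <- new_crn(net$species, reactions, net$params)
  attr(out, "scheme") <- scheme
  attr(out, "groups") <- group
  attr(out, "origin") <- net
  out
}

#' Verify that a translated network preserves the stochastic dynamics
#'
#' Checks, for every stoichiometric vector `gamma`, that the sum of original
#' propensities with that `gamma` equals the sum of translated propensities
#' with that `gamma`, on every state of a per-species window.
#'
#' @param original,translated `crn` objects over the same species.
#' @param window per-species window half-width for the state check.
#' @param tol relative tolerance.
#' @return logical.
#' @export
verify_scheme <- function(original, translated, window = 15L, tol = 1e-9) {
  d <- length(original$species)
  if (!identical(original$species, translated$species)) return(FALSE)
  W <- if (d <= 2) window else if (d <= 3) 8L else 4L
  N <- state_grid(rep(0L, d), rep(W, d))
  gam_key <- function(rx) cx_key(rx$product - rx$source)
  gk_o <- vapply(original$reactions, gam_key, "")
  gk_t <- vapply(translated$reactions, gam_key, "")
  for (g in union(gk_o, gk_t)) {
    so <- Reduce(`+`, lapply(which(gk_o == g), function(k)
      prop_eval(original$reactions[[k]]$propensity, N)), rep(0, nrow(N)))
    st <- Reduce(`+`, lapply(which(gk_t == g), function(k)
      prop_eval(translated$reactions[[k]]$propensity, N)), rep(0, nrow(N)))
    if (max(abs(so - st)) > tol * max(1, max(abs(so)))) return(FALSE)
  }
  TRUE
}

## ---- search ----------------------------------------------------------------

## Candidate shift list for one reaction: all s with |s|_inf <= max_shift,
## non-negative shifted complexes, and translated complex order bounded.
## For networks with more than two species the shift support is restricted
## to the species appearing in the reaction's own complexes (a documented
## search-space bound, like max_shift, that tames the 5^d branching).
candidate_shifts <- function(rx, max_shift, max_order, d) {
  rng <- (-max_shift):max_shift
  if (d > 2L) {
    supp <- which(rx$source + rx$product > 0L)
    axes <- rep(list(0L), d)
    axes[supp] <- list(rng)
    S <- as.matrix(expand.grid(axes))
  } else {
    S <- as.matrix(expand.grid(rep(list(rng), d)))
  }
  keep <- apply(S, 1, function(s) {
    src <- rx$source + s; dst <- rx$product + s
    all(src >= 0) && all(dst >= 0) && sum(src) <= max_order && sum(dst) <= max_order
  })
  S <- S[keep, , drop = FALSE]
  ord <- order(rowSums(abs(S)), apply(S, 1, function(s) paste(s, collapse = ",")))
  S[ord, , drop = FALSE]
}

## Depth-first enumeration of shift assignments whose translated undirected
## complex graph satisfies (#nodes - #components) <= s at every step (a sound
## prune: the quantity is monotone in the reaction set, and equality with s is
## necessary for deficiency zero). Returns shift matrices.
search_shift_assignments <- function(net, max_shift, max_order, s_target,
                                     budget = 20000L, max_found = 64L,
                                     stop_first = FALSE) {
  d <- length(net$species)
  r <- length(net$reactions)
  cands <- lapply(net$reactions, candidate_shifts, max_shift = max_shift,
                  max_order = max_order, d = d)
  found <- list()
  expansions <- 0L
  truncated <- FALSE
  ## incremental union-find over complex keys
  recurse <- function(k, shifts, nodes, parent) {
    if (truncated || (stop_first && length(found))) return()
    if (k > r) { found[[length(found) + 1L]] <<- shifts; return() }
    Ck <- cands[[k]]
    for (ci in seq_len(nrow(Ck))) {
      expansions <<- expansions + 1L
      if (expansions > budget) { truncated <<- TRUE; return() }
      s <- Ck[ci, ]
      src <- net$reactions[[k]]$source + s
      dst <- net$reactions[[k]]$product + s
      ks <- cx_key(src); kd <- cx_key(dst)
      nodes2 <- nodes; parent2 <- parent
      for (key in c(ks, kd)) if (is.na(match(key, nodes2))) {
        nodes2 <- c(nodes2, key); parent2 <- c(parent2, length(nodes2))
      }
      find <- function(i) { while (parent2[i] != i) i <- parent2[i]; i }
      a <- find(match(ks, nodes2)); b <- find(match(kd, nodes2))
      if (a != b) parent2[a] <- b
      ncomp <- sum(vapply(seq_along(nodes2), find, 1L) ==
                     seq_along(nodes2))
      if (length(nodes2) - ncomp > s_target) next
      recurse(k + 1L, rbind(shifts, s), nodes2, parent2)
      if (truncated || (stop_first && length(found))) return()
    }
  }
  recurse(1L, matrix(0L, 0, d), character(0), integer(0))
  list(found = found, truncated = truncated)
}

#' Search for translations to a weakly reversible deficiency-zero network
#'
#' Enumerates shift assignments (merging is implicit: reactions landing on the
#' same translated complex pair are merged) with `|shift|_inf <= max_shift`
#' and translated complex order bounded by the maximal original order plus
#' `max_shift`. Branches are pruned when the translated complex count already
#' forces positive deficiency. Accepted schemes yield a weakly reversible
#' network with deficiency zero and pass [verify_scheme()]. Results are
#' ordered canonically: fewest translated reactions, then smallest total
#' shift magnitude, then lexicographic shifts.
#'
#' @param net a `crn`.
#' @param max_shift shift bound (default 2).
#' @param max_schemes maximal number of schemes returned.
#' @param budget search-node budget; when exceeded the result carries
#'   attribute `truncated = TRUE`.
#' @return list of [translation_scheme()]s (possibly empty).
#' @export
search_translations <- function(net, max_shift = 2L, max_schemes = 10L,
                                budget = 20000L) {
  s_target <- int_echelon(stoich_matrix(net))$rank
  max_order <- max(vapply(net$reactions, function(rx)
    max(sum(rx$source), sum(rx$product)), 0)) + max_shift
  res <- search_shift_assignments(net, max_shift, max_order, s_target,
                                  budget = budget)
  schemes <- list()
  meta <- NULL
  for (sh in res$found) {
    sc <- translation_scheme(sh)
    tn <- tryCatch(apply_scheme(net, sc), error = function(e) NULL)
    if (is.null(tn)) next
    if (deficiency(tn) != 0L || !is_weakly_reversible(tn)) next
    if (!verify_scheme(net, tn, window = 6L)) next
    schemes[[length(schemes) + 1L]] <- sc
    meta <- rbind(meta, c(length(tn$reactions), sum(abs(sh)),
                          nrow(complex_matrix(tn))))
  }
  if (length(schemes)) {
    keys <- vapply(schemes, function(s) paste(s$shifts, collapse = ","), "")
    ord <- order(meta[, 1], meta[, 2], meta[, 3], keys)
    schemes <- schemes[ord][seq_len(min(length(schemes), max_schemes))]
  }
  attr(schemes, "truncated") <- res$truncated
  schemes
}

## Fast existence check used by the random-network survey: is there ANY
## translation with deficiency zero (weak reversibility not required)?
## Precheck: after translation the undirected complex graph must satisfy
## nodes - components = s, which forces all edges into components with at
## most s+1 nodes; hence at most C(s+1, 2) + s distinct stoichiometric
## directions (up to sign) can be hosted. Then a budgeted DFS decides.
translatable_deficiency_zero <- function(net, max_shift = 2L, budget = 5000L) {
  if (!length(net$reactions)) return(list(ok = TRUE, truncated = FALSE))
  if (deficiency(net) == 0L) return(list(ok = TRUE, truncated = FALSE))
  S <- stoich_matrix(net)
  s_target <- int_echelon(S)$rank
  ## distinct gammas up to sign
  gk <- apply(S, 1, function(g) {
    nz <- g[which(g != 0)[1]]
    if (nz < 0) g <- -g
    cx_key(g)
  })
  n_dirs <- length(unique(gk))
  max_dirs <- if (s_target <= 1) 1L else choose(s_target + 1, 2)
  if (n_dirs > max_dirs) return(list(ok = FALSE, truncated = FALSE))
  max_order <- max(vapply(net$reactions, function(rx)
    max(sum(rx$source), sum(rx$product)), 0)) + max_shift
  res <- search_shift_assignments(net, max_shift, max_order, s_target,
                                  budget = budget, stop_first = TRUE)
  ## any completed assignment has nodes - components <= s; combined with
  ## delta >= 0 this forces delta = 0, but assert explicitly for safety
  for (sh in res$found) {
    tn <- tryCatch(apply_scheme(net, translation_scheme(sh)),
                   error = function(e) NULL)
    if (!is.null(tn) && deficiency(tn) == 0L)
      return(list(ok = TRUE, truncated = res$truncated))
  }
  list(ok = FALSE, truncated = res$truncated)
}
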