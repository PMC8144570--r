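## Erdos-Renyi random reaction networks over the complex universe of all
## complexes with coefficient sum <= max_order, and the deficiency /
## translatability survey. The default edge model is the classical
## undirected one: each unordered complex pair is an edge with probability p
## and each sampled edge receives a uniformly random direction (deficiency
## does not depend on directions). A `directed` flag instead samples each of
## the ordered pairs independently.

#' Random reaction-network model
#'
#' @param n_species number of species `d`.
#' @param max_order maximal total coefficient of a complex (2 = up to
#'   bimolecular; for `d = 2` the universe is 0, A, B, 2A, 2B, A+B).
#' @param edge_prob edge probability `p`.
#' @param directed sample the ordered pairs independently instead of the
#'   undirected pairs.
#' @param seed model master seed.
#' @return a `random_crn_model`.
#' @export
random_crn_model <- function(n_species = 2L, max_order = 2L, edge_prob = 0.5,
                             directed = FALSE, seed = 1L) {
  cx <- complex_universe(n_species, max_order)
  m <- nrow(cx)
  if (directed) {
    idx <- which(outer(seq_len(m), seq_len(m), `!=`), arr.ind = TRUE)
    pairs <- cbind(src = idx[, 1], dst = idx[, 2])
  } else {
    cb <- t(utils::combn(m, 2))
    pairs <- cbind(src = cb[, 1], dst = cb[, 2])
  }
  structure(list(n_species = n_species, max_order = max_order,
                 edge_prob = edge_prob, directed = directed, seed = seed,
                 complexes = cx, pairs = pairs),
            class = "random_crn_model")
}

complex_universe <- function(d, max_order) {
  G <- state_grid(rep(0L, d), rep(max_order, d))
  G[rowSums(G) <= max_order, , drop = FALSE]
}

## draw the edge indicators (and directions) for networks index..index+k-1;
## each network's stream is seeded from its own index so that batched draws
## and single-network draws agree exactly
model_draw <- function(model, index, k = 1L) {
  np <- nrow(model$pairs)
  edges <- matrix(FALSE, k, np)
  flips <- if (model$directed) NULL else matrix(FALSE, k, np)
  ## the per-index seed is scrambled by two Lehmer rounds: seeding the
  ## generator with *consecutive* integers leaves its first draws
  ## correlated, which visibly biases rare-event fractions at the 1e-4 level
  m31 <- 2147483647
  for (j in seq_len(k)) {
    h <- (model$seed * 1000003 + index + j - 1) %% m31
    h <- (h * 48271) %% m31
    h <- (h * 69621) %% m31
    set.seed(h)
    edges[j, ] <- runif(np) < model$edge_prob
    if (!model$directed) flips[j, ] <- runif(np) < 0.5
  }
  list(edges = edges, flips = flips)
}

#' Sample one random reaction network
#'
#' Mass-action rate 1 on every sampled reaction; reproducible from
#' `(model$seed, index)`.
#'
#' @param model a [random_crn_model()].
#' @param index network index.
#' @return a `crn` (possibly with zero reactions).
#' @export
sample_random_crn <- function(model, index = 1L) {
  dr <- model_draw(model, index)
  e <- which(dr$edges[1, ])
  species <- paste0("S", seq_len(model$n_species))
  if (model$n_species == 2) species <- c("A", "B")
  reactions <- lapply(e, function(j) {
    a <- model$pairs[j, 1]; b <- model$pairs[j, 2]
    if (!model$directed && dr$flips[1, j]) { tmp <- a; a <- b; b <- tmp }
    src <- model$complexes[a, ]; dst <- model$complexes[b, ]
    list(source = src, product = dst,
         propensity = mass_action_propensity(1, src),
         label = paste(cx_label(src, species), "->", cx_label(dst, species)))
  })
  new_crn(species, reactions)
}

#' Deficiency / translatability survey over random networks
#'
#' Samples `n_samples` networks from the model and reports the fraction with
#' deficiency zero as sampled and (optionally) the fraction admitting any
#' translation with deficiency zero within the shift bound, with 95%
#' binomial confidence intervals. Per-network search-budget exhaustion is
#' counted as not translatable and tallied separately.
#'
#' @param model a [random_crn_model()].
#' @param n_samples number of networks.
#' @param translate also run the translatability search.
#' @param max_shift shift bound for the search.
#' @param budget per-network search budget (DFS node expansions).
#' @param require_wr additionally require weak reversibility of the
#'   translated network when counting translatable networks.
#' @param chunk batch size for the deficiency computation.
#' @return a `crn_survey` list of counts, fractions and confidence intervals.
#' @export
survey <- function(model, n_samples, translate = FALSE, max_shift = 2L,
                   budget = 5000L, require_wr = FALSE, chunk = 100000L) {
  stopifnot(n_samples >= 1)
  n_def0 <- 0L
  defs_all <- integer(0)
  done <- 0L
  while (done < n_samples) {
    k <- min(chunk, n_samples - done)
    dr <- model_draw(model, done + 1L, k)
    defs <- batch_deficiency(dr$edges, model$pairs[, 1], model$pairs[, 2],
                             model$complexes)
    n_def0 <- n_def0 + sum(defs == 0L)
    if (translate) defs_all <- c(defs_all, defs)
    done <- done + k
  }
  out <- list(model = model, n_samples = n_samples, n_def0 = n_def0,
              frac_def0 = n_def0 / n_samples,
              ci_def0 = binom_ci(n_def0, n_samples))
  if (translate) {
    n_trans <- sum(defs_all == 0L)  # identity scheme
    n_budget <- 0L
    for (i in which(defs_all != 0L)) {
      net <- sample_random_crn(model, i)
      tr <- translatable_deficiency_zero(net, max_shift = max_shift,
                                         budget = budget)
      okv <- tr$ok
      if (okv && require_wr) {
        sch <- search_translations(net, max_shift = max_shift, budget = budget,
                                   max_schemes = 1L)
        okv <- length(sch) > 0
      }
      if (okv) n_trans <- n_trans + 1L
      if (tr$truncated) n_budget <- n_budget + 1L
    }
    out$n_translatable <- n_trans
    out$frac_translatable <- n_trans / n_samples
    out$ci_translatable <- binom_ci(n_trans, n_samples)
    out$n_budget_exhausted <- n_budget
    out$ratio <- if (n_def0 > 0) n_trans / n_def0 else Inf
  }
  class(out) <- "crn_survey"
  out
}

binom_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  se <- sqrt(p * (1 - p) / n)
  c(lower = max(0, p - z * se), upper = min(1, p + z * se))
}

#' @export
print.crn_survey <- function(x, ...) {
  cat(sprintf("Random-network survey: %d samples (d=%d, order<=%d, p=%g)\n",
              x$n_samples, x$model$n_species, x$model$max_order,
              x$model$edge_prob))
  cat(sprintf("  deficiency zero as sampled: %d (%.4g%%, CI %.4g-%.4g%%)\n",
              x$n_def0, 100 * x$frac_def0, 100 * x$ci_def0[1], 100 * x$ci_def0[2]))
  if (!is.null(x$n_translatable)) {
    cat(sprintf("  translatable to deficiency zero: %d (%.4g%%), ratio %.3g\n",
                x$n_translatable, 100 * x$frac_translatable, x$ratio))
    if (x$n_budget_exhausted > 0)
      cat(sprintf("  search budget exhausted on %d networks\n", x$n_budget_exhausted))
  }
  invisible(x)
}
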