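## Propensity representations.
##
## A propensity is a function lambda: Z_{>=0}^d -> R_{>=0} attached to a
## reaction. Kinds:
##   mass_action: alpha * prod_i n_i!/(n_i - nu_i)! 1{n_i >= nu_i}
##   gma:         alpha * prod_i f_i(n_i) f_i(n_i-1) ... f_i(n_i-nu_i+1) 1{...}
##   expr:        arbitrary arithmetic in n_<species> and parameters
##   sum:         sum of propensities (arises from merging reactions)
## The stored source complex of a mass_action/gma propensity is the source it
## was *constructed* with; translation shifts a reaction's complexes but never
## its propensity, so the stored source stays meaningful.

## falling factorial prod_{j=0}^{k-1} (n - j), with 0 when n < k for integer n;
## defined by the same product for non-integer n (used by QSS-reduced models)
falling_factorial <- function(n, k) {
  if (k == 0L) return(rep(1, length(n)))
  out <- rep(1, length(n))
  for (j in 0:(k - 1L)) out <- out * (n - j)
  out[n < k] <- 0
  out
}

#' Stochastic mass-action propensity
#'
#' Builds the propensity `alpha * prod_i n_i!/(n_i - nu_i)!` with indicator
#' `n_i >= nu_i`, the number of ways the source complex can assemble from the
#' current state, scaled by the rate constant.
#'
#' @param alpha positive rate constant.
#' @param source source complex as an integer vector in species coordinates.
#' @return a `crn_prop` object.
#' @export
mass_action_propensity <- function(alpha, source) {
  stopifnot(is.numeric(alpha), alpha > 0, all(source >= 0))
  structure(list(kind = "mass_action", rate = alpha, source = as.integer(source)),
            class = "crn_prop")
}

#' Generalized mass-action propensity
#'
#' `alpha * prod_i f_i(n_i) f_i(n_i - 1) ... f_i(n_i - (nu_i - 1))` with
#' indicator `n_i >= nu_i`. With identity `f` this reduces to
#' [mass_action_propensity()]. Non-identity `f` covers e.g. Michaelis-Menten
#' or Hill-type saturation per species.
#'
#' @param alpha positive rate constant.
#' @param source source complex (integer vector).
#' @param f list of per-species functions, indexed like the species; entries
#'   may be `NULL` for species not in the source (identity is used).
#' @param f_text optional character descriptions for printing.
#' @return a `crn_prop` object.
#' @export
gma_propensity <- function(alpha, source, f, f_text = NULL) {
  stopifnot(is.numeric(alpha), alpha > 0, all(source >= 0))
  structure(list(kind = "gma", rate = alpha, source = as.integer(source),
                 f = f, f_text = f_text),
            class = "crn_prop")
}

prop_expr <- function(fun, text) {
  structure(list(kind = "expr", fun = fun, text = text), class = "crn_prop")
}

prop_sum <- function(a, b) {
  ## merging two mass-action propensities with the same stored source is just
  ## a rate sum; otherwise keep an explicit sum node
  if (a$kind == "mass_action" && b$kind == "mass_action" &&
      identical(a$source, b$source)) {
    return(mass_action_propensity(a$rate + b$rate, a$source))
  }
  pa <- if (a$kind == "sum") a$parts else list(a)
  pb <- if (b$kind == "sum") b$parts else list(b)
  structure(list(kind = "sum", parts = c(pa, pb)), class = "crn_prop")
}

## Evaluate a propensity on a matrix of states (rows = states, cols = species).
prop_eval <- function(p, N) {
  if (is.null(dim(N))) N <- matrix(N, nrow = 1)
  switch(p$kind,
    mass_action = {
      out <- rep(p$rate, nrow(N))
      for (i in which(p$source > 0L))
        out <- out * falling_factorial(N[, i], p$source[i])
      out
    },
    gma = {
      out <- rep(p$rate, nrow(N))
      for (i in which(p$source > 0L)) {
        nu_i <- p$source[i]
        fi <- p$f[[i]]
        if (is.null(fi)) fi <- function(x) x
        term <- rep(1, nrow(N))
        for (j in 0:(nu_i - 1L)) term <- term * fi(N[, i] - j)
        term[N[, i] < nu_i] <- 0
        out <- out * term
      }
      out
    },
    expr = p$fun(N),
    sum = Reduce(`+`, lapply(p$parts, prop_eval, N = N)),
    stop("unknown propensity kind"))
}

prop_describe <- function(p, species) {
  switch(p$kind,
    mass_action = sprintf("mass_action(%g) from %s", p$rate,
                          cx_label(p$source, species)),
    gma = sprintf("gma(%g) from %s", p$rate, cx_label(p$source, species)),
    expr = sprintf("expr(%s)", p$text),
    sum = paste(vapply(p$parts, prop_describe, "", species = species),
                collapse = " + "))
}

prop_serialize <- function(p, species) {
  switch(p$kind,
    mass_action = sprintf("mass_action(%.17g)", p$rate),
    gma = {
      ft <- p$f_text
      fs <- paste(sprintf("f%s=%s", species[!vapply(ft, is.null, TRUE)],
                          unlist(ft[!vapply(ft, is.null, TRUE)])), collapse = ", ")
      sprintf("gma(%.17g; %s)", p$rate, fs)
    },
    expr = sprintf("expr(%s)", p$text),
    sum = sprintf("expr(%s)", paste(vapply(p$parts, function(q)
      prop_to_expr_text(q, species), ""), collapse = " + ")))
}

prop_to_expr_text <- function(p, species) {
  if (p$kind == "expr") return(p$text)
  if (p$kind == "mass_action") {
    terms <- sprintf("%.17g", p$rate)
    for (i in which(p$source > 0L))
      for (j in 0:(p$source[i] - 1L))
        terms <- paste0(terms, sprintf(" * (n_%s - %d)", species[i], j))
    return(gsub(" - 0\\)", ")", terms))
  }
  stop("cannot serialize propensity kind ", p$kind)
}

## ---- kinetics expression parsing -------------------------------------------

expr_allowed_calls <- c("+", "-", "*", "/", "^", "(", "factorial", "exp", "log", "sqrt")

check_expr_symbols <- function(e, vars, line) {
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!(fn %in% expr_allowed_calls))
      stop(sprintf("line %s: disallowed function '%s' in expression", line, fn),
           call. = FALSE)
    for (a in as.list(e)[-1]) check_expr_symbols(a, vars, line)
  } else if (is.name(e)) {
    if (!(as.character(e) %in% vars))
      stop(sprintf("line %s: unknown symbol '%s' in expression", line,
                   as.character(e)), call. = FALSE)
  } else if (!is.numeric(e)) {
    stop(sprintf("line %s: invalid token in expression", line), call. = FALSE)
  }
}

make_expr_fun <- function(txt, species, params, line = NA) {
  e <- tryCatch(str2lang(txt),
                error = function(err) stop(sprintf("line %s: cannot parse expression '%s'",
                                                   line, txt), call. = FALSE))
  vars <- c(paste0("n_", species), names(params))
  check_expr_symbols(e, vars, line)
  force(params)
  function(N) {
    env <- list2env(as.list(params), parent = baseenv())
    for (i in seq_along(species)) assign(paste0("n_", species[i]), N[, i], envir = env)
    v <- eval(e, env)
    rep_len(v, nrow(N))
  }
}

rate_value <- function(txt, params, line) {
  txt <- trimws(txt)
  v <- suppressWarnings(as.numeric(txt))
  if (!is.na(v)) return(v)
  if (!is.null(params) && txt %in% names(params)) return(unname(params[[txt]]))
  stop(sprintf("line %s: rate '%s' is neither numeric nor a bound parameter",
               line, txt), call. = FALSE)
}

parse_kinetics <- function(kin, src_coef, species, params, line) {
  m <- regmatches(kin, regexec("^([a-z_]+)\\s*\\((.*)\\)$", kin))[[1]]
  if (length(m) == 0)
    stop(sprintf("line %s: cannot parse kinetics '%s'", line, kin), call. = FALSE)
  kind <- m[2]; body <- m[3]
  ## source in full species coordinates (species table already complete enough:
  ## pad later in parse_network; here indices by name)
  src <- coef_to_vec(src_coef, species)
  if (kind == "mass_action") {
    mass_action_propensity(rate_value(body, params, line), src)
  } else if (kind == "gma") {
    parts <- strsplit(body, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("line %s: gma needs 'gma(RATE; fX=EXPR, ...)'", line), call. = FALSE)
    alpha <- rate_value(parts[1], params, line)
    f <- vector("list", length(species))
    f_text <- vector("list", length(species))
    for (spec1 in trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])) {
      mm <- regmatches(spec1, regexec("^f([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*)$", spec1))[[1]]
      if (length(mm) == 0)
        stop(sprintf("line %s: cannot parse gma spec '%s'", line, spec1), call. = FALSE)
      i <- match(mm[2], species)
      if (is.na(i))
        stop(sprintf("line %s: unknown species '%s' in gma", line, mm[2]), call. = FALSE)
      fn1 <- make_expr_fun(gsub("\\bn\\b", paste0("n_", species[i]), mm[3]),
                           species, params, line)
      ii <- i
      f[[i]] <- local({
        sp_i <- ii; g <- fn1
        function(x) {
          N <- matrix(0, length(x), length(species)); N[, sp_i] <- x
          g(N)
        }
      })
      f_text[[i]] <- mm[3]
    }
    for (i in which(src > 0L)) if (is.null(f[[i]])) {
      ii <- i
      f[[i]] <- function(x) x
      f_text[[i]] <- "n"
    }
    gma_propensity(alpha, src, f, f_text)
  } else if (kind == "expr") {
    prop_expr(make_expr_fun(body, species, params, line), body)
  } else {
    stop(sprintf("line %s: unknown kinetics kind '%s'", line, kind), call. = FALSE)
  }
}

## ---- positivity threshold (factorization base point) -----------------------

## Axis-aligned grid of states low..high (inclusive), rows = states.
state_grid <- function(low, high) {
  d <- length(low)
  as.matrix(expand.grid(lapply(seq_len(d), function(i) low[i]:high[i])))
}

#' Base-point contribution of one propensity
#'
#' Finds the minimal non-negative vector `t` such that, on a finite window,
#' `lambda(n) > 0` exactly when `n >= t`, and returns `b = t - nu` (the
#' contribution of this reaction to the factorization base point). Certified
#' on the window `0..(W)` per species; returns `NULL` when the positivity set
#' is not an upper orthant, in which case no factorization domain exists for
#' this reaction.
#'
#' @param prop a `crn_prop`.
#' @param nu source complex of the (translated) reaction.
#' @param window certification window half-width `W`.
#' @return integer vector `b`-contribution, or `NULL` on failure.
#' @export
positivity_threshold <- function(prop, nu, window = NULL) {
  d <- length(nu)
  if (is.null(window)) window <- c(25L, 25L, 12L, 8L, 6L)[min(d, 5L)]
  G <- state_grid(rep(0L, d), rep(window, d) + nu)
  lam <- prop_eval(prop, G)
  if (any(lam < 0)) return(NULL)
  pos <- lam > 0
  if (!any(pos)) return(NULL)
  t_min <- apply(G[pos, , drop = FALSE], 2, min)
  ok <- all(pos == apply(G, 1, function(n) all(n >= t_min)))
  if (!ok) return(NULL)
  b <- t_min - nu
  if (any(b < 0)) return(NULL)
  as.integer(b)
}

## ---- pmf tables and the CME stationarity residual --------------------------

#' Probability mass table over integer states
#'
#' @param states integer matrix, one state per row.
#' @param prob numeric masses (same length as rows of `states`).
#' @param species species names (column order of `states`).
#' @param zero_outside if `TRUE`, states absent from the table are taken to
#'   have mass zero instead of raising an error on lookup.
#' @return a `pmf_table` object.
#' @export
pmf_table <- function(states, prob, species, zero_outside = TRUE) {
  if (is.null(dim(states))) states <- matrix(states, ncol = length(species))
  stopifnot(nrow(states) == length(prob), all(prob >= -1e-15))
  keys <- apply(states, 1, cx_key)
  structure(list(states = states, prob = as.numeric(prob),
                 index = setNames(seq_along(keys), keys),
                 species = species, zero_outside = zero_outside),
            class = "pmf_table")
}

pmf_lookup <- function(pmf, n) {
  j <- pmf$index[cx_key(n)]
  if (is.na(j)) {
    if (pmf$zero_outside) return(0)
    stop("state (", paste(n, collapse = ", "), ") missing from pmf table")
  }
  pmf$prob[[j]]
}

#' CME stationarity residual at a state
#'
#' Returns `sum_k lambda_k(n - gamma_k) pi(n - gamma_k) - sum_k lambda_k(n) pi(n)`,
#' the net probability in-flow of the chemical master equation at state `n`.
#' A pmf is stationary precisely when this vanishes at every state.
#'
#' @param net a `crn`.
#' @param pmf a [pmf_table()].
#' @param n integer state vector.
#' @return numeric residual.
#' @export
cme_residual <- function(net, pmf, n) {
  n <- as.integer(n)
  inflow <- 0; outflow <- 0
  for (rx in net$reactions) {
    gam <- rx$product - rx$source
    prev <- n - gam
    if (all(prev >= 0L))
      inflow <- inflow + prop_eval(rx$propensity, matrix(prev, 1)) * pmf_lookup(pmf, prev)
    outflow <- outflow + prop_eval(rx$propensity, matrix(n, 1)) * pmf_lookup(pmf, n)
  }
  inflow - outflow
}
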