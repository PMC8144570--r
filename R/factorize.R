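## Propensity factorization: find constants kappa_k and functions theta > 0,
## omega >= 0 on the lattice domain Gamma = {n >= b} with
##   lambda_k(n) = kappa_k * theta(n) * omega(n - nu_k) * 1{n >= nu_k}.
## Taking logs this is a linear system coupling theta-nodes, omega-nodes and
## kappa's through one equation per (reaction, state with positive
## propensity); it is solved exactly by unit propagation with the gauge
## theta(b) = omega(b) = 1, with a sparse least-squares fallback, and
## verified by a full residual scan. Everything is kept in log space since
## theta grows factorially.

## network-level base point: componentwise max of per-reaction contributions,
## then re-verified (lambda_k > 0 iff n >= nu_k + b for n in Gamma)
factor_base_point <- function(net, window = NULL) {
  d <- length(net$species)
  contrib <- lapply(net$reactions, function(rx)
    positivity_threshold(rx$propensity, rx$source, window))
  if (any(vapply(contrib, is.null, TRUE))) return(NULL)
  b <- Reduce(pmax, contrib, rep(0L, d))
  as.integer(b)
}

## check lambda_k(n) > 0 iff n >= nu_k + b for all k on the given states;
## returns NULL if ok, else list(reaction, state)
check_positivity_pattern <- function(net, b, states) {
  for (k in seq_along(net$reactions)) {
    rx <- net$reactions[[k]]
    lam <- prop_eval(rx$propensity, states)
    should <- apply(states, 1, function(n) all(n >= rx$source + b))
    bad <- which((lam > 0) != should)
    if (length(bad))
      return(list(reaction = k, state = states[bad[1], ]))
    if (any(lam < 0))
      return(list(reaction = k, state = states[which(lam < 0)[1], ]))
  }
  NULL
}

new_factorization <- function(net, b, kappa, states, log_theta,
                              omega_states, log_omega, method,
                              f = NULL, status = "ok", certificate = NULL) {
  structure(list(net = net, b = as.integer(b), kappa = kappa,
                 states = states, log_theta = log_theta,
                 theta_index = if (!is.null(states))
                   setNames(seq_len(nrow(states)), apply(states, 1, cx_key)),
                 omega_states = omega_states, log_omega = log_omega,
                 omega_index = if (!is.null(omega_states))
                   setNames(seq_len(nrow(omega_states)),
                            apply(omega_states, 1, cx_key)),
                 method = method, f = f, status = status,
                 certificate = certificate),
            class = "crn_factorization")
}

#' @export
print.crn_factorization <- function(x, ...) {
  cat(sprintf("Propensity factorization (%s), status: %s\n", x$method, x$status))
  if (x$status == "ok") {
    cat("  b = (", paste(x$b, collapse = ", "), ")\n")
    cat("  kappa = ", paste(sprintf("%.6g", x$kappa), collapse = ", "), "\n")
    if (!is.null(x$states))
      cat(sprintf("  theta tabulated on %d states\n", nrow(x$states)))
  } else if (!is.null(x$certificate)) {
    cat(sprintf("  inconsistency at reaction %d, state (%s)\n",
                x$certificate$reaction,
                paste(x$certificate$state, collapse = ", ")))
  }
  invisible(x)
}

## log theta at states N (matrix); table lookup or gma closed form
fac_log_theta <- function(fac, N) {
  if (is.null(dim(N))) N <- matrix(N, ncol = length(fac$b))
  if (fac$method == "gma") {
    out <- numeric(nrow(N))
    for (i in seq_len(ncol(N))) {
      fi <- fac$f[[i]]
      if (is.null(fi)) fi <- function(x) x
      hi <- max(N[, i])
      if (hi > fac$b[i]) {
        lf <- c(0, cumsum(log(fi((fac$b[i] + 1):hi))))
        out <- out + lf[pmax(N[, i] - fac$b[i], 0) + 1]
      }
    }
    return(out)
  }
  j <- fac$theta_index[apply(N, 1, cx_key)]
  if (anyNA(j))
    stop("theta requested outside the tabulated factorization window")
  fac$log_theta[j]
}

## log omega at states M; -Inf outside {m >= b}
fac_log_omega <- function(fac, M) {
  if (is.null(dim(M))) M <- matrix(M, ncol = length(fac$b))
  out <- rep(-Inf, nrow(M))
  inb <- apply(M, 1, function(m) all(m >= fac$b))
  if (!any(inb)) return(out)
  if (fac$method == "gma") {
    out[inb] <- -fac_log_theta(fac, M[inb, , drop = FALSE])
  } else {
    j <- fac$omega_index[apply(M[inb, , drop = FALSE], 1, cx_key)]
    if (anyNA(j))
      stop("omega requested outside the tabulated factorization window")
    out[inb] <- fac$log_omega[j]
  }
  out
}

#' Closed-form factorization for generalized mass-action networks
#'
#' When every propensity follows generalized mass action with a shared
#' per-species family `f`, the factorization is
#' `kappa_k = alpha_k`, `theta(n) = prod_i prod_{j=b_i+1}^{n_i} f_i(j)` and
#' `omega = 1/theta` on the domain (empty products are 1). For identity `f`
#' this is `theta(n) = prod_i n_i!`, the mass-action/Poisson case.
#'
#' @param net translated `crn` whose propensities are all mass-action or
#'   `gma` with the shared `f`.
#' @param f list of per-species functions (NULL entries mean identity).
#' @param base base point `b` (defaults to the computed positivity base).
#' @param check_window window for verifying the `f`-form of each propensity.
#' @return a `crn_factorization`.
#' @export
factorize_gma <- function(net, f = NULL, base = NULL, check_window = 12L) {
  d <- length(net$species)
  if (is.null(f)) f <- vector("list", d)
  if (is.null(base)) base <- factor_base_point(net)
  if (is.null(base)) stop("no valid factorization base point")
  ## every propensity must equal alpha * prod f-falling products
  rates <- numeric(length(net$reactions))
  G <- state_grid(rep(0L, d), rep(check_window, d))
  for (k in seq_along(net$reactions)) {
    rx <- net$reactions[[k]]
    p <- rx$propensity
    if (!(p$kind %in% c("mass_action", "gma")))
      stop("non-gma propensity present; use factorize_general()")
    rates[k] <- p$rate
    gp <- gma_propensity(p$rate, rx$source, f)
    if (max(abs(prop_eval(p, G) - prop_eval(gp, G))) > 1e-9 * max(1, p$rate))
      stop("propensity of reaction ", k,
           " does not follow the shared generalized mass-action family; ",
           "use factorize_general()")
  }
  ## f_i must be positive above b_i on a sanity window
  for (i in seq_len(d)) {
    fi <- if (is.null(f[[i]])) function(x) x else f[[i]]
    v <- fi((base[i] + 1):(base[i] + check_window))
    if (any(v <= 0)) stop("f for species ", net$species[i],
                          " is not positive above the base point")
  }
  new_factorization(net, base, kappa = rates, states = NULL, log_theta = NULL,
                    omega_states = NULL, log_omega = NULL,
                    method = "gma", f = f)
}

#' General propensity factorization by recurrence solving
#'
#' Determines the base point from the positivity pattern of each translated
#' propensity, then solves the log-linear system
#' `log lambda_k(n) = log kappa_k + log theta(n) + log omega(n - nu_k)`
#' over all states of the working region by exact unit propagation with the
#' gauge `theta(b) = omega(b) = 1` (underdetermined directions, which arise
#' e.g. on conserved networks whose recurrences only couple states within a
#' stoichiometric class, are fixed by additional unit gauges). A sparse
#' least-squares fallback covers systems that propagation alone cannot
#' order. The result is verified by a full residual scan; on inconsistency a
#' certificate (reaction, state) where the factorization condition fails is
#' returned with status `"inconsistent"`.
#'
#' @param net translated `crn`.
#' @param states optional explicit working region (matrix of states), e.g. a
#'   conserved stoichiometric class; default is the box `b .. b + window`.
#' @param window per-species window for the default box region.
#' @param tol residual tolerance on log-scale identities.
#' @return a `crn_factorization` (check `$status`).
#' @export
factorize_general <- function(net, states = NULL, window = 50L, tol = 1e-8) {
  d <- length(net$species)
  r <- length(net$reactions)
  b <- factor_base_point(net)
  if (is.null(b))
    return(new_factorization(net, rep(0L, d), NULL, NULL, NULL, NULL, NULL,
                             method = "recurrence", status = "no_base_point"))
  if (is.null(states)) {
    max_nu <- Reduce(pmax, lapply(net$reactions, `[[`, "source"), rep(0L, d))
    hi <- b + pmax(window, max_nu + 2L)
    states <- state_grid(b, hi)
  } else {
    states <- states[apply(states, 1, function(n) all(n >= b)), , drop = FALSE]
  }
  bad <- check_positivity_pattern(net, b, states)
  if (!is.null(bad))
    return(new_factorization(net, b, NULL, NULL, NULL, NULL, NULL,
                             method = "recurrence", status = "no_base_point",
                             certificate = bad))
  theta_keys <- apply(states, 1, cx_key)
  theta_index <- setNames(seq_along(theta_keys), theta_keys)
  ## build equations
  eq_t <- integer(0); eq_w_key <- character(0); eq_k <- integer(0)
  eq_rhs <- numeric(0); eq_state <- integer(0)
  for (k in seq_len(r)) {
    rx <- net$reactions[[k]]
    lam <- prop_eval(rx$propensity, states)
    posi <- which(lam > 0)
    if (!length(posi)) next
    M <- sweep(states[posi, , drop = FALSE], 2, rx$source)
    eq_t <- c(eq_t, posi)
    eq_w_key <- c(eq_w_key, apply(M, 1, cx_key))
    eq_k <- c(eq_k, rep(k, length(posi)))
    eq_rhs <- c(eq_rhs, log(lam[posi]))
    eq_state <- c(eq_state, posi)
  }
  if (!length(eq_t))
    return(new_factorization(net, b, NULL, NULL, NULL, NULL, NULL,
                             method = "recurrence", status = "no_base_point"))
  omega_keys <- unique(eq_w_key)
  omega_index <- setNames(seq_along(omega_keys), omega_keys)
  eq_w <- omega_index[eq_w_key]
  ## gauge seeds: theta(b) = 1 and omega(b) = 1 (indices may be absent from
  ## an explicit-state region; seed whatever exists)
  bkey <- cx_key(b)
  seeds <- integer(0)
  if (!is.na(theta_index[bkey])) seeds <- c(seeds, theta_index[[bkey]] - 1L)
  if (!is.na(omega_index[bkey]))
    seeds <- c(seeds, length(theta_index) + omega_index[[bkey]] - 1L)
  res <- factor_propagate(length(theta_index), length(omega_keys), r,
                          eq_t - 1L, eq_w - 1L, eq_k - 1L, eq_rhs,
                          seeds, numeric(length(seeds)))
  lt <- res$ltheta; lw <- res$lomega; lk <- res$lkappa
  resid <- abs(lt[eq_t] + lw[eq_w] + lk[eq_k] - eq_rhs)
  if (max(resid) > tol) {
    ## least-squares fallback over the full system (gauge rows appended)
    nt <- length(theta_index); nw <- length(omega_keys)
    ii <- c(seq_along(eq_t), seq_along(eq_t), seq_along(eq_t))
    jj <- c(eq_t, nt + eq_w, nt + nw + eq_k)
    ne <- length(eq_t)
    gr <- seq_along(seeds) + ne
    A <- Matrix::sparseMatrix(i = c(ii, gr), j = c(jj, seeds + 1L),
                              x = 1, dims = c(ne + length(seeds), nt + nw + r))
    rhs <- c(eq_rhs, numeric(length(seeds)))
    xt <- tryCatch(
      as.numeric(Matrix::solve(Matrix::crossprod(A) +
                                 Matrix::Diagonal(nt + nw + r, 1e-10),
                               Matrix::crossprod(A, rhs))),
      error = function(e) NULL)
    if (!is.null(xt)) {
      lt <- xt[seq_len(nt)]; lw <- xt[nt + seq_len(nw)]; lk <- xt[nt + nw + seq_len(r)]
      resid <- abs(lt[eq_t] + lw[eq_w] + lk[eq_k] - eq_rhs)
    }
  }
  if (max(resid) > tol) {
    j <- which.max(resid)
    return(new_factorization(net, b, NULL, NULL, NULL, NULL, NULL,
                             method = "recurrence", status = "inconsistent",
                             certificate = list(reaction = eq_k[j],
                                                state = states[eq_state[j], ])))
  }
  omega_states <- do.call(rbind, lapply(strsplit(omega_keys, ":", fixed = TRUE),
                                        as.integer))
  new_factorization(net, b, kappa = exp(lk), states = states, log_theta = lt,
                    omega_states = omega_states, log_omega = lw,
                    method = "recurrence")
}

#' Verify a factorization by exhaustive identity check
#'
#' Checks `lambda_k(n) = kappa_k * theta(n) * omega(n - nu_k) * 1{n >= nu_k}`
#' for every reaction at every state of the window (or of the tabulated
#' region for explicit-state factorizations), in log space, to `tol`.
#'
#' @param net translated `crn` (defaults to the one stored in `fac`).
#' @param fac a `crn_factorization`.
#' @param window per-species window half-width.
#' @param tol relative tolerance.
#' @return logical.
#' @export
verify_factorization <- function(fac, net = fac$net, window = 20L, tol = 1e-8) {
  if (fac$status != "ok") return(FALSE)
  d <- length(net$species)
  if (fac$method == "recurrence" && !is.null(fac$states)) {
    states <- fac$states
  } else {
    W <- if (d <= 2) window else min(window, 8L)
    states <- state_grid(fac$b, fac$b + W)
  }
  lth <- fac_log_theta(fac, states)
  for (k in seq_along(net$reactions)) {
    rx <- net$reactions[[k]]
    lam <- prop_eval(rx$propensity, states)
    hasnu <- apply(states, 1, function(n) all(n >= rx$source))
    M <- sweep(states, 2, rx$source)
    lom <- rep(-Inf, nrow(states))
    lom[hasnu] <- tryCatch(fac_log_omega(fac, M[hasnu, , drop = FALSE]),
                           error = function(e) rep(NA_real_, sum(hasnu)))
    pred <- ifelse(hasnu, exp(log(fac$kappa[k]) + lth + lom), 0)
    pred[is.na(pred)] <- Inf
    if (any(abs(pred - lam) > tol * pmax(1, abs(lam)))) return(FALSE)
  }
  TRUE
}
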