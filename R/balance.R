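## Complex balanced equilibrium (CBE): a positive concentration vector c with,
## for every complex z,  sum_{k: product=z} kappa_k c^{nu_k}
##                     = sum_{k: source=z}  kappa_k c^{nu_k}.
## Equivalently, the vector (c^{z})_z is a stationary measure of the
## continuous-time Markov chain on the complex graph with jump rates kappa.
## For weakly reversible deficiency-zero networks that chain has a positive
## per-class stationary vector (matrix-tree theorem) and the log-linear system
## nu_z . log(c) = log(x_z) + mu_class is exactly solvable; this is how the
## solver proceeds, with a damped Gauss-Newton fallback for other inputs.

#' Complex-balance equation set
#'
#' Builds, for each complex, the in-flow and out-flow reaction index sets and
#' a readable equation string for the deterministic mass-action model with
#' rate constants `kappa`.
#'
#' @param net translated `crn`.
#' @param kappa per-reaction positive rate constants.
#' @return list with `complexes`, and per complex `inflow`, `outflow`
#'   (reaction indices) and `equation` strings.
#' @export
cbe_equations <- function(net, kappa) {
  cx <- complex_matrix(net)
  ed <- reaction_edges(net, cx)
  mono <- function(k) {
    nu <- net$reactions[[k]]$source
    tm <- sprintf("k%d", k)
    for (i in which(nu > 0))
      tm <- paste0(tm, if (nu[i] == 1) sprintf("*c_%s", net$species[i])
                   else sprintf("*c_%s^%d", net$species[i], nu[i]))
    tm
  }
  eqs <- lapply(seq_len(nrow(cx)), function(z) {
    inflow <- which(ed[, "dst"] == z)
    outflow <- which(ed[, "src"] == z)
    list(inflow = inflow, outflow = outflow,
         equation = paste(
           if (length(inflow)) paste(vapply(inflow, mono, ""), collapse = " + ") else "0",
           "=",
           if (length(outflow)) paste(vapply(outflow, mono, ""), collapse = " + ") else "0"))
  })
  list(complexes = cx, kappa = kappa, equations = eqs, species = net$species)
}

## per-complex balance residuals at concentrations c, both raw and relative
cbe_residuals <- function(net, kappa, c) {
  cx <- complex_matrix(net)
  ed <- reaction_edges(net, cx)
  flux <- vapply(seq_along(net$reactions), function(k)
    kappa[k] * prod(c ^ net$reactions[[k]]$source), 0)
  raw <- vapply(seq_len(nrow(cx)), function(z) {
    sum(flux[ed[, "dst"] == z]) - sum(flux[ed[, "src"] == z])
  }, 0)
  scale <- vapply(seq_len(nrow(cx)), function(z) {
    max(sum(flux[ed[, "dst"] == z]), sum(flux[ed[, "src"] == z]), 1e-300)
  }, 0)
  list(raw = raw, rel = raw / scale)
}

#' Solve the complex-balance equations
#'
#' For weakly reversible deficiency-zero translated networks a CBE exists for
#' every choice of positive `kappa`; it is computed from the stationary vector
#' of the kappa-weighted complex graph per linkage class followed by an exact
#' log-linear solve. For other networks a Gauss-Newton iteration is attempted
#' and non-existence is reported as a legal `"no_cbe"` outcome rather than an
#' error.
#'
#' @param net translated `crn`.
#' @param kappa per-reaction positive rate constants.
#' @param tol maximal relative per-complex residual accepted.
#' @return object of class `crn_equilibrium` with fields `c`, `residuals`,
#'   `status` (`"ok"` or `"no_cbe"`).
#' @export
solve_cbe <- function(net, kappa, tol = 1e-12) {
  d <- length(net$species)
  cx <- complex_matrix(net)
  ed <- reaction_edges(net, cx)
  m <- nrow(cx)
  cg <- complex_graph(net)
  comp <- igraph::components(cg$graph, mode = "weak")$membership
  lx <- rep(NA_real_, m)
  ok_chain <- TRUE
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    ## CTMC generator on the complexes of this class
    Q <- matrix(0, length(idx), length(idx))
    for (k in seq_len(nrow(ed))) {
      i <- match(ed[k, "src"], idx); j <- match(ed[k, "dst"], idx)
      if (!is.na(i) && !is.na(j)) Q[i, j] <- Q[i, j] + kappa[k]
    }
    diag(Q) <- diag(Q) - rowSums(Q)
    ns <- svd(t(Q))
    x <- ns$v[, ncol(ns$v)]
    if (max(abs(t(Q) %*% x)) > 1e-8 * max(abs(Q))) { ok_chain <- FALSE; break }
    if (sum(x) < 0) x <- -x
    if (any(x <= 0)) { ok_chain <- FALSE; break }
    lx[idx] <- log(x / sum(x))
  }
  cvec <- NULL
  if (ok_chain) {
    ## nu_z . logc - mu_class = log x_z
    l <- length(unique(comp))
    A <- cbind(cx, -outer(comp, seq_len(l), `==`) * 1)
    fit <- qr(A)
    sol <- qr.coef(fit, lx)
    sol[is.na(sol)] <- 0
    if (max(abs(A %*% sol - lx)) < 1e-8) cvec <- exp(sol[seq_len(d)])
  }
  ## Gauss-Newton polish (or full solve when the log-linear route fails)
  cvec <- cbe_newton(net, kappa, cx, ed,
                     x0 = if (is.null(cvec)) NULL else log(cvec))
  if (!is.null(cvec)) {
    res <- cbe_residuals(net, kappa, cvec)
    if (max(abs(res$rel)) < tol)
      return(structure(list(c = setNames(cvec, net$species),
                            residuals = res, status = "ok"),
                       class = "crn_equilibrium"))
  }
  structure(list(c = NULL, residuals = NULL, status = "no_cbe"),
            class = "crn_equilibrium")
}

## damped Gauss-Newton on log-concentrations, balance residuals as objective
cbe_newton <- function(net, kappa, cx, ed, iter = 200L, x0 = NULL) {
  d <- length(net$species)
  x <- if (is.null(x0)) numeric(d) else x0
  resid <- function(x) {
    cvec <- exp(x)
    flux <- vapply(seq_along(net$reactions), function(k)
      kappa[k] * prod(cvec ^ net$reactions[[k]]$source), 0)
    vapply(seq_len(nrow(cx)), function(z)
      sum(flux[ed[, "dst"] == z]) - sum(flux[ed[, "src"] == z]), 0)
  }
  jac <- function(x) {
    h <- 1e-6
    r0 <- resid(x)
    J <- matrix(0, length(r0), d)
    for (i in seq_len(d)) {
      xp <- x; xp[i] <- xp[i] + h
      J[, i] <- (resid(xp) - r0) / h
    }
    J
  }
  for (it in seq_len(iter)) {
    r0 <- resid(x)
    if (max(abs(r0)) < 1e-13 * max(1, exp(max(abs(x))))) break
    J <- jac(x)
    step <- tryCatch(qr.solve(crossprod(J) + diag(1e-12, d), -crossprod(J, r0)),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * as.numeric(step)
      if (sum(resid(xn)^2) < sum(r0^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6) break
    x <- x + lam * as.numeric(step)
  }
  exp(x)
}

#' @export
print.crn_equilibrium <- function(x, ...) {
  if (x$status == "ok") {
    cat("Complex balanced equilibrium:\n")
    for (i in seq_along(x$c))
      cat(sprintf("  c_%s = %.10g\n", names(x$c)[i], x$c[i]))
    cat(sprintf("  max |relative residual| = %.3g\n", max(abs(x$residuals$rel))))
  } else cat("No complex balanced equilibrium found (status: no_cbe)\n")
  invisible(x)
}
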