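## Structural indices of a reaction network: linkage classes, deficiency
## delta = |C| - l - s, weak reversibility, conservation laws. The rank s and
## the conservation basis are computed exactly over the rationals (integer
## fraction-free elimination), since the deficiency is an integer identity.

## Fraction-free Gaussian elimination on an integer matrix (stored in doubles;
## entries stay integral, rows reduced by their gcd to limit growth).
## Returns list(rank, echelon, pivot_cols).
int_echelon <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  gcd2 <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }
  gcd_row <- function(v) { g <- 0; for (x in abs(v)) g <- gcd2(g, x); g }
  nr <- nrow(M); nc <- ncol(M)
  piv_cols <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    p <- which(M[row:nr, col] != 0)
    if (!length(p)) next
    p <- p[1] + row - 1L
    if (p != row) M[c(row, p), ] <- M[c(p, row), ]
    for (j in seq_len(nr)) {
      if (j == row || M[j, col] == 0) next
      M[j, ] <- M[j, ] * M[row, col] - M[row, ] * M[j, col]
      g <- gcd_row(M[j, ])
      if (g > 1) M[j, ] <- M[j, ] / g
    }
    piv_cols <- c(piv_cols, col)
    row <- row + 1L
  }
  list(rank = length(piv_cols), echelon = M, pivot_cols = piv_cols)
}

## Rational right-null-space basis of an integer matrix, returned with integer
## entries (each basis vector scaled to clear denominators).
int_nullspace <- function(M) {
  nc <- ncol(M)
  if (nrow(M) == 0 || nc == 0) return(diag(1, nc))
  e <- int_echelon(M)
  piv <- e$pivot_cols
  free <- setdiff(seq_len(nc), piv)
  if (!length(free)) return(matrix(0, nc, 0))
  E <- e$echelon
  basis <- matrix(0, nc, length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    x <- numeric(nc); x[fc] <- 1
    for (i in rev(seq_along(piv))) {
      pc <- piv[i]
      x[pc] <- -sum(E[i, -pc] * x[-pc]) / E[i, pc]
    }
    ## clear denominators: find smallest q <= 10^6 with q*x integral
    for (q in 1:1000000) {
      if (max(abs(q * x - round(q * x))) < 1e-9) { x <- round(q * x); break }
    }
    g <- 0; for (v in abs(x)) { while (v != 0) { t <- v; v <- g %% v; g <- t } }
    if (g > 1) x <- x / g
    if (x[fc] < 0) x <- -x
    basis[, j] <- x
  }
  basis
}

complex_graph <- function(net) {
  cx <- complex_matrix(net)
  ed <- reaction_edges(net, cx)
  g <- igraph::make_empty_graph(n = nrow(cx), directed = TRUE)
  if (nrow(ed)) g <- igraph::add_edges(g, t(ed))
  list(graph = g, complexes = cx, edges = ed)
}

#' Linkage classes of a reaction network
#'
#' Connected components of the reaction graph with reactions taken as
#' undirected edges. Complexes not incident to any reaction do not exist in
#' this representation, so a network with no reactions has an empty partition.
#'
#' @param net a `crn`.
#' @return list of integer vectors, each indexing rows of the complex set.
#' @export
linkage_classes <- function(net) {
  if (!length(net$reactions)) return(list())
  cg <- complex_graph(net)
  comp <- igraph::components(cg$graph, mode = "weak")
  lapply(seq_len(comp$no), function(k) which(comp$membership == k))
}

#' Deficiency of a reaction network
#'
#' The non-negative integer `|C| - l - s`: number of complexes, minus number
#' of linkage classes, minus the rank (over the rationals) of the set of
#' stoichiometric vectors.
#'
#' @param net a `crn`.
#' @return non-negative integer.
#' @export
deficiency <- function(net) {
  if (!length(net$reactions)) return(0L)
  cx <- complex_matrix(net)
  l <- length(linkage_classes(net))
  s <- int_echelon(stoich_matrix(net))$rank
  as.integer(nrow(cx) - l - s)
}

#' Weak reversibility
#'
#' `TRUE` when every directed path between complexes has a directed return
#' path, i.e. every linkage class is strongly connected. Vacuously true for a
#' network with no reactions.
#'
#' @param net a `crn`.
#' @return logical.
#' @export
is_weakly_reversible <- function(net) {
  if (!length(net$reactions)) return(TRUE)
  cg <- complex_graph(net)
  weak <- igraph::components(cg$graph, mode = "weak")
  strong <- igraph::components(cg$graph, mode = "strong")
  weak$no == strong$no
}

#' Conservation laws
#'
#' Basis of the left null space of the stoichiometric matrix: vectors `w`
#' with `w . gamma_k = 0` for every reaction, so `w . n(t)` is constant along
#' every trajectory. Returned as a matrix with one integer basis vector per
#' row (empty when the stoichiometric vectors span the full species space).
#'
#' @param net a `crn`.
#' @return numeric matrix, rows = conservation vectors.
#' @export
conservation_laws <- function(net) {
  d <- length(net$species)
  S <- stoich_matrix(net)
  if (!nrow(S)) return(diag(1, d))
  t(int_nullspace(S))
}

#' Structure report
#'
#' Bundles the structural indices: number of complexes, linkage classes,
#' stoichiometric rank, deficiency, weak reversibility and the conservation
#' basis.
#'
#' @param net a `crn`.
#' @return an object of class `crn_structure`.
#' @export
structure_report <- function(net) {
  cx <- complex_matrix(net)
  lk <- linkage_classes(net)
  s <- if (length(net$reactions)) int_echelon(stoich_matrix(net))$rank else 0L
  structure(list(
    n_complexes = nrow(cx),
    linkage_classes = lk,
    stoich_dim = as.integer(s),
    deficiency = as.integer(nrow(cx) - length(lk) - s),
    weakly_reversible = is_weakly_reversible(net),
    conservation_basis = conservation_laws(net),
    complexes = cx, species = net$species), class = "crn_structure")
}

#' @export
print.crn_structure <- function(x, ...) {
  cat(sprintf("complexes: %d, linkage classes: %d, stoich. rank: %d\n",
              x$n_complexes, length(x$linkage_classes), x$stoich_dim))
  cat(sprintf("deficiency: %d, weakly reversible: %s\n",
              x$deficiency, x$weakly_reversible))
  if (nrow(x$conservation_basis))
    for (i in seq_len(nrow(x$conservation_basis)))
      cat("conserved: ", paste(sprintf("%g*%s", x$conservation_basis[i, ],
                                       x$species), collapse = " + "), "\n")
  invisible(x)
}
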