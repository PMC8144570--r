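#' @useDynLib crntrans, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp runif setNames var
#' @importFrom utils head tail
NULL

cx_key <- function(v) paste(v, collapse = ":")

cx_label <- function(v, species) {
  nz <- which(v != 0)
  if (!length(nz)) return("0")
  paste(vapply(nz, function(i) {
    if (v[i] == 1) species[i] else paste0(v[i], species[i])
  }, ""), collapse = " + ")
}

## Parse one side of a reaction ("0", "2A", "A + A_P") against a growing
## species table. Returns list(coef = named integer, species = updated table).
parse_complex <- function(txt, species, line = NA_integer_) {
  txt <- trimws(txt)
  if (txt == "0") return(list(coef = integer(0), species = species))
  if (grepl("^\\+|\\+\\s*\\+|\\+$", txt) || txt == "")
    stop(sprintf("line %s: empty term in complex '%s'", line, txt), call. = FALSE)
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  coef <- integer(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(m) == 0)
      stop(sprintf("line %s: cannot parse complex term '%s'", line, tm), call. = FALSE)
    k <- if (m[2] == "") 1L else as.integer(m[2])
    if (is.na(k) || k < 0)
      stop(sprintf("line %s: negative or invalid stoichiometric coefficient in '%s'", line, tm),
           call. = FALSE)
    sp <- m[3]
    if (!(sp %in% species)) species <- c(species, sp)
    coef[sp] <- if (sp %in% names(coef)) coef[[sp]] + k else k
  }
  list(coef = coef, species = species)
}

coef_to_vec <- function(coef, species) {
  v <- integer(length(species))
  names(v) <- species
  if (length(coef)) v[names(coef)] <- coef
  unname(v)
}

#' Parse a reaction network from `.crn` text
#'
#' The `.crn` format has one reaction per line, `SRC -> DST : KINETICS`.
#' Complexes are `0` or `+`-separated terms with optional integer multipliers
#' (`2A`, `A + A_P`). `KINETICS` is `mass_action(RATE)`,
#' `gma(RATE; fX=EXPR, ...)` or `expr(EXPR)`, where expressions are arithmetic
#' in `n_<species>` and named parameters. `SRC <-> DST : KIN1, KIN2` expands to
#' two reactions and `#` starts a comment. Species order is first-appearance
#' order and fixes the coordinates of all state vectors. Reactions that share
#' the same ordered (source, product) pair are merged by summing propensities,
#' so the reaction graph has simple directed edges.
#'
#' @param text character scalar (or vector of lines) with `.crn` content.
#' @param params named numeric vector binding symbolic rate parameters.
#' @return an object of class `crn` with fields `species` and `reactions`.
#' @export
parse_network <- function(text, params = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  species <- character(0)
  raw <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    ## split off kinetics
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: missing ': KINETICS' in '%s'", i, trimws(ln)), call. = FALSE)
    lhs <- trimws(parts[1])
    kin <- trimws(paste(parts[-1], collapse = ":"))
    rev2 <- grepl("<->", lhs, fixed = TRUE)
    arrow <- if (rev2) "<->" else "->"
    sides <- strsplit(lhs, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2)
      stop(sprintf("line %d: expected 'SRC %s DST' in '%s'", i, arrow, lhs), call. = FALSE)
    p1 <- parse_complex(sides[1], species, i); species <- p1$species
    p2 <- parse_complex(sides[2], species, i); species <- p2$species
    if (rev2) {
      kins <- trimws(strsplit(kin, ",", fixed = TRUE)[[1]])
      if (length(kins) != 2)
        stop(sprintf("line %d: '<->' needs two comma-separated kinetics", i), call. = FALSE)
      raw[[length(raw) + 1L]] <- list(src = p1$coef, dst = p2$coef, kin = kins[1], line = i)
      raw[[length(raw) + 1L]] <- list(src = p2$coef, dst = p1$coef, kin = kins[2], line = i)
    } else {
      raw[[length(raw) + 1L]] <- list(src = p1$coef, dst = p2$coef, kin = kin, line = i)
    }
  }
  reactions <- list()
  seen <- character(0)
  for (r in raw) {
    src <- coef_to_vec(r$src, species)
    dst <- coef_to_vec(r$dst, species)
    if (all(src == dst))
      stop(sprintf("line %d: reaction with identical source and product", r$line), call. = FALSE)
    prop <- parse_kinetics(r$kin, r$src, species, params, r$line)
    key <- paste(cx_key(src), cx_key(dst), sep = ">")
    j <- match(key, seen)
    if (is.na(j)) {
      seen <- c(seen, key)
      reactions[[length(reactions) + 1L]] <-
        list(source = src, product = dst, propensity = prop,
             label = paste(cx_label(src, species), "->", cx_label(dst, species)))
    } else {
      reactions[[j]]$propensity <- prop_sum(reactions[[j]]$propensity, prop)
    }
  }
  new_crn(species, reactions, params)
}

new_crn <- function(species, reactions, params = NULL) {
  structure(list(species = species, reactions = reactions, params = params),
            class = "crn")
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("Reaction network: %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              length(x$reactions)))
  for (rx in x$reactions) {
    cat(sprintf("  %-24s : %s\n",
                paste(cx_label(rx$source, x$species), "->",
                      cx_label(rx$product, x$species)),
                prop_describe(rx$propensity, x$species)))
  }
  invisible(x)
}

## stoichiometric vectors as r x d integer matrix
stoich_matrix <- function(net) {
  d <- length(net$species)
  if (!length(net$reactions)) return(matrix(0L, 0, d))
  m <- vapply(net$reactions, function(rx) rx$product - rx$source, integer(d))
  t(matrix(m, nrow = d))
}

## unique complexes (rows), in order of first appearance as source then product
complex_matrix <- function(net) {
  d <- length(net$species)
  if (!length(net$reactions)) return(matrix(0L, 0, d))
  m <- do.call(rbind, lapply(net$reactions, function(rx) rbind(rx$source, rx$product)))
  m[!duplicated(apply(m, 1, cx_key)), , drop = FALSE]
}

## per-reaction complex indices into complex_matrix rows
reaction_edges <- function(net, cx = complex_matrix(net)) {
  keys <- apply(cx, 1, cx_key)
  src <- vapply(net$reactions, function(rx) match(cx_key(rx$source), keys), 1L)
  dst <- vapply(net$reactions, function(rx) match(cx_key(rx$product), keys), 1L)
  cbind(src = src, dst = dst)
}

#' Serialize a network back to `.crn` text
#' @param net a `crn` object.
#' @return character vector of `.crn` lines.
#' @export
format_crn <- function(net) {
  vapply(net$reactions, function(rx) {
    sprintf("%s -> %s : %s", cx_label(rx$source, net$species),
            cx_label(rx$product, net$species),
            prop_serialize(rx$propensity, net$species))
  }, "")
}
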