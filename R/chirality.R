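# Enantiomeric structure: the L/D involution, pseudochirality, dual
# reactions, rate-label classes, and the racemic condition.

#' Verify pseudochirality and extract the chiral structure
#'
#' A network is pseudochiral when it is indistinguishable from its mirror
#' image: swapping every L-species with its D-partner maps each reaction
#' onto a *dual* reaction that is present in the network and carries a rate
#' constant from the same equal-value class.  Reactions invariant under the
#' swap (e.g. `L + D -> P`) are their own duals.
#'
#' Rate-label classes are generated by `dual` declarations together with
#' literal label sharing; the class representative is the lexicographically
#' smallest label.  The check fails, naming the offending reaction, if some
#' reaction's mirror image is absent or if a dual pair's labels fall in
#' different classes.
#'
#' @param net a `reaction_network`.
#' @param pairs optional list of `c(L, D)` character pairs; defaults to the
#'   `pair` declarations carried by the network.
#' @return an object of class `chiral_structure` with fields `pairs`
#'   (dynamic pairs first), `order` (number of dynamic enantiomeric pairs),
#'   `achiral`, `involution` (named character map on species), `dual_map`
#'   (involutive permutation of reaction indices) and `label_classes`
#'   (named character map label -> class representative).
#' @export
check_pseudochiral <- function(net, pairs = NULL) {
  if (is.null(pairs)) pairs <- net$pairs
  if (length(pairs) == 0L) stop("no enantiomeric pairs declared")
  pnames <- unlist(pairs)
  miss <- setdiff(pnames, net$species)
  if (length(miss)) stop("paired species not in network: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pnames)) stop("pairs are not disjoint")

  dyn <- dynamic_species(net)
  is_dyn <- vapply(pairs, function(p) all(p %in% dyn), TRUE)
  pairs <- c(pairs[is_dyn], pairs[!is_dyn])   # dynamic pairs lead
  k <- sum(is_dyn)
  if (k == 0L) stop("all enantiomeric pairs are constant species")

  inv <- structure(net$species, names = net$species)
  for (p in pairs) {
    inv[p[1L]] <- p[2L]
    inv[p[2L]] <- p[1L]
  }

  mirror_side <- function(co) {
    if (length(co) == 0L) return(co)
    nm <- unname(inv[names(co)])
    out <- as.integer(co)
    names(out) <- nm
    out[order(names(out))]
  }
  side_key <- function(co) {
    if (length(co) == 0L) return("")
    co <- co[order(names(co))]
    paste(names(co), co, sep = ":", collapse = ",")
  }
  rx_key <- function(re, pr) paste(side_key(re), side_key(pr), sep = ">")

  r <- n_reactions(net)
  keys <- vapply(net$reactions, function(rx) rx_key(rx$reactants, rx$products), "")

  # rate-label classes: same literal label, plus `dual` declarations
  labels <- rate_labels(net)
  reps <- structure(sort(unique(labels)), names = sort(unique(labels)))
  find_rep <- function(l) {
    while (reps[[l]] != l) l <- reps[[l]]
    l
  }
  union_lab <- function(a, b) {
    ra <- find_rep(a); rb <- find_rep(b)
    if (ra != rb) {
      lo <- min(ra, rb); hi <- max(ra, rb)
      reps[[hi]] <<- lo
    }
  }
  for (dl in net$dual_labels) {
    if (!all(dl %in% labels))
      stop("dual declaration names unknown rate label: ",
           paste(dl, collapse = "~"))
    union_lab(dl[1L], dl[2L])
  }

  dual_map <- integer(r)
  for (i in seq_len(r)) {
    rx <- net$reactions[[i]]
    mk <- rx_key(mirror_side(rx$reactants), mirror_side(rx$products))
    cand <- which(keys == mk)
    if (length(cand) == 0L)
      stop("not pseudochiral: reaction R", i, " (",
           format_reaction(rx), ") has no mirror-image reaction")
    # prefer a partner whose label is already in the same class, else first
    j <- cand[1L]
    if (length(cand) > 1L) {
      same <- cand[vapply(cand, function(c2)
        find_rep(labels[c2]) == find_rep(labels[i]), TRUE)]
      if (length(same)) j <- same[1L]
    }
    dual_map[i] <- j
    if (find_rep(labels[i]) != find_rep(labels[j]))
      stop("not pseudochiral: reactions R", i, " and R", j,
           " are duals but their rate labels (", labels[i], ", ",
           labels[j], ") are not declared equal")
  }
  if (!all(dual_map[dual_map] == seq_len(r)))
    stop("dual map is not an involution; ambiguous duplicate reactions?")

  label_classes <- vapply(structure(names(reps), names = names(reps)),
                          find_rep, "")

  structure(list(
    pairs = pairs,
    order = k,
    achiral = setdiff(net$species, unlist(pairs)),
    involution = inv,
    dual_map = dual_map,
    label_classes = label_classes
  ), class = "chiral_structure")
}

#' @export
print.chiral_structure <- function(x, ...) {
  cat("Pseudochiral structure of order", x$order, "\n  pairs:",
      paste(vapply(x$pairs, paste, "", collapse = ":"), collapse = ", "), "\n")
  shown <- rep(FALSE, length(x$dual_map))
  cat("  dual reactions:")
  for (i in seq_along(x$dual_map)) {
    if (shown[i]) next
    j <- x$dual_map[i]
    shown[c(i, j)] <- TRUE
    cat(if (i == j) sprintf(" R%d~R%d(self)", i, j) else sprintf(" R%d~R%d", i, j))
  }
  cat("\n")
  invisible(x)
}

#' Reorder species into the canonical chiral order
#'
#' The canonical order puts the dynamic L-species first (in pair order),
#' then their D-partners, then the dynamic achiral species, then all
#' constant species.  Block extraction of the racemic Jacobian (the A and B
#' blocks) assumes this order.  Reaction order is untouched.
#'
#' @param net a `reaction_network`.
#' @param chiral a `chiral_structure` for `net`.
#' @return the reordered `reaction_network`.
#' @export
canonical_species_order <- function(net, chiral) {
  dyn <- dynamic_species(net)
  dpairs <- chiral$pairs[seq_len(chiral$order)]
  ls <- vapply(dpairs, `[[`, "", 1L)
  ds <- vapply(dpairs, `[[`, "", 2L)
  rest <- setdiff(dyn, c(ls, ds))
  cons <- intersect(net$species, net$constant_species)
  net$species <- c(ls, ds, rest, cons)
  net
}

is_canonical_order <- function(net, chiral) {
  dpairs <- chiral$pairs[seq_len(chiral$order)]
  k <- chiral$order
  identical(dynamic_species(net)[seq_len(2L * k)],
            c(vapply(dpairs, `[[`, "", 1L), vapply(dpairs, `[[`, "", 2L)))
}

#' Enantiomeric gap of a state
#'
#' `sum_i |L_i - D_i|` over the enantiomeric pairs; zero exactly when the
#' state is racemic (`L_i = D_i` for every pair).
#'
#' @param state a `network_state` (or anything with a named
#'   `concentrations` vector).
#' @param chiral a `chiral_structure`.
#' @return nonnegative number.
#' @export
enantiomeric_gap <- function(state, chiral) {
  x <- state$concentrations
  sum(vapply(chiral$pairs, function(p) abs(x[[p[1L]]] - x[[p[2L]]]), 0))
}

#' Racemic substitution map
#'
#' The variable renaming that imposes the racemic condition symbolically:
#' every D-concentration symbol is sent to its L-partner and every rate
#' label to its equal-value class representative.
#'
#' @param net a `reaction_network`.
#' @param chiral a `chiral_structure`.
#' @return named list mapping symbol -> symbol (identity entries omitted).
#' @export
racemic_substitution <- function(net, chiral) {
  map <- list()
  for (p in chiral$pairs) map[[p[2L]]] <- p[1L]
  for (lab in names(chiral$label_classes)) {
    rep <- chiral$label_classes[[lab]]
    if (rep != lab) map[[lab]] <- rep
  }
  map
}

# Is the state racemic, steady, with equal dual rate constants?
is_racemic_steady <- function(net, chiral, state, tol = 1e-8) {
  scale <- max(1, max(abs(velocity(net, state))))
  if (enantiomeric_gap(state, chiral) > tol * max(1, max(state$concentrations)))
    return(FALSE)
  k <- state$rate_constants
  for (lab in names(chiral$label_classes)) {
    rep <- chiral$label_classes[[lab]]
    if (lab %in% names(k) && rep %in% names(k) &&
        abs(k[[lab]] - k[[rep]]) > tol * max(1, abs(k[[rep]])))
      return(FALSE)
  }
  max(abs(ode_rhs(net, state))) <= tol * scale
}

#' Apply the L/D involution to a state
#'
#' Swaps the concentrations of every enantiomeric pair; rate constants are
#' untouched.
#'
#' @inheritParams enantiomeric_gap
#' @return a `network_state`.
#' @export
mirror_state <- function(state, chiral) {
  x <- state$concentrations
  for (p in chiral$pairs) {
    tmp <- x[[p[1L]]]
    x[[p[1L]]] <- x[[p[2L]]]
    x[[p[2L]]] <- tmp
  }
  network_state(x, state$rate_constants)
}
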