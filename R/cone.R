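# Clarke's stoichiometric network analysis: the steady-state flux cone,
# exact extreme-current enumeration, convex coordinates and the
# factorization J = S.E.R.Delta.

vec_gcd <- function(v) {
  g <- 0
  for (x in abs(v)) {
    while (x != 0) {
      t <- g %% x
      g <- x
      x <- t
    }
  }
  g
}

normalize_ray <- function(v) {
  g <- vec_gcd(v)
  if (g > 0) v / g else v
}

#' Dual-pair-extended stoichiometric matrix
#'
#' Appends to the stoichiometric matrix one row `e_p - e_q` per pair of
#' reactions that must carry equal steady-state currents because their rate
#' constants are equal.  Reactions are grouped by rate-label class (dual
#' declarations plus literal label sharing); a class of m >= 2 reactions
#' contributes m - 1 chained difference rows.  At the unit-concentration
#' states the sampler back-maps to, equal currents are exactly equal rate
#' constants, so these rows force the racemic rate condition into the cone
#' and prune its extreme currents substantially.
#'
#' Two modes: `"all"` (default) appends rows for every such class;
#' `"paper"` additionally drops dual pairs whose two reactions directly
#' interconvert the enantiomers (each reaction being the mirror-reverse of
#' the other, e.g. racemization `L -> D` / `D -> L`), matching the
#' published treatment of the Calvin model.
#'
#' @param net a `reaction_network`.
#' @param chiral a `chiral_structure` for `net` (may be `NULL` for an
#'   achiral network, in which case `S` is returned unchanged).
#' @param mode `"all"` or `"paper"`.
#' @return integer matrix with `r` columns; the appended rows carry
#'   `"Rp&Rq"` row names.
#' @export
extended_stoichiometric_matrix <- function(net, chiral = NULL,
                                           mode = c("all", "paper")) {
  mode <- match.arg(mode)
  S <- stoichiometric_matrix(net)
  if (is.null(chiral)) return(S)
  r <- n_reactions(net)
  labels <- rate_labels(net)
  cls <- chiral$label_classes[labels]

  is_interconverting_pair <- function(p, q) {
    if (chiral$dual_map[p] != q) return(FALSE)
    rp <- net$reactions[[p]]
    rq <- net$reactions[[q]]
    side_key <- function(co) {
      if (length(co) == 0L) return("")
      co <- co[order(names(co))]
      paste(names(co), co, sep = ":", collapse = ",")
    }
    side_key(rp$reactants) == side_key(rq$products) &&
      side_key(rp$products) == side_key(rq$reactants)
  }

  rows <- list()
  rnames <- character(0)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    if (length(idx) < 2L) next
    if (mode == "paper" && length(idx) == 2L &&
        is_interconverting_pair(idx[1L], idx[2L])) next
    for (t in seq_len(length(idx) - 1L)) {
      row <- integer(r)
      row[idx[t]] <- 1L
      row[idx[t + 1L]] <- -1L
      rows[[length(rows) + 1L]] <- row
      rnames <- c(rnames, paste0("R", idx[t], "&R", idx[t + 1L]))
    }
  }
  if (length(rows) == 0L) return(S)
  ext <- do.call(rbind, rows)
  rownames(ext) <- rnames
  colnames(ext) <- colnames(S)
  rbind(S, ext)
}

#' Extreme currents of the steady-state cone
#'
#' Enumerates the extreme rays of the polyhedral cone
#' `{v in R^r : v >= 0, M v = 0}` by the double-description method in exact
#' integer arithmetic: starting from the coordinate rays of the orthant,
#' each equality row is intersected in turn, combining positive- and
#' negative-side rays and keeping only support-minimal vectors (for cones
#' of this form, extreme rays are exactly the nonzero solutions of minimal
#' support, unique up to scale).  Rays are integer-normalized (gcd 1) and
#' sorted lexicographically.
#'
#' @param M integer matrix with `r` columns (typically the plain or
#'   extended stoichiometric matrix).
#' @param r number of reactions; defaults to `ncol(M)`.
#' @return object of class `current_cone`: list with `matrix_used`,
#'   `currents` (list of integer vectors), and `s` (the count; 0 when the
#'   cone is `{0}`).
#' @export
extreme_currents <- function(M, r = ncol(M)) {
  stopifnot(ncol(M) == r)
  rays <- diag(r)   # rows = rays
  for (ri in seq_len(nrow(M))) {
    a <- M[ri, ]
    d <- drop(rays %*% a)
    keep <- rays[d == 0, , drop = FALSE]
    pos <- which(d > 0)
    neg <- which(d < 0)
    newr <- list()
    for (p in pos) for (q in neg) {
      cand <- d[p] * rays[q, ] - d[q] * rays[p, ]
      newr[[length(newr) + 1L]] <- normalize_ray(cand)
    }
    if (length(newr)) {
      cand <- rbind(keep, do.call(rbind, newr))
    } else {
      cand <- keep
    }
    if (nrow(cand) == 0L) {
      rays <- cand
      break
    }
    cand <- unique(cand)
    # support-minimality filter: extreme rays of {v >= 0, M'v = 0} are
    # exactly the support-minimal nonzero solutions, unique up to scale
    supp <- cand > 0
    ord <- order(rowSums(supp))
    cand <- cand[ord, , drop = FALSE]
    supp <- supp[ord, , drop = FALSE]
    keepi <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keepi[i]) next
      for (j in seq_len(nrow(cand))) {
        if (i == j || !keepi[j]) next
        if (all(supp[j, ] | !supp[i, ])) {        # supp(i) subseteq supp(j)
          if (!all(supp[i, ] == supp[j, ]) || j > i)
            keepi[j] <- FALSE
        }
      }
    }
    rays <- cand[keepi, , drop = FALSE]
  }
  if (nrow(rays) > 0L) {
    ord <- do.call(order, as.data.frame(rays))
    rays <- rays[ord, , drop = FALSE]
  }
  currents <- lapply(seq_len(nrow(rays)), function(i) {
    v <- rays[i, ]
    names(v) <- colnames(M)
    v
  })
  # exact verification
  for (v in currents) {
    if (any(v < 0) || any(M %*% v != 0))
      stop("internal error: enumerated ray violates the cone constraints")
  }
  structure(list(matrix_used = M, currents = currents,
                 s = length(currents)), class = "current_cone")
}

#' @export
print.current_cone <- function(x, ...) {
  cat("current_cone with", x$s, "extreme currents over",
      ncol(x$matrix_used), "reactions\n")
  for (i in seq_along(x$currents))
    cat("  v", i, ": (", paste(x$currents[[i]], collapse = ", "), ")\n",
        sep = "")
  invisible(x)
}

#' Export the extreme currents as a reactions x currents table
#' @param cone a `current_cone`.
#' @param path optional TSV path.
#' @return integer matrix (invisibly when written to file).
#' @export
currents_matrix <- function(cone, path = NULL) {
  if (cone$s == 0L) {
    M <- matrix(0L, ncol(cone$matrix_used), 0L)
  } else {
    M <- do.call(cbind, cone$currents)
    colnames(M) <- paste0("v", seq_len(cone$s))
  }
  rownames(M) <- colnames(cone$matrix_used)
  if (!is.null(path)) {
    utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
    return(invisible(M))
  }
  M
}

#' Diagonal E matrix of Clarke's factorization
#'
#' `E[i, i] = sum_l v_l[i] * j_l`: each diagonal entry is the current
#' through reaction i, a linear form in the convex coordinates.
#'
#' @param cone a `current_cone`.
#' @param j either a numeric vector of convex coordinates (length `s`) or
#'   a character vector of symbol names; defaults to symbols
#'   `j1, ..., js`.
#' @return numeric diagonal matrix, or a symbolic (list) matrix when `j`
#'   is symbolic.
#' @export
e_matrix <- function(cone, j = paste0("j", seq_len(cone$s))) {
  r <- ncol(cone$matrix_used)
  if (length(j) != cone$s) stop("j must have length s = ", cone$s)
  if (is.numeric(j)) {
    w <- composite_current(cone, j)
    return(diag(w, nrow = r))
  }
  E <- matrix(vector("list", r * r), r, r)
  for (a in seq_len(r)) for (b in seq_len(r)) E[[a, b]] <- cp_zero()
  for (a in seq_len(r)) {
    E[[a, a]] <- cp_sum(lapply(seq_len(cone$s), function(l) {
      co <- cone$currents[[l]][a]
      if (co == 0) cp_zero() else cp_var(j[l], coef = co)
    }))
  }
  E
}

#' Composite current of convex coordinates
#' @param cone a `current_cone`.
#' @param j nonnegative numeric vector of length `s`.
#' @return the combination `sum_l j_l v_l`, a length-`r` vector.
#' @export
composite_current <- function(cone, j) {
  stopifnot(length(j) == cone$s)
  if (any(j < 0)) stop("convex coordinates must be nonnegative")
  w <- numeric(ncol(cone$matrix_used))
  for (l in seq_len(cone$s)) w <- w + j[l] * cone$currents[[l]]
  names(w) <- colnames(cone$matrix_used)
  w
}

#' The SNA stability matrix V = S.E(j).R
#'
#' Clarke's reduced stability matrix in convex coordinates: the plain
#' stoichiometric matrix times the diagonal current matrix times the
#' kinetic-order matrix.  Its entries are linear polynomials in
#' `j1, ..., js`; at a steady state with all concentrations equal to 1 it
#' coincides with the true Jacobian (the scaling matrix Delta is then the
#' identity).
#'
#' @param net a `reaction_network`.
#' @param cone a `current_cone` computed for `net` (possibly from the
#'   extended matrix; only its currents are used here).
#' @return symbolic matrix, dynamic species x dynamic species.
#' @export
sna_matrix <- function(net, cone) {
  S <- smat_from_numeric(stoichiometric_matrix(net))
  R <- smat_from_numeric(kinetic_order_matrix(net))
  E <- e_matrix(cone)
  V <- smat_mul(smat_mul(S, E), R)
  dimnames(V) <- list(dynamic_species(net), dynamic_species(net))
  V
}

#' Convex coordinates of a steady-state velocity
#'
#' Solves `velocity = sum_l j_l v_l` for `j >= 0`.  When the extreme
#' currents are linearly independent the solution is unique and found by
#' exact linear solving; otherwise a minimum-norm nonnegative solution is
#' returned and flagged as non-unique.
#'
#' @param cone a `current_cone`.
#' @param state_velocity numeric vector of length `r` (see [velocity()]).
#' @param tol relative residual tolerance; a larger residual means the
#'   velocity is not in the cone (the state is not steady) and is an error.
#' @return nonnegative numeric vector `j` with attributes `residual` and
#'   `unique`.
#' @export
convex_coordinates <- function(cone, state_velocity, tol = 1e-8) {
  if (cone$s == 0L) stop("cone is trivial; no positive steady-state currents")
  V <- do.call(cbind, cone$currents)
  indep <- qr(V)$rank == ncol(V)
  if (indep) {
    j <- qr.solve(V, as.numeric(state_velocity))
  } else {
    j <- pracma::lsqnonneg(V, as.numeric(state_velocity))$x
  }
  resid <- sqrt(sum((V %*% j - state_velocity)^2))
  nv <- sqrt(sum(state_velocity^2))
  if (resid > tol * max(1, nv))
    stop("velocity is not in the current cone (residual ",
         format(resid), "); state is not steady")
  if (any(j < -tol)) stop("negative convex coordinate; state not in cone")
  j <- pmax(j, 0)
  structure(j, residual = resid, unique = indep)
}

#' Verify Clarke's factorization J = S.E.R.Delta at a state
#'
#' Evaluates both sides at a positive steady state, with
#' `Delta = diag(1/X_1, ..., 1/X_n)` over the dynamic species and `E`
#' built from the convex coordinates of the state's velocity.
#'
#' @param net a `reaction_network`.
#' @param state a positive steady `network_state`; a zero dynamic
#'   concentration is an error (Delta undefined).
#' @param cone optional `current_cone`; computed from the plain
#'   stoichiometric matrix when missing.
#' @param tol relative tolerance on the maximum entry discrepancy.
#' @return logical, with attribute `discrepancy`.
#' @export
verify_clarke_factorization <- function(net, state, cone = NULL, tol = 1e-8) {
  dyn <- dynamic_species(net)
  x <- state$concentrations[dyn]
  if (any(x == 0)) stop("zero concentration: scaling matrix Delta undefined")
  if (is.null(cone)) cone <- extreme_currents(stoichiometric_matrix(net))
  vel <- velocity(net, state)
  j <- convex_coordinates(cone, vel)
  S <- stoichiometric_matrix(net)
  R <- kinetic_order_matrix(net)
  E <- diag(composite_current(cone, as.numeric(j)), nrow = n_reactions(net))
  Delta <- diag(1 / x, nrow = length(dyn))
  lhs <- jacobian_numeric(net, state)
  rhs <- S %*% E %*% R %*% Delta
  disc <- max(abs(lhs - rhs))
  structure(disc <= tol * max(1, max(abs(lhs))), discrepancy = disc)
}
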