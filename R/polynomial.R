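# Sparse multivariate polynomials with exact integer-valued coefficients.
#
# All symbolic objects in the package (Jacobian entries, the stability matrix
# in convex coordinates, characteristic-polynomial coefficients) are built
# from integer stoichiometry, so their coefficients stay integers throughout;
# storing them in doubles is exact as long as |coef| < 2^53, far beyond any
# network treated here.
#
# Representation: a named numeric vector of class "cpoly".  Names are
# canonical monomial keys: "1" for the constant term (an empty name would
# defeat R's name-based indexing), otherwise variable names sorted
# lexicographically, powers > 1 written "x^2", factors joined by "*"
# (e.g. "k0*L1^2").  Zero coefficients are always dropped.  Variable names
# are identifiers, so the key "1" is unambiguous.

cp_canon <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0L) return(structure(numeric(0), names = character(0), class = "cpoly"))
  x <- x[order(names(x))]
  class(x) <- "cpoly"
  x
}

cp_zero <- function() cp_canon(numeric(0))

cp_const <- function(c) {
  v <- as.numeric(c)
  names(v) <- "1"
  cp_canon(v)
}

cp_var <- function(name, pow = 1L, coef = 1) {
  stopifnot(nchar(name) > 0, pow >= 1)
  key <- if (pow == 1L) name else paste0(name, "^", pow)
  v <- as.numeric(coef)
  names(v) <- key
  cp_canon(v)
}

as_cpoly <- function(x) {
  if (inherits(x, "cpoly")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(cp_const(x))
  stop("cannot coerce to cpoly")
}

# key <-> named integer exponent vector
mono_parse <- function(key) {
  if (key == "1") return(structure(integer(0), names = character(0)))
  parts <- strsplit(key, "*", fixed = TRUE)[[1L]]
  hasp <- grepl("^", parts, fixed = TRUE)
  vars <- parts
  pows <- rep(1L, length(parts))
  if (any(hasp)) {
    sp <- strsplit(parts[hasp], "^", fixed = TRUE)
    vars[hasp] <- vapply(sp, `[[`, "", 1L)
    pows[hasp] <- as.integer(vapply(sp, `[[`, "", 2L))
  }
  structure(pows, names = vars)
}

mono_key <- function(expv) {
  expv <- expv[expv != 0L]
  if (length(expv) == 0L) return("1")
  expv <- expv[order(names(expv))]
  paste(ifelse(expv == 1L, names(expv), paste0(names(expv), "^", expv)),
        collapse = "*")
}

mono_mul <- function(k1, k2) {
  if (k1 == "1") return(k2)
  if (k2 == "1") return(k1)
  e1 <- mono_parse(k1); e2 <- mono_parse(k2)
  all <- union(names(e1), names(e2))
  e <- structure(integer(length(all)), names = all)
  e[names(e1)] <- e1
  e[names(e2)] <- e[names(e2)] + e2
  mono_key(e)
}

cp_add <- function(p, q) {
  p <- as_cpoly(p); q <- as_cpoly(q)
  keys <- union(names(p), names(q))
  v <- structure(numeric(length(keys)), names = keys)
  v[names(p)] <- p
  v[names(q)] <- v[names(q)] + q
  cp_canon(v)
}

cp_neg <- function(p) cp_canon(-as_cpoly(p))

cp_sub <- function(p, q) cp_add(p, cp_neg(q))

cp_scal <- function(p, a) cp_canon(as_cpoly(p) * a)

cp_mul <- function(p, q) {
  p <- as_cpoly(p); q <- as_cpoly(q)
  if (length(p) == 0L || length(q) == 0L) return(cp_zero())
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(p)) {
    for (j in seq_along(q)) {
      k <- mono_mul(names(p)[i], names(q)[j])
      prev <- if (is.null(acc[[paste0("m", k)]])) 0 else acc[[paste0("m", k)]]
      acc[[paste0("m", k)]] <- prev + p[[i]] * q[[j]]
    }
  }
  keys <- ls(acc)
  v <- vapply(keys, function(k) acc[[k]], numeric(1))
  names(v) <- substring(keys, 2L)
  cp_canon(v)
}

cp_sum <- function(lst) Reduce(cp_add, lst, cp_zero())

cp_is_zero <- function(p) length(as_cpoly(p)) == 0L

cp_equal <- function(p, q) cp_is_zero(cp_sub(p, q))

cp_vars <- function(p) {
  p <- as_cpoly(p)
  if (length(p) == 0L) return(character(0))
  sort(unique(unlist(lapply(names(p), function(k) names(mono_parse(k))))))
}

cp_degree <- function(p) {
  p <- as_cpoly(p)
  if (length(p) == 0L) return(-Inf)
  max(vapply(names(p), function(k) sum(mono_parse(k)), numeric(1)))
}

# Evaluate at a named numeric point (every variable of p must be supplied).
cp_eval <- function(p, values) {
  p <- as_cpoly(p)
  if (length(p) == 0L) return(0)
  miss <- setdiff(cp_vars(p), names(values))
  if (length(miss) > 0)
    stop("missing values for: ", paste(miss, collapse = ", "))
  s <- 0
  for (i in seq_along(p)) {
    e <- mono_parse(names(p)[i])
    s <- s + p[[i]] * prod(values[names(e)]^e)
  }
  s
}

# Evaluate at many points at once.  X is an N x m matrix whose colnames
# cover the variables of p; returns a length-N vector.
cp_eval_rows <- function(p, X) {
  p <- as_cpoly(p)
  n <- nrow(X)
  if (length(p) == 0L) return(numeric(n))
  miss <- setdiff(cp_vars(p), colnames(X))
  if (length(miss) > 0)
    stop("missing columns for: ", paste(miss, collapse = ", "))
  out <- numeric(n)
  for (i in seq_along(p)) {
    e <- mono_parse(names(p)[i])
    term <- rep(p[[i]], n)
    for (v in names(e)) term <- term * X[, v]^e[[v]]
    out <- out + term
  }
  out
}

# Rename variables (used for the racemic substitution D_i -> L_i and the
# collapse of dual rate labels onto their class representative).  Renaming
# may merge formerly distinct variables, e.g. L1*D1 -> L1^2.
cp_subst <- function(p, map) {
  p <- as_cpoly(p)
  if (length(p) == 0L || length(map) == 0L) return(p)
  keys <- vapply(names(p), function(k) {
    e <- mono_parse(k)
    if (length(e) == 0L) return(k)
    vars <- names(e)
    hit <- vars %in% names(map)
    if (!any(hit)) return(k)
    vars[hit] <- unlist(map[vars[hit]])
    agg <- tapply(e, vars, sum)
    mono_key(structure(as.integer(agg), names = names(agg)))
  }, "")
  v <- as.numeric(tapply(as.numeric(p), keys, sum))
  names(v) <- names(tapply(as.numeric(p), keys, sum))
  cp_canon(v)
}

#' @export
format.cpoly <- function(x, ...) {
  if (length(x) == 0L) return("0")
  deg <- vapply(names(x), function(k) sum(mono_parse(k)), numeric(1))
  ord <- order(-deg, names(x))
  terms <- character(length(x))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    co <- x[[i]]; key <- names(x)[i]
    mag <- if (key == "1") as.character(abs(co))
           else if (abs(co) == 1) key
           else paste0(abs(co), "*", key)
    terms[ii] <- if (ii == 1L) {
      if (co < 0) paste0("-", mag) else mag
    } else {
      paste(if (co < 0) "-" else "+", mag)
    }
  }
  paste(terms, collapse = " ")
}

#' @export
print.cpoly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- matrices of polynomials -------------------------------------------
# A "symbolic matrix" is a plain R matrix with list storage whose cells are
# cpoly objects (numeric scalars are accepted and coerced on the fly).

smat <- function(cells, nrow, ncol, dimnames = NULL) {
  m <- matrix(cells, nrow = nrow, ncol = ncol, dimnames = dimnames)
  m
}

smat_from_numeric <- function(M) {
  out <- matrix(vector("list", length(M)), nrow(M), ncol(M), dimnames = dimnames(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    out[[i, j]] <- cp_const(M[i, j])
  out
}

smat_entry <- function(M, i, j) as_cpoly(M[[i, j]])

smat_mul <- function(A, B) {
  stopifnot(ncol(A) == nrow(B))
  out <- matrix(vector("list", nrow(A) * ncol(B)), nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      out[[i, j]] <- cp_sum(lapply(seq_len(ncol(A)), function(l)
        cp_mul(smat_entry(A, i, l), smat_entry(B, l, j))))
    }
  }
  rownames(out) <- rownames(A)
  colnames(out) <- colnames(B)
  out
}

smat_sub <- function(A, B) {
  stopifnot(dim(A) == dim(B))
  out <- A
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    out[[i, j]] <- cp_sub(smat_entry(A, i, j), smat_entry(B, i, j))
  out
}

smat_subst <- function(A, map) {
  out <- A
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    out[[i, j]] <- cp_subst(smat_entry(A, i, j), map)
  out
}

smat_eval <- function(A, values) {
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    out[i, j] <- cp_eval(smat_entry(A, i, j), values)
  out
}

smat_equal <- function(A, B) {
  if (!all(dim(A) == dim(B))) return(FALSE)
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (!cp_equal(smat_entry(A, i, j), smat_entry(B, i, j))) return(FALSE)
  TRUE
}

# Symbolic determinant by Laplace expansion along the first row.  Intended
# for the small (k <= 5) enantiomeric blocks; cost is k!.
smat_det <- function(A) {
  n <- nrow(A)
  stopifnot(n == ncol(A))
  if (n == 1L) return(smat_entry(A, 1L, 1L))
  if (n == 2L) {
    return(cp_sub(cp_mul(smat_entry(A, 1, 1), smat_entry(A, 2, 2)),
                  cp_mul(smat_entry(A, 1, 2), smat_entry(A, 2, 1))))
  }
  acc <- cp_zero()
  for (j in seq_len(n)) {
    a <- smat_entry(A, 1L, j)
    if (cp_is_zero(a)) next
    minor <- A[-1L, -j, drop = FALSE]
    term <- cp_mul(a, smat_det(minor))
    acc <- if (j %% 2L == 1L) cp_add(acc, term) else cp_sub(acc, term)
  }
  acc
}

smat_format <- function(A) {
  apply(A, c(1, 2), function(cell) format(as_cpoly(cell[[1L]])))
}
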