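# Independent oracles and small builders shared across the test files.
# Everything here is deliberately written as plainly as possible and stays
# independent of the code paths it cross-checks.

# --- tiny polynomial expression parser (builds chiralnet's cpoly) --------
# Accepts sums of terms like "-9*k1*I^2 + 2*A*I*k2 - A*k3"; whitespace free
# or not.  Only used to state expected symbolic values readably.
P <- function(expr) {
  s <- gsub("\\s+", "", expr)
  if (s == "0") return(chiralnet:::cp_zero())
  s <- gsub("-", "+-", s, fixed = TRUE)
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  acc <- chiralnet:::cp_zero()
  for (tm in terms) {
    neg <- startsWith(tm, "-")
    if (neg) tm <- substring(tm, 2)
    factors <- strsplit(tm, "*", fixed = TRUE)[[1]]
    p <- chiralnet:::cp_const(if (neg) -1 else 1)
    for (f in factors) {
      if (grepl("^[0-9.]+$", f)) {
        p <- chiralnet:::cp_scal(p, as.numeric(f))
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*(\\^[0-9]+)?$", f)) {
        parts <- strsplit(f, "^", fixed = TRUE)[[1]]
        pow <- if (length(parts) == 2) as.integer(parts[2]) else 1L
        p <- chiralnet:::cp_mul(p, chiralnet:::cp_var(parts[1], pow = pow))
      } else {
        stop("cannot parse factor: ", f)
      }
    }
    acc <- chiralnet:::cp_add(acc, p)
  }
  acc
}

expect_poly_equal <- function(actual, expected_str) {
  expect_true(chiralnet:::cp_equal(chiralnet:::as_cpoly(actual),
                                   P(expected_str)),
              label = sprintf("polynomial %s == %s",
                              format(chiralnet:::as_cpoly(actual)),
                              expected_str))
}

expect_smat_equal <- function(M, expected_strs) {
  expect_equal(dim(M), dim(expected_strs))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    expect_poly_equal(M[[i, j]], expected_strs[i, j])
}

# --- direct term-by-term mass-action derivative (oracle for ode_rhs) -----
ode_rhs_direct <- function(net, state) {
  x <- state$concentrations
  k <- state$rate_constants
  dyn <- dynamic_species(net)
  out <- numeric(length(dyn))
  names(out) <- dyn
  for (i in dyn) {
    for (rx in net$reactions) {
      ci <- if (i %in% names(rx$reactants)) rx$reactants[[i]] else 0
      di <- if (i %in% names(rx$products)) rx$products[[i]] else 0
      if (di == ci) next
      mono <- k[[rx$rate]]
      for (sp in names(rx$reactants)) mono <- mono * x[[sp]]^rx$reactants[[sp]]
      out[i] <- out[i] + (di - ci) * mono
    }
  }
  out
}

# --- brute-force characteristic polynomial by interpolation --------------
# Evaluates det(lambda I - M) at k+1 points and solves the Vandermonde
# system; returns the Omega_i (so that the coefficient of lambda^{k-i} is
# (-1)^i Omega_i).
char_poly_bruteforce <- function(M) {
  k <- nrow(M)
  pts <- seq_len(k + 1)
  vals <- vapply(pts, function(l) det(l * diag(k) - M), 0)
  V <- outer(pts, k:0, `^`)
  a <- solve(V, vals)        # monic: a[1] = 1
  vapply(seq_len(k), function(i) (-1)^i * a[i + 1], 0)
}

# --- instability by companion-matrix eigenvalues -------------------------
companion_unstable <- function(a, tol = 0) {
  k <- length(a) - 1
  C <- rbind(-a[-1], cbind(diag(k - 1), 0))
  max(Re(eigen(C, only.values = TRUE)$values)) > tol
}

# --- support-subset brute force for extreme rays of {v>=0, Mv=0} ---------
# For every support set T, keeps T if the restriction of M to columns T has
# a one-dimensional nullspace spanned by a strictly positive vector; the
# support-minimal survivors are the extreme rays.
extreme_rays_bruteforce <- function(M) {
  r <- ncol(M)
  cand <- list()
  supports <- list()
  for (mask in seq_len(2^r - 1)) {
    T <- which(bitwAnd(mask, 2^(seq_len(r) - 1)) > 0)
    A <- M[, T, drop = FALSE]
    ns <- qr(A)
    if (ns$rank != length(T) - 1) next
    # one-dimensional nullspace: solve by SVD
    sv <- svd(A, nv = length(T))
    v <- sv$v[, length(T)]
    if (all(v <= 1e-9)) v <- -v
    if (any(v <= 1e-9)) next          # must be strictly positive on T
    full <- numeric(r)
    full[T] <- v
    if (max(abs(M %*% full)) > 1e-8) next
    cand[[length(cand) + 1]] <- full / max(full)
    supports[[length(supports) + 1]] <- T
  }
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i != j && keep[i] && keep[j] &&
        all(supports[[i]] %in% supports[[j]]) &&
        length(supports[[i]]) < length(supports[[j]]))
      keep[j] <- FALSE
  }
  cand[keep]
}

rays_as_sorted_matrix <- function(rays) {
  if (length(rays) == 0) return(matrix(0, 0, 0))
  m <- do.call(rbind, lapply(rays, function(v) v / max(v)))
  m <- round(m, 9)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# --- general random positive steady states via the cone ------------------
# Chooses positive concentrations and cone coordinates, then sets each rate
# constant so that the reaction's velocity equals its composite current.
# Reactions that carry no current at the drawn point are removed (the state
# is then a positive steady state of the remaining subnetwork).  Works only
# for networks where no two reactions share a rate label.
random_positive_steady_state <- function(net, cone) {
  if (cone$s == 0) return(NULL)
  x <- stats::runif(length(net$species), 0.2, 2)
  names(x) <- net$species
  j <- stats::runif(cone$s, 0.1, 2)
  w <- composite_current(cone, j)
  keep <- w > 1e-9
  if (sum(keep) < 2) return(NULL)
  net$reactions <- net$reactions[keep]
  w <- w[keep]
  labs <- rate_labels(net)
  if (anyDuplicated(labs)) return(NULL)
  C <- chiralnet:::full_order_matrix(net)
  k <- numeric(length(labs))
  names(k) <- labs
  for (q in seq_along(labs)) {
    mono <- prod(x[C[q, ] > 0]^C[q, C[q, ] > 0])
    k[q] <- w[q] / mono
  }
  list(net = net, state = network_state(x, k))
}

frank_fixture <- function() fixture("frank")
calvin_fixture <- function() fixture("calvin")
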