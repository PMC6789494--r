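# Numerical confirmation of mirror-symmetry breaking: stiff integration of
# the mass-action ODE, enantiomeric-excess series, bifurcation scans.

make_rhs <- function(net, state) {
  dyn <- dynamic_species(net)
  S <- stoichiometric_matrix(net)
  C <- full_order_matrix(net)
  kvec <- vapply(net$reactions, function(rx)
    state$rate_constants[[rx$rate]], 0)
  consts <- state$concentrations[net$constant_species]
  function(t, y, parms) {
    x <- c(pmax(y, 0), consts)[net$species]
    v <- numeric(length(kvec))
    for (q in seq_along(kvec)) {
      cq <- C[q, ]
      v[q] <- kvec[q] * prod(x[cq > 0]^cq[cq > 0])
    }
    list(drop(S %*% v))
  }
}

#' Integrate the mass-action ODE
#'
#' Solves the network dynamics with a stiff-capable implicit method
#' (`deSolve::lsoda`); constant species are held fixed as parameters.
#'
#' @param net a `reaction_network`.
#' @param state0 initial `network_state` (supplies the rate constants and
#'   every concentration).
#' @param t_end final time (> 0).
#' @param times optional explicit output times; defaults to 201 points on
#'   `[0, t_end]`.
#' @param rtol,atol solver tolerances.
#' @return object of class `trajectory`: `times`, `concentrations` (time x
#'   species, constant species included as fixed columns), `diagnostics`.
#' @export
integrate_network <- function(net, state0, t_end, times = NULL,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_end > 0)
  check_state(net, state0)
  dyn <- dynamic_species(net)
  y0 <- state0$concentrations[dyn]
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  rhs <- make_rhs(net, state0)
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  tt <- sol[, 1L]
  conc <- sol[, -1L, drop = FALSE]
  clipped <- sum(conc < -1e-12)
  conc[conc < 0] <- 0
  full <- matrix(0, nrow(conc), length(net$species),
                 dimnames = list(NULL, net$species))
  full[, dyn] <- conc
  for (sp in net$constant_species)
    full[, sp] <- state0$concentrations[[sp]]
  structure(list(times = tt, concentrations = full,
                 diagnostics = list(solver = "lsoda", clipped = clipped,
                                    istate = attr(sol, "istate")[1L])),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "time points over [",
      min(x$times), ",", max(x$times), "],",
      ncol(x$concentrations), "species\n")
  invisible(x)
}

#' Enantiomeric-excess time series
#'
#' `ee(t) = (L(t) - D(t)) / (L(t) + D(t))` for a designated enantiomeric
#' pair; defined as 0 where both concentrations vanish.
#'
#' @param traj a `trajectory`.
#' @param pair character pair `c(L, D)`.
#' @return numeric vector in `[-1, 1]`, one value per time point.
#' @export
enantiomeric_excess <- function(traj, pair) {
  L <- traj$concentrations[, pair[1L]]
  D <- traj$concentrations[, pair[2L]]
  tot <- L + D
  ee <- ifelse(tot > 0, (L - D) / tot, 0)
  pmin(pmax(ee, -1), 1)
}

final_state_of <- function(net, traj, state0) {
  x <- traj$concentrations[nrow(traj$concentrations), ]
  network_state(x, state0$rate_constants)
}

# integrate in expanding chunks until |ee| saturates, the flow is at rest
# with a non-growing enantiomeric gap, or t_end is reached; robust to
# finite-time blow-up of winner-takes-all models (the last successful
# chunk is kept).  The gap-growth test matters for perturbations of size
# ~1e-16: the flow at such a state is already below any rhs tolerance,
# yet the instability still needs time to amplify the gap.
run_until_settled <- function(net, state, pair, t_end, rhs_tol = 1e-12,
                              ee_stop = 0.999) {
  t_done <- 0
  cur <- state
  gap_of <- function(st) abs(st$concentrations[[pair[1L]]] -
                             st$concentrations[[pair[2L]]])
  ee_of <- function(st) {
    L <- st$concentrations[[pair[1L]]]
    D <- st$concentrations[[pair[2L]]]
    if (L + D > 0) (L - D) / (L + D) else 0
  }
  ee <- ee_of(cur)
  gap0 <- gap_of(cur)
  gap_prev <- gap0
  settled <- 0L
  chunk <- max(t_end * 1e-6, 1e-3)
  while (t_done < t_end) {
    chunk <- min(chunk, t_end - t_done)
    traj <- tryCatch(
      integrate_network(net, cur, chunk, times = c(0, chunk / 2, chunk)),
      error = function(e) NULL)
    if (is.null(traj)) break
    if (any(!is.finite(traj$concentrations))) break
    cur <- final_state_of(net, traj, cur)
    t_done <- t_done + chunk
    ee <- ee_of(cur)
    gap <- gap_of(cur)
    rhs <- tryCatch(max(abs(ode_rhs(net, cur))), error = function(e) Inf)
    if (abs(ee) >= ee_stop) break
    # Early stop only when the initial gap was resolvable above round-off
    # (otherwise a latent instability seeded at machine noise is
    # indistinguishable from rest, and the full horizon must be run --
    # cheap near a steady state) and the gap has relaxed back: three
    # consecutive at-rest checks with no net amplification.
    tot <- sum(abs(cur$concentrations))
    resolvable <- gap0 > 1e-12 * max(1, tot)
    at_rest <- resolvable && rhs < rhs_tol && gap <= gap_prev &&
      gap <= 2 * gap0
    settled <- if (at_rest) settled + 1L else 0L
    if (settled >= 3L) break
    gap_prev <- gap
    chunk <- chunk * 4
  }
  list(state = cur, ee = ee, t = t_done)
}

#' Detect spontaneous mirror-symmetry breaking by simulation
#'
#' Perturbs the first enantiomeric pair of a racemic steady state by a
#' relative `epsilon` in both directions, integrates each perturbed system
#' until the enantiomeric excess saturates (or the dynamics comes to rest,
#' or `t_end` is reached), and reports SMSB when both runs reach a final
#' `|ee|` above `ee_threshold` with mirror-image signs.
#'
#' @param net a `reaction_network`.
#' @param chiral a `chiral_structure`.
#' @param state a racemic steady `network_state` (checked; non-steady input
#'   is an error).
#' @param epsilon relative perturbation (default `1e-10`); `epsilon = 0`
#'   leaves the state exactly racemic and yields `FALSE`.
#' @param t_end integration horizon (default `1e6`).
#' @param ee_threshold final-|ee| threshold for calling SMSB (default 0.1).
#' @return logical with attributes `ee_plus`, `ee_minus` (final excesses
#'   for the two perturbation signs).
#' @export
detect_smsb <- function(net, chiral, state, epsilon = 1e-10, t_end = 1e6,
                        ee_threshold = 0.1) {
  if (!is_racemic_steady(net, chiral, state))
    stop("state is not a racemic steady state")
  pair <- chiral$pairs[[1L]]
  perturb <- function(sgn) {
    x <- state$concentrations
    base <- x[[pair[1L]]]
    if (base == 0) base <- max(x, 1e-6)
    x[[pair[1L]]] <- x[[pair[1L]]] + sgn * epsilon * base
    x[[pair[2L]]] <- x[[pair[2L]]] - sgn * epsilon * base
    network_state(pmax(x, 0), state$rate_constants)
  }
  up <- run_until_settled(net, perturb(+1), pair, t_end)
  dn <- run_until_settled(net, perturb(-1), pair, t_end)
  ok <- abs(up$ee) > ee_threshold && abs(dn$ee) > ee_threshold &&
    sign(up$ee) == -sign(dn$ee)
  structure(ok, ee_plus = up$ee, ee_minus = dn$ee)
}

# drive the racemic-restricted dynamics to a steady state: integrate and
# re-symmetrize the pairs after each leg (the symmetric subsystem is
# invariant; symmetrization only removes accumulated round-off)
racemic_equilibrate <- function(net, chiral, state, t_max = 1e5,
                                rhs_tol = 1e-10) {
  cur <- state
  t_done <- 0
  chunk <- 1
  while (t_done < t_max) {
    traj <- tryCatch(
      integrate_network(net, cur, chunk, times = c(0, chunk)),
      error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    cur <- final_state_of(net, traj, cur)
    x <- cur$concentrations
    for (p in chiral$pairs) {
      m <- (x[[p[1L]]] + x[[p[2L]]]) / 2
      x[[p[1L]]] <- m
      x[[p[2L]]] <- m
    }
    cur <- network_state(x, cur$rate_constants)
    t_done <- t_done + chunk
    if (max(abs(ode_rhs(net, cur))) < rhs_tol) return(cur)
    chunk <- chunk * 4
  }
  if (max(abs(ode_rhs(net, cur))) < 1e-6) cur else NULL
}

#' One-parameter bifurcation scan of the SMSB window
#'
#' For each grid value of a rate constant (its whole equal-value class is
#' moved together so the network stays pseudochiral), the racemic steady
#' state is re-equilibrated by continuation from the previous grid point
#' (integrating the symmetric subsystem) and [detect_smsb()] is run.
#'
#' @param net a `reaction_network`.
#' @param chiral a `chiral_structure`.
#' @param state a racemic steady `network_state` used as the starting
#'   point.
#' @param param_label a rate-constant label.
#' @param grid strictly increasing positive values for the parameter.
#' @param ... passed to [detect_smsb()].
#' @return data frame of class `bifurcation_table`: columns `value`,
#'   `ee_final` (largest final |ee| over the two perturbation signs),
#'   `smsb`, `flagged` (TRUE when no racemic steady state was found at the
#'   grid point).
#' @export
bifurcation_scan <- function(net, chiral, state, param_label, grid, ...) {
  if (any(grid <= 0) || any(diff(grid) <= 0))
    stop("grid must be strictly increasing and positive")
  if (!param_label %in% rate_labels(net)) stop("unknown rate label")
  class_members <- names(chiral$label_classes)[
    chiral$label_classes == chiral$label_classes[[param_label]]]
  cur <- state
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    k <- cur$rate_constants
    for (lab in class_members) k[[lab]] <- grid[g]
    trial <- network_state(cur$concentrations, k)
    eq <- racemic_equilibrate(net, chiral, trial)
    if (is.null(eq)) {
      rows[[g]] <- data.frame(value = grid[g], ee_final = NA_real_,
                              smsb = FALSE, flagged = TRUE)
      next
    }
    cur <- eq
    sm <- detect_smsb(net, chiral, eq, ...)
    rows[[g]] <- data.frame(value = grid[g],
                            ee_final = max(abs(attr(sm, "ee_plus")),
                                           abs(attr(sm, "ee_minus"))),
                            smsb = as.logical(sm), flagged = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "param") <- param_label
  class(out) <- c("bifurcation_table", "data.frame")
  out
}
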