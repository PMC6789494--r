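# Mass-action reaction networks: plain-text DSL, stoichiometry, kinetics.

#' Parse a reaction network from its plain-text description
#'
#' The network DSL has one statement per line; `#` starts a comment.
#'
#' * `constant <name> [<name> ...]` marks species as pool chemicals: their
#'   concentrations enter every rate law but are held fixed (they contribute
#'   no ODE, no row of the stoichiometric matrix and no Jacobian column).
#' * `pair <L>:<D>` declares an enantiomeric pair; the order of `pair`
#'   statements defines the pair index.
#' * `dual <label>~<label>` declares that two rate-constant labels belong to
#'   the same equal-value class (the labels of a dual reaction pair).
#' * Reaction lines: `c1 S1 + c2 S2 -> d1 P1 | k1` for an irreversible
#'   reaction and `... <-> ... | kf, kr` for a reversible one, which is
#'   split into two irreversible reactions (forward first).  An omitted
#'   stoichiometric coefficient is 1.  An empty reactant side (`-> A | k`)
#'   is an inflow with zero-order kinetics; an empty product side an
#'   outflow.
#'
#' Species are declared by first appearance (in `constant`/`pair`
#' statements or reaction lines) and keep that order.
#'
#' @param text character: the network description, either a single string
#'   with newlines or a vector of lines.
#' @param name optional network name.
#' @return an object of class `reaction_network` with fields `species`,
#'   `reactions`, `constant_species`, `pairs`, `dual_labels`, and the
#'   derived counts `n` (dynamic species) and `r` (reactions after
#'   splitting reversibles).
#' @seealso [write_network()] for the inverse, [read_network()] to parse a
#'   file.
#' @export
parse_network <- function(text, name = "network") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  species <- character(0)
  constant <- character(0)
  pairs <- list()
  duals <- list()
  reactions <- list()

  note_species <- function(s) {
    new <- setdiff(s, species)
    if (length(new)) species <<- c(species, new)
  }

  for (ln in lines) {
    if (grepl("^constant\\b", ln)) {
      nm <- strsplit(trimws(sub("^constant", "", ln)), "\\s+")[[1L]]
      note_species(nm)
      constant <- union(constant, nm)
    } else if (grepl("^pair\\b", ln)) {
      body <- trimws(sub("^pair", "", ln))
      pr <- trimws(strsplit(body, ":", fixed = TRUE)[[1L]])
      if (length(pr) != 2L || !all(nzchar(pr)))
        stop("malformed pair statement: ", ln)
      note_species(pr)
      pairs[[length(pairs) + 1L]] <- pr
    } else if (grepl("^dual\\b", ln)) {
      body <- trimws(sub("^dual", "", ln))
      dl <- trimws(strsplit(body, "~", fixed = TRUE)[[1L]])
      if (length(dl) != 2L) stop("malformed dual statement: ", ln)
      duals[[length(duals) + 1L]] <- dl
    } else {
      parsed <- parse_reaction_line(ln)
      for (rx in parsed) {
        note_species(names(rx$reactants))
        note_species(names(rx$products))
        reactions[[length(reactions) + 1L]] <- rx
      }
    }
  }

  if (length(reactions) == 0L) stop("network has no reactions")
  for (pr in pairs) {
    if (pr[1L] %in% constant && !(pr[2L] %in% constant) ||
        pr[2L] %in% constant && !(pr[1L] %in% constant))
      stop("pair (", pr[1L], ", ", pr[2L], ") mixes constant and dynamic species")
  }
  pnames <- unlist(pairs)
  if (anyDuplicated(pnames))
    stop("species ", pnames[duplicated(pnames)][1L], " occurs in two pairs")

  net <- structure(list(
    name = name,
    species = species,
    reactions = reactions,
    constant_species = constant,
    pairs = pairs,
    dual_labels = duals
  ), class = "reaction_network")
  validate_network(net)
  net
}

#' Read a network from a `.crn` file
#' @param path file path.
#' @param name optional name; defaults to the file name.
#' @return a `reaction_network`.
#' @export
read_network <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.crn$", "", basename(path))
  parse_network(readLines(path, warn = FALSE), name = name)
}

parse_side <- function(txt) {
  txt <- trimws(txt)
  out <- integer(0)
  if (!nzchar(txt)) return(out)
  if (grepl("^\\+", txt) || grepl("\\+$", txt) || grepl("\\+\\s*\\+", txt))
    stop("malformed reaction side '", txt, "'")
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1L]]
    if (length(m) == 0L) stop("malformed term '", tm, "'")
    coef <- if (nzchar(m[2L])) as.integer(m[2L]) else 1L
    sp <- m[3L]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + coef
  }
  out
}

parse_reaction_line <- function(ln) {
  halves <- strsplit(ln, "|", fixed = TRUE)[[1L]]
  if (length(halves) != 2L) stop("reaction line needs '| <rate label(s)>': ", ln)
  eqn <- trimws(halves[1L])
  labels <- trimws(strsplit(halves[2L], ",", fixed = TRUE)[[1L]])
  rev <- grepl("<->", eqn, fixed = TRUE)
  arrow <- if (rev) "<->" else "->"
  if (!grepl(arrow, eqn, fixed = TRUE)) stop("no arrow in reaction line: ", ln)
  sides <- strsplit(eqn, arrow, fixed = TRUE)[[1L]]
  if (length(sides) == 1L) sides <- c(sides, "")
  lhs <- parse_side(sides[1L])
  rhs <- parse_side(sides[2L])
  if (length(lhs) == 0L && length(rhs) == 0L)
    stop("reaction with two empty sides: ", ln)
  mk <- function(re, pr, lab) list(reactants = re, products = pr, rate = lab)
  if (rev) {
    if (length(labels) != 2L)
      stop("reversible reaction needs two rate labels: ", ln)
    list(mk(lhs, rhs, labels[1L]), mk(rhs, lhs, labels[2L]))
  } else {
    if (length(labels) != 1L)
      stop("irreversible reaction needs one rate label: ", ln)
    list(mk(lhs, rhs, labels[1L]))
  }
}

validate_network <- function(net) {
  if (anyDuplicated(net$species))
    stop("duplicate species name")
  for (rx in net$reactions) {
    co <- c(rx$reactants, rx$products)
    if (length(co) && (any(co < 0) || any(co != round(co))))
      stop("stoichiometric coefficients must be nonnegative integers")
  }
  und <- setdiff(net$constant_species, net$species)
  if (length(und)) stop("undeclared species: ", paste(und, collapse = ", "))
  used <- unique(unlist(lapply(net$reactions, function(rx)
    c(names(rx$reactants), names(rx$products)))))
  unused <- setdiff(net$species, used)
  if (length(unused))
    stop("species never occur in a reaction: ",
         paste(unused, collapse = ", "))
  if (n_dynamic(net) < 1L)
    stop("network must retain at least one dynamic species")
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network '", x$name, "': ",
      length(x$species), " species (", n_dynamic(x), " dynamic), ",
      length(x$reactions), " reactions\n", sep = "")
  if (length(x$constant_species))
    cat("  constant:", paste(x$constant_species, collapse = ", "), "\n")
  if (length(x$pairs))
    cat("  pairs:", paste(vapply(x$pairs, paste, "", collapse = ":"),
                          collapse = ", "), "\n")
  for (i in seq_along(x$reactions))
    cat(sprintf("  R%-3d %s\n", i, format_reaction(x$reactions[[i]])))
  invisible(x)
}

format_side <- function(co) {
  if (length(co) == 0L) return("")
  paste(ifelse(co == 1L, names(co), paste(co, names(co))), collapse = " + ")
}

format_reaction <- function(rx) {
  sprintf("%s -> %s | %s", format_side(rx$reactants),
          format_side(rx$products), rx$rate)
}

#' Write a network back to its DSL text
#'
#' Produces text that [parse_network()] maps back to an identical network
#' (reversible reactions stay split, since splitting happens at parse time).
#'
#' @param net a `reaction_network`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the character
#'   vector of DSL lines.
#' @export
write_network <- function(net, path = NULL) {
  lines <- character(0)
  if (length(net$constant_species))
    lines <- c(lines, paste("constant", paste(net$constant_species, collapse = " ")))
  for (pr in net$pairs)
    lines <- c(lines, paste0("pair ", pr[1L], ":", pr[2L]))
  for (dl in net$dual_labels)
    lines <- c(lines, paste0("dual ", dl[1L], "~", dl[2L]))
  lines <- c(lines, vapply(net$reactions, format_reaction, ""))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Dynamic species of a network
#' @param net a `reaction_network`.
#' @return character vector of species not held constant, in declaration
#'   order.
#' @export
dynamic_species <- function(net) setdiff(net$species, net$constant_species)

n_dynamic <- function(net) length(dynamic_species(net))

#' Number of (irreversible) reactions in a network
#' @param net a `reaction_network`.
#' @return integer count, after reversible splitting.
#' @export
n_reactions <- function(net) length(net$reactions)

#' Rate-constant labels of a network
#' @param net a `reaction_network`.
#' @return character vector, one entry per reaction (labels may repeat when
#'   dual reactions share a constant).
#' @export
rate_labels <- function(net) vapply(net$reactions, `[[`, "", "rate")

coef_of <- function(co, sp) if (sp %in% names(co)) co[[sp]] else 0L

#' Stoichiometric matrix
#'
#' Entry (i, j) is the net production `d_ij - c_ij` of dynamic species i in
#' reaction j.  Constant (pool) species contribute no row.
#'
#' @param net a `reaction_network`.
#' @return integer matrix, dynamic species x reactions.
#' @export
stoichiometric_matrix <- function(net) {
  dyn <- dynamic_species(net)
  r <- n_reactions(net)
  S <- matrix(0L, length(dyn), r,
              dimnames = list(dyn, paste0("R", seq_len(r))))
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    for (sp in dyn)
      S[sp, j] <- coef_of(rx$products, sp) - coef_of(rx$reactants, sp)
  }
  S
}

#' Kinetic-order matrix
#'
#' Entry (j, i) is the reactant coefficient of dynamic species i in
#' reaction j (the kinetic order under mass action).  Orders with respect
#' to constant species are excluded; they are folded into the rate law at
#' evaluation time.
#'
#' @param net a `reaction_network`.
#' @return integer matrix, reactions x dynamic species.
#' @export
kinetic_order_matrix <- function(net) {
  dyn <- dynamic_species(net)
  r <- n_reactions(net)
  R <- matrix(0L, r, length(dyn),
              dimnames = list(paste0("R", seq_len(r)), dyn))
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    for (sp in dyn) R[j, sp] <- coef_of(rx$reactants, sp)
  }
  R
}

# reactant orders over ALL species (r x n), used by velocity evaluation
full_order_matrix <- function(net) {
  r <- n_reactions(net)
  M <- matrix(0L, r, length(net$species),
              dimnames = list(paste0("R", seq_len(r)), net$species))
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    for (sp in names(rx$reactants)) M[j, sp] <- rx$reactants[[sp]]
  }
  M
}

#' Write an integer/numeric matrix as TSV
#'
#' Convenience writer for stoichiometric, kinetic-order and extended
#' matrices; row and column names are preserved.
#'
#' @param M matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Construct a network state
#'
#' A state bundles the full parameter vector of the mass-action dynamics:
#' every concentration (dynamic and constant species) together with every
#' rate constant.
#'
#' @param concentrations named nonnegative numeric vector, one entry per
#'   species.
#' @param rate_constants named positive numeric vector, one entry per rate
#'   label.
#' @return an object of class `network_state`.
#' @export
network_state <- function(concentrations, rate_constants) {
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (any(rate_constants <= 0)) stop("rate constants must be positive")
  structure(list(concentrations = concentrations,
                 rate_constants = rate_constants),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("network_state\n  concentrations:",
      paste(names(x$concentrations), signif(x$concentrations, 6),
            sep = "=", collapse = ", "),
      "\n  rate constants:",
      paste(names(x$rate_constants), signif(x$rate_constants, 6),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

check_state <- function(net, state) {
  miss <- setdiff(net$species, names(state$concentrations))
  if (length(miss))
    stop("state lacks concentrations for: ", paste(miss, collapse = ", "))
  miss <- setdiff(unique(rate_labels(net)), names(state$rate_constants))
  if (length(miss))
    stop("state lacks rate constants for: ", paste(miss, collapse = ", "))
  invisible(state)
}

#' Mass-action velocity vector
#'
#' Component j is `k_j * prod_i X_i^{c_ij}` taken over every species,
#' constant species included.  An inflow (empty reactant side) has velocity
#' equal to its rate constant.
#'
#' @param net a `reaction_network`.
#' @param state a `network_state` (or list with `concentrations` and
#'   `rate_constants`).
#' @return numeric vector of length `r`.
#' @export
velocity <- function(net, state) {
  check_state(net, state)
  x <- state$concentrations[net$species]
  k <- state$rate_constants
  C <- full_order_matrix(net)
  v <- numeric(n_reactions(net))
  for (j in seq_len(n_reactions(net))) {
    cj <- C[j, ]
    v[j] <- k[[net$reactions[[j]]$rate]] * prod(x[cj > 0]^cj[cj > 0])
  }
  names(v) <- paste0("R", seq_len(n_reactions(net)))
  v
}

#' Right-hand side of the mass-action ODE
#'
#' `dX/dt = S %*% velocity`, restricted to dynamic species.
#'
#' @inheritParams velocity
#' @return named numeric vector over the dynamic species.
#' @export
ode_rhs <- function(net, state) {
  drop(stoichiometric_matrix(net) %*% velocity(net, state))
}

#' Numeric Jacobian of the mass-action ODE at a state
#'
#' Differentiates `ode_rhs` with respect to the dynamic concentrations
#' only; constant species act as fixed parameters.  Uses the closed form
#' `dv_j/dX_m = v_j c_mj / X_m` (with the monomial factor expanded when
#' `X_m = 0`).
#'
#' @inheritParams velocity
#' @return numeric matrix, dynamic species x dynamic species.
#' @export
jacobian_numeric <- function(net, state) {
  check_state(net, state)
  dyn <- dynamic_species(net)
  S <- stoichiometric_matrix(net)
  x <- state$concentrations[net$species]
  k <- state$rate_constants
  C <- full_order_matrix(net)
  r <- n_reactions(net)
  Dv <- matrix(0, r, length(dyn), dimnames = list(NULL, dyn))
  for (j in seq_len(r)) {
    kj <- k[[net$reactions[[j]]$rate]]
    for (m in dyn) {
      cm <- C[j, m]
      if (cm == 0L) next
      others <- C[j, ]
      others[m] <- 0L
      pref <- prod(x[others > 0]^others[others > 0])
      Dv[j, m] <- kj * cm * (if (cm > 1L) x[[m]]^(cm - 1L) else 1) * pref
    }
  }
  J <- S %*% Dv
  dimnames(J) <- list(dyn, dyn)
  J
}
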