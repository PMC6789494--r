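# Benchmark fixtures and a random pseudochiral-network generator.

fixture_names <- function() {
  c("theta0", "frank", "calvin", "aped", "replicator",
    "iwamoto_perfect", "iwamoto_imperfect", "iwamoto_imperfect_equal")
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "chiralnet")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

#' Load a benchmark network fixture
#'
#' Available fixtures: `theta0` (achiral toy network), `frank` (order 1),
#' `calvin` (order 2, the classical negative control), `aped` (order 4,
#' generic stereoselectivity), `replicator` (order 2),
#' `iwamoto_perfect` / `iwamoto_imperfect` (order 2), and
#' `iwamoto_imperfect_equal` (the imperfect model with the stereoselective
#' and stereospecific rate-constant equalities imposed, which removes its
#' symmetry-breaking states).
#'
#' @param name fixture name.
#' @return list with `network` (a `reaction_network`), `chiral` (a
#'   `chiral_structure`, `NULL` for the achiral toy network), `order`, and
#'   `expected_verdict` (`"accept"`, `"reject"` or `NA` where no
#'   qualitative verdict is recorded).
#' @export
fixture <- function(name) {
  if (!name %in% fixture_names())
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "))
  file <- if (name == "iwamoto_imperfect_equal") "iwamoto_imperfect.crn"
          else paste0(name, ".crn")
  net <- read_network(fixture_path(file), name = name)
  if (name == "iwamoto_imperfect_equal") {
    # impose k2 = k2a = k4 = k4a, k3 = ..., k6 = ..., k7 = ... by merging
    # the label classes of the a-channels with their perfect counterparts
    net$dual_labels <- c(net$dual_labels,
                         list(c("k2", "k2a"), c("k3", "k3a"),
                              c("k6", "k6a"), c("k7", "k7a")))
  }
  exp <- jsonlite::fromJSON(fixture_path("fixtures.json"))[[name]]
  chiral <- if (length(net$pairs)) check_pseudochiral(net) else NULL
  list(network = net,
       chiral = chiral,
       order = if (is.null(chiral)) 0L else chiral$order,
       expected_verdict = if (is.null(exp$verdict)) NA_character_
                          else exp$verdict)
}

#' APED network with chosen stereoselectivity factors
#'
#' The APED mechanism distinguishes homochiral from heterochiral steps by
#' the factors `alpha` (polymerization), `beta` (depolymerization) and
#' `gamma` (epimerization).  A factor equal to 1 makes the corresponding
#' hetero step kinetically identical to its homo step, which is expressed
#' here by merging the two rate labels into one equal-value class (`kap`
#' with `kp`, `kbh` with `kh`, `kge` with `ke`); the network topology
#' never changes.  Factors different from 1 leave the labels as free,
#' independent parameters (the sampler then explores their values), and
#' are recorded on the returned network as attribute `factors`.
#'
#' @param alpha,beta,gamma positive stereoselectivity factors.
#' @return a `reaction_network`.
#' @export
aped_variant <- function(alpha = 1, beta = 1, gamma = 1) {
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("stereoselectivity factors must be positive")
  net <- read_network(fixture_path("aped.crn"), name = "aped")
  merge <- list(c("kp", "kap"), c("kh", "kbh"), c("ke", "kge"))
  use <- c(alpha == 1, beta == 1, gamma == 1)
  net$dual_labels <- c(net$dual_labels, merge[use])
  attr(net, "factors") <- c(alpha = alpha, beta = beta, gamma = gamma)
  net
}

#' Generate a random pseudochiral network
#'
#' Draws random mass-action reactions (stoichiometric coefficients at most
#' 2, at most two distinct species per side) over `order_k` enantiomeric
#' pairs plus `n_achiral` achiral species, then closes the reaction set
#' under the L/D involution with shared rate labels, so the result always
#' passes [check_pseudochiral()].  Deterministic per seed.  Intended as a
#' property-test input generator.
#'
#' @param order_k number of enantiomeric pairs (>= 1); each pair anchors
#'   one seed reaction, so every pair takes part in the chemistry.
#' @param n_achiral number of achiral species (idle ones are dropped).
#' @param n_reactions number of additional seed reactions before closure.
#' @param seed integer seed.
#' @return list with `network` and `chiral`.
#' @export
random_pseudochiral <- function(order_k, n_achiral = 1L, n_reactions = 3L,
                                seed) {
  stopifnot(order_k >= 1L, n_reactions >= 1L)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  ls <- paste0("L", seq_len(order_k))
  ds <- paste0("D", seq_len(order_k))
  ach <- if (n_achiral > 0L) paste0("A", seq_len(n_achiral)) else character(0)
  species <- c(ls, ds, ach)
  inv <- structure(species, names = species)
  inv[ls] <- ds
  inv[ds] <- ls

  rand_side <- function() {
    nsp <- sample(0:2, 1L, prob = c(0.1, 0.55, 0.35))
    if (nsp == 0L) return(integer(0))
    sp <- sample(species, nsp)
    co <- sample(1:2, nsp, replace = TRUE, prob = c(0.8, 0.2))
    structure(as.integer(co), names = sp)
  }
  side_key <- function(co) {
    if (length(co) == 0L) return("")
    co <- co[order(names(co))]
    paste(names(co), co, sep = ":", collapse = ",")
  }
  mirror <- function(co) {
    if (length(co) == 0L) return(co)
    structure(as.integer(co), names = unname(inv[names(co)]))
  }

  rxs <- list()
  keys <- character(0)
  q <- 0L
  # one seed reaction per pair guarantees every pair takes part
  pending <- as.list(ls)
  while (q < n_reactions + order_k) {
    if (length(pending)) {
      anchor <- pending[[1L]]
      re <- rand_side()
      re[anchor] <- (if (anchor %in% names(re)) re[[anchor]] else 0L) + 1L
      pr <- rand_side()
    } else {
      re <- rand_side()
      pr <- rand_side()
    }
    if (length(re) == 0L && length(pr) == 0L) next
    if (side_key(re) == side_key(pr)) next
    key <- paste(side_key(re), side_key(pr), sep = ">")
    if (key %in% keys) next
    if (length(pending)) pending <- pending[-1L]
    q <- q + 1L
    lab <- paste0("k", q)
    rxs[[length(rxs) + 1L]] <- list(reactants = re, products = pr, rate = lab)
    keys <- c(keys, key)
    mre <- mirror(re)
    mpr <- mirror(pr)
    mkey <- paste(side_key(mre), side_key(mpr), sep = ">")
    if (!mkey %in% keys) {
      rxs[[length(rxs) + 1L]] <- list(reactants = mre, products = mpr,
                                      rate = lab)
      keys <- c(keys, mkey)
    }
  }
  used <- unique(unlist(lapply(rxs, function(rx)
    c(names(rx$reactants), names(rx$products)))))
  species <- c(ls, ds, intersect(ach, used))   # drop idle achiral species
  net <- structure(list(
    name = sprintf("random_k%d_seed%d", order_k, as.integer(seed)),
    species = species,
    reactions = rxs,
    constant_species = character(0),
    pairs = lapply(seq_len(order_k), function(i) c(ls[i], ds[i])),
    dual_labels = list()
  ), class = "reaction_network")
  validate_network(net)
  list(network = net, chiral = check_pseudochiral(net))
}
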