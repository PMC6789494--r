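# Steady-state flux cone: extended matrix, extreme currents, convex
# coordinates and Clarke's factorization.

test_that("toy-network cone has the two printed extreme currents", {
  net <- fixture("theta0")$network
  cone <- extreme_currents(stoichiometric_matrix(net))
  expect_equal(cone$s, 2L)
  m <- currents_matrix(cone)
  # select by support: one current on reactions {1,2}, one on {2,3}
  on12 <- m[, m["R3", ] == 0]
  on23 <- m[, m["R1", ] == 0]
  expect_equal(unname(on12), c(1, 3, 0))
  expect_equal(unname(on23), c(0, 1, 1))
})

test_that("a full-rank constraint matrix leaves only the zero current", {
  cone <- extreme_currents(diag(4))
  expect_equal(cone$s, 0L)
})

test_that("Frank's extended matrix appends the dual-pair row", {
  fr <- fixture("frank")
  ext <- extended_stoichiometric_matrix(fr$network, fr$chiral)
  expect_equal(nrow(ext), 3L)
  expect_equal(unname(ext[3, ]), c(1, -1, 0))
  cone <- extreme_currents(ext)
  expect_equal(cone$s, 1L)
  expect_equal(unname(cone$currents[[1]]), c(1, 1, 1))
})

test_that("Calvin's paper-mode extension reproduces the printed matrix", {
  ca <- fixture("calvin")
  ext <- extended_stoichiometric_matrix(ca$network, ca$chiral,
                                        mode = "paper")
  S <- stoichiometric_matrix(ca$network)
  expect_equal(ext[1:4, ], S)
  expect_equal(rownames(ext)[5:8],
               c("R1&R2", "R3&R4", "R7&R8", "R9&R10"))
  rowfor <- function(p, q) {
    v <- integer(10)
    v[p] <- 1L
    v[q] <- -1L
    v
  }
  expect_equal(unname(ext[5:8, ]),
               rbind(rowfor(1, 2), rowfor(3, 4), rowfor(7, 8), rowfor(9, 10)))
  # `all` mode also constrains the racemization pair
  exta <- extended_stoichiometric_matrix(ca$network, ca$chiral, mode = "all")
  expect_equal(nrow(exta), 9L)
  expect_true("R5&R6" %in% rownames(exta))
})

test_that("an achiral network is not extended", {
  net <- fixture("theta0")$network
  expect_equal(extended_stoichiometric_matrix(net, NULL),
               stoichiometric_matrix(net))
})

test_that("dual-pair constraints only remove extreme currents", {
  for (nm in c("frank", "calvin", "replicator", "aped", "iwamoto_perfect")) {
    fx <- fixture(nm)
    plain <- extreme_currents(stoichiometric_matrix(fx$network))
    ext <- extreme_currents(
      extended_stoichiometric_matrix(fx$network, fx$chiral))
    expect_lte(ext$s, plain$s)
    # every extended-cone current still lies in the plain cone
    S <- stoichiometric_matrix(fx$network)
    for (v in ext$currents) expect_true(all(S %*% v == 0))
  }
})

test_that("nonnegative combinations of extreme currents stay in the cone", {
  ca <- fixture("calvin")
  ext <- extended_stoichiometric_matrix(ca$network, ca$chiral)
  cone <- extreme_currents(ext)
  set.seed(2)
  for (rep in 1:20) {
    w <- composite_current(cone, runif(cone$s, 0, 3))
    expect_true(all(w >= 0))
    expect_lt(max(abs(ext %*% w)), 1e-9)
  }
})

test_that("no extreme current is redundant", {
  for (nm in c("theta0", "calvin")) {
    fx <- fixture(nm)
    M <- if (is.null(fx$chiral)) stoichiometric_matrix(fx$network)
         else extended_stoichiometric_matrix(fx$network, fx$chiral)
    cone <- extreme_currents(M)
    V <- do.call(cbind, cone$currents)
    for (i in seq_len(cone$s)) {
      fit <- pracma::lsqnonneg(V[, -i, drop = FALSE],
                               as.numeric(V[, i]))
      expect_gt(fit$resid.norm, 1e-6)
    }
  }
})

test_that("double description agrees with support-subset brute force", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    r <- sample(3:7, 1)
    M <- matrix(sample(-2:2, n * r, replace = TRUE), n, r)
    dd <- extreme_currents(M)
    bf <- extreme_rays_bruteforce(M)
    expect_equal(rays_as_sorted_matrix(dd$currents),
                 rays_as_sorted_matrix(bf), tolerance = 1e-6,
                 label = paste("matrix", rep))
  }
})

test_that("the current matrix E is the diagonal of linear forms", {
  net <- fixture("theta0")$network
  cone <- extreme_currents(stoichiometric_matrix(net))
  E <- e_matrix(cone)
  # with currents sorted as (0,1,1) < (1,3,0): j1 rides the {2,3} cycle
  expect_poly_equal(E[[1, 1]], "j2")
  expect_poly_equal(E[[2, 2]], "3*j2 + j1")
  expect_poly_equal(E[[3, 3]], "j1")
  expect_true(all(vapply(seq_len(3), function(i)
    max(1, chiralnet:::cp_degree(E[[i, i]])) == 1, TRUE)))
  # numeric coordinates give the composite current on the diagonal
  En <- e_matrix(cone, c(2, 1))
  expect_equal(diag(En), c(1, 5, 2))
  expect_error(e_matrix(cone, c(1, 2, 3)), "length")
})

test_that("the SNA matrix is S.E.R with linear entries", {
  net <- fixture("theta0")$network
  cone <- extreme_currents(stoichiometric_matrix(net))
  V <- sna_matrix(net, cone)
  # paper coordinates (j1', j2') correspond to (j2, j1) here
  expect_smat_equal(V, rbind(c("-3*j2 + j1", "3*j2"),
                             c("3*j2 - j1", "-3*j2")))
  fr <- fixture("frank")
  conef <- extreme_currents(
    extended_stoichiometric_matrix(fr$network, fr$chiral))
  Vf <- sna_matrix(fr$network, conef)
  expect_smat_equal(Vf, rbind(c("0", "-j1"), c("-j1", "0")))
})

test_that("convex coordinates invert the composite current", {
  net <- fixture("theta0")$network
  cone <- extreme_currents(stoichiometric_matrix(net))
  st <- network_state(c(I = 1, A = 1), c(k1 = 1, k2 = 5, k3 = 2))
  j <- convex_coordinates(cone, velocity(net, st))
  expect_equal(unname(composite_current(cone, as.numeric(j))), c(1, 5, 2))
  expect_true(attr(j, "unique"))
  # a single extreme current has a unit coordinate vector
  j2 <- convex_coordinates(cone, cone$currents[[2]])
  expect_equal(as.numeric(j2), c(0, 1))
  # round trip on random nonnegative coordinates
  set.seed(4)
  for (rep in 1:20) {
    j0 <- runif(cone$s, 0, 2)
    jj <- convex_coordinates(cone, composite_current(cone, j0))
    expect_equal(as.numeric(jj), j0, tolerance = 1e-9)
  }
  # a velocity outside the cone (not a steady state) is rejected
  expect_error(convex_coordinates(cone, c(1, 0, 5)), "not")
})

test_that("Clarke's factorization holds at positive steady states", {
  net <- fixture("theta0")$network
  st <- network_state(c(I = 1, A = 1), c(k1 = 1, k2 = 5, k3 = 2))
  expect_true(verify_clarke_factorization(net, st))
  fr <- fixture("frank")
  stf <- network_state(c(L = 0.8, D = 0.8, A = 1.25, P = 1),
                       c(k1 = 0.64, k2 = 0.64, k3 = 1))
  expect_true(verify_clarke_factorization(fr$network, stf))
  st0 <- network_state(c(I = 0, A = 1), c(k1 = 1, k2 = 1, k3 = 1))
  expect_error(verify_clarke_factorization(net, st0), "zero concentration")
})
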