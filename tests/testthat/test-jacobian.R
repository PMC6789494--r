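# Symbolic Jacobian, racemic blocks, characteristic polynomials and the
# instability criteria.

test_that("toy-network symbolic Jacobian matches the hand derivative", {
  net <- fixture("theta0")$network
  J <- symbolic_jacobian(net)
  expect_smat_equal(J, rbind(
    c("-9*k1*I^2 + 2*k2*I*A - k3*A", "k2*I^2 - k3*I"),
    c("9*k1*I^2 - 2*k2*I*A + k3*A", "-k2*I^2 + k3*I")))
})

test_that("a linear conversion has a constant Jacobian", {
  net <- parse_network("X -> Y | k")
  J <- symbolic_jacobian(net)
  expect_smat_equal(J, rbind(c("-k", "0"), c("k", "0")))
})

test_that("Calvin's racemic Jacobian shows the mirror block structure", {
  ca <- fixture("calvin")
  bl <- racemic_blocks(ca$network, ca$chiral)
  a11 <- "-k0*L2 - k4 - k6"
  a12 <- "-k0*L1 + 2*k2*L2 + k8"
  a21 <- "k0*L2 + k6"
  a22 <- "k0*L1 - 2*k2*L2 - k8"
  expect_smat_equal(bl$J, rbind(
    c(a11, a12, "k4", "0"),
    c(a21, a22, "0", "0"),
    c("k4", "0", a11, a12),
    c("0", "0", a21, a22)))
  expect_smat_equal(bl$A, rbind(c(a11, a12), c(a21, a22)))
  expect_smat_equal(bl$B, rbind(c("k4", "0"), c("0", "0")))
  M <- mm_matrix(ca$network, ca$chiral)
  expect_smat_equal(M, rbind(c("-k0*L2 - 2*k4 - k6", a12), c(a21, a22)))
})

test_that("generic racemic Jacobians satisfy the pair-swap symmetry", {
  for (seed in 1:10) {
    rn <- random_pseudochiral(order_k = 2, n_achiral = 1, n_reactions = 3,
                              seed = seed + 40)
    bl <- racemic_blocks(rn$network, rn$chiral)
    k <- rn$chiral$order
    # rows/cols k+1..2k mirror rows/cols 1..k: J[k+i, k+j] == J[i, j],
    # J[i, k+j] == J[k+i, j]
    for (i in seq_len(k)) for (j in seq_len(k)) {
      expect_true(chiralnet:::cp_equal(bl$J[[k + i, k + j]], bl$J[[i, j]]))
      expect_true(chiralnet:::cp_equal(bl$J[[i, k + j]], bl$J[[k + i, j]]))
    }
  }
})

test_that("Frank's MM value reduces to the autocatalysis drive", {
  fr <- fixture("frank")
  M <- mm_matrix(fr$network, fr$chiral)
  expect_equal(dim(M), c(1L, 1L))
  # J11 - J12 = (k1 A - k3 D) - (-k3 L); racemic substitution D -> L
  # cancels the sink terms, leaving the autocatalytic drive k1 A, which at
  # any racemic steady state equals k3 L > 0
  expect_poly_equal(M[[1, 1]], "k1*A")
  st <- network_state(c(L = 0.8, D = 0.8, A = 1.25, P = 0),
                      c(k1 = 0.64, k2 = 0.64, k3 = 1))
  expect_equal(unname(ode_rhs(fr$network, st)), c(0, 0))
  expect_equal(chiralnet:::cp_eval(M[[1, 1]],
                                   c(st$concentrations, st$rate_constants)),
               st$rate_constants[["k3"]] * st$concentrations[["L"]])
})

test_that("symbolic matrices export to text, JSON trees and TSV", {
  fr <- fixture("frank")
  M <- mm_matrix(fr$network, fr$chiral)
  expect_equal(format_symbolic(M)[1, 1], "A*k1")
  tree <- symbolic_to_json(M)
  expect_equal(tree[[1]][[1]][[1]]$coefficient, 1)
  expect_equal(tree[[1]][[1]][[1]]$variables, list(A = 1L, k1 = 1L))
  tmp <- withr::local_tempfile(fileext = ".json")
  symbolic_to_json(M, tmp)
  expect_equal(jsonlite::fromJSON(tmp, simplifyVector = FALSE)[[1]][[1]][[1]]$coefficient, 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(stoichiometric_matrix(fr$network), tsv)
  back <- utils::read.delim(tsv, row.names = 1)
  expect_equal(as.matrix(back), stoichiometric_matrix(fr$network) + 0,
               ignore_attr = TRUE)
})

test_that("characteristic coefficients are trace, minors, determinant", {
  set.seed(77)
  M <- matrix(rnorm(9), 3, 3)
  p <- char_poly(M)
  expect_equal(p$omega[[1]], sum(diag(M)))
  expect_equal(p$omega[[3]], det(M), tolerance = 1e-12)
  # and char_poly_roots recovers the eigenvalues
  expect_equal(sort(Re(char_poly_roots(p))),
               sort(Re(eigen(M)$values)), tolerance = 1e-8)
})

test_that("principal-minor coefficients match brute-force expansion", {
  set.seed(101)
  for (rep in 1:60) {
    k <- sample(2:6, 1)
    M <- matrix(sample(-4:4, k * k, replace = TRUE), k, k)
    p <- char_poly(M)
    expect_equal(unlist(p$omega), char_poly_bruteforce(M),
                 tolerance = 1e-8)
  }
})

test_that("Calvin's 2x2 determinant factors through the racemization rate", {
  ca <- fixture("calvin")
  M <- mm_matrix(ca$network, ca$chiral)
  p <- char_poly(M)
  expect_poly_equal(p$omega[[2]], "-2*k4*k0*L1 + 4*k4*k2*L2 + 2*k4*k8")
  # the printed trace inequality: -Omega_1 < 0
  expect_poly_equal(chiralnet:::cp_neg(p$omega[[1]]),
                    "k0*L2 + 2*k4 + k6 - k0*L1 + 2*k2*L2 + k8")
})

test_that("polynomial instability matches the sign of the largest root", {
  expect_true(is_unstable_polynomial(c(1, -1)))    # root +1
  expect_false(is_unstable_polynomial(c(1, 1)))    # root -1
  expect_error(is_unstable_polynomial(c(1)), "degree-0")
  # 2x2: unstable iff trace > 0 or det < 0
  set.seed(31)
  for (rep in 1:100) {
    M <- matrix(rnorm(4), 2, 2)
    p <- char_poly(M)
    expect_equal(as.logical(is_unstable_polynomial(p)),
                 sum(diag(M)) > 0 || det(M) < 0)
  }
})

test_that("Routh table and root finding agree on random cubics/quartics", {
  set.seed(13)
  n_checked <- 0
  for (rep in 1:300) {
    k <- sample(3:4, 1)
    a <- c(1, rnorm(k))
    v <- is_unstable_polynomial(a)
    if (abs(attr(v, "max_re")) <= 1e-7) next
    expect_equal(as.logical(v), attr(v, "routh_unstable"),
                 label = paste(a, collapse = ","))
    expect_equal(as.logical(v), companion_unstable(a))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("Frank racemic steady states are symmetry-breaking", {
  fr <- fixture("frank")
  st <- network_state(c(L = 1, D = 1, A = 1, P = 0),
                      c(k1 = 1, k2 = 1, k3 = 1))
  vd <- is_symmetry_breaking_state(fr$network, fr$chiral, st)
  expect_true(vd$breaking)
  expect_true(vd$oracle_breaking)
  expect_equal(vd$max_re, 1)   # k3 * L
  expect_gt(Re(vd$lambda), 0)
})

test_that("Calvin racemic steady states are never symmetry-breaking", {
  ca <- fixture("calvin")
  ext <- extended_stoichiometric_matrix(ca$network, ca$chiral)
  cone <- extreme_currents(ext)
  set.seed(9)
  for (rep in 1:10) {
    j <- runif(cone$s, 0.1, 2)
    st <- back_map(ca$network, cone, j)
    vd <- is_symmetry_breaking_state(ca$network, ca$chiral, st)
    expect_false(vd$breaking)
    expect_false(vd$oracle_breaking)
  }
})

test_that("non-steady input to the symmetry-breaking test is rejected", {
  fr <- fixture("frank")
  st <- network_state(c(L = 1, D = 1, A = 1, P = 0),
                      c(k1 = 2, k2 = 2, k3 = 1))   # k1 A != k3 D
  expect_error(is_symmetry_breaking_state(fr$network, fr$chiral, st),
               "not a racemic steady state")
  st2 <- network_state(c(L = 2, D = 1, A = 1, P = 0),
                       c(k1 = 1, k2 = 1, k3 = 1))
  expect_error(is_symmetry_breaking_state(fr$network, fr$chiral, st2),
               "not a racemic steady state")
})

test_that("the MM verdict equals the eigenvector oracle on random models", {
  n_agree <- 0
  for (seed in 1:200) {
    if (n_agree >= 30) break
    k <- 1 + seed %% 2
    rn <- random_pseudochiral(order_k = k, n_achiral = 1, n_reactions = 3,
                              seed = seed + 500)
    ext <- extended_stoichiometric_matrix(rn$network, rn$chiral)
    cone <- tryCatch(extreme_currents(ext), error = function(e) NULL)
    if (is.null(cone) || cone$s == 0) next
    set.seed(seed)
    j <- runif(cone$s, 0.1, 2)
    st <- tryCatch(back_map(rn$network, cone, j), error = function(e) NULL)
    if (is.null(st)) next
    vd <- is_symmetry_breaking_state(rn$network, rn$chiral, st)
    if (vd$marginal) next
    expect_equal(vd$breaking, vd$oracle_breaking, label = rn$network$name)
    n_agree <- n_agree + 1
  }
  expect_gt(n_agree, 20)
})
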