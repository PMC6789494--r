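# The sampling heuristic over the signed characteristic coefficients.

frank_cone <- function(fx) {
  extreme_currents(extended_stoichiometric_matrix(fx$network, fx$chiral))
}

test_that("Frank's single signed coefficient is minus the current", {
  fr <- fixture("frank")
  cone <- frank_cone(fr)
  polys <- omega_polynomials(fr$network, fr$chiral, cone)
  expect_length(polys, 1L)
  expect_poly_equal(polys[[1]], "-j1")
  # order-1: the i = 1 polynomial is -(V11 - V12)
  V <- sna_matrix(canonical_species_order(fr$network, fr$chiral), cone)
  expect_true(chiralnet:::cp_equal(
    polys[[1]],
    chiralnet:::cp_neg(chiralnet:::cp_sub(V[[1, 1]], V[[1, 2]]))))
})

test_that("signed coefficients have the degree bound i", {
  ca <- fixture("calvin")
  cone <- extreme_currents(
    extended_stoichiometric_matrix(ca$network, ca$chiral))
  polys <- omega_polynomials(ca$network, ca$chiral, cone)
  expect_length(polys, 2L)
  expect_lte(chiralnet:::cp_degree(polys[[1]]), 1)
  expect_lte(chiralnet:::cp_degree(polys[[2]]), 2)
})

test_that("the coefficient certificate is sound and sharp on examples", {
  expect_equal(emptiness_certificate(P("-j1")), "unknown")
  expect_equal(emptiness_certificate(P("j1 + 2*j1*j2")), "certified_empty")
  expect_equal(emptiness_certificate(chiralnet:::cp_zero()),
               "certified_empty")
  expect_equal(emptiness_certificate(P("j1*j2 - j3")), "unknown")
})

test_that("Calvin's coefficient regions are certified empty", {
  ca <- fixture("calvin")
  cone <- extreme_currents(
    extended_stoichiometric_matrix(ca$network, ca$chiral))
  polys <- omega_polynomials(ca$network, ca$chiral, cone)
  expect_equal(vapply(polys, emptiness_certificate, ""),
               rep("certified_empty", 2L))
})

test_that("sampling is deterministic and respects the certificates", {
  fr <- fixture("frank")
  cone <- frank_cone(fr)
  polys <- omega_polynomials(fr$network, fr$chiral, cone)
  s1 <- sample_instability_region(polys, s = cone$s, n_samples = 200,
                                  seed = 123)
  s2 <- sample_instability_region(polys, s = cone$s, n_samples = 200,
                                  seed = 123)
  expect_identical(s1, s2)
  # every positive j satisfies -j < 0, so acceptance is total
  expect_equal(nrow(s1[[1]]$samples), 200L)
  expect_equal(s1[[1]]$status, "found")
  # a positive polynomial yields no samples
  s3 <- sample_instability_region(list(P("1")), s = 2, n_samples = 100,
                                  seed = 5)
  expect_equal(s3[[1]]$status, "certified_empty")
  s4 <- sample_instability_region(list(P("j1 - 10")), s = 1,
                                  n_samples = 50, seed = 5)
  expect_equal(s4[[1]]$status, "found")   # linear fallback construction
  expect_true(all(chiralnet:::cp_eval_rows(P("j1 - 10"),
                                           s4[[1]]$samples) < 0))
})

test_that("back-mapping realizes the composite current at unit concentrations", {
  net <- fixture("theta0")$network
  cone <- extreme_currents(stoichiometric_matrix(net))
  # coordinates (2, 1) give the worked composite current (1, 5, 2)
  st <- back_map(net, cone, c(2, 1))
  expect_equal(st$concentrations, c(I = 1, A = 1))
  expect_equal(st$rate_constants, c(k1 = 1, k2 = 5, k3 = 2))
  expect_equal(unname(velocity(net, st)), c(1, 5, 2))
  expect_equal(unname(ode_rhs(net, st)), c(0, 0))
  # a boundary point with a dead reaction is rejected
  expect_error(back_map(net, cone, c(1, 0)), "zero current")
})

test_that("back-mapped states satisfy the racemic rate equalities", {
  fr <- fixture("frank")
  cone <- frank_cone(fr)
  st <- back_map(fr$network, cone, 1)
  expect_equal(st$concentrations[c("L", "D", "A", "P")],
               c(L = 1, D = 1, A = 1, P = 1))
  expect_equal(st$rate_constants, c(k1 = 1, k2 = 1, k3 = 1))
  ca <- fixture("calvin")
  conec <- extreme_currents(
    extended_stoichiometric_matrix(ca$network, ca$chiral))
  set.seed(8)
  stc <- back_map(ca$network, conec, runif(conec$s, 0.2, 2))
  k <- stc$rate_constants
  for (lab in names(ca$chiral$label_classes)) {
    rep <- ca$chiral$label_classes[[lab]]
    expect_equal(k[[lab]], k[[rep]])
  }
  expect_true(chiralnet:::is_racemic_steady(ca$network, ca$chiral, stc))
})

test_that("the full pipeline accepts Frank and rejects Calvin", {
  fr <- fixture("frank")
  rep1 <- sna_sampling(fr$network, fr$chiral, seed = 42, n_samples = 300)
  expect_equal(rep1$verdict, "accept")
  expect_gt(length(rep1$confirmed), 0L)
  # order-1 networks never end inconclusive: the linear decision is exact
  expect_true(rep1$verdict %in% c("accept", "reject"))
  ca <- fixture("calvin")
  rep2 <- sna_sampling(ca$network, ca$chiral, seed = 42, n_samples = 300)
  expect_equal(rep2$verdict, "reject")
  expect_equal(vapply(rep2$per_i, `[[`, "", "status"),
               rep("certified_empty", 2L))
})

test_that("confirmed states pass both independent instability criteria", {
  fr <- fixture("frank")
  rep1 <- sna_sampling(fr$network, fr$chiral, seed = 1, n_samples = 100)
  for (cs in rep1$confirmed) {
    st <- cs$state
    expect_lt(max(abs(ode_rhs(fr$network, st))), 1e-10)
    expect_equal(enantiomeric_gap(st, fr$chiral), 0)
    vd <- is_symmetry_breaking_state(fr$network, fr$chiral, st)
    expect_true(vd$breaking)
    expect_true(vd$oracle_breaking)
    expect_false(vd$marginal)
    # at unit concentrations the SNA matrix is the exact Jacobian, so the
    # confirmed eigenvalue matches the sampled coefficient sign
    expect_gt(cs$max_re, 0)
  }
})

test_that("identical seeds give identical reports", {
  fr <- fixture("frank")
  a <- sna_sampling(fr$network, fr$chiral, seed = 77, n_samples = 150)
  b <- sna_sampling(fr$network, fr$chiral, seed = 77, n_samples = 150)
  expect_identical(a, b)
  c <- sna_sampling(fr$network, fr$chiral, seed = 78, n_samples = 150)
  expect_false(identical(a$per_i[[1]]$samples, c$per_i[[1]]$samples))
})

test_that("an isolated irreversible chain has no steady currents", {
  net <- parse_network(c("pair L:D",
                         "L -> X | k1",
                         "D -> X | k1"))
  rep0 <- sna_sampling(net, seed = 1, n_samples = 10)
  expect_equal(rep0$verdict, "reject")
  expect_match(rep0$reason, "no positive steady-state currents")
})
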