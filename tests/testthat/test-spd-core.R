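test_that("matrix log and exp agree with closed forms and round-trip", {
  expect_equal(spd_logm(diag(3)), matrix(0, 3, 3))
  expect_equal(spd_logm(diag(c(exp(1), exp(2)))), diag(c(1, 2)))
  expect_equal(spd_expm(matrix(0, 3, 3)), diag(3))
  expect_equal(spd_expm(diag(c(1, 2))), diag(c(exp(1), exp(2))))

  for (s in 1:5) {
    S <- rand_spd_spread(4, seed = s)
    L <- spd_logm(S)
    expect_lt(frob(spd_expm(L) - S) / frob(S), 1e-8)
    expect_lt(frob(spd_logm(spd_expm(L)) - L) / max(frob(L), 1), 1e-8)
  }

  expect_error(spd_logm(matrix(1:4, 2)), "symmetric")
  expect_error(spd_logm(diag(c(1, -1))), "positive definite")
  expect_error(spd_expm(matrix(1:4, 2)), "symmetric")
})

test_that("geodesic distance satisfies the metric axioms", {
  S <- rand_spd(3, seed = 1)
  expect_equal(geodesic_distance(S, S), 0)
  expect_equal(geodesic_distance(diag(2), diag(c(exp(1), exp(1)))), sqrt(2))
  expect_error(geodesic_distance(diag(2), diag(3)), "mismatch")

  set.seed(42)
  for (i in 1:20) {
    A <- rand_spd(3)
    B <- rand_spd(3)
    expect_equal(geodesic_distance(A, B), geodesic_distance(B, A))
  }
  # triangle inequality and identity over random triples, both metrics
  for (metric in c("log_euclidean", "affine_invariant")) {
    set.seed(7)
    for (i in 1:30) {
      A <- rand_spd(3); B <- rand_spd(3); C <- rand_spd(3)
      dAB <- geodesic_distance(A, B, metric)
      dBC <- geodesic_distance(B, C, metric)
      dAC <- geodesic_distance(A, C, metric)
      expect_lte(dAC, dAB + dBC + 1e-10)
      expect_gt(dAB, 0)
    }
  }
})

test_that("Frechet means match their closed-form oracles", {
  A <- rand_spd(3, seed = 2)
  expect_equal(frechet_mean(list(A)), A)
  expect_equal(frechet_mean(list(diag(c(1, 1)), diag(c(exp(2), exp(2))))),
               diag(c(exp(1), exp(1))))

  # two-point affine-invariant mean equals the geodesic midpoint
  for (s in 1:5) {
    A <- rand_spd(4, seed = 10 + s)
    B <- rand_spd(4)
    sA <- spdstates:::.spd_sqrtm(A)
    iA <- spdstates:::.spd_isqrtm(A)
    mid <- sA %*% spdstates:::.spd_sqrtm(iA %*% B %*% iA) %*% sA
    M <- frechet_mean(list(A, B), metric = "affine_invariant")
    expect_lt(frob(M - mid) / frob(mid), 1e-7)
  }
  expect_error(frechet_mean(list()), "non-empty")
})

test_that("log-Euclidean mean minimises squared distances along the geodesic", {
  A <- rand_spd(3, seed = 5)
  B <- rand_spd(3)
  M <- frechet_mean(list(A, B))
  LA <- spd_logm(A); LB <- spd_logm(B)
  obj <- vapply(seq(0, 1, length.out = 101), function(t) {
    P <- spd_expm((1 - t) * LA + t * LB)
    geodesic_distance(P, A)^2 + geodesic_distance(P, B)^2
  }, numeric(1))
  expect_lte(geodesic_distance(M, A)^2 + geodesic_distance(M, B)^2,
             min(obj) + 1e-10)
})

test_that("parallel transport maps base points correctly", {
  X <- rand_spd(3, seed = 3)
  S <- rand_spd(3)
  expect_equal(parallel_transport(X, S, S), X, tolerance = 1e-10)
  expect_equal(parallel_transport(diag(c(2, 2)), diag(c(1, 1)), diag(c(4, 4))),
               diag(c(8, 8)))

  set.seed(11)
  for (i in 1:5) {
    src <- rand_spd(4); tgt <- rand_spd(4)
    # the subject mean lands exactly on the target mean
    expect_lt(frob(parallel_transport(src, src, tgt) - tgt) / frob(tgt), 1e-8)
    # E is a genuine square root of target %*% solve(source)
    E <- spdstates:::.transport_operator(src, tgt)
    expect_lt(frob(E %*% E - tgt %*% solve(src)) / frob(tgt %*% solve(src)),
              1e-8)
  }
  expect_error(parallel_transport(diag(2), matrix(1:4, 2), diag(2)))
})

test_that("transport preserves affine-invariant geometry (congruence invariance)", {
  set.seed(21)
  for (i in 1:10) {
    A <- rand_spd(3); B <- rand_spd(3)
    src <- rand_spd(3); tgt <- rand_spd(3)
    d0 <- geodesic_distance(A, B, "affine_invariant")
    d1 <- geodesic_distance(parallel_transport(A, src, tgt),
                            parallel_transport(B, src, tgt),
                            "affine_invariant")
    expect_lt(abs(d0 - d1) / d0, 1e-8)
  }
})

test_that("trajectory alignment centres every subject on the population mean", {
  A <- rand_spd(3, seed = 31)
  B <- rand_spd(3)
  trA <- spd_trajectory(rep(list(A), 4), subject_id = "a")
  trB <- spd_trajectory(rep(list(B), 4), subject_id = "b")
  al <- align_trajectories(list(trA, trB))
  M <- frechet_mean(list(A, B))
  expect_lt(frob(al$population_mean - M) / frob(M), 1e-8)
  for (tr in al$trajectories)
    for (X in tr$matrices) expect_lt(frob(X - M) / frob(M), 1e-8)

  # general trajectories: post-alignment subject means all equal the centre.
  # The congruence transport is exactly mean-equivariant under the
  # affine-invariant metric (the log-Euclidean mean is only approximately so).
  set.seed(32)
  trs <- lapply(1:3, function(m)
    spd_trajectory(lapply(1:5, function(i) rand_spd(3)),
                   subject_id = paste0("s", m)))
  al <- align_trajectories(trs, metric = "affine_invariant")
  for (tr in al$trajectories) {
    sm <- frechet_mean(tr$matrices, metric = "affine_invariant")
    expect_lt(frob(sm - al$population_mean) / frob(al$population_mean), 1e-6)
  }
})

test_that("trajectory and matrix text serialisation round-trips", {
  S <- rand_spd(4, seed = 41)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_spd_matrix(S, p)
  expect_equal(unname(read_spd_matrix(p)), unname(S), tolerance = 1e-12)

  expect_error(spd_trajectory(list()), "non-empty")
  expect_error(spd_trajectory(list(diag(2), diag(3))), "share a dimension")
  expect_error(spd_trajectory(list(diag(2), diag(2)), times = c(2, 1)),
               "increasing")
})
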