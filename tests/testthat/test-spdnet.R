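test_that("BiMap forward matches the bilinear oracle and preserves SPD", {
  X <- rand_spd(3, seed = 1)
  expect_equal(bimap_forward(diag(3), X), X)

  sel <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(bimap_forward(sel, diag(c(1, 2, 3))), diag(c(1, 2)))

  W <- init_semiorthogonal(2, 4, seed = 2)
  X4 <- rand_spd(4, seed = 3)
  out <- bimap_forward(W, X4)
  expect_equal(out, W %*% X4 %*% t(W), tolerance = 1e-12)
  expect_equal(out, t(out))
  expect_gt(min(eigen(out, only.values = TRUE)$values), 0)
  expect_error(bimap_forward(W, diag(3)), "mismatch")
})

test_that("ReEig rectifies the spectrum and is idempotent", {
  X <- rand_spd(3, seed = 4) + diag(3) # eigenvalues well above epsilon
  expect_equal(reeig_forward(X, 1e-4), X, tolerance = 1e-12)
  expect_equal(reeig_forward(diag(c(1, 1e-6)), 1e-4), diag(c(1, 1e-4)))

  set.seed(5)
  for (i in 1:50) {
    A <- matrix(rnorm(16), 4)
    X <- crossprod(A) / 10 # some near-zero eigenvalues
    r1 <- reeig_forward(X, 1e-3)
    expect_equal(reeig_forward(r1, 1e-3), r1, tolerance = 1e-10)
    expect_gte(min(eigen(r1, only.values = TRUE)$values), 1e-3 - 1e-12)
  }
})

test_that("semi-orthogonal initialisation is exact and deterministic", {
  W <- init_semiorthogonal(3, 3, seed = 6)
  expect_equal(abs(det(W)), 1, tolerance = 1e-10)

  W2 <- init_semiorthogonal(2, 5, seed = 7)
  expect_lt(max(abs(W2 %*% t(W2) - diag(2))), 1e-10)
  expect_identical(W2, init_semiorthogonal(2, 5, seed = 7))
  expect_false(identical(W2, init_semiorthogonal(2, 5, seed = 8)))
  expect_error(init_semiorthogonal(5, 2), "exceed")
})

test_that("network forward composes the layers and preserves structure", {
  # square orthogonal BiMap + tiny epsilon: congruence, eigenvalues kept
  m <- spdnet_model(c(4, 4), epsilon = 1e-8, seed = 9)
  X <- rand_spd(4, seed = 10)
  tr <- spd_trajectory(list(X))
  out <- spdnet_forward(m, tr)$matrices[[1]]
  expect_equal(sort(eigen(out, only.values = TRUE)$values),
               sort(eigen(X, only.values = TRUE)$values), tolerance = 1e-8)

  # one 3->2 layer equals the bimap-then-reeig oracle
  m2 <- spdnet_model(c(3, 2), epsilon = 1e-4, seed = 11)
  X3 <- rand_spd(3, seed = 12)
  out2 <- spdnet_forward(m2, spd_trajectory(list(X3)))$matrices[[1]]
  expect_equal(out2, reeig_forward(bimap_forward(m2$W[[1]], X3), 1e-4),
               tolerance = 1e-12)

  traj <- spd_trajectory(lapply(1:6, function(i) rand_spd(4)), subject_id = "x")
  m3 <- spdnet_model(c(4, 3, 2), seed = 13)
  expect_length(spdnet_forward(m3, traj)$matrices, 6)
})

test_that("analytic layer gradients match central finite differences", {
  set.seed(14)
  U <- qr.Q(qr(matrix(rnorm(16), 4)))
  X <- U %*% (c(4, 2.2, 1.1, 0.3) * t(U)) # well-separated eigenvalues
  X <- (X + t(X)) / 2
  G <- matrix(rnorm(16), 4); G <- (G + t(G)) / 2
  h <- 1e-6

  fd_grad <- function(f) {
    out <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      Xp <- X; Xp[i, j] <- Xp[i, j] + h; Xp <- (Xp + t(Xp)) / 2 * 0 + Xp
      Xm <- X; Xm[i, j] <- Xm[i, j] - h
      out[i, j] <- sum(G * (f(Xp) - f(Xm))) / (2 * h)
    }
    (out + t(out)) / 2 # pull back to the symmetric parameterisation
  }

  eps <- 1
  gr <- spdstates:::.reeig_backward(X, G, eps)
  gr_fd <- fd_grad(function(S) reeig_forward((S + t(S)) / 2, eps))
  expect_lt(frob(gr - gr_fd) / frob(gr_fd), 1e-4)

  gl <- spdstates:::.logm_backward(X, G)
  gl_fd <- fd_grad(function(S) spd_logm((S + t(S)) / 2))
  expect_lt(frob(gl - gl_fd) / frob(gl_fd), 1e-4)

  # BiMap weight gradient
  W <- init_semiorthogonal(2, 4, seed = 15)
  G2 <- matrix(rnorm(4), 2); G2 <- (G2 + t(G2)) / 2
  gw <- 2 * G2 %*% W %*% X
  gw_fd <- matrix(0, 2, 4)
  for (i in 1:2) for (j in 1:4) {
    Wp <- W; Wp[i, j] <- Wp[i, j] + h
    Wm <- W; Wm[i, j] <- Wm[i, j] - h
    gw_fd[i, j] <- sum(G2 * (bimap_forward(Wp, X) - bimap_forward(Wm, X))) /
      (2 * h)
  }
  expect_lt(frob(gw - gw_fd) / frob(gw_fd), 1e-4)
})

test_that("full-pipeline analytic gradient matches finite differences", {
  set.seed(16)
  mats <- lapply(1:6, function(i) rand_spd(5))
  traj <- spd_trajectory(mats)
  model <- spdnet_model(c(5, 3), seed = 17)
  ms <- msrnn_params(c(0.6, 0.9), bandwidth = "absolute")
  labels <- c(1, 1, 1, 2, 2, 2)
  lossfun <- function(model, ms) {
    st <- spdstates:::.pipeline_forward(model, ms, traj)
    spdstates:::.contrastive_on_rows(st$L, labels, 0.5, want_grad = FALSE)$loss
  }
  st <- spdstates:::.pipeline_forward(model, ms, traj)
  cl <- spdstates:::.contrastive_on_rows(st$L, labels, 0.5)
  bk <- spdstates:::.pipeline_backward(model, ms, st, cl$grad)
  h <- 1e-6
  for (idx in list(c(1, 1), c(2, 4), c(3, 5))) {
    mp <- model; mp$W[[1]][idx[1], idx[2]] <- mp$W[[1]][idx[1], idx[2]] + h
    mm <- model; mm$W[[1]][idx[1], idx[2]] <- mm$W[[1]][idx[1], idx[2]] - h
    fd <- (lossfun(mp, ms) - lossfun(mm, ms)) / (2 * h)
    expect_lt(abs(fd - bk$gW[[1]][idx[1], idx[2]]) / max(abs(fd), 1e-8), 1e-4)
  }
  for (e in 1:2) {
    msp <- ms; msp$sigmas[e] <- msp$sigmas[e] + h
    msm <- ms; msm$sigmas[e] <- msm$sigmas[e] - h
    fd <- (lossfun(model, msp) - lossfun(model, msm)) / (2 * h)
    expect_lt(abs(fd - bk$gsigma[e]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("the batched compiled backward agrees with the reference path", {
  set.seed(30)
  mats <- lapply(1:5, function(i) rand_spd(6))
  model <- spdnet_model(c(6, 4, 3), seed = 31)
  arr <- array(unlist(mats), dim = c(6, 6, 5))
  fwd <- spdstates:::.spdnet_batch_forward_cpp(arr, model$W, model$epsilon)
  gL <- matrix(rnorm(5 * 9), 5, 9)
  gW_cpp <- spdstates:::.spdnet_batch_backward_cpp(fwd, model$W,
                                                   model$epsilon, gL)
  gW_ref <- lapply(model$W, function(W) matrix(0, nrow(W), ncol(W)))
  for (t in 1:5) {
    fw <- spdstates:::.spdnet_forward_one(model, mats[[t]])
    expect_equal(fw$out, fwd$out[, , t], tolerance = 1e-10)
    Gt <- spdstates:::.sym(matrix(gL[t, ], 3, 3))
    Gv <- spdstates:::.logm_backward(fw$out, Gt)
    bk <- spdstates:::.spdnet_backward_one(model, fw$cache, Gv)
    for (k in 1:2) gW_ref[[k]] <- gW_ref[[k]] + bk$gW[[k]]
  }
  for (k in 1:2)
    expect_lt(frob(gW_cpp[[k]] - gW_ref[[k]]) / frob(gW_ref[[k]]), 1e-8)
})

test_that("Stiefel steps keep the weights semi-orthogonal", {
  m <- spdnet_model(c(6, 3), seed = 18)
  W0 <- m$W[[1]]
  expect_equal(stiefel_step(m, list(matrix(0, 3, 6)), 0.01)$W[[1]], W0)

  # gradient normal to the manifold: retraction restores orthogonality exactly
  S <- rand_spd(6, seed = 19)
  m2 <- stiefel_step(m, list(m$W[[1]] %*% S), 0.05)
  expect_lt(max(abs(m2$W[[1]] %*% t(m2$W[[1]]) - diag(3))), 1e-10)

  set.seed(20)
  drift <- 0
  for (i in 1:100) {
    g <- list(matrix(rnorm(18), 3, 6))
    m <- stiefel_step(m, g, 0.01)
    drift <- max(drift, max(abs(m$W[[1]] %*% t(m$W[[1]]) - diag(3))))
  }
  expect_lt(drift, 1e-6)
})

test_that("model checkpoints round-trip through text files", {
  m <- spdnet_model(c(5, 4, 3), epsilon = c(1e-4, 1e-3), seed = 21)
  d <- withr::local_tempdir()
  save_spdnet(m, d)
  m2 <- load_spdnet(d)
  expect_equal(m2$dims, m$dims)
  expect_equal(m2$epsilon, m$epsilon)
  for (k in 1:2) expect_equal(m2$W[[k]], m$W[[k]], tolerance = 1e-12)
})
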