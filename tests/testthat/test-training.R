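test_that("similarity transform of distances matches the closed form", {
  expect_equal(pairwise_similarity(0), 1)
  expect_equal(pairwise_similarity(1), 0.5)
  expect_equal(pairwise_similarity(3), 0.25)
  expect_equal(pairwise_similarity(c(0, 1, 3)), c(1, 0.5, 0.25))
  expect_error(pairwise_similarity(-0.1), "non-negative")
})

test_that("contrastive loss matches hand-computed pair values", {
  S <- rand_spd(2, seed = 1)
  same4 <- spd_trajectory(rep(list(S), 4))
  expect_equal(contrastive_loss(same4, rep(1L, 4)), 0)

  # two windows at geodesic distance 3 with different labels, margin 0.5:
  # d = 0.25, both ordered-pair terms clip to zero
  c_ <- 3 / sqrt(2)
  A <- diag(c(1, 1)); B <- diag(c(exp(c_), exp(c_)))
  tr <- spd_trajectory(list(A, B))
  expect_equal(geodesic_distance(A, B), 3)
  expect_equal(contrastive_loss(tr, c(1L, 2L), alpha = 0.5), 0)

  # same labels at distance 1: each ordered pair contributes 1 - 0.5
  c1 <- 1 / sqrt(2)
  B1 <- diag(c(exp(c1), exp(c1)))
  tr1 <- spd_trajectory(list(A, B1))
  expect_equal(contrastive_loss(tr1, c(1L, 1L), alpha = 0.5), 1)

  # margin boundary: different labels at distance 1 give d = 0.5 = alpha
  expect_equal(contrastive_loss(tr1, c(1L, 2L), alpha = 0.5), 0)
  expect_gt(contrastive_loss(tr1, c(1L, 2L), alpha = 0.4), 0)
  expect_error(contrastive_loss(tr1, c(1L, 1L, 2L)), "length")
})

test_that("the loss vanishes exactly on a perfectly arranged configuration", {
  # same-label points coincide; different-label pairs have d <= alpha
  A <- diag(c(1, 1)); B <- diag(c(exp(2), exp(2)))
  tr <- spd_trajectory(list(A, A, B, B))
  labels <- c(1L, 1L, 2L, 2L)
  expect_equal(contrastive_loss(tr, labels, alpha = 0.5), 0)
  # perturb one same-label point: loss becomes positive
  tr2 <- spd_trajectory(list(A, diag(c(exp(0.1), 1)), B, B))
  expect_gt(contrastive_loss(tr2, labels, alpha = 0.5), 0)
})

test_that("subsampled pair loss estimates the full pair sum", {
  set.seed(2)
  mats <- lapply(1:30, function(i) rand_spd(3))
  labels <- rep(1:3, each = 10)
  L <- spdstates:::.traj_log_rows(spd_trajectory(mats))
  full <- spdstates:::.contrastive_on_rows(L, labels, 0.5, want_grad = FALSE)$loss
  set.seed(3)
  t_ <- sample.int(30, 20000, replace = TRUE)
  s_ <- sample.int(29, 20000, replace = TRUE)
  s_ <- ifelse(s_ >= t_, s_ + 1L, s_)
  sub <- spdstates:::.contrastive_on_rows(L, labels, 0.5,
                                          pairs = cbind(t_, s_))
  expect_lt(abs(sub$loss - full) / full, 0.05)
  expect_equal(dim(sub$grad), dim(L))
})

test_that("training is deterministic, inert at zero epochs, and reduces loss", {
  d <- toy_design(seed = 4, durations = rep(40L, 2L), window = 11L)
  d$states <- d$states[1:2]
  sim <- simulate_series(sim_design(n_regions = 10, durations = rep(40L, 2L),
                                    window = 11L, seed = 4))
  traj <- align_trajectories(list(sliding_window_fc(sim$series, 11)))$trajectories[[1]]
  truth <- window_truth_labels(sim$labels, traj$times)
  model <- spdnet_model(c(10, 6, 4), seed = 5)
  ms <- msrnn_params(rep(0.5, 3))
  data <- list(list(traj = traj, truth = truth))

  cfg0 <- loss_config(epochs = 0, seed = 6, label_source = "known_schedule")
  fit0 <- train_geometric(model, ms, data, cfg0)
  expect_identical(fit0$model$W, model$W)
  expect_identical(fit0$ms$sigmas, ms$sigmas)
  expect_length(fit0$history, 0)

  cfg <- loss_config(epochs = 8, seed = 6, label_source = "known_schedule")
  fit1 <- train_geometric(model, ms, data, cfg)
  fit2 <- train_geometric(model, ms, data, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_lt(fit1$history[8], fit1$history[1])
  expect_true(all(fit1$ms$sigmas > 0))
  # weights stay on the Stiefel manifold throughout
  for (W in fit1$model$W)
    expect_lt(max(abs(W %*% t(W) - diag(nrow(W)))), 1e-8)

  # self-supervised label source runs end to end
  cfg_ss <- loss_config(epochs = 2, seed = 7, label_source = "ms_grouping")
  fit_ss <- train_geometric(model, ms, list(list(traj = traj)), cfg_ss)
  expect_length(fit_ss$history, 2)
  expect_error(train_geometric(model, ms, list(list(traj = traj)),
                               loss_config(label_source = "known_schedule")),
               "truth")
})

test_that("training improves held-out purity over the seeded initialisation", {
  res <- vapply(1:5, function(s) {
    mk <- function(sd) simulate_series(sim_design(durations = rep(50L, 4L),
                                                  window = 15L, seed = sd))
    train <- list(mk(9000 + s))
    test <- mk(9100 + s)
    cfg_tr <- loss_config(epochs = 25, seed = s, label_source = "known_schedule")
    det_tr <- fit_state_detector(train, window = 15L, cfg = cfg_tr)
    cfg_un <- loss_config(epochs = 0, seed = s, label_source = "known_schedule")
    det_un <- fit_state_detector(train, window = 15L, cfg = cfg_un)
    c(predict(det_tr, test$series, truth = test$labels)$purity,
      predict(det_un, test$series, truth = test$labels)$purity)
  }, numeric(2))
  expect_gt(mean(res[1, ]), mean(res[2, ]))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(loss_config(alpha = 0), "alpha")
  expect_error(loss_config(alpha = 1.2), "alpha")
  expect_error(loss_config(lr = -1), "lr")
  expect_s3_class(loss_config(), "loss_config")
})
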