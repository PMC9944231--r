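test_that("the clamped linear activation matches its piecewise definition", {
  expect_identical(relu_clamp(1.5), 1)
  expect_identical(relu_clamp(-2), -1)
  expect_identical(relu_clamp(0.3), 0.3)
  expect_identical(relu_clamp(c(-3, -0.5, 0, 2)), c(-1, -0.5, 0, 1))
})

test_that("a node update is the clamped response to the current state", {
  amn <- default_amn()
  zero <- amn
  zero$W[] <- 0
  zero$b <- rep(-0.6, 13)
  s <- update_node(zero, rep(0, 13), 5)
  expect_identical(s[5], -0.6)            # bias-only response
  big <- zero; big$b <- rep(2, 13)
  expect_identical(update_node(big, rep(0, 13), 1)[1], 1)  # clamped
})

test_that("the trained attractor is a fixed point of the dynamics", {
  amn <- default_amn()
  traj <- restore_pattern(amn, amn$attractor)
  expect_identical(nrow(traj), 1L)        # no perturbation: trajectory of 1
  s1 <- amn$attractor
  for (i in 1:13) s1 <- update_node(amn, s1, i)
  expect_lt(max(abs(s1 - amn$attractor)), 1e-6)
})

test_that("perturbed patterns are recalled to the attractor", {
  amn <- default_amn()
  set.seed(5)
  # one node nudged by 8%
  s <- amn$attractor; s[4] <- s[4] * 1.08
  traj <- restore_pattern(amn, s)
  expect_lt(max(abs(traj[nrow(traj), ] - amn$attractor)), 1e-6)
  # all nodes shifted by up to +/-10%
  for (i in 1:25) {
    s <- amn$attractor * (1 + runif(13, -0.1, 0.1))
    traj <- restore_pattern(amn, s)
    expect_lt(max(abs(traj[nrow(traj), ] - amn$attractor)), 1e-6)
  }
  # deviation from the attractor never grows along the trajectory
  s <- amn$attractor * (1 + runif(13, -0.1, 0.1))
  traj <- restore_pattern(amn, s)
  dev <- apply(traj, 1, function(r) max(abs(r - amn$attractor)))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("training converges across random initialisations and recalls the pattern", {
  w <- default_worm()
  for (s in 1:5) {
    amn <- train_amn(w, amn_config(seed = s))
    expect_true(amn$trained)
    got <- predict(amn, amn$attractor * (1 + 0.1 * sin(1:13 + s)))
    expect_lt(max(abs(got - amn$attractor)), 1e-6)
  }
})

test_that("directional sign structure survives training", {
  amn <- default_amn()
  expect_true(all(amn$W[amn$topology$sign > 0] >= 0))  # head-to-tail activates
  expect_true(all(amn$W[amn$topology$sign < 0] <= 0))  # tail-to-head inhibits
  expect_true(all(amn$W[amn$topology$sign == 0] == 0)) # sparse chain only
})

test_that("retraining after repair touches only links of rebuilt nodes", {
  amn <- default_amn()
  w <- default_worm()
  expect_identical(retrain_after_repair(amn, w), amn)   # nothing rebuilt
  re <- retrain_after_repair(amn, w, rebuilt = 13L)
  incident <- outer(1:13, 1:13, function(i, j) i == 13 | j == 13)
  expect_equal(re$W[!incident], amn$W[!incident], tolerance = 1e-4)
  expect_true(all(re$W[re$topology$sign > 0] >= 0))
  expect_lt(max(abs(predict(re) - amn$attractor)), 1e-6)
  # a worm with unhealed anatomy is rejected
  expect_error(retrain_after_repair(amn, kill_cells(w, cbind(12L, 72L)), 13L),
               "not fully repaired")
})

test_that("simulated training patterns respect the stated noise regimes", {
  amn <- default_amn()
  pats <- simulate(amn, nsim = 200, seed = 9)
  expect_identical(dim(pats), c(200L, 13L))
  rel <- abs(sweep(pats, 2, amn$attractor, "/") - 1)
  normal <- pats[seq(1, 200, by = 2), , drop = FALSE]
  rel_n <- abs(sweep(normal, 2, amn$attractor, "/") - 1)
  expect_lt(max(rel_n), 0.10 + 1e-12)     # normal regime bounded at 10%
  expect_true(any(rel > 0.10))            # damage regime exceeds it
  expect_true(any(pats == 0))             # destroyed nodes appear
})
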