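test_that("voltage standardization encodes presence of hyperpolarized neighbours", {
  expect_identical(standardize_inputs(c(-0.8, -0.5)), c(1L, 1L))
  expect_identical(standardize_inputs(c(-0.8, NA, -0.5)), c(1L, 0L, 1L))
  expect_identical(standardize_inputs(c(NA, NA)), c(0L, 0L))
  expect_error(standardize_inputs(c(-0.8, 0.2)), "hyperpolarized")
  expect_error(standardize_inputs(c(-0.8)), "between 2 and 4")
})

test_that("each trained motif computes the AND of its inputs exhaustively", {
  for (kind in c("corner", "border", "interior")) {
    m <- train_motif(kind)
    X <- as.matrix(expand.grid(rep(list(0:1), m$k)))
    out <- apply(X, 1, function(x) apply_motif(m, x))
    expect_identical(out, as.integer(rowSums(X) == m$k),
                     label = paste("truth table of", kind))
  }
})

test_that("motif training is reproducible and robust to the random start", {
  m1 <- train_motif("interior", motif_config(seed = 42))
  m2 <- train_motif("interior", motif_config(seed = 42))
  expect_identical(m1$w, m2$w)
  expect_identical(m1$b, m2$b)
  # different seeds may give different weights but the same function
  for (s in 1:5) {
    m <- train_motif("border", motif_config(seed = s))
    X <- as.matrix(expand.grid(rep(list(0:1), 3)))
    expect_identical(apply(X, 1, function(x) apply_motif(m, x)),
                     as.integer(rowSums(X) == 3))
  }
})

test_that("motif application validates its inputs", {
  m <- train_motif("corner")
  expect_error(apply_motif(m, c(1, 1, 1)), "expects 2 inputs")
  expect_identical(apply_motif(m, c(1, 1)), 1L)
  expect_identical(apply_motif(m, c(0, 0)), 0L)
})
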