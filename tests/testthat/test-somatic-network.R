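test_that("sub-threshold voltage changes read as normal, >=10% as damage", {
  w <- default_worm()
  w9 <- w; w9$voltage[w9$alive] <- w9$home_voltage[w9$alive] * (1 - 0.09)
  expect_identical(detect_change(w9), "normal")
  w12 <- w; w12$voltage[12, 72] <- w12$home_voltage[12, 72] * (1 - 0.12)
  expect_identical(detect_change(w12), "damage")
  w10 <- w; w10$voltage[12, 72] <- w10$home_voltage[12, 72] * (1 - 0.10)
  expect_identical(detect_change(w10), "damage")  # boundary is damage
  expect_identical(detect_change(kill_cells(w, cbind(12L, 72L))), "damage")
})

test_that("increasing a fractional change never flips damage back to normal", {
  w <- default_worm()
  for (f in c(0.02, 0.05, 0.09, 0.11, 0.2, 0.5)) {
    wf <- w
    wf$voltage[13, 40] <- wf$home_voltage[13, 40] * (1 - f)
    verdict <- detect_change(wf)
    expect_identical(verdict, if (f >= 0.10) "damage" else "normal")
  }
})

test_that("one interior dead cell yields the four neighbouring border cells", {
  w <- kill_cells(default_worm(), cbind(12L, 72L))
  b <- find_somatic_border(w)
  expect_identical(nrow(b$cells), 4L)
  expect_setequal(paste(b$cells[, 1], b$cells[, 2]),
                  c("11 72", "13 72", "12 71", "12 73"))
  expect_true(all(b$worm$status[b$cells] == "border"))
})

test_that("an intact worm has an empty damage border", {
  b <- find_somatic_border(default_worm())
  expect_identical(nrow(b$cells), 0L)
})

test_that("motif-detected border equals the adjacency oracle on random ablations", {
  w0 <- default_worm()
  set.seed(7)
  for (rep in 1:20) {
    inside <- which(w0$original_mask)
    cells <- arrayInd(sample(inside, 50), dim(w0$alive))
    w <- kill_cells(w0, cells)
    got <- find_somatic_border(w)$cells
    want <- oracle_somatic_border(w)
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }
})

test_that("damage signals reach the stem cells of the touched blocks", {
  w0 <- default_worm()
  # mid-block cell: one affected stem (its own block)
  w <- kill_cells(w0, cbind(12L, 72L))
  aff <- propagate_to_stem(w, find_somatic_border(w))
  expect_length(aff, 1L)
  expect_identical(unname(as.integer(
    w0$stems[w0$stems$id == aff, c("brow", "bcol")])), c(3L, 15L))
  # block-edge cell: border cell lands in the adjacent block -> two stems
  w2 <- kill_cells(w0, cbind(11L, 72L))
  expect_length(propagate_to_stem(w2, find_somatic_border(w2)), 2L)
  # no damage -> no affected stems
  expect_length(propagate_to_stem(w0, find_somatic_border(w0)), 0L)
})
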