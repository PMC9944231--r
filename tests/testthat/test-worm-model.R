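test_that("default worm reproduces the structural constants of the body plan", {
  w <- default_worm()
  s <- worm_summary(w)
  expect_identical(s$somatic_alive, 3750L)
  expect_identical(s$stem_alive, 150L)
  expect_identical(s$n_nodes, 13L)
  expect_equal(s$mean_cells_per_node, 300)
  expect_equal(round(s$stem_percent_of_total), 4)
  expect_equal(unname(s$AR), c(1, 3, 1))
  expect_equal(unname(s$n_corners), c(3L, 4L, 3L))
  # 9 body nodes of 12 blocks each; head/tail nodes slightly different
  expect_equal(s$stem_per_node[3:11], rep(12L, 9))
  expect_equal(sum(s$stem_per_node), 150L)
  expect_equal(sum(s$node_cell_counts), 3900L)
})

test_that("every cell belongs to exactly one block, tissue, and node", {
  w <- default_worm()
  inside <- w$original_mask
  expect_true(all(!is.na(w$tissue_cell[inside])))
  expect_true(all(!is.na(w$node_cell[inside])))
  expect_true(all(is.na(w$tissue_cell[!inside])))
  expect_true(all(is.na(w$node_cell[!inside])))
  # tissue masks are disjoint and tile the worm (block level)
  expect_identical(sum(w$block_mask), 150L)
  expect_identical(sum(table(w$tissue_block)), 150L)
  expect_equal(as.vector(table(w$tissue_block)[c("head", "body", "tail")]),
               c(21L, 108L, 21L))
  # one stem per block, at the block centre
  expect_identical(nrow(w$stems), 150L)
  expect_true(all(w$stems$row %% w$config$block_size == 3))
  expect_false(any(duplicated(w$stems[, c("brow", "bcol")])))
})

test_that("homeostatic gradient is hyperpolarized and strictly monotone", {
  w <- default_worm()
  v <- w$node_voltages
  expect_true(all(v < 0))
  expect_true(all(diff(abs(v)) < 0))
  # every cell carries its node's voltage
  for (k in c(1L, 7L, 13L)) {
    sel <- !is.na(w$node_cell) & w$node_cell == k
    expect_true(all(w$voltage[sel] == v[k]))
  }
  expect_true(all(abs(w$voltage[w$node_cell == 1 & !is.na(w$node_cell)]) ==
                    abs(v[1])))
})

test_that("bioelectric pattern assignment rejects invalid gradients", {
  w <- default_worm()
  expect_error(assign_bioelectric_pattern(w, rep(-0.5, 13)), "monotone")
  expect_error(assign_bioelectric_pattern(w, seq(0.95, 0.35, length.out = 13)),
               "negative")
  expect_error(assign_bioelectric_pattern(w, seq(-0.35, -0.95, length.out = 13)),
               "monotone")
  expect_error(assign_bioelectric_pattern(w, c(-0.9, -0.8)), "13")
})

test_that("invalid geometry configurations name the violated invariant", {
  expect_error(worm_config(taper = c(6, 5, 4, 3, 2)), "corners")
  expect_error(worm_config(taper = c(5, 4, 3, 2, 1)), "AR")
  expect_error(worm_config(node_blocks_body = 11), "divisible|node")
  expect_error(worm_config(head_voltage = -0.3, tail_voltage = -0.9),
               "head to tail")
})

test_that("summary flags any departure from the original anatomy", {
  w <- default_worm()
  expect_true(worm_summary(w)$matches_original)
  w2 <- kill_cells(w, cbind(12L, 72L))
  expect_false(worm_summary(w2)$matches_original)
})
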