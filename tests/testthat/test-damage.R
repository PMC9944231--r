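test_that("voltage perturbation is seeded, bounded, and validates inputs", {
  w <- default_worm()
  p1 <- perturb_voltage(w, "all", 0.1, seed = 3)
  p2 <- perturb_voltage(w, "all", 0.1, seed = 3)
  expect_identical(p1$voltage, p2$voltage)
  rel <- abs(p1$voltage[p1$alive] / w$voltage[w$alive] - 1)
  expect_true(all(rel < 0.1))
  expect_error(perturb_voltage(w, "all", 0), "\\(0, 1\\]")
  wd <- kill_cells(w, cbind(12L, 72L))
  expect_error(perturb_voltage(wd, cbind(12L, 72L), 0.1), "dead")
})

test_that("killing cells depolarizes the border and is idempotent", {
  w <- default_worm()
  w1 <- kill_cells(w, cbind(12L, 72L))
  expect_false(w1$alive[12, 72])
  expect_true(is.na(w1$voltage[12, 72]))
  # neighbours lose 15% of their voltage magnitude (electrolyte release)
  expect_equal(w1$voltage[11, 72], w1$home_voltage[11, 72] * 0.85)
  expect_identical(w1$status[11, 72], "affected")
  w2 <- kill_cells(w1, cbind(12L, 72L))
  expect_identical(w2$alive, w1$alive)
  expect_identical(w2$voltage, w1$voltage)
  expect_error(kill_cells(w, cbind(30L, 150L)), "outside")
})

test_that("region kills take stems with their centre cells; empty regions are no-ops", {
  w <- default_worm()
  w1 <- kill_region(w, c(11, 15, 71, 75))    # one full block
  expect_identical(sum(w$alive) - sum(w1$alive), 25L)
  expect_identical(sum(!w1$stems$alive), 1L)
  w2 <- kill_region(w, c(26, 30, 141, 150))  # below the tail taper
  expect_identical(w2$alive, w$alive)
  w3 <- kill_stem(w, cbind(3L, 15L))
  expect_identical(sum(!w3$stems$alive), 1L)
  expect_identical(sum(w3$alive), sum(w$alive))
})

test_that("cut fragments partition the worm's cells exactly", {
  w <- default_worm()
  frags <- cut_worm(w, list(list(axis = "vertical", after = 30),
                            list(axis = "vertical", after = 120)))
  expect_length(frags, 3L)
  tot <- Reduce(`+`, lapply(frags, function(f) f$alive))
  expect_identical(tot == 1L, w$alive)     # each cell in exactly one fragment
  stem_tot <- Reduce(`+`, lapply(frags, function(f) as.integer(f$stems$alive)))
  expect_true(all(stem_tot == 1L))
  expect_identical(vapply(frags, function(f) sum(f$alive), 1L),
                   c(525L, 2700L, 525L))
})

test_that("degenerate and invalid cut planes are handled", {
  w <- default_worm()
  expect_length(cut_worm(w, list(axis = "vertical", after = 0)), 1L)
  expect_error(cut_worm(w, list(axis = "vertical", after = 999)), "outside")
  expect_warning(cut_worm(w, list(axis = "vertical", after = 73)),
                 "block boundary")
})

test_that("all seven documented damage cases are emitted as scenarios", {
  w <- default_worm()
  expect_identical(fixture_cases(), c("1a", "1b", "2a", "2b", "3a", "3b", "4"))
  for (case in fixture_cases()) {
    sc <- fixture_scenario(case, w)
    expect_s3_class(sc, "scenario")
  }
  # case 2a removes exactly 1 stem + 24 somatic cells
  w2a <- apply_scenario(w, fixture_scenario("2a", w))
  expect_identical(sum(w$alive) - sum(w2a$alive), 24L)
  expect_identical(sum(!w2a$stems$alive), 1L)
  # case 2b removes a node's 12 stems + 288 somatic cells
  w2b <- apply_scenario(w, fixture_scenario("2b", w))
  expect_identical(sum(w$alive) - sum(w2b$alive), 288L)
  expect_identical(sum(!w2b$stems$alive), 12L)
})
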