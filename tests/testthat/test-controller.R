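test_that("normal perturbations run stages 2-5-1 without regeneration", {
  w <- perturb_voltage(default_worm(), "all", 0.08, seed = 3)
  res <- run_cycle(w, default_amn())
  expect_identical(stage_sequence(res$log), c(2L, 5L, 1L))
  expect_identical(nrow(res$regen), 0L)
  expect_true(matches_homeostasis(res$worm))
})

test_that("an unperturbed worm only monitors", {
  res <- run_cycle(default_worm(), default_amn())
  expect_identical(stage_sequence(res$log), 1L)
})

test_that("single-cell damage runs the full damage mode and restores everything", {
  w <- apply_scenario(default_worm(), fixture_scenario("1a", default_worm()))
  res <- run_cycle(w, default_amn())
  expect_identical(stage_sequence(res$log), c(2L, 3L, 4L, 5L, 1L))
  expect_identical(nrow(res$regen), 1L)
  expect_identical(res$regen$type, "somatic")
  # the regenerated cell carries the producing stem cell's voltage
  prod <- default_worm()$stems[res$regen$producer, ]
  expect_identical(res$regen$voltage, prod$voltage)
  expect_true(matches_homeostasis(res$worm))
})

test_that("stem-and-tissue damage regenerates 1 stem plus 24 somatic cells", {
  w <- apply_scenario(default_worm(), fixture_scenario("2a", default_worm()))
  res <- run_cycle(w, default_amn())
  expect_identical(stage_sequence(res$log), c(2L, 3L, 4L, 5L, 1L))
  expect_identical(sum(res$regen$type == "stem"), 1L)
  expect_identical(sum(res$regen$type == "somatic"), 24L)
  # the new stem takes its producer's voltage
  new_stem <- res$regen[res$regen$type == "stem", ]
  expect_identical(new_stem$voltage,
                   default_worm()$stems$voltage[new_stem$producer])
  expect_true(matches_homeostasis(res$worm))
})

test_that("scattered multi-cell damage and whole-node lesions recover fully", {
  for (case in c("1b", "2b")) {
    res <- run_until_homeostasis(default_worm(), default_amn(),
                                 fixture_scenario(case, default_worm()))
    expect_length(res$fragments, 1L)
    expect_true(res$fragments[[1]]$recovered, label = paste("case", case))
  }
})

test_that("dead-cell count never increases during repair", {
  w <- apply_scenario(default_worm(), fixture_scenario("2b", default_worm()))
  before <- sum(w$original_mask & !w$alive)
  res <- run_cycle(w, default_amn())
  # every stage-4 event adds cells; the log records only non-negative counts
  s4 <- res$log[res$log$stage == 4L, ]
  expect_true(all(s4$n_regen >= 0))
  expect_identical(sum(res$worm$original_mask & !res$worm$alive), 0L)
  expect_gte(before, 1L)
})

test_that("each fragment of the triple cut regenerates a complete worm", {
  res <- run_until_homeostasis(default_worm(), default_amn(),
                               fixture_scenario("3a", default_worm()))
  expect_length(res$fragments, 3L)
  for (f in res$fragments) {
    s <- worm_summary(f$worm)
    expect_identical(s$somatic_alive, 3750L)
    expect_identical(s$stem_alive, 150L)
    expect_equal(unname(s$AR), c(1, 3, 1))
    expect_equal(unname(s$n_corners), c(3L, 4L, 3L))
    expect_true(f$recovered)
    expect_identical(stage_sequence(f$log), c(2L, 3L, 4L, 5L, 1L))
  }
})

test_that("composite damage (amputation plus interior lesion) recovers fully", {
  res <- run_until_homeostasis(default_worm(), default_amn(),
                               fixture_scenario("3b", default_worm()))
  expect_length(res$fragments, 2L)
  expect_true(all(vapply(res$fragments, `[[`, logical(1), "recovered")))
})

test_that("identical inputs give byte-identical stage logs", {
  run_once <- function() {
    res <- run_until_homeostasis(default_worm(), default_amn(),
                                 fixture_scenario("2a", default_worm()))
    tf <- tempfile(fileext = ".jsonl")
    write_stage_log(res$fragments[[1]]$log, tf)
    on.exit(unlink(tf))
    readLines(tf)
  }
  expect_identical(run_once(), run_once())
})

test_that("whole-tissue regrowth respects the bioelectric gradient while growing", {
  w <- default_worm()
  frags <- apply_scenario(w, fixture_scenario("3a", w))
  head_frag <- frags[[1]]
  rep <- assess_damage(head_frag)
  grown <- regenerate_tissue(head_frag, rep$missing_tissues)
  regen <- attr(grown, "regen")
  stems <- regen[regen$type == "stem", ]
  # new stem voltages decrease in magnitude towards the tail (flat within
  # a node, since voltage is constant inside a node)
  mean_by_col <- tapply(abs(stems$voltage), stems$col, mean)
  mean_by_col <- mean_by_col[order(as.numeric(names(mean_by_col)))]
  expect_true(all(diff(mean_by_col) <= 1e-12))
  expect_lt(mean_by_col[length(mean_by_col)], mean_by_col[1])
  expect_gt(attr(grown, "ticks"), 1L)      # staged, not instantaneous
  expect_true(matches_anatomy(grown))
})
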