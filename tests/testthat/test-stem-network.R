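stem_pipeline <- function(w) {
  sb <- find_somatic_border(w)
  aff <- propagate_to_stem(w, sb)
  stb <- find_stem_border(w, aff)
  list(sb = sb, stb = stb, report = classify_damage(w, stb, sb))
}

test_that("a lost stem with its tissue raises the four nearest stems as border", {
  w <- apply_scenario(default_worm(), fixture_scenario("2a", default_worm()))
  p <- stem_pipeline(w)
  expect_length(p$stb$ids, 4L)
  st <- w$stems[w$stems$id %in% p$stb$ids, ]
  expect_setequal(paste(st$brow, st$bcol), c("2 15", "4 15", "3 14", "3 16"))
  expect_identical(p$report$category, "local_enclosed")
  expect_true(all(p$report$primitives_matched))
})

test_that("an intact worm has an empty stem border", {
  p <- stem_pipeline(default_worm())
  expect_length(p$stb$ids, 0L)
  expect_identical(p$report$category, "none")
})

test_that("a single dead somatic cell leaves the stem layer undamaged", {
  w <- apply_scenario(default_worm(), fixture_scenario("1a", default_worm()))
  p <- stem_pipeline(w)
  expect_length(p$stb$ids, 0L)
  expect_identical(p$report$category, "no_stem_damage")
})

test_that("stem border matches the stem-lattice adjacency oracle under random stem loss", {
  w0 <- default_worm()
  set.seed(11)
  for (rep in 1:15) {
    picks <- w0$stems[sample(nrow(w0$stems), 4), c("brow", "bcol")]
    w <- kill_stem(w0, as.matrix(picks))
    stb <- find_stem_border(w, w0$stems$id)   # scan the whole layer
    expect_setequal(stb$ids, oracle_stem_border(w))
  }
})

test_that("severed fragments classify as whole-tissue loss and name the missing tissues", {
  w <- default_worm()
  frags <- apply_scenario(w, fixture_scenario("3a", w))
  expect_length(frags, 3L)
  missing <- lapply(frags, function(f) stem_pipeline(f)$report$missing_tissues)
  expect_setequal(missing[[1]], c("body", "tail"))
  expect_setequal(missing[[2]], c("head", "tail"))
  expect_setequal(missing[[3]], c("head", "body"))
  for (f in frags) {
    rep <- stem_pipeline(f)$report
    expect_identical(rep$category, "whole_tissue")
    expect_identical(sum(rep$primitives_matched), 1L)
  }
})

test_that("classification agrees with the flood-fill oracle on random scenarios", {
  w0 <- default_worm()
  for (seed in 1:100) {
    w <- random_block_damage(w0, seed)
    got <- tryCatch(stem_pipeline(w)$report$category,
                    error = function(e) "unclassifiable")
    expect_identical(got, oracle_classify(w), label = paste("seed", seed))
  }
})

test_that("stem border identification is deterministic", {
  w <- apply_scenario(default_worm(), fixture_scenario("2a", default_worm()))
  p1 <- stem_pipeline(w); p2 <- stem_pipeline(w)
  expect_identical(p1$stb$ids, p2$stb$ids)
  expect_identical(p1$report$category, p2$report$category)
})
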