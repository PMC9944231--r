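# Deterministic damage and perturbation operators.

#' Perturb membrane voltages
#'
#' Multiplies each listed cell's voltage by `1 + u`, `u` uniform on
#' `(-fraction, +fraction)`, seeded.
#'
#' @param worm a `worm`.
#' @param cells `"all"` for every live somatic cell, or an n x 2 matrix of
#'   (row, col) positions.
#' @param fraction maximum fractional change, in `(0, 1]`.
#' @param seed RNG seed.
#' @return the perturbed worm.
#' @export
perturb_voltage <- function(worm, cells = "all", fraction = 0.10, seed = 0L) {
  if (!(fraction > 0 && fraction <= 1))
    stop("validation error: fraction must lie in (0, 1]")
  if (identical(cells, "all")) {
    idx <- which(worm$alive)
  } else {
    cells <- as.matrix(cells)
    if (any(!worm$alive[cells]))
      stop("validation error: cannot perturb a dead or missing cell")
    idx <- (cells[, 2] - 1L) * worm$nrow + cells[, 1]
  }
  rng <- local_rng(seed)
  u <- rng$runif(length(idx), -fraction, fraction)
  worm$voltage[idx] <- worm$voltage[idx] * (1 + u)
  worm$status[idx] <- "affected"
  worm
}

# Depolarize live neighbours of newly dead cells: electrolytes released by
# the dying cells reduce the neighbours' voltage magnitude by the
# configured fraction (default 15%, above the 10% damage threshold).
apply_electrolyte_rule <- function(worm, new_dead) {
  if (!nrow(new_dead)) return(worm)
  bd <- worm$config$border_depolarization
  for (d in seq_len(4)) {
    rr <- new_dead[, 1] + dir_offsets[d, 1]
    cc <- new_dead[, 2] + dir_offsets[d, 2]
    ok <- rr >= 1 & rr <= worm$nrow & cc >= 1 & cc <= worm$ncol
    nb <- cbind(rr[ok], cc[ok])
    live <- worm$alive[nb]
    nb <- nb[live, , drop = FALSE]
    if (!nrow(nb)) next
    worm$voltage[nb] <- worm$home_voltage[nb] * (1 - bd)
    worm$status[nb] <- "affected"
  }
  worm
}

#' Kill individual somatic cells
#'
#' Marks the listed cells dead (together with any co-located stem cell)
#' and applies the electrolyte depolarization to their live neighbours.
#' Idempotent on already-dead cells.
#'
#' @param worm a `worm`.
#' @param cells n x 2 matrix of (row, col) positions within the worm's
#'   outline.
#' @return the damaged worm.
#' @export
kill_cells <- function(worm, cells) {
  cells <- matrix(as.integer(as.matrix(cells)), ncol = 2)
  if (!nrow(cells)) return(worm)
  if (any(!worm$original_mask[cells]))
    stop("validation error: target cell outside the worm outline")
  newly <- cells[worm$alive[cells], , drop = FALSE]
  worm$alive[newly] <- FALSE
  worm$voltage[newly] <- NA_real_
  worm$status[newly] <- NA_character_
  co <- worm$stems$alive &
    paste(worm$stems$row, worm$stems$col) %in% paste(newly[, 1], newly[, 2])
  worm$stems$alive[co] <- FALSE
  worm$stems$voltage[co] <- NA_real_
  apply_electrolyte_rule(worm, newly)
}

#' Kill a rectangular region
#'
#' @param worm a `worm`.
#' @param rect `c(row1, row2, col1, col2)` (inclusive bounds).
#' @return the damaged worm; an empty intersection with the outline is a
#'   no-op.
#' @export
kill_region <- function(worm, rect) {
  rect <- as.integer(rect)
  rows <- max(1L, rect[1]):min(worm$nrow, rect[2])
  cols <- max(1L, rect[3]):min(worm$ncol, rect[4])
  idx <- as.matrix(expand.grid(row = rows, col = cols))
  idx <- idx[worm$original_mask[idx], , drop = FALSE]
  if (!nrow(idx)) return(worm)
  kill_cells(worm, idx)
}

#' Kill stem cells only
#'
#' Removes the stem cells anchoring the given blocks, leaving the somatic
#' sheet (including the centre somatic cell sharing the stem's position)
#' intact.
#'
#' @param worm a `worm`.
#' @param blocks n x 2 matrix of (block row, block col).
#' @return the damaged worm.
#' @export
kill_stem <- function(worm, blocks) {
  blocks <- matrix(as.integer(as.matrix(blocks)), ncol = 2)
  hit <- paste(worm$stems$brow, worm$stems$bcol) %in%
    paste(blocks[, 1], blocks[, 2])
  worm$stems$alive[hit] <- FALSE
  worm$stems$voltage[hit] <- NA_real_
  worm
}

#' Cut the worm along lattice planes
#'
#' Severs all gap junctions crossing each plane and returns the resulting
#' fragments as independent worms.  A vertical plane at `after = c` cuts
#' between cell columns `c` and `c + 1`; horizontal planes cut between
#' rows.  Each fragment keeps the full lattice geometry, motifs, and
#' information-field access; cells of the other fragments are missing from
#' it, and its severed-edge cells take `"affected"` status with the
#' electrolyte depolarization.
#'
#' @param worm a `worm`.
#' @param planes a list of `list(axis = "vertical"|"horizontal",
#'   after = <int>)`, or a single such plane.
#' @return list of `worm` fragments (possibly of length 1).
#' @export
cut_worm <- function(worm, planes) {
  if (!is.null(planes$axis)) planes <- list(planes)
  for (p in planes) {
    lim <- if (p$axis == "vertical") worm$ncol else worm$nrow
    if (p$after < 0 || p$after > lim)
      stop("validation error: cut plane outside the worm lattice")
    if (p$after %% worm$config$block_size != 0)
      warning("cut plane does not fall on a block boundary")
  }
  vcuts <- vapply(Filter(function(p) p$axis == "vertical", planes),
                  `[[`, numeric(1), "after")
  hcuts <- vapply(Filter(function(p) p$axis == "horizontal", planes),
                  `[[`, numeric(1), "after")

  # the planes partition the lattice into rectangular pieces; each piece
  # holding at least one live cell becomes an independent fragment
  nr <- worm$nrow; nc <- worm$ncol
  hb <- unique(c(0, sort(hcuts), nr))
  vb <- unique(c(0, sort(vcuts), nc))
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  for (hi in seq_len(length(hb) - 1L)) for (vi in seq_len(length(vb) - 1L)) {
    rows <- (hb[hi] + 1L):hb[hi + 1L]
    cols <- (vb[vi] + 1L):vb[vi + 1L]
    if (!any(worm$alive[rows, cols])) next
    nxt <- nxt + 1L
    lab[rows, cols] <- nxt
  }
  if (nxt == 0L) stop("validation error: no live cells to cut")

  lapply(seq_len(nxt), function(fi) {
    frag <- worm
    keep <- !is.na(lab) & lab == fi
    frag$alive <- worm$alive & keep
    frag$voltage[!frag$alive] <- NA_real_
    frag$status[!frag$alive] <- NA_character_
    in_frag <- frag$alive[cbind(worm$stems$row, worm$stems$col)]
    frag$stems$alive <- worm$stems$alive & in_frag
    frag$stems$voltage[!frag$stems$alive] <- NA_real_
    severed <- which(worm$original_mask & !frag$alive, arr.ind = TRUE)
    apply_electrolyte_rule(frag, severed)
  })
}

#' Build a damage scenario description
#'
#' @param kind one of `"perturb_voltage"`, `"kill_cells"`, `"kill_region"`,
#'   `"kill_stem"`, `"cut"`, `"composite"`.
#' @param ... kind-specific parameters (`cells`, `rect`, `blocks`,
#'   `planes`, `fraction`, `seed`, `steps`).
#' @return a list of class `scenario`.
#' @export
scenario <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "scenario")
}

#' Apply a damage scenario to a worm
#'
#' @param worm a `worm`.
#' @param sc a [scenario()].
#' @return the damaged worm, or a list of fragment worms when the scenario
#'   ends in a cut.
#' @export
apply_scenario <- function(worm, sc) {
  switch(sc$kind,
    perturb_voltage = perturb_voltage(worm,
      cells = sc$cells %or_default% "all",
      fraction = sc$fraction, seed = sc$seed %or_default% 0L),
    kill_cells = kill_cells(worm, sc$cells),
    kill_region = kill_region(worm, sc$rect),
    kill_stem = kill_stem(worm, sc$blocks),
    cut = cut_worm(worm, sc$planes),
    composite = {
      for (i in seq_along(sc$steps)) {
        step <- sc$steps[[i]]
        if (step$kind == "cut" && i < length(sc$steps))
          stop("composite scenario: a cut must be the final step")
        worm <- apply_scenario(worm, step)
      }
      worm
    },
    stop("unknown scenario kind: ", sc$kind)
  )
}

`%or_default%` <- function(a, b) if (is.null(a)) b else a

#' The named damage cases shipped as fixtures
#'
#' @return character vector of case labels.
#' @export
fixture_cases <- function() c("1a", "1b", "2a", "2b", "3a", "3b", "4")

# Kill a block's stem cell and its 24 surrounding somatic cells.  The
# centre somatic cell shares the stem's lattice position and survives, so
# the lesion removes 1 stem + 24 somatic cells.
kill_stem_block_steps <- function(worm, brow, bcol) {
  bs <- worm$config$block_size
  ctr <- (bs + 1L) %/% 2L
  rows <- (brow - 1L) * bs + seq_len(bs)
  cols <- (bcol - 1L) * bs + seq_len(bs)
  cells <- as.matrix(expand.grid(row = rows, col = cols))
  centre <- cells[, 1] == (brow - 1L) * bs + ctr & cells[, 2] == (bcol - 1L) * bs + ctr
  list(scenario("kill_cells", cells = cells[!centre, , drop = FALSE]),
       scenario("kill_stem", blocks = cbind(brow, bcol)))
}

#' Damage scenarios of the documented recovery cases
#'
#' Emits the scenario for each of the seven damage cases: single somatic
#' cell loss (1a), several scattered somatic cells (1b), one stem cell
#' with its surrounding tissue (2a), all stem-anchored lesions of a whole
#' AMN node (2b), the triple cut into head, body and tail (3a), a
#' tail amputation combined with an enclosed interior lesion (3b), and a
#' combined vertical plus horizontal cut (4).  Cases 1b, 2b, 3b, and 4 are
#' reconstructed representatives of their damage classes.
#'
#' @param case a label from [fixture_cases()].
#' @param worm the worm the scenario will be applied to (geometry source;
#'   defaults to the standard worm).
#' @return a [scenario()].
#' @export
fixture_scenario <- function(case, worm = NULL) {
  if (is.null(worm)) worm <- build_worm()
  bs <- worm$config$block_size
  head_w <- length(worm$config$taper) * bs
  body_w <- worm$config$body_block_cols * bs
  switch(as.character(case),
    "1a" = scenario("kill_cells", cells = cbind(12L, 72L)),
    "1b" = scenario("kill_cells", cells = rbind(c(12L, 72L), c(7L, 37L),
                                                c(22L, 97L))),
    "2a" = scenario("composite", steps = kill_stem_block_steps(worm, 3L, 15L)),
    "2b" = {
      node <- 7L
      blk <- which(worm$node_block == node, arr.ind = TRUE)
      steps <- list()
      for (i in seq_len(nrow(blk)))
        steps <- c(steps, kill_stem_block_steps(worm, blk[i, 1], blk[i, 2]))
      scenario("composite", steps = steps)
    },
    "3a" = scenario("cut", planes = list(
      list(axis = "vertical", after = head_w),
      list(axis = "vertical", after = head_w + body_w))),
    "3b" = scenario("composite", steps = c(
      kill_stem_block_steps(worm, 3L, 11L),
      list(scenario("cut", planes = list(
        list(axis = "vertical", after = head_w + body_w)))))),
    "4" = scenario("cut", planes = list(
      list(axis = "vertical", after = head_w + body_w %/% 2L),
      list(axis = "horizontal", after = (worm$config$body_block_rows %/% 2L) * bs))),
    stop("unknown fixture case: ", case)
  )
}
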