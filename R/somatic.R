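#' Derive the current perturbation event of a worm
#'
#' Compares every live cell's voltage against the homeostatic pattern and
#' collects the cells whose voltage has changed, with their fractional
#' change, plus the set of dead cells.
#'
#' @param worm a `worm`.
#' @return list of class `perturbation_event`: `cells` (n x 2 matrix of
#'   row/col), `fractional_change`, and `dead` (m x 2 matrix).
#' @export
perturbation_event <- function(worm) {
  live <- worm$alive
  fc <- (worm$voltage - worm$home_voltage) / abs(worm$home_voltage)
  fc[!live] <- NA
  idx <- which(live & !is.na(fc) & fc != 0, arr.ind = TRUE)
  dead <- which(worm$original_mask & !worm$alive, arr.ind = TRUE)
  structure(list(cells = idx,
                 fractional_change = fc[idx],
                 dead = dead),
            class = "perturbation_event")
}

#' Classify a bioelectric change as normal physiology or damage
#'
#' Voltage fluctuations below the 10% threshold are normal physiological
#' variation; a fractional change of 10% or more in any affected cell, or
#' any dead cell, indicates damage.
#'
#' @param worm a `worm`.
#' @param event a [perturbation_event()]; computed from the worm when
#'   omitted.
#' @return `"normal"` or `"damage"`.
#' @export
detect_change <- function(worm, event = perturbation_event(worm)) {
  thr <- worm$config$detect_threshold
  if (nrow(event$dead) > 0) return("damage")
  # a change of exactly 10% classifies as damage; the small slack keeps the
  # boundary decision stable against floating-point rounding
  if (length(event$fractional_change) &&
      any(abs(event$fractional_change) >= thr - 1e-9)) return("damage")
  "normal"
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(M, dr, dc, fill = FALSE) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  r_to <- rs[rs + dr >= 1 & rs + dr <= nr]
  c_to <- cs[cs + dc >= 1 & cs + dc <= nc]
  out[r_to, c_to] <- M[r_to + dr, c_to + dc]
  out
}

# Direction offsets in N, E, S, W order (row decreases northwards).
dir_offsets <- rbind(N = c(-1L, 0L), E = c(0L, 1L), S = c(1L, 0L), W = c(0L, -1L))

#' Identify the somatic damage border
#'
#' Every live cell applies the motif matching its neighbourhood class --
#' the class is given by how many 4-neighbours the cell has in the
#' original (homeostatic) outline, so outline cells are not flagged merely
#' for having fewer neighbours.  Inputs are the binarised presence of each
#' expected neighbour.  Cells whose motif reports a missing neighbour
#' (output 0) form the damage border and take status `"border"`.
#'
#' @param worm a `worm` with trained motifs in `worm$motifs`.
#' @return list of class `somatic_border`: `cells` (n x 2 positions),
#'   `worm` (with updated statuses), `enclosing_region` (dead positions).
#' @export
find_somatic_border <- function(worm) {
  if (is.null(worm$motifs)) worm$motifs <- train_motifs()
  m <- worm$original_mask
  alive <- worm$alive
  exp_nb <- lapply(seq_len(4), function(d)
    shift_mat(m, dir_offsets[d, 1], dir_offsets[d, 2]))
  alive_nb <- lapply(seq_len(4), function(d)
    shift_mat(alive, dir_offsets[d, 1], dir_offsets[d, 2]))
  exp_ct <- Reduce(`+`, exp_nb)

  border <- matrix(FALSE, worm$nrow, worm$ncol)
  motif_for_k <- list(NULL, worm$motifs$corner, worm$motifs$border,
                      worm$motifs$interior)
  # Group cells by which subset of the four directions is expected, so each
  # group shares one motif and one fixed input ordering (N, E, S, W).
  for (dirs in all_dir_subsets()) {
    k <- length(dirs)
    sel <- alive & exp_ct == k
    for (d in seq_len(4)) {
      sel <- sel & (if (d %in% dirs) exp_nb[[d]] else !exp_nb[[d]])
    }
    idx <- which(sel)
    if (!length(idx)) next
    X <- vapply(dirs, function(d) as.integer(alive_nb[[d]][idx]),
                integer(length(idx)))
    X <- matrix(X, ncol = k)
    out <- apply_motif_rows(motif_for_k[[k]], X)
    border[idx[out == 0L]] <- TRUE
  }
  worm$status[border] <- "border"
  structure(list(cells = which(border, arr.ind = TRUE),
                 enclosing_region = which(m & !alive, arr.ind = TRUE),
                 worm = worm),
            class = "somatic_border")
}

all_dir_subsets <- function() {
  out <- list()
  for (k in 2:4) {
    cm <- utils::combn(4, k)
    for (j in seq_len(ncol(cm))) out[[length(out) + 1L]] <- cm[, j]
  }
  out
}

#' Propagate a damage signal from the somatic sheet to the stem layer
#'
#' Border and dead cells signal, through gap junctions and ion fluxes, the
#' stem cell of the block they lie in; a cell dying on a block edge raises
#' a border cell in the adjacent block, so that block's stem is affected
#' too.
#'
#' @param worm a `worm`.
#' @param border a [find_somatic_border()] result.
#' @return integer vector of affected live stem-cell ids.
#' @export
propagate_to_stem <- function(worm, border) {
  pts <- rbind(border$cells, border$enclosing_region)
  if (!nrow(pts)) return(integer(0))
  blocks <- unique(cell_block(worm, pts[, 1], pts[, 2]))
  key <- paste(blocks[, 1], blocks[, 2])
  st <- worm$stems
  hit <- paste(st$brow, st$bcol) %in% key & st$alive
  st$id[hit]
}
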