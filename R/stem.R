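# Stem-cell network: organism-wide damage border, pattern-primitive
# classification, and missing-tissue identification.

# Does the stem in block (brow, bcol) receive a signal from the direction
# `d` (index into dir_offsets)?  The signal travels from the neighbouring
# stem through the straight line of somatic relay cells between the two
# block centres.  It is lost when the neighbour stem is dead or missing,
# or when the entire relay line is dead (as across a cut); a single dead
# relay cell does not break the path, since ion fluxes can route around it.
stem_signal <- function(worm, brow, bcol, d) {
  nb <- c(brow + dir_offsets[d, 1], bcol + dir_offsets[d, 2])
  st <- worm$stems
  j <- which(st$brow == nb[1] & st$bcol == nb[2])
  if (!length(j)) return(NA_integer_)     # no neighbour expected there
  if (!st$alive[j]) return(0L)
  bs <- worm$config$block_size
  ctr <- (bs + 1L) %/% 2L
  from <- c((brow - 1L) * bs + ctr, (bcol - 1L) * bs + ctr)
  to <- c((nb[1] - 1L) * bs + ctr, (nb[2] - 1L) * bs + ctr)
  steps <- seq_len(bs - 1L)
  relay <- cbind(from[1] + sign(to[1] - from[1]) * steps,
                 from[2] + sign(to[2] - from[2]) * steps)
  if (all(!worm$alive[relay])) 0L else 1L
}

# Expected stem neighbours (directions with a block in the body plan).
stem_expected_dirs <- function(worm, brow, bcol) {
  which(vapply(seq_len(4), function(d) {
    nb <- c(brow + dir_offsets[d, 1], bcol + dir_offsets[d, 2])
    nb[1] >= 1 && nb[1] <= nrow(worm$block_mask) &&
      nb[2] >= 1 && nb[2] <= ncol(worm$block_mask) &&
      worm$block_mask[nb[1], nb[2]]
  }, logical(1)))
}

#' Identify the stem-cell damage border
#'
#' Each affected stem cell applies the motif matching its position class
#' (2, 3, or 4 expected stem neighbours in the block lattice, using the
#' same trained motifs as the somatic network) over the presence signals
#' relayed through intermediate somatic cells.  Stem cells whose motif
#' reports a missing neighbour form the stem-cell border.
#'
#' @param worm a `worm` with trained motifs.
#' @param affected integer ids of affected stem cells, as returned by
#'   [propagate_to_stem()].
#' @return list of class `stem_border` with `ids` (border stem ids) and
#'   `signals` (per-stem named direction inputs).
#' @export
find_stem_border <- function(worm, affected) {
  if (is.null(worm$motifs)) worm$motifs <- train_motifs()
  motif_for_k <- list(NULL, worm$motifs$corner, worm$motifs$border,
                      worm$motifs$interior)
  ids <- integer(0)
  signals <- list()
  st <- worm$stems
  for (id in affected) {
    j <- which(st$id == id)
    if (!st$alive[j]) next
    dirs <- stem_expected_dirs(worm, st$brow[j], st$bcol[j])
    x <- vapply(dirs, function(d) stem_signal(worm, st$brow[j], st$bcol[j], d),
                integer(1))
    k <- length(dirs)
    if (k == 0L) next
    # the two tip blocks have a single stem neighbour; the presence check
    # degenerates to that one input (a 1-input AND)
    out <- if (k == 1L) x else apply_motif(motif_for_k[[k]], x)
    signals[[as.character(id)]] <- stats::setNames(x, rownames(dir_offsets)[dirs])
    if (out == 0L) ids <- c(ids, id)
  }
  structure(list(ids = ids, signals = signals), class = "stem_border")
}

# Flood-fill labelling of connected components (4-adjacency) of a logical
# matrix.  Returns an integer matrix (NA where FALSE).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- integer(1024); queue[1] <- start; qn <- 1L
    lab[start] <- nxt
    while (qn > 0L) {
      cur <- queue[qn]; qn <- qn - 1L
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in seq_len(4)) {
        rr <- r + dir_offsets[d, 1]; cc <- c + dir_offsets[d, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && is.na(lab[j])) {
          lab[j] <- nxt
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- j
        }
      }
    }
  }
  lab
}

# Blocks (rows of a 2-col matrix) covered by a set of cell positions.
blocks_of_cells <- function(worm, cells) {
  unique(cell_block(worm, cells[, 1], cells[, 2]))
}

# Is any cell of the component adjacent to the exterior (off-lattice or
# outside the original outline)?  Enclosed damage has no such contact.
component_touches_outline <- function(worm, cells) {
  for (d in seq_len(4)) {
    rr <- cells[, 1] + dir_offsets[d, 1]
    cc <- cells[, 2] + dir_offsets[d, 2]
    off <- rr < 1 | rr > worm$nrow | cc < 1 | cc > worm$ncol
    if (any(off)) return(TRUE)
    if (any(!worm$original_mask[cbind(rr[!off], cc[!off])])) return(TRUE)
  }
  FALSE
}

#' Classify damage with the three pattern primitives
#'
#' For each connected component of missing cells the stem-cell border is
#' checked for the three pattern primitives: border stem cells (1) to the
#' left (anterior) of the damage, (2) above or below it, and (3) to its
#' right (posterior).  A primitive is read off the direction of disrupted
#' communication: a border stem whose posterior-side signal is lost sits
#' to the left of the damage, and so on.  All three primitives matching
#' indicates local damage -- enclosed when the region has no contact with
#' the worm's outline, otherwise an open border; exactly one primitive
#' indicates whole-tissue loss.  Two primitives indicate large-scale
#' open-border damage.  A component that killed no stem cells is left to
#' the somatic network (`no_stem_damage`).
#'
#' @param worm a `worm`.
#' @param border a [find_stem_border()] result.
#' @param somatic_border a [find_somatic_border()] result (defaults to
#'   computing it).
#' @return object of class `damage_report` with `category` (the most
#'   severe component's class), `composite`, `primitives_matched`,
#'   `components`, `stem_border`, `somatic_border`, `missing_tissues`,
#'   `lost_nodes`.
#' @export
classify_damage <- function(worm, border,
                            somatic_border = find_somatic_border(worm)) {
  dead <- worm$original_mask & !worm$alive
  severity <- c(none = 0, no_stem_damage = 1, local_enclosed = 2,
                open_border = 3, whole_tissue = 4)
  st <- worm$stems
  comp_lab <- label_components(dead)
  n_comp <- if (any(dead)) max(comp_lab, na.rm = TRUE) else 0L
  comp_cells <- lapply(seq_len(n_comp), function(ci)
    which(!is.na(comp_lab) & comp_lab == ci, arr.ind = TRUE))

  # a dead stem whose surrounding somatic cells survived leaves no dead
  # somatic component; treat its home position as a damage component
  covered <- unlist(lapply(comp_cells, function(cells) {
    bl <- blocks_of_cells(worm, cells)
    st$id[!st$alive & paste(st$brow, st$bcol) %in% paste(bl[, 1], bl[, 2])]
  }))
  orphan <- st[!st$alive & !(st$id %in% covered), , drop = FALSE]
  if (nrow(orphan))
    comp_cells <- c(comp_cells,
                    lapply(seq_len(nrow(orphan)), function(i)
                      cbind(row = orphan$home_row[i], col = orphan$home_col[i])))

  # which direction of a border stem's lost signals point into a given
  # block set (the component)
  opp_dir <- c(N = "S", E = "W", S = "N", W = "E")
  components <- list()
  for (ci in seq_along(comp_cells)) {
    cells <- comp_cells[[ci]]
    cblocks <- blocks_of_cells(worm, cells)
    comp_key <- paste(cblocks[, 1], cblocks[, 2])
    dead_stems <- st$id[!st$alive & paste(st$brow, st$bcol) %in% comp_key]
    bbox <- c(rmin = min(cblocks[, 1]), rmax = max(cblocks[, 1]),
              cmin = min(cblocks[, 2]), cmax = max(cblocks[, 2]))
    # border stems with a lost signal pointing into this component
    prim <- c(left = FALSE, above_below = FALSE, right = FALSE)
    bstems <- integer(0)
    for (id in border$ids) {
      sig <- border$signals[[as.character(id)]]
      j <- which(st$id == id)
      lost_into <- vapply(names(sig), function(dn) {
        if (is.na(sig[[dn]]) || sig[[dn]] != 0L) return(FALSE)
        d <- match(dn, rownames(dir_offsets))
        nb_key <- paste(st$brow[j] + dir_offsets[d, 1],
                        st$bcol[j] + dir_offsets[d, 2])
        nb_key %in% comp_key
      }, logical(1))
      if (!any(lost_into)) next
      bstems <- c(bstems, id)
      has <- function(dn) isTRUE(unname(lost_into[dn]))
      if (has("E")) prim["left"] <- TRUE
      if (has("W")) prim["right"] <- TRUE
      if (has("N") || has("S")) prim["above_below"] <- TRUE
    }
    np <- sum(prim)
    cat_i <- if (length(dead_stems) == 0L) {
      "no_stem_damage"
    } else if (np == 3L) {
      if (component_touches_outline(worm, cells)) "open_border" else "local_enclosed"
    } else if (np == 2L) {
      "open_border"
    } else if (np == 1L) {
      "whole_tissue"
    } else {
      stop("unclassifiable damage: a component with missing stem cells has ",
           "a stem border matching none of the three pattern primitives")
    }
    components[[ci]] <- list(cells = cells, blocks = cblocks, bbox = bbox,
                             primitives = prim, category = cat_i,
                             dead_stems = dead_stems, border_stems = bstems)
  }

  if (!length(components)) {
    category <- "none"; composite <- FALSE
    prim_all <- c(left = FALSE, above_below = FALSE, right = FALSE)
  } else {
    cats <- vapply(components, `[[`, character(1), "category")
    category <- cats[which.max(severity[cats])]
    composite <- length(unique(cats)) > 1L
    prim_all <- components[[which.max(severity[cats])]]$primitives
  }

  lost <- which(vapply(seq_len(worm$n_nodes), function(k)
    !any(worm$alive[!is.na(worm$node_cell) & worm$node_cell == k]), logical(1)))

  rep <- structure(list(category = category,
                        composite = composite,
                        primitives_matched = prim_all,
                        components = components,
                        stem_border = border,
                        somatic_border = somatic_border,
                        missing_tissues = character(0),
                        lost_nodes = lost),
                   class = "damage_report")
  if (any(vapply(components, function(x) x$category == "whole_tissue", logical(1))))
    rep$missing_tissues <- identify_missing_tissue(worm, rep)
  rep
}

#' Identify which tissues are missing after whole-tissue damage
#'
#' Border stem cells of a whole-tissue damage component check the
#' direction of disrupted communication: an absent anterior-side (head
#' side) signal means everything anterior is lost; an absent
#' posterior-side (tail side) signal means everything posterior is lost;
#' both mean an isolated body fragment.  The missing tissues are those of
#' the body plan whose span lies in the lost region.
#'
#' @param worm a `worm` (fragment).
#' @param report a `damage_report` (or a `stem_border`, in which case the
#'   report is built first).
#' @return character subset of `c("head", "body", "tail")`.
#' @export
identify_missing_tissue <- function(worm, report) {
  if (inherits(report, "stem_border"))
    report <- classify_damage(worm, report)
  missing <- character(0)
  spans <- worm$tissue_spans
  st <- worm$stems
  for (comp in report$components) {
    if (comp$category != "whole_tissue") next
    bb <- st[st$id %in% comp$border_stems, , drop = FALSE]
    anterior_lost <- comp$bbox["cmin"] < min(bb$bcol)
    posterior_lost <- comp$bbox["cmax"] > max(bb$bcol)
    for (t in names(spans)) {
      sp <- spans[[t]]
      if (anterior_lost && sp[1] < min(bb$bcol) && sp[1] >= comp$bbox["cmin"])
        missing <- c(missing, t)
      if (posterior_lost && sp[2] > max(bb$bcol) && sp[2] <= comp$bbox["cmax"])
        missing <- c(missing, t)
    }
  }
  intersect(c("head", "body", "tail"), unique(missing))
}

#' Full stage-3 damage assessment
#'
#' Convenience pipeline: somatic border, propagation to the stem layer,
#' stem border, and pattern-primitive classification.
#'
#' @param worm a `worm` with trained motifs.
#' @return a `damage_report`.
#' @export
assess_damage <- function(worm) {
  sb <- find_somatic_border(worm)
  affected <- propagate_to_stem(worm, sb)
  stb <- find_stem_border(worm, affected)
  classify_damage(worm, stb, sb)
}

#' @export
print.damage_report <- function(x, ...) {
  cat(sprintf("<damage_report> category: %s%s\n", x$category,
              if (x$composite) " (composite)" else ""))
  cat(sprintf("  primitives matched: %s\n",
              paste(names(x$primitives_matched)[x$primitives_matched],
                    collapse = ", ")))
  cat(sprintf("  dead components: %d; stem border: %d cells; somatic border: %d cells\n",
              length(x$components), length(x$stem_border$ids),
              nrow(x$somatic_border$cells)))
  if (length(x$missing_tissues))
    cat("  missing tissues:", paste(x$missing_tissues, collapse = ", "), "\n")
  if (length(x$lost_nodes))
    cat("  destroyed AMN nodes:", paste(x$lost_nodes, collapse = ", "), "\n")
  invisible(x)
}
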