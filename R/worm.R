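#' Configuration for the default in-silico worm
#'
#' The worm is a 2D sheet of somatic cells built from repeated 5x5 blocks,
#' each anchored by a stem cell that overlays the block's centre cell.  The
#' body is a rectangle of blocks; head and tail are triangular tapers whose
#' block-column heights decrease towards the tips, giving each end tissue an
#' aspect ratio of 1 and three corners.
#'
#' @param block_size side length of a somatic block, in cells.
#' @param body_block_rows number of block rows across the body (D/V extent).
#' @param body_block_cols number of block columns along the body (A/P
#'   extent); this is the body-plan length `d` stored in the information
#'   field.
#' @param taper block-column heights of the head (and, mirrored, the tail)
#'   from the body outwards to the tip.  Must start at `body_block_rows`
#'   and decrease strictly to 1 so each end tissue is a triangle with
#'   three corners.
#' @param node_blocks_body number of blocks per body node of the
#'   associative memory network.
#' @param head_voltage,tail_voltage endpoints of the default homeostatic
#'   bioelectric gradient (normalized membrane voltage, hyperpolarized so
#'   strictly negative; magnitude decreases head to tail).
#' @param detect_threshold fractional voltage change at or above which a
#'   perturbation is classified as damage rather than normal physiology.
#' @param border_depolarization fractional loss of voltage magnitude
#'   suffered by live cells bordering a dead cell, modelling the
#'   electrolytes released on cell death.
#' @param stem_relay_cells number of somatic cells relaying a stem-to-stem
#'   signal between adjacent block centres.
#' @param seed integer seed controlling all stochastic defaults downstream.
#' @return a list of class `worm_config`.
#' @export
worm_config <- function(block_size = 5L,
                        body_block_rows = 6L,
                        body_block_cols = 18L,
                        taper = c(6L, 5L, 4L, 3L, 2L, 1L),
                        node_blocks_body = 12L,
                        head_voltage = -0.95,
                        tail_voltage = -0.35,
                        detect_threshold = 0.10,
                        border_depolarization = 0.15,
                        stem_relay_cells = NULL,
                        seed = 0L) {
  cfg <- list(
    block_size = as.integer(block_size),
    body_block_rows = as.integer(body_block_rows),
    body_block_cols = as.integer(body_block_cols),
    taper = as.integer(taper),
    node_blocks_body = as.integer(node_blocks_body),
    head_voltage = head_voltage,
    tail_voltage = tail_voltage,
    detect_threshold = detect_threshold,
    border_depolarization = border_depolarization,
    stem_relay_cells = if (is.null(stem_relay_cells)) as.integer(block_size) - 1L
                       else as.integer(stem_relay_cells),
    seed = as.integer(seed)
  )
  class(cfg) <- "worm_config"
  validate_worm_config(cfg)
  cfg
}

validate_worm_config <- function(cfg) {
  if (cfg$block_size < 3L || cfg$block_size %% 2L == 0L)
    stop("configuration error: block_size must be odd and >= 3 so a block has a centre cell")
  if (cfg$taper[1] != cfg$body_block_rows)
    stop("configuration error: head/tail taper must start at body_block_rows ",
         "(violated invariant: AR(head) = AR(tail) = 1)")
  if (any(diff(cfg$taper) >= 0L) || cfg$taper[length(cfg$taper)] != 1L)
    stop("configuration error: taper must decrease strictly to 1 ",
         "(violated invariant: head/tail have 3 corners)")
  n_body <- cfg$body_block_rows * cfg$body_block_cols
  if (n_body %% cfg$node_blocks_body != 0L)
    stop("configuration error: body blocks (", n_body,
         ") not divisible by node_blocks_body (violated invariant: equal body nodes)")
  if (cfg$node_blocks_body %% cfg$body_block_rows != 0L)
    stop("configuration error: node_blocks_body must be a whole number of block columns")
  if (!(cfg$head_voltage < 0 && cfg$tail_voltage < 0))
    stop("configuration error: homeostatic voltages must be hyperpolarized (negative)")
  if (abs(cfg$head_voltage) <= abs(cfg$tail_voltage))
    stop("configuration error: voltage magnitude must decrease head to tail ",
         "(violated invariant: monotone bioelectric gradient)")
  invisible(cfg)
}

# Block-lattice layout.  Head occupies the first length(taper) block columns
# with column heights 1..body_block_rows anchored to row 1 (a right triangle,
# tip anterior); tail mirrors it at the posterior end.  Returns logical
# block mask plus tissue and node assignment matrices on the block lattice.
build_block_layout <- function(cfg) {
  nt <- length(cfg$taper)
  n_bcols <- 2L * nt + cfg$body_block_cols
  n_brows <- cfg$body_block_rows
  mask <- matrix(FALSE, n_brows, n_bcols)
  tissue <- matrix(NA_character_, n_brows, n_bcols)
  heights_head <- rev(cfg$taper)            # tip -> body
  for (j in seq_len(nt)) {
    mask[seq_len(heights_head[j]), j] <- TRUE
    tissue[seq_len(heights_head[j]), j] <- "head"
  }
  body_cols <- nt + seq_len(cfg$body_block_cols)
  mask[, body_cols] <- TRUE
  tissue[, body_cols] <- "body"
  for (j in seq_len(nt)) {
    col <- nt + cfg$body_block_cols + j
    mask[seq_len(cfg$taper[j]), col] <- TRUE
    tissue[seq_len(cfg$taper[j]), col] <- "tail"
  }

  # Node partition, anterior -> posterior.  Body nodes take whole block
  # columns; head and tail blocks are split into two nodes each, sized
  # ceiling/floor of the tissue block count (the end tissues are the ones
  # allowed a slightly different form).
  node <- matrix(NA_integer_, n_brows, n_bcols)
  order_blocks <- function(cols) {
    idx <- which(mask[, cols, drop = FALSE], arr.ind = TRUE)
    idx[, 2] <- cols[idx[, 2]]
    idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  }
  head_blocks <- order_blocks(seq_len(nt))
  nh <- nrow(head_blocks)
  n1 <- ceiling(nh / 2)
  node[head_blocks[seq_len(n1), , drop = FALSE]] <- 1L
  node[head_blocks[(n1 + 1):nh, , drop = FALSE]] <- 2L
  cols_per_node <- cfg$node_blocks_body %/% cfg$body_block_rows
  n_body_nodes <- cfg$body_block_cols %/% cols_per_node
  for (k in seq_len(n_body_nodes)) {
    cols <- nt + (k - 1L) * cols_per_node + seq_len(cols_per_node)
    node[, cols] <- 2L + k
  }
  tail_blocks <- order_blocks(nt + cfg$body_block_cols + seq_len(nt))
  ntl <- nrow(tail_blocks)
  n12 <- floor(ntl / 2)
  node[tail_blocks[seq_len(n12), , drop = FALSE]] <- 2L + n_body_nodes + 1L
  node[tail_blocks[(n12 + 1):ntl, , drop = FALSE]] <- 2L + n_body_nodes + 2L

  list(mask = mask, tissue = tissue, node = node,
       n_nodes = 2L + n_body_nodes + 2L,
       n_brows = n_brows, n_bcols = n_bcols)
}

#' Build the default in-silico worm
#'
#' Constructs the worm lattice: 150 five-by-five somatic blocks (21 head,
#' 108 body, 21 tail) giving 3750 somatic cells; one stem cell overlaid on
#' each block centre (150 stem cells); tissue masks with aspect ratios
#' 1/3/1 and corner counts 3/4/3; and a 13-node partition for the
#' associative memory network (2 head nodes, 9 body nodes of 12 blocks
#' each, 2 tail nodes).  The homeostatic bioelectric gradient is assigned
#' immediately (see [assign_bioelectric_pattern()]).
#'
#' @param config a [worm_config()].
#' @param node_voltages optional explicit nodal gradient passed on to
#'   [assign_bioelectric_pattern()].
#' @return an object of class `worm`.
#' @export
build_worm <- function(config = worm_config(), node_voltages = NULL) {
  cfg <- config
  lay <- build_block_layout(cfg)
  bs <- cfg$block_size
  nr <- lay$n_brows * bs
  nc <- lay$n_bcols * bs

  expand <- function(M) M[rep(seq_len(lay$n_brows), each = bs),
                          rep(seq_len(lay$n_bcols), each = bs)]
  mask <- expand(lay$mask)
  tissue_cell <- expand(lay$tissue)
  node_cell <- expand(lay$node)

  blk <- which(lay$mask, arr.ind = TRUE)
  blk <- blk[order(blk[, 2], blk[, 1]), , drop = FALSE]
  ctr <- (bs + 1L) %/% 2L
  stems <- data.frame(
    id = seq_len(nrow(blk)),
    brow = blk[, 1], bcol = blk[, 2],
    row = (blk[, 1] - 1L) * bs + ctr,
    col = (blk[, 2] - 1L) * bs + ctr,
    voltage = NA_real_,
    alive = TRUE
  )
  stems$home_row <- stems$row
  stems$home_col <- stems$col

  status <- matrix(NA_character_, nr, nc)
  status[mask] <- "normal"

  tissue_spans <- lapply(c(head = "head", body = "body", tail = "tail"),
                         function(t) range(which(apply(lay$tissue == t, 2,
                                                       any, na.rm = TRUE))))

  worm <- structure(list(
    config = cfg,
    nrow = nr, ncol = nc,
    block_mask = lay$mask,
    tissue_block = lay$tissue,
    node_block = lay$node,
    n_nodes = lay$n_nodes,
    original_mask = mask,
    tissue_cell = tissue_cell,
    node_cell = node_cell,
    alive = mask,
    voltage = matrix(NA_real_, nr, nc),
    status = status,
    stems = stems,
    node_voltages = NULL,
    home_voltage = NULL,
    motifs = NULL,
    info_field = NULL,
    tissue_spans = tissue_spans
  ), class = "worm")

  assign_bioelectric_pattern(worm, node_voltages)
}

#' Assign the homeostatic body-wide bioelectric pattern
#'
#' Sets every somatic and stem cell's membrane voltage to its node's
#' voltage (voltage is held constant within a node) and records the
#' 13-value pattern as the homeostasis reference and the attractor entry of
#' the information field.
#'
#' @param worm a `worm`.
#' @param node_voltages ordered vector of one normalized voltage per node,
#'   anterior to posterior; all strictly negative with strictly decreasing
#'   magnitude.  Defaults to a linear gradient from the configured head
#'   voltage to the tail voltage.
#' @return the worm with voltages, homeostasis pattern, and information
#'   field set.
#' @export
assign_bioelectric_pattern <- function(worm, node_voltages = NULL) {
  if (is.null(node_voltages))
    node_voltages <- seq(worm$config$head_voltage, worm$config$tail_voltage,
                         length.out = worm$n_nodes)
  v <- as.numeric(node_voltages)
  if (length(v) != worm$n_nodes)
    stop("validation error: expected ", worm$n_nodes, " nodal voltages, got ",
         length(v))
  if (any(v >= 0))
    stop("validation error: nodal voltages must be strictly negative ",
         "(hyperpolarized homeostasis)")
  if (any(diff(abs(v)) >= 0))
    stop("validation error: voltage magnitudes must be strictly monotone ",
         "decreasing anterior to posterior")
  vol <- matrix(NA_real_, worm$nrow, worm$ncol)
  vol[worm$original_mask] <- v[worm$node_cell[worm$original_mask]]
  worm$voltage <- vol
  worm$node_voltages <- v
  worm$home_voltage <- vol
  worm$stems$voltage <- v[worm$node_block[cbind(worm$stems$brow, worm$stems$bcol)]]
  worm$info_field <- list(
    d = worm$config$body_block_cols,
    AR = measure_AR(worm),
    n_corners = measure_corners(worm),
    attractor = v,
    geometry = worm$config
  )
  worm
}

# Aspect ratio (A/P length over D/V width of the block bounding box) per
# tissue, measured from the block masks.
measure_AR <- function(worm) {
  vapply(c(head = "head", body = "body", tail = "tail"), function(t) {
    idx <- which(worm$tissue_block == t, arr.ind = TRUE)
    (diff(range(idx[, 2])) + 1) / (diff(range(idx[, 1])) + 1)
  }, numeric(1))
}

# Number of corners per tissue: vertices of the convex hull of the block
# centres, with collinear hull points removed.
measure_corners <- function(worm) {
  vapply(c(head = "head", body = "body", tail = "tail"), function(t) {
    idx <- which(worm$tissue_block == t, arr.ind = TRUE)
    hull_vertex_count(idx[, 2], idx[, 1])
  }, integer(1))
}

hull_vertex_count <- function(x, y) {
  h <- grDevices::chull(x, y)
  px <- x[h]; py <- y[h]
  n <- length(h)
  if (n < 3L) return(n)
  keep <- vapply(seq_len(n), function(i) {
    a <- if (i == 1L) n else i - 1L
    b <- if (i == n) 1L else i + 1L
    cross <- (px[i] - px[a]) * (py[b] - py[a]) - (py[i] - py[a]) * (px[b] - px[a])
    abs(cross) > 1e-9
  }, logical(1))
  sum(keep)
}

#' Summarize a worm state
#'
#' Counts of live and dead somatic and stem cells, per-node cell counts and
#' mean voltages, measured tissue aspect ratios and corner counts, and
#' whether the current occupancy (somatic sheet plus stem layer) matches
#' the homeostatic original.
#'
#' @param worm a `worm`.
#' @return a list of class `worm_summary`.
#' @export
worm_summary <- function(worm) {
  dead <- worm$original_mask & !worm$alive
  node_counts <- vapply(seq_len(worm$n_nodes), function(k)
    sum(worm$alive[!is.na(worm$node_cell) & worm$node_cell == k]), integer(1))
  stem_per_node <- vapply(seq_len(worm$n_nodes), function(k)
    sum(worm$stems$alive[worm$node_block[cbind(worm$stems$brow, worm$stems$bcol)] == k]),
    integer(1))
  ns <- sum(worm$alive)
  nst <- sum(worm$stems$alive)
  out <- list(
    somatic_alive = ns,
    somatic_dead = sum(dead),
    stem_alive = nst,
    stem_dead = sum(!worm$stems$alive),
    n_nodes = worm$n_nodes,
    node_cell_counts = node_counts + stem_per_node,
    stem_per_node = stem_per_node,
    node_voltages = node_state(worm),
    mean_cells_per_node = (ns + nst) / worm$n_nodes,
    stem_percent_of_total = 100 * nst / (ns + nst),
    AR = measure_AR(worm),
    n_corners = measure_corners(worm),
    matches_original = matches_original(worm)
  )
  class(out) <- "worm_summary"
  out
}

#' @export
print.worm_summary <- function(x, ...) {
  cat("worm summary\n")
  cat(sprintf("  somatic cells : %d alive, %d dead\n", x$somatic_alive, x$somatic_dead))
  cat(sprintf("  stem cells    : %d alive, %d dead (%.1f%% of total)\n",
              x$stem_alive, x$stem_dead, x$stem_percent_of_total))
  cat(sprintf("  AMN nodes     : %d (mean %.0f cells/node)\n",
              x$n_nodes, x$mean_cells_per_node))
  cat(sprintf("  tissue AR     : head %.2f, body %.2f, tail %.2f\n",
              x$AR[["head"]], x$AR[["body"]], x$AR[["tail"]]))
  cat(sprintf("  corners       : head %d, body %d, tail %d\n",
              x$n_corners[["head"]], x$n_corners[["body"]], x$n_corners[["tail"]]))
  cat(sprintf("  matches original anatomy: %s\n", x$matches_original))
  invisible(x)
}

# TRUE iff the somatic sheet and stem layer exactly reproduce the
# homeostatic occupancy.
matches_original <- function(worm) {
  identical(worm$alive, worm$original_mask) && all(worm$stems$alive)
}

#' Aggregate nodal voltage state
#'
#' The voltage of a node, as sensed by the associative memory network, is
#' the mean membrane voltage of its live somatic cells; a node with no
#' live cells reads 0 (no voltage), matching the encoding used for
#' destroyed nodes during training.
#'
#' @param worm a `worm`.
#' @return numeric vector, one value per node.
#' @export
node_state <- function(worm) {
  vapply(seq_len(worm$n_nodes), function(k) {
    sel <- worm$alive & !is.na(worm$node_cell) & worm$node_cell == k
    if (!any(sel)) 0 else mean(worm$voltage[sel])
  }, numeric(1))
}

# Write a nodal pattern down to every live cell (voltage is constant within
# a node); stems take their node's voltage as well.
push_node_voltages <- function(worm, s) {
  for (k in seq_len(worm$n_nodes)) {
    sel <- worm$alive & !is.na(worm$node_cell) & worm$node_cell == k
    worm$voltage[sel] <- s[k]
  }
  nodes <- worm$node_block[cbind(worm$stems$brow, worm$stems$bcol)]
  worm$stems$voltage[worm$stems$alive] <- s[nodes[worm$stems$alive]]
  worm
}

#' @export
print.worm <- function(x, ...) {
  s <- worm_summary(x)
  cat(sprintf("<worm> %dx%d lattice, %d somatic + %d stem cells, %d AMN nodes\n",
              x$nrow, x$ncol, s$somatic_alive, s$stem_alive, x$n_nodes))
  if (s$somatic_dead + s$stem_dead > 0)
    cat(sprintf("  damaged: %d somatic, %d stem cells dead\n",
                s$somatic_dead, s$stem_dead))
  invisible(x)
}

#' @export
summary.worm <- function(object, ...) worm_summary(object)

#' Plot a worm's voltage grid
#'
#' Renders the somatic voltage lattice; dead cells within the original
#' outline are drawn black, stem cells as dots.
#'
#' @param x a `worm`.
#' @param ... passed to [graphics::image()].
#' @export
plot.worm <- function(x, ...) {
  z <- t(x$voltage[rev(seq_len(x$nrow)), ])
  zlim <- range(x$node_voltages)
  cols <- grDevices::hcl.colors(64, "viridis")
  graphics::image(seq_len(x$ncol), seq_len(x$nrow), z, zlim = zlim,
                  col = cols, xlab = "A/P (col)", ylab = "D/V (row)",
                  useRaster = TRUE, ...)
  dead <- which(x$original_mask & !x$alive, arr.ind = TRUE)
  if (nrow(dead))
    graphics::points(dead[, 2], x$nrow + 1 - dead[, 1], pch = 15, cex = 0.3)
  st <- x$stems[x$stems$alive, ]
  graphics::points(st$col, x$nrow + 1 - st$row, pch = 16, cex = 0.4, col = "red")
  invisible(x)
}

# Internal: block id (row, col) of a cell position.
cell_block <- function(worm, row, col) {
  bs <- worm$config$block_size
  cbind((row - 1L) %/% bs + 1L, (col - 1L) %/% bs + 1L)
}
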