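# Shared fixtures (built once per test run) and independent oracles.

.cache <- new.env()

default_worm <- function() {
  if (is.null(.cache$worm)) {
    w <- build_worm()
    w$motifs <- train_motifs()
    .cache$worm <- w
  }
  .cache$worm
}

default_amn <- function() {
  if (is.null(.cache$amn)) .cache$amn <- train_amn(default_worm())
  .cache$amn
}

matches_anatomy <- function(w) {
  identical(w$alive, w$original_mask) && all(w$stems$alive)
}

matches_homeostasis <- function(w, tol = 1e-6) {
  matches_anatomy(w) &&
    max(abs(w$voltage[w$alive] - w$home_voltage[w$alive])) < tol
}

# --- independent oracles -----------------------------------------------

# Brute-force adjacency scan: live cells with at least one dead/missing
# 4-neighbour inside the original outline.
oracle_somatic_border <- function(worm) {
  dead <- worm$original_mask & !worm$alive
  out <- matrix(FALSE, worm$nrow, worm$ncol)
  idx <- which(worm$alive, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > worm$nrow || cc < 1 || cc > worm$ncol) next
      if (dead[rr, cc]) { out[r, c] <- TRUE; break }
    }
  }
  which(out, arr.ind = TRUE)
}

# Brute-force stem-lattice scan: live stems with a dead/missing expected
# stem neighbour.
oracle_stem_border <- function(worm) {
  st <- worm$stems
  alive_key <- paste(st$brow[st$alive], st$bcol[st$alive])
  ids <- integer(0)
  for (j in which(st$alive)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- c(st$brow[j] + d[1], st$bcol[j] + d[2])
      if (nb[1] < 1 || nb[1] > nrow(worm$block_mask) ||
          nb[2] < 1 || nb[2] > ncol(worm$block_mask)) next
      if (!worm$block_mask[nb[1], nb[2]]) next
      if (!(paste(nb[1], nb[2]) %in% alive_key)) { ids <- c(ids, st$id[j]); break }
    }
  }
  ids
}

# Flood-fill oracle for damage classification of block-aligned rectangular
# ablations: connected dead components; per component the live stems one
# block away give the primitives against the component's block bounding
# box; enclosed vs outline contact decides local vs open.
oracle_classify <- function(worm) {
  dead <- worm$original_mask & !worm$alive
  st <- worm$stems
  if (!any(dead) && all(st$alive)) return("none")
  lab <- flood_label(dead)
  n <- if (any(dead)) max(lab, na.rm = TRUE) else 0L
  cats <- character(0)
  bs <- worm$config$block_size
  for (ci in seq_len(n)) {
    cells <- which(!is.na(lab) & lab == ci, arr.ind = TRUE)
    bl <- unique(cbind((cells[, 1] - 1) %/% bs + 1, (cells[, 2] - 1) %/% bs + 1))
    key <- paste(bl[, 1], bl[, 2])
    has_dead_stem <- any(!st$alive & paste(st$brow, st$bcol) %in% key)
    if (!has_dead_stem) { cats <- c(cats, "no_stem_damage"); next }
    near <- st$alive & vapply(seq_len(nrow(st)), function(j)
      any(abs(st$brow[j] - bl[, 1]) + abs(st$bcol[j] - bl[, 2]) == 1), logical(1))
    nb <- st[near, , drop = FALSE]
    prim <- c(any(nb$bcol < min(bl[, 2])),
              any(nb$brow < min(bl[, 1]) | nb$brow > max(bl[, 1])),
              any(nb$bcol > max(bl[, 2])))
    touches <- any(cells[, 1] == 1 | cells[, 1] == worm$nrow |
                   cells[, 2] == 1 | cells[, 2] == worm$ncol)
    if (!touches) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nbc <- cbind(cells[, 1] + d[1], cells[, 2] + d[2])
        if (any(!worm$original_mask[nbc])) { touches <- TRUE; break }
      }
    }
    cats <- c(cats, switch(as.character(sum(prim)),
                           "3" = if (touches) "open_border" else "local_enclosed",
                           "2" = "open_border",
                           "1" = "whole_tissue",
                           "unclassifiable"))
  }
  sev <- c(no_stem_damage = 1, local_enclosed = 2, open_border = 3,
           whole_tissue = 4, unclassifiable = 5)
  cats[which.max(sev[cats])]
}

flood_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    q <- start
    lab[start] <- nxt
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && is.na(lab[j])) { lab[j] <- nxt; q <- c(q, j) }
      }
    }
  }
  lab
}

# Random damage scenario on block-aligned rectangles, for classification
# property tests.  Kinds: enclosed interior rectangle, rectangle touching
# the outline, anterior chunk, posterior chunk, somatic-only nick.
random_block_damage <- function(worm, seed) {
  set.seed(seed)
  bs <- worm$config$block_size
  kind <- sample(c("enclosed", "edge", "anterior", "posterior", "nick"), 1)
  if (kind == "nick") {
    # a few somatic cells inside one block, stem untouched
    brow <- sample(2:5, 1); bcol <- sample(8:22, 1)
    r0 <- (brow - 1) * bs; c0 <- (bcol - 1) * bs
    cells <- rbind(c(r0 + 2, c0 + 2), c(r0 + 2, c0 + 4))
    return(kill_cells(worm, cells))
  }
  if (kind == "enclosed") {
    br <- sample(2:4, 1); bc <- sample(8:20, 1)
    h <- sample(1:2, 1); v <- sample(1:2, 1)
    return(kill_region(worm, c((br - 1) * bs + 1, (br + h - 1) * bs,
                               (bc - 1) * bs + 1, (bc + v - 1) * bs)))
  }
  if (kind == "edge") {
    bc <- sample(8:20, 1); v <- sample(1:2, 1)
    return(kill_region(worm, c(1, 2 * bs,
                               (bc - 1) * bs + 1, (bc + v - 1) * bs)))
  }
  if (kind == "anterior") {
    bc <- sample(3:8, 1)
    return(kill_region(worm, c(1, worm$nrow, 1, bc * bs)))
  }
  bc <- sample(22:28, 1)
  kill_region(worm, c(1, worm$nrow, (bc - 1) * bs + 1, worm$ncol))
}
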