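# Five-stage control loop: (1) monitoring, (2) change detection,
# (3) damage identification, (4) repair, (5) bioelectric restoration.
# Mode 1 (no damage) runs 2 -> 5 -> 1; mode 2 (damage) runs 2 -> 3 -> 4 -> 5 -> 1.

new_stage_log <- function() {
  data.frame(tick = integer(), stage = integer(), actor = character(),
             event = character(), n_regen = integer(),
             stringsAsFactors = FALSE)
}

log_event <- function(log, tick, stage, actor, event, n_regen = 0L) {
  rbind(log, data.frame(tick = as.integer(tick), stage = as.integer(stage),
                        actor = actor, event = event,
                        n_regen = as.integer(n_regen),
                        stringsAsFactors = FALSE))
}

#' Stage sequence of a stage log
#'
#' @param log a stage log as produced by [run_cycle()].
#' @return integer vector of the stages visited, consecutive duplicates
#'   collapsed.
#' @export
stage_sequence <- function(log) rle(log$stage)$values

empty_regen <- function() {
  data.frame(row = integer(), col = integer(), type = character(),
             voltage = numeric(), producer = integer(),
             stringsAsFactors = FALSE)
}

# Deterministic choice of the repairing stem: anterior-most, then
# dorsal-most, among the candidates (tie-breaking fixed for
# reproducibility; any border stem would do).
pick_stem <- function(stems, ids) {
  cand <- stems[stems$id %in% ids & stems$alive, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand$bcol, cand$brow), , drop = FALSE]
  cand[1, ]
}

nearest_live_stem <- function(worm, row, col) {
  st <- worm$stems[worm$stems$alive, , drop = FALSE]
  if (!nrow(st)) stop("unrepairable: no live stem cells anywhere")
  d2 <- (st$home_row - row)^2 + (st$home_col - col)^2
  st <- st[order(d2, st$home_row, st$home_col), , drop = FALSE]
  st[1, ]
}

#' Repair local somatic damage (intact stem layer)
#'
#' For each dead somatic cell the nearest live stem cell (Euclidean
#' lattice distance; ties broken anterior-most then dorsal-most) migrates
#' to the damage border, divides to produce the new somatic cell -- whose
#' voltage is that of the producing stem cell -- and returns to its home
#' position.  Border statuses return to normal once their neighbourhoods
#' are complete.
#'
#' @param worm a damaged `worm`.
#' @param report a `damage_report` (used for context only).
#' @return the repaired worm, with a `regen` attribute recording each
#'   regenerated cell and its voltage at creation.
#' @export
repair_local_somatic <- function(worm, report = NULL) {
  dead <- which(worm$original_mask & !worm$alive, arr.ind = TRUE)
  regen <- empty_regen()
  if (nrow(dead)) {
    dead <- dead[order(dead[, 1], dead[, 2]), , drop = FALSE]
    for (i in seq_len(nrow(dead))) {
      r <- dead[i, 1]; c <- dead[i, 2]
      prod <- nearest_live_stem(worm, r, c)
      worm$alive[r, c] <- TRUE
      worm$voltage[r, c] <- prod$voltage
      worm$status[r, c] <- "normal"
      regen <- rbind(regen, data.frame(row = r, col = c, type = "somatic",
                                       voltage = prod$voltage,
                                       producer = prod$id,
                                       stringsAsFactors = FALSE))
    }
  }
  worm$status[worm$alive & worm$status %in% c("border", "affected")] <- "normal"
  attr(worm, "regen") <- regen
  worm
}

#' Repair damage involving missing stem cells
#'
#' A deterministic border stem cell (anterior-most, then dorsal-most)
#' migrates to the somatic damage border and produces one new stem cell
#' per missing block, each with the producer's voltage.  Each new stem
#' cell then refills its block's dead somatic cells, guided by the
#' somatic damage border; regeneration stops exactly when the dead region
#' is filled.
#'
#' @param worm a damaged `worm`.
#' @param report a `damage_report` with a non-empty stem border.
#' @return the repaired worm, with a `regen` attribute.
#' @export
repair_stem_region <- function(worm, report) {
  regen <- empty_regen()
  producer <- pick_stem(worm$stems, report$stem_border$ids)
  if (is.null(producer)) {
    any_live <- worm$stems[worm$stems$alive, , drop = FALSE]
    if (!nrow(any_live)) stop("unrepairable: no live stem cells anywhere")
    producer <- any_live[order(any_live$bcol, any_live$brow), ][1, ]
  }
  miss <- which(!worm$stems$alive)
  miss <- miss[order(worm$stems$bcol[miss], worm$stems$brow[miss])]
  for (j in miss) {
    worm$stems$alive[j] <- TRUE
    worm$stems$voltage[j] <- producer$voltage
    regen <- rbind(regen, data.frame(row = worm$stems$home_row[j],
                                     col = worm$stems$home_col[j],
                                     type = "stem",
                                     voltage = producer$voltage,
                                     producer = producer$id,
                                     stringsAsFactors = FALSE))
  }
  # each block's stem refills the dead somatic cells of its block
  dead <- which(worm$original_mask & !worm$alive, arr.ind = TRUE)
  if (nrow(dead)) {
    dead <- dead[order(dead[, 1], dead[, 2]), , drop = FALSE]
    blk <- cell_block(worm, dead[, 1], dead[, 2])
    key <- paste(worm$stems$brow, worm$stems$bcol)
    own <- match(paste(blk[, 1], blk[, 2]), key)
    for (i in seq_len(nrow(dead))) {
      r <- dead[i, 1]; c <- dead[i, 2]
      st <- worm$stems[own[i], ]
      worm$alive[r, c] <- TRUE
      worm$voltage[r, c] <- st$voltage
      worm$status[r, c] <- "normal"
      regen <- rbind(regen, data.frame(row = r, col = c, type = "somatic",
                                       voltage = st$voltage,
                                       producer = st$id,
                                       stringsAsFactors = FALSE))
    }
  }
  worm$status[worm$alive & worm$status %in% c("border", "affected")] <- "normal"
  attr(worm, "regen") <- regen
  worm
}

#' Regenerate whole missing tissues from the information field
#'
#' Border stem cells seed new stem cells for the missing tissues and grow
#' them towards the target anatomy reconstructed from the information
#' field's minimal body plan (`d`, `AR`, `n`).  Growth proceeds one block
#' column per direction per tick, anterior- and posterior-missing tissues
#' growing concurrently.  A new block's stem takes the producer's voltage
#' scaled by the ratio of the attractor voltages of the two nodes, so new
#' cells sit below their producers on the head-to-tail gradient; the
#' block's somatic cells take the new stem's voltage.
#'
#' @param worm a fragment `worm`.
#' @param missing tissues to regenerate (from
#'   [identify_missing_tissue()]); an empty set is a no-op.
#' @param info the information field (defaults to the worm's own).
#' @return the regrown worm, with `regen` and `ticks` attributes.
#' @export
regenerate_tissue <- function(worm, missing, info = worm$info_field) {
  if (!length(missing)) {
    attr(worm, "regen") <- empty_regen(); attr(worm, "ticks") <- 0L
    return(worm)
  }
  for (f in c("d", "AR", "n_corners", "attractor", "geometry"))
    if (is.null(info[[f]]))
      stop("configuration error: information field is missing '", f, "'")
  T_ <- info$attractor
  regen <- empty_regen()
  ticks <- 0L
  key <- paste(worm$stems$brow, worm$stems$bcol)
  target_cols <- sort(unique(which(apply(worm$block_mask, 2, any))))

  grow_block <- function(brow, bcol, from_bcol) {
    j <- match(paste(brow, bcol), key)
    prod_j <- match(paste(brow, from_bcol), key)
    prod <- if (!is.na(prod_j) && worm$stems$alive[prod_j])
      worm$stems[prod_j, ]
    else nearest_live_stem(worm, worm$stems$home_row[j], worm$stems$home_col[j])
    node_new <- worm$node_block[brow, bcol]
    node_prod <- worm$node_block[prod$brow, prod$bcol]
    v_new <- prod$voltage * T_[node_new] / T_[node_prod]
    worm$stems$alive[j] <<- TRUE
    worm$stems$voltage[j] <<- v_new
    regen <<- rbind(regen, data.frame(row = worm$stems$home_row[j],
                                      col = worm$stems$home_col[j],
                                      type = "stem", voltage = v_new,
                                      producer = prod$id,
                                      stringsAsFactors = FALSE))
    bs <- worm$config$block_size
    rows <- (brow - 1L) * bs + seq_len(bs)
    cols <- (bcol - 1L) * bs + seq_len(bs)
    for (r in rows) for (c in cols) {
      if (!worm$original_mask[r, c] || worm$alive[r, c]) next
      worm$alive[r, c] <<- TRUE
      worm$voltage[r, c] <<- v_new
      worm$status[r, c] <<- "normal"
      regen <<- rbind(regen, data.frame(row = r, col = c, type = "somatic",
                                        voltage = v_new,
                                        producer = worm$stems$id[j],
                                        stringsAsFactors = FALSE))
    }
  }

  repeat {
    live_bc <- which(vapply(target_cols, function(bc) {
      cols <- (bc - 1L) * worm$config$block_size + seq_len(worm$config$block_size)
      any(worm$alive[, cols])
    }, logical(1)))
    lo <- target_cols[min(live_bc)]; hi <- target_cols[max(live_bc)]
    grew <- FALSE
    nxt_hi <- target_cols[target_cols > hi]
    if (length(nxt_hi)) {
      bc <- nxt_hi[1]
      for (brow in which(worm$block_mask[, bc])) grow_block(brow, bc, hi)
      grew <- TRUE
    }
    nxt_lo <- target_cols[target_cols < lo]
    if (length(nxt_lo)) {
      bc <- nxt_lo[length(nxt_lo)]
      for (brow in which(worm$block_mask[, bc])) grow_block(brow, bc, lo)
      grew <- TRUE
    }
    if (!grew) break
    ticks <- ticks + 1L
  }
  worm$status[worm$alive & worm$status %in% c("border", "affected")] <- "normal"
  attr(worm, "regen") <- regen
  attr(worm, "ticks") <- ticks
  worm
}

#' Run one cycle of the five-stage controller
#'
#' Detects the current bioelectric change (stage 2); with no damage the
#' associative memory network restores the pattern directly (stage 5) and
#' the system returns to monitoring (stage 1).  With damage, the somatic
#' and stem networks identify and classify it (stage 3), the appropriate
#' repair operator restores the anatomy (stage 4), the AMN -- retrained
#' first if whole nodes were destroyed -- restores the bioelectric
#' pattern (stage 5), and monitoring resumes (stage 1).
#'
#' @param worm a `worm` with trained motifs.
#' @param amn a trained [train_amn()] network.
#' @param sc optional [scenario()] applied before the cycle (must not be
#'   a cut; see [run_until_homeostasis()] for cuts).
#' @param max_repair_rounds safety bound on stage-4 dispatch rounds.
#' @return list of class `cycle_result`: `worm`, `amn`, `log`, `report`,
#'   `regen`, `trajectory`.
#' @export
run_cycle <- function(worm, amn, sc = NULL, max_repair_rounds = 10L) {
  if (!is.null(sc)) {
    worm <- apply_scenario(worm, sc)
    if (is.list(worm) && !inherits(worm, "worm"))
      stop("run_cycle cannot follow a cut; use run_until_homeostasis()")
  }
  log <- new_stage_log()
  regen <- empty_regen()
  tick <- 0L
  ev <- perturbation_event(worm)
  report <- NULL
  traj <- NULL

  if (nrow(ev$cells) == 0 && nrow(ev$dead) == 0) {
    log <- log_event(log, tick, 1L, "controller", "monitoring: no change")
    return(structure(list(worm = worm, amn = amn, log = log, report = NULL,
                          regen = regen, trajectory = NULL),
                     class = "cycle_result"))
  }

  verdict <- detect_change(worm, ev)
  log <- log_event(log, tick, 2L, "somatic+stem network",
                   paste0("change detected: ", verdict))

  if (verdict == "damage") {
    report <- assess_damage(worm)
    log <- log_event(log, tick, 3L, "stem network",
                     paste0("damage classified: ", report$category,
                            if (report$composite) " (composite)" else ""))
    rebuilt <- report$lost_nodes
    rounds <- 0L
    while (any(worm$original_mask & !worm$alive) || !all(worm$stems$alive)) {
      rounds <- rounds + 1L
      if (rounds > max_repair_rounds)
        stop("non-termination error: stage 4 did not restore anatomy in ",
             max_repair_rounds, " rounds")
      rep_i <- if (rounds == 1L) report else assess_damage(worm)
      cats <- vapply(rep_i$components, `[[`, character(1), "category")
      worm <- if ("whole_tissue" %in% cats) {
        regenerate_tissue(worm, rep_i$missing_tissues)
      } else if (!all(worm$stems$alive)) {
        repair_stem_region(worm, rep_i)
      } else {
        repair_local_somatic(worm, rep_i)
      }
      step_regen <- attr(worm, "regen")
      regen <- rbind(regen, step_regen)
      tick <- tick + max(1L, attr(worm, "ticks") %or_default% 1L)
      log <- log_event(log, tick, 4L, "stem+somatic network",
                       "regeneration", nrow(step_regen))
    }
    if (length(rebuilt)) {
      amn <- retrain_after_repair(amn, worm, rebuilt)
      log <- log_event(log, tick, 5L, "AMN",
                       paste0("retrained after rebuilding nodes ",
                              paste(rebuilt, collapse = ",")))
    }
  }

  s0 <- node_state(worm)
  traj <- restore_pattern(amn, s0)
  worm <- push_node_voltages(worm, final_state(traj))
  worm$status[worm$alive] <- "normal"
  log <- log_event(log, tick, 5L, "AMN",
                   paste0("bioelectric pattern restored in ",
                          nrow(traj) - 1L, " step(s)"))
  log <- log_event(log, tick, 1L, "controller", "monitoring resumed")
  structure(list(worm = worm, amn = amn, log = log, report = report,
                 regen = regen, trajectory = traj),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result> stages:", paste(stage_sequence(x$log), collapse = " -> "),
      "\n")
  if (nrow(x$regen))
    cat(sprintf("  regenerated %d cells (%d stem, %d somatic)\n",
                nrow(x$regen), sum(x$regen$type == "stem"),
                sum(x$regen$type == "somatic")))
  print(worm_summary(x$worm))
  invisible(x)
}

#' Run the controller until anatomical and bioelectric homeostasis
#'
#' Applies a damage scenario and iterates controller cycles until the
#' worm's anatomy matches the original body plan and every cell voltage
#' equals its attractor-implied value.  After a cut every fragment is run
#' independently, each regenerating into a complete worm.
#'
#' @param worm a `worm` with trained motifs.
#' @param amn a trained `amn`.
#' @param sc a [scenario()], or `NULL` to run on the worm as-is.
#' @param max_cycles safety bound on controller cycles per fragment.
#' @param tol voltage tolerance for homeostasis.
#' @return object of class `regen_result`: a list with one element per
#'   fragment, each holding `worm`, `amn`, `log`, `report`, `regen`,
#'   `recovered`.
#' @export
run_until_homeostasis <- function(worm, amn, sc = NULL, max_cycles = 5L,
                                  tol = 1e-6) {
  state <- if (is.null(sc)) worm else apply_scenario(worm, sc)
  frags <- if (inherits(state, "worm")) list(state) else state
  results <- lapply(frags, function(w) {
    log <- new_stage_log()
    regen <- empty_regen()
    report <- NULL
    a <- amn
    for (cy in seq_len(max_cycles)) {
      res <- run_cycle(w, a)
      w <- res$worm; a <- res$amn
      log <- rbind(log, res$log)
      regen <- rbind(regen, res$regen)
      if (!is.null(res$report)) report <- res$report
      done <- matches_original(w) &&
        max(abs(w$voltage[w$alive] - w$home_voltage[w$alive])) < tol
      if (done) break
    }
    recovered <- matches_original(w) &&
      max(abs(w$voltage[w$alive] - w$home_voltage[w$alive])) < tol
    if (!recovered)
      warning("non-termination: fragment did not reach homeostasis within ",
              max_cycles, " cycles")
    list(worm = w, amn = a, log = log, report = report, regen = regen,
         recovered = recovered)
  })
  structure(list(fragments = results, scenario = sc), class = "regen_result")
}

#' @export
print.regen_result <- function(x, ...) {
  cat(sprintf("<regen_result> %d fragment(s)\n", length(x$fragments)))
  for (i in seq_along(x$fragments)) {
    f <- x$fragments[[i]]
    cat(sprintf(" fragment %d: recovered = %s, stages %s, %d cells regenerated\n",
                i, f$recovered, paste(stage_sequence(f$log), collapse = "->"),
                nrow(f$regen)))
  }
  invisible(x)
}
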