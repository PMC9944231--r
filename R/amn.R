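# Associative memory network (AMN): a 13-node sparsified Hopfield variant
# storing the body-wide bioelectric gradient as its attractor.

#' Clamped linear activation
#'
#' Piecewise-linear transfer function of the AMN nodes: the identity
#' clamped to \[-1, 1\].
#'
#' @param a numeric.
#' @return `1` if `a >= 1`, `-1` if `a <= -1`, else `a` (vectorised).
#' @export
relu_clamp <- function(a) pmin(1, pmax(-1, a))

#' AMN training configuration
#'
#' @param delta learning rate.
#' @param n_patterns number of perturbed training patterns; half drawn
#'   from the normal-physiology regime (all nodes shifted by up to ±10%),
#'   half from the damage regime (shifts of 10-50% in magnitude, with a
#'   random contiguous run of nodes zeroed in half of those patterns, as
#'   when nodes are destroyed).
#' @param normal_noise upper bound of the normal-regime fractional shift.
#' @param damage_noise range (low, high) of the damage-regime shift.
#' @param tol convergence tolerance: training stops when the largest
#'   per-node error over a full epoch falls below it.
#' @param max_epochs epoch budget before training is declared failed.
#' @param full_connectivity connect every node pair instead of only
#'   anterior/posterior-adjacent ones (for comparison runs).
#' @param seed seed for weight initialisation and pattern generation.
#' @return list of class `amn_config`.
#' @export
amn_config <- function(delta = 0.05, n_patterns = 500L,
                       normal_noise = 0.10, damage_noise = c(0.10, 0.50),
                       tol = 1e-6, max_epochs = 10000L,
                       full_connectivity = FALSE, seed = 0L) {
  structure(list(delta = delta, n_patterns = as.integer(n_patterns),
                 normal_noise = normal_noise, damage_noise = damage_noise,
                 tol = tol, max_epochs = as.integer(max_epochs),
                 full_connectivity = isTRUE(full_connectivity),
                 seed = as.integer(seed)),
            class = "amn_config")
}

# Directed link mask and sign structure over n nodes.  Anterior->posterior
# links (input node j anterior to receiving node i, j < i) are activating
# (weights >= 0); posterior->anterior links are inhibitory (<= 0).  The
# sparse topology keeps only links between A/P-adjacent nodes.
amn_topology <- function(n, full = FALSE) {
  allow <- matrix(FALSE, n, n)
  if (full) {
    allow[] <- TRUE; diag(allow) <- FALSE
  } else {
    for (i in seq_len(n - 1)) {
      allow[i + 1, i] <- TRUE   # forward link i -> i+1 (input to node i+1)
      allow[i, i + 1] <- TRUE   # backward link i+1 -> i
    }
  }
  sign <- matrix(0, n, n)
  sign[lower.tri(sign)] <- 1    # receiving node i > source j: forward
  sign[upper.tri(sign)] <- -1
  sign[!allow] <- 0
  list(allow = allow, sign = sign)
}

amn_init_weights <- function(topo, rng) {
  n <- nrow(topo$allow)
  W <- matrix(0, n, n)
  nl <- sum(topo$allow)
  W[topo$allow] <- rng$runif(nl, 0, 0.5)
  W[topo$sign < 0] <- -W[topo$sign < 0]
  b <- rng$runif(n, -0.5, 0.5)
  list(W = W, b = b)
}

clip_signs <- function(W, topo) {
  W[topo$sign > 0] <- pmax(0, W[topo$sign > 0])
  W[topo$sign < 0] <- pmin(0, W[topo$sign < 0])
  W[!topo$allow] <- 0
  W
}

# Draw perturbed training patterns around the target T.
amn_patterns <- function(T_, cfg, rng) {
  n <- length(T_)
  lapply(seq_len(cfg$n_patterns), function(p) {
    if (p %% 2L == 1L) {
      u <- rng$runif(n, -cfg$normal_noise, cfg$normal_noise)
      T_ * (1 + u)
    } else {
      mag <- rng$runif(n, cfg$damage_noise[1], cfg$damage_noise[2])
      sgn <- ifelse(rng$runif(n) < 0.5, -1, 1)
      I <- T_ * (1 + sgn * mag)
      if (rng$runif(1) < 0.5) {
        len <- rng$sample_int(n %/% 2L, 1L)
        start <- rng$sample_int(n - len + 1L, 1L)
        I[start:(start + len - 1L)] <- 0
      }
      I
    }
  })
}

# One pass of the error-driven learning rule over a pattern set.
amn_train_epoch <- function(W, b, topo, patterns, T_, delta) {
  maxerr <- 0
  for (I in patterns) {
    s <- relu_clamp(drop(W %*% I) + b)
    e <- T_ - s
    maxerr <- max(maxerr, max(abs(e)))
    W <- clip_signs(W + delta * (e %o% I) * topo$allow, topo)
    b <- b + delta * e
  }
  list(W = W, b = b, maxerr = maxerr)
}

#' Train the associative memory network
#'
#' Stores the worm's homeostatic nodal voltage pattern as the attractor of
#' a 13-node recurrent network with clamped-linear units
#' (`s_i = theta(sum_j w_ij s_j + b_i)`).  Weights start at random
#' magnitudes with the directional sign structure (head-to-tail activation,
#' tail-to-head inhibition) and are adjusted per perturbed training
#' pattern by the error-driven rule `w_ij <- w_ij + e_i * delta * s_j`,
#' `b_i <- b_i + e_i * delta` with `e_i = T_i - s_i`, until the largest
#' error over an epoch drops below `tol`.  The learned attractor is also
#' written to the worm's information field by the caller.
#'
#' @param worm a `worm` with an assigned bioelectric pattern.
#' @param cfg an [amn_config()].
#' @return object of class `amn`.
#' @export
train_amn <- function(worm, cfg = amn_config()) {
  T_ <- worm$node_voltages
  if (is.null(T_)) stop("worm has no homeostatic bioelectric pattern assigned")
  n <- length(T_)
  topo <- amn_topology(n, cfg$full_connectivity)
  rng <- local_rng(cfg$seed)
  init <- amn_init_weights(topo, rng)
  patterns <- amn_patterns(T_, cfg, rng)
  W <- init$W; b <- init$b
  epochs <- 0L
  repeat {
    epochs <- epochs + 1L
    fit <- amn_train_epoch(W, b, topo, patterns, T_, cfg$delta)
    W <- fit$W; b <- fit$b
    if (fit$maxerr < cfg$tol) break
    if (epochs >= cfg$max_epochs)
      stop("training error: AMN did not converge in ", cfg$max_epochs,
           " epochs (final max error ", signif(fit$maxerr, 4), ")")
  }
  structure(list(n = n, W = W, b = b, attractor = T_, topology = topo,
                 config = cfg, epochs = epochs, final_err = fit$maxerr,
                 trained = TRUE),
            class = "amn")
}

#' Asynchronously update one AMN node
#'
#' Replaces `s[i]` with the clamped linear response to the current
#' (partially updated) state.
#'
#' @param amn a trained `amn`.
#' @param state numeric state vector of length `amn$n`.
#' @param i node index.
#' @return the updated state vector.
#' @export
update_node <- function(amn, state, i) {
  state[i] <- relu_clamp(sum(amn$W[i, ] * state) + amn$b[i])
  state
}

amn_sweep <- function(amn, state) {
  for (i in seq_len(amn$n)) state <- update_node(amn, state, i)
  state
}

#' Restore a perturbed bioelectric pattern
#'
#' Iterates asynchronous update sweeps (node 1 to n) from the perturbed
#' state until the largest node change in a sweep falls below `tol`,
#' returning the full restoration trajectory.
#'
#' @param amn a trained `amn`.
#' @param perturbed numeric state vector.
#' @param max_sweeps sweep budget.
#' @param tol per-sweep convergence tolerance.
#' @return object of class `amn_trajectory`: a matrix with one row per
#'   visited state (the perturbed input first), plus attributes
#'   `converged` and `recalled` (final state within `tol` of the
#'   attractor).
#' @export
restore_pattern <- function(amn, perturbed, max_sweeps = 100L, tol = 1e-6) {
  if (!isTRUE(amn$trained)) stop("AMN is not trained")
  s <- as.numeric(perturbed)
  if (length(s) != amn$n)
    stop("validation error: state has ", length(s), " nodes, AMN has ", amn$n)
  traj <- list(s)
  converged <- FALSE
  for (sw in seq_len(max_sweeps)) {
    s2 <- amn_sweep(amn, s)
    if (max(abs(s2 - s)) < tol) { converged <- TRUE; break }
    s <- s2
    traj[[length(traj) + 1L]] <- s
  }
  out <- do.call(rbind, traj)
  attr(out, "converged") <- converged
  attr(out, "recalled") <- converged &&
    max(abs(traj[[length(traj)]] - amn$attractor)) < 1e-4
  class(out) <- c("amn_trajectory", class(out))
  if (!converged)
    warning("restoration error: AMN did not settle within ", max_sweeps,
            " sweeps; trajectory returned")
  out
}

final_state <- function(traj) traj[nrow(traj), ]

#' Retrain the AMN after structural repair
#'
#' When whole nodes were destroyed and rebuilt, the network re-establishes
#' the links touching the rebuilt nodes (re-initialised with the
#' directional sign structure) and retrains against the attractor fetched
#' from the worm's information field.  With no rebuilt nodes the AMN is
#' returned unchanged.
#'
#' @param amn a trained `amn`.
#' @param worm the repaired `worm` (anatomy must be fully restored).
#' @param rebuilt integer ids of the rebuilt nodes.
#' @return a retrained `amn`.
#' @export
retrain_after_repair <- function(amn, worm, rebuilt = integer(0)) {
  if (!matches_original(worm))
    stop("precondition error: anatomy is not fully repaired")
  if (!length(rebuilt)) return(amn)
  T_ <- worm$info_field$attractor
  cfg <- amn$config
  topo <- amn$topology
  rng <- local_rng(cfg$seed + 1L)
  fresh <- amn_init_weights(topo, rng)
  touched <- outer(seq_len(amn$n) %in% rebuilt, rep(TRUE, amn$n), `|`) |
    outer(rep(TRUE, amn$n), seq_len(amn$n) %in% rebuilt, `|`)
  W <- amn$W; b <- amn$b
  W[touched & topo$allow] <- fresh$W[touched & topo$allow]
  b[rebuilt] <- fresh$b[rebuilt]
  patterns <- amn_patterns(T_, cfg, rng)
  epochs <- 0L
  repeat {
    epochs <- epochs + 1L
    fit <- amn_train_epoch(W, b, topo, patterns, T_, cfg$delta)
    W <- fit$W; b <- fit$b
    if (fit$maxerr < cfg$tol) break
    if (epochs >= cfg$max_epochs)
      stop("training error: AMN retraining did not converge")
  }
  amn$W <- W; amn$b <- b
  amn$attractor <- T_
  amn$epochs <- epochs
  amn$final_err <- fit$maxerr
  amn
}

#' @export
print.amn <- function(x, ...) {
  cat(sprintf("<amn> %d nodes, %s topology, trained in %d epochs (max err %.2e)\n",
              x$n, if (x$config$full_connectivity) "full" else "sparse A/P chain",
              x$epochs, x$final_err))
  cat("  attractor:", paste(sprintf("%.3f", x$attractor), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.amn <- function(object, ...) {
  fwd <- object$W[object$topology$sign > 0]
  bwd <- object$W[object$topology$sign < 0]
  out <- list(n = object$n, epochs = object$epochs,
              final_err = object$final_err,
              forward_weight_range = range(fwd),
              backward_weight_range = range(bwd),
              bias_range = range(object$b),
              attractor = object$attractor)
  class(out) <- "summary.amn"
  out
}

#' @export
print.summary.amn <- function(x, ...) {
  cat(sprintf("AMN: %d nodes, %d training epochs, final max error %.2e\n",
              x$n, x$epochs, x$final_err))
  cat(sprintf("  forward (activating) weights in [%.2e, %.2e]\n",
              x$forward_weight_range[1], x$forward_weight_range[2]))
  cat(sprintf("  backward (inhibitory) weights in [%.2e, %.2e]\n",
              x$backward_weight_range[1], x$backward_weight_range[2]))
  invisible(x)
}

#' @export
coef.amn <- function(object, ...) list(W = object$W, b = object$b)

#' Recall the stored pattern from a perturbed state
#'
#' @param object a trained `amn`.
#' @param newdata perturbed nodal state; defaults to the attractor.
#' @param ... passed to [restore_pattern()].
#' @return the final recalled state vector.
#' @export
predict.amn <- function(object, newdata = object$attractor, ...) {
  final_state(restore_pattern(object, newdata, ...))
}

#' Simulate perturbed bioelectric patterns from the training regimes
#'
#' @param object a trained `amn`.
#' @param nsim number of patterns.
#' @param seed RNG seed.
#' @param ... unused.
#' @return matrix with one pattern per row.
#' @export
simulate.amn <- function(object, nsim = 1, seed = 0L, ...) {
  cfg <- object$config
  cfg$n_patterns <- as.integer(nsim)
  do.call(rbind, amn_patterns(object$attractor, cfg, local_rng(seed)))
}
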