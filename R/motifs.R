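#' Training configuration for perceptron communication motifs
#'
#' @param delta learning rate of the error-driven update.
#' @param max_epochs maximum passes over the truth table before training
#'   is declared failed.
#' @param seed seed for the random initial weights and bias.
#' @return list of class `motif_config`.
#' @export
motif_config <- function(delta = 0.1, max_epochs = 1000L, seed = 0L) {
  if (delta <= 0) stop("validation error: learning rate must be positive")
  structure(list(delta = delta, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "motif_config")
}

motif_kinds <- c(corner = 2L, border = 3L, interior = 4L)

#' Standardize neighbour voltages to binary presence inputs
#'
#' A live neighbour holds a negative (hyperpolarized) voltage and maps to
#' 1; a dead or missing neighbour (encoded `NA`) maps to 0.  Non-negative
#' voltages are rejected: the system is hyperpolarized by construction.
#'
#' @param neighbor_states numeric vector of length 2 to 4; `NA` marks an
#'   absent neighbour.
#' @return integer vector of 0/1, order preserved.
#' @export
standardize_inputs <- function(neighbor_states) {
  v <- as.numeric(neighbor_states)
  if (length(v) < 2L || length(v) > 4L)
    stop("validation error: a cell has between 2 and 4 neighbours")
  if (any(!is.na(v) & v >= 0))
    stop("validation error: non-negative neighbour voltage; ",
         "live cells are hyperpolarized (negative)")
  as.integer(!is.na(v))
}

#' Train one perceptron communication motif
#'
#' A motif is a single threshold unit whose weights stand for the
#' normalized gap-junction conductances between a cell and its k
#' neighbours (k = 2 corner, 3 border, 4 interior).  Starting from random
#' weights and bias, the error-driven rule `w <- w + e * delta * x`,
#' `b <- b + e * delta` (error `e` = target minus thresholded output,
#' threshold 0.5) is applied over the full binary truth table until every
#' input is classified: output 1 exactly when all neighbours are present.
#'
#' @param kind one of `"corner"`, `"border"`, `"interior"`.
#' @param cfg a [motif_config()].
#' @return object of class `motif` with elements `kind`, `k`, `w`, `b`,
#'   `trained`, `epochs`.
#' @export
train_motif <- function(kind = c("corner", "border", "interior"),
                        cfg = motif_config()) {
  kind <- match.arg(kind)
  k <- motif_kinds[[kind]]
  X <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(X) <- NULL
  target <- as.integer(rowSums(X) == k)
  rng <- local_rng(cfg$seed + k)
  w <- rng$runif(k, -0.5, 0.5)
  b <- rng$runif(1, -0.5, 0.5)
  epochs <- 0L
  repeat {
    epochs <- epochs + 1L
    errs <- 0L
    for (i in seq_len(nrow(X))) {
      y <- as.integer(sum(w * X[i, ]) + b >= 0.5)
      e <- target[i] - y
      if (e != 0L) {
        w <- w + e * cfg$delta * X[i, ]
        b <- b + e * cfg$delta
        errs <- errs + 1L
      }
    }
    if (errs == 0L) break
    if (epochs >= cfg$max_epochs)
      stop("training error: motif '", kind, "' did not converge in ",
           cfg$max_epochs, " epochs")
  }
  structure(list(kind = kind, k = k, w = w, b = b,
                 trained = TRUE, epochs = epochs, seed = cfg$seed),
            class = "motif")
}

#' Train the full set of three motifs
#'
#' @param cfg a [motif_config()].
#' @return list of class `motif_set` with elements `corner`, `border`,
#'   `interior`.
#' @export
train_motifs <- function(cfg = motif_config()) {
  out <- lapply(names(motif_kinds), train_motif, cfg = cfg)
  names(out) <- names(motif_kinds)
  class(out) <- "motif_set"
  out
}

#' Apply a trained motif to binary presence inputs
#'
#' @param motif a trained `motif`.
#' @param inputs 0/1 vector of length `motif$k`.
#' @return 0 or 1: 1 means all neighbours present.
#' @export
apply_motif <- function(motif, inputs) {
  if (!isTRUE(motif$trained)) stop("validation error: motif is not trained")
  if (length(inputs) != motif$k)
    stop("validation error: motif '", motif$kind, "' expects ", motif$k,
         " inputs, got ", length(inputs))
  as.integer(sum(motif$w * inputs) + motif$b >= 0.5)
}

# Vectorised motif response for an n x k matrix of binary inputs.
apply_motif_rows <- function(motif, X) {
  if (ncol(X) != motif$k)
    stop("validation error: motif '", motif$kind, "' expects ", motif$k, " inputs")
  as.integer(drop(X %*% motif$w) + motif$b >= 0.5)
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif:%s> k=%d, trained in %d epochs\n  w = %s, b = %.3f\n",
              x$kind, x$k, x$epochs,
              paste(sprintf("%.3f", x$w), collapse = ", "), x$b))
  invisible(x)
}

#' @export
print.motif_set <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}

# Small self-contained RNG scope: draws are reproducible for a given seed
# and do not disturb the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = draw(stats::runif),
       sample = draw(base::sample),
       sample_int = draw(base::sample.int))
}
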