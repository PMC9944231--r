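# Worm-state serialization (JSON), scenario files (YAML), and grid/log
# dumps (CSV, JSON-lines).

WORM_SCHEMA_VERSION <- "1.0"

worm_required_fields <- c("schema_version", "config", "block_mask",
                          "tissue_block", "node_block", "alive", "voltage",
                          "status", "original_mask", "stems", "node_voltages")

#' Save a worm (and its AMN) to a JSON document
#'
#' The document is self-contained: geometry, per-cell state, the stem
#' table, trained motif weights, the AMN weights and attractor, and the
#' configuration echo.  The schema is shipped in
#' `inst/schema/worm-state-schema.json`.
#'
#' @param worm a `worm`.
#' @param amn optional trained `amn` to embed.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_worm <- function(worm, amn = NULL, path) {
  doc <- list(
    schema_version = WORM_SCHEMA_VERSION,
    config = unclass(worm$config),
    block_mask = worm$block_mask,
    tissue_block = worm$tissue_block,
    node_block = worm$node_block,
    alive = worm$alive,
    voltage = worm$voltage,
    status = worm$status,
    original_mask = worm$original_mask,
    stems = worm$stems,
    node_voltages = worm$node_voltages,
    motifs = if (!is.null(worm$motifs))
      lapply(worm$motifs, function(m) unclass(m)) else NULL,
    amn = if (!is.null(amn)) list(
      n = amn$n, W = amn$W, b = amn$b, attractor = amn$attractor,
      allow = amn$topology$allow, sign = amn$topology$sign,
      config = unclass(amn$config), epochs = amn$epochs,
      final_err = amn$final_err) else NULL
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a worm (and AMN) from a JSON document
#'
#' Validates the document structure and reconstructs the worm, including
#' derived per-cell lookup tables and the information field.
#'
#' @param path a file written by [save_worm()].
#' @return list with elements `worm` and `amn` (the latter `NULL` if the
#'   document has none).
#' @export
load_worm <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("load error: cannot parse '", path, "': ",
                         conditionMessage(e)))
  miss <- setdiff(worm_required_fields, names(doc))
  if (length(miss))
    stop("load error: worm document is missing field(s): ",
         paste(miss, collapse = ", "))
  if (!identical(doc$schema_version, WORM_SCHEMA_VERSION))
    stop("load error: unsupported schema version '", doc$schema_version, "'")

  cfg <- doc$config
  cfg$taper <- as.integer(cfg$taper)
  cfg <- do.call(worm_config, cfg)
  worm <- build_worm(cfg, node_voltages = as.numeric(doc$node_voltages))

  to_mat <- function(x, mode) {
    m <- as.matrix(x)
    storage.mode(m) <- mode
    dimnames(m) <- NULL
    m
  }
  worm$alive <- to_mat(doc$alive, "logical")
  worm$voltage <- to_mat(doc$voltage, "double")
  worm$status <- to_mat(doc$status, "character")
  stems <- as.data.frame(doc$stems)
  stems$id <- as.integer(stems$id)
  for (f in c("brow", "bcol", "row", "col", "home_row", "home_col"))
    stems[[f]] <- as.integer(stems[[f]])
  stems$voltage <- as.numeric(stems$voltage)
  stems$alive <- as.logical(stems$alive)
  worm$stems <- stems[names(worm$stems)]
  if (length(doc$motifs)) {
    worm$motifs <- lapply(doc$motifs, function(m) {
      m$w <- as.numeric(m$w); m$k <- as.integer(m$k)
      class(m) <- "motif"; m
    })
    class(worm$motifs) <- "motif_set"
  }
  amn <- NULL
  if (length(doc$amn)) {
    a <- doc$amn
    amn <- structure(list(
      n = as.integer(a$n),
      W = to_mat(a$W, "double"), b = as.numeric(a$b),
      attractor = as.numeric(a$attractor),
      topology = list(allow = to_mat(a$allow, "logical"),
                      sign = to_mat(a$sign, "double")),
      config = do.call(amn_config, a$config[setdiff(names(a$config), NULL)]),
      epochs = as.integer(a$epochs), final_err = as.numeric(a$final_err),
      trained = TRUE), class = "amn")
  }
  list(worm = worm, amn = amn)
}

# ---- scenario files ---------------------------------------------------

ser_scenario <- function(sc) {
  out <- list(kind = sc$kind)
  if (!is.null(sc$cells)) out$cells <- list(row = as.integer(sc$cells[, 1]),
                                            col = as.integer(sc$cells[, 2]))
  if (!is.null(sc$blocks)) out$blocks <- list(row = as.integer(sc$blocks[, 1]),
                                              col = as.integer(sc$blocks[, 2]))
  if (!is.null(sc$rect)) out$rect <- as.integer(sc$rect)
  if (!is.null(sc$planes)) out$planes <- sc$planes
  if (!is.null(sc$fraction)) out$fraction <- sc$fraction
  if (!is.null(sc$seed)) out$seed <- sc$seed
  if (!is.null(sc$steps)) out$steps <- lapply(sc$steps, ser_scenario)
  out
}

deser_scenario <- function(x) {
  args <- list(kind = x$kind)
  if (!is.null(x$cells)) args$cells <- cbind(x$cells$row, x$cells$col)
  if (!is.null(x$blocks)) args$blocks <- cbind(x$blocks$row, x$blocks$col)
  if (!is.null(x$rect)) args$rect <- x$rect
  if (!is.null(x$planes)) args$planes <- x$planes
  if (!is.null(x$fraction)) args$fraction <- x$fraction
  if (!is.null(x$seed)) args$seed <- x$seed
  if (!is.null(x$steps)) args$steps <- lapply(x$steps, deser_scenario)
  do.call(scenario, args)
}

#' Save / load a damage scenario as YAML
#'
#' @param sc a [scenario()].
#' @param path file path.
#' @return `path` (save) or the scenario (load).
#' @export
save_scenario <- function(sc, path) {
  yaml::write_yaml(ser_scenario(sc), path)
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) deser_scenario(yaml::read_yaml(path))

# ---- grids and logs ---------------------------------------------------

#' Write the voltage grid as CSV
#'
#' Header row then row-major voltages; dead or out-of-outline cells carry
#' the sentinel `NA`.
#'
#' @param worm a `worm`.
#' @param path file path.
#' @export
write_voltage_grid <- function(worm, path) {
  utils::write.csv(worm$voltage, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write cell statuses as CSV
#'
#' One `(row, col, status)` record per cell inside the worm outline;
#' missing cells are reported with status `"dead"`.
#'
#' @param worm a `worm`.
#' @param path file path.
#' @export
write_status_csv <- function(worm, path) {
  idx <- which(worm$original_mask, arr.ind = TRUE)
  status <- ifelse(worm$alive[idx], worm$status[idx], "dead")
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2], status = status),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a stage log as JSON-lines
#'
#' @param log a stage log.
#' @param path file path.
#' @export
write_stage_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i)
    as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
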