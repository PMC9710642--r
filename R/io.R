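# All on-disk formats are plain UTF-8 TSV with '.' decimals: portable,
# diff-able and byte-stable across runs, which the determinism contract
# (same resolved config + seed => byte-identical outputs) relies on.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

dim_colnames <- function(node, dim) paste(node, seq_len(dim) - 1L, sep = "_")

#' Write a timecourse to per-node TSV files
#'
#' Writes `<node>_Z.tsv`, `<node>_X.tsv` and `<node>_Y.tsv` for every node
#' into `dir`: first column `time`, remaining columns
#' `<node>_0 ... <node>_{d-1}`, tab-delimited.
#'
#' @param timecourse A `timecourse`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_timecourse <- function(timecourse, dir) {
  stopifnot(inherits(timecourse, "timecourse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nd in timecourse$node_names) {
    cols <- dim_colnames(nd, timecourse$node_dims[[nd]])
    for (m in c("Z", "X", "Y")) {
      df <- data.frame(time = timecourse$times,
                       timecourse[[m]][, cols, drop = FALSE],
                       check.names = FALSE)
      write_tsv(df, file.path(dir, sprintf("%s_%s.tsv", nd, m)))
    }
  }
  invisible(dir)
}

#' Read a timecourse written by [write_timecourse()]
#'
#' @param dir Directory holding `<node>_Z.tsv` (and optionally `_X`/`_Y`)
#'   files.
#' @param nodes Node names in order; default: inferred from the `*_Z.tsv`
#'   file names, sorted.
#' @return A `timecourse`.
#' @export
read_timecourse <- function(dir, nodes = NULL) {
  if (is.null(nodes)) {
    zf <- list.files(dir, pattern = "_Z\\.tsv$")
    if (!length(zf)) glv_config_error(sprintf("no *_Z.tsv files in '%s'", dir))
    nodes <- sort(sub("_Z\\.tsv$", "", zf))
  }
  read_mat <- function(node, m) {
    path <- file.path(dir, sprintf("%s_%s.tsv", node, m))
    if (!file.exists(path)) return(NULL)
    df <- read_tsv(path)
    list(times = df$time, mat = as.matrix(df[, -1L, drop = FALSE]))
  }
  per_node <- lapply(nodes, read_mat, m = "Z")
  times <- per_node[[1L]]$times
  Z <- do.call(cbind, lapply(per_node, `[[`, "mat"))
  dims <- stats::setNames(vapply(per_node, function(x) ncol(x$mat), integer(1)), nodes)
  bindm <- function(m) {
    parts <- lapply(nodes, read_mat, m = m)
    if (any(vapply(parts, is.null, logical(1)))) return(NULL)
    do.call(cbind, lapply(parts, `[[`, "mat"))
  }
  X <- bindm("X") %||% suppressWarnings(to_relative(Z))
  Y <- bindm("Y")
  if (is.null(Y)) Y <- matrix(0L, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  new_timecourse(nodes, dims, Z, X, Y, times)
}

#' Write gLV parameter vectors for a set of nodes
#'
#' Writes `<node>_growth_rates.tsv` and `<node>_initial_abundances.tsv`
#' (one column per dimension, single value row) for each node.
#'
#' @param nodes List of [node_spec()] with parameters filled in.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_node_params <- function(nodes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nd in nodes) {
    cols <- dim_colnames(nd$name, nd$dim)
    if (!is.null(nd$growth_rates))
      write_tsv(stats::setNames(as.data.frame(t(nd$growth_rates)), cols),
                file.path(dir, sprintf("%s_growth_rates.tsv", nd$name)))
    if (!is.null(nd$initial_abundances))
      write_tsv(stats::setNames(as.data.frame(t(nd$initial_abundances)), cols),
                file.path(dir, sprintf("%s_initial_abundances.tsv", nd$name)))
  }
  invisible(dir)
}

#' Read gLV parameter vectors written by [write_node_params()]
#'
#' @param dir Directory with `<node>_growth_rates.tsv` /
#'   `<node>_initial_abundances.tsv` files.
#' @param node_names Node names to read, in order.
#' @return List of [node_spec()]; a missing file leaves that field `NULL`
#'   (to be default-sampled at simulation time).
#' @export
read_node_params <- function(dir, node_names) {
  lapply(node_names, function(nm) {
    gpath <- file.path(dir, sprintf("%s_growth_rates.tsv", nm))
    zpath <- file.path(dir, sprintf("%s_initial_abundances.tsv", nm))
    g <- if (file.exists(gpath)) as.numeric(read_tsv(gpath)[1L, ]) else NULL
    z <- if (file.exists(zpath)) as.numeric(read_tsv(zpath)[1L, ]) else NULL
    d <- length(g %||% z)
    if (d == 0L)
      glv_config_error(sprintf("no parameter files for node '%s' in '%s'", nm, dir))
    node_spec(nm, d, growth_rates = g, initial_abundances = z)
  })
}

#' Write an interaction map as per-block TSV matrices
#'
#' One `<target>__<source>.tsv` dense matrix per stored block, columns
#' named after the source dimensions.
#'
#' @param map An [interaction_map()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_interaction_map <- function(map, dir) {
  stopifnot(inherits(map, "interaction_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(map$blocks)) {
    src <- strsplit(key, "__", fixed = TRUE)[[1L]][2L]
    blk <- map$blocks[[key]]
    colnames(blk) <- dim_colnames(src, ncol(blk))
    write_tsv(as.data.frame(blk), file.path(dir, paste0(key, ".tsv")))
  }
  invisible(dir)
}

#' Read an interaction map written by [write_interaction_map()]
#'
#' @param dir Directory holding `<target>__<source>.tsv` block files.
#' @param node_dims Named integer vector of node dimensionalities in order.
#' @return An [interaction_map()].
#' @export
read_interaction_map <- function(dir, node_dims) {
  files <- list.files(dir, pattern = "__.*\\.tsv$")
  blocks <- lapply(files, function(f) {
    unname(as.matrix(read_tsv(file.path(dir, f))))
  })
  names(blocks) <- sub("\\.tsv$", "", files)
  interaction_map(blocks, node_dims)
}

#' Write a case-control cohort directory
#'
#' Lays out `cases/<k>/` and `controls/<k>/` subdirectories with the
#' per-node timecourse TSVs, plus `response_vector.tsv` (the drawn case
#' response) and `manifest.tsv` (individual id, arm, seeds).
#'
#' @param cc A [generate_case_control()] result.
#' @param dir Output directory.
#' @param intervention_node Node name used to label the response-vector
#'   columns.
#' @return `dir`, invisibly.
#' @export
write_case_control <- function(cc, dir, intervention_node) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cc$cases))
    write_timecourse(cc$cases[[k]], file.path(dir, "cases", k))
  for (k in seq_along(cc$controls))
    write_timecourse(cc$controls[[k]], file.path(dir, "controls", k))
  write_tsv(stats::setNames(as.data.frame(t(cc$response)),
                            dim_colnames(intervention_node, length(cc$response))),
            file.path(dir, "response_vector.tsv"))
  write_tsv(cc$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
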