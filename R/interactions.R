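#' Block-structured directed interaction map
#'
#' Holds the pairwise directed interactions between nodes as a collection
#' of blocks keyed by (target, source) node-name pairs. The block for pair
#' (i, i') has one row per target dimension and one column per source
#' dimension: entry (r, c) is the effect of source dimension c's abundance
#' on target dimension r's per-capita growth. Missing pairs act as zero
#' matrices.
#'
#' @param blocks Named list of numeric matrices; names are
#'   `"<target>__<source>"` pairs.
#' @param node_dims Named integer vector mapping node name to
#'   dimensionality, in node order; fixes the D x D assembly order.
#' @return An object of class `interaction_map`.
#' @examples
#' im <- interaction_map(
#'   list(a__a = matrix(-1, 1, 1), a__b = matrix(0.5, 1, 2)),
#'   node_dims = c(a = 1, b = 2))
#' as.matrix(im)
#' @export
interaction_map <- function(blocks = list(), node_dims) {
  node_dims <- as.integer(node_dims) |> stats::setNames(names(node_dims))
  if (is.null(names(node_dims)) || any(!nzchar(names(node_dims))))
    glv_config_error("`node_dims` must be a named vector")
  if (length(blocks) && (is.null(names(blocks)) || any(!nzchar(names(blocks)))))
    glv_config_error("`blocks` must be named '<target>__<source>'")
  for (key in names(blocks)) {
    pair <- strsplit(key, "__", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% names(node_dims)))
      glv_config_error(sprintf(
        "block '%s' does not name two known nodes (known: %s)",
        key, paste(names(node_dims), collapse = ", ")))
    blk <- blocks[[key]]
    if (!is.matrix(blk) || nrow(blk) != node_dims[[pair[1]]] ||
        ncol(blk) != node_dims[[pair[2]]])
      glv_config_error(sprintf(
        "block '%s' must be a %d x %d matrix (target dim x source dim)",
        key, node_dims[[pair[1]]], node_dims[[pair[2]]]))
  }
  structure(list(blocks = blocks, node_dims = node_dims),
            class = "interaction_map")
}

#' Retrieve one (target, source) block
#'
#' @param map An [interaction_map()].
#' @param target,source Node names.
#' @return The stored block, or an all-zero matrix of the right shape if
#'   the pair is absent.
#' @export
interaction_block <- function(map, target, source) {
  stopifnot(inherits(map, "interaction_map"))
  if (!all(c(target, source) %in% names(map$node_dims)))
    glv_config_error("unknown node name in (target, source) pair")
  key <- paste(target, source, sep = "__")
  map$blocks[[key]] %||%
    matrix(0, map$node_dims[[target]], map$node_dims[[source]])
}

#' Assemble the full D x D interaction matrix
#'
#' Tiles the blocks in node order into the dense community matrix used by
#' the integrator.
#'
#' @param x An [interaction_map()].
#' @param ... Unused.
#' @return A numeric D x D matrix, D the sum of node dimensions.
#' @export
as.matrix.interaction_map <- function(x, ...) {
  dims <- x$node_dims
  D <- sum(dims)
  offsets <- c(0L, cumsum(dims))
  M <- matrix(0, D, D)
  nms <- names(dims)
  for (i in seq_along(dims)) for (j in seq_along(dims)) {
    blk <- x$blocks[[paste(nms[i], nms[j], sep = "__")]]
    if (!is.null(blk))
      M[(offsets[i] + 1):offsets[i + 1], (offsets[j] + 1):offsets[j + 1]] <- blk
  }
  M
}

#' Partition a dense D x D matrix into node-pair blocks
#'
#' Inverse of [as.matrix.interaction_map()]: cuts the matrix along the
#' node-dimension boundaries. Reassembling the returned blocks reproduces
#' the input exactly.
#'
#' @param M Numeric D x D matrix, D the sum of `node_dims`.
#' @param node_dims Named integer vector of node dimensionalities in order.
#' @return An [interaction_map()] with one block per ordered node pair.
#' @export
partition_matrix <- function(M, node_dims) {
  node_dims <- as.integer(node_dims) |> stats::setNames(names(node_dims))
  D <- sum(node_dims)
  if (!is.matrix(M) || nrow(M) != D || ncol(M) != D)
    glv_config_error(sprintf("`M` must be %d x %d for these node dims", D, D))
  offsets <- c(0L, cumsum(node_dims))
  nms <- names(node_dims)
  blocks <- list()
  for (i in seq_along(node_dims)) for (j in seq_along(node_dims)) {
    blocks[[paste(nms[i], nms[j], sep = "__")]] <-
      M[(offsets[i] + 1):offsets[i + 1], (offsets[j] + 1):offsets[j + 1],
        drop = FALSE]
  }
  interaction_map(blocks, node_dims)
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("<interaction_map> %d nodes (D = %d), %d stored block(s)\n",
              length(x$node_dims), sum(x$node_dims), length(x$blocks)))
  invisible(x)
}
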