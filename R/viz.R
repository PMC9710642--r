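#' Project multi-individual trajectories onto two principal components
#'
#' Pools the rows of every individual's trajectory, centers them, and fits
#' a single PCA so all trajectories live in a common plane; each
#' trajectory is then projected onto the top two axes. The axis sign is
#' fixed (largest-magnitude loading positive) so the projection is
#' deterministic. Useful for inspecting convergence to attractors and the
#' divergence of case and control arms under an intervention.
#'
#' @param timecourses List of `timecourse` objects sharing D and `|T|`.
#' @param source Which matrix to project: `"X"` (relative abundances,
#'   default — the observable scale) or `"Z"` (latent absolute).
#' @param labels Optional per-individual arm tags (e.g. "case"/"control");
#'   defaults to `"individual"`.
#' @return An object of class `projected_trajectories`: list with
#'   `coords` (per-individual `|T|` x 2 matrices), `explained_variance`
#'   (two decreasing nonnegative shares summing to <= 1) and `labels`.
#' @export
project_trajectories <- function(timecourses, source = c("X", "Z"),
                                 labels = NULL) {
  source <- match.arg(source)
  if (inherits(timecourses, "timecourse")) timecourses <- list(timecourses)
  if (!length(timecourses))
    glv_domain_error("`timecourses` must be nonempty")
  mats <- lapply(timecourses, `[[`, source)
  D <- ncol(mats[[1L]])
  if (D < 2L) glv_domain_error("projection needs at least 2 dimensions")
  if (!all(vapply(mats, function(m) ncol(m) == D, logical(1))))
    glv_domain_error("all timecourses must share the same dimension")
  pooled <- do.call(rbind, mats)
  pca <- prcomp(pooled, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  ctr <- pca$center
  coords <- lapply(mats, function(m) sweep(m, 2L, ctr) %*% rot)
  labels <- labels %||% rep("individual", length(mats))
  if (length(labels) != length(mats))
    glv_config_error("`labels` must have one entry per timecourse")
  structure(list(coords = coords, explained_variance = ev[1:2],
                 labels = as.character(labels)),
            class = "projected_trajectories")
}

# open a graphics device matched to the file extension, run the plot,
# close; avoids depending on svglite for SVG output
render_to_file <- function(plot, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  # the raster devices only touch the file at first draw, so check now
  if (!dir.exists(dirname(path)) || file.access(dirname(path), mode = 2L) != 0L)
    glv_error(sprintf("cannot write image to '%s': directory missing or read-only", path),
              "glvsim_io_error")
  opened <- tryCatch(
    switch(ext,
      png = png(path, width = width, height = height, units = "in", res = 150),
      svg = svg(path, width = width, height = height),
      pdf = pdf(path, width = width, height = height),
      glv_config_error(sprintf("unsupported image extension '.%s' (png/svg/pdf)", ext))),
    error = function(e) glv_error(
      sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
      "glvsim_io_error"))
  on.exit(dev.off())
  print(plot)
  invisible(path)
}

#' Stacked relative-abundance bar plot of one timecourse
#'
#' Draws one bar per recorded time point, split into segments proportional
#' to the chosen node's relative abundances renormalized within that node
#' (so single-node views stay readable in multi-node simulations); each
#' nonzero bar totals height 1. This is the standard way to eyeball
#' compositional timecourses and intervention responses.
#'
#' @param timecourse A `timecourse`.
#' @param node Node to display; default the first node.
#' @param output_path Optional `.png`/`.svg`/`.pdf` path; when given the
#'   plot is written there.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_stacked_bars <- function(timecourse, node = NULL, output_path = NULL,
                              width = 8, height = 4) {
  stopifnot(inherits(timecourse, "timecourse"))
  node <- node %||% timecourse$node_names[[1L]]
  if (!node %in% timecourse$node_names)
    glv_config_error(sprintf("unknown node '%s'", node))
  cols <- grep(paste0("^", node, "_"), colnames(timecourse$X))
  Xn <- timecourse$X[, cols, drop = FALSE]
  rs <- rowSums(Xn)
  Xn[rs > 0, ] <- Xn[rs > 0, , drop = FALSE] / rs[rs > 0]
  df <- data.frame(
    time = rep(timecourse$times, times = ncol(Xn)),
    dimension = factor(rep(colnames(Xn), each = nrow(Xn)), levels = colnames(Xn)),
    abundance = as.vector(Xn))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$time), y = .data$abundance, fill = .data$dimension)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::labs(x = "time", y = "relative abundance", fill = NULL,
                  title = sprintf("node '%s'", node)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6),
                   legend.position = if (length(cols) > 16) "none" else "right")
  if (!is.null(output_path)) {
    render_to_file(p, output_path, width, height)
    return(invisible(p))
  }
  p
}

#' Plot projected trajectories in the principal-component plane
#'
#' One polyline per individual through its `|T|` projected points, colored
#' by arm label; makes trajectory convergence and case/control divergence
#' visible at a glance.
#'
#' @param projected A [project_trajectories()] result.
#' @param output_path Optional `.png`/`.svg`/`.pdf` path.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_pca_trajectories <- function(projected, output_path = NULL,
                                  width = 6, height = 5) {
  stopifnot(inherits(projected, "projected_trajectories"))
  if (!length(projected$coords)) glv_domain_error("empty projection")
  df <- do.call(rbind, lapply(seq_along(projected$coords), function(k) {
    m <- projected$coords[[k]]
    data.frame(individual = k, label = projected$labels[[k]],
               step = seq_len(nrow(m)), PC1 = m[, 1L], PC2 = m[, 2L])
  }))
  ev <- 100 * projected$explained_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, group = .data$individual, color = .data$label)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(data = df[df$step == 1L, ], size = 1.2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ev[1L]),
                  y = sprintf("PC2 (%.1f%%)", ev[2L]), color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(output_path)) {
    render_to_file(p, output_path, width, height)
    return(invisible(p))
  }
  p
}
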