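#' Construct and validate a plot layout
#'
#' A plot layout maps each field plot to a rectangular raster region and
#' records which plots are neighbours.  Pixel bounds are 0-based,
#' half-open intervals `[row0, row1) x [col0, col1)`, which makes
#' disjointness checks unambiguous.  The adjacency relation is data, not
#' code: the generator precomputes the six nearest plots in the planting
#' grid and ships them in `layout.yaml`, so alternative field geometries
#' need no code change.
#'
#' @param plots Data frame with columns `plot_id`, `line_id`, `replicate`,
#'   `row0`, `row1`, `col0`, `col1` (and optionally the planting-grid
#'   position `grid_row`, `grid_col`).
#' @param adjacency Named list: `plot_id` -> character vector of
#'   neighbouring plot ids.  Must be symmetric and irreflexive.
#' @param raster_dim Integer vector `c(nrow, ncol)` of the rasters this
#'   layout indexes, used to check bounds.
#' @return An object of class `plot_layout`.
#' @export
plot_layout <- function(plots, adjacency, raster_dim) {
  plots <- as.data.frame(plots)
  need <- c("plot_id", "line_id", "replicate", "row0", "row1", "col0", "col1")
  miss <- setdiff(need, names(plots))
  if (length(miss)) {
    stop("layout plots table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  plots$plot_id <- as.character(plots$plot_id)
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicated plot ids in layout", call. = FALSE)
  }
  if (any(plots$row1 <= plots$row0) || any(plots$col1 <= plots$col0)) {
    stop("empty plot region: need row0 < row1 and col0 < col1", call. = FALSE)
  }
  raster_dim <- as.integer(raster_dim)
  if (any(plots$row0 < 0) || any(plots$col0 < 0) ||
      any(plots$row1 > raster_dim[1]) || any(plots$col1 > raster_dim[2])) {
    stop("plot bounds exceed raster dimensions ",
         raster_dim[1], "x", raster_dim[2], call. = FALSE)
  }
  .check_disjoint(plots)
  .check_adjacency(adjacency, plots$plot_id)
  structure(
    list(plots = plots, adjacency = adjacency, raster_dim = raster_dim),
    class = "plot_layout"
  )
}

.check_disjoint <- function(plots) {
  n <- nrow(plots)
  if (n < 2L) return(invisible())
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      overlap_r <- plots$row0[i] < plots$row1[j] && plots$row0[j] < plots$row1[i]
      overlap_c <- plots$col0[i] < plots$col1[j] && plots$col0[j] < plots$col1[i]
      if (overlap_r && overlap_c) {
        stop("plot regions overlap: ", plots$plot_id[i], " and ",
             plots$plot_id[j], call. = FALSE)
      }
    }
  }
  invisible()
}

.check_adjacency <- function(adjacency, ids) {
  unknown <- setdiff(names(adjacency), ids)
  if (length(unknown)) {
    stop("adjacency names unknown plots: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (p in names(adjacency)) {
    nb <- adjacency[[p]]
    if (p %in% nb) stop("plot ", p, " adjacent to itself", call. = FALSE)
    bad <- setdiff(nb, ids)
    if (length(bad)) {
      stop("adjacency of ", p, " names unknown plots: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (q in nb) {
      if (!p %in% adjacency[[q]]) {
        stop("adjacency not symmetric: ", p, " -> ", q, " but not back",
             call. = FALSE)
      }
    }
  }
  invisible()
}

#' @export
print.plot_layout <- function(x, ...) {
  cat(sprintf("<plot_layout> %d plots, %d lines, raster %dx%d\n",
              nrow(x$plots), length(unique(x$plots$line_id)),
              x$raster_dim[1], x$raster_dim[2]))
  invisible(x)
}

#' Write / read a plot layout as YAML
#'
#' The YAML file lists, per plot: its line and replicate, the half-open
#' pixel bounds, the planting-grid position, and the neighbour list.
#'
#' @param layout A [plot_layout()].
#' @param path File path (`layout.yaml`).
#' @return `write_layout` returns `path` invisibly; `read_layout` returns
#'   a validated [plot_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plot_layout"))
  p <- layout$plots
  entries <- lapply(seq_len(nrow(p)), function(i) {
    e <- as.list(p[i, , drop = FALSE])
    e <- lapply(e, function(v) if (is.factor(v)) as.character(v) else v)
    e$neighbors <- as.list(layout$adjacency[[p$plot_id[i]]] %||% character())
    e
  })
  yaml::write_yaml(
    list(raster_dim = as.list(layout$raster_dim), plots = entries),
    path
  )
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  plots <- do.call(rbind, lapply(y$plots, function(e) {
    data.frame(
      plot_id = as.character(e$plot_id),
      line_id = as.character(e$line_id),
      replicate = as.integer(e$replicate),
      row0 = as.integer(e$row0), row1 = as.integer(e$row1),
      col0 = as.integer(e$col0), col1 = as.integer(e$col1),
      grid_row = as.integer(e$grid_row %||% NA),
      grid_col = as.integer(e$grid_col %||% NA),
      stringsAsFactors = FALSE
    )
  }))
  adjacency <- stats::setNames(
    lapply(y$plots, function(e) as.character(unlist(e$neighbors))),
    vapply(y$plots, function(e) as.character(e$plot_id), character(1))
  )
  plot_layout(plots, adjacency, unlist(y$raster_dim))
}
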