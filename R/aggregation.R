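#' Deterministic spiral ordering of a region's cells
#'
#' Enumerates cells in Chebyshev-distance rings r = 0, 1, 2, ... around the
#' start cell; within each ring the perimeter is walked clockwise starting
#' due north. Cells outside the grid or outside the region are skipped, so
#' on concave or disconnected regions a prefix may be transiently
#' disconnected; the full order is always an exact permutation of the
#' region's cells. Prefixes of the order define the nested areas
#' A = 1, ..., |region| used to build species- and network-area curves.
#'
#' @param grid a [grid_spec()].
#' @param region region label.
#' @param start_cell 0-based cell id; must belong to the region.
#' @return An object of class `aggregation_path`: list with `region`,
#'   `start_cell`, `order` (0-based cell ids) and `seed` (`NA` here; set by
#'   [sample_paths()]).
#' @export
spiral_order <- function(grid, region, start_cell) {
  cells <- region_cells(grid, region)
  if (!length(cells)) stop("region ", region, " has no cells")
  start_cell <- as.integer(start_cell)
  if (!start_cell %in% cells)
    stop("start_cell ", start_cell, " is not in region ", region)
  in_region <- logical(n_cells(grid))
  in_region[cells + 1L] <- TRUE
  r0 <- start_cell %/% grid$n_cols
  c0 <- start_cell %% grid$n_cols
  order <- integer(length(cells))
  order[1L] <- start_cell
  k <- 1L
  max_r <- max(grid$n_rows, grid$n_cols)  # ring bound = grid diameter
  for (r in seq_len(max_r)) {
    if (k == length(cells)) break
    ring <- ring_cells(r0, c0, r)
    ok <- ring[, 1] >= 0L & ring[, 1] < grid$n_rows &
      ring[, 2] >= 0L & ring[, 2] < grid$n_cols
    if (!any(ok)) next
    ids <- ring[ok, 1, drop = TRUE] * grid$n_cols + ring[ok, 2, drop = TRUE]
    ids <- ids[in_region[ids + 1L]]
    if (length(ids)) {
      order[k + seq_along(ids)] <- ids
      k <- k + length(ids)
    }
  }
  if (k != length(cells))
    stop("spiral enumeration did not cover region ", region)  # unreachable
  structure(list(region = region, start_cell = start_cell, order = order,
                 seed = NA_integer_),
            class = "aggregation_path")
}

# Clockwise perimeter of the Chebyshev ring at distance r, starting due
# north of (r0, c0). Returns an 8r x 2 matrix of (row, col), possibly
# off-grid. Segments: top edge east from (top, c0) to the NE corner, right
# edge down, bottom edge west, left edge up, top edge east back to just
# west of due north.
ring_cells <- function(r0, c0, r) {
  top <- r0 - r; bottom <- r0 + r; left <- c0 - r; right <- c0 + r
  tail_cols <- if (r > 1L) seq(left + 1L, c0 - 1L) else integer(0)
  rows <- c(rep(top, r + 1L),
            seq(top + 1L, bottom),
            rep(bottom, 2L * r),
            seq(bottom - 1L, top),
            rep(top, length(tail_cols)))
  cols <- c(seq(c0, right),
            rep(right, 2L * r),
            seq(right - 1L, left),
            rep(left, 2L * r),
            tail_cols)
  cbind(rows, cols)
}

#' @export
print.aggregation_path <- function(x, ...) {
  cat(sprintf("<aggregation_path> region %s, %d cells, start %d\n",
              x$region, length(x$order), x$start_cell))
  invisible(x)
}

#' Replicated spiral paths from random start cells
#'
#' Start cells are drawn uniformly with replacement from the region's
#' cells; replicate k uses a sub-seed derived deterministically from
#' `(seed, k)`, so the list is reproducible and independent of evaluation
#' order.
#'
#' @param grid a [grid_spec()].
#' @param region region label.
#' @param n_replicates number of paths (default 100, the standard
#'   replication used for region-level fits).
#' @param seed master seed.
#' @return list of [spiral_order()] paths.
#' @export
sample_paths <- function(grid, region, n_replicates = 100, seed = 1L) {
  cells <- region_cells(grid, region)
  if (!length(cells)) stop("region ", region, " has no cells")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  lapply(seq_len(n_replicates), function(k) {
    set.seed(sub_seed(seed, 7000L + k))
    start <- cells[sample.int(length(cells), 1L)]
    p <- spiral_order(grid, region, start)
    p$seed <- sub_seed(seed, 7000L + k)
    p
  })
}

#' Serialise paths to a long audit table
#' @param paths list of [spiral_order()] paths.
#' @param grid the [grid_spec()] the paths live on.
#' @return data.frame with columns `replicate, step, row, col`.
#' @export
paths_table <- function(paths, grid) {
  do.call(rbind, lapply(seq_along(paths), function(k) {
    rc <- cell_rowcol(paths[[k]]$order, grid)
    data.frame(replicate = k, step = seq_along(paths[[k]]$order),
               row = rc[, "row"], col = rc[, "col"])
  }))
}

# Deterministic 32-bit sub-seed from (seed, offset); keeps values in
# [0, 2^31) so set.seed() always accepts them.
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %%
               2147483647)
}
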