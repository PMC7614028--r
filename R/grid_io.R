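#' Regular analysis grid with region membership
#'
#' A `grid_spec` describes the regular cell grid on which presence, habitat
#' and climate data live. Cells are indexed row-major and 0-based: cell id
#' `row * n_cols + col` for 0-based `(row, col)`. Each cell carries exactly
#' one region label; cells outside the study area are labelled `"outside"`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size_km side length of a cell in kilometres.
#' @param region_label character vector of length `n_rows * n_cols` in
#'   row-major cell-id order, or a single label recycled to all cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 10,
                      region_label = "region_1") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("grid dimensions must be >= 1")
  n <- n_rows * n_cols
  region_label <- as.character(region_label)
  if (length(region_label) == 1L) region_label <- rep(region_label, n)
  if (length(region_label) != n)
    stop("region_label must have length n_rows * n_cols (", n, ")")
  if (anyNA(region_label)) stop("region labels must not be NA")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size_km = cell_size_km, region_label = region_label),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  regs <- setdiff(unique(x$region_label), "outside")
  cat(sprintf("<grid_spec> %d x %d cells (%g km), %d region(s): %s\n",
              x$n_rows, x$n_cols, x$cell_size_km, length(regs),
              paste(utils::head(regs, 8), collapse = ", ")))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell id arithmetic
#'
#' Convert between 0-based `(row, col)` coordinates and row-major 0-based
#' cell ids.
#' @param row,col 0-based coordinates.
#' @param cell 0-based cell ids.
#' @param grid a [grid_spec()].
#' @return `cell_id()` returns integer ids; `cell_rowcol()` a two-column
#'   integer matrix with columns `row`, `col`.
#' @export
cell_id <- function(row, col, grid) {
  if (any(row < 0L | row >= grid$n_rows | col < 0L | col >= grid$n_cols))
    stop("(row, col) outside grid")
  as.integer(row) * grid$n_cols + as.integer(col)
}

#' @rdname cell_id
#' @export
cell_rowcol <- function(cell, grid) {
  cell <- as.integer(cell)
  cbind(row = cell %/% grid$n_cols, col = cell %% grid$n_cols)
}

#' Cells belonging to a region
#' @param grid a [grid_spec()].
#' @param region region label.
#' @return 0-based cell ids, in row-major order.
#' @export
region_cells <- function(grid, region) {
  which(grid$region_label == region) - 1L
}

#' Region labels present on a grid
#' @param grid a [grid_spec()].
#' @return character vector of region labels, `"outside"` excluded.
#' @export
region_names <- function(grid) {
  setdiff(unique(grid$region_label), "outside")
}

#' Trophic metaweb: species pool and potential feeding links
#'
#' The metaweb holds the regional pool of species and the directed set of
#' potential trophic interactions (consumer -> resource). Local food webs
#' are induced subgraphs of it (see [induced_web()]).
#'
#' @param species data.frame with columns `species_id`, `name`, `group`
#'   (`name`/`group` optional; filled with the id / `NA`).
#' @param links data.frame with columns `consumer_id`, `resource_id`.
#' @param lenient if `TRUE`, duplicate links are silently dropped instead of
#'   raising an error.
#' @return An object of class `metaweb` with elements `species` (data.frame)
#'   and `links` (data.frame). Self-links are retained on input; consumers of
#'   the induced-web machinery drop them.
#' @export
metaweb <- function(species, links, lenient = FALSE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (!"species_id" %in% names(species)) stop("species table needs species_id")
  species$species_id <- as.character(species$species_id)
  if (anyDuplicated(species$species_id))
    stop("duplicate species_id: ",
         paste(unique(species$species_id[duplicated(species$species_id)]),
               collapse = ", "))
  if (!"name" %in% names(species)) species$name <- species$species_id
  if (!"group" %in% names(species)) species$group <- NA_character_
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0L)
    links <- data.frame(consumer_id = character(), resource_id = character(),
                        stringsAsFactors = FALSE)
  if (!all(c("consumer_id", "resource_id") %in% names(links)))
    stop("edge list needs consumer_id and resource_id columns")
  links$consumer_id <- as.character(links$consumer_id)
  links$resource_id <- as.character(links$resource_id)
  unknown <- setdiff(c(links$consumer_id, links$resource_id),
                     species$species_id)
  if (length(unknown))
    stop("edge list references unknown species id(s): ",
         paste(unknown, collapse = ", "))
  key <- paste(links$consumer_id, links$resource_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (!lenient)
      stop("duplicate link(s) in edge list: ",
           paste(unique(gsub("\r", " -> ", key[duplicated(key)])),
                 collapse = ", "))
    links <- links[!duplicated(key), , drop = FALSE]
  }
  rownames(links) <- NULL
  structure(list(species = species,
                 links = links[, c("consumer_id", "resource_id")]),
            class = "metaweb")
}

#' @export
print.metaweb <- function(x, ...) {
  cat(sprintf("<metaweb> %d species, %d potential links\n",
              nrow(x$species), nrow(x$links)))
  invisible(x)
}

#' Read a metaweb from a species table and an edge list
#'
#' @param species_table_path CSV with header `species_id,name,group`
#'   (`name`, `group` optional).
#' @param edge_list_path CSV with header `consumer_id,resource_id`.
#' @param lenient deduplicate repeated edges instead of erroring.
#' @return A [metaweb()].
#' @export
read_metaweb <- function(species_table_path, edge_list_path, lenient = FALSE) {
  sp <- utils::read.csv(species_table_path, colClasses = "character")
  el <- utils::read.csv(edge_list_path, colClasses = "character")
  metaweb(sp, el, lenient = lenient)
}

#' Write a metaweb to CSV files
#' @param web a [metaweb()].
#' @param species_table_path,edge_list_path output paths.
#' @export
write_metaweb <- function(web, species_table_path, edge_list_path) {
  write_table(web$species, species_table_path)
  write_table(web$links, edge_list_path)
  invisible(NULL)
}

#' Boolean species-by-cell presence stack
#'
#' @param grid a [grid_spec()].
#' @param presence logical matrix, species in rows (rownames = species ids),
#'   cells in columns in row-major cell-id order.
#' @return An object of class `range_stack`.
#' @export
range_stack <- function(grid, presence) {
  presence <- as.matrix(presence)
  if (ncol(presence) != n_cells(grid))
    stop("presence must have one column per grid cell")
  if (is.null(rownames(presence))) stop("presence rows must be named by species id")
  storage.mode(presence) <- "logical"
  if (anyNA(presence)) stop("presence must be strictly boolean")
  structure(list(grid = grid, presence = presence), class = "range_stack")
}

#' @export
print.range_stack <- function(x, ...) {
  cat(sprintf("<range_stack> %d species x %d cells, %d presences\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Read long-format presence records onto a grid
#'
#' Rows are `(species_id, row, col)` with 0-based coordinates; a pair listed
#' at least once is present (duplicates are idempotent). Species listed in
#' `species_ids` but absent from the table get all-absent rows.
#'
#' @param long_table_path CSV with header `species_id,row,col`.
#' @param grid a [grid_spec()].
#' @param species_ids optional character vector fixing the species set and
#'   row order; defaults to the species appearing in the table.
#' @return A [range_stack()].
#' @export
read_presence <- function(long_table_path, grid, species_ids = NULL) {
  tab <- utils::read.csv(long_table_path,
                         colClasses = c(species_id = "character",
                                        row = "integer", col = "integer"))
  if (is.null(species_ids)) species_ids <- unique(tab$species_id)
  pres <- matrix(FALSE, nrow = length(species_ids), ncol = n_cells(grid),
                 dimnames = list(species_ids, NULL))
  if (nrow(tab)) {
    bad <- tab$row < 0L | tab$row >= grid$n_rows |
      tab$col < 0L | tab$col >= grid$n_cols
    if (any(bad))
      stop("presence record(s) outside grid, first at table row ", which(bad)[1])
    unknown <- setdiff(tab$species_id, species_ids)
    if (length(unknown))
      stop("presence table references species not in species_ids: ",
           paste(unknown, collapse = ", "))
    pres[cbind(match(tab$species_id, species_ids),
               cell_id(tab$row, tab$col, grid) + 1L)] <- TRUE
  }
  range_stack(grid, pres)
}

#' Write a range stack as a long-format presence table
#' @param ranges a [range_stack()].
#' @param path output CSV path.
#' @export
write_presence <- function(ranges, path) {
  idx <- which(ranges$presence, arr.ind = TRUE)
  rc <- cell_rowcol(idx[, 2] - 1L, ranges$grid)
  tab <- data.frame(species_id = rownames(ranges$presence)[idx[, 1]],
                    row = rc[, "row"], col = rc[, "col"],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$species_id, tab$row, tab$col), , drop = FALSE]
  write_table(tab, path)
}

#' Upscale fine-grid presence by boolean max-pooling
#'
#' A coarse cell is occupied iff any of its `factor x factor` constituent
#' fine cells is occupied, mirroring the aggregation of fine-resolution
#' range maps onto a coarser analysis grid. Fine grids whose dimensions are
#' not divisible by `factor` are padded with absences on the bottom/right.
#' Region labels of the coarse grid are taken from the top-left fine cell of
#' each block.
#'
#' @param fine a [range_stack()] on the fine grid.
#' @param factor integer block size (>= 1).
#' @return A [range_stack()] on the coarse grid.
#' @export
upscale_presence <- function(fine, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(fine)
  g <- fine$grid
  cr <- ceiling(g$n_rows / factor); cc <- ceiling(g$n_cols / factor)
  fr <- rep(seq_len(g$n_rows) - 1L, each = g$n_cols)
  fc <- rep(seq_len(g$n_cols) - 1L, times = g$n_rows)
  coarse_of_fine <- (fr %/% factor) * cc + (fc %/% factor)  # 0-based
  pres <- matrix(FALSE, nrow = nrow(fine$presence), ncol = cr * cc,
                 dimnames = list(rownames(fine$presence), NULL))
  occ <- which(fine$presence, arr.ind = TRUE)
  if (nrow(occ)) pres[cbind(occ[, 1], coarse_of_fine[occ[, 2]] + 1L)] <- TRUE
  top_left <- cell_id(pmin((seq_len(cr) - 1L) * factor, g$n_rows - 1L)[
    rep(seq_len(cr), each = cc)],
    pmin((seq_len(cc) - 1L) * factor, g$n_cols - 1L)[rep(seq_len(cc), cr)], g)
  coarse_grid <- grid_spec(cr, cc, cell_size_km = g$cell_size_km * factor,
                           region_label = g$region_label[top_left + 1L])
  range_stack(coarse_grid, pres)
}

#' Per-cell habitat-class cover proportions
#'
#' @param grid a [grid_spec()].
#' @param proportions numeric matrix, cells (row-major) x habitat classes,
#'   column names = class ids; every in-region row must sum to 1.
#' @param renormalise rescale rows whose sum is within `tol` of 1.
#' @param tol tolerance on the per-cell sum before renormalisation.
#' @return An object of class `habitat_raster`.
#' @export
habitat_raster <- function(grid, proportions, renormalise = TRUE, tol = 1e-3) {
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != n_cells(grid))
    stop("proportions must have one row per grid cell")
  if (is.null(colnames(proportions)))
    colnames(proportions) <- paste0("class_", seq_len(ncol(proportions)))
  if (any(proportions < 0)) stop("habitat proportions must be non-negative")
  in_region <- grid$region_label != "outside"
  s <- rowSums(proportions)
  bad <- in_region & abs(s - 1) > tol
  if (any(bad))
    stop("habitat proportions for cell(s) ",
         paste(utils::head(which(bad) - 1L, 5), collapse = ", "),
         " deviate from 1 by more than ", tol)
  if (renormalise) {
    fix <- in_region & s > 0
    proportions[fix, ] <- proportions[fix, , drop = FALSE] / s[fix]
  }
  structure(list(grid = grid, proportions = proportions),
            class = "habitat_raster")
}

#' Named per-cell climate layers
#'
#' @param grid a [grid_spec()].
#' @param variables named list of numeric vectors, one value per cell
#'   (row-major). All in-region cells must be finite in every layer.
#' @return An object of class `climate_raster`.
#' @export
climate_raster <- function(grid, variables) {
  if (is.null(names(variables)) || any(names(variables) == ""))
    stop("climate layers must be named")
  in_region <- grid$region_label != "outside"
  variables <- lapply(variables, as.numeric)
  for (v in names(variables)) {
    if (length(variables[[v]]) != n_cells(grid))
      stop("layer ", v, " must have one value per cell")
    if (!all(is.finite(variables[[v]][in_region])))
      stop("layer ", v, " has non-finite values on in-region cells")
  }
  structure(list(grid = grid, variables = variables),
            class = "climate_raster")
}

#' Read a long-format per-cell raster table
#'
#' Habitat tables have columns `row,col,class_id,proportion`; climate tables
#' `row,col,variable,value`. Coordinates are 0-based. Habitat proportions
#' are renormalised to sum 1 per cell when within 1e-3 of 1, otherwise an
#' error is raised.
#'
#' @param long_table_path CSV path.
#' @param grid a [grid_spec()].
#' @param kind `"habitat"` or `"climate"`.
#' @return A [habitat_raster()] or [climate_raster()].
#' @export
read_cell_raster <- function(long_table_path, grid,
                             kind = c("habitat", "climate")) {
  kind <- match.arg(kind)
  tab <- utils::read.csv(long_table_path, stringsAsFactors = FALSE)
  if (nrow(tab) &&
      any(tab$row < 0L | tab$row >= grid$n_rows |
          tab$col < 0L | tab$col >= grid$n_cols))
    stop("raster record outside grid")
  cells <- cell_id(tab$row, tab$col, grid)
  if (kind == "habitat") {
    if (!all(c("class_id", "proportion") %in% names(tab)))
      stop("habitat table needs class_id and proportion columns")
    if (any(tab$proportion < 0)) stop("negative habitat proportion")
    classes <- sort(unique(as.character(tab$class_id)))
    m <- matrix(0, nrow = n_cells(grid), ncol = length(classes),
                dimnames = list(NULL, classes))
    m[cbind(cells + 1L, match(as.character(tab$class_id), classes))] <-
      tab$proportion
    habitat_raster(grid, m)
  } else {
    if (!all(c("variable", "value") %in% names(tab)))
      stop("climate table needs variable and value columns")
    vars <- unique(as.character(tab$variable))
    layers <- lapply(vars, function(v) {
      x <- rep(NA_real_, n_cells(grid))
      sel <- tab$variable == v
      x[cells[sel] + 1L] <- tab$value[sel]
      x
    })
    names(layers) <- vars
    in_region <- grid$region_label != "outside"
    for (v in vars)
      if (anyNA(layers[[v]][in_region]))
        stop("missing value for climate variable ", v, " on in-region cell(s)")
    climate_raster(grid, layers)
  }
}

#' Read a region-membership map onto a grid
#'
#' @param long_table_path CSV with header `row,col,region`; unlisted cells
#'   are labelled `"outside"`.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_km cell side length in km.
#' @return A [grid_spec()].
#' @export
read_region_map <- function(long_table_path, n_rows, n_cols,
                            cell_size_km = 10) {
  tab <- utils::read.csv(long_table_path, stringsAsFactors = FALSE)
  grid <- grid_spec(n_rows, n_cols, cell_size_km, "outside")
  if (nrow(tab)) {
    ids <- cell_id(tab$row, tab$col, grid)
    grid$region_label[ids + 1L] <- as.character(tab$region)
  }
  grid
}

#' Write a grid's region labels as a long table
#' @param grid a [grid_spec()].
#' @param path output CSV path.
#' @export
write_region_map <- function(grid, path) {
  ids <- which(grid$region_label != "outside") - 1L
  rc <- cell_rowcol(ids, grid)
  write_table(data.frame(row = rc[, "row"], col = rc[, "col"],
                         region = grid$region_label[ids + 1L]), path)
}

#' Write a habitat raster as a long table
#' @param habitat a [habitat_raster()].
#' @param path output CSV path.
#' @export
write_habitat <- function(habitat, path) {
  idx <- which(habitat$proportions > 0, arr.ind = TRUE)
  rc <- cell_rowcol(idx[, 1] - 1L, habitat$grid)
  tab <- data.frame(row = rc[, "row"], col = rc[, "col"],
                    class_id = colnames(habitat$proportions)[idx[, 2]],
                    proportion = habitat$proportions[idx])
  tab <- tab[order(tab$row, tab$col, tab$class_id), , drop = FALSE]
  write_table(tab, path)
}

#' Write a climate raster as a long table
#' @param climate a [climate_raster()].
#' @param path output CSV path.
#' @export
write_climate <- function(climate, path) {
  g <- climate$grid
  ids <- seq_len(n_cells(g)) - 1L
  rc <- cell_rowcol(ids, g)
  tabs <- lapply(names(climate$variables), function(v)
    data.frame(row = rc[, "row"], col = rc[, "col"], variable = v,
               value = climate$variables[[v]]))
  write_table(do.call(rbind, tabs), path)
}

#' Write a table as deterministic CSV
#'
#' Header row mandatory; column and row order preserved; numeric columns
#' rendered with 10 significant digits so repeated writes are
#' byte-identical and round-trips are exact to <= 1e-9 relative error.
#'
#' @param records a data.frame (possibly zero rows).
#' @param path output path.
#' @param comment optional character vector written as `#`-prefixed header
#'   lines (provenance).
#' @export
write_table <- function(records, path, comment = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- records
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (j in which(num)) out[[j]] <- signif_chr(out[[j]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

signif_chr <- function(x) {
  # 10 significant digits, stable across platforms

  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Read a CSV written by [write_table()]
#' @param path input path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
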