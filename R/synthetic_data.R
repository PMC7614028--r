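#' Scenario configuration for the synthetic world
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' describe a desk-scale stand-in for a continental tetrapod analysis: a
#' 150-species pool with 70% basal species and connectance 0.08 (a pool
#' dense enough that local webs of a few dozen species carry links), a
#' 30 x 30 grid of 10-km cells split into 4 contiguous regions,
#' heavy-tailed lognormal range sizes, a clustered habitat mosaic with 6
#' classes, and four climate layers combining a smooth latitudinal gradient
#' with cell-level noise.
#'
#' @param seed master seed; every generator derives its own stream from it.
#' @param S_pool species-pool size (>= 2).
#' @param C_target target metaweb connectance L / S^2 (0 < C < 0.5).
#' @param basal_fraction fraction of the pool forced basal.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size_km cell side length.
#' @param n_regions number of contiguous regions partitioning the grid.
#' @param range_median,range_sigma lognormal range-size parameters (cells).
#' @param trophic_range_scaling multiplicative factor on the median range
#'   size of consumers relative to basal species (home ranges grow with
#'   trophic position).
#' @param habitat_K number of habitat classes.
#' @param habitat_clustering habitat domain compactness in `[0, 1]`.
#' @param climate list of per-variable `c(base, gradient_per_cell,
#'   noise_sd)` specifications.
#' @param n_replicates spiral-path replicates per region.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, S_pool = 150L, C_target = 0.08,
                            basal_fraction = 0.7, n_rows = 30L, n_cols = 30L,
                            cell_size_km = 10, n_regions = 4L,
                            range_median = 40, range_sigma = 1,
                            trophic_range_scaling = 3,
                            habitat_K = 6L, habitat_clustering = 0.7,
                            climate = NULL, n_replicates = 100L) {
  if (is.null(climate))
    climate <- list(
      mean_annual_temperature = c(base = 4, gradient = 0.4, noise_sd = 1.5),
      temperature_seasonality = c(base = 300, gradient = 5, noise_sd = 40),
      annual_precipitation = c(base = 900, gradient = -8, noise_sd = 120),
      precipitation_seasonality = c(base = 30, gradient = 0.2, noise_sd = 6))
  stopifnot(S_pool >= 2, C_target > 0, C_target < 0.5,
            basal_fraction >= 0, basal_fraction <= 1,
            n_rows >= 1, n_cols >= 1, n_regions >= 1)
  structure(list(seed = as.integer(seed), S_pool = as.integer(S_pool),
                 C_target = C_target, basal_fraction = basal_fraction,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size_km = cell_size_km, n_regions = as.integer(n_regions),
                 range_median = range_median, range_sigma = range_sigma,
                 trophic_range_scaling = trophic_range_scaling,
                 habitat_K = as.integer(habitat_K),
                 habitat_clustering = habitat_clustering,
                 climate = climate, n_replicates = as.integer(n_replicates)),
            class = "scenario_config")
}

#' Niche-model metaweb generator
#'
#' Each species receives a niche value uniform on (0, 1). The
#' `basal_fraction` species with the smallest niche values get feeding
#' range 0 (forced basal). Each remaining consumer i draws a feeding-range
#' fraction x ~ Beta(1, beta) and feeds on every species whose niche value
#' falls in an interval of width `x * n_i` centred at a point drawn uniform
#' on `[x * n_i / 2, n_i]`. `beta` is calibrated so the expected
#' connectance L / S^2 equals `C_target`: consumers are the high-niche
#' `1 - b` tail of the pool (`b = basal_fraction`), with mean niche value
#' `(1 + b) / 2` and mean feeding range `E[x] (1 + b) / 2`, giving expected
#' connectance `(1 - b^2) / (2 (1 + beta))` and hence
#' `beta = (1 - b^2) / (2 C_target) - 1`, which must be > 0.
#'
#' @param S_pool pool size (>= 2).
#' @param C_target target connectance (must satisfy
#'   `C_target < (1 - basal_fraction^2) / 2`).
#' @param basal_fraction fraction forced basal.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return A [metaweb()] whose species table carries columns `niche`
#'   (niche value) and `group` (`"basal"` / `"consumer"` designation at
#'   generation time). Self-links may occur and are retained.
#' @export
gen_metaweb <- function(S_pool, C_target, basal_fraction, seed = 1L) {
  if (S_pool < 2L) stop("S_pool must be >= 2")
  if (C_target <= 0 || C_target >= 0.5) stop("C_target must be in (0, 0.5)")
  n_basal <- ceiling(basal_fraction * S_pool)
  n_cons <- S_pool - n_basal
  if (n_cons > 0L) {
    beta <- (1 - basal_fraction^2) / (2 * C_target) - 1
    if (beta <= 0)
      stop("infeasible C_target ", C_target, " given basal_fraction ",
           basal_fraction, ": requires C_target < (1 - basal_fraction^2) / 2")
  }
  set.seed(sub_seed(seed, 101L))
  niche <- sort(stats::runif(S_pool))
  ids <- sprintf("sp_%03d", seq_len(S_pool))
  is_basal <- seq_len(S_pool) <= n_basal  # smallest niche values
  links <- NULL
  if (n_cons > 0L) {
    cons_idx <- which(!is_basal)
    x <- stats::rbeta(n_cons, 1, beta)
    range_w <- x * niche[cons_idx]
    centre <- stats::runif(n_cons, range_w / 2, niche[cons_idx])
    lo <- centre - range_w / 2
    hi <- centre + range_w / 2
    links <- do.call(rbind, lapply(seq_len(n_cons), function(k) {
      prey <- which(niche >= lo[k] & niche <= hi[k])
      if (!length(prey)) return(NULL)
      data.frame(consumer_id = ids[cons_idx[k]], resource_id = ids[prey],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(links))
    links <- data.frame(consumer_id = character(), resource_id = character())
  species <- data.frame(species_id = ids, name = ids,
                        group = ifelse(is_basal, "basal", "consumer"),
                        niche = niche, stringsAsFactors = FALSE)
  metaweb(species, links)
}

#' Contiguous spatially autocorrelated species ranges
#'
#' Per species, a range size (in cells) is drawn from a lognormal with the
#' given median and sigma, truncated to `[1, n in-region cells]`, a seed
#' cell is placed uniformly at random among in-region cells, and the range
#' grows to the drawn size by randomised breadth-first accretion over rook
#' neighbours (each step occupies a uniformly chosen frontier cell), so
#' every range is rook-connected. Consumers' median range size is
#' multiplied by `trophic_range_scaling`: species higher in the web need
#' larger home ranges, which is also what makes their spatial accumulation
#' saturate sooner than that of basal species.
#'
#' @param grid a [grid_spec()]; ranges are confined to non-"outside" cells.
#' @param web the [metaweb()] providing the species list (and basal status
#'   via out-degree).
#' @param range_median lognormal median range size for basal species, cells.
#' @param range_sigma lognormal sigma (log scale).
#' @param trophic_range_scaling consumers' median multiplier (>= 1).
#' @param seed integer seed.
#' @return A [range_stack()].
#' @export
gen_ranges <- function(grid, web, range_median = 40, range_sigma = 1,
                       trophic_range_scaling = 3, seed = 1L) {
  cells <- which(grid$region_label != "outside") - 1L
  if (!length(cells)) stop("grid has no in-region cells")
  set.seed(sub_seed(seed, 211L))
  ids <- web$species$species_id
  is_cons <- ids %in% web$links$consumer_id
  med <- ifelse(is_cons, range_median * trophic_range_scaling, range_median)
  sizes <- round(stats::rlnorm(length(ids), log(med), range_sigma))
  sizes <- pmin(pmax(sizes, 1L), length(cells))
  in_region <- logical(n_cells(grid))
  in_region[cells + 1L] <- TRUE
  pres <- matrix(FALSE, nrow = length(ids), ncol = n_cells(grid),
                 dimnames = list(ids, NULL))
  for (s in seq_along(ids)) {
    start <- cells[sample.int(length(cells), 1L)]
    pres[s, grow_patch(grid, in_region, start, sizes[s]) + 1L] <- TRUE
  }
  range_stack(grid, pres)
}

# Randomised rook-BFS accretion: occupy `size` in-region cells connected to
# `start`, choosing uniformly among frontier cells at each step. Returns
# 0-based cell ids. May return fewer cells if the connected component is
# smaller than `size`.
grow_patch <- function(grid, in_region, start, size) {
  nr <- grid$n_rows; nc <- grid$n_cols
  occupied <- integer(size)
  occ_mask <- logical(nr * nc)
  frontier <- integer(0)
  front_mask <- logical(nr * nc)
  add_neighbours <- function(cell) {
    r <- cell %/% nc; c <- cell %% nc
    nb <- c(if (r > 0L) cell - nc, if (r < nr - 1L) cell + nc,
            if (c > 0L) cell - 1L, if (c < nc - 1L) cell + 1L)
    nb <- nb[in_region[nb + 1L] & !occ_mask[nb + 1L] & !front_mask[nb + 1L]]
    front_mask[nb + 1L] <<- TRUE
    frontier <<- c(frontier, nb)
  }
  occupied[1L] <- start
  occ_mask[start + 1L] <- TRUE
  add_neighbours(start)
  k <- 1L
  while (k < size && length(frontier)) {
    pick <- sample.int(length(frontier), 1L)
    cell <- frontier[pick]
    frontier <- frontier[-pick]
    front_mask[cell + 1L] <- FALSE
    k <- k + 1L
    occupied[k] <- cell
    occ_mask[cell + 1L] <- TRUE
    add_neighbours(cell)
  }
  occupied[seq_len(k)]
}

#' Clustered habitat mosaic
#'
#' K random seed cells define competing habitat domains. Each cell is
#' assigned the class minimising `distance_to_seed * clustering_strength +
#' noise * (1 - clustering_strength)` with fresh uniform noise per
#' (cell, class), so `clustering_strength` near 1 gives compact Voronoi-like
#' domains (high Moran's I) and near 0 gives salt-and-pepper mosaics (low
#' Moran's I). Proportions are the one-hot encoding of the winning class.
#'
#' @param grid a [grid_spec()].
#' @param K number of habitat classes (1 <= K <= number of cells).
#' @param clustering_strength compactness in `[0, 1]`.
#' @param seed integer seed.
#' @return A [habitat_raster()] with one-hot per-cell proportions.
#' @export
gen_habitat <- function(grid, K, clustering_strength = 0.7, seed = 1L) {
  n <- n_cells(grid)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of cells")
  if (clustering_strength < 0 || clustering_strength > 1)
    stop("clustering_strength must be in [0, 1]")
  set.seed(sub_seed(seed, 307L))
  seeds <- sample.int(n, K) - 1L
  rc <- cell_rowcol(seq_len(n) - 1L, grid)
  sc <- cell_rowcol(seeds, grid)
  diam <- max(grid$n_rows, grid$n_cols)
  score <- matrix(0, nrow = n, ncol = K)
  for (k in seq_len(K)) {
    d <- sqrt((rc[, "row"] - sc[k, "row"])^2 + (rc[, "col"] - sc[k, "col"])^2)
    score[, k] <- clustering_strength * d / diam +
      (1 - clustering_strength) * stats::runif(n)
  }
  winner <- max.col(-score, ties.method = "first")
  prop <- matrix(0, nrow = n, ncol = K,
                 dimnames = list(NULL, paste0("class_", seq_len(K))))
  prop[cbind(seq_len(n), winner)] <- 1
  habitat_raster(grid, prop)
}

#' Smooth-plus-noise climate field
#'
#' One layer: `value = base + gradient_per_cell * row + N(0, noise_sd)`,
#' emulating a smooth latitudinal gradient plus cell-level heterogeneity.
#'
#' @param grid a [grid_spec()].
#' @param base intercept (units of the variable).
#' @param gradient_per_cell additive change per grid row.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @param name layer name.
#' @return A [climate_raster()] with a single layer.
#' @export
gen_climate_field <- function(grid, base = 0, gradient_per_cell = 0,
                              noise_sd = 0, seed = 1L, name = "var") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(sub_seed(seed, 401L))
  n <- n_cells(grid)
  rows <- cell_rowcol(seq_len(n) - 1L, grid)[, "row"]
  vals <- base + gradient_per_cell * rows + stats::rnorm(n, 0, noise_sd)
  climate_raster(grid, stats::setNames(list(vals), name))
}

#' Contiguous random partition of the grid into regions
#'
#' `n_regions` seed cells grow simultaneously by randomised multi-source
#' rook-BFS until every cell is claimed, so each region is rook-connected
#' and the labels partition the grid (no "outside" cells).
#'
#' @param grid a [grid_spec()] (its labels are replaced).
#' @param n_regions number of regions (1 <= n_regions <= number of cells).
#' @param seed integer seed.
#' @return A [grid_spec()] with labels `region_1 ... region_n`.
#' @export
gen_bioregions <- function(grid, n_regions, seed = 1L) {
  n <- n_cells(grid)
  if (n_regions < 1L || n_regions > n)
    stop("n_regions must be in [1, number of cells]")
  set.seed(sub_seed(seed, 503L))
  lab <- integer(n)  # 0 = unclaimed
  seeds <- sample.int(n, n_regions)
  lab[seeds] <- seq_len(n_regions)
  nr <- grid$n_rows; nc <- grid$n_cols
  # per-region frontier of claimed cells; regions take turns at random so
  # sizes stay roughly balanced rather than snowballing
  frontier <- as.list(seeds)
  alive <- rep(TRUE, n_regions)
  while (any(alive)) {
    g <- sample(which(alive), 1L)
    advanced <- FALSE
    while (length(frontier[[g]]) && !advanced) {
      pick <- sample.int(length(frontier[[g]]), 1L)
      cell <- frontier[[g]][pick] - 1L
      r <- cell %/% nc; c <- cell %% nc
      nb <- c(if (r > 0L) cell - nc, if (r < nr - 1L) cell + nc,
              if (c > 0L) cell - 1L, if (c < nc - 1L) cell + 1L) + 1L
      free <- nb[lab[nb] == 0L]
      if (!length(free)) {
        frontier[[g]] <- frontier[[g]][-pick]
      } else {
        claim <- free[sample.int(length(free), 1L)]
        lab[claim] <- g
        frontier[[g]] <- c(frontier[[g]], claim)
        advanced <- TRUE
      }
    }
    if (!length(frontier[[g]])) alive[g] <- FALSE
  }
  grid_spec(nr, nc, grid$cell_size_km, paste0("region_", lab))
}

#' Generate a complete synthetic scenario
#'
#' Runs all five generators from a [scenario_config()], each on its own
#' seed stream derived from the master seed.
#'
#' @param config a [scenario_config()].
#' @return list with elements `config`, `grid`, `metaweb`, `ranges`,
#'   `habitat`, `climate`.
#' @export
gen_scenario <- function(config = scenario_config()) {
  base_grid <- grid_spec(config$n_rows, config$n_cols, config$cell_size_km)
  grid <- gen_bioregions(base_grid, config$n_regions, seed = config$seed)
  web <- gen_metaweb(config$S_pool, config$C_target, config$basal_fraction,
                     seed = config$seed)
  ranges <- gen_ranges(grid, web, config$range_median, config$range_sigma,
                       config$trophic_range_scaling, seed = config$seed)
  habitat <- gen_habitat(grid, config$habitat_K, config$habitat_clustering,
                         seed = config$seed)
  layers <- list()
  for (i in seq_along(config$climate)) {
    v <- names(config$climate)[i]
    p <- config$climate[[i]]
    cl <- gen_climate_field(grid, p[["base"]], p[["gradient"]],
                            p[["noise_sd"]], seed = config$seed + 13L * i,
                            name = v)
    layers[[v]] <- cl$variables[[v]]
  }
  list(config = config, grid = grid, metaweb = web, ranges = ranges,
       habitat = habitat, climate = climate_raster(grid, layers))
}
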