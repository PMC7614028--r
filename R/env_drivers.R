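#' Bray-Curtis dissimilarity between two cells' habitat composition
#'
#' `BC_ij = 1 - 2 C_ij / (S_i + S_j)` where `C_ij` is the sum over habitat
#' classes of the lesser cover proportion and, under the default
#' abundance-sum convention, `S_i` and `S_j` are the total cover of each
#' cell (the convention of vegan's `vegdist`). `convention = "richness"`
#' instead uses the counts of habitats present (> 0) in each cell, the
#' literal "total number of habitats" reading.
#'
#' @param cell_i,cell_j numeric vectors of per-class proportions, same
#'   length, entries >= 0.
#' @param convention `"abundance"` (default) or `"richness"`.
#' @return dissimilarity in `[0, 1]`; `NA` if both cells are empty.
#' @export
bray_curtis_pair <- function(cell_i, cell_j,
                             convention = c("abundance", "richness")) {
  convention <- match.arg(convention)
  if (length(cell_i) != length(cell_j))
    stop("cells must have the same number of habitat classes")
  if (any(cell_i < 0) || any(cell_j < 0))
    stop("habitat proportions must be non-negative")
  C_ij <- sum(pmin(cell_i, cell_j))
  if (convention == "abundance") {
    S_i <- sum(cell_i); S_j <- sum(cell_j)
  } else {
    S_i <- sum(cell_i > 0); S_j <- sum(cell_j > 0)
    C_ij <- sum(cell_i > 0 & cell_j > 0)
  }
  if (S_i + S_j == 0) return(NA_real_)
  1 - 2 * C_ij / (S_i + S_j)
}

#' Mean habitat dissimilarity of a region
#'
#' Bray-Curtis dissimilarity over pairs of in-region cells, averaged.
#' All pairs are used when their number does not exceed `pair_budget`;
#' beyond that a uniform random sample of `pair_budget` pairs is averaged
#' instead (seeded, and flagged via the `"estimated"` attribute).
#'
#' @param habitat a [habitat_raster()].
#' @param region region label.
#' @param pair_budget maximum number of pairs evaluated exactly.
#' @param seed seed for pair subsampling.
#' @param convention passed to [bray_curtis_pair()].
#' @return mean dissimilarity (`NA` for regions with < 2 cells), with
#'   attribute `estimated` (logical).
#' @export
region_bray_curtis <- function(habitat, region, pair_budget = 50000L,
                               seed = 1L, convention = "abundance") {
  cells <- region_cells(habitat$grid, region)
  n <- length(cells)
  if (n < 2L) return(structure(NA_real_, estimated = FALSE))
  P <- habitat$proportions[cells + 1L, , drop = FALSE]
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= pair_budget) {
    tot <- 0
    for (i in seq_len(n - 1L)) {
      Ci <- colSums(pmin(t(P[(i + 1L):n, , drop = FALSE]), P[i, ]))
      if (convention == "abundance") {
        Si <- sum(P[i, ]); Sj <- rowSums(P[(i + 1L):n, , drop = FALSE])
        tot <- tot + sum(1 - 2 * Ci / (Si + Sj))
      } else {
        for (j in (i + 1L):n)
          tot <- tot + bray_curtis_pair(P[i, ], P[j, ], convention)
      }
    }
    return(structure(tot / n_pairs, estimated = FALSE))
  }
  set.seed(sub_seed(seed, 811L))
  i <- sample.int(n, pair_budget, replace = TRUE)
  j <- sample.int(n - 1L, pair_budget, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
  vals <- vapply(seq_len(pair_budget), function(k)
    bray_curtis_pair(P[i[k], ], P[j[k], ], convention), 0)
  structure(mean(vals), estimated = TRUE)
}

#' Rook/queen adjacency pairs within a region
#'
#' Binary symmetric spatial weights with zero diagonal: `w_ij = 1` iff
#' cells i and j are directly adjacent (4-neighbour rook or 8-neighbour
#' queen) and both belong to the region.
#'
#' @param grid a [grid_spec()].
#' @param region region label.
#' @param scheme `"rook"` or `"queen"`.
#' @return list with `pairs` (two-column matrix of ordered adjacent
#'   0-based cell-id pairs, both directions present) and `W` (sum of all
#'   weights = number of ordered pairs).
#' @export
adjacency_pairs <- function(grid, region, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  cells <- region_cells(grid, region)
  in_region <- logical(n_cells(grid))
  in_region[cells + 1L] <- TRUE
  nr <- grid$n_rows; nc <- grid$n_cols
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (scheme == "queen") offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rc <- cell_rowcol(cells, grid)
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    r2 <- rc[, "row"] + off[1]; c2 <- rc[, "col"] + off[2]
    ok <- r2 >= 0L & r2 < nr & c2 >= 0L & c2 < nc
    nb <- r2[ok] * nc + c2[ok]
    keep <- in_region[nb + 1L]
    from <- c(from, cells[ok][keep]); to <- c(to, nb[keep])
  }
  pairs <- rbind(cbind(from, to), cbind(to, from))  # both directions
  list(pairs = pairs, W = nrow(pairs))
}

#' Moran's I of a binary habitat layer within a region
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` over the region's N cells, with binary adjacency weights.
#' Undefined (NA) when the layer has zero variance within the region.
#'
#' @param x numeric/logical vector over all grid cells (row-major), or over
#'   the region's cells only (length N).
#' @param grid a [grid_spec()].
#' @param region region label.
#' @param adjacency result of [adjacency_pairs()] (recomputed if `NULL`).
#' @param scheme used when `adjacency` is `NULL`.
#' @return Moran's I, or `NA` for a constant layer.
#' @export
morans_i_layer <- function(x, grid, region, adjacency = NULL,
                           scheme = "rook") {
  cells <- region_cells(grid, region)
  N <- length(cells)
  if (!N) stop("region ", region, " has no cells")
  if (length(x) == n_cells(grid)) {
    xr <- as.numeric(x[cells + 1L])
  } else if (length(x) == N) {
    xr <- as.numeric(x)
  } else stop("x must cover the grid or the region's cells")
  xbar <- mean(xr)
  denom <- sum((xr - xbar)^2)
  if (denom == 0) return(NA_real_)
  if (is.null(adjacency)) adjacency <- adjacency_pairs(grid, region, scheme)
  if (adjacency$W == 0) return(NA_real_)
  pos <- match(adjacency$pairs[, 1], cells)
  qos <- match(adjacency$pairs[, 2], cells)
  num <- sum((xr[pos] - xbar) * (xr[qos] - xbar))
  (N / adjacency$W) * num / denom
}

#' Mean habitat clustering (Moran's I) of a region
#'
#' Derives a binary presence layer per habitat class (cover proportion
#' >= `presence_threshold`, default any positive cover), computes Moran's I
#' for each, and averages the defined values into one clustering score.
#'
#' @param habitat a [habitat_raster()].
#' @param region region label.
#' @param scheme adjacency scheme, `"rook"` (default) or `"queen"`.
#' @param presence_threshold minimum cover counting as presence; 0 means
#'   any positive cover.
#' @return mean Moran's I over habitats with defined I (`NA` if none).
#' @export
region_habitat_clustering <- function(habitat, region, scheme = "rook",
                                      presence_threshold = 0) {
  adjacency <- adjacency_pairs(habitat$grid, region, scheme)
  cells <- region_cells(habitat$grid, region)
  vals <- apply(habitat$proportions, 2, function(p) {
    pres <- if (presence_threshold > 0) p >= presence_threshold else p > 0
    morans_i_layer(pres[cells + 1L], habitat$grid, region, adjacency)
  })
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Per-region climate means and SDs
#'
#' @param climate a [climate_raster()].
#' @param region region label.
#' @return data.frame with one row per variable: `variable, mean, sd`
#'   (sample SD, n - 1; 0 for single-cell regions).
#' @export
climate_summary <- function(climate, region) {
  cells <- region_cells(climate$grid, region)
  if (!length(cells)) stop("region ", region, " has no cells")
  rows <- lapply(names(climate$variables), function(v) {
    x <- climate$variables[[v]][cells + 1L]
    data.frame(variable = v, mean = mean(x),
               sd = if (length(x) < 2L) 0 else stats::sd(x))
  })
  do.call(rbind, rows)
}

#' Environmental summary table over regions
#'
#' One row per region: climate means/SDs, mean Bray-Curtis habitat
#' dissimilarity, mean habitat clustering (Moran's I), region area in
#' cells, and the number of habitats present.
#'
#' @param habitat a [habitat_raster()].
#' @param climate a [climate_raster()].
#' @param regions region labels (default: all on the grid).
#' @param scheme adjacency scheme for clustering.
#' @param pair_budget,seed passed to [region_bray_curtis()].
#' @return data.frame keyed by `region`.
#' @export
env_summary <- function(habitat, climate, regions = NULL, scheme = "rook",
                        pair_budget = 50000L, seed = 1L) {
  if (is.null(regions)) regions <- region_names(habitat$grid)
  rows <- lapply(regions, function(rg) {
    cells <- region_cells(habitat$grid, rg)
    cs <- climate_summary(climate, rg)
    out <- data.frame(region = rg, area_cells = length(cells),
                      n_habitats = sum(colSums(
                        habitat$proportions[cells + 1L, , drop = FALSE]) > 0),
                      bray_curtis = as.numeric(
                        region_bray_curtis(habitat, rg, pair_budget, seed)),
                      habitat_clustering = region_habitat_clustering(
                        habitat, rg, scheme))
    for (i in seq_len(nrow(cs))) {
      out[[paste0(cs$variable[i], "_mean")]] <- cs$mean[i]
      out[[paste0(cs$variable[i], "_sd")]] <- cs$sd[i]
    }
    out
  })
  do.call(rbind, rows)
}

#' Commonality analysis of a linear regression
#'
#' Decomposes the full-model R^2 of `y ~ X` into 2^p - 1 commonality
#' coefficients: a unique effect per predictor and a common effect per
#' predictor subset, obtained by inclusion-exclusion over the R^2 of all
#' non-empty predictor subsets. The coefficients sum to the full-model
#' R^2; the unique effect of predictor k equals
#' `R2(full) - R2(full without k)`.
#'
#' @param X data.frame or matrix of predictors (p <= 10 columns).
#' @param y response vector, `length(y) > p + 1`.
#' @return An object of class `commonality_result`: list with
#'   `predictors`, `subset_r2` (named by comma-joined predictor names),
#'   `coefficients` (same naming; unique effects are the singleton
#'   entries), `full_r2`.
#' @export
commonality_analysis <- function(X, y) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 1L || p > 10L) stop("need 1 to 10 predictors")
  if (length(y) <= p + 1L) stop("need more observations than predictors + 1")
  Xm <- as.matrix(X)
  if (qr(cbind(1, Xm))$rank < p + 1L) {
    cc <- stats::cor(Xm)
    bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    stop("rank-deficient predictor matrix",
         if (nrow(bad)) paste0("; collinear: ",
           paste(colnames(Xm)[bad[, 1]], colnames(Xm)[bad[, 2]],
                 sep = " ~ ", collapse = ", ")))
  }
  nsub <- 2L^p - 1L
  r2 <- numeric(nsub)
  sst <- sum((y - mean(y))^2)
  for (m in seq_len(nsub)) {
    sel <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    fit <- stats::lm.fit(cbind(1, Xm[, sel, drop = FALSE]), y)
    r2[m] <- 1 - sum(fit$residuals^2) / sst
  }
  full <- nsub
  r2_of <- function(mask) if (mask == 0L) 0 else r2[mask]
  # h(B) = sum of coefficients over non-empty subsets of B
  #      = R2(full) - R2(complement of B)
  h <- function(mask) r2[full] - r2_of(bitwAnd(full, bitwNot(mask)))
  coefs <- numeric(nsub)
  for (m in seq_len(nsub)) {
    bits_m <- sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    s <- m
    total <- 0
    repeat {  # enumerate submasks of m (including 0)
      bits_s <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      total <- total + (-1)^(bits_m - bits_s) * h(s)
      if (s == 0L) break
      s <- bitwAnd(s - 1L, m)
    }
    coefs[m] <- total
  }
  nm <- vapply(seq_len(nsub), function(m)
    paste(colnames(X)[which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L)],
          collapse = ","), "")
  structure(list(predictors = colnames(X),
                 subset_r2 = stats::setNames(r2, nm),
                 coefficients = stats::setNames(coefs, nm),
                 full_r2 = r2[full]),
            class = "commonality_result")
}

#' @export
print.commonality_result <- function(x, ...) {
  cat(sprintf("<commonality_result> %d predictors, full R2 = %.4f\n",
              length(x$predictors), x$full_r2))
  u <- x$coefficients[x$predictors]
  for (p in x$predictors)
    cat(sprintf("  unique(%s) = %.4f\n", p, u[[p]]))
  invisible(x)
}

#' Commonality-guided predictor selection
#'
#' Ranks predictors by unique effect and greedily retains those whose
#' absolute pairwise correlation with every already-retained predictor
#' stays below `cor_threshold`.
#'
#' @param X predictor data.frame.
#' @param y response.
#' @param n_keep maximum number retained.
#' @param cor_threshold collinearity cutoff (default 0.7).
#' @return character vector of retained predictor names.
#' @export
select_predictors <- function(X, y, n_keep = 2L, cor_threshold = 0.7) {
  ca <- commonality_analysis(X, y)
  u <- sort(ca$coefficients[ca$predictors], decreasing = TRUE)
  keep <- character(0)
  for (p in names(u)) {
    if (length(keep) >= n_keep) break
    if (!length(keep) ||
        all(abs(stats::cor(X[[p]], X[, keep, drop = FALSE])) < cor_threshold))
      keep <- c(keep, p)
  }
  keep
}

#' Linear regression of scaling exponents on environmental predictors
#'
#' OLS with intercept of the per-region z-exponents on the selected
#' predictors; per-coefficient t statistics on n - k - 1 degrees of
#' freedom.
#'
#' @param X predictor data.frame (k columns, n rows).
#' @param y response (z-exponents), length n > k + 1.
#' @return list with `coefficients` (data.frame: term, estimate, se, t,
#'   p_value), `r_squared`, `adj_r_squared`, `df_residual`, `n`.
#' @export
fit_z_regression <- function(X, y) {
  X <- as.data.frame(X)
  k <- ncol(X); n <- length(y)
  if (n <= k + 1L) stop("need n > k + 1 observations")
  if (qr(cbind(1, as.matrix(X)))$rank < k + 1L)
    stop("collinear predictor matrix")
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p_value")
  co <- cbind(data.frame(term = rownames(co), stringsAsFactors = FALSE), co)
  rownames(co) <- NULL
  list(coefficients = co, r_squared = sm$r.squared,
       adj_r_squared = sm$adj.r.squared,
       df_residual = fit$df.residual, n = n)
}
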