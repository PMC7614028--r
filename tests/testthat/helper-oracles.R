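# Fixtures and independent oracles used across the suite.

# Tiny three-species chain: c eats b, b eats a.
chain_metaweb <- function() {
  metaweb(data.frame(species_id = c("a", "b", "c")),
          data.frame(consumer_id = c("c", "b"), resource_id = c("b", "a")))
}

# Random directed metaweb on n species with link probability p (no
# self-links), as a metaweb object.
random_metaweb <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  pairs <- expand.grid(consumer_id = ids, resource_id = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$consumer_id != pairs$resource_id, ]
  keep <- stats::runif(nrow(pairs)) < p
  metaweb(data.frame(species_id = ids), pairs[keep, , drop = FALSE])
}

# Naive double-loop computation of all web metrics; the independent oracle
# for compute_metrics(). Works directly on the edge list.
naive_metrics <- function(species, cons, res) {
  keep <- cons != res
  cons <- cons[keep]; res <- res[keep]
  S <- length(species)
  L <- length(cons)
  n_prey <- n_pred <- integer(S)
  for (i in seq_len(S)) {
    for (k in seq_len(L)) {
      if (cons[k] == species[i]) n_prey[i] <- n_prey[i] + 1L
      if (res[k] == species[i]) n_pred[i] <- n_pred[i] + 1L
    }
  }
  basal <- inter <- top <- 0L
  for (i in seq_len(S)) {
    if (n_prey[i] == 0L) basal <- basal + 1L
    else if (n_pred[i] == 0L) top <- top + 1L
    else inter <- inter + 1L
  }
  gen <- n_prey[n_prey > 0]; vul <- n_pred[n_pred > 0]
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  shared <- 0L
  for (k in seq_len(L)) {
    nshare <- 0L
    for (m in seq_len(L)) if (res[m] == res[k]) nshare <- nshare + 1L
    if (nshare >= 2L) shared <- shared + 1L
  }
  list(S = S, L = L,
       gen_mean = if (length(gen)) mean(gen) else NA_real_,
       gen_sd = if (length(gen)) sd0(gen) else NA_real_,
       vul_mean = if (length(vul)) mean(vul) else NA_real_,
       vul_sd = if (length(vul)) sd0(vul) else NA_real_,
       frac_basal = basal / S, frac_intermediate = inter / S,
       frac_top = top / S,
       consumer_overlap = if (L) shared / L else NA_real_)
}

# Literal brute-force double sum of the Moran's I formula over all ordered
# cell pairs of a full rectangular grid with rook/queen weights.
brute_morans_i <- function(mat, scheme = "rook") {
  nr <- nrow(mat); nc <- ncol(mat)
  x <- as.numeric(t(mat))  # row-major
  N <- nr * nc
  xbar <- mean(x)
  num <- 0; W <- 0
  for (i in seq_len(N)) {
    ri <- (i - 1) %/% nc; ci <- (i - 1) %% nc
    for (j in seq_len(N)) {
      if (i == j) next
      rj <- (j - 1) %/% nc; cj <- (j - 1) %% nc
      dr <- abs(ri - rj); dc <- abs(ci - cj)
      adj <- if (scheme == "rook") (dr + dc == 1) else (max(dr, dc) == 1)
      if (adj) {
        W <- W + 1
        num <- num + (x[i] - xbar) * (x[j] - xbar)
      }
    }
  }
  denom <- sum((x - xbar)^2)
  if (denom == 0) return(NA_real_)
  (N / W) * num / denom
}

# Grid-search oracle for the power-law fit: exhaustive (c, z) lattice
# refined around the best cell.
grid_search_power <- function(A, y, z_range = c(-1, 2)) {
  sse <- function(cc, z) sum((y - cc * A^z)^2)
  zs <- seq(z_range[1], z_range[2], length.out = 121)
  best <- c(NA, NA, Inf)
  for (z in zs) {
    Az <- A^z
    cc <- sum(Az * y) / sum(Az^2)  # optimal c given z (linear)
    v <- sse(cc, z)
    if (v < best[3]) best <- c(cc, z, v)
  }
  for (halve in 1:25) {
    width <- (z_range[2] - z_range[1]) / 2^halve
    zs <- seq(best[2] - width, best[2] + width, length.out = 41)
    for (z in zs) {
      Az <- A^z
      cc <- sum(Az * y) / sum(Az^2)
      v <- sse(cc, z)
      if (v < best[3]) best <- c(cc, z, v)
    }
  }
  list(c = best[1], z = best[2], sse = best[3])
}

# Flood fill over rook neighbours: is the 0-based cell set connected?
rook_connected <- function(cells, n_rows, n_cols) {
  if (!length(cells)) return(TRUE)
  inset <- logical(n_rows * n_cols)
  inset[cells + 1L] <- TRUE
  seen <- logical(n_rows * n_cols)
  stack <- cells[1]
  seen[cells[1] + 1L] <- TRUE
  while (length(stack)) {
    cell <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- cell %/% n_cols; c <- cell %% n_cols
    nb <- c(if (r > 0) cell - n_cols, if (r < n_rows - 1) cell + n_cols,
            if (c > 0) cell - 1L, if (c < n_cols - 1) cell + 1L)
    nb <- nb[inset[nb + 1L] & !seen[nb + 1L]]
    seen[nb + 1L] <- TRUE
    stack <- c(stack, nb)
  }
  sum(seen) == length(cells)
}

# Queen-adjacency connectivity of a 0-based cell set.
queen_connected <- function(cells, n_rows, n_cols) {
  if (!length(cells)) return(TRUE)
  inset <- logical(n_rows * n_cols)
  inset[cells + 1L] <- TRUE
  seen <- logical(n_rows * n_cols)
  stack <- cells[1]
  seen[cells[1] + 1L] <- TRUE
  while (length(stack)) {
    cell <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- cell %/% n_cols; c <- cell %% n_cols
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 0 && r2 < n_rows && c2 >= 0 && c2 < n_cols)
        nb <- c(nb, r2 * n_cols + c2)
    }
    nb <- nb[inset[nb + 1L] & !seen[nb + 1L]]
    seen[nb + 1L] <- TRUE
    stack <- c(stack, nb)
  }
  sum(seen) == length(cells)
}

# A range stack in which species k occupies exactly cell k of an n-cell
# single-region grid: forces S(A) = A along any spiral path.
singleton_ranges <- function(n_rows, n_cols) {
  grid <- grid_spec(n_rows, n_cols, region_label = "r1")
  n <- n_rows * n_cols
  ids <- sprintf("sp%03d", seq_len(n))
  pres <- diag(n) == 1
  rownames(pres) <- ids
  list(grid = grid,
       web = metaweb(data.frame(species_id = ids),
                     data.frame(consumer_id = character(),
                                resource_id = character())),
       ranges = range_stack(grid, pres))
}
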