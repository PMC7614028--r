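test_that("bray_curtis_pair matches the formula and its bounds", {
  expect_equal(bray_curtis_pair(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis_pair(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis_pair(c(0.6, 0.4, 0), c(0.2, 0.3, 0.5)), 0.5)
  expect_error(bray_curtis_pair(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  expect_error(bray_curtis_pair(c(1), c(0.5, 0.5)), "same number")

  # symmetry and bounds on random compositions
  set.seed(10)
  for (k in 1:50) {
    a <- stats::runif(5); b <- stats::runif(5)
    d1 <- bray_curtis_pair(a, b)
    expect_equal(d1, bray_curtis_pair(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
  # richness convention counts shared classes
  expect_equal(bray_curtis_pair(c(0.6, 0.4, 0), c(0.2, 0.3, 0.5),
                                convention = "richness"), 1 - 4 / 5)
})

test_that("bray_curtis_pair agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (k in 1:20) {
    a <- stats::runif(6); b <- stats::runif(6)
    ref <- as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
    expect_equal(bray_curtis_pair(a, b), ref, tolerance = 1e-12)
  }
})

test_that("region_bray_curtis: exact all-pairs mean and fair subsampling", {
  g <- grid_spec(2, 1, region_label = "r1")
  h <- habitat_raster(g, matrix(c(0.6, 0.4, 0, 0.2, 0.3, 0.5), nrow = 2,
                                byrow = TRUE))
  expect_equal(as.numeric(region_bray_curtis(h, "r1")), 0.5)

  same <- habitat_raster(g, matrix(0.5, 2, 2))
  expect_equal(as.numeric(region_bray_curtis(same, "r1")), 0)

  g1 <- grid_spec(1, 1, region_label = "r1")
  expect_true(is.na(region_bray_curtis(
    habitat_raster(g1, matrix(1, 1, 1)), "r1")))

  # 40-cell region: budgeted estimate close to the exact mean
  g40 <- grid_spec(5, 8, region_label = "r1")
  hab <- gen_habitat(g40, 4, 0.5, seed = 3)
  exact <- as.numeric(region_bray_curtis(hab, "r1", pair_budget = 10000))
  errs <- vapply(1:20, function(s)
    abs(as.numeric(region_bray_curtis(hab, "r1", pair_budget = 500,
                                      seed = s)) - exact), 0)
  expect_lt(mean(errs), 0.02)
  est <- region_bray_curtis(hab, "r1", pair_budget = 500, seed = 1)
  expect_true(attr(est, "estimated"))
})

test_that("morans_i_layer reproduces closed-form cases", {
  # constant layer: undefined
  g2 <- grid_spec(2, 2, region_label = "r1")
  expect_true(is.na(morans_i_layer(rep(1, 4), g2, "r1")))

  # perfect checkerboard on an even grid, rook: exactly -1
  g6 <- grid_spec(6, 6, region_label = "r1")
  rc <- cell_rowcol(0:35, g6)
  checker <- (rc[, "row"] + rc[, "col"]) %% 2
  expect_equal(morans_i_layer(checker, g6, "r1"), -1)

  # 2x2 single presence, rook: -1/3 (brute-force double sum)
  x <- c(1, 0, 0, 0)
  expect_equal(morans_i_layer(x, g2, "r1"), -1 / 3)
  expect_equal(brute_morans_i(matrix(x, 2, 2, byrow = TRUE)), -1 / 3)
})

test_that("morans_i_layer equals the brute-force double sum exactly", {
  g10 <- grid_spec(10, 10, region_label = "r1")
  adj_rook <- adjacency_pairs(g10, "r1", "rook")
  adj_queen <- adjacency_pairs(g10, "r1", "queen")
  set.seed(19)
  for (k in 1:100) {
    x <- as.numeric(stats::runif(100) < stats::runif(1, 0.2, 0.8))
    if (stats::var(x) == 0) next
    m <- matrix(x, 10, 10, byrow = TRUE)
    expect_equal(morans_i_layer(x, g10, "r1", adj_rook),
                 brute_morans_i(m, "rook"), tolerance = 1e-12)
    if (k <= 10)
      expect_equal(morans_i_layer(x, g10, "r1", adj_queen),
                   brute_morans_i(m, "queen"), tolerance = 1e-12)
  }
})

test_that("adjacency restricts to in-region pairs", {
  # two disjoint 1-cell regions: no pairs, I undefined
  g <- grid_spec(1, 3, region_label = c("a", "b", "a"))
  adj <- adjacency_pairs(g, "a")
  expect_equal(adj$W, 0)
  expect_true(is.na(morans_i_layer(c(1, 0), g, "a")))
})

test_that("region_habitat_clustering averages defined layers", {
  g <- grid_spec(4, 4, region_label = "r1")
  # one habitat covering the compact left half, its complement the right
  left <- as.numeric(cell_rowcol(0:15, g)[, "col"] < 2)
  prop <- cbind(class_1 = left, class_2 = 1 - left)
  h <- habitat_raster(g, prop)
  i1 <- morans_i_layer(left, g, "r1")
  expect_gt(i1, 0)
  expect_equal(region_habitat_clustering(h, "r1"), i1)  # both layers equal

  # identical copies of one layer leave the mean unchanged
  h3 <- habitat_raster(g, cbind(a = left / 2, b = left / 2, c = 1 - left),
                       renormalise = TRUE)
  expect_equal(region_habitat_clustering(h3, "r1"), i1)

  # one-hot mosaics are threshold-invariant
  hh <- gen_habitat(g, 3, 0.6, seed = 2)
  expect_equal(region_habitat_clustering(hh, "r1", presence_threshold = 0),
               region_habitat_clustering(hh, "r1", presence_threshold = 0.5))
})

test_that("climate_summary matches two-pass oracle", {
  g <- grid_spec(1, 2, region_label = "r1")
  cl <- climate_raster(g, list(t = c(0, 10)))
  cs <- climate_summary(cl, "r1")
  expect_equal(cs$mean, 5)
  expect_equal(cs$sd, sqrt(50), tolerance = 1e-12)

  g1 <- grid_spec(1, 1, region_label = "r1")
  cs1 <- climate_summary(climate_raster(g1, list(t = 4)), "r1")
  expect_equal(cs1$sd, 0)

  gg <- grid_spec(5, 10, region_label = "r1")
  set.seed(23)
  for (k in 1:50) {
    x <- stats::rnorm(50)
    cs <- climate_summary(climate_raster(gg, list(v = x)), "r1")
    n <- length(x); mu <- sum(x) / n
    expect_equal(cs$mean, mu)
    expect_equal(cs$sd, sqrt(sum((x - mu)^2) / (n - 1)))
  }
})

test_that("commonality coefficients decompose R2", {
  set.seed(29)
  # p = 1: unique effect is the R2
  x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20, 0, 0.3)
  ca1 <- commonality_analysis(data.frame(x = x), y)
  expect_equal(unname(ca1$coefficients["x"]), ca1$full_r2)

  # exactly orthogonal predictors: zero common effect
  x1 <- rep(c(-1, 1), each = 10)
  x2 <- rep(c(-1, 1), times = 10)
  y2 <- x1 + 0.5 * x2 + stats::rnorm(20, 0, 0.2)
  ca2 <- commonality_analysis(data.frame(x1 = x1, x2 = x2), y2)
  expect_equal(unname(ca2$coefficients["x1,x2"]), 0, tolerance = 1e-10)
  expect_equal(unname(ca2$coefficients["x1"]),
               unname(ca2$subset_r2["x1"]), tolerance = 1e-10)

  # identity: coefficients sum to the full R2; uniques match the drop-one
  # definition, for random designs up to p = 6
  for (p in c(2, 3, 4, 6)) {
    n <- 40
    X <- as.data.frame(matrix(stats::rnorm(n * p), n, p))
    names(X) <- paste0("v", seq_len(p))
    yy <- rowSums(X[, 1:2, drop = FALSE]) + stats::rnorm(n)
    ca <- commonality_analysis(X, yy)
    expect_equal(sum(ca$coefficients), ca$full_r2, tolerance = 1e-10)
    for (k in seq_len(p)) {
      drop_r2 <- ca$subset_r2[[paste(names(X)[-k], collapse = ",")]]
      expect_equal(unname(ca$coefficients[names(X)[k]]),
                   ca$full_r2 - drop_r2, tolerance = 1e-10)
    }
  }

  Xc <- data.frame(a = x, b = 2 * x)
  expect_error(commonality_analysis(Xc, y), "rank-deficient")
})

test_that("fit_z_regression recovers constructed coefficients", {
  X <- data.frame(x = c(1, 2, 3, 4, 5))
  y <- 2 + 3 * X$x
  f <- suppressWarnings(fit_z_regression(X, y))  # lm: perfect fit
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$coefficients$estimate[2], 3, tolerance = 1e-10)

  set.seed(31)
  ok <- 0L
  for (k in 1:20) {
    X <- data.frame(clim = stats::rnorm(10), hab = stats::rnorm(10))
    y <- 0.3 + 0.54 * X$clim + 0.06 * X$hab + stats::rnorm(10, 0, 0.05)
    f <- fit_z_regression(X, y)
    est <- f$coefficients
    if (abs(est$estimate[2] - 0.54) < 2 * est$se[2] &&
        abs(est$estimate[3] - 0.06) < 2 * est$se[3]) ok <- ok + 1L
    expect_equal(f$df_residual, 7)
  }
  expect_gte(ok, 17L)

  # joint permutation invariance
  X <- data.frame(a = stats::rnorm(8), b = stats::rnorm(8))
  y <- X$a - X$b + stats::rnorm(8, 0, 0.1)
  perm <- sample.int(8)
  f1 <- fit_z_regression(X, y)
  f2 <- fit_z_regression(X[perm, , drop = FALSE], y[perm])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-12)

  expect_error(fit_z_regression(data.frame(a = 1:5, b = 2 * (1:5)),
                                c(1, 2, 3, 4, 5)), "collinear")
})

test_that("z-regression recovers positive drivers built into a scenario", {
  # regions constructed so SAR z increases with habitat clustering and
  # temperature SD: both signs should come out positive most of the time
  set.seed(37)
  ok <- 0L
  for (trial in 1:20) {
    n <- 10
    clust <- stats::runif(n, 0, 1)
    tsd <- stats::runif(n, 0.5, 3)
    z <- 0.1 + 0.3 * clust + 0.08 * tsd + stats::rnorm(n, 0, 0.02)
    f <- fit_z_regression(data.frame(clust = clust, tsd = tsd), z)
    if (all(f$coefficients$estimate[2:3] > 0)) ok <- ok + 1L
  }
  expect_gte(ok, 16L)
})

test_that("env_summary assembles the per-region predictor table", {
  g <- gen_bioregions(grid_spec(10, 10), 2, seed = 41)
  hab <- gen_habitat(g, 4, 0.7, seed = 41)
  cl1 <- gen_climate_field(g, 5, 0.3, 1, seed = 41, name = "temp")
  cl2 <- gen_climate_field(g, 800, -5, 50, seed = 42, name = "precip")
  clim <- climate_raster(g, c(cl1$variables, cl2$variables))
  es <- env_summary(hab, clim)
  expect_equal(nrow(es), 2L)
  expect_true(all(c("bray_curtis", "habitat_clustering", "temp_mean",
                    "temp_sd", "precip_mean", "precip_sd") %in% names(es)))
  expect_equal(sum(es$area_cells), 100L)
  expect_true(all(es$bray_curtis >= 0 & es$bray_curtis <= 1))
})
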