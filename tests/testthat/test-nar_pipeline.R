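test_that("build_curve rows match single-cell and regional webs", {
  grid <- gen_bioregions(grid_spec(8, 8), 1, seed = 2)
  web <- gen_metaweb(40, 0.08, 0.6, seed = 2)
  rs <- gen_ranges(grid, web, range_median = 10, seed = 2)
  path <- spiral_order(grid, "region_1", 27L)
  cv <- build_curve(web, rs, path)

  sp1 <- rownames(rs$presence)[rs$presence[, path$order[1] + 1]]
  m1 <- compute_metrics(induced_web(web, sp1))
  expect_equal(cv$S[1], m1$S)
  expect_equal(cv$L[1], m1$L)

  all_sp <- rownames(rs$presence)[rowSums(rs$presence) > 0]
  mfull <- compute_metrics(induced_web(web, all_sp))
  expect_equal(cv$S[nrow(cv)], mfull$S)
  expect_equal(cv$L[nrow(cv)], mfull$L)
  expect_equal(cv$gen_mean[nrow(cv)], mfull$gen_mean)

  # final row is path-independent
  cv2 <- build_curve(web, rs, spiral_order(grid, "region_1", 0L))
  last <- nrow(cv)
  for (col in c("S", "L", "frac_basal", "consumer_overlap"))
    expect_equal(cv[[col]][last], cv2[[col]][last])
})

test_that("S(A) and L(A) are monotone along every curve", {
  grid <- gen_bioregions(grid_spec(10, 10), 2, seed = 6)
  web <- gen_metaweb(50, 0.07, 0.6, seed = 6)
  rs <- gen_ranges(grid, web, range_median = 15, seed = 6)
  for (rg in region_names(grid)) {
    cv <- build_curves(web, rs, sample_paths(grid, rg, 3, seed = 8))
    for (k in unique(cv$replicate)) {
      sub <- cv[cv$replicate == k, ]
      expect_true(all(diff(sub$S) >= 0))
      expect_true(all(diff(sub$L) >= 0))
      expect_true(all(diff(sub$A) > 0))
    }
  }
})

test_that("fit_power recovers exact, noiseless and noisy power laws", {
  A <- 1:50
  f_id <- fit_power(A, A)
  expect_equal(f_id$c, 1, tolerance = 1e-8)
  expect_equal(f_id$z, 1, tolerance = 1e-8)

  y <- 3 * (1:100)^0.3
  f <- fit_power(1:100, y)
  expect_equal(f$z, 0.3, tolerance = 1e-6)
  expect_equal(f$c, 3, tolerance = 1e-5)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  set.seed(1234)
  A <- seq_len(1000)
  yn <- 3 * A^0.3 + stats::rnorm(1000, 0, 0.1)
  fn <- fit_power(A, yn)
  expect_gt(fn$z, 0.28)
  expect_lt(fn$z, 0.32)
  expect_equal(fn$method, "nls")

  expect_error(fit_power(1:2, 1:2), ">= 3")
  expect_error(fit_power(1:5, rep(0, 5)), "all y <= 0")
})

test_that("fit_power agrees with the grid-search oracle", {
  set.seed(77)
  for (k in 1:20) {
    z_true <- stats::runif(1, 0.1, 0.9)
    c_true <- stats::runif(1, 0.5, 5)
    A <- sort(sample(1:200, 40))
    y <- c_true * A^z_true * exp(stats::rnorm(40, 0, 0.05))
    f <- fit_power(A, y)
    o <- grid_search_power(A, y)
    expect_lt(abs(f$z - o$z), 1e-3)
    expect_lte(sum((y - f$c * A^f$z)^2), o$sse * (1 + 1e-6))
  }
})

test_that("fit_region pools replicates and is order-invariant", {
  sc <- singleton_ranges(5, 5)
  paths <- sample_paths(sc$grid, "r1", 10, seed = 3)
  cv <- build_curves(sc$web, sc$ranges, paths)
  f <- fit_region(cv, "S")
  expect_equal(f$z, 1, tolerance = 0.01)

  one <- build_curve(sc$web, sc$ranges, paths[[1]])
  hundred <- do.call(rbind, lapply(1:100, function(k) {
    o <- one; o$replicate <- k; o
  }))
  f1 <- fit_power(one$A, one$S)
  f100 <- fit_region(hundred, "S")
  expect_equal(f100$c, f1$c, tolerance = 1e-9)
  expect_equal(f100$z, f1$z, tolerance = 1e-9)

  shuffled <- cv[sample.int(nrow(cv)), ]
  fs <- fit_region(shuffled, "S")
  expect_equal(fs$z, f$z, tolerance = 1e-12)

  expect_error(fit_region(cv, "no_such_metric"), "not found")
})

test_that("per-level SARs partition richness; basal scales faster than top", {
  grid <- gen_bioregions(grid_spec(12, 12), 1, seed = 4)
  web <- gen_metaweb(60, 0.07, 0.7, seed = 4)
  rs <- gen_ranges(grid, web, range_median = 12,
                   trophic_range_scaling = 3, seed = 4)
  cv <- build_curves(web, rs, sample_paths(grid, "region_1", 2, seed = 4))
  expect_equal(cv$n_basal + cv$n_intermediate + cv$n_top, cv$S)

  # all-basal web: basal SAR is the total SAR
  sc <- singleton_ranges(5, 5)
  cvb <- build_curve(sc$web, sc$ranges, spiral_order(sc$grid, "r1", 12L))
  fb <- per_level_sar(cvb, "basal")
  ft <- fit_power(cvb$A, cvb$S)
  expect_equal(fb$z, ft$z, tolerance = 1e-9)
  expect_error(per_level_sar(cvb, "top"), "never populated")

  # consumers carry larger home ranges, so basal richness accumulates
  # faster with area than top richness in most realisations
  wins <- 0L
  for (seed in 1:20) {
    grid <- gen_bioregions(grid_spec(12, 12), 1, seed = seed)
    web <- gen_metaweb(60, 0.07, 0.7, seed = seed)
    rs <- gen_ranges(grid, web, range_median = 10,
                     trophic_range_scaling = 4, seed = seed)
    cv <- build_curves(web, rs,
                       sample_paths(grid, "region_1", 2, seed = seed))
    zb <- per_level_sar(cv, "basal")$z
    zt <- tryCatch(per_level_sar(cv, "top")$z, error = function(e) NA)
    if (is.na(zt) || zb >= zt) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("normalize_curve divides extensive metrics once", {
  grid <- gen_bioregions(grid_spec(8, 8), 1, seed = 9)
  web <- gen_metaweb(40, 0.08, 0.6, seed = 9)
  rs <- gen_ranges(grid, web, range_median = 10, seed = 9)
  cv <- build_curve(web, rs, spiral_order(grid, "region_1", 0L))
  nv <- normalize_curve(cv)
  expect_equal(nv$L, cv$L / cv$S)
  expect_error(normalize_curve(nv), "already")

  fake <- cv
  fake$L <- 2 * fake$S
  expect_equal(unique(normalize_curve(fake)$L), 2)
})

test_that("subsampled-null normalised generality flattens at large areas", {
  grid <- gen_bioregions(grid_spec(10, 10), 1, seed = 13)
  web <- gen_metaweb(60, 0.08, 0.6, seed = 13)
  rs <- gen_ranges(grid, web, range_median = 20, seed = 13)
  cv <- build_curve(web, rs, spiral_order(grid, "region_1", 45L))
  null <- null_subsampled_curve(web, cv, seed = 13)
  nn <- normalize_curve(null)
  upper <- nn[nn$A > max(nn$A) / 2, "gen_mean"]
  expect_lt((max(upper) - min(upper)) / stats::median(upper), 0.2)
})

test_that("richness regressions recover constructed slopes", {
  S <- rep(2:30, each = 2)
  curves <- data.frame(region = "r", replicate = 1, A = seq_along(S),
                       S = S, L = S^2, frac_basal = 0.7)
  f <- suppressWarnings(richness_regressions(curves, "L"))  # perfect fit
  expect_equal(f$scale, "loglog")
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-10)

  fb <- suppressWarnings(richness_regressions(curves, "frac_basal"))
  expect_equal(fb$scale, "raw")
  expect_equal(fb$slope, 0, tolerance = 1e-12)

  expect_error(richness_regressions(
    data.frame(S = rep(5, 10), L = 1:10, region = "r"), "L"),
    "distinct S")
})

test_that("uniform metaweb subsampling gives the L ~ S^2 scaling law", {
  web <- gen_metaweb(120, 0.06, 0.6, seed = 21)
  pool <- web$species$species_id
  set.seed(22)
  sizes <- rep(seq(30, 110, by = 10), each = 30)
  rows <- lapply(seq_along(sizes), function(i) {
    sub <- sample(pool, sizes[i])
    lw <- induced_web(web, sub)
    data.frame(region = "pool", replicate = i, A = i, S = sizes[i],
               L = nrow(lw$links))
  })
  curves <- do.call(rbind, rows)
  curves <- curves[curves$L > 0, ]
  f <- richness_regressions(curves, "L")
  expect_gt(f$slope, 1.85)
  expect_lt(f$slope, 2.15)
})
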