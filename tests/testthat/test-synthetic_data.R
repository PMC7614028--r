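test_that("gen_metaweb is deterministic, hits connectance and basal targets", {
  m1 <- gen_metaweb(60, 0.06, 0.6, seed = 42)
  m2 <- gen_metaweb(60, 0.06, 0.6, seed = 42)
  expect_identical(m1$links, m2$links)
  expect_identical(m1$species, m2$species)

  expect_equal(nrow(gen_metaweb(40, 0.05, 1.0, seed = 1)$links), 0L)

  expect_error(gen_metaweb(50, 0.3, 0.7, seed = 1), "infeasible")

  # Monte Carlo: mean realised connectance near the target
  cvals <- vapply(1:50, function(s) {
    m <- gen_metaweb(100, 0.05, 0.5, seed = s)
    nrow(m$links) / 100^2
  }, 0)
  expect_gt(mean(cvals), 0.03)
  expect_lt(mean(cvals), 0.07)

  # forced basal fraction is a floor on the realised one
  for (s in 1:5) {
    m <- gen_metaweb(73, 0.05, 0.7, seed = s)
    lw <- induced_web(m, m$species$species_id)
    tc <- trophic_classes(lw)
    expect_gte(length(tc$basal) / 73, 0.7)
  }
})

test_that("gen_ranges produces connected ranges of the drawn size", {
  grid <- gen_bioregions(grid_spec(15, 15), 2, seed = 3)
  web <- gen_metaweb(30, 0.06, 0.5, seed = 3)
  rs <- gen_ranges(grid, web, range_median = 10, range_sigma = 0.8,
                   seed = 9)
  expect_identical(rs$presence,
                   gen_ranges(grid, web, range_median = 10,
                              range_sigma = 0.8, seed = 9)$presence)
  for (i in seq_len(nrow(rs$presence))) {
    cells <- which(rs$presence[i, ]) - 1L
    expect_gte(length(cells), 1L)
    expect_true(rook_connected(cells, 15, 15))
  }
})

test_that("forced singleton ranges give SAR z = 1 and whole-region ranges z = 0", {
  sc <- singleton_ranges(6, 6)
  path <- spiral_order(sc$grid, "r1", start_cell = 14L)
  cv <- build_curve(sc$web, sc$ranges, path)
  expect_equal(cv$S, cv$A)  # S(A) = A exactly
  f <- fit_power(cv$A, cv$S)
  expect_equal(f$z, 1, tolerance = 1e-6)

  # every species everywhere: S(A) constant, z ~ 0
  grid <- grid_spec(5, 5, region_label = "r1")
  pres <- matrix(TRUE, 4, 25,
                 dimnames = list(sprintf("sp%d", 1:4), NULL))
  web <- metaweb(data.frame(species_id = sprintf("sp%d", 1:4)),
                 data.frame(consumer_id = character(),
                            resource_id = character()))
  cv2 <- build_curve(web, range_stack(grid, pres),
                     spiral_order(grid, "r1", 0L))
  f2 <- fit_power(cv2$A, cv2$S)
  expect_lt(abs(f2$z), 1e-8)
})

test_that("lognormal ranges yield SAR exponents strictly inside (0, 1)", {
  for (seed in 1:10) {
    grid <- grid_spec(20, 20, region_label = "r1")
    web <- gen_metaweb(50, 0.06, 0.5, seed = seed)
    rs <- gen_ranges(grid, web, range_median = 20, range_sigma = 1,
                     seed = seed)
    cv <- build_curve(web, rs, spiral_order(grid, "r1", 190L),
                      thin = unique(round(exp(seq(0, log(400),
                                                  length.out = 40)))))
    f <- fit_power(cv$A, cv$S)
    expect_gt(f$z, 0)
    expect_lt(f$z, 1)
  }
})

test_that("gen_habitat is one-hot, deterministic, and clustering is monotone", {
  grid <- grid_spec(12, 12, region_label = "r1")
  h1 <- gen_habitat(grid, 1, 0.5, seed = 2)
  expect_true(all(h1$proportions == 1))
  expect_true(is.na(region_habitat_clustering(h1, "r1")))

  for (s in 1:5) {
    h <- gen_habitat(grid, 4, stats::runif(1), seed = s)
    expect_equal(unname(rowSums(h$proportions)), rep(1, 144))
    expect_true(all(h$proportions %in% c(0, 1)))
  }
  expect_identical(gen_habitat(grid, 4, 0.7, seed = 8)$proportions,
                   gen_habitat(grid, 4, 0.7, seed = 8)$proportions)

  g30 <- grid_spec(30, 30, region_label = "r1")
  mi <- function(strength, seed)
    region_habitat_clustering(gen_habitat(g30, 5, strength, seed), "r1")
  hi <- vapply(1:20, function(s) mi(0.9, s), 0)
  lo <- vapply(1:20, function(s) mi(0.1, s), 0)
  expect_gt(mean(hi), mean(lo))

  expect_error(gen_habitat(grid, 0, 0.5, 1), ">= 1")
  expect_error(gen_habitat(grid, 145, 0.5, 1), "exceeds")
})

test_that("gen_climate_field matches closed forms", {
  grid <- grid_spec(10, 8, region_label = "r1")
  flat <- gen_climate_field(grid, base = 5, gradient_per_cell = 0,
                            noise_sd = 0, seed = 1)
  expect_equal(stats::sd(flat$variables$var), 0)

  g <- 0.7
  grad <- gen_climate_field(grid, base = 2, gradient_per_cell = g,
                            noise_sd = 0, seed = 1)
  rows <- rep(0:9, each = 8)
  expect_equal(stats::sd(grad$variables$var), stats::sd(g * rows),
               tolerance = 1e-12)

  g30 <- grid_spec(30, 30, region_label = "r1")
  sds <- vapply(1:10, function(s)
    stats::sd(gen_climate_field(g30, 0, 0, noise_sd = 2,
                                seed = s)$variables$var), 0)
  expect_gt(mean(sds), 1.8)
  expect_lt(mean(sds), 2.2)
})

test_that("gen_bioregions partitions the grid into connected regions", {
  g1 <- gen_bioregions(grid_spec(7, 7), 1, seed = 4)
  expect_equal(unique(g1$region_label), "region_1")

  for (s in 1:20) {
    g <- gen_bioregions(grid_spec(10, 10), 4, seed = s)
    expect_equal(sort(unique(g$region_label)), paste0("region_", 1:4))
    expect_equal(length(g$region_label), 100L)
    for (rg in region_names(g))
      expect_true(rook_connected(region_cells(g, rg), 10, 10))
  }
})

test_that("a full synthetic scenario runs the whole pipeline", {
  cfg <- run_config(seed = 5,
                    scenario = scenario_config(seed = 5, n_rows = 14,
                                               n_cols = 14, S_pool = 60,
                                               n_regions = 2,
                                               range_median = 12,
                                               n_replicates = 2),
                    n_replicates = 2, null_replicates = 1)
  res <- run_pipeline(cfg)
  expect_s3_class(res$curves, "nar_curve")
  expect_true(all(c("S", "L") %in% res$fits$property))
  expect_false(any(!is.finite(res$fits$z)))
  expect_true(all(is.finite(res$env$bray_curtis)))
  expect_gt(nrow(res$z_ratios), 0)
})
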