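#' Run configuration for the end-to-end pipeline
#'
#' Either a synthetic scenario (via `scenario`) or paths to the six CSV
#' inputs. Every stage derives its randomness from `seed`, so two runs
#' with the same configuration produce byte-identical outputs.
#'
#' @param seed master seed.
#' @param scenario a [scenario_config()], or `NULL` when reading CSVs.
#' @param paths named list of input CSV paths (`species`, `edges`,
#'   `presence`, `regions`, `habitat`, `climate`) plus `n_rows`, `n_cols`
#'   grid dimensions; ignored when `scenario` is given.
#' @param n_replicates spiral replicates per region.
#' @param thin `NULL` or increasing integer vector of areas to retain.
#' @param null_models character subset of `c("subsampled", "random")`.
#' @param null_replicates observed replicates per region fed to each null
#'   model (capped at `n_replicates`).
#' @param scheme adjacency scheme for habitat clustering.
#' @param bc_convention Bray-Curtis convention.
#' @param overlap_method consumers' overlap definition.
#' @param z_property property whose per-region z is regressed on the
#'   environment (default `"S"`, the SAR exponent).
#' @param n_predictors predictors retained by commonality-guided selection.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, scenario = scenario_config(seed = seed),
                       paths = NULL, n_replicates = 100L, thin = NULL,
                       null_models = c("subsampled", "random"),
                       null_replicates = 5L, scheme = "rook",
                       bc_convention = "abundance",
                       overlap_method = "shared_links", z_property = "S",
                       n_predictors = 2L, out_dir = NULL) {
  structure(list(seed = as.integer(seed), scenario = scenario, paths = paths,
                 n_replicates = as.integer(n_replicates), thin = thin,
                 null_models = null_models,
                 null_replicates = as.integer(null_replicates),
                 scheme = scheme, bc_convention = bc_convention,
                 overlap_method = overlap_method, z_property = z_property,
                 n_predictors = as.integer(n_predictors), out_dir = out_dir),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$scenario)) return(gen_scenario(config$scenario))
  p <- config$paths
  need <- c("species", "edges", "presence", "regions", "habitat", "climate")
  missing_keys <- setdiff(c(need, "n_rows", "n_cols"), names(p))
  if (length(missing_keys))
    stop("run_config paths missing: ", paste(missing_keys, collapse = ", "))
  for (k in need)
    if (!file.exists(p[[k]]))
      stop("input stage '", k, "': file not found: ", p[[k]])
  grid <- read_region_map(p$regions, p$n_rows, p$n_cols)
  web <- read_metaweb(p$species, p$edges)
  list(grid = grid, metaweb = web,
       ranges = read_presence(p$presence, grid,
                              species_ids = web$species$species_id),
       habitat = read_cell_raster(p$habitat, grid, "habitat"),
       climate = read_cell_raster(p$climate, grid, "climate"))
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) synthetic-data generation -> spiral aggregation ->
#' curve building -> per-region power fits -> null models and z-ratios ->
#' environmental summaries -> commonality-guided selection and linear
#' regression of the chosen z-exponents on the environment. Deterministic
#' given the configuration; when `out_dir` is set every table is written
#' as CSV with a provenance header.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress to stderr.
#' @return list with `curves`, `fits`, `level_fits`, `null_curves`,
#'   `null_fits`, `z_ratios`, `env`, `richness`, `commonality`,
#'   `regression`, `selected_predictors`, `inputs`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[narweb] ", ...)
  say("loading inputs")
  inputs <- load_inputs(config)
  grid <- inputs$grid
  regions <- region_names(grid)

  say("building curves for ", length(regions), " region(s)")
  curves <- list(); fits <- list(); level_fits <- list()
  null_curves <- list(); null_fits <- list()
  for (rg in regions) {
    paths <- sample_paths(grid, rg, config$n_replicates,
                          seed = sub_seed(config$seed, match(rg, regions)))
    cv <- build_curves(inputs$metaweb, inputs$ranges, paths,
                       thin = config$thin,
                       overlap_method = config$overlap_method)
    curves[[rg]] <- cv
    fits[[rg]] <- fit_all_properties(cv)
    lf <- lapply(c("basal", "intermediate", "top"), function(lv) {
      f <- tryCatch(per_level_sar(cv, lv), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(region = rg, level = lv, c = f$c, z = f$z,
                 r_squared = f$r_squared)
    })
    level_fits[[rg]] <- do.call(rbind, lf)
    for (model in config$null_models) {
      nk <- min(config$null_replicates, config$n_replicates)
      ncv <- do.call(rbind, lapply(seq_len(nk), function(k) {
        obs <- cv[cv$replicate == k, , drop = FALSE]
        fun <- if (model == "subsampled") null_subsampled_curve
               else null_random_curve
        fun(inputs$metaweb, obs,
            seed = sub_seed(config$seed, 900L + 7L * k + match(rg, regions)))
      }))
      class(ncv) <- c("nar_curve", "data.frame")
      null_curves[[paste(rg, model, sep = ".")]] <- ncv
      nf <- fit_all_properties(ncv)
      nf$model <- model
      null_fits[[paste(rg, model, sep = ".")]] <- nf
    }
  }
  curves <- do.call(rbind, curves)
  fits <- do.call(rbind, fits)
  level_fits <- do.call(rbind, level_fits)
  null_curves <- do.call(rbind, null_curves)
  null_fits <- do.call(rbind, null_fits)
  rownames(curves) <- rownames(fits) <- NULL

  say("null-model z ratios")
  z_ratios <- NULL
  if (!is.null(null_fits))
    z_ratios <- do.call(rbind, lapply(unique(null_fits$model), function(m) {
      zr <- z_ratio_table(null_fits[null_fits$model == m, , drop = FALSE],
                          fits)
      zr$model <- m
      zr
    }))

  say("richness regressions")
  richness <- do.call(rbind, lapply(regions, function(rg) {
    cv <- curves[curves$region == rg, , drop = FALSE]
    do.call(rbind, lapply(c("L", "links_per_species", "gen_mean", "vul_mean",
                            "frac_basal", "consumer_overlap"), function(p) {
      r <- tryCatch(richness_regressions(cv, p), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(region = rg, property = p, scale = r$scale,
                 slope = r$slope, intercept = r$intercept,
                 adj_r_squared = r$adj_r_squared, n = r$n)
    }))
  }))

  say("environmental summaries")
  env <- env_summary(inputs$habitat, inputs$climate, regions,
                     scheme = config$scheme, seed = config$seed)

  say("z-exponent regression")
  zsel <- fits[fits$property == config$z_property, , drop = FALSE]
  env_o <- env[match(zsel$region, env$region), , drop = FALSE]
  predictor_cols <- setdiff(names(env_o),
                            c("region", "area_cells", "n_habitats"))
  keep_col <- vapply(env_o[predictor_cols], function(x)
    stats::var(x) > 0 && all(is.finite(x)), TRUE)
  X <- env_o[, predictor_cols[keep_col], drop = FALSE]
  commonality <- NULL; regression <- NULL; selected <- character(0)
  enough <- nrow(X) > ncol(X) + 1L
  p_max <- max(1L, nrow(X) - 2L)
  if (ncol(X) > p_max) {
    # keep the predictors most correlated with y so the CA model stays
    # estimable on few regions
    ord <- order(abs(vapply(X, function(x) stats::cor(x, zsel$z), 0)),
                 decreasing = TRUE)
    X <- X[, ord[seq_len(p_max)], drop = FALSE]
  }
  if (nrow(X) > ncol(X) + 1L && ncol(X) >= 1L) {
    commonality <- tryCatch(commonality_analysis(X, zsel$z),
                            error = function(e) NULL)
    if (!is.null(commonality)) {
      selected <- select_predictors(X, zsel$z,
                                    n_keep = min(config$n_predictors,
                                                 nrow(X) - 2L))
      if (length(selected))
        regression <- fit_z_regression(X[, selected, drop = FALSE], zsel$z)
    }
  }

  out <- list(curves = curves, fits = fits, level_fits = level_fits,
              null_curves = null_curves, null_fits = null_fits,
              z_ratios = z_ratios, env = env, richness = richness,
              commonality = commonality, regression = regression,
              selected_predictors = selected, inputs = inputs,
              config = config)
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

# Provenance header for every output CSV.
run_comment <- function(config) {
  c(paste0("narweb ", as.character(utils::packageVersion("narweb"))),
    paste0("seed ", config$seed),
    paste0("config_hash ",
           sum(utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                      "out_dir")]),
                               collapse = ""))) %% 1000000L))
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- run_comment(result$config)
  w <- function(x, f) if (!is.null(x))
    write_table(x, file.path(out_dir, f), comment = cm)
  w(result$curves, "curves.csv")
  w(result$fits, "fits.csv")
  w(result$level_fits, "level_fits.csv")
  w(result$null_fits, "null_fits.csv")
  w(result$z_ratios, "z_ratios.csv")
  w(result$env, "env_summary.csv")
  w(result$richness, "richness_regressions.csv")
  if (!is.null(result$commonality))
    w(data.frame(subset = names(result$commonality$coefficients),
                 coefficient = as.numeric(result$commonality$coefficients),
                 subset_r2 = as.numeric(result$commonality$subset_r2)),
      "commonality.csv")
  if (!is.null(result$regression))
    w(result$regression$coefficients, "regression.csv")
  invisible(NULL)
}

#' Write a synthetic scenario as the six input CSV files
#'
#' @param scenario a [scenario_config()].
#' @param out_dir output directory.
#' @return invisibly, the named list of file paths written.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- gen_scenario(scenario)
  paths <- list(species = file.path(out_dir, "species.csv"),
                edges = file.path(out_dir, "edges.csv"),
                presence = file.path(out_dir, "presence.csv"),
                regions = file.path(out_dir, "regions.csv"),
                habitat = file.path(out_dir, "habitat.csv"),
                climate = file.path(out_dir, "climate.csv"),
                n_rows = sc$grid$n_rows, n_cols = sc$grid$n_cols)
  write_metaweb(sc$metaweb, paths$species, paths$edges)
  write_presence(sc$ranges, paths$presence)
  write_region_map(sc$grid, paths$regions)
  write_habitat(sc$habitat, paths$habitat)
  write_climate(sc$climate, paths$climate)
  invisible(paths)
}
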