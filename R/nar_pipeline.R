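#' Build a species/network-area curve along an aggregation path
#'
#' Walks the path's prefixes A = 1, 2, ..., |region|; at each retained A
#' the species set is the union of presences over the first A cells, the
#' local web is induced from the metaweb, and all network properties are
#' computed. The default retains every prefix (cell-by-cell aggregation);
#' `thin` may give a sparser strictly increasing set of A values (the final
#' A is always retained so the regional web is present).
#'
#' @param web a [metaweb()].
#' @param ranges a [range_stack()] on the path's grid.
#' @param path an [spiral_order()] path.
#' @param thin `NULL` (keep all A) or an increasing integer vector of A
#'   values to retain.
#' @param replicate replicate id recorded in the rows.
#' @param ... passed to [compute_metrics()].
#' @return data.frame of class `nar_curve`: columns `region, replicate, A`
#'   plus the [compute_metrics()] columns.
#' @export
build_curve <- function(web, ranges, path, thin = NULL, replicate = 1L, ...) {
  n <- length(path$order)
  keep <- if (is.null(thin)) seq_len(n) else sort(unique(c(thin[thin <= n], n)))
  if (any(keep < 1L)) stop("thin values must be >= 1")
  ids <- rownames(ranges$presence)
  unknown <- setdiff(ids, web$species$species_id)
  if (length(unknown))
    stop("range stack contains species absent from the metaweb: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  idx <- metaweb_index(web)
  sp_of <- match(ids, idx$ids)
  present <- logical(length(idx$ids))  # by pool index
  rows <- vector("list", length(keep))
  ki <- 1L
  for (a in seq_len(n)) {
    newly <- ids[ranges$presence[, path$order[a] + 1L]]
    present[sp_of[match(newly, ids)]] <- TRUE
    if (ki <= length(keep) && a == keep[ki]) {
      sub <- idx$ids[present]
      lk <- present[idx$cons] & present[idx$res]
      lw <- local_web_fast(sub, idx$ids[idx$cons[lk]], idx$ids[idx$res[lk]])
      m <- compute_metrics(lw, ...)
      rows[[ki]] <- cbind(data.frame(region = path$region,
                                     replicate = replicate, A = a), m)
      ki <- ki + 1L
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nar_curve", "data.frame")
  attr(out, "normalized") <- FALSE
  out
}

# local_web() without validation/dedup for pre-validated induced links.
local_web_fast <- function(subset, cons, res) {
  structure(list(species_subset = subset,
                 links = data.frame(consumer_id = cons, resource_id = res,
                                    stringsAsFactors = FALSE)),
            class = "local_web")
}

#' Curves for all replicates of a region
#'
#' @param web a [metaweb()].
#' @param ranges a [range_stack()].
#' @param paths list of paths from [sample_paths()].
#' @param thin,... passed to [build_curve()].
#' @return A single `nar_curve` data.frame with one block per replicate.
#' @export
build_curves <- function(web, ranges, paths, thin = NULL, ...) {
  out <- do.call(rbind, lapply(seq_along(paths), function(k)
    build_curve(web, ranges, paths[[k]], thin = thin, replicate = k, ...)))
  class(out) <- c("nar_curve", "data.frame")
  attr(out, "normalized") <- FALSE
  out
}

#' Fit a power law y = c * A^z by damped least squares
#'
#' Minimises the raw-scale residual sum of squares with a
#' Levenberg-damped Gauss-Newton iteration, started from ordinary least
#' squares on log y vs log A (positive y only). Convergence is declared at
#' a relative loss change below `tol` (default 1e-8) within `max_iter`
#' iterations; on failure the log-log OLS estimate is returned flagged
#' `method = "loglog-fallback"`. R^2 is computed on the raw scale.
#'
#' @param A,y numeric vectors (>= 3 finite points; A >= 1).
#' @param property label stored in the result.
#' @param tol relative loss tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `power_fit`: list with `property, c, z, se_c,
#'   se_z, r_squared, n_points, converged, method`.
#' @export
fit_power <- function(A, y, property = "y", tol = 1e-8, max_iter = 1000L) {
  ok <- is.finite(A) & is.finite(y)
  A <- A[ok]; y <- y[ok]
  if (length(A) < 3L) stop("need >= 3 finite points to fit a power law")
  if (any(A < 1)) stop("A must be >= 1")
  if (all(y <= 0)) stop("all y <= 0: power law unfit")
  pos <- y > 0
  lf <- stats::lm.fit(cbind(1, log(A[pos])), log(y[pos]))
  z <- unname(lf$coefficients[2]); cc <- exp(unname(lf$coefficients[1]))
  sse <- function(p) sum((y - p[1] * A^p[2])^2)
  loss <- sse(c(cc, z))
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Az <- A^z
    r <- y - cc * Az
    # Jacobian of the model wrt (c, z)
    J <- cbind(Az, cc * Az * log(A))
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (tries in 1:30) {
      Hd <- H + lambda * diag(diag(H) + 1e-12, 2)
      delta <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- c(cc + delta[1], z + delta[2])
      new_loss <- sse(cand)
      if (is.finite(new_loss) && new_loss <= loss) {
        step_ok <- TRUE
        rel <- if (loss > 0) (loss - new_loss) / loss else 0
        cc <- cand[1]; z <- cand[2]; loss <- new_loss
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok || rel < tol || loss == 0) { converged <- TRUE; break }
  }
  method <- if (converged) "nls" else "loglog-fallback"
  if (!converged) {  # report the log-log start
    cc <- exp(unname(lf$coefficients[1])); z <- unname(lf$coefficients[2])
  }
  res <- y - cc * A^z
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  se <- c(NA_real_, NA_real_)
  if (length(A) > 2L) {
    Az <- A^z
    J <- cbind(Az, cc * Az * log(A))
    s2 <- sum(res^2) / (length(A) - 2L)
    covm <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }
  structure(list(property = property, c = cc, z = z,
                 se_c = se[1], se_z = se[2], r_squared = r2,
                 n_points = length(A), converged = converged,
                 method = method),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> %s = %.4g * A^%.4g (se_z %.3g, R2 %.3f, %s)\n",
              x$property, x$c, x$z, x$se_z, x$r_squared, x$method))
  invisible(x)
}

#' Region-level power fit of a property across replicates
#'
#' Pools the (A, y) points of all replicate curves into a single fit --
#' fitting one power function to the relationship obtained across
#' replicates. `mode = "per_replicate"` instead fits each replicate and
#' averages c and z (sensitivity mode).
#'
#' @param curves an `nar_curve` data.frame (one or more replicates).
#' @param property a metric column name.
#' @param mode `"pooled"` (default) or `"per_replicate"`.
#' @param ... passed to [fit_power()].
#' @return A `power_fit`.
#' @export
fit_region <- function(curves, property, mode = c("pooled", "per_replicate"),
                       ...) {
  mode <- match.arg(mode)
  if (!property %in% names(curves))
    stop("property ", property, " not found in curves")
  if (mode == "pooled")
    return(fit_power(curves$A, curves[[property]], property = property, ...))
  reps <- split(curves, curves$replicate)
  fits <- lapply(reps, function(cv)
    fit_power(cv$A, cv[[property]], property = property, ...))
  f <- fits[[1]]
  f$c <- mean(vapply(fits, `[[`, 0, "c"))
  f$z <- mean(vapply(fits, `[[`, 0, "z"))
  f$se_c <- stats::sd(vapply(fits, `[[`, 0, "c")) / sqrt(length(fits))
  f$se_z <- stats::sd(vapply(fits, `[[`, 0, "z")) / sqrt(length(fits))
  f$r_squared <- mean(vapply(fits, `[[`, 0, "r_squared"))
  f$n_points <- sum(vapply(fits, `[[`, 0L, "n_points"))
  f$method <- "per-replicate-mean"
  f
}

#' Species-area fit for one trophic level
#'
#' Fits the power law of the per-level species count (basal, intermediate
#' or top) against area, pooling replicates. Level counts at each A sum to
#' S, so these SARs decompose the total SAR.
#'
#' @param curves an `nar_curve` data.frame with `n_basal`/`n_intermediate`/
#'   `n_top` columns.
#' @param level `"basal"`, `"intermediate"` or `"top"`.
#' @param ... passed to [fit_power()].
#' @return A `power_fit`.
#' @export
per_level_sar <- function(curves, level = c("basal", "intermediate", "top"),
                          ...) {
  level <- match.arg(level)
  col <- paste0("n_", level)
  y <- curves[[col]]
  if (all(!is.finite(y)) || all(y == 0, na.rm = TRUE))
    stop("trophic level '", level, "' is never populated in these curves")
  fit_power(curves$A, y, property = paste0("S_", level), ...)
}

#' Normalise extensive curve properties by species richness
#'
#' Divides L, links_per_species, gen_mean, gen_sd, vul_mean and vul_sd by S
#' at the same A. Scale-invariant checks use these normalised properties:
#' if richness alone drives a NAR, the normalised property is flat in A.
#' A `normalized` attribute guards against double application.
#'
#' @param curve an `nar_curve` data.frame.
#' @return the normalised `nar_curve`.
#' @export
normalize_curve <- function(curve) {
  if (isTRUE(attr(curve, "normalized")))
    stop("curve is already normalised")
  ext <- c("L", "links_per_species", "gen_mean", "gen_sd", "vul_mean",
           "vul_sd")
  keep <- curve$S > 0
  for (col in ext) curve[[col]] <- ifelse(keep, curve[[col]] / curve$S, NA)
  attr(curve, "normalized") <- TRUE
  curve
}

#' Regression of a network property on species richness
#'
#' Complexity properties (L, links_per_species, generality/vulnerability
#' statistics) are regressed in log-log space (OLS of log y on log S over
#' positive points); proportions and overlap on the raw scale. Reports the
#' slope, intercept and adjusted R^2.
#'
#' @param curves an `nar_curve` data.frame.
#' @param property metric column name.
#' @param scale `"auto"`, `"loglog"` or `"raw"`.
#' @return list with `property, scale, slope, intercept, adj_r_squared, n`.
#' @export
richness_regressions <- function(curves, property,
                                 scale = c("auto", "loglog", "raw")) {
  scale <- match.arg(scale)
  if (!property %in% names(curves)) stop("unknown property ", property)
  if (scale == "auto") {
    raw_props <- c("frac_basal", "frac_intermediate", "frac_top",
                   "consumer_overlap", "modularity")
    scale <- if (property %in% raw_props) "raw" else "loglog"
  }
  S <- curves$S; y <- curves[[property]]
  ok <- is.finite(S) & is.finite(y) & S > 0
  if (scale == "loglog") ok <- ok & y > 0
  S <- S[ok]; y <- y[ok]
  if (length(unique(S)) < 3L) stop("need >= 3 distinct S values")
  if (stats::var(S) == 0) stop("zero variance in S")
  if (scale == "loglog") { xs <- log(S); ys <- log(y) } else { xs <- S; ys <- y }
  fit <- stats::lm(ys ~ xs)
  sm <- summary(fit)
  list(property = property, scale = scale,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = sm$adj.r.squared, n = length(xs))
}

#' Power fits for every standard property of a region's curves
#'
#' @param curves an `nar_curve` data.frame for one region.
#' @param properties metric columns to fit (default: the complexity
#'   metrics plus richness).
#' @param ... passed to [fit_region()].
#' @return data.frame with one row per property: `region, property, c, z,
#'   se_z, r_squared, n_points, method`.
#' @export
fit_all_properties <- function(curves,
                               properties = c("S", "L", "links_per_species",
                                              "gen_mean", "gen_sd",
                                              "vul_mean", "vul_sd"),
                               ...) {
  region <- unique(curves$region)[1]
  rows <- lapply(properties, function(p) {
    f <- tryCatch(fit_region(curves, p, ...), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(region = region, property = p, c = f$c, z = f$z,
               se_z = f$se_z, r_squared = f$r_squared,
               n_points = f$n_points, method = f$method)
  })
  do.call(rbind, rows)
}
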