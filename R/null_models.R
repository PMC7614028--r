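#' Richness-matched metaweb-subsampled null curve (null model-1)
#'
#' Rebuilds a curve with the observed cumulative species richness S(A) but
#' random species identities: at each step, `S_t - S_{t-1}` new species are
#' drawn uniformly without replacement from the remaining pool (nested
#' sets), and the links among the selected species are taken from the
#' metaweb. This preserves the metaweb's inherited structure while
#' destroying the spatial identity of assemblages.
#'
#' @param web a [metaweb()].
#' @param observed an `nar_curve` data.frame for a single replicate, with
#'   non-decreasing `S`.
#' @param seed integer seed.
#' @param nested draw nested species sets (default); `FALSE` re-draws the
#'   whole set independently at each step.
#' @param ... passed to [compute_metrics()].
#' @return data.frame of class `nar_curve` with a `model = "subsampled"`
#'   column; at every A its S equals the observed S.
#' @export
null_subsampled_curve <- function(web, observed, seed = 1L, nested = TRUE,
                                  ...) {
  S_t <- observed$S
  if (any(diff(S_t) < 0)) stop("observed S must be non-decreasing")
  pool <- web$species$species_id
  if (max(S_t) > length(pool)) stop("observed S exceeds metaweb pool size")
  set.seed(sub_seed(seed, 601L))
  idx <- metaweb_index(web)
  selected <- character(0)
  remaining <- pool
  rows <- vector("list", length(S_t))
  for (t in seq_along(S_t)) {
    if (nested) {
      need <- S_t[t] - length(selected)
      if (need > 0L) {
        draw <- remaining[sample.int(length(remaining), need)]
        selected <- c(selected, draw)
        remaining <- setdiff(remaining, draw)
      }
    } else {
      selected <- pool[sample.int(length(pool), S_t[t])]
    }
    present <- idx$ids %in% selected
    lk <- present[idx$cons] & present[idx$res]
    lw <- local_web_fast(selected, idx$ids[idx$cons[lk]],
                         idx$ids[idx$res[lk]])
    m <- compute_metrics(lw, ...)
    rows[[t]] <- cbind(data.frame(region = observed$region[t],
                                  replicate = observed$replicate[t],
                                  model = "subsampled", A = observed$A[t]), m)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nar_curve", "data.frame")
  out
}

#' Richness- and link-matched random-network null curve (null model-2)
#'
#' Like [null_subsampled_curve()] for the species sets, but at each step
#' the observed number of links L_t is distributed uniformly at random over
#' ordered pairs of distinct selected species (no self-links, no duplicate
#' links), destroying every structural signal inherited from the metaweb.
#'
#' @inheritParams null_subsampled_curve
#' @return data.frame of class `nar_curve` with `model = "random"`; at
#'   every A its S and L equal the observed ones.
#' @export
null_random_curve <- function(web, observed, seed = 1L, nested = TRUE, ...) {
  S_t <- observed$S; L_t <- observed$L
  if (any(diff(S_t) < 0)) stop("observed S must be non-decreasing")
  cap <- as.double(S_t) * (S_t - 1)
  if (any(L_t > cap))
    stop("observed L exceeds S(S-1) capacity at step ", which(L_t > cap)[1])
  pool <- web$species$species_id
  if (max(S_t) > length(pool)) stop("observed S exceeds metaweb pool size")
  set.seed(sub_seed(seed, 701L))
  selected <- character(0)
  remaining <- pool
  rows <- vector("list", length(S_t))
  for (t in seq_along(S_t)) {
    if (nested) {
      need <- S_t[t] - length(selected)
      if (need > 0L) {
        draw <- remaining[sample.int(length(remaining), need)]
        selected <- c(selected, draw)
        remaining <- setdiff(remaining, draw)
      }
    } else {
      selected <- pool[sample.int(length(pool), S_t[t])]
    }
    S <- length(selected)
    if (L_t[t] > 0L && S >= 2L) {
      # ordered pairs of distinct species, enumerated 1..S(S-1)
      pick <- sample.int(S * (S - 1L), L_t[t])
      ci <- (pick - 1L) %/% (S - 1L) + 1L
      rj <- (pick - 1L) %% (S - 1L) + 1L
      rj <- ifelse(rj >= ci, rj + 1L, rj)  # skip the diagonal
      lw <- local_web_fast(selected, selected[ci], selected[rj])
    } else {
      lw <- local_web_fast(selected, character(0), character(0))
    }
    m <- compute_metrics(lw, ...)
    rows[[t]] <- cbind(data.frame(region = observed$region[t],
                                  replicate = observed$replicate[t],
                                  model = "random", A = observed$A[t]), m)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nar_curve", "data.frame")
  out
}

#' Ratios of null to observed scaling exponents
#'
#' Joins two fit tables on `(region, property)` and reports
#' `z_null / z_observed`; a ratio near 1 means the null model reproduces
#' the observed scaling. Keys present in only one table are listed with a
#' diagnostic instead of being dropped.
#'
#' @param null_fits,observed_fits data.frames as produced by
#'   [fit_all_properties()] (columns `region, property, z`).
#' @return data.frame with columns `region, property, z_null, z_observed,
#'   ratio, note`.
#' @export
z_ratio_table <- function(null_fits, observed_fits) {
  key <- function(d) paste(d$region, d$property, sep = "\r")
  kn <- key(null_fits); ko <- key(observed_fits)
  all_keys <- union(kn, ko)
  rows <- lapply(all_keys, function(k) {
    i <- match(k, kn); j <- match(k, ko)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    zn <- if (!is.na(i)) null_fits$z[i] else NA_real_
    zo <- if (!is.na(j)) observed_fits$z[j] else NA_real_
    note <- if (is.na(i)) "missing in null fits"
            else if (is.na(j)) "missing in observed fits"
            else if (zo == 0) "z_observed = 0"
            else ""
    data.frame(region = parts[1], property = parts[2], z_null = zn,
               z_observed = zo,
               ratio = if (nzchar(note)) NA_real_ else zn / zo,
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
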