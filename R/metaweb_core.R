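#' Local food web: a species subset with its realised links
#'
#' @param species_subset character vector of species ids.
#' @param links data.frame with columns `consumer_id`, `resource_id`, both
#'   endpoints within `species_subset`; self-links are dropped.
#' @return An object of class `local_web`.
#' @export
local_web <- function(species_subset, links) {
  species_subset <- unique(as.character(species_subset))
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links)) {
    links$consumer_id <- as.character(links$consumer_id)
    links$resource_id <- as.character(links$resource_id)
    if (!all(links$consumer_id %in% species_subset) ||
        !all(links$resource_id %in% species_subset))
      stop("link endpoint outside species subset")
    links <- links[links$consumer_id != links$resource_id, , drop = FALSE]
    links <- links[!duplicated(paste(links$consumer_id, links$resource_id,
                                     sep = "\r")), , drop = FALSE]
  } else {
    links <- data.frame(consumer_id = character(), resource_id = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(links) <- NULL
  structure(list(species_subset = species_subset, links = links),
            class = "local_web")
}

#' @export
print.local_web <- function(x, ...) {
  cat(sprintf("<local_web> S = %d, L = %d\n",
              length(x$species_subset), nrow(x$links)))
  invisible(x)
}

# Integer-indexed view of the metaweb for fast repeated induction.
# cons/res are 1-based indices into ids; self-links already removed.
metaweb_index <- function(web) {
  ids <- web$species$species_id
  cons <- match(web$links$consumer_id, ids)
  res <- match(web$links$resource_id, ids)
  keep <- cons != res
  list(ids = ids, cons = cons[keep], res = res[keep])
}

#' Induce the local web on a species subset
#'
#' The local web on a set of co-occurring species has exactly the metaweb
#' links whose consumer and resource both belong to the subset;
#' self-links (cannibalism) are dropped.
#'
#' @param web a [metaweb()].
#' @param subset character vector of species ids (must all be pool members).
#' @return A [local_web()].
#' @export
induced_web <- function(web, subset) {
  subset <- unique(as.character(subset))
  unknown <- setdiff(subset, web$species$species_id)
  if (length(unknown))
    stop("unknown species in subset: ", paste(unknown, collapse = ", "))
  keep <- web$links$consumer_id %in% subset & web$links$resource_id %in% subset
  local_web(subset, web$links[keep, , drop = FALSE])
}

#' Classify species as basal, intermediate or top
#'
#' Within the local web, basal species have no prey; top species have prey
#' but no predators; intermediate species have both. Species with neither
#' prey nor predators count as basal: their out-of-web resources
#' (invertebrates, plants, carrion, fish) are assumed ubiquitous. With
#' `basal = "inherited"` a species is basal locally iff it is basal in the
#' supplied metaweb, freezing pool-level status.
#'
#' @param web a [local_web()].
#' @param basal `"topological"` (default) or `"inherited"`.
#' @param pool the [metaweb()], required for `basal = "inherited"`.
#' @return list with character vectors `basal`, `intermediate`, `top`
#'   forming a partition of the species subset.
#' @export
trophic_classes <- function(web, basal = c("topological", "inherited"),
                            pool = NULL) {
  basal <- match.arg(basal)
  sp <- web$species_subset
  if (!length(sp)) stop("empty web")
  has_prey <- sp %in% web$links$consumer_id
  has_pred <- sp %in% web$links$resource_id
  if (basal == "inherited") {
    if (is.null(pool)) stop("pool metaweb required for basal = 'inherited'")
    pool_basal <- setdiff(pool$species$species_id, pool$links$consumer_id)
    is_basal <- sp %in% pool_basal
  } else {
    is_basal <- !has_prey
  }
  list(basal = sp[is_basal],
       top = sp[!is_basal & has_prey & !has_pred],
       intermediate = sp[!is_basal & !(has_prey & !has_pred)])
}

#' Generality and vulnerability statistics
#'
#' Generality is a consumer's number of prey, vulnerability a resource's
#' number of predators. Means and sample SDs (n - 1) are taken over species
#' with at least one such link; a single-member SD is reported as 0, and a
#' statistic with an empty base set as `NA`.
#'
#' @param web a [local_web()].
#' @return named numeric vector `gen_mean, gen_sd, vul_mean, vul_sd`.
#' @export
degree_stats <- function(web) {
  if (!nrow(web$links))
    return(c(gen_mean = NA_real_, gen_sd = NA_real_,
             vul_mean = NA_real_, vul_sd = NA_real_))
  gen <- tabulate(factor(web$links$consumer_id))
  vul <- tabulate(factor(web$links$resource_id))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  c(gen_mean = mean(gen), gen_sd = sd0(gen),
    vul_mean = mean(vul), vul_sd = sd0(vul))
}

#' Consumers' diet overlap
#'
#' Default (`"shared_links"`): the fraction of predatory links whose prey is
#' consumed by at least two distinct consumers in the web. Alternative
#' (`"jaccard"`): the mean pairwise Jaccard similarity of consumers' diets.
#'
#' @param web a [local_web()].
#' @param method `"shared_links"` or `"jaccard"`.
#' @return proportion in `[0, 1]`, or `NA` for a linkless web.
#' @export
consumer_overlap <- function(web, method = c("shared_links", "jaccard")) {
  method <- match.arg(method)
  L <- nrow(web$links)
  if (!L) return(NA_real_)
  if (method == "shared_links") {
    ncons <- table(web$links$resource_id)
    shared <- ncons[web$links$resource_id] >= 2L
    return(sum(shared) / L)
  }
  cons <- unique(web$links$consumer_id)
  if (length(cons) < 2L) return(0)
  diets <- split(web$links$resource_id, web$links$consumer_id)
  tot <- 0; np <- 0
  for (i in seq_along(diets)[-length(diets)])
    for (j in seq((i + 1L), length(diets))) {
      inter <- length(intersect(diets[[i]], diets[[j]]))
      uni <- length(union(diets[[i]], diets[[j]]))
      tot <- tot + inter / uni
      np <- np + 1L
    }
  tot / np
}

#' Directed modularity via igraph community detection (optional plug-in)
#'
#' Not equivalent to any particular published food-web modularity score;
#' provided only as a default for the pluggable `modularity_fn` slot of
#' [compute_metrics()]. Uses igraph's walktrap communities on the directed
#' graph and the standard modularity of the resulting membership.
#'
#' @param web a [local_web()].
#' @return modularity score, or `NA` when igraph is unavailable or the web
#'   has no links.
#' @export
modularity_igraph <- function(web) {
  if (!requireNamespace("igraph", quietly = TRUE)) return(NA_real_)
  if (!nrow(web$links)) return(NA_real_)
  g <- igraph::graph_from_data_frame(web$links, directed = TRUE,
                                     vertices = web$species_subset)
  cl <- igraph::cluster_walktrap(g)
  igraph::modularity(g, igraph::membership(cl))
}

#' All network properties of a local web
#'
#' @param web a [local_web()].
#' @param overlap_method passed to [consumer_overlap()].
#' @param basal,pool passed to [trophic_classes()].
#' @param modularity_fn optional `function(web) -> numeric`; modularity is
#'   `NA` unless supplied (see [modularity_igraph()]).
#' @return one-row data.frame with columns `S, L, links_per_species,
#'   gen_mean, gen_sd, vul_mean, vul_sd, frac_basal, frac_intermediate,
#'   frac_top, consumer_overlap, modularity` plus the trophic-level counts
#'   `n_basal, n_intermediate, n_top`.
#' @export
compute_metrics <- function(web, overlap_method = "shared_links",
                            basal = "topological", pool = NULL,
                            modularity_fn = NULL) {
  S <- length(web$species_subset)
  if (S == 0L)
    return(data.frame(S = 0L, L = 0L, links_per_species = NA_real_,
                      gen_mean = NA_real_, gen_sd = NA_real_,
                      vul_mean = NA_real_, vul_sd = NA_real_,
                      frac_basal = NA_real_, frac_intermediate = NA_real_,
                      frac_top = NA_real_, consumer_overlap = NA_real_,
                      modularity = NA_real_, n_basal = 0L,
                      n_intermediate = 0L, n_top = 0L))
  L <- nrow(web$links)
  tc <- trophic_classes(web, basal = basal, pool = pool)
  ds <- degree_stats(web)
  data.frame(S = S, L = L, links_per_species = L / S,
             gen_mean = ds[["gen_mean"]], gen_sd = ds[["gen_sd"]],
             vul_mean = ds[["vul_mean"]], vul_sd = ds[["vul_sd"]],
             frac_basal = length(tc$basal) / S,
             frac_intermediate = length(tc$intermediate) / S,
             frac_top = length(tc$top) / S,
             consumer_overlap = consumer_overlap(web, overlap_method),
             modularity = if (is.null(modularity_fn)) NA_real_
                          else modularity_fn(web),
             n_basal = length(tc$basal),
             n_intermediate = length(tc$intermediate),
             n_top = length(tc$top))
}

metric_columns <- function() {
  c("S", "L", "links_per_species", "gen_mean", "gen_sd", "vul_mean",
    "vul_sd", "frac_basal", "frac_intermediate", "frac_top",
    "consumer_overlap", "modularity")
}
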