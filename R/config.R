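#' Synthetic inventory configuration
#'
#' Bundles the parameters of the synthetic NFI generator.  Defaults emulate
#' the study conditions of a country-scale inventory of woody species:
#' about a thousand cluster plots of three subplots each, ~90 species on an
#' ultrametric phylogeny, per-plot species richness around 5 (sd ~2) and
#' mean basal area around 30 m²/ha, with assemblages arranged along an
#' elevation gradient and species pools concentrated on clades.
#'
#' @param n_species number of species on the phylogeny.
#' @param n_clusters number of cluster plots (3 subplots each).
#' @param n_assemblages number of true assemblage pools (>= 2).
#' @param elevation_range length-2 numeric, min/max elevation (m asl).
#' @param niche_width sd (m) of the Gaussian elevation niche of each
#'   assemblage; default 150 m keeps the four default niches disjoint.
#' @param richness_mean,richness_sd per-plot species richness distribution
#'   (rounded normal, clipped to [1, 12]).
#' @param ba_mean target mean basal area per plot (m²/ha).
#' @param ba_cv coefficient of variation of the per-plot BA target.
#' @param dbh_meanlog,dbh_sdlog lognormal DBH parameters (cm scale),
#'   truncated at the 8 cm census threshold.
#' @param phylo_signal probability in [0,1] that a pool member is drawn
#'   from the focal clade rather than uniformly from all species.
#' @param dead_fraction,slopover_fraction,genus_only_fraction noise
#'   fractions exercising the inventory filters (defaults 5% each).
#' @param gps_error_m constant recorded GPS error per plot.
#' @param seed integer seed of the single random stream of a run.
#' @return a validated list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(n_species = 90L, n_clusters = 1000L,
                            n_assemblages = 4L,
                            elevation_range = c(50, 2550),
                            niche_width = 150,
                            richness_mean = 4.96, richness_sd = 2.14,
                            ba_mean = 30.4, ba_cv = 0.42,
                            dbh_meanlog = log(18), dbh_sdlog = 0.45,
                            phylo_signal = 1.0,
                            dead_fraction = 0.05, slopover_fraction = 0.05,
                            genus_only_fraction = 0.05,
                            gps_error_m = 5, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_clusters = as.integer(n_clusters),
              n_assemblages = as.integer(n_assemblages),
              elevation_range = as.numeric(elevation_range),
              niche_width = as.numeric(niche_width),
              richness_mean = richness_mean, richness_sd = richness_sd,
              ba_mean = ba_mean, ba_cv = ba_cv,
              dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
              phylo_signal = phylo_signal,
              dead_fraction = dead_fraction,
              slopover_fraction = slopover_fraction,
              genus_only_fraction = genus_only_fraction,
              gps_error_m = gps_error_m, seed = as.integer(seed))
  stopifnot(cfg$n_assemblages >= 2L,
            cfg$n_species >= cfg$n_assemblages,
            cfg$niche_width > 0,
            length(cfg$elevation_range) == 2L,
            diff(cfg$elevation_range) > 0,
            cfg$phylo_signal >= 0, cfg$phylo_signal <= 1,
            cfg$dead_fraction >= 0, cfg$slopover_fraction >= 0,
            cfg$genus_only_fraction >= 0)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Cluster-plot filter configuration
#'
#' Controls which cluster plots enter the analysis.  Defaults reproduce the
#' sample definition of a forest NFI: forest land use only, no slopover
#' subplots (subplots intersecting a forest boundary), exactly three
#' non-empty subplots, and every record identified at species level.
#'
#' @param allowed_landuse land-use classes retained.
#' @param required_subplots number of non-empty subplots a cluster must
#'   have (exactly).
#' @param species_level_only drop clusters containing genus-level or
#'   otherwise ambiguous taxa.
#' @param exclude_slopover drop clusters with any slopover subplot.
#' @param exclude_empty_subplots require all \code{required_subplots}
#'   subplots to contain woody species observations.
#' @param non_species_pattern regex identifying non-species labels
#'   (e.g. "Deciduous spp.", bare genus names).
#' @param synonyms optional named character vector mapping recorded names
#'   to accepted names, applied before any other check.
#' @return a validated list of class "FilterConfig".
#' @export
filterConfig <- function(allowed_landuse = c("Forest"),
                         required_subplots = 3L,
                         species_level_only = TRUE,
                         exclude_slopover = TRUE,
                         exclude_empty_subplots = TRUE,
                         non_species_pattern = "(\\bspp?\\.($|\\s))|(^\\S+$)",
                         synonyms = NULL) {
  stopifnot(required_subplots >= 1L)
  if (!is.null(synonyms) && is.null(names(synonyms)))
    stop("'synonyms' must be a named character vector")
  cfg <- list(allowed_landuse = allowed_landuse,
              required_subplots = as.integer(required_subplots),
              species_level_only = isTRUE(species_level_only),
              exclude_slopover = isTRUE(exclude_slopover),
              exclude_empty_subplots = isTRUE(exclude_empty_subplots),
              non_species_pattern = non_species_pattern,
              synonyms = synonyms)
  class(cfg) <- "FilterConfig"
  cfg
}

#' Isopam-style clustering parameters
#'
#' Search ranges and stopping rules of the divisive clustering.  The
#' candidate grids default to odd neighbourhood sizes 3..min(30, n-1),
#' 2..min(10, n-2) ordination axes and 2..6 children per split; splits must
#' leave every child with at least \code{min_cluster_size} samples and
#' produce at least one indicator species significant at
#' \code{alpha_indicator} to be accepted.
#'
#' @param max_levels maximum hierarchy depth (default 4).
#' @param candidate_k_neighbors integer vector of kNN sizes, or NULL for
#'   the default grid (resolved against n at run time).
#' @param candidate_axes integer vector of ordination axes, or NULL.
#' @param candidate_children integer vector of split arities.
#' @param min_cluster_size smallest admissible cluster (>= 2).
#' @param alpha_indicator Fisher significance level qualifying a species
#'   as indicator during split scoring.
#' @param seed integer seed (the search itself is deterministic; the seed
#'   is recorded for provenance).
#' @return a validated list of class "IsopamParams".
#' @export
isopamParams <- function(max_levels = 4L,
                         candidate_k_neighbors = NULL,
                         candidate_axes = NULL,
                         candidate_children = 2:6,
                         min_cluster_size = 3L,
                         alpha_indicator = 0.05,
                         seed = 1L) {
  stopifnot(max_levels >= 1L, min_cluster_size >= 2L,
            alpha_indicator > 0, alpha_indicator <= 1,
            all(candidate_children >= 2L))
  p <- list(max_levels = as.integer(max_levels),
            candidate_k_neighbors = candidate_k_neighbors,
            candidate_axes = candidate_axes,
            candidate_children = as.integer(candidate_children),
            min_cluster_size = as.integer(min_cluster_size),
            alpha_indicator = alpha_indicator,
            seed = as.integer(seed))
  class(p) <- "IsopamParams"
  p
}

# Resolve the default candidate grids for a node of n samples.
.resolve_grid <- function(params, n) {
  k <- params$candidate_k_neighbors
  if (is.null(k)) {
    kmax <- min(30L, n - 1L)
    k <- seq(3L, max(3L, kmax), by = 2L)
  }
  k <- k[k >= 2L & k < n]
  ax <- params$candidate_axes
  if (is.null(ax)) ax <- seq(2L, max(2L, min(10L, n - 2L)))
  ax <- ax[ax >= 1L & ax < n]
  ch <- params$candidate_children
  ch <- ch[ch >= 2L & ch < n & ch * params$min_cluster_size <= n]
  list(k = as.integer(k), axes = as.integer(ax), children = as.integer(ch))
}
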