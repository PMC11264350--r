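#' Validate pipeline inputs
#'
#' Schema and consistency checks on the stem table, phylogeny and
#' elevation raster, before any computation.  Findings are split into
#' fatal problems (malformed schema, DBH below the census threshold,
#' non-positive DBH) and non-fatal notes (species absent from the tree,
#' clusters outside the raster, genus-level labels; all of which the
#' filters or the matching step handle explicitly).
#'
#' @param stems stem record data.frame.
#' @param tree an [ape::phylo] phylogeny, or NULL.
#' @param raster elevation raster list, or NULL.
#' @return list(fatal, notes), character vectors of findings.
#' @export
validateInputs <- function(stems, tree = NULL, raster = NULL) {
  fatal <- character(); notes <- character()
  miss <- setdiff(.stem_columns, names(stems))
  if (length(miss)) {
    fatal <- c(fatal, paste("missing stem columns:",
                            paste(miss, collapse = ", ")))
    return(list(fatal = fatal, notes = notes))
  }
  if (any(!is.finite(stems$dbh_cm) | stems$dbh_cm < 8))
    fatal <- c(fatal, "stems with DBH below the 8 cm census threshold")
  if (!all(stems$subplot_id %in% 1:3))
    fatal <- c(fatal, "subplot_id outside {1,2,3}")
  if (!all(stems$status %in% c("living", "dead")))
    fatal <- c(fatal, "status values other than living/dead")
  genus_only <- grepl("\\bspp?\\.($|\\s)", stems$species)
  if (any(genus_only))
    notes <- c(notes, paste0(sum(genus_only),
                             " records with genus-level labels (clusters ",
                             "will be dropped by the filter)"))
  if (!is.null(tree)) {
    sp <- unique(unname(consolidateInfraspecific(
      stems$species[!genus_only])))
    unmatched <- setdiff(sp, gsub("_", " ", tree$tip.label))
    if (length(unmatched))
      notes <- c(notes, paste("species not on the tree:",
                              paste(unmatched, collapse = ", ")))
  }
  if (!is.null(raster) && all(c("x", "y") %in% names(stems))) {
    xmax <- raster$xll + raster$ncols * raster$cellsize
    ymax <- raster$yll + raster$nrows * raster$cellsize
    out <- stems$x < raster$xll | stems$x > xmax |
           stems$y < raster$yll | stems$y > ymax
    if (any(out))
      notes <- c(notes, paste0(length(unique(stems$cluster_id[out])),
                               " clusters outside the raster extent"))
  }
  list(fatal = fatal, notes = notes)
}

# median elevation of each cluster's southwestern subplot
.cluster_elevations <- function(stems, raster, radius_m = 15) {
  ids <- unique(stems$cluster_id)
  vapply(ids, function(id) {
    cl <- stems[stems$cluster_id == id, , drop = FALSE]
    sw <- which.min(cl$x + cl$y)
    sampleElevation(raster, c(cl$x[sw], cl$y[sw]), radius_m,
                    cl$gps_error_m[sw])
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(as.character(ids))
}

#' Run the full discrimination pipeline
#'
#' End-to-end orchestration: synthetic generation (or ingestion of stem
#' table, Newick phylogeny and elevation raster), cluster-plot filtering,
#' community-matrix construction, phylogeny matching and normalized
#' cophenetic distances, Bray-Curtis and Discriminating Avalanche
#' dissimilarities, one isopam-style hierarchy per index, indicator
#' tables, and the evaluation report.  Deterministic given the seed; all
#' artifacts are regenerated from the configuration alone.
#'
#' @param synthetic a [syntheticConfig()], or NULL to supply real inputs.
#' @param stems stem data.frame or CSV path (ignored if synthetic).
#' @param tree [ape::phylo], Newick path or string (ignored if
#'   synthetic).
#' @param raster raster list or ESRI-ASCII path; NULL skips elevations.
#' @param filter a [filterConfig()].
#' @param isopam an [isopamParams()].
#' @param da_norm dA normalization mode.
#' @param drop_unmatched drop species absent from the tree instead of
#'   stopping.
#' @param n_perm Mantel permutations.
#' @param out_dir optional directory for all written artifacts.
#' @param seed seed for the stochastic stages (Mantel permutations; the
#'   synthetic config carries its own seed).
#' @return list with community, species distances, both dissimilarity
#'   matrices, both hierarchies, both indicator tables, the evaluation
#'   report, the rejection log and a provenance record.
#' @export
runPipeline <- function(synthetic = NULL, stems = NULL, tree = NULL,
                        raster = NULL, filter = filterConfig(),
                        isopam = isopamParams(), da_norm = "theoretical",
                        drop_unmatched = FALSE, n_perm = 999,
                        out_dir = NULL, seed = 1L) {
  truth <- NULL
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "SyntheticConfig"))
    bundle <- generateSyntheticNFI(synthetic)
    stems <- bundle$stems; tree <- bundle$tree; raster <- bundle$raster
    truth <- bundle$truth
  } else {
    if (is.null(stems) || is.null(tree))
      stop("config error: need either a synthetic config or stems + tree")
    if (is.character(stems)) stems <- readStemTable(stems)
    if (is.character(tree))
      tree <- if (file.exists(tree)) readNewickTree(file = tree)
              else readNewickTree(text = tree)
    if (is.character(raster)) raster <- readAsciiRaster(raster)
  }
  chk <- validateInputs(stems, tree, raster)
  if (length(chk$fatal))
    stop("input validation [ingest]: ", paste(chk$fatal, collapse = "; "))
  flt <- filterClusters(stems, filter)
  elev <- NULL
  if (!is.null(raster) && all(c("x", "y", "gps_error_m") %in% names(stems)))
    elev <- .cluster_elevations(flt$stems, raster)
  sd_df <- if (!is.null(elev))
    data.frame(elevation_m = unname(elev), row.names = names(elev))
  community <- buildCommunityMatrix(flt$stems, sample_data = sd_df)
  mp <- matchPhylogeny(community, tree, drop_unmatched = drop_unmatched)
  d_bc <- pairwiseDissimilarity(mp$community, "BC")
  d_da <- pairwiseDissimilarity(mp$community, "dA", sdist = mp$dist,
                                da_norm = da_norm)
  h_bc <- buildHierarchy(d_bc, mp$community, isopam)
  h_da <- buildHierarchy(d_da, mp$community, isopam)
  L <- isopam$max_levels
  it_bc <- isotab(h_bc, L, mp$community)
  it_da <- isotab(h_da, L, mp$community)
  elev_vec <- if (!is.null(elev)) elev[rownames(baMatrix(mp$community))]
  report <- evaluateClustering(d_bc, d_da, h_bc, h_da,
                               elevation = elev_vec, n_perm = n_perm,
                               seed = seed)
  provenance <- list(
    package_version = as.character(utils::packageVersion("avalanche")),
    seed = seed,
    n_clusters_input = length(unique(stems$cluster_id)),
    n_clusters_retained = nrow(baMatrix(mp$community)),
    n_rejected = nrow(flt$rejections),
    rejection_reasons = as.list(table(flt$rejections$reason)),
    n_species = ncol(baMatrix(mp$community)),
    dropped_species = mp$dropped_species,
    da_norm = da_norm)
  result <- list(community = mp$community, species_dist = mp$dist,
                 d_bc = d_bc, d_da = d_da, h_bc = h_bc, h_da = h_da,
                 isotab_bc = it_bc, isotab_da = it_da, report = report,
                 rejections = flt$rejections, truth = truth,
                 elevation = elev_vec, provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeCommunityMatrix(mp$community, file.path(out_dir, "community.csv"))
    writeSpeciesDist(mp$dist, file.path(out_dir, "species_dist.csv"))
    writeDissimilarity(d_bc, file.path(out_dir, "dissim_bc.csv"))
    writeDissimilarity(d_da, file.path(out_dir, "dissim_da.csv"))
    writeHierarchy(h_bc, file.path(out_dir, "hierarchy_bc"))
    writeHierarchy(h_da, file.path(out_dir, "hierarchy_da"))
    writeIndicatorTable(it_bc, file.path(out_dir, "indicators_bc.csv"))
    writeIndicatorTable(it_da, file.path(out_dir, "indicators_da.csv"))
    utils::write.table(flt$rejections, file.path(out_dir, "rejections.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeReport(report, file.path(out_dir, "report.json"))
    writeLines(reportSummary(report), file.path(out_dir, "report.txt"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
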