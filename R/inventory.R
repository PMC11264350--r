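#' Basal area of a single stem
#'
#' Cross-sectional area at breast height from the diameter, in m²:
#' pi * (dbh / 200)^2.
#'
#' @param dbh_cm diameter at breast height in cm (> 0); vectorized.
#' @return basal area in m².
#' @examples
#' stemBasalArea(30)  # 0.0707 m²
#' @export
stemBasalArea <- function(dbh_cm) {
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0))
    stop("dbh_cm must be positive and finite")
  pi * (dbh_cm / 200)^2
}

#' Per-hectare expansion factor of a stem on a nested concentric plot
#'
#' Stems are recorded on one of three concentric circles according to DBH:
#' radius 15 m for DBH >= 30 cm, 10 m for DBH >= 15 cm, and 5 m for
#' DBH >= 8 cm (the census threshold).  Each stem then represents
#' 10000 / (pi r²) stems per hectare.
#'
#' @param dbh_cm diameter at breast height in cm (>= 8); vectorized.
#' @return stems-per-hectare expansion factor.
#' @export
expansionFactor <- function(dbh_cm) {
  if (any(!is.finite(dbh_cm)) || any(dbh_cm < 8))
    stop("dbh_cm below the 8 cm census threshold")
  r <- ifelse(dbh_cm >= 30, 15, ifelse(dbh_cm >= 15, 10, 5))
  10000 / (pi * r^2)
}

.stem_columns <- c("cluster_id", "subplot_id", "species", "dbh_cm",
                   "status", "landuse_class", "slopover_flag")

.check_stems <- function(stems) {
  miss <- setdiff(.stem_columns, names(stems))
  if (length(miss))
    stop("stem table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(stems) == 0L) stop("stem table is empty")
  invisible(stems)
}

#' Filter cluster plots for analysis
#'
#' Applies the sample-definition rules cluster by cluster, in a fixed
#' order so every rejected cluster gets one deterministic reason: land use
#' not in the allowed set ("landuse"), any subplot flagged as slopover
#' ("slopover"), not exactly the required number of non-empty subplots
#' ("subplot_count"), and records not identified at species level
#' ("non_species_taxon").  An optional synonym map is applied to species
#' names before any check.
#'
#' @param stems data.frame of stem records (columns cluster_id,
#'   subplot_id, species, dbh_cm, status, landuse_class, slopover_flag;
#'   further columns are carried through).
#' @param cfg a [filterConfig()].
#' @return list with \code{stems} (retained records) and \code{rejections}
#'   (data.frame cluster_id, reason).
#' @export
filterClusters <- function(stems, cfg = filterConfig()) {
  .check_stems(stems)
  if (!is.null(cfg$synonyms)) {
    hit <- stems$species %in% names(cfg$synonyms)
    stems$species[hit] <- unname(cfg$synonyms[stems$species[hit]])
  }
  ids <- unique(stems$cluster_id)
  reason <- setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    cl <- stems[stems$cluster_id == id, , drop = FALSE]
    if (!all(cl$landuse_class %in% cfg$allowed_landuse)) {
      reason[as.character(id)] <- "landuse"
    } else if (cfg$exclude_slopover && any(cl$slopover_flag)) {
      reason[as.character(id)] <- "slopover"
    } else if (length(unique(cl$subplot_id)) != cfg$required_subplots &&
               cfg$exclude_empty_subplots) {
      reason[as.character(id)] <- "subplot_count"
    } else if (cfg$species_level_only &&
               any(grepl(cfg$non_species_pattern, cl$species))) {
      reason[as.character(id)] <- "non_species_taxon"
    }
  }
  dropped <- ids[!is.na(reason)]
  keep <- stems[!stems$cluster_id %in% dropped, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("empty sample: all ", length(ids), " clusters rejected")
  list(stems = keep,
       rejections = data.frame(cluster_id = dropped,
                               reason = unname(reason[as.character(dropped)]),
                               stringsAsFactors = FALSE))
}

#' Build the mean basal-area community matrix
#'
#' For every cluster plot and species, the basal area of all living stems
#' is expanded to per-hectare values on the stem's concentric circle,
#' summed, and divided by the number of subplots to give the mean BA in
#' m²/ha.  Dead stems are excluded; samples left without any living stem
#' are dropped (and reported via the \code{"dropped"} attribute).
#'
#' @param stems filtered stem records (see [filterClusters()]).
#' @param n_subplots number of subplots per cluster (divisor; default 3).
#' @param sample_data optional data.frame of per-sample metadata indexed
#'   by cluster id (e.g. elevation_m); matched by row name.
#' @return a [CommunityMatrix-class] object.
#' @export
buildCommunityMatrix <- function(stems, n_subplots = 3, sample_data = NULL) {
  .check_stems(stems)
  live <- stems[stems$status == "living", , drop = FALSE]
  all_ids <- unique(as.character(stems$cluster_id))
  if (nrow(live) == 0L) stop("no living stems")
  contrib <- stemBasalArea(live$dbh_cm) * expansionFactor(live$dbh_cm) / n_subplots
  agg <- tapply(contrib,
                list(sample = as.character(live$cluster_id),
                     species = as.character(live$species)),
                sum, default = 0)
  m <- matrix(agg, nrow = nrow(agg), ncol = ncol(agg),
              dimnames = dimnames(agg))
  # deterministic ordering independent of stem row order
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  dropped <- setdiff(all_ids, rownames(m))
  sd <- data.frame(row.names = rownames(m))
  if (!is.null(sample_data)) {
    sd <- sample_data[match(rownames(m), rownames(sample_data)), , drop = FALSE]
    rownames(sd) <- rownames(m)
  }
  cm <- new("CommunityMatrix", ba = m, sampleData = sd)
  attr(cm, "dropped") <- sort(dropped)
  cm
}

#' Read / write a plain-text elevation raster (ESRI ASCII grid)
#'
#' The raster is a list with fields \code{ncols}, \code{nrows},
#' \code{xll}, \code{yll}, \code{cellsize}, \code{nodata} and \code{z}, a
#' numeric matrix whose first row is the northernmost row (the on-disk
#' order of the format).
#'
#' @param path file path.
#' @return for \code{readAsciiRaster}, the raster list.
#' @export
readAsciiRaster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("raster value count does not match header")
  list(ncols = nc, nrows = nr,
       xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize,
       nodata = if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999,
       z = matrix(vals, nrow = nr, ncol = nc, byrow = TRUE))
}

#' @rdname readAsciiRaster
#' @param raster raster list as above.
#' @export
writeAsciiRaster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$ncols),
               paste("nrows", raster$nrows),
               paste("xllcorner", raster$xll),
               paste("yllcorner", raster$yll),
               paste("cellsize", raster$cellsize),
               paste("NODATA_value", raster$nodata)), con)
  write.table(raster$z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Median elevation of a circular subplot
#'
#' Median of all raster cell values whose square is contained in or
#' crossed by the circle of radius \code{radius_m + gps_error_m} around
#' the subplot centre (the southwestern subplot, in the sampling design).
#'
#' @param raster raster list (see [readAsciiRaster()]).
#' @param center numeric length-2 (x, y) in the raster's planar units.
#' @param radius_m subplot radius in m.
#' @param gps_error_m recorded GPS error added to the radius.
#' @return elevation in m.
#' @export
sampleElevation <- function(raster, center, radius_m, gps_error_m = 0) {
  r <- radius_m + gps_error_m
  stopifnot(r > 0, length(center) == 2L)
  cs <- raster$cellsize
  nr <- raster$nrows; nc <- raster$ncols
  # candidate cell window
  cmin <- max(1L, floor((center[1] - r - raster$xll) / cs) + 1L)
  cmax <- min(nc, floor((center[1] + r - raster$xll) / cs) + 1L)
  rowy <- function(row) raster$yll + (nr - row) * cs  # southern edge of row
  vals <- numeric(0)
  if (cmin <= cmax) {
    for (row in seq_len(nr)) {
      y0 <- rowy(row)
      if (y0 > center[2] + r || y0 + cs < center[2] - r) next
      for (col in cmin:cmax) {
        x0 <- raster$xll + (col - 1L) * cs
        # distance from circle centre to the cell rectangle
        dx <- max(x0 - center[1], 0, center[1] - (x0 + cs))
        dy <- max(y0 - center[2], 0, center[2] - (y0 + cs))
        if (dx * dx + dy * dy <= r * r) vals <- c(vals, raster$z[row, col])
      }
    }
  }
  if (length(vals) == 0L) stop("subplot circle lies outside the raster")
  vals <- vals[vals != raster$nodata]
  if (length(vals) == 0L) stop("all intersected cells are no-data")
  stats::median(vals)
}

#' Read / write stem record tables and community matrices as CSV
#'
#' @param path file path.
#' @return \code{readStemTable}: the stem data.frame.
#' @export
readStemTable <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  st$slopover_flag <- as.logical(st$slopover_flag)
  .check_stems(st)
  st
}

#' @rdname readStemTable
#' @param stems stem data.frame.
#' @export
writeStemTable <- function(stems, path) {
  utils::write.csv(stems, path, row.names = FALSE)
  invisible(path)
}

#' @rdname readStemTable
#' @param x a [CommunityMatrix-class].
#' @export
writeCommunityMatrix <- function(x, path) {
  utils::write.csv(data.frame(sample = rownames(baMatrix(x)),
                              baMatrix(x), check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
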