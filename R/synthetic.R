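#' Generate a random ultrametric phylogeny
#'
#' Coalescent tree over n synthetic woody species; binary, ultrametric,
#' positive branch lengths.  Tips are relabelled as binomials grouped
#' into genera along the tree (consecutive tips in cladewise order share
#' a genus), so genus structure is phylogenetically coherent.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed, or NULL to draw from the current stream.
#' @return an [ape::phylo] ultrametric tree.
#' @export
generatePhylogeny <- function(n_species, seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_species)
  # genera of 1-5 species along the cladewise tip order
  ord <- tree$edge[tree$edge[, 2] <= n_species, 2]
  sizes <- integer(0)
  while (sum(sizes) < n_species)
    sizes <- c(sizes, sample(1:5, 1))
  genus_of <- rep(seq_along(sizes), sizes)[seq_len(n_species)]
  labels <- character(n_species)
  labels[ord] <- sprintf("Genus%02d_species%03d", genus_of, ord)
  tree$tip.label <- labels
  tree
}

#' Generate phylogenetically clustered assemblage species pools
#'
#' Each assemblage gets a species weight vector concentrated on one focal
#' clade (found by walking up from a seed species until the clade reaches
#' the target pool size; seed species are chosen by greedy farthest-point
#' selection on cophenetic distances so pools occupy distinct parts of the
#' tree) mixed with a uniform background: weight_i = phylo_signal *
#' uniform(clade) + (1 - phylo_signal) * uniform(all species).  Each pool
#' is assigned an elevation niche centre, evenly spaced over the elevation
#' range.
#'
#' @param tree ultrametric [ape::phylo] over the species.
#' @param cfg a [syntheticConfig()].
#' @return list of assemblages, each with \code{weights} (named, sums to
#'   1), \code{clade} (focal clade tip labels) and \code{elevation} (niche
#'   centre, m).
#' @export
generateAssemblagePools <- function(tree, cfg) {
  n <- length(tree$tip.label)
  stopifnot(n >= cfg$n_species)
  k <- cfg$n_assemblages
  dmat <- ape::cophenetic.phylo(tree)
  # greedy farthest-point seeds
  seeds <- which.max(colSums(dmat))
  while (length(seeds) < k) {
    mind <- apply(dmat[, seeds, drop = FALSE], 1, min)
    mind[seeds] <- -Inf
    seeds <- c(seeds, which.max(mind))
  }
  target <- max(2L, round(n / k))
  centers <- cfg$elevation_range[1] +
    (seq_len(k) - 0.5) / k * diff(cfg$elevation_range)
  lapply(seq_len(k), function(a) {
    anc <- c(seeds[a], phangorn::Ancestors(tree, seeds[a], "all"))
    clade_tips <- seeds[a]
    for (nd in anc[-1]) {
      tips <- phangorn::Descendants(tree, nd, "tips")[[1]]
      if (length(tips) >= target) { clade_tips <- tips; break }
      clade_tips <- tips
    }
    # geometric rank-abundance within the clade (ranked by distance from
    # the seed species): every assemblage has dominant, constant species
    # and a tail of rarer ones, as in real vegetation classes
    rnk <- rank(dmat[clade_tips, seeds[a]], ties.method = "first")
    gw <- 0.65^(rnk - 1)
    w <- rep((1 - cfg$phylo_signal) / n, n)
    w[clade_tips] <- w[clade_tips] + cfg$phylo_signal * gw / sum(gw)
    names(w) <- tree$tip.label
    list(weights = w / sum(w),
         clade = tree$tip.label[clade_tips],
         elevation = centers[a])
  })
}

# smooth synthetic elevation field over the landscape (m asl)
.elev_field <- function(x, y, cfg, lx) {
  rng <- cfg$elevation_range
  base <- rng[1] + (rng[2] - rng[1]) * pmin(pmax(x / lx, 0), 1)
  pmin(pmax(base + 15 * sin(2 * pi * y / 400), rng[1]), rng[2])
}

#' Generate a synthetic stem-level inventory
#'
#' Places cluster plots (three subplots in an L-shape, 100 m apart) on an
#' elevation-gradient landscape, assigns each cluster to an assemblage
#' with probability proportional to the Gaussian elevation niche of each
#' pool at the cluster's elevation, draws per-plot species richness and a
#' per-plot basal-area target, and emits individual stems with lognormal
#' DBH (truncated at the 8 cm census threshold) on the concentric
#' subplot circle their DBH qualifies for.  Configurable fractions of
#' dead stems, slopover subplots and genus-only labels are injected to
#' exercise the inventory filters.
#'
#' @param pools output of [generateAssemblagePools()].
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed, or NULL to draw from the current stream.
#' @return list with \code{stems} (stem record data.frame), \code{truth}
#'   (cluster_id, assemblage, elevation_m), and \code{raster} (elevation
#'   grid, see [readAsciiRaster()]).
#' @export
generateInventory <- function(pools, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_clusters
  species_names <- gsub("_", " ", names(pools[[1]]$weights))
  lx <- max(3000, n * 15)
  ly <- 600
  x <- round(stats::runif(n, 100, lx - 200), 1)
  y <- round(stats::runif(n, 100, ly - 200), 1)
  elev <- .elev_field(x, y, cfg, lx)
  centers <- vapply(pools, `[[`, numeric(1), "elevation")
  # assemblage membership: Gaussian niche weight at the cluster elevation
  loglik <- -0.5 * outer(elev, centers, "-")^2 / cfg$niche_width^2
  loglik <- loglik - apply(loglik, 1, max)
  pr <- exp(loglik) / rowSums(exp(loglik))
  assem <- vapply(seq_len(n), function(i)
    sample.int(length(pools), 1, prob = pr[i, ]), integer(1))
  sdl <- sqrt(log(1 + cfg$ba_cv^2))
  mul <- log(cfg$ba_mean) - sdl^2 / 2
  p8 <- stats::plnorm(8, cfg$dbh_meanlog, cfg$dbh_sdlog)
  draw_dbh <- function(m)   # truncated lognormal >= 8 cm
    round(stats::qlnorm(p8 + stats::runif(m) * (1 - p8),
                        cfg$dbh_meanlog, cfg$dbh_sdlog), 1)
  rows <- vector("list", n)
  ids <- sprintf("C%04d", seq_len(n))
  for (i in seq_len(n)) {
    w <- pools[[assem[i]]]$weights
    npos <- sum(w > 0)
    R <- max(1L, min(12L, npos,
                     as.integer(round(stats::rnorm(1, cfg$richness_mean,
                                                   cfg$richness_sd)))))
    sp <- sample(species_names, R, prob = w)
    Tba <- stats::rlnorm(1, mul, sdl)
    # BA shares follow the pool weights of the drawn species, with noise:
    # dominant species also dominate basal area
    shares <- w[match(sp, species_names)] * stats::rgamma(R, 1)
    shares <- shares / sum(shares)
    sp_rows <- lapply(seq_len(R), function(s) {
      tgt <- shares[s] * Tba
      dbh <- numeric(0); contrib <- numeric(0)
      while (sum(contrib) < tgt && length(dbh) < 5000L) {
        m <- max(4L, ceiling((tgt - sum(contrib)) / 0.3))
        dd <- draw_dbh(m)
        dbh <- c(dbh, dd)
        contrib <- c(contrib, stemBasalArea(dd) * expansionFactor(dd) / 3)
      }
      nuse <- which(cumsum(contrib) >= tgt)[1]
      if (is.na(nuse)) nuse <- length(dbh)
      data.frame(species = sp[s], dbh_cm = dbh[seq_len(nuse)],
                 stringsAsFactors = FALSE)
    })
    st <- do.call(rbind, sp_rows)
    st$subplot_id <- sample(1:3, nrow(st), replace = TRUE)
    st$status <- "living"
    rows[[i]] <- data.frame(cluster_id = ids[i], st,
                            stringsAsFactors = FALSE)
  }
  stems <- do.call(rbind, rows)
  # dead-stem injection
  if (cfg$dead_fraction > 0) {
    nd <- stats::rbinom(1, nrow(stems), cfg$dead_fraction)
    if (nd > 0) {
      src <- stems[sample.int(nrow(stems), nd), , drop = FALSE]
      src$dbh_cm <- draw_dbh(nd)
      src$status <- "dead"
      stems <- rbind(stems, src)
    }
  }
  stems$landuse_class <- "Forest"
  stems$slopover_flag <- FALSE
  # slopover subplots
  if (cfg$slopover_fraction > 0) {
    hit <- ids[stats::runif(n) < cfg$slopover_fraction]
    for (id in hit) {
      sub <- sample(1:3, 1)
      sel <- stems$cluster_id == id & stems$subplot_id == sub
      stems$slopover_flag[sel] <- TRUE
    }
  }
  # genus-only labels
  if (cfg$genus_only_fraction > 0) {
    hit <- which(stats::runif(n) < cfg$genus_only_fraction)
    for (i in hit) {
      g <- sub(" .*", "", sample(species_names, 1))
      extra <- data.frame(cluster_id = ids[i],
                          species = paste(g, "spp."),
                          dbh_cm = draw_dbh(1),
                          subplot_id = sample(1:3, 1),
                          status = "living", landuse_class = "Forest",
                          slopover_flag = FALSE, stringsAsFactors = FALSE)
      stems <- rbind(stems, extra)
    }
  }
  # subplot centre coordinates: L-shape, subplot 1 is the SW corner
  off <- cbind(c(0, 0, 100), c(0, 100, 0))
  stems$x <- x[match(stems$cluster_id, ids)] + off[stems$subplot_id, 1]
  stems$y <- y[match(stems$cluster_id, ids)] + off[stems$subplot_id, 2]
  stems$gps_error_m <- cfg$gps_error_m
  stems <- stems[order(stems$cluster_id, stems$subplot_id,
                       stems$species, stems$dbh_cm), ]
  rownames(stems) <- NULL
  cs <- 30
  nc <- ceiling(lx / cs); nr <- ceiling(ly / cs)
  cx <- (seq_len(nc) - 0.5) * cs
  cy <- (seq_len(nr) - 0.5) * cs
  z <- outer(rev(cy), cx, function(yy, xx) round(.elev_field(xx, yy, cfg, lx), 1))
  raster <- list(ncols = nc, nrows = nr, xll = 0, yll = 0,
                 cellsize = cs, nodata = -9999, z = z)
  list(stems = stems[, c("cluster_id", "subplot_id", "species", "dbh_cm",
                         "status", "landuse_class", "slopover_flag",
                         "x", "y", "gps_error_m")],
       truth = data.frame(cluster_id = ids, assemblage = assem,
                          elevation_m = elev, stringsAsFactors = FALSE),
       raster = raster)
}

#' Generate a complete synthetic NFI bundle
#'
#' One call, one random stream: phylogeny, assemblage pools, stem
#' inventory, truth table and elevation raster, all reproducible from
#' \code{cfg$seed}.
#'
#' @param cfg a [syntheticConfig()].
#' @return list(tree, pools, stems, truth, raster, config).
#' @export
generateSyntheticNFI <- function(cfg = syntheticConfig()) {
  set.seed(cfg$seed)
  tree <- generatePhylogeny(cfg$n_species, seed = NULL)
  pools <- generateAssemblagePools(tree, cfg)
  inv <- generateInventory(pools, cfg, seed = NULL)
  c(list(tree = tree, pools = pools), inv, list(config = cfg))
}

#' Write a synthetic bundle to disk
#'
#' Stem table and truth table as CSV, phylogeny as Newick, elevation grid
#' as an ESRI-ASCII raster.
#'
#' @param bundle output of [generateSyntheticNFI()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStemTable(bundle$stems, file.path(dir, "stems.csv"))
  ape::write.tree(bundle$tree, file.path(dir, "phylogeny.nwk"))
  writeAsciiRaster(bundle$raster, file.path(dir, "elevation.asc"))
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
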