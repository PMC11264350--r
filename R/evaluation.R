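#' Mantel test between two dissimilarity matrices
#'
#' Spearman correlation of the strictly-lower-triangle entries, with the
#' null distribution built by simultaneous row/column permutation of the
#' second matrix.  Because such a permutation only permutes the
#' triangle's multiset of values, ranks are computed once and the
#' permutation loop is a plain Pearson correlation on rank vectors.
#' p = (1 + #\{perm rho >= observed\}) / (1 + n_perm), so p is never 0.
#'
#' @param d1,d2 symmetric matrices (or [SampleDissimilarity-class]) over
#'   the same samples in the same order.
#' @param n_perm number of permutations (default 999; the study scale is
#'   9999).
#' @param seed optional seed for the permutation stream.
#' @return list(rho, p, n_perm).
#' @export
mantelTest <- function(d1, d2, n_perm = 999, seed = NULL) {
  if (is(d1, "SampleDissimilarity")) d1 <- distMatrix(d1)
  if (is(d2, "SampleDissimilarity")) d2 <- distMatrix(d2)
  stopifnot(identical(dim(d1), dim(d2)), n_perm >= 1)
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]; v2 <- d2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("Mantel statistic undefined for a constant matrix")
  r1 <- rank(v1)
  rho <- stats::cor(r1, rank(v2))
  R2 <- matrix(0, n, n)
  R2[lt] <- rank(v2)
  R2 <- R2 + t(R2)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(r1, R2[p, p][lt]) >= rho) count <- count + 1L
  }
  list(rho = rho, p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}

#' Cophenetic correlation between a hierarchy and the original
#' dissimilarities
#'
#' Pearson correlation between the lower triangle of the dissimilarity
#' matrix and the dendrogram distance of each sample pair, defined as
#' max_levels + 1 - depth of the pair's deepest common node (root depth
#' 0; a divisive level hierarchy carries no metric heights, so level
#' depth is the height scale).
#'
#' @param hierarchy an [AssemblageHierarchy-class].
#' @param d symmetric dissimilarity matrix (or
#'   [SampleDissimilarity-class]) over the hierarchy's samples.
#' @return the correlation coefficient.
#' @export
copheneticCorrelation <- function(hierarchy, d) {
  if (is(d, "SampleDissimilarity")) d <- distMatrix(d)
  a <- assignments(hierarchy)
  stopifnot(identical(rownames(d), sampleIds(hierarchy)))
  cd <- .common_depth(a)
  dd <- hierarchy@maxLevels + 1 - cd
  lt <- lower.tri(d)
  if (stats::sd(dd[lt]) == 0)
    stop("cophenetic correlation undefined: hierarchy has a single cluster")
  stats::cor(d[lt], dd[lt])
}

# depth of the deepest common node for every sample pair; node depth of a
# label is its number of path components ("1.2" -> 2), root is 0.
.common_depth <- function(a) {
  n <- nrow(a)
  cd <- matrix(0, n, n)
  for (l in seq_len(ncol(a))) {
    lab <- a[, l]
    dep <- lengths(strsplit(lab, ".", fixed = TRUE))
    eq <- outer(lab, lab, "==")
    cd[eq] <- matrix(dep, n, n)[eq]
  }
  diag(cd) <- ncol(a) + 1
  cd
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement; 1 for identical partitions
#' (up to relabelling), ~0 for independent ones.
#'
#' @param p1,p2 cluster label vectors over the same samples.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  mclust::adjustedRandIndex(p1, p2)
}

#' Distance-based within-cluster sum of squares
#'
#' WSS = sum over clusters c of (sum of squared within-cluster
#' dissimilarities) / |c|; for Euclidean distances this equals the sum of
#' squared distances to cluster centroids (Huygens' theorem).
#'
#' @param d symmetric dissimilarity matrix (or
#'   [SampleDissimilarity-class]).
#' @param assignment cluster label per sample.
#' @return WSS >= 0.
#' @export
withinSS <- function(d, assignment) {
  if (is(d, "SampleDissimilarity")) d <- distMatrix(d)
  stopifnot(nrow(d) == length(assignment))
  total <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    if (length(idx) < 2) next
    sub <- d[idx, idx]
    total <- total + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  total
}

#' Within- and between-cluster distance summary
#'
#' Mean dissimilarity over within-cluster pairs (per cluster and pooled
#' over all within pairs) and over between-cluster pairs.  Singleton
#' clusters have no within pairs and are reported as NA.
#'
#' @inheritParams withinSS
#' @return list(per_cluster, mean_within, mean_between).
#' @export
clusterDistanceStats <- function(d, assignment) {
  if (is(d, "SampleDissimilarity")) d <- distMatrix(d)
  stopifnot(nrow(d) == length(assignment))
  cls <- sort(unique(assignment))
  same <- outer(assignment, assignment, "==")
  lt <- lower.tri(d)
  per <- vapply(cls, function(cl) {
    idx <- assignment == cl
    if (sum(idx) < 2) return(NA_real_)
    sub <- d[idx, idx]
    mean(sub[lower.tri(sub)])
  }, numeric(1))
  names(per) <- as.character(cls)
  within_vals <- d[lt & same]
  between_vals <- d[lt & !same]
  list(per_cluster = per,
       mean_within = if (length(within_vals)) mean(within_vals) else NA_real_,
       mean_between = if (length(between_vals)) mean(between_vals)
                      else NA_real_)
}

#' Kruskal-Wallis test of a variable across clusters
#'
#' Rank-based H with tie correction, df = groups - 1, chi-square
#' upper-tail p.  All-identical values give H = 0 and p = 1.
#'
#' @param values numeric vector (e.g. sample elevations).
#' @param assignment cluster label per sample (>= 2 groups).
#' @return list(H, df, p).
#' @export
kruskalWallisGroups <- function(values, assignment) {
  stopifnot(length(values) == length(assignment))
  g <- factor(assignment)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Full cluster-evaluation report
#'
#' Computes the comparison suite for a pair of dissimilarity matrices and
#' their hierarchies: Mantel correlation between the matrices, cophenetic
#' correlation per hierarchy, adjusted Rand index between the terminal
#' partitions, WSS, within/between distance summaries, and (when sample
#' elevations are available) Kruskal-Wallis on elevation across each
#' hierarchy's terminal assemblages.
#'
#' @param d_bc,d_da [SampleDissimilarity-class] matrices over the same
#'   samples.
#' @param h_bc,h_da matching [AssemblageHierarchy-class] objects.
#' @param elevation optional named numeric vector of sample elevations.
#' @param level hierarchy level to evaluate at (default: the deepest).
#' @param n_perm Mantel permutations.
#' @param seed seed for the Mantel permutation stream.
#' @return a nested list (the evaluation report).
#' @export
evaluateClustering <- function(d_bc, d_da, h_bc, h_da, elevation = NULL,
                               level = NULL, n_perm = 999, seed = NULL) {
  L <- ncol(assignments(h_bc))
  if (is.null(level)) level <- L
  a_bc <- cutAssemblages(h_bc, level)
  a_da <- cutAssemblages(h_da, level)
  rep_for <- function(d, h, a) {
    st <- clusterDistanceStats(d, a)
    list(n_clusters = length(unique(a)),
         clusters_per_level = levelCounts(h),
         # degenerate (single-cluster) hierarchies report NA, not an error
         cophenetic_corr = tryCatch(copheneticCorrelation(h, d),
                                    error = function(e) NA_real_),
         wss = withinSS(d, a),
         mean_within = st$mean_within,
         mean_within_per_cluster = as.list(st$per_cluster),
         mean_between = st$mean_between,
         mean_dissimilarity = mean(distMatrix(d)[lower.tri(distMatrix(d))]),
         kruskal_wallis = if (!is.null(elevation))
           tryCatch(kruskalWallisGroups(elevation[names(a)], a),
                    error = function(e) list(H = NA_real_,
                                             df = NA_integer_,
                                             p = NA_real_)) else NULL)
  }
  list(level = level,
       mantel = mantelTest(d_bc, d_da, n_perm = n_perm, seed = seed),
       adjusted_rand = adjustedRand(a_bc, a_da),
       BC = rep_for(d_bc, h_bc, a_bc),
       dA = rep_for(d_da, h_da, a_da))
}

#' @rdname evaluateClustering
#' @param report an evaluation report.
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname evaluateClustering
#' @export
reportSummary <- function(report) {
  fmt <- function(x, d = 3) ifelse(is.na(x), "NA", formatC(x, digits = d,
                                                           format = "g"))
  line_for <- function(side) {
    r <- report[[side]]
    c(sprintf("%s: %d assemblages over levels (%s)", side, r$n_clusters,
              paste(r$clusters_per_level, collapse = "/")),
      sprintf("  mean pairwise dissimilarity %s (within %s, between %s)",
              fmt(r$mean_dissimilarity), fmt(r$mean_within),
              fmt(r$mean_between)),
      sprintf("  WSS %s, cophenetic correlation %s", fmt(r$wss, 5),
              fmt(r$cophenetic_corr)),
      if (!is.null(r$kruskal_wallis))
        sprintf("  Kruskal-Wallis on elevation: H = %s, df = %s, p = %s",
                fmt(r$kruskal_wallis$H, 4), r$kruskal_wallis$df,
                fmt(r$kruskal_wallis$p, 3)))
  }
  c(sprintf("Mantel test between matrices: rho = %s, p = %s (%d permutations)",
            fmt(report$mantel$rho), fmt(report$mantel$p),
            report$mantel$n_perm),
    line_for("BC"), line_for("dA"),
    sprintf("Adjusted Rand index between partitions (level %d): %s",
            report$level, fmt(report$adjusted_rand)))
}
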