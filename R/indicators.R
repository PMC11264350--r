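# Shared presence bookkeeping: per-cluster sizes and presence counts.
# presence: logical/0-1 matrix samples x species; assignment: labels.
.presence_counts <- function(presence, assignment) {
  stopifnot(nrow(presence) == length(assignment))
  pres <- presence > 0
  cl <- sort(unique(assignment))
  sizes <- vapply(cl, function(c) sum(assignment == c), integer(1))
  if (any(sizes == 0L)) stop("empty cluster")
  counts <- vapply(cl, function(c)
    colSums(pres[assignment == c, , drop = FALSE]), numeric(ncol(pres)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = ncol(pres),
                     dimnames = list(colnames(pres), cl))
  list(clusters = cl, sizes = sizes, counts = counts,
       total = colSums(pres), n = nrow(pres))
}

#' Per-cluster species presence frequencies
#'
#' freq(s, c) = 100 * (number of samples of cluster c containing species
#' s) / |c|, plus the total frequency over all samples.  Presence is
#' abundance > 0.
#'
#' @param presence samples x species matrix (abundances or 0/1).
#' @param assignment cluster label per sample.
#' @return list with \code{freq} (species x clusters, %) and \code{total}
#'   (named vector, %).
#' @export
presenceFrequencies <- function(presence, assignment) {
  pc <- .presence_counts(presence, assignment)
  freq <- 100 * sweep(pc$counts, 2, pc$sizes, "/")
  colnames(freq) <- as.character(pc$clusters)
  list(freq = freq, total = 100 * pc$total / pc$n)
}

# Vectorized one-sided (enrichment) Fisher p for all species x clusters:
# hypergeometric upper tail P(X >= a) with K presences among n samples,
# drawing the n_c samples of the cluster.
.fisher_p_matrix <- function(pc) {
  k <- length(pc$clusters)
  S <- nrow(pc$counts)
  p <- matrix(1, S, k, dimnames = list(rownames(pc$counts),
                                       as.character(pc$clusters)))
  for (j in seq_len(k))
    p[, j] <- stats::phyper(pc$counts[, j] - 1, pc$total,
                            pc$n - pc$total, pc$sizes[j],
                            lower.tail = FALSE)
  p
}

# Vectorized equalized phi for all species x clusters.  Every cluster is
# re-weighted to equal size before collapsing to in/out of the target
# cluster; with within-cluster frequencies f the equalized 2x2 table per
# unit cluster size is (f_c, 1 - f_c, sum_{c' != c} f_c', (k-1) - ...).
.equalized_phi_matrix <- function(pc) {
  k <- length(pc$clusters)
  f <- sweep(pc$counts, 2, pc$sizes, "/")      # species x clusters
  tot_f <- rowSums(f)
  a <- f
  b <- 1 - f
  cc <- tot_f - f
  d <- (k - 1) - cc
  num <- a * d - b * cc
  den <- sqrt((k - 1) * (a + cc) * (b + d))    # (a+b)=1, (c+d)=k-1
  phi <- ifelse(den > 0, num / den, 0)
  dimnames(phi) <- list(rownames(pc$counts), as.character(pc$clusters))
  phi
}

#' One-sided Fisher's exact test for a species-cluster association
#'
#' Tests whether the observed presence frequency of a species inside a
#' cluster exceeds chance expectation: hypergeometric upper-tail
#' probability of the 2x2 (in/out of cluster x present/absent) table.
#'
#' @param presence samples x species matrix.
#' @param assignment cluster label per sample.
#' @param species species (column) name.
#' @param cluster cluster label.
#' @return one-sided p-value.
#' @export
fisherIndicator <- function(presence, assignment, species, cluster) {
  pc <- .presence_counts(presence, assignment)
  j <- match(as.character(cluster), as.character(pc$clusters))
  s <- match(species, rownames(pc$counts))
  if (is.na(j) || is.na(s)) stop("unknown species or cluster")
  stats::phyper(pc$counts[s, j] - 1, pc$total[s], pc$n - pc$total[s],
                pc$sizes[j], lower.tail = FALSE)
}

#' Equalized phi fidelity of a species for a cluster
#'
#' Phi association coefficient between species presence and membership of
#' the target cluster, computed on a virtually equalized table in which
#' every cluster is re-weighted to equal size before collapsing to
#' in-cluster vs out-of-cluster.  1 means perfect fidelity; 0 means the
#' species is independent of the clustering; degenerate margins give 0.
#'
#' @inheritParams fisherIndicator
#' @return phi in [-1, 1].
#' @export
equalizedPhi <- function(presence, assignment, species, cluster) {
  pc <- .presence_counts(presence, assignment)
  if (length(pc$clusters) < 2L) stop("need >= 2 clusters")
  phi <- .equalized_phi_matrix(pc)
  j <- match(as.character(cluster), colnames(phi))
  s <- match(species, rownames(phi))
  if (is.na(j) || is.na(s)) stop("unknown species or cluster")
  phi[s, j]
}

#' Synoptic indicator table for one hierarchy level
#'
#' Builds the full per-(species, cluster) table of frequencies, equalized
#' phi and one-sided Fisher p at a given level of the hierarchy, sorted
#' by significance then fidelity.  The headline view (see
#' [headlineIndicators()]) applies the characterization thresholds:
#' highly significant species (p <= alpha) with total frequency >=
#' min_total_freq %.
#'
#' @param hierarchy an [AssemblageHierarchy-class].
#' @param level hierarchy level to cut at.
#' @param community the [CommunityMatrix-class] the hierarchy was built
#'   from.
#' @param alpha headline significance threshold (default 0.001).
#' @param min_total_freq headline total-frequency threshold in %
#'   (default 50).
#' @return an [IndicatorTable-class].
#' @export
isotab <- function(hierarchy, level, community, alpha = 0.001,
                   min_total_freq = 50) {
  stopifnot(level >= 1L, level <= ncol(assignments(hierarchy)))
  assignment <- cutAssemblages(hierarchy, level)
  ba <- baMatrix(community)[sampleIds(hierarchy), , drop = FALSE]
  pc <- .presence_counts(ba, assignment)
  fr <- presenceFrequencies(ba, assignment)
  pm <- .fisher_p_matrix(pc)
  phim <- .equalized_phi_matrix(pc)
  tb <- data.frame(
    species = rep(rownames(fr$freq), times = ncol(fr$freq)),
    cluster = rep(colnames(fr$freq), each = nrow(fr$freq)),
    freq = as.vector(fr$freq),
    phi = as.vector(phim),
    p = as.vector(pm),
    total_freq = rep(unname(fr$total), times = ncol(fr$freq)),
    stringsAsFactors = FALSE)
  tb <- tb[order(tb$p, -tb$phi, tb$species, tb$cluster), ]
  rownames(tb) <- NULL
  new("IndicatorTable", table = tb, level = as.integer(level),
      alpha = alpha, minTotalFreq = min_total_freq)
}

#' @rdname isotab
#' @param x an [IndicatorTable-class].
#' @param path output path; the long format is written as CSV, the
#'   synoptic (species x clusters) view as TSV with cells
#'   "freq% (phi, p)".
#' @export
writeIndicatorTable <- function(x, path) {
  tb <- indicatorTable(x)
  utils::write.csv(tb, path, row.names = FALSE)
  syn <- paste0(sub("[.]csv$", "", path), "_synoptic.tsv")
  cell <- sprintf("%.0f%% (%.2f, %.3g)", tb$freq, tb$phi, tb$p)
  wide <- tapply(cell, list(tb$species, tb$cluster), identity)
  utils::write.table(data.frame(species = rownames(wide), wide,
                                check.names = FALSE),
                     syn, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
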