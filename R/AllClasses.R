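#' @import methods
NULL

.check_square_sym <- function(m, zero_diag = TRUE, tol = 1e-8) {
  msg <- character()
  if (!is.matrix(m) || !is.numeric(m)) msg <- c(msg, "must be a numeric matrix")
  else {
    if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
    else {
      if (any(!is.finite(m))) msg <- c(msg, "contains non-finite values")
      if (max(abs(m - t(m))) > tol) msg <- c(msg, "must be symmetric")
      if (zero_diag && any(abs(diag(m)) > tol)) msg <- c(msg, "diagonal must be zero")
    }
  }
  msg
}

#' Community matrix of mean basal area per sample and species
#'
#' Samples (cluster plots) in rows, woody species in columns, entries the
#' mean basal area in m^2/ha obtained by expanding every living stem to a
#' per-hectare value on its concentric subplot circle, summing per cluster
#' and species, and dividing by the number of subplots.  Row order carries
#' the sample ids shared with sample-level metadata (elevation).
#'
#' @slot ba numeric matrix, samples x species, mean basal area (m^2/ha).
#' @slot sampleData data.frame of per-sample metadata (one row per sample,
#'   same order as \code{ba}); typically holds \code{elevation_m}.
#' @export
setClass("CommunityMatrix",
  slots = c(ba = "matrix", sampleData = "data.frame"),
  validity = function(object) {
    m <- object@ba
    msg <- character()
    if (!is.numeric(m)) msg <- c(msg, "'ba' must be numeric")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msg <- c(msg, "'ba' needs sample row names and species column names")
    else {
      if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicated sample ids")
      if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicated species names")
    }
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "abundances must be finite and >= 0")
    if (nrow(m) > 0 && any(rowSums(m > 0) == 0))
      msg <- c(msg, "every sample must contain at least one species")
    if (nrow(object@sampleData) != nrow(m))
      msg <- c(msg, "'sampleData' must have one row per sample")
    if (length(msg)) msg else TRUE
  })

#' Normalized interspecies cophenetic distance matrix
#'
#' Pairwise phylogenetic distances d_ij between species: total branch
#' length connecting two tips of an ultrametric tree, divided by the
#' maximum observed tip-to-tip distance so that off-diagonal values fall
#' in (0, 1] with the maximum exactly 1.
#'
#' @slot d numeric matrix over species, symmetric, zero diagonal.
#' @export
setClass("SpeciesDist",
  slots = c(d = "matrix"),
  validity = function(object) {
    m <- object@d
    msg <- .check_square_sym(m)
    if (!length(msg)) {
      if (is.null(rownames(m))) msg <- c(msg, "species names required")
      off <- m[upper.tri(m)]
      if (length(off)) {
        if (any(off <= 0)) msg <- c(msg, "off-diagonal distances must be > 0")
        if (abs(max(off) - 1) > 1e-8)
          msg <- c(msg, "maximum off-diagonal distance must be 1 (normalized)")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Pairwise sample dissimilarity matrix
#'
#' Square matrix of Bray-Curtis or Discriminating Avalanche dissimilarities
#' between samples, values in [0, 1], with metadata on the index and the
#' dA normalization mode used.
#'
#' @slot d numeric matrix, samples x samples.
#' @slot index "BC" or "dA".
#' @slot normalization "none", "theoretical" (x / (1 - 1/n)) or
#'   "observed" (min-max over off-diagonal entries).
#' @slot nClipped number of entries clipped into [0, 1] during
#'   normalization (theoretical mode only; logged, see vignette).
#' @export
setClass("SampleDissimilarity",
  slots = c(d = "matrix", index = "character", normalization = "character",
            nClipped = "integer"),
  prototype = prototype(index = "BC", normalization = "none", nClipped = 0L),
  validity = function(object) {
    msg <- .check_square_sym(object@d)
    if (!length(msg)) {
      if (any(object@d < -1e-12) || any(object@d > 1 + 1e-12))
        msg <- c(msg, "dissimilarities must lie in [0, 1]")
      if (is.null(rownames(object@d))) msg <- c(msg, "sample ids required")
    }
    if (!object@index %in% c("BC", "dA")) msg <- c(msg, "index must be BC or dA")
    if (!object@normalization %in% c("none", "theoretical", "observed"))
      msg <- c(msg, "unknown normalization mode")
    if (length(msg)) msg else TRUE
  })

#' Divisive cluster hierarchy of samples
#'
#' Result of the isopam-style divisive clustering: a nested partition of
#' samples over at most \code{maxLevels} levels.  Node labels are path
#' strings ("1", "1.2", "1.2.1", ...) so that the label of a sample at
#' level l is a prefix of its label at level l+1; terminal nodes shallower
#' than a requested level keep their terminal label when the hierarchy is
#' cut.
#'
#' @slot sampleIds character vector of sample ids.
#' @slot assignments character matrix (samples x levels) of node labels.
#' @slot nodes data.frame of per-node diagnostics: id, parent, level, size,
#'   medoid, k_neighbors, n_axes, n_children, quality, stop_reason.
#' @slot maxLevels maximum depth allowed when the hierarchy was built.
#' @export
setClass("AssemblageHierarchy",
  slots = c(sampleIds = "character", assignments = "matrix",
            nodes = "data.frame", maxLevels = "integer"),
  validity = function(object) {
    a <- object@assignments
    msg <- character()
    if (nrow(a) != length(object@sampleIds))
      msg <- c(msg, "one assignment row per sample required")
    if (ncol(a) < 1) msg <- c(msg, "at least one level required")
    if (anyNA(a)) msg <- c(msg, "every sample must be assigned at every level")
    if (ncol(a) > 1) {
      for (l in seq_len(ncol(a) - 1)) {
        # refinement: level-(l+1) labels extend level-l labels
        ok <- startsWith(a[, l + 1], a[, l])
        if (!all(ok)) { msg <- c(msg, "levels must refine their parent"); break }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Indicator species synoptic table
#'
#' Long-format per (species, cluster) indicator statistics at one hierarchy
#' level: within-cluster frequency (%), equalized phi fidelity, one-sided
#' Fisher p-value, plus the species' total frequency over all samples.
#'
#' @slot table data.frame with columns species, cluster, freq, phi, p,
#'   total_freq; sorted by significance then fidelity.
#' @slot level hierarchy level the table was computed at.
#' @slot alpha significance threshold of the headline view.
#' @slot minTotalFreq total-frequency threshold (%) of the headline view.
#' @export
setClass("IndicatorTable",
  slots = c(table = "data.frame", level = "integer", alpha = "numeric",
            minTotalFreq = "numeric"),
  validity = function(object) {
    tb <- object@table
    need <- c("species", "cluster", "freq", "phi", "p", "total_freq")
    msg <- character()
    if (!all(need %in% names(tb)))
      msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
    else {
      if (any(tb$freq < 0 | tb$freq > 100)) msg <- c(msg, "freq must be in [0,100]")
      if (any(tb$phi < -1 - 1e-9 | tb$phi > 1 + 1e-9)) msg <- c(msg, "phi must be in [-1,1]")
      if (any(tb$p <= 0 | tb$p > 1)) msg <- c(msg, "p must be in (0,1]")
    }
    if (length(msg)) msg else TRUE
  })
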