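#' @rdname CommunityMatrix-class
#' @export
setMethod("baMatrix", "CommunityMatrix", function(x) x@ba)

#' @rdname CommunityMatrix-class
#' @export
setMethod("sampleData", "CommunityMatrix", function(x) x@sampleData)

#' @rdname SpeciesDist-class
#' @export
setMethod("distMatrix", "SpeciesDist", function(x) x@d)

#' @rdname SampleDissimilarity-class
#' @export
setMethod("distMatrix", "SampleDissimilarity", function(x) x@d)

#' @rdname SampleDissimilarity-class
#' @export
setMethod("indexName", "SampleDissimilarity", function(x) x@index)

#' @rdname AssemblageHierarchy-class
#' @export
setMethod("assignments", "AssemblageHierarchy", function(x) x@assignments)

#' @rdname AssemblageHierarchy-class
#' @export
setMethod("sampleIds", "AssemblageHierarchy", function(x) x@sampleIds)

#' @rdname AssemblageHierarchy-class
#' @export
setMethod("hierarchyNodes", "AssemblageHierarchy", function(x) x@nodes)

#' @rdname IndicatorTable-class
#' @export
setMethod("indicatorTable", "IndicatorTable", function(x) x@table)

#' Headline indicator view
#'
#' Filters the synoptic table to the highly significant species with
#' sufficient total frequency (defaults p <= .001 and total frequency
#' >= 50%), the criteria used to characterize clusters.
#' @rdname IndicatorTable-class
#' @export
setMethod("headlineIndicators", "IndicatorTable", function(x) {
  tb <- x@table
  tb[tb$p <= x@alpha & tb$total_freq >= x@minTotalFreq, , drop = FALSE]
})

setMethod("show", "CommunityMatrix", function(object) {
  cat("CommunityMatrix:", nrow(object@ba), "samples x", ncol(object@ba),
      "species (mean BA, m²/ha)\n")
  cat("  total BA per sample: mean", round(mean(rowSums(object@ba)), 2),
      " richness: mean", round(mean(rowSums(object@ba > 0)), 2), "\n")
  if (ncol(object@sampleData))
    cat("  sampleData:", paste(names(object@sampleData), collapse = ", "), "\n")
})

setMethod("show", "SpeciesDist", function(object) {
  off <- object@d[upper.tri(object@d)]
  cat("SpeciesDist:", nrow(object@d), "species, normalized cophenetic",
      "distances in (0, 1]\n")
  cat("  range:", round(min(off), 4), "-", round(max(off), 4), "\n")
})

setMethod("show", "SampleDissimilarity", function(object) {
  off <- object@d[upper.tri(object@d)]
  cat("SampleDissimilarity (", object@index, "): ", nrow(object@d),
      " samples, normalization=", object@normalization, "\n", sep = "")
  if (length(off))
    cat("  off-diagonal: min", round(min(off), 3), " mean", round(mean(off), 3),
        " max", round(max(off), 3), "\n")
  if (object@nClipped > 0L)
    cat("  ", object@nClipped, "entries clipped into [0,1]\n")
})

setMethod("show", "AssemblageHierarchy", function(object) {
  L <- ncol(object@assignments)
  counts <- vapply(seq_len(L), function(l)
    length(unique(object@assignments[, l])), integer(1))
  cat("AssemblageHierarchy:", length(object@sampleIds), "samples,",
      L, "levels\n")
  cat("  clusters per level:", paste(counts, collapse = " / "), "\n")
  term <- object@nodes$stop_reason[match(unique(object@assignments[, L]),
                                         object@nodes$id)]
  cat("  terminal assemblages:", counts[L],
      sprintf("(stopped: %s)", paste(sort(unique(term)), collapse = ", ")), "\n")
})

setMethod("show", "IndicatorTable", function(object) {
  cat("IndicatorTable: level", object@level, "-", nrow(object@table),
      "(species, cluster) rows\n")
  hl <- headlineIndicators(object)
  cat("  headline indicators (p <=", object@alpha, ", total freq >=",
      object@minTotalFreq, "%):", nrow(hl), "\n")
})
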