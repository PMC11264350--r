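#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] with up-front syntax checks that
#' report the offending character position (unbalanced parentheses,
#' missing terminating semicolon) and a check that every edge carries a
#' branch length.
#'
#' @param text Newick string, or NULL to read from \code{file}.
#' @param file path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
readNewickTree <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at position ",
         length(chars))
  if (!endsWith(text, ";"))
    stop("Newick parse error: missing ';' at position ", nchar(text))
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error: ape could not parse the string")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("Newick parse error: branch lengths missing")
  tree
}

#' Consolidate infraspecific taxa to their parental species
#'
#' Names containing an infraspecific marker ("subsp.", "ssp.", "var.",
#' "f.") are mapped to the leading genus + epithet binomial; binomials map
#' to themselves.  Underscores are treated as spaces.
#'
#' @param names character vector of taxon names.
#' @return named character vector: original name -> parental binomial.
#' @examples
#' consolidateInfraspecific("Alnus glutinosa subsp. barbata")
#' @export
consolidateInfraspecific <- function(names) {
  stopifnot(length(names) > 0L)
  clean <- gsub("_", " ", names)
  marker <- "\\s+(subsp\\.|ssp\\.|var\\.|f\\.)\\s+.*$"
  parent <- sub(marker, "", clean)
  # keep only genus + epithet of whatever remains
  parent <- vapply(strsplit(parent, "\\s+"), function(w)
    paste(w[seq_len(min(2L, length(w)))], collapse = " "), character(1))
  setNames(parent, names)
}

#' Cophenetic distances between species on a tree
#'
#' Total branch length along the path connecting each pair of species at
#' the tips of the phylogeny.  Species names are matched to tip labels
#' exactly after infraspecific consolidation, with underscores and spaces
#' interchangeable.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param species character vector of species to keep (default: all tips).
#' @return symmetric numeric matrix of raw cophenetic distances, zero
#'   diagonal, in the tree's branch-length units.
#' @export
copheneticDistances <- function(tree, species = NULL) {
  full <- ape::cophenetic.phylo(tree)
  tips <- gsub("_", " ", rownames(full))
  rownames(full) <- colnames(full) <- tips
  if (is.null(species)) return(full)
  wanted <- unname(consolidateInfraspecific(species))
  missing <- setdiff(unique(wanted), tips)
  if (length(missing))
    stop("species not found on the tree: ", paste(missing, collapse = ", "))
  m <- full[wanted, wanted, drop = FALSE]
  dimnames(m) <- list(species, species)
  m
}

#' Normalize a cophenetic distance matrix to (0, 1]
#'
#' Divides every entry by the maximum off-diagonal distance, so the
#' largest interspecies distance is exactly 1.  Scale-invariant and
#' idempotent.
#'
#' @param raw symmetric numeric matrix, zero diagonal, max > 0.
#' @return a [SpeciesDist-class] object.
#' @export
normalizeDistances <- function(raw) {
  msg <- .check_square_sym(raw)
  if (length(msg)) stop("invalid distance matrix: ", paste(msg, collapse = "; "))
  off <- raw[upper.tri(raw)]
  if (length(off) == 0L || max(off) <= 0)
    stop("all distances are zero; cannot normalize")
  new("SpeciesDist", d = raw / max(off))
}

#' @rdname normalizeDistances
#' @param x a [SpeciesDist-class].
#' @param path output CSV path (square matrix with species header row and
#'   column).
#' @export
writeSpeciesDist <- function(x, path) {
  utils::write.csv(data.frame(species = rownames(distMatrix(x)),
                              distMatrix(x), check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Match community-matrix species to the phylogeny
#'
#' Consolidates infraspecific taxa (summing their abundance columns into
#' the parental species), verifies every remaining species is a tree tip,
#' and returns the community matrix together with the normalized species
#' distance matrix in a shared, fixed species order.  Species absent from
#' the tree abort the run unless \code{drop_unmatched} is TRUE, in which
#' case they are dropped and reported.
#'
#' @param community a [CommunityMatrix-class].
#' @param tree an [ape::phylo] tree.
#' @param drop_unmatched drop species missing from the tree instead of
#'   stopping.
#' @return list(community, dist, dropped_species).
#' @export
matchPhylogeny <- function(community, tree, drop_unmatched = FALSE) {
  ba <- baMatrix(community)
  map <- consolidateInfraspecific(colnames(ba))
  if (anyDuplicated(unname(map))) {
    merged <- t(rowsum(t(ba), group = unname(map)))
    ba <- merged[, sort(colnames(merged)), drop = FALSE]
  } else {
    colnames(ba) <- unname(map)
    ba <- ba[, order(colnames(ba)), drop = FALSE]
  }
  tips <- gsub("_", " ", tree$tip.label)
  missing <- setdiff(colnames(ba), tips)
  if (length(missing)) {
    if (!drop_unmatched)
      stop("species not on the tree: ", paste(missing, collapse = ", "),
           " (set drop_unmatched = TRUE to drop them)")
    ba <- ba[, !colnames(ba) %in% missing, drop = FALSE]
    keep <- rowSums(ba > 0) > 0
    ba <- ba[keep, , drop = FALSE]
  }
  raw <- copheneticDistances(tree, colnames(ba))
  sdist <- normalizeDistances(raw)
  cm <- new("CommunityMatrix", ba = ba,
            sampleData = sampleData(community)[rownames(ba), , drop = FALSE])
  list(community = cm, dist = sdist,
       dropped_species = if (length(missing)) sort(missing) else character(0))
}
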