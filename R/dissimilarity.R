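#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC = sum |a_i - b_i| / sum (a_i + b_i), computed on the abundances as
#' given (mean basal area per species).  1 means the samples share no
#' species; 0 means identical composition.
#'
#' @param a,b non-negative abundance vectors in a shared species order.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be >= 0")
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("Bray-Curtis undefined: both samples are empty")
  sum(abs(a - b)) / tot
}

#' Discriminating Avalanche dissimilarity between two samples
#'
#' Weights pairwise differences in relative abundance by the interspecies
#' phylogenetic distance: with p_i the relative frequencies within each
#' sample and Delta_i = |p_i^a - p_i^b|,
#' dA = 1/2 * sum_i sum_j Delta_i d_ij Delta_j  (d_ii = 0).
#' Complete species turnover between phylogenetically close samples thus
#' yields small values, unlike Bray-Curtis.
#'
#' @param a,b non-negative abundance vectors in the species order of
#'   \code{D}.
#' @param D a [SpeciesDist-class] or a symmetric numeric matrix of
#'   normalized interspecies distances.
#' @param relative convert abundances to within-sample relative
#'   frequencies first (the index's definition; default TRUE).
#' @return the raw (unnormalized) dA value.
#' @export
discriminatingAvalanche <- function(a, b, D, relative = TRUE) {
  if (is(D, "SpeciesDist")) D <- distMatrix(D)
  if (length(a) != length(b) || length(a) != nrow(D))
    stop("vectors and distance matrix differ in species dimension")
  if (sum(a) == 0 || sum(b) == 0) stop("dA undefined: empty sample")
  if (relative) { a <- a / sum(a); b <- b / sum(b) }
  delta <- abs(a - b)
  0.5 * as.numeric(crossprod(delta, D %*% delta))
}

#' Normalize a raw Discriminating Avalanche matrix
#'
#' The theoretical mode (default) divides by the maximum attainable raw
#' value 2 * (1 - 1/n) (n = number of species), reached by two samples
#' with disjoint supports, each uniform over half the species, at maximal
#' interspecies distance; a normalized value of 1 therefore means two
#' samples are completely different both compositionally and
#' phylogenetically.  Any numerical excess is clipped into [0, 1] and
#' counted (see the methods vignette for the derivation of the bound).
#' The observed mode applies min-max scaling over the off-diagonal
#' entries, which forces the extremes to 0 and 1 exactly.
#'
#' @param raw symmetric raw dA matrix, zero diagonal.
#' @param n_species number of species behind the matrix (>= 2).
#' @param mode "theoretical" or "observed".
#' @return a [SampleDissimilarity-class] with index "dA".
#' @export
normalizeDA <- function(raw, n_species, mode = c("theoretical", "observed")) {
  mode <- match.arg(mode)
  msg <- .check_square_sym(raw)
  if (length(msg)) stop("invalid raw dA matrix: ", paste(msg, collapse = "; "))
  n_clip <- 0L
  if (mode == "theoretical") {
    if (n_species < 2) stop("n_species must be >= 2")
    x <- raw / (2 * (1 - 1 / n_species))
    n_clip <- sum(x > 1 | x < 0) %/% 2L
    x[x > 1] <- 1
    x[x < 0] <- 0
  } else {
    off <- raw[upper.tri(raw)]
    if (length(off) == 0L || diff(range(off)) == 0)
      stop("observed min-max normalization undefined for a constant matrix")
    x <- (raw - min(off)) / (max(off) - min(off))
    x[x < 0] <- 0
    diag(x) <- 0
  }
  new("SampleDissimilarity", d = x, index = "dA", normalization = mode,
      nClipped = as.integer(n_clip))
}

#' Pairwise sample dissimilarity matrix
#'
#' Applies Bray-Curtis or the Discriminating Avalanche index to every
#' unordered pair of samples of a community matrix.  BC is computed on the
#' raw mean-BA abundances; dA on within-sample relative frequencies and
#' then normalized (see [normalizeDA()]).  Both conventions are
#' switchable.
#'
#' @param community a [CommunityMatrix-class].
#' @param index "BC" or "dA".
#' @param sdist a [SpeciesDist-class] covering the community's species
#'   (required for dA) in the same column order.
#' @param da_norm dA normalization mode.
#' @param bc_relative compute BC on relative frequencies instead of raw
#'   abundances.
#' @param da_relative compute dA on relative frequencies (default TRUE).
#' @return a [SampleDissimilarity-class].
#' @export
pairwiseDissimilarity <- function(community, index = c("BC", "dA"),
                                  sdist = NULL,
                                  da_norm = c("theoretical", "observed"),
                                  bc_relative = FALSE, da_relative = TRUE) {
  index <- match.arg(index)
  m <- baMatrix(community)
  if (index == "BC") {
    if (bc_relative) m <- m / rowSums(m)
    num <- as.matrix(stats::dist(m, method = "manhattan"))
    den <- outer(rowSums(m), rowSums(m), "+")
    d <- num / den
    diag(d) <- 0
    return(new("SampleDissimilarity", d = d, index = "BC",
               normalization = "none", nClipped = 0L))
  }
  if (is.null(sdist)) stop("dA requires a species distance matrix")
  D <- if (is(sdist, "SpeciesDist")) distMatrix(sdist) else sdist
  if (!identical(colnames(m), rownames(D)))
    stop("community matrix and species distances must share species order")
  P <- if (da_relative) m / rowSums(m) else m
  n <- nrow(P)
  raw <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    jj <- (i + 1):n
    Delta <- abs(P[jj, , drop = FALSE] -
                 matrix(P[i, ], length(jj), ncol(P), byrow = TRUE))
    v <- 0.5 * rowSums((Delta %*% D) * Delta)
    raw[i, jj] <- v
    raw[jj, i] <- v
  }
  normalizeDA(raw, n_species = ncol(m), mode = match.arg(da_norm))
}

#' @rdname pairwiseDissimilarity
#' @param x a [SampleDissimilarity-class].
#' @param path output CSV path.
#' @export
writeDissimilarity <- function(x, path) {
  utils::write.csv(data.frame(sample = rownames(distMatrix(x)),
                              distMatrix(x), check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
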