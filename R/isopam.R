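#' Geodesic distances on a k-nearest-neighbour graph
#'
#' Builds the symmetric kNN graph of the samples weighted by the input
#' dissimilarity (union of each sample's k nearest neighbours), bridges
#' disconnected components by their minimum inter-component dissimilarity
#' edge, and returns all-pairs shortest-path distances.  This is the
#' "neighbours of neighbours" geodesic underlying isomap ordination.
#'
#' @param d a [SampleDissimilarity-class] or symmetric matrix.
#' @param k neighbourhood size, 1 <= k < n.
#' @return symmetric geodesic distance matrix.
#' @export
geodesicDistances <- function(d, k) {
  if (is(d, "SampleDissimilarity")) d <- distMatrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples")
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][ord]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  while (length(unique(comp)) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in unique(comp)) {
      ia <- which(comp == a); ib <- which(comp != a)
      sub <- d[ia, ib, drop = FALSE]
      m <- which.min(sub)
      if (sub[m] < best[1]) {
        ri <- (m - 1) %% length(ia) + 1; ci <- (m - 1) %/% length(ia) + 1
        best <- c(sub[m], ia[ri], ib[ci])
      }
    }
    adj[best[2], best[3]] <- adj[best[3], best[2]] <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  w <- d
  w[!adj] <- 0
  gw <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  # zero-weight edges are dropped by 'weighted'; re-add them explicitly
  zero_edges <- which(adj & d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero_edges))
    gw <- igraph::add_edges(gw, t(zero_edges), weight = 0)
  geo <- igraph::distances(gw, algorithm = "dijkstra")
  dimnames(geo) <- dimnames(d)
  geo
}

#' Classical-scaling embedding of a geodesic matrix
#'
#' Double-centers the squared distances, eigendecomposes, and returns the
#' top axes with non-negative eigenvalues, scaled by sqrt(eigenvalue)
#' (isomap's ordination step).  If fewer positive eigenvalues than
#' requested axes exist, the available axes are returned (with a
#' message).  Axis signs follow a deterministic convention: the
#' largest-magnitude loading of each axis is positive.
#'
#' @param geo symmetric geodesic distance matrix.
#' @param n_axes number of ordination axes requested.
#' @return coordinate matrix (samples x axes) with attribute "eig".
#' @export
isomapEmbed <- function(geo, n_axes) {
  n <- nrow(geo)
  stopifnot(n_axes >= 1L, n_axes < n)
  A <- -0.5 * geo^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) == 0L) {
    # all points coincide: one degenerate axis at the origin
    coords <- matrix(0, n, 1, dimnames = list(rownames(geo), NULL))
    attr(coords, "eig") <- e$values
    return(coords)
  }
  if (length(pos) < n_axes)
    message("only ", length(pos), " positive axes available (",
            n_axes, " requested)")
  use <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, use, drop = FALSE] %*%
    diag(sqrt(e$values[use]), length(use))
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(geo)
  attr(coords, "eig") <- e$values
  coords
}

#' Partitioning around medoids (BUILD + SWAP, exact on small instances)
#'
#' Deterministic PAM on a distance matrix: the BUILD phase greedily seeds
#' medoids (first the sample minimizing total distance, then the sample
#' with the largest objective gain), and the SWAP phase exchanges a
#' medoid for a non-medoid while any exchange lowers the objective
#' sum_i d(i, medoid(i)).  BUILD+SWAP is a local search; on small
#' instances (choose(n, k) <= 300 candidate medoid sets) the optimum is
#' found by direct enumeration instead, so small clusters are always
#' partitioned optimally.  All ties break to the lowest sample index /
#' first candidate in enumeration order, so results are reproducible.
#'
#' @param d symmetric distance matrix.
#' @param n_clusters number of clusters, 2 <= n_clusters <= n.
#' @return list with \code{medoids} (sorted indices), \code{assignment}
#'   (cluster number per sample, numbered by ascending medoid index) and
#'   \code{objective}.
#' @export
pamCluster <- function(d, n_clusters) {
  n <- nrow(d)
  k <- as.integer(n_clusters)
  stopifnot(k >= 1L, k <= n)
  if (k == n) {
    return(list(medoids = seq_len(n), assignment = seq_len(n),
                objective = 0))
  }
  if (choose(n, k) <= 300) {
    sets <- utils::combn(n, k)
    objs <- apply(sets, 2, function(s)
      sum(apply(d[, s, drop = FALSE], 1, min)))
    M <- sets[, which.min(objs)]
    Dm <- d[, M, drop = FALSE]
    nearest <- max.col(-Dm, ties.method = "first")
    return(list(medoids = M, assignment = nearest,
                objective = sum(Dm[cbind(seq_len(n), nearest)])))
  }
  # BUILD
  M <- which.min(colSums(d))
  Dnear <- d[, M]
  while (length(M) < k) {
    gains <- colSums(pmax(Dnear - d, 0))
    gains[M] <- -Inf
    M <- c(M, which.max(gains))
    Dnear <- pmin(Dnear, d[, M[length(M)]])
  }
  # SWAP
  repeat {
    Dm <- d[, M, drop = FALSE]
    nearest <- max.col(-Dm, ties.method = "first")
    Dnear <- Dm[cbind(seq_len(n), nearest)]
    Dm2 <- Dm
    Dm2[cbind(seq_len(n), nearest)] <- Inf
    Dsecond <- do.call(pmin, as.data.frame(Dm2))
    H <- setdiff(seq_len(n), M)
    best <- list(delta = -1e-12, m = NA, h = NA)
    for (mi in seq_along(M)) {
      inm <- nearest == mi
      delta_h <- numeric(length(H))
      if (any(inm)) {
        A <- pmin(d[inm, H, drop = FALSE], Dsecond[inm])
        delta_h <- delta_h + colSums(A) - sum(Dnear[inm])
      }
      if (any(!inm)) {
        B <- pmin(d[!inm, H, drop = FALSE] - Dnear[!inm], 0)
        delta_h <- delta_h + colSums(B)
      }
      j <- which.min(delta_h)
      if (delta_h[j] < best$delta) best <- list(delta = delta_h[j],
                                                m = mi, h = H[j])
    }
    if (is.na(best$m)) break
    M[best$m] <- best$h
  }
  M <- sort(unname(M))
  Dm <- d[, M, drop = FALSE]
  nearest <- max.col(-Dm, ties.method = "first")
  list(medoids = M, assignment = nearest,
       objective = sum(Dm[cbind(seq_len(n), nearest)]))
}

#' Indicator-based quality of a candidate split
#'
#' Score of a partition: the sum, over all species whose best one-sided
#' Fisher p across clusters falls below \code{alpha}, of that species'
#' maximum equalized phi across clusters.  A split into clusters with
#' many faithful indicator species scores high; a species present
#' everywhere contributes nothing.
#'
#' @param assignment cluster label per sample (>= 2 clusters, none
#'   empty).
#' @param presence samples x species abundance or presence matrix.
#' @param alpha Fisher significance level.
#' @return non-negative quality score.
#' @export
splitQuality <- function(assignment, presence, alpha = 0.05) {
  if (length(unique(assignment)) < 2L) stop("need >= 2 clusters")
  pc <- .presence_counts(presence, assignment)
  pm <- .fisher_p_matrix(pc)
  phim <- .equalized_phi_matrix(pc)
  sig <- apply(pm, 1, min) < alpha
  if (!any(sig)) return(0)
  sum(apply(phim[sig, , drop = FALSE], 1, max))
}

#' Best split of a set of samples
#'
#' Grid search over neighbourhood size x ordination axes x number of
#' children: geodesic distances, classical-scaling embedding, PAM on the
#' embedded Euclidean distances, and indicator-based scoring of the
#' resulting partition.  Returns the highest-scoring admissible split
#' (every child >= min_cluster_size, at least one significant indicator)
#' or NULL when no candidate qualifies.  Ties keep the first candidate in
#' grid order, so the search is deterministic.
#'
#' @param d dissimilarity matrix of the node's samples.
#' @param presence abundance/presence matrix of the node's samples.
#' @param params an [isopamParams()].
#' @return NULL, or list(assignment, k_neighbors, n_axes, n_children,
#'   medoids, quality).
#' @export
bestSplit <- function(d, presence, params = isopamParams()) {
  n <- nrow(d)
  if (n < 2L * params$min_cluster_size) return(NULL)
  grid <- .resolve_grid(params, n)
  best <- NULL
  for (k in grid$k) {
    geo <- geodesicDistances(d, k)
    coords_full <- suppressMessages(isomapEmbed(geo, max(grid$axes)))
    for (ax in grid$axes) {
      ax_use <- min(ax, ncol(coords_full))
      de <- as.matrix(stats::dist(coords_full[, seq_len(ax_use),
                                              drop = FALSE]))
      for (ch in grid$children) {
        fit <- pamCluster(de, ch)
        sizes <- tabulate(fit$assignment, nbins = ch)
        if (any(sizes < params$min_cluster_size)) next
        q <- splitQuality(fit$assignment, presence,
                          params$alpha_indicator)
        if (q <= 0) next
        if (is.null(best) || q > best$quality)
          best <- list(assignment = fit$assignment, k_neighbors = k,
                       n_axes = ax_use, n_children = ch,
                       medoids = fit$medoids, quality = q)
      }
    }
  }
  best
}

#' Divisive isopam-style cluster hierarchy
#'
#' Recursively applies [bestSplit()] starting from all samples, down to at
#' most \code{max_levels} levels.  Every node records why recursion
#' stopped there ("split" for internal nodes, otherwise "max_depth",
#' "too_small" or "no_indicators"); terminal nodes are the discriminated
#' assemblages.
#'
#' @param d a [SampleDissimilarity-class] (or symmetric matrix) over all
#'   samples.
#' @param community the matching [CommunityMatrix-class] (supplies the
#'   presence structure used to score splits).
#' @param params an [isopamParams()].
#' @return an [AssemblageHierarchy-class].
#' @export
buildHierarchy <- function(d, community, params = isopamParams()) {
  dm <- if (is(d, "SampleDissimilarity")) distMatrix(d) else d
  ba <- baMatrix(community)
  stopifnot(identical(rownames(dm), rownames(ba)))
  ids <- rownames(dm)
  n <- length(ids)
  L <- params$max_levels
  assign_mat <- matrix(NA_character_, n, L,
                       dimnames = list(ids, paste0("level_", seq_len(L))))
  nodes <- list()
  recurse <- function(idx, label, level) {
    node <- list(id = if (label == "") "root" else label,
                 parent = NA_character_, level = level, size = length(idx),
                 medoid = NA_character_, k_neighbors = NA_integer_,
                 n_axes = NA_integer_, n_children = NA_integer_,
                 quality = NA_real_, stop_reason = "split")
    if (label != "")
      node$parent <- if (grepl("\\.", label))
        sub("\\.[0-9]+$", "", label) else "root"
    fill <- if (level < L) (level + 1):L else integer(0)
    stop_here <- function(reason) {
      node$stop_reason <<- reason
      if (level >= 1L) assign_mat[idx, level:L] <<- label
      nodes[[length(nodes) + 1L]] <<- node
    }
    if (level >= L) { stop_here("max_depth"); return(invisible()) }
    if (length(idx) < 2L * params$min_cluster_size) {
      stop_here("too_small")
      return(invisible())
    }
    bs <- bestSplit(dm[idx, idx, drop = FALSE],
                    ba[idx, , drop = FALSE], params)
    if (is.null(bs)) { stop_here("no_indicators"); return(invisible()) }
    node$k_neighbors <- bs$k_neighbors
    node$n_axes <- bs$n_axes
    node$n_children <- bs$n_children
    node$quality <- bs$quality
    nodes[[length(nodes) + 1L]] <- node
    for (j in seq_len(bs$n_children)) {
      child_label <- if (label == "") as.character(j) else
        paste0(label, ".", j)
      child_idx <- idx[bs$assignment == j]
      assign_mat[child_idx, level + 1L] <<- child_label
      med <- ids[idx[bs$medoids[j]]]
      recurse(child_idx, child_label, level + 1L)
      # record the child's medoid on its node entry
      for (q in seq_along(nodes))
        if (nodes[[q]]$id == child_label && is.na(nodes[[q]]$medoid))
          nodes[[q]]$medoid <- med
    }
    invisible()
  }
  recurse(seq_len(n), "", 0L)
  if (anyNA(assign_mat[, 1L])) assign_mat[is.na(assign_mat[, 1L]), ] <- "root"
  nodes_df <- do.call(rbind, lapply(nodes, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  rownames(nodes_df) <- NULL
  new("AssemblageHierarchy", sampleIds = ids, assignments = assign_mat,
      nodes = nodes_df, maxLevels = L)
}

#' Cut a hierarchy at a level
#'
#' Labels every sample by its deepest ancestor node at depth <= level;
#' branches terminating above the requested level keep their terminal
#' label.
#'
#' @param hierarchy an [AssemblageHierarchy-class].
#' @param level 1 <= level <= max levels.
#' @return named character vector of cluster labels.
#' @export
cutAssemblages <- function(hierarchy, level) {
  a <- assignments(hierarchy)
  stopifnot(level >= 1L, level <= ncol(a))
  setNames(a[, level], sampleIds(hierarchy))
}

#' Number of clusters at each hierarchy level
#'
#' @param hierarchy an [AssemblageHierarchy-class].
#' @return integer vector, clusters per level.
#' @export
levelCounts <- function(hierarchy) {
  a <- assignments(hierarchy)
  vapply(seq_len(ncol(a)), function(l) length(unique(a[, l])), integer(1))
}

#' Serialize a hierarchy
#'
#' Writes the flat per-level assignment TSV, a JSON tree of per-node
#' diagnostics, and a Newick-like dendrogram string with node heights
#' equal to level depths.
#'
#' @param hierarchy an [AssemblageHierarchy-class].
#' @param prefix output path prefix; writes \code{<prefix>_levels.tsv}
#'   and \code{<prefix>_nodes.json}.
#' @return the Newick-like dendrogram string, invisibly.
#' @export
writeHierarchy <- function(hierarchy, prefix) {
  a <- assignments(hierarchy)
  utils::write.table(data.frame(sample_id = sampleIds(hierarchy), a,
                                check.names = FALSE),
                     paste0(prefix, "_levels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(hierarchyNodes(hierarchy),
                       paste0(prefix, "_nodes.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  nwk <- paste0(hierarchyNewick(hierarchy), ";")
  writeLines(nwk, paste0(prefix, "_dendrogram.nwk"))
  invisible(nwk)
}

#' @rdname writeHierarchy
#' @export
hierarchyNewick <- function(hierarchy) {
  nd <- hierarchyNodes(hierarchy)
  L <- hierarchy@maxLevels
  build <- function(id, level) {
    kids <- nd$id[!is.na(nd$parent) & nd$parent == id]
    if (length(kids) == 0L)
      return(sprintf("%s:%d", gsub("[ ,():;]", "_", id), L + 1L - level))
    inner <- paste(vapply(kids, function(k) build(k, level + 1L),
                          character(1)), collapse = ",")
    sprintf("(%s)%s:%d", inner, gsub("[ ,():;]", "_", id),
            if (level == 0L) 0L else L + 1L - level)
  }
  build("root", 0L)
}
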