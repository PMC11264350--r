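# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the package's own code paths.

toy_newick <- "((A:1,B:1):2,C:3);"

# Bray-Curtis by the literal formula, scalar loop
bc_loop <- function(a, b) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + abs(a[i] - b[i])
    den <- den + a[i] + b[i]
  }
  num / den
}

# raw Discriminating Avalanche by the literal double loop
da_loop <- function(a, b, D) {
  pa <- a / sum(a); pb <- b / sum(b)
  s <- 0
  for (i in seq_along(a))
    for (j in seq_along(a))
      s <- s + abs(pa[i] - pb[i]) * D[i, j] * abs(pa[j] - pb[j])
  s / 2
}

# exhaustive PAM optimum: best medoid set over all combinations
pam_exhaustive <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  sets <- utils::combn(n, k)
  for (s in seq_len(ncol(sets))) {
    obj <- sum(apply(d[, sets[, s], drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# exact one-sided Fisher p by enumeration of all equally likely subsets:
# among C(N, K) placements of the K presences, the fraction with at least
# `a` inside the n1 cluster samples
fisher_enum <- function(N, n1, K, a) {
  if (K == 0) return(if (a <= 0) 1 else 0)
  sets <- utils::combn(N, K)
  hits <- colSums(sets <= n1)   # samples 1..n1 form the cluster
  mean(hits >= a)
}

# adjusted Rand from explicit pair counting
ari_pairs <- function(p1, p2) {
  n <- length(p1)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
      if (s1 && s2) a <- a + 1
      else if (s1 && !s2) b <- b + 1
      else if (!s1 && s2) cc <- cc + 1
      else d <- d + 1
    }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(NaN)
  2 * (a * d - b * cc) / den
}

# all set partitions of n items as label vectors (restricted growth)
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    pos <- length(labels) + 1L
    if (pos > n) { out[[length(out) + 1L]] <<- labels; return() }
    for (v in seq_len(mx + 1L)) rec(c(labels, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# small community matrix with block structure: n_per samples per group,
# each group holding its own species set (perfect indicators)
block_community <- function(n_groups = 3, n_per = 4, sp_per = 3,
                            ba = 10) {
  n <- n_groups * n_per
  S <- n_groups * sp_per
  m <- matrix(0, n, S,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("sp%02d", 1:S)))
  for (g in seq_len(n_groups)) {
    rows <- ((g - 1) * n_per + 1):(g * n_per)
    cols <- ((g - 1) * sp_per + 1):(g * sp_per)
    m[rows, cols] <- ba
  }
  new("CommunityMatrix", ba = m, sampleData = data.frame(row.names = rownames(m)))
}

# random abundance matrix with guaranteed nonzero rows
random_community <- function(n, S, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * S) * stats::rbinom(n * S, 1, 0.5), n, S,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("sp%02d", 1:S)))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(S, sum(empty), replace = TRUE))] <- 1
  m
}

# minimal clean stem table: one cluster, three subplots
clean_stems <- function(cluster_id = "C1",
                        species = c("Fagus orientalis", "Picea orientalis",
                                    "Carpinus betulus"),
                        dbh = c(30, 20, 12), status = rep("living", 3)) {
  data.frame(cluster_id = cluster_id, subplot_id = 1:3,
             species = species, dbh_cm = dbh, status = status,
             landuse_class = "Forest", slopover_flag = FALSE,
             stringsAsFactors = FALSE)
}
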