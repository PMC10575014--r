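# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementations.

# Brute-force DBSCAN by density reachability: core points are found by
# counting closed-ball neighbors, clusters are connected components of
# the core-core reachability graph (igraph), components are ordered by
# their smallest core index, and border points join the earliest
# component owning a core neighbor.
dbscanOracle <- function(Y, eps, minPts) {
  n <- nrow(Y)
  D <- as.matrix(dist(Y))
  A <- D <= eps
  core <- which(rowSums(A) >= minPts)
  cl <- integer(n)
  if (length(core)) {
    sub <- A[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # order components by smallest core index so ids match creation order
    firstIdx <- tapply(seq_along(core), comp, function(i) min(core[i]))
    rank <- rank(firstIdx)
    compId <- as.integer(rank[as.character(comp)])
    cl[core] <- compId
    border <- setdiff(which(rowSums(A[, core, drop = FALSE]) > 0), core)
    for (b in border) {
      owners <- compId[A[b, core]]
      cl[b] <- min(owners)
    }
  }
  cl
}

# From-scratch NMI via explicit entropy arithmetic on the contingency
# table (arithmetic-mean normalization, natural log).
nmiOracle <- function(a, b) {
  tab <- as.matrix(table(a, b))
  n <- sum(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- H(rowSums(tab) / n)
  hy <- H(colSums(tab) / n)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0)
      mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  mi / ((hx + hy) / 2)
}

# Two well-separated Gaussian clouds in feature space (243-D by default)
makeGaussianFeatures <- function(n1, n2, p = 243, sep = 20, seed = 42) {
  set.seed(seed)
  mu <- rep(0, p)
  mu[1] <- sep
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p), n2, p) + rep(mu, each = n2))
  list(X = X, group = rep(c(1L, 2L), c(n1, n2)))
}

# 1-nearest-neighbor class purity in a 2-D map
knnPurity <- function(Y, group) {
  D <- as.matrix(dist(Y))
  diag(D) <- Inf
  mean(group[apply(D, 1L, which.min)] == group)
}

# tiny recording CSV writers for ingest tests
writeRecordingCsv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
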