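# small builders and independent oracles shared across test files

make_table <- function(values, site = "gut", mode = "counts",
                       taxonomy = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("t%02d", seq_len(ncol(values)))
  }
  abundance_table(values, site = site, mode = mode, taxonomy = taxonomy)
}

# random relative-abundance table via independent gamma draws
random_rel_table <- function(n, t, seed, site = "gut") {
  set.seed(seed)
  m <- matrix(rgamma(n * t, shape = 0.7), n, t)
  m <- m / rowSums(m)
  make_table(m, site = site, mode = "relative")
}

# distance matrix from 1-D or 2-D coordinates
coord_dist <- function(x) {
  m <- as.matrix(dist(as.matrix(x)))
  rownames(m) <- colnames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  dist_matrix(m, metric = "euclidean")
}

# exhaustive k-medoids oracle: all medoid sets, minimal cost
brute_pam <- function(d, k) {
  d <- if (inherits(d, "dist_matrix")) d$values else as.matrix(d)
  sets <- utils::combn(nrow(d), k)
  costs <- apply(sets, 2, function(s) {
    sum(apply(d[, s, drop = FALSE], 1, min))
  })
  best <- min(costs)
  list(cost = best,
       medoid_sets = lapply(which(costs <= best + 1e-9),
                            function(j) sets[, j]))
}

# centroid-form Calinski-Harabasz oracle for Euclidean coordinates
ch_centroid <- function(coords, labels) {
  coords <- as.matrix(coords)
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(coords)
  centroids <- rowsum(coords, f) / as.integer(table(f))
  overall <- colMeans(coords)
  B <- sum(as.integer(table(f)) *
             rowSums(sweep(centroids, 2, overall)^2))
  W <- sum((coords - centroids[as.integer(f), , drop = FALSE])^2)
  (B / (k - 1)) / (W / (n - k))
}

# orthogonal-Procrustes residual after centring (no scaling): how far a
# recovered configuration is from the original up to rotation/reflection
procrustes_error <- function(x, y) {
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  if (ncol(y) < ncol(x)) y <- cbind(y, matrix(0, nrow(y), ncol(x) - ncol(y)))
  if (ncol(x) < ncol(y)) x <- cbind(x, matrix(0, nrow(x), ncol(y) - ncol(x)))
  s <- svd(crossprod(y, x))
  rot <- s$u %*% t(s$v)
  sqrt(sum((y %*% rot - x)^2))
}

# partition agreement ignoring label names
same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) == 1
}
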