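#' Calinski-Harabasz index from a distance matrix
#'
#' Distance form needing no coordinates: with squared distances
#' \eqn{d^2_{ij}}, the within-cluster dispersion is
#' \eqn{W = \sum_c \frac{1}{2 n_c} \sum_{i,j \in c} d^2_{ij}} (ordered
#' pairs), the total \eqn{T = \frac{1}{2n} \sum_{i,j} d^2_{ij}}, the
#' between-cluster part \eqn{B = T - W}, and
#' \eqn{CH = (B/(k-1)) / (W/(n-k))}. For Euclidean distances this equals
#' the classical centroid-based index.
#'
#' @param dist A `dist_matrix` or square symmetric matrix.
#' @param labels Integer/factor cluster assignment per sample.
#' @return The CH value; `Inf` when all within-cluster distances vanish.
#' @export
ch_index <- function(dist, labels) {
  d <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2 || k > n - 1) {
    stop("ch_index requires 2 <= k <= n - 1 non-empty clusters",
         call. = FALSE)
  }
  d2 <- d^2
  W <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    W <- W + sum(d2[idx, idx]) / (2 * length(idx))
  }
  T <- sum(d2) / (2 * n)
  B <- T - W
  if (W <= 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette widths from a distance matrix
#'
#' For each sample, \eqn{s_i = (b_i - a_i)/\max(a_i, b_i)} where
#' \eqn{a_i} is the mean distance to its own cluster (excluding itself)
#' and \eqn{b_i} the smallest mean distance to another cluster. Members
#' of singleton clusters get \eqn{s_i = 0}, as do samples with
#' \eqn{a_i = b_i = 0}.
#'
#' @param dist A `dist_matrix` or square symmetric matrix.
#' @param labels Cluster assignment per sample (at least 2 clusters).
#' @return List with `widths` (per-sample values) and `mean`.
#' @export
silhouette_widths <- function(dist, labels) {
  d <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters", call. = FALSE)
  sizes <- tabulate(labels, k)
  # mean distance from every sample to every cluster
  agg <- vapply(seq_len(k), function(c) rowSums(d[, labels == c, drop = FALSE]),
                numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    c <- labels[i]
    if (sizes[c] == 1) { s[i] <- 0; next }
    a <- agg[i, c] / (sizes[c] - 1)
    b <- min(agg[i, -c] / sizes[-c])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  names(s) <- rownames(d)
  list(widths = s, mean = mean(s))
}

#' Choose the number of community types by the Calinski-Harabasz index
#'
#' Runs PAM for every `k` in `k_range` and keeps the clustering maximizing
#' the CH index; ties go to the smaller `k`.
#'
#' @param dist A `dist_matrix`.
#' @param k_range Integer vector of candidate cluster numbers, within
#'   `[2, n - 1]`. Default `2:6`.
#' @return List with `k`, `labels`, `medoids`, `medoid_idx`, `cost`,
#'   `ch_by_k` (named vector over the searched range), and `silhouette`
#'   (per-sample widths and mean for the chosen clustering).
#' @export
select_k <- function(dist, k_range = 2:6) {
  d <- if (inherits(dist, "dist_matrix")) dist else
    dist_matrix(as.matrix(dist))
  n <- length(d$ids)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k range", call. = FALSE)
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop("k range must lie within [2, n - 1]", call. = FALSE)
  }
  fits <- lapply(k_range, function(k) pam_medoids(d, k))
  ch <- vapply(fits, function(f) ch_index(d, f$labels), numeric(1))
  names(ch) <- as.character(k_range)
  best <- which.max(ch) # first max -> smaller k on ties
  fit <- fits[[best]]
  list(k = k_range[best], labels = fit$labels, medoids = fit$medoids,
       medoid_idx = fit$medoid_idx, cost = fit$cost, ch_by_k = ch,
       silhouette = silhouette_widths(d, fit$labels))
}

#' Permutation null test for clustering significance
#'
#' The observed statistic is the mean silhouette width of the CH-optimal
#' clustering of the table's sqrt-JSD distances. Null datasets are formed
#' by independently permuting each taxon column across samples — this
#' destroys inter-taxon structure while preserving every taxon's marginal
#' distribution — and the identical select-k pipeline is applied to each.
#' The p-value is `(1 + #(null >= observed)) / (1 + n_null)`.
#'
#' @param table An `abundance_table` in `relative` mode.
#' @param k_range Candidate cluster numbers, default `2:6`.
#' @param n_null Number of null datasets, at least 19 (default 99).
#' @param seed Integer seed making the permutations reproducible.
#' @return List with `p`, `observed` (mean silhouette), `null` (vector of
#'   null statistics), `k` (chosen on the observed data).
#' @export
null_silhouette_test <- function(table, k_range = 2:6, n_null = 99,
                                 seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (n_null < 19) stop("`n_null` must be at least 19", call. = FALSE)
  x <- table$values
  sel <- select_k(jsd_distance_matrix(table), k_range)
  observed <- sel$silhouette$mean
  n <- nrow(x)
  null_stats <- numeric(n_null)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (b in seq_len(n_null)) {
    xp <- apply(x, 2, function(col) col[sample.int(n)])
    rownames(xp) <- rownames(x)
    dp <- dist_matrix(sqrt(pmax(jsd_matrix_raw(xp), 0)), metric = "jsd_sqrt")
    selp <- select_k(dp, k_range)
    null_stats[b] <- selp$silhouette$mean
  }
  list(p = (1 + sum(null_stats >= observed)) / (1 + n_null),
       observed = observed, null = null_stats, k = sel$k)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
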