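#' Partitioning around medoids (PAM) on a distance matrix
#'
#' Classical k-medoids: the BUILD phase greedily seeds `k` medoids, the
#' SWAP phase exchanges medoids with non-medoids until no single swap
#' lowers the total distance of samples to their nearest medoid. The full
#' swap neighbourhood is searched each iteration and all ties are broken
#' toward the lowest sample index, so the result is deterministic given
#' the distance matrix.
#'
#' Steepest-descent SWAP is a local search; on very small instances
#' (fewer than 500 candidate medoid sets) the objective is instead
#' minimized exactly by enumeration — the global optimum is itself a
#' swap-stable solution, and enumeration is cheaper than SWAP there.
#'
#' @param dist A `dist_matrix` (or square symmetric numeric matrix).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return List with `medoids` (ids), `medoid_idx`, `labels` (integer
#'   cluster per sample, clusters numbered in ascending medoid index
#'   order, named by sample id), and `cost` (total distance to nearest
#'   medoid).
#' @export
pam_medoids <- function(dist, k) {
  d <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  if (k < 1 || k > n) stop("`k` must be between 1 and n", call. = FALSE)
  if (k == n) {
    med <- seq_len(n)
  } else if (choose(n, k) <= 500) {
    # exact minimization; combn order makes ties lexicographic
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, function(s) {
      sum(apply(d[, s, drop = FALSE], 1, min))
    })
    med <- sets[, which.min(costs)]
  } else {
    # BUILD: start from the 1-medoid optimum, then add the medoid giving
    # the largest cost reduction; ties to the lowest index.
    med <- which.min(colSums(d))
    dmin <- d[, med]
    while (length(med) < k) {
      gains <- colSums(pmax(dmin - d, 0))
      gains[med] <- -Inf
      nxt <- which.max(gains)
      med <- c(med, nxt)
      dmin <- pmin(dmin, d[, nxt])
    }
    med <- sort(med)
    # SWAP: full neighbourhood, steepest descent, deterministic ties.
    repeat {
      dm <- d[, med, drop = FALSE]
      near <- apply(dm, 1, which.min)
      d1 <- dm[cbind(seq_len(n), near)]
      d2 <- if (length(med) > 1) {
        apply(dm, 1, function(r) sort(r, partial = 2)[2])
      } else rep(Inf, n)
      cost <- sum(d1)
      best <- list(cost = cost - 1e-12, m = NA, h = NA)
      nonmed <- setdiff(seq_len(n), med)
      for (mi in seq_along(med)) {
        dropped <- ifelse(near == mi, d2, d1)
        for (h in nonmed) {
          newcost <- sum(pmin(dropped, d[, h]))
          if (newcost < best$cost) best <- list(cost = newcost, m = mi, h = h)
        }
      }
      if (is.na(best$m)) break
      med[best$m] <- best$h
      med <- sort(med)
    }
  }
  dm <- d[, med, drop = FALSE]
  labels <- apply(dm, 1, which.min)
  cost <- sum(dm[cbind(seq_len(n), labels)])
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  list(medoids = ids[med], medoid_idx = med,
       labels = stats::setNames(as.integer(labels), ids), cost = cost)
}
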