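#' Construct a labelled distance matrix
#'
#' Light wrapper around a symmetric base matrix carrying the sample (or
#' taxon) ids and the name of the metric that produced it.
#'
#' @param values Square numeric matrix, symmetric within `1e-12`, zero
#'   diagonal, non-negative, with identical row and column names.
#' @param metric Name of the metric, e.g. `"jsd_sqrt"`.
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(values, metric = "unknown") {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("`values` must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("obj", seq_len(nrow(values)))
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column names must match", call. = FALSE)
  }
  if (any(values < 0)) stop("distances must be non-negative", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix not symmetric within 1e-12", call. = FALSE)
  }
  if (any(abs(diag(values)) > 1e-12)) {
    stop("diagonal must be zero", call. = FALSE)
  }
  diag(values) <- 0
  structure(list(values = values, ids = rownames(values), metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d x %d (%s)\n", length(x$ids), length(x$ids),
              x$metric))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Shannon entropy of a probability vector (nats)
#'
#' \eqn{H(p) = -\sum_i p_i \ln p_i}, with the convention
#' \eqn{0 \cdot \ln 0 = 0}.
#'
#' @param p Non-negative numeric vector summing to 1 within `1e-9`.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("probabilities must sum to 1 (got %.12g)", sum(p)),
         call. = FALSE)
  }
  -sum(xlogx(p))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Jensen-Shannon divergence between two distributions (nats)
#'
#' \eqn{JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2}; symmetric and bounded
#' by \eqn{\ln 2}. Inputs are regularized by a `1e-10` pseudocount and
#' renormalized so zero abundances are handled gracefully.
#'
#' @param p,q Non-negative numeric vectors of equal length.
#' @return The divergence in nats, in `[0, log(2)]`.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) {
    stop("`p` and `q` must have the same length", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  p <- regularize_prob(p)
  q <- regularize_prob(q)
  m <- (p + q) / 2
  h <- function(x) -sum(xlogx(x))
  max(h(m) - (h(p) + h(q)) / 2, 0)
}

regularize_prob <- function(p, pseudocount = 1e-10) {
  p <- p + pseudocount
  p / sum(p)
}

#' Square-root Jensen-Shannon distance matrix over samples
#'
#' The clustering distance of the typing engine: entry (i, j) is
#' \eqn{\sqrt{JSD(p_i', p_j')}} where each relative-abundance profile gets
#' a `1e-10` pseudocount and is renormalized. The square root of JSD is a
#' true metric (triangle inequality holds), unlike JSD itself.
#'
#' @param table An `abundance_table` in `relative` mode (rows need not sum
#'   exactly to one if low-abundance taxa were filtered; the internal
#'   renormalization restores distributions), or a bare numeric matrix of
#'   non-negative profiles.
#' @return A `dist_matrix` with metric `"jsd_sqrt"`.
#' @export
jsd_distance_matrix <- function(table) {
  if (inherits(table, "abundance_table")) {
    if (table$mode != "relative") {
      stop("jsd_distance_matrix() requires a relative-mode table",
           call. = FALSE)
    }
    x <- table$values
  } else {
    x <- as.matrix(table)
  }
  if (nrow(x) < 3) {
    stop("need at least 3 samples to build a clustering distance matrix",
         call. = FALSE)
  }
  d <- jsd_matrix_raw(x)
  dist_matrix(sqrt(pmax(d, 0)), metric = "jsd_sqrt")
}

# Pairwise JSD over the rows of a non-negative matrix (internal; used by
# the null-simulation path where permuted rows no longer sum to one).
jsd_matrix_raw <- function(x) {
  p <- x + 1e-10
  p <- p / rowSums(p)
  hrow <- -rowSums(xlogx(p))
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    m <- (p[idx, , drop = FALSE] + rep(p[i, ], each = length(idx))) / 2
    hm <- -rowSums(xlogx(m))
    v <- hm - (hrow[idx] + hrow[i]) / 2
    d[i, idx] <- d[idx, i] <- pmax(v, 0)
  }
  d
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' \eqn{BC(i,j) = 1 - 2\sum_k \min(x_{ik}, x_{jk}) / (\sum_k x_{ik} +
#' \sum_k x_{jk})}, computed through `vegan::vegdist`.
#'
#' @param table An `abundance_table` (counts or relative).
#' @return A `dist_matrix` with metric `"bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  zero <- which(rowSums(x) == 0)
  if (length(zero)) {
    stop("zero-sum sample(s): ",
         paste(rownames(x)[zero], collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dist_matrix(d, metric = "bray_curtis")
}

#' Euclidean distances between taxon profiles across both sites
#'
#' Treats each taxon-at-a-site as an object whose coordinates are its
#' abundances across the paired subjects, and returns all pairwise
#' Euclidean distances in the joint gut+oral profile space (the input to
#' the cross-site average-linkage heatmap).
#'
#' @param x,y `abundance_table`s (typically core-filtered gut and oral
#'   tables) over the same subjects in the same order.
#' @return A `dist_matrix` over `site|taxon` labels, metric
#'   `"euclidean"`.
#' @export
euclidean_profile_distance <- function(x, y) {
  stopifnot(inherits(x, "abundance_table"), inherits(y, "abundance_table"))
  if (nrow(x$values) != nrow(y$values)) {
    stop("tables must cover the same number of paired samples",
         call. = FALSE)
  }
  profiles <- rbind(t(x$values), t(y$values))
  rownames(profiles) <- c(paste0(x$site, "|", colnames(x$values)),
                          paste0(y$site, "|", colnames(y$values)))
  d <- as.matrix(stats::dist(profiles, method = "euclidean"))
  dist_matrix(d, metric = "euclidean")
}
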