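#' Spearman correlation grid with BH adjustment
#'
#' Rank correlations (mid-ranks for ties) between every column of `x` and
#' every column of `y`, two-sided p-values from the t approximation
#' (appropriate at cohort sizes of tens of subjects), and
#' Benjamini-Hochberg adjustment across all pairs tested in the call.
#' Constant columns give undefined correlations; these entries are
#' recorded as `NA` and reported via a message.
#'
#' @param x,y Numeric matrices (observations x variables) with equal row
#'   counts and aligned observation order, or `abundance_table`s.
#' @param flag_adjusted Mark significance on BH-adjusted p-values
#'   (default `TRUE`); set `FALSE` to flag on raw p.
#' @return A `correlation_result`: list with `rho`, `p`, `p_adjusted`
#'   (matrices, rows = columns of `x`, cols = columns of `y`), `flags`
#'   (`""`, `"*"` p < 0.05, `"**"` p < 0.01) and `n` (observations).
#' @export
spearman_matrix <- function(x, y = x, flag_adjusted = TRUE) {
  xm <- if (inherits(x, "abundance_table")) x$values else as.matrix(x)
  ym <- if (inherits(y, "abundance_table")) y$values else as.matrix(y)
  if (nrow(xm) != nrow(ym)) {
    stop("`x` and `y` must have the same observations", call. = FALSE)
  }
  n <- nrow(xm)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  const_x <- apply(xm, 2, function(v) length(unique(v)) == 1)
  const_y <- apply(ym, 2, function(v) length(unique(v)) == 1)
  if (any(const_x) || any(const_y)) {
    message("spearman_matrix: constant column(s), correlations recorded as NA: ",
            paste(c(colnames(xm)[const_x], colnames(ym)[const_y]),
                  collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(xm, ym, method = "spearman"))
  rho[const_x, ] <- NA_real_
  rho[, const_y] <- NA_real_
  p <- spearman_p(rho, n)
  padj <- p
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  pf <- if (flag_adjusted) padj else p
  flags <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  flags[!is.na(pf) & pf < 0.05] <- "*"
  flags[!is.na(pf) & pf < 0.01] <- "**"
  structure(list(rho = rho, p = p, p_adjusted = padj, flags = flags, n = n),
            class = "correlation_result")
}

# two-sided p from the t approximation t = rho * sqrt((n-2)/(1-rho^2))
spearman_p <- function(rho, n) {
  p <- rho
  r <- pmin(pmax(rho, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  exact <- !is.na(r) & abs(r) >= 1 - 1e-15
  tt[exact] <- Inf * sign(r[exact])
  p[] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.na(rho)] <- NA_real_
  p
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d x %d Spearman grid over n = %d observations\n",
              nrow(x$rho), ncol(x$rho), x$n))
  cat(sprintf("  BH-significant at 0.05: %d of %d tested pairs\n",
              sum(x$p_adjusted < 0.05, na.rm = TRUE),
              sum(!is.na(x$p_adjusted))))
  invisible(x)
}

#' Cross-site correlation of each core taxon with itself
#'
#' For every taxon of the shared core, the Spearman correlation between
#' its gut and its oral relative abundances across the paired subjects —
#' the statistic behind "the same genus is positively correlated between
#' the two sites". Raw and BH-adjusted p-values are reported; a taxon
#' constant at either site is returned with `NA` and noted in a message.
#'
#' @param cohort A `paired_cohort` (counts are converted internally).
#' @param core A `core_set` (or a character vector of taxon ids).
#' @return Data frame with columns `taxon`, `rho`, `p`, `p_adjusted`,
#'   `significant` (BH < 0.05).
#' @export
same_taxon_cross_site <- function(cohort, core) {
  stopifnot(inherits(cohort, "paired_cohort"))
  taxa <- if (inherits(core, "core_set")) core$core else as.character(core)
  if (!length(taxa)) stop("empty core", call. = FALSE)
  g <- to_relative(cohort$gut)$values
  o <- to_relative(cohort$oral)$values
  taxa <- taxa[taxa %in% colnames(g) & taxa %in% colnames(o)]
  rho <- p <- rep(NA_real_, length(taxa))
  for (i in seq_along(taxa)) {
    gv <- g[, taxa[i]]; ov <- o[, taxa[i]]
    if (length(unique(gv)) == 1 || length(unique(ov)) == 1) {
      message("same_taxon_cross_site: '", taxa[i],
              "' constant at one site; recorded as NA")
      next
    }
    rho[i] <- stats::cor(gv, ov, method = "spearman")
    p[i] <- spearman_p(rho[i], nrow(g))
  }
  padj <- rep(NA_real_, length(taxa))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(taxon = taxa, rho = rho, p = p, p_adjusted = padj,
             significant = !is.na(padj) & padj < 0.05,
             stringsAsFactors = FALSE)
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' Agglomerates with `stats::hclust(method = "average")`; merge heights
#' are non-decreasing and the leaf order is recorded for heatmap export.
#'
#' @param dist A `dist_matrix`.
#' @return List with `hclust` (the fitted tree), `merge`, `height`,
#'   `order` and `labels`.
#' @export
average_linkage <- function(dist) {
  d <- if (inherits(dist, "dist_matrix")) dist else dist_matrix(as.matrix(dist))
  if (length(d$ids) < 2) stop("need at least 2 objects", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d$values), method = "average")
  list(hclust = hc, merge = hc$merge, height = hc$height,
       order = hc$order, labels = hc$labels)
}

#' Write a dendrogram as merge-list TSV and Newick
#'
#' @param dend Result of [average_linkage()].
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"dendrogram"`.
#' @return Written paths, invisibly.
#' @export
write_dendrogram <- function(dend, dir, prefix = "dendrogram") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(prefix, "_merges.tsv"))
  utils::write.table(
    data.frame(step = seq_along(dend$height), left = dend$merge[, 1],
               right = dend$merge[, 2], height = dend$height),
    mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  npath <- file.path(dir, paste0(prefix, ".nwk"))
  ape::write.tree(ape::as.phylo(dend$hclust), file = npath)
  invisible(c(mpath, npath))
}

#' Principal coordinates analysis
#'
#' Gower double-centring and eigen-decomposition of the distance matrix
#' (through `stats::cmdscale`). Axes are built from positive eigenvalues
#' only; negative eigenvalues (possible for non-Euclidean
#' dissimilarities like Bray-Curtis) are reported, not used.
#'
#' @param dist A `dist_matrix`.
#' @param n_axes Number of axes requested, default 3.
#' @return List with `coordinates` (n x axes), `eigenvalues` (all n,
#'   including negatives) and `explained` (fraction of positive-eigenvalue
#'   inertia per returned axis; sums to at most 1).
#' @export
pcoa <- function(dist, n_axes = 3) {
  d <- if (inherits(dist, "dist_matrix")) dist else dist_matrix(as.matrix(dist))
  n <- length(d$ids)
  if (n < n_axes + 1) stop("need at least n_axes + 1 samples", call. = FALSE)
  if (all(d$values == 0)) stop("all-zero distance matrix", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(d$values), k = n_axes, eig = TRUE)
  coords <- fit$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos <- pmax(fit$eig, 0)
  list(coordinates = coords, eigenvalues = fit$eig,
       explained = pos[seq_len(ncol(coords))] / sum(pos))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: with squared distances,
#' \eqn{SS_{total} = \frac{1}{n}\sum_{i<j} d^2_{ij}},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}}, and
#' pseudo-\eqn{F = (SS_{between}/(k-1)) / (SS_{within}/(n-k))}. The
#' p-value comes from free label permutation:
#' `(1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param dist A `dist_matrix`.
#' @param groups Group labels per sample (at least 2 non-empty groups).
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer seed for the permutations.
#' @return List with `pseudo_F`, `p`, `df` (`c(k - 1, n - k)`), and the
#'   observed `ss_between`/`ss_within`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  f <- factor(groups)
  if (length(f) != n) stop("`groups` length must match samples", call. = FALSE)
  if (nlevels(f) < 2 || any(table(f) < 1)) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  k <- nlevels(f)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  within <- function(lab) {
    s <- 0
    for (g in levels(f)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  fstat <- function(lab) {
    ssw <- within(lab)
    ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- fstat(f)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  exceed <- 0
  for (b in seq_len(n_perm)) {
    if (fstat(f[sample.int(n)]) >= f_obs) exceed <- exceed + 1
  }
  ssw <- within(f)
  list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm),
       df = as.integer(c(k - 1, n - k)), ss_between = ss_total - ssw,
       ss_within = ssw)
}

#' Kruskal-Wallis comparison across community types
#'
#' Wraps `stats::kruskal.test` (mid-rank ties correction, chi-square
#' reference with k - 1 degrees of freedom) and attaches per-group
#' summaries. Fully degenerate input (all values identical) is reported
#' as H = 0, p = 1 rather than an error.
#'
#' @param values Numeric vector of per-subject measurements.
#' @param groups Group (type) labels, at least 2 non-empty groups.
#' @param variable Name of the measured variable, for reporting.
#' @return A `group_comparison`: list with `variable`, `groups`
#'   (levels), `H`, `df`, `p`, `group_means`, `group_medians`, `n`.
#' @export
kruskal_wallis <- function(values, groups, variable = "value") {
  f <- factor(groups)
  if (nlevels(f) < 2 || any(table(f) < 1)) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (length(values) != length(f)) {
    stop("`values` and `groups` lengths differ", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, f)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(variable = variable, groups = levels(f), H = H,
                 df = nlevels(f) - 1L, p = p,
                 group_means = tapply(values, f, mean),
                 group_medians = tapply(values, f, stats::median),
                 n = as.integer(table(f))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on '%s': H = %.4g, df = %d, p = %.4g\n",
              x$variable, x$H, x$df, x$p))
  invisible(x)
}

#' Export a correlation grid (and its 1 - rho distance) as TSV
#'
#' Writes the rho, raw-p, adjusted-p and flag matrices, plus `1 - rho`
#' labelled explicitly as a correlation-derived distance for heatmap
#' tools that expect one.
#'
#' @param cr A `correlation_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Written paths, invisibly.
#' @export
write_correlation <- function(cr, dir, prefix = "correlation") {
  stopifnot(inherits(cr, "correlation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, what) {
    p <- file.path(dir, paste0(prefix, "_", what, ".tsv"))
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wr(cr$rho, "rho"), wr(cr$p, "p"), wr(cr$p_adjusted, "p_adjusted"),
             wr(cr$flags, "flags"), wr(1 - cr$rho, "one_minus_rho_distance"))
  invisible(paths)
}
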