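#' Between-class analysis of abundance profiles
#'
#' Supervised ordination of the class (community-type) means: the data are
#' column-centred (optionally scaled), the class-size-weighted covariance
#' of the class means is eigen-decomposed, and all samples are projected
#' onto the resulting axes. At most `k - 1` axes carry variance. The
#' between-class inertia ratio — the share of total inertia explained by
#' the class means — summarizes how well the typing separates profiles.
#'
#' @param table An `abundance_table` in `relative` mode (or a bare numeric
#'   matrix, samples x taxa).
#' @param labels Class assignment per sample.
#' @param scale Scale columns to unit variance before the analysis
#'   (default `FALSE`: centring only).
#' @return A `bca_result`: list with `axes` (taxa x n_axes loadings),
#'   `eigenvalues`, `sample_scores`, `class_scores`,
#'   `between_inertia_ratio`, `classes`.
#' @export
bca <- function(table, labels, scale = FALSE) {
  x <- if (inherits(table, "abundance_table")) {
    if (table$mode != "relative") {
      stop("bca() requires a relative-mode table", call. = FALSE)
    }
    table$values
  } else as.matrix(table)
  n <- nrow(x)
  f <- if (is.factor(labels)) labels else factor(labels)
  if (any(table(f) == 0)) stop("empty class", call. = FALSE)
  k <- nlevels(f)
  xc <- scale(x, center = TRUE, scale = scale)
  xc[is.nan(xc)] <- 0 # constant columns under scaling
  tot <- sum(xc^2) / n
  if (k == 1) {
    return(structure(list(axes = NULL, eigenvalues = numeric(0),
                          sample_scores = NULL, class_scores = NULL,
                          between_inertia_ratio = 0, classes = f),
                     class = "bca_result"))
  }
  sizes <- as.numeric(table(f))
  m <- rowsum(xc, f) / sizes # class means, k x t
  cw <- crossprod(m * sqrt(sizes / n)) # weighted covariance of class means
  between <- sum(diag(cw))
  eg <- eigen(cw, symmetric = TRUE)
  naxes <- min(k - 1, sum(eg$values > max(eg$values[1], 0) * 1e-10))
  naxes <- max(naxes, 1)
  axes <- eg$vectors[, seq_len(naxes), drop = FALSE]
  rownames(axes) <- colnames(x)
  colnames(axes) <- paste0("Axis", seq_len(naxes))
  structure(list(axes = axes,
                 eigenvalues = pmax(eg$values[seq_len(naxes)], 0),
                 sample_scores = xc %*% axes,
                 class_scores = m %*% axes,
                 between_inertia_ratio = if (tot > 0) min(between / tot, 1) else 0,
                 classes = f),
            class = "bca_result")
}

#' @export
print.bca_result <- function(x, ...) {
  cat(sprintf("bca_result: %d classes, %d axes, between-inertia ratio %.3f\n",
              nlevels(x$classes), length(x$eigenvalues),
              x$between_inertia_ratio))
  invisible(x)
}

#' Identify the driver taxon of each community type
#'
#' For each cluster, the driver is the taxon maximizing the contrast
#' (mean relative abundance inside the cluster) minus (mean outside);
#' ties break lexicographically on taxon id. Each driver is reported with
#' its within-type abundance summary (mean, quartiles, range).
#'
#' @param table An `abundance_table` in `relative` mode.
#' @param labels Cluster assignment per sample.
#' @return Data frame with one row per cluster: `cluster`, `driver`,
#'   `contrast`, `mean`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
identify_drivers <- function(table, labels) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  f <- factor(labels)
  out <- lapply(levels(f), function(cl) {
    inside <- f == cl
    contrast <- colMeans(x[inside, , drop = FALSE]) -
      colMeans(x[!inside, , drop = FALSE])
    if (all(!inside) || all(inside)) contrast <- colMeans(x)
    ord <- order(-contrast, colnames(x))
    drv <- colnames(x)[ord[1]]
    v <- x[inside, drv]
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(cluster = cl, driver = drv, contrast = contrast[ord[1]],
               mean = mean(v), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Type microbial communities (enterotyping / orotyping)
#'
#' The full typing engine for one body site: relative abundances are
#' computed if needed, taxa of very low mean abundance are dropped,
#' samples are clustered by PAM on sqrt-JSD distances with the cluster
#' number chosen by the Calinski-Harabasz index, the clustering is scored
#' by the mean silhouette width and (optionally) tested against a
#' permutation null, the driver taxon of every type is identified, and a
#' between-class analysis supplies an ordination of the types. Types are
#' named by descending size — `E1..Ek` for gut, `O1..Ok` for oral, `T1..`
#' otherwise.
#'
#' @param table An `abundance_table` (counts are converted internally).
#' @param k_range Candidate cluster numbers, default `2:6`.
#' @param filter_threshold Mean relative-abundance floor below which taxa
#'   are dropped before typing (default `1e-4`, i.e. 0.01%).
#' @param n_null Null datasets for the silhouette significance test;
#'   `0` skips the test. Default `99`.
#' @param seed Seed for the null simulation.
#' @param scale_bca Passed to [bca()].
#' @return A `community_typing` object: list with `k`, `types` (named
#'   factor per sample), `type_names`, `labels` (raw cluster indices),
#'   `medoids`, `ch_by_k`, `silhouette` (`widths`, `mean`),
#'   `silhouette_p` (or `NA` if the null test was skipped), `null_stats`,
#'   `drivers` (data frame), `bca`, `dist`, `table` (the filtered
#'   relative table), `site`.
#' @examples
#' spec <- cohort_preset("gut-paper")
#' spec$n_subjects <- 30
#' cohort <- generate_cohort(spec)$cohort
#' fit <- type_communities(cohort$gut, n_null = 0)
#' print(fit)
#' @export
type_communities <- function(table, k_range = 2:6, filter_threshold = 1e-4,
                             n_null = 99, seed = 1, scale_bca = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- to_relative(table)
  rel <- filter_low_abundance(rel, filter_threshold)
  d <- jsd_distance_matrix(rel)
  sel <- select_k(d, k_range)
  prefix <- switch(rel$site, gut = "E", oral = "O", "T")
  sizes <- tabulate(sel$labels, sel$k)
  rank <- order(-sizes, seq_len(sel$k)) # descending size, ties by index
  type_names <- paste0(prefix, seq_len(sel$k))
  name_of <- character(sel$k)
  name_of[rank] <- type_names
  types <- factor(name_of[sel$labels], levels = type_names)
  names(types) <- names(sel$labels)
  nulltest <- NULL
  if (n_null > 0) {
    nulltest <- null_silhouette_test(rel, k_range = k_range,
                                     n_null = n_null, seed = seed)
  }
  drv <- identify_drivers(rel, types)
  structure(list(k = sel$k, types = types, type_names = type_names,
                 labels = sel$labels, medoids = sel$medoids,
                 ch_by_k = sel$ch_by_k, silhouette = sel$silhouette,
                 silhouette_p = if (is.null(nulltest)) NA_real_ else nulltest$p,
                 null_stats = if (is.null(nulltest)) NULL else nulltest$null,
                 drivers = drv, bca = bca(rel, types, scale = scale_bca),
                 dist = d, table = rel, site = rel$site,
                 call = match.call()),
            class = "community_typing")
}

#' @export
print.community_typing <- function(x, ...) {
  cat(sprintf("Community typing (%s site): k = %d\n", x$site, x$k))
  sizes <- table(x$types)
  cat("  type sizes: ",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  cat("  CH by k:    ",
      paste(sprintf("%s:%.1f", names(x$ch_by_k), x$ch_by_k),
            collapse = "  "), "\n")
  cat(sprintf("  mean silhouette: %.4f", x$silhouette$mean))
  if (!is.na(x$silhouette_p)) {
    cat(sprintf("  (null test p = %.4g)", x$silhouette_p))
  }
  cat("\n  drivers:    ",
      paste(sprintf("%s:%s", x$drivers$cluster, x$drivers$driver),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.community_typing <- function(object, ...) {
  print(object)
  cat(sprintf("  between-class inertia ratio: %.3f\n",
              object$bca$between_inertia_ratio))
  cat("  medoid samples:", paste(object$medoids, collapse = ", "), "\n")
  cat("  driver abundance by type (mean [q1, q3]):\n")
  d <- object$drivers
  for (i in seq_len(nrow(d))) {
    cat(sprintf("    %s %-25s %.3f [%.3f, %.3f]\n", d$cluster[i],
                d$driver[i], d$mean[i], d$q1[i], d$q3[i]))
  }
  invisible(object)
}

#' Plot a community typing as a between-class ordination
#'
#' Samples on the first two BCA axes, coloured by type, with type
#' centroids as labelled squares.
#'
#' @param x A `community_typing` object.
#' @param ... Passed to `plot`.
#' @export
plot.community_typing <- function(x, ...) {
  sc <- x$bca$sample_scores
  if (is.null(sc) || ncol(sc) < 1) {
    stop("no BCA axes available to plot", call. = FALSE)
  }
  if (ncol(sc) == 1) sc <- cbind(sc, 0)
  cols <- grDevices::hcl.colors(x$k, "Dark 3")
  graphics::plot(sc[, 1], sc[, 2], col = cols[as.integer(x$types)],
                 pch = 16, xlab = "BCA axis 1", ylab = "BCA axis 2",
                 main = sprintf("%s community types (k = %d)", x$site, x$k),
                 ...)
  cs <- x$bca$class_scores
  if (ncol(cs) == 1) cs <- cbind(cs, 0)
  graphics::points(cs[, 1], cs[, 2], pch = 15, cex = 1.6, col = cols)
  graphics::text(cs[, 1], cs[, 2], labels = x$type_names, pos = 3)
  invisible(x)
}

#' Write a community typing to disk
#'
#' Emits a JSON summary (k, CH curve, medoids, silhouette statistics,
#' null-test p, drivers), a per-sample TSV (`sample_id`, `site`, `type`)
#' and a TSV of BCA sample scores for ordination plotting.
#'
#' @param fit A `community_typing` object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default the site name.
#' @return Character vector of the written paths, invisibly.
#' @export
write_typing <- function(fit, dir, prefix = fit$site) {
  stopifnot(inherits(fit, "community_typing"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, paste0(prefix, "_typing.json"))
  jsonlite::write_json(list(
    site = fit$site, k = fit$k,
    ch_by_k = as.list(fit$ch_by_k),
    medoids = fit$medoids,
    mean_silhouette = fit$silhouette$mean,
    silhouette_p = fit$silhouette_p,
    drivers = stats::setNames(as.list(fit$drivers$driver),
                              fit$drivers$cluster)),
    jpath, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  tpath <- file.path(dir, paste0(prefix, "_types.tsv"))
  utils::write.table(
    data.frame(sample_id = names(fit$types), site = fit$site,
               type = as.character(fit$types)),
    tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  bpath <- file.path(dir, paste0(prefix, "_bca_scores.tsv"))
  sc <- fit$bca$sample_scores
  utils::write.table(
    data.frame(sample_id = rownames(sc), sc, check.names = FALSE),
    bpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jpath, tpath, bpath))
}
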