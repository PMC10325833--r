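#' Construct an abundance table
#'
#' The central container of the package: a samples x taxa matrix of
#' genus-level abundances for one body site, either raw counts or relative
#' abundances (rows summing to one).
#'
#' @param values Numeric matrix, samples in rows and taxa in columns, with
#'   unique row and column names. All entries must be non-negative; in
#'   `mode = "relative"` every row must sum to 1 within `1e-9`.
#' @param site Body site the samples come from: `"gut"`, `"oral"` or
#'   `"other"`.
#' @param mode `"counts"` for raw read counts, `"relative"` for
#'   row-normalized abundances.
#' @param taxonomy Optional named character vector mapping taxon ids to
#'   semicolon-delimited lineage strings
#'   (`phylum;class;order;family;genus`). Names must be a subset of the
#'   taxon ids.
#' @return An object of class `abundance_table` with elements `values`,
#'   `site`, `mode` and `taxonomy`.
#' @seealso [read_abundance()], [to_relative()], [filter_low_abundance()]
#' @export
abundance_table <- function(values, site = c("gut", "oral", "other"),
                            mode = c("counts", "relative"),
                            taxonomy = NULL) {
  site <- match.arg(site)
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x taxa)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and taxon column names",
         call. = FALSE)
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  dup_t <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_t)) {
    stop("duplicated taxon id(s): ", paste(unique(dup_t), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("`values` contains missing entries", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance for taxon '%s' in sample '%s'",
                 colnames(values)[bad[2]], rownames(values)[bad[1]]),
         call. = FALSE)
  }
  if (mode == "relative") {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off)) {
      stop(sprintf("relative abundance row '%s' sums to %.12g, not 1",
                   rownames(values)[off[1]], rs[off[1]]), call. = FALSE)
    }
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !is.character(taxonomy)) {
      stop("`taxonomy` must be a named character vector", call. = FALSE)
    }
    unknown <- setdiff(names(taxonomy), colnames(values))
    if (length(unknown)) {
      stop("taxonomy refers to unknown taxa: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, site = site, mode = mode,
                 taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s, %s site)\n",
              nrow(x$values), ncol(x$values), x$mode, x$site))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy for %d taxa\n", length(x$taxonomy)))
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample identifiers of an abundance table
#' @param table An `abundance_table`.
#' @return Character vector of sample ids (row order).
#' @export
sample_ids <- function(table) rownames(table$values)

#' Taxon identifiers of an abundance table
#' @param table An `abundance_table`.
#' @return Character vector of taxon ids (column order).
#' @export
taxon_ids <- function(table) colnames(table$values)

#' Convert a count table to relative abundances
#'
#' Divides every sample's counts by the sample total so that rows sum to
#' one; community typing and pathway projection operate on these relative
#' genus abundances.
#'
#' @param table An `abundance_table` in `counts` mode. A table already in
#'   `relative` mode is returned unchanged.
#' @return The table in `relative` mode.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  rs <- rowSums(table$values)
  zero <- which(rs == 0)
  if (length(zero)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(table$values)[zero], collapse = ", "), call. = FALSE)
  }
  abundance_table(table$values / rs, site = table$site, mode = "relative",
                  taxonomy = table$taxonomy)
}

#' Drop taxa of very low average abundance
#'
#' Removes noise taxa before community typing: every taxon whose mean
#' relative abundance across all samples is strictly below `threshold`
#' (default 0.01%) is dropped. Rows are deliberately not renormalized —
#' the distance layer renormalizes internally, keeping the filter
#' side-effect free.
#'
#' @param table An `abundance_table` in `relative` mode.
#' @param threshold Fraction in (0, 1); taxa with mean relative abundance
#'   `< threshold` are removed. Default `1e-4`.
#' @return The filtered table (still flagged `relative`; retained rows may
#'   now sum to less than one). The `orogut.relative_floor` internal flag
#'   on the result records that renormalization is deferred.
#' @export
filter_low_abundance <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") {
    stop("filter_low_abundance() requires a relative-mode table; call to_relative() first",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single fraction in (0, 1)", call. = FALSE)
  }
  keep <- colMeans(table$values) >= threshold
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  if (!is.null(table$taxonomy)) {
    out$taxonomy <- table$taxonomy[names(table$taxonomy) %in%
                                     colnames(out$values)]
    if (!length(out$taxonomy)) out$taxonomy <- NULL
  }
  out
}

#' Pair gut and oral samples by subject
#'
#' Reorders two site tables to a common subject order using a pairing map.
#' Subjects missing a sample at either site are dropped with a message.
#'
#' @param gut,oral `abundance_table`s with `site = "gut"` and
#'   `site = "oral"` respectively.
#' @param pairing Data frame with columns `subject_id`, `site`
#'   (`"gut"`/`"oral"`) and `sample_id`, one row per subject-site, e.g.
#'   from [read_pairing()].
#' @return A `paired_cohort`: list with elements `gut`, `oral` (tables
#'   reordered to the shared subject order), `subjects`, and the per-site
#'   sample ids.
#' @export
align_pairs <- function(gut, oral, pairing) {
  stopifnot(inherits(gut, "abundance_table"), inherits(oral, "abundance_table"))
  if (gut$site != "gut" || oral$site != "oral") {
    stop("tables must have site 'gut' and 'oral' respectively", call. = FALSE)
  }
  req <- c("subject_id", "site", "sample_id")
  if (!all(req %in% names(pairing))) {
    stop("`pairing` needs columns subject_id, site, sample_id", call. = FALSE)
  }
  for (s in c("gut", "oral")) {
    sub <- pairing[pairing$site == s, ]
    dup <- sub$subject_id[duplicated(sub$subject_id)]
    if (length(dup)) {
      stop(sprintf("subject(s) mapped to more than one %s sample: %s",
                   s, paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  gmap <- pairing[pairing$site == "gut", ]
  omap <- pairing[pairing$site == "oral", ]
  gmap <- gmap[gmap$sample_id %in% sample_ids(gut), ]
  omap <- omap[omap$sample_id %in% sample_ids(oral), ]
  subjects <- unique(pairing$subject_id)
  complete <- subjects[subjects %in% gmap$subject_id &
                         subjects %in% omap$subject_id]
  dropped <- setdiff(subjects, complete)
  if (length(dropped)) {
    message("align_pairs: dropping subject(s) without both sites: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(complete)) stop("no paired subjects", call. = FALSE)
  gs <- gmap$sample_id[match(complete, gmap$subject_id)]
  os <- omap$sample_id[match(complete, omap$subject_id)]
  g2 <- gut; g2$values <- gut$values[gs, , drop = FALSE]
  o2 <- oral; o2$values <- oral$values[os, , drop = FALSE]
  structure(list(gut = g2, oral = o2, subjects = complete,
                 gut_samples = gs, oral_samples = os),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort: %d subjects; gut %d taxa, oral %d taxa\n",
              length(x$subjects), ncol(x$gut$values), ncol(x$oral$values)))
  invisible(x)
}
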