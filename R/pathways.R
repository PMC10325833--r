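#' Construct a taxon-to-pathway gene-copy reference
#'
#' The reference used by the linear metagenome-prediction surrogate: a
#' non-negative taxa x pathways matrix of gene copy numbers, optionally
#' with a KEGG-style class label per pathway.
#'
#' @param copies Non-negative numeric matrix with unique taxon row names
#'   and pathway column names.
#' @param category Optional named character vector, pathway id to class
#'   label.
#' @return A `gene_copy_reference`.
#' @export
gene_copy_reference <- function(copies, category = NULL) {
  if (!is.matrix(copies) || !is.numeric(copies)) {
    stop("`copies` must be a numeric matrix (taxa x pathways)", call. = FALSE)
  }
  if (is.null(rownames(copies)) || is.null(colnames(copies))) {
    stop("`copies` needs taxon row names and pathway column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(copies))) {
    stop("duplicated taxon ids in reference", call. = FALSE)
  }
  if (any(copies < 0)) stop("gene copies must be non-negative", call. = FALSE)
  if (!is.null(category)) {
    unknown <- setdiff(names(category), colnames(copies))
    if (length(unknown)) {
      stop("category refers to unknown pathways: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(copies = copies, category = category),
            class = "gene_copy_reference")
}

#' @export
print.gene_copy_reference <- function(x, ...) {
  cat(sprintf("gene_copy_reference: %d taxa x %d pathways\n",
              nrow(x$copies), ncol(x$copies)))
  invisible(x)
}

#' Project taxon abundances into pathway space
#'
#' The metagenome-prediction surrogate: predicted pathway abundance is
#' the relative taxon abundance weighted by gene copy number and summed
#' over taxa — a plain matrix product, linear in the abundances. All
#' downstream pathway statistics operate on this table.
#'
#' @param table An `abundance_table` in `relative` mode; every taxon must
#'   appear in the reference.
#' @param ref A `gene_copy_reference`.
#' @return A `pathway_table`: list with `values` (samples x pathways),
#'   `category`, `site`.
#' @export
project_pathways <- function(table, ref) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(ref, "gene_copy_reference"))
  if (table$mode != "relative") {
    stop("project_pathways() requires a relative-mode table", call. = FALSE)
  }
  missing <- setdiff(taxon_ids(table), rownames(ref$copies))
  if (length(missing)) {
    stop("taxa absent from the gene-copy reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- table$values %*% ref$copies[taxon_ids(table), , drop = FALSE]
  structure(list(values = values, category = ref$category,
                 site = table$site),
            class = "pathway_table")
}

#' @export
print.pathway_table <- function(x, ...) {
  cat(sprintf("pathway_table: %d samples x %d pathways (%s site)\n",
              nrow(x$values), ncol(x$values), x$site))
  invisible(x)
}

#' Rank pathways by log abundance-based average
#'
#' Scores every pathway by `log10(mean abundance + 1e-12)` (the epsilon
#' keeps all-zero pathways finite and last) and returns the `top_n` in
#' descending order, ties broken by pathway id.
#'
#' @param pt A `pathway_table`.
#' @param top_n Number of pathways to return, default 20 (capped at the
#'   pathway count).
#' @return Data frame with `pathway`, `mean_abundance`, `log_score`,
#'   `category` (if available), in rank order.
#' @export
rank_pathways <- function(pt, top_n = 20) {
  stopifnot(inherits(pt, "pathway_table"))
  if (top_n > ncol(pt$values)) {
    stop("`top_n` exceeds the number of pathways", call. = FALSE)
  }
  mu <- colMeans(pt$values)
  score <- log10(mu + 1e-12)
  ord <- order(-score, colnames(pt$values))
  sel <- ord[seq_len(top_n)]
  out <- data.frame(pathway = colnames(pt$values)[sel],
                    mean_abundance = mu[sel], log_score = score[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(pt$category)) out$category <- unname(pt$category[out$pathway])
  out
}

#' Type-enriched pathways by Kruskal-Wallis with BH control
#'
#' Tests every pathway for differential abundance across community types
#' (Kruskal-Wallis), adjusts across pathways by Benjamini-Hochberg, and
#' for each significant pathway reports the representative type — the
#' type with the highest mean predicted abundance. Pathways constant
#' across samples get H = 0, p = 1 and can never be significant.
#'
#' @param pt A `pathway_table`.
#' @param types Per-sample type labels (at least 2 types).
#' @param alpha BH significance level, default 0.05.
#' @return Data frame with `pathway`, `H`, `p`, `p_adjusted`,
#'   `significant`, `representative_type` (`NA` unless significant), and
#'   `category` if available.
#' @export
type_enriched_pathways <- function(pt, types, alpha = 0.05) {
  stopifnot(inherits(pt, "pathway_table"))
  f <- factor(types)
  if (nlevels(f) < 2) stop("need at least 2 types", call. = FALSE)
  paths <- colnames(pt$values)
  H <- p <- numeric(length(paths))
  for (j in seq_along(paths)) {
    kw <- kruskal_wallis(pt$values[, j], f, variable = paths[j])
    H[j] <- kw$H; p[j] <- kw$p
  }
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj < alpha
  rep_type <- rep(NA_character_, length(paths))
  if (any(sig)) {
    means <- rowsum(pt$values, f) / as.integer(table(f)) # types x pathways
    rep_type[sig] <- rownames(means)[apply(means[, sig, drop = FALSE], 2,
                                           which.max)]
  }
  out <- data.frame(pathway = paths, H = H, p = p, p_adjusted = padj,
                    significant = sig, representative_type = rep_type,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(pt$category)) out$category <- unname(pt$category[paths])
  out
}

#' Spearman correlation between taxa and predicted pathways
#'
#' The taxon-pathway heatmap grid: Spearman rho / p / BH-adjusted p
#' between selected taxon abundances and selected pathway abundances over
#' the same samples (delegates to [spearman_matrix()]).
#'
#' @param table An `abundance_table` (relative mode) sharing samples with
#'   `pt` in identical order.
#' @param pt A `pathway_table`.
#' @param taxa,pathways Optional id subsets; default all.
#' @return A `correlation_result` (rows = taxa, cols = pathways).
#' @export
taxon_pathway_correlation <- function(table, pt, taxa = NULL,
                                      pathways = NULL) {
  stopifnot(inherits(table, "abundance_table"), inherits(pt, "pathway_table"))
  if (nrow(table$values) != nrow(pt$values)) {
    stop("table and pathway table must share samples", call. = FALSE)
  }
  tx <- if (is.null(taxa)) taxon_ids(table) else intersect(taxa, taxon_ids(table))
  pw <- if (is.null(pathways)) colnames(pt$values) else
    intersect(pathways, colnames(pt$values))
  if (!length(tx) || !length(pw)) stop("empty taxon or pathway subset",
                                       call. = FALSE)
  spearman_matrix(table$values[, tx, drop = FALSE],
                  pt$values[, pw, drop = FALSE])
}

#' Read / write gene-copy references and pathway tables as TSV
#'
#' The reference TSV has taxa as rows (first column `taxon_id`), pathway
#' columns, and an optional trailing `category` row is not supported —
#' categories travel in a separate two-column TSV (`pathway`, `category`).
#'
#' @param path TSV path.
#' @param category_path Optional path to a pathway-category TSV.
#' @return A `gene_copy_reference`.
#' @export
read_gene_copy_reference <- function(path, category_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  category <- NULL
  if (!is.null(category_path)) {
    cd <- utils::read.delim(category_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    category <- stats::setNames(as.character(cd$category),
                                as.character(cd$pathway))
  }
  gene_copy_reference(m, category)
}

#' @rdname read_gene_copy_reference
#' @param ref A `gene_copy_reference`.
#' @export
write_gene_copy_reference <- function(ref, path) {
  stopifnot(inherits(ref, "gene_copy_reference"))
  utils::write.table(
    data.frame(taxon_id = rownames(ref$copies), ref$copies,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pathway table as TSV (samples x pathways)
#'
#' @param pt A `pathway_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(pt, path) {
  stopifnot(inherits(pt, "pathway_table"))
  utils::write.table(
    data.frame(sample_id = rownames(pt$values), pt$values,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
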