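#' Per-taxon prevalence
#'
#' Fraction of samples in which each taxon is detected (abundance
#' strictly greater than zero; no detection floor is applied).
#'
#' @param table An `abundance_table` (counts or relative).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  colMeans(table$values > 0)
}

#' Minimum-incidence (core) filter
#'
#' Keeps taxa detected in at least `min_prevalence` of the samples
#' (boundary inclusive: a taxon at exactly the threshold is retained,
#' since taxa *below* it are the ones regarded as individual
#' variability). Samples are unchanged.
#'
#' @param table An `abundance_table`.
#' @param min_prevalence Fraction in (0, 1], default `0.30`.
#' @return The filtered table.
#' @export
core_filter <- function(table, min_prevalence = 0.30) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1 ||
      min_prevalence <= 0 || min_prevalence > 1) {
    stop("`min_prevalence` must be a fraction in (0, 1]", call. = FALSE)
  }
  keep <- prevalence(table) >= min_prevalence
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  if (!is.null(table$taxonomy)) {
    out$taxonomy <- table$taxonomy[names(table$taxonomy) %in%
                                     colnames(out$values)]
    if (!length(out$taxonomy)) out$taxonomy <- NULL
  }
  out
}

#' Cross-site core intersection
#'
#' Intersects the taxon sets of two already core-filtered site tables:
#' the shared ("core") microbiome is every taxon prevalent at both sites,
#' reported in the gut table's taxon order, together with the per-site
#' prevalence vectors.
#'
#' @param gut_core,oral_core Core-filtered `abundance_table`s for the two
#'   sites.
#' @param threshold The prevalence threshold the inputs were filtered at
#'   (recorded for provenance), default `0.30`.
#' @return A `core_set`: list with `core` (shared taxon ids, gut order),
#'   `site_core` (per-site taxon lists), `site_prevalence` (per-site named
#'   vectors over that site's core) and `threshold`.
#' @export
core_intersection <- function(gut_core, oral_core, threshold = 0.30) {
  stopifnot(inherits(gut_core, "abundance_table"),
            inherits(oral_core, "abundance_table"))
  gt <- taxon_ids(gut_core)
  ot <- taxon_ids(oral_core)
  core <- gt[gt %in% ot]
  if (!length(core)) warning("cross-site core is empty", call. = FALSE)
  structure(list(core = core,
                 site_core = list(gut = gt, oral = ot),
                 site_prevalence = list(gut = prevalence(gut_core),
                                        oral = prevalence(oral_core)),
                 threshold = threshold),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d gut, %d oral, %d shared core taxa (prevalence >= %.0f%%)\n",
              length(x$site_core$gut), length(x$site_core$oral),
              length(x$core), 100 * x$threshold))
  invisible(x)
}

#' Core microbiome of a paired cohort
#'
#' Convenience wrapper: core-filters both site tables at
#' `min_prevalence` and intersects them.
#'
#' @param cohort A `paired_cohort`.
#' @param min_prevalence Prevalence threshold, default `0.30`.
#' @return A `core_set`.
#' @export
core_microbiome <- function(cohort, min_prevalence = 0.30) {
  stopifnot(inherits(cohort, "paired_cohort"))
  core_intersection(core_filter(cohort$gut, min_prevalence),
                    core_filter(cohort$oral, min_prevalence),
                    threshold = min_prevalence)
}

#' Write a core set to disk
#'
#' JSON summary plus a flat TSV (`taxon`, `gut_prevalence`,
#' `oral_prevalence`, `in_core`) over the union of both site cores.
#'
#' @param core A `core_set`.
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"core"`.
#' @return Written paths, invisibly.
#' @export
write_core_set <- function(core, dir, prefix = "core") {
  stopifnot(inherits(core, "core_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(threshold = core$threshold,
                            gut_core = core$site_core$gut,
                            oral_core = core$site_core$oral,
                            core = core$core),
                       jpath, auto_unbox = TRUE, digits = NA)
  all_taxa <- union(core$site_core$gut, core$site_core$oral)
  gp <- core$site_prevalence$gut[all_taxa]
  op <- core$site_prevalence$oral[all_taxa]
  df <- data.frame(taxon = all_taxa,
                   gut_prevalence = ifelse(is.na(gp), 0, gp),
                   oral_prevalence = ifelse(is.na(op), 0, op),
                   in_core = all_taxa %in% core$core)
  tpath <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jpath, tpath))
}

#' Node/edge table for alluvial or arc rendering of the core structure
#'
#' Emits the edge list underlying the site-to-family flow diagrams:
#' one edge per (membership group, family) pair, where the groups are
#' `gut`, `oral` and `core` and families come from the semicolon-delimited
#' taxonomy lineages (4th field). Taxa without taxonomy map to
#' `"Unclassified"`.
#'
#' @param core A `core_set`.
#' @param taxonomy Named character vector, taxon id to lineage string.
#' @return Data frame with columns `source`, `target` (family), `weight`
#'   (taxon count).
#' @export
core_edge_list <- function(core, taxonomy = NULL) {
  stopifnot(inherits(core, "core_set"))
  fam <- function(taxa) {
    if (is.null(taxonomy)) return(rep("Unclassified", length(taxa)))
    lin <- taxonomy[taxa]
    vapply(lin, function(s) {
      if (is.na(s)) return("Unclassified")
      parts <- strsplit(s, ";", fixed = TRUE)[[1]]
      if (length(parts) >= 4 && nzchar(parts[4])) parts[4] else "Unclassified"
    }, character(1), USE.NAMES = FALSE)
  }
  groups <- list(gut = core$site_core$gut, oral = core$site_core$oral,
                 core = core$core)
  out <- lapply(names(groups), function(g) {
    f <- fam(groups[[g]])
    if (!length(f)) return(NULL)
    agg <- table(f)
    data.frame(source = g, target = names(agg),
               weight = as.integer(agg), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
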