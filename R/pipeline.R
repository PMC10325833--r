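#' Configure a full pipeline run
#'
#' Either a preset name (synthetic cohort) or paths to abundance tables
#' and a pairing file, plus the thresholds and simulation sizes of every
#' stage. The single `seed` governs the generator, the silhouette null
#' simulation and the PERMANOVA permutations through derived substreams,
#' so a run is reproducible from its config alone.
#'
#' @param preset Preset name for a synthetic run (see [cohort_preset()]),
#'   or `NULL` to read real input.
#' @param gut_path,oral_path,pairing_gut,pairing_oral Input files for a
#'   real-data run (ignored when `preset` is set).
#' @param pathway_ref_path Optional gene-copy reference TSV; when `NULL`
#'   a synthetic reference is generated.
#' @param filter_threshold Mean relative-abundance floor, default `1e-4`.
#' @param min_prevalence Core prevalence threshold, default `0.30`.
#' @param k_range Candidate cluster numbers, default `2:6`.
#' @param n_null Silhouette null datasets, default 99.
#' @param n_perm PERMANOVA permutations, default 999.
#' @param alpha Significance level, default 0.05.
#' @param seed Master seed, default 1.
#' @param out_dir Output directory, default `"orogut_run"`.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, gut_path = NULL, oral_path = NULL,
                       pairing_gut = NULL, pairing_oral = NULL,
                       pathway_ref_path = NULL, filter_threshold = 1e-4,
                       min_prevalence = 0.30, k_range = 2:6, n_null = 99,
                       n_perm = 999, alpha = 0.05, seed = 1,
                       out_dir = "orogut_run") {
  if (is.null(preset) &&
      (is.null(gut_path) || is.null(oral_path) ||
       is.null(pairing_gut) || is.null(pairing_oral))) {
    stop("either `preset` or all four input paths must be given",
         call. = FALSE)
  }
  stopifnot(filter_threshold > 0, filter_threshold < 1,
            min_prevalence > 0, min_prevalence <= 1,
            alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(preset = preset, gut_path = gut_path,
                 oral_path = oral_path, pairing_gut = pairing_gut,
                 pairing_oral = pairing_oral,
                 pathway_ref_path = pathway_ref_path,
                 filter_threshold = filter_threshold,
                 min_prevalence = min_prevalence, k_range = k_range,
                 n_null = n_null, n_perm = n_perm, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full paired gut-oral analysis
#'
#' Executes, in order: input (or synthetic generation) -> relative
#' abundances -> low-abundance filter -> community typing per site
#' (sqrt-JSD distances, CH-selected PAM, silhouette null test, BCA,
#' drivers) -> Bray-Curtis PCoA + PERMANOVA per site -> core filtering
#' and cross-site core intersection -> cross-site same-taxon correlations
#' and the taxon-profile UPGMA tree -> pathway projection, top-pathway
#' ranking and type-stratified enrichment. Every stage's output is
#' written under `config$out_dir`; a run with the same config and seed
#' writes identical artifacts.
#'
#' @param config A `run_config`.
#' @return A `run_report`: list of summary statistics and artifact paths
#'   (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logpath <- file.path(config$out_dir, "run.log")
  logcon <- file(logpath, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(...)
    writeLines(line, logcon)
    message(line)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  subseed <- sample.int(.Machine$integer.max - 1, 6)

  # -- stage: input ----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$preset)) {
    logmsg("stage input: synthetic preset '", config$preset,
           "', seed ", subseed[1])
    spec <- cohort_preset(config$preset, seed = subseed[1])
    gen <- generate_cohort(spec)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    for (p in c(config$gut_path, config$oral_path, config$pairing_gut,
                config$pairing_oral)) {
      if (!file.exists(p)) stop("stage input: missing file ", p,
                                call. = FALSE)
    }
    logmsg("stage input: reading ", config$gut_path, " + ",
           config$oral_path)
    gut <- read_abundance(config$gut_path, site = "gut", mode = "counts")
    oral <- read_abundance(config$oral_path, site = "oral", mode = "counts")
    pairing <- read_pairing(config$pairing_gut, config$pairing_oral)
    cohort <- align_pairs(gut, oral, pairing)
  }
  write_abundance(cohort$gut, file.path(config$out_dir, "gut_counts.tsv"))
  write_abundance(cohort$oral, file.path(config$out_dir, "oral_counts.tsv"))
  logmsg("stage input: ", length(cohort$subjects), " paired subjects")

  # -- stage: typing per site ------------------------------------------------
  fits <- list()
  for (site in c("gut", "oral")) {
    tb <- cohort[[site]]
    logmsg("stage typing (", site, "): relative -> filter (",
           config$filter_threshold, ") -> sqrt-JSD -> PAM/CH")
    fit <- type_communities(tb, k_range = config$k_range,
                            filter_threshold = config$filter_threshold,
                            n_null = config$n_null,
                            seed = subseed[if (site == "gut") 2 else 3])
    fits[[site]] <- fit
    write_typing(fit, config$out_dir, prefix = site)
    logmsg(sprintf("stage typing (%s): k = %d, mean silhouette %.4f, p = %s",
                   site, fit$k, fit$silhouette$mean,
                   format(fit$silhouette_p)))
  }

  # -- stage: ordination + PERMANOVA ----------------------------------------
  ordin <- list()
  for (site in c("gut", "oral")) {
    rel <- fits[[site]]$table
    bc <- bray_curtis_matrix(rel)
    pc <- pcoa(bc, n_axes = 3)
    utils::write.table(
      data.frame(sample_id = rownames(pc$coordinates), pc$coordinates),
      file.path(config$out_dir, paste0(site, "_pcoa.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- permanova(bc, fits[[site]]$types, n_perm = config$n_perm,
                    seed = subseed[4])
    ordin[[site]] <- list(pcoa = pc, permanova = pm)
    logmsg(sprintf("stage ordination (%s): PERMANOVA F = %.3f, p = %.4g",
                   site, pm$pseudo_F, pm$p))
  }

  # -- stage: core -----------------------------------------------------------
  core <- core_microbiome(cohort, config$min_prevalence)
  write_core_set(core, config$out_dir)
  taxonomy <- c(cohort$gut$taxonomy, cohort$oral$taxonomy)
  taxonomy <- taxonomy[!duplicated(names(taxonomy))]
  edges <- core_edge_list(core, taxonomy)
  utils::write.table(edges, file.path(config$out_dir, "core_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg(sprintf("stage core: gut %d, oral %d, shared core %d taxa",
                 length(core$site_core$gut), length(core$site_core$oral),
                 length(core$core)))

  # -- stage: cross-site statistics -----------------------------------------
  cross <- same_taxon_cross_site(cohort, core)
  utils::write.table(cross, file.path(config$out_dir, "cross_site_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig_cross <- sum(cross$significant, na.rm = TRUE)
  logmsg(sprintf("stage cross-site: %d of %d core taxa BH-significant",
                 n_sig_cross, nrow(cross)))
  gut_core_rel <- core_filter(to_relative(cohort$gut),
                              config$min_prevalence)
  oral_core_rel <- core_filter(to_relative(cohort$oral),
                               config$min_prevalence)
  shared_gut <- gut_core_rel
  shared_gut$values <- shared_gut$values[, core$core, drop = FALSE]
  shared_oral <- oral_core_rel
  shared_oral$values <- shared_oral$values[, core$core, drop = FALSE]
  epd <- euclidean_profile_distance(shared_gut, shared_oral)
  dend <- average_linkage(epd)
  write_dendrogram(dend, config$out_dir, prefix = "core_profiles")
  corr <- spearman_matrix(shared_gut$values, shared_oral$values)
  write_correlation(corr, config$out_dir, prefix = "core_cross_site")

  # -- stage: pathways -------------------------------------------------------
  all_taxa <- sort(union(taxon_ids(cohort$gut), taxon_ids(cohort$oral)))
  if (!is.null(config$pathway_ref_path)) {
    ref <- read_gene_copy_reference(config$pathway_ref_path)
  } else {
    logmsg("stage pathways: generating synthetic gene-copy reference, seed ",
           subseed[5])
    ref <- generate_pathway_reference(length(all_taxa), 60, sparsity = 0.3,
                                      seed = subseed[5],
                                      taxon_ids = all_taxa)
  }
  pathres <- list()
  for (site in c("gut", "oral")) {
    rel <- to_relative(cohort[[site]])
    pt <- project_pathways(rel, ref)
    write_pathway_table(pt, file.path(config$out_dir,
                                      paste0(site, "_pathways.tsv")))
    top <- rank_pathways(pt, top_n = min(20, ncol(pt$values)))
    utils::write.table(top,
                       file.path(config$out_dir,
                                 paste0(site, "_top_pathways.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- type_enriched_pathways(pt, fits[[site]]$types,
                                  alpha = config$alpha)
    utils::write.table(enr,
                       file.path(config$out_dir,
                                 paste0(site, "_enriched_pathways.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pathres[[site]] <- list(n_pathways = ncol(pt$values),
                            n_enriched = sum(enr$significant),
                            top_pathway = top$pathway[1])
    logmsg(sprintf("stage pathways (%s): %d enriched of %d pathways",
                   site, pathres[[site]]$n_enriched, ncol(pt$values)))
  }

  report <- list(
    seed = config$seed,
    n_subjects = length(cohort$subjects),
    gut_k = fits$gut$k, oral_k = fits$oral$k,
    gut_silhouette = fits$gut$silhouette$mean,
    oral_silhouette = fits$oral$silhouette$mean,
    gut_silhouette_p = fits$gut$silhouette_p,
    oral_silhouette_p = fits$oral$silhouette_p,
    gut_permanova_F = ordin$gut$permanova$pseudo_F,
    gut_permanova_p = ordin$gut$permanova$p,
    oral_permanova_F = ordin$oral$permanova$pseudo_F,
    oral_permanova_p = ordin$oral$permanova$p,
    gut_drivers = fits$gut$drivers$driver,
    oral_drivers = fits$oral$drivers$driver,
    core_size = length(core$core),
    n_significant_cross_site = n_sig_cross,
    gut_enriched_pathways = pathres$gut$n_enriched,
    oral_enriched_pathways = pathres$oral$n_enriched,
    out_dir = normalizePath(config$out_dir))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  logmsg("run complete")
  structure(c(report,
              list(typing = fits, core = core, cross_site = cross,
                   ordination = ordin, truth = truth)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("orogut run report\n")
  cat(sprintf("  subjects: %d   seed: %d\n", x$n_subjects, x$seed))
  cat(sprintf("  gut:  k = %d, silhouette %.3f (p = %s), drivers %s\n",
              x$gut_k, x$gut_silhouette, format(x$gut_silhouette_p),
              paste(x$gut_drivers, collapse = "/")))
  cat(sprintf("  oral: k = %d, silhouette %.3f (p = %s), drivers %s\n",
              x$oral_k, x$oral_silhouette, format(x$oral_silhouette_p),
              paste(x$oral_drivers, collapse = "/")))
  cat(sprintf("  core: %d shared taxa; %d cross-site significant\n",
              x$core_size, x$n_significant_cross_site))
  cat(sprintf("  enriched pathways: gut %d, oral %d\n",
              x$gut_enriched_pathways, x$oral_enriched_pathways))
  cat("  artifacts in ", x$out_dir, "\n")
  invisible(x)
}
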