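#' Specify one mixture component of a synthetic community
#'
#' A component is a Dirichlet distribution over genus profiles: a base
#' concentration vector plus a multiplicative boost on its driver
#' genus/genera, which is what makes the component a distinct community
#' type.
#'
#' @param weight Mixing proportion in (0, 1].
#' @param concentration Named positive numeric vector of Dirichlet
#'   concentrations, one entry per taxon of the site.
#' @param driver_taxa Taxa whose concentration is multiplied by `boost`.
#' @param boost Multiplier (> 1 for a real driver; 1 disables).
#' @return A `component_spec`.
#' @export
component_spec <- function(weight, concentration, driver_taxa = character(0),
                           boost = 1) {
  if (weight <= 0 || weight > 1) stop("`weight` must be in (0, 1]",
                                      call. = FALSE)
  if (is.null(names(concentration)) || any(concentration <= 0)) {
    stop("`concentration` must be a named, strictly positive vector",
         call. = FALSE)
  }
  if (length(driver_taxa) && !all(driver_taxa %in% names(concentration))) {
    stop("driver taxa missing from concentration vector", call. = FALSE)
  }
  if (boost < 1) stop("`boost` must be >= 1", call. = FALSE)
  structure(list(weight = weight, concentration = concentration,
                 driver_taxa = driver_taxa, boost = boost),
            class = "component_spec")
}

#' Specify a synthetic paired gut-oral cohort
#'
#' Full parameterization of the generator: per-site component mixtures,
#' negative-binomial sequencing depth, cross-site coupled taxa (a shared
#' per-subject lognormal factor scales the taxon's concentration at both
#' sites, producing positive cross-site rank correlation), a block of
#' universally prevalent core taxa, and a block of zero-inflated rare
#' taxa that the prevalence filter should reject.
#'
#' @param n_subjects Number of paired subjects.
#' @param gut_components,oral_components Non-empty lists of
#'   [component_spec()]s; weights must sum to 1 within `1e-9` per site,
#'   and all components of a site must share one taxon set.
#' @param depth_mean Expected reads per sample (> 0).
#' @param depth_dispersion Negative-binomial size parameter (> 0); smaller
#'   means more depth variation.
#' @param coupled_taxa Named numeric vector: taxon id -> coupling strength
#'   sigma (>= 0, the log-sd of the shared lognormal factor). Taxa must
#'   exist at both sites.
#' @param core_block Taxon ids planted as universally prevalent at both
#'   sites (ground truth for core recovery).
#' @param rare_block Taxon ids subject to zero-inflation.
#' @param rare_presence Per-sample presence probability of rare-block
#'   taxa; must be < 0.3 so they are true negatives of the 30% prevalence
#'   filter. Default 0.15.
#' @param pathway_ref Optional `gene_copy_reference` covering all taxa of
#'   both sites; enables the expected pathway table in the ground truth.
#' @param seed Integer master seed; all randomness flows from it through
#'   one substream per subject (shared coupling draws) and per
#'   subject-site (profile, depth and count draws).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, gut_components, oral_components,
                        depth_mean = 66902, depth_dispersion = 20,
                        coupled_taxa = numeric(0),
                        core_block = character(0),
                        rare_block = character(0), rare_presence = 0.15,
                        pathway_ref = NULL, seed = 1) {
  if (n_subjects < 1) stop("`n_subjects` must be positive", call. = FALSE)
  if (!length(gut_components) || !length(oral_components)) {
    stop("component lists must be non-empty", call. = FALSE)
  }
  check_site <- function(comps, site) {
    w <- vapply(comps, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-9) {
      stop(sprintf("%s component weights sum to %.12g, not 1", site, sum(w)),
           call. = FALSE)
    }
    taxa <- names(comps[[1]]$concentration)
    for (c in comps) {
      if (!identical(names(c$concentration), taxa)) {
        stop(site, " components disagree on the taxon set", call. = FALSE)
      }
    }
    taxa
  }
  gut_taxa <- check_site(gut_components, "gut")
  oral_taxa <- check_site(oral_components, "oral")
  if (length(coupled_taxa)) {
    if (is.null(names(coupled_taxa)) || any(coupled_taxa < 0)) {
      stop("`coupled_taxa` must be a named vector of sigmas >= 0",
           call. = FALSE)
    }
    bad <- setdiff(names(coupled_taxa), intersect(gut_taxa, oral_taxa))
    if (length(bad)) {
      stop("coupled taxa must exist at both sites: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) {
    stop("`depth_mean` and `depth_dispersion` must be positive",
         call. = FALSE)
  }
  if (rare_presence < 0 || rare_presence >= 0.3) {
    stop("`rare_presence` must lie in [0, 0.3)", call. = FALSE)
  }
  all_taxa <- union(gut_taxa, oral_taxa)
  if (!all(rare_block %in% all_taxa)) {
    stop("rare_block taxa unknown to both sites", call. = FALSE)
  }
  if (!is.null(pathway_ref)) {
    stopifnot(inherits(pathway_ref, "gene_copy_reference"))
    missing <- setdiff(all_taxa, rownames(pathway_ref$copies))
    if (length(missing)) {
      stop("pathway reference lacks taxa: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 gut_components = gut_components,
                 oral_components = oral_components,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 coupled_taxa = coupled_taxa, core_block = core_block,
                 rare_block = rare_block, rare_presence = rare_presence,
                 pathway_ref = pathway_ref, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort_spec: %d subjects; %d gut / %d oral components; ",
                     "depth NB(mean=%g, size=%g); %d coupled, %d core, %d rare taxa; seed %d\n"),
              x$n_subjects, length(x$gut_components),
              length(x$oral_components), x$depth_mean, x$depth_dispersion,
              length(x$coupled_taxa), length(x$core_block),
              length(x$rare_block), x$seed))
  invisible(x)
}

# -- preset taxon universe ---------------------------------------------------

GUT_DRIVERS <- c("Bifidobacterium", "Ruminococcus", "Prevotella")
ORAL_DRIVERS <- c("Neisseria", "Prevotella", "Streptococcus")
COUPLED_DEFAULT <- c("Eubacterium_g11", "Actinomyces", "Atopobium",
                     "Enterococcus")
CORE_BLOCK_DEFAULT <- c(
  "Veillonella", "Haemophilus", "Rothia", "Fusobacterium", "Granulicatella",
  "Gemella", "Lactobacillus", "Blautia", "Dorea", "Roseburia",
  "Faecalibacterium", "Dialister", "Megasphaera", "Oribacterium",
  "Solobacterium", "Mogibacterium", "Leptotrichia", "Porphyromonas",
  "Campylobacter", "Capnocytophaga")
GUT_FILLERS <- c(
  "Bacteroides", "Alistipes", "Parabacteroides", "Akkermansia",
  "Phascolarctobacterium", "Subdoligranulum", "Coprococcus", "Anaerostipes",
  "Collinsella", "Eggerthella", "Holdemanella", "Catenibacterium",
  "Megamonas", "Odoribacter", "Butyricicoccus", "Oscillibacter",
  "Romboutsia", "Turicibacter", "Intestinibacter", "Fusicatenibacter",
  "Agathobacter", "Eubacterium_g5", "Lachnospira", "Lachnoclostridium",
  "Barnesiella", "Butyricimonas", "Sutterella", "Bilophila",
  "Desulfovibrio", "Christensenella")
ORAL_FILLERS <- c(
  "Aggregatibacter", "Lautropia", "Kingella", "Eikenella",
  "Cardiobacterium", "Corynebacterium", "Selenomonas", "Alloprevotella",
  "Bergeyella", "Stomatobaculum", "Johnsonella", "Catonella",
  "Peptostreptococcus", "Peptococcus", "Abiotrophia", "Lachnoanaerobaculum",
  "Howardella", "Moraxella", "Actinobacillus", "Bulleidia")
GUT_NOISE <- c("Methanobrevibacter", "Pyramidobacter", "Cloacibacillus",
               "Victivallis", "Synergistes", "Slackia")
ORAL_NOISE <- c("Tannerella", "Treponema", "Filifactor", "Parvimonas",
                "Scardovia", "Olsenella")
RARE_BLOCK_DEFAULT <- sprintf("PAC%06d_g", c(1041, 1100, 1152, 1207, 1266,
                                             1313, 1378, 1424, 1489, 1533,
                                             1601, 1668))

preset_concentration <- function(site) {
  drivers <- if (site == "gut") GUT_DRIVERS else ORAL_DRIVERS
  fillers <- if (site == "gut") GUT_FILLERS else ORAL_FILLERS
  noise <- if (site == "gut") GUT_NOISE else ORAL_NOISE
  conc <- c(stats::setNames(rep(2, 3), drivers),
            stats::setNames(rep(1.5, length(COUPLED_DEFAULT)),
                            COUPLED_DEFAULT),
            stats::setNames(rep(1, length(CORE_BLOCK_DEFAULT)),
                            CORE_BLOCK_DEFAULT),
            stats::setNames(rep(0.3, length(fillers)), fillers),
            stats::setNames(rep(0.004, length(noise)), noise),
            stats::setNames(rep(1, length(RARE_BLOCK_DEFAULT)),
                            RARE_BLOCK_DEFAULT))
  conc
}

#' Built-in cohort presets
#'
#' `"gut-paper"` / `"oral-paper"`: the paired study conditions — 83
#' subjects, mean depth 66,902 reads, three gut components driven by
#' Bifidobacterium / Ruminococcus / Prevotella and three oral components
#' driven by Neisseria / Prevotella / Streptococcus (driver boost 15),
#' four cross-site coupled taxa (Eubacterium_g11, Actinomyces, Atopobium,
#' Enterococcus; sigma = 1), a 20-genus universal core block and a
#' 12-taxon zero-inflated rare block. The two names return the same
#' paired specification; both exist so either site can be named as the
#' focus of a run. `"null-single-component"`: one component per site, no
#' boosts, no coupling — the no-clustering null used for silhouette-test
#' calibration (40 subjects, 30 taxa).
#'
#' @param name One of `"gut-paper"`, `"oral-paper"`,
#'   `"null-single-component"`.
#' @param seed Master seed stored in the spec, default 1.
#' @param boost Driver boost for the paper presets, default 15.
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(name, seed = 1, boost = 15) {
  known <- c("gut-paper", "oral-paper", "null-single-component")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (name == "null-single-component") {
    taxa <- c(CORE_BLOCK_DEFAULT, GUT_FILLERS[1:10])
    conc <- stats::setNames(c(rep(1, 20), rep(0.5, 10)), taxa)
    comp <- list(component_spec(1, conc))
    return(cohort_spec(n_subjects = 40, gut_components = comp,
                       oral_components = comp, depth_mean = 66902,
                       depth_dispersion = 20, seed = seed))
  }
  mk <- function(site, weights) {
    conc <- preset_concentration(site)
    drivers <- if (site == "gut") GUT_DRIVERS else ORAL_DRIVERS
    lapply(seq_along(weights), function(i) {
      component_spec(weights[i], conc, driver_taxa = drivers[i],
                     boost = boost)
    })
  }
  cohort_spec(n_subjects = 83,
              gut_components = mk("gut", c(0.40, 0.32, 0.28)),
              oral_components = mk("oral", c(0.38, 0.32, 0.30)),
              depth_mean = 66902, depth_dispersion = 20,
              coupled_taxa = stats::setNames(rep(1, 4), COUPLED_DEFAULT),
              core_block = CORE_BLOCK_DEFAULT,
              rare_block = RARE_BLOCK_DEFAULT, rare_presence = 0.15,
              seed = seed)
}

#' Generate a synthetic paired cohort with ground truth
#'
#' For each subject and site: a component is drawn from the mixture
#' weights; the component's driver boost and the subject's shared
#' lognormal coupling factors scale the Dirichlet concentrations; rare
#' taxa are zeroed by independent Bernoulli presence draws; a genus
#' probability vector is drawn from the resulting Dirichlet; sequencing
#' depth is drawn from a negative binomial around `depth_mean`; and
#' counts are drawn multinomially. Deterministic given `spec$seed`
#' (one RNG substream per subject for the shared coupling draws, one per
#' subject-site for everything else, so results do not depend on
#' evaluation order).
#'
#' @param spec A `cohort_spec`.
#' @return List with `cohort` (a `paired_cohort` of count tables carrying
#'   preset taxonomy) and `truth` (list: `gut_labels`, `oral_labels` —
#'   integer component per subject; `latent_factors` — subjects x coupled
#'   taxa matrix; `true_core` — the planted core block; `rare_block`;
#'   `true_pathway_table` — per-site expected pathway tables when the
#'   spec carries a `pathway_ref`, else `NULL`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  subseeds <- matrix(sample.int(.Machine$integer.max - 1, n * 3), n, 3)
  subjects <- sprintf("Sub%03d", seq_len(n))
  coupled <- names(spec$coupled_taxa)
  latent <- matrix(1, n, length(coupled),
                   dimnames = list(subjects, coupled))
  for (i in seq_len(n)) {
    set.seed(subseeds[i, 1])
    if (length(coupled)) {
      latent[i, ] <- exp(spec$coupled_taxa * stats::rnorm(length(coupled)))
    }
  }
  draw_site <- function(comps, seed_col, site) {
    taxa <- names(comps[[1]]$concentration)
    w <- vapply(comps, `[[`, numeric(1), "weight")
    counts <- matrix(0L, n, length(taxa),
                     dimnames = list(NULL, taxa))
    labels <- integer(n)
    expected <- matrix(0, n, length(taxa), dimnames = list(NULL, taxa))
    rare <- intersect(spec$rare_block, taxa)
    for (i in seq_len(n)) {
      set.seed(subseeds[i, seed_col])
      z <- sample.int(length(comps), 1, prob = w)
      labels[i] <- z
      alpha <- comps[[z]]$concentration
      if (comps[[z]]$boost > 1 && length(comps[[z]]$driver_taxa)) {
        alpha[comps[[z]]$driver_taxa] <-
          alpha[comps[[z]]$driver_taxa] * comps[[z]]$boost
      }
      if (length(coupled)) {
        idx <- intersect(coupled, taxa)
        alpha[idx] <- alpha[idx] * latent[i, idx]
      }
      ealpha <- alpha
      if (length(rare)) {
        ealpha[rare] <- alpha[rare] * spec$rare_presence
        present <- stats::rbinom(length(rare), 1, spec$rare_presence) == 1
        alpha[rare][!present] <- 0
      }
      expected[i, ] <- ealpha / sum(ealpha)
      p <- numeric(length(alpha))
      pos <- alpha > 0
      p[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
      p <- p / sum(p)
      depth <- max(1L, stats::rnbinom(1, mu = spec$depth_mean,
                                      size = spec$depth_dispersion))
      counts[i, ] <- stats::rmultinom(1, depth, p)
    }
    rownames(counts) <- paste0(subjects, if (site == "gut") "_G" else "_O")
    rownames(expected) <- rownames(counts)
    list(counts = counts, labels = labels, expected = expected)
  }
  g <- draw_site(spec$gut_components, 2, "gut")
  o <- draw_site(spec$oral_components, 3, "oral")
  gut <- abundance_table(g$counts, site = "gut", mode = "counts",
                         taxonomy = preset_taxonomy(colnames(g$counts)))
  oral <- abundance_table(o$counts, site = "oral", mode = "counts",
                          taxonomy = preset_taxonomy(colnames(o$counts)))
  pairing <- rbind(
    data.frame(subject_id = subjects, site = "gut",
               sample_id = rownames(g$counts), stringsAsFactors = FALSE),
    data.frame(subject_id = subjects, site = "oral",
               sample_id = rownames(o$counts), stringsAsFactors = FALSE))
  cohort <- align_pairs(gut, oral, pairing)
  true_pt <- NULL
  if (!is.null(spec$pathway_ref)) {
    ref <- spec$pathway_ref
    true_pt <- list(
      gut = g$expected %*% ref$copies[colnames(g$expected), , drop = FALSE],
      oral = o$expected %*% ref$copies[colnames(o$expected), , drop = FALSE])
  }
  list(cohort = cohort,
       truth = list(gut_labels = g$labels, oral_labels = o$labels,
                    latent_factors = latent, true_core = spec$core_block,
                    rare_block = spec$rare_block,
                    true_pathway_table = true_pt))
}

# semicolon lineages (phylum;class;order;family;genus) for the preset
# universe; unknown genera fall back to an unclassified lineage.
preset_taxonomy <- function(taxa) {
  fam <- c(
    Bifidobacterium = "Actinobacteria;Actinomycetia;Bifidobacteriales;Bifidobacteriaceae",
    Ruminococcus = "Firmicutes;Clostridia;Clostridiales;Ruminococcaceae",
    Faecalibacterium = "Firmicutes;Clostridia;Clostridiales;Ruminococcaceae",
    Subdoligranulum = "Firmicutes;Clostridia;Clostridiales;Ruminococcaceae",
    Prevotella = "Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae",
    Alloprevotella = "Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae",
    Neisseria = "Proteobacteria;Betaproteobacteria;Neisseriales;Neisseriaceae",
    Kingella = "Proteobacteria;Betaproteobacteria;Neisseriales;Neisseriaceae",
    Eikenella = "Proteobacteria;Betaproteobacteria;Neisseriales;Neisseriaceae",
    Streptococcus = "Firmicutes;Bacilli;Lactobacillales;Streptococcaceae",
    Lactobacillus = "Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae",
    Enterococcus = "Firmicutes;Bacilli;Lactobacillales;Enterococcaceae",
    Granulicatella = "Firmicutes;Bacilli;Lactobacillales;Carnobacteriaceae",
    Abiotrophia = "Firmicutes;Bacilli;Lactobacillales;Aerococcaceae",
    Gemella = "Firmicutes;Bacilli;Bacillales;Bacillales_f",
    Actinomyces = "Actinobacteria;Actinomycetia;Actinomycetales;Actinomycetaceae",
    Atopobium = "Actinobacteria;Coriobacteriia;Coriobacteriales;Atopobiaceae",
    Collinsella = "Actinobacteria;Coriobacteriia;Coriobacteriales;Coriobacteriaceae",
    Eggerthella = "Actinobacteria;Coriobacteriia;Eggerthellales;Eggerthellaceae",
    Slackia = "Actinobacteria;Coriobacteriia;Eggerthellales;Eggerthellaceae",
    Olsenella = "Actinobacteria;Coriobacteriia;Coriobacteriales;Atopobiaceae",
    Scardovia = "Actinobacteria;Actinomycetia;Bifidobacteriales;Bifidobacteriaceae",
    Corynebacterium = "Actinobacteria;Actinomycetia;Corynebacteriales;Corynebacteriaceae",
    Rothia = "Actinobacteria;Actinomycetia;Micrococcales;Micrococcaceae",
    Veillonella = "Firmicutes;Negativicutes;Veillonellales;Veillonellaceae",
    Dialister = "Firmicutes;Negativicutes;Veillonellales;Veillonellaceae",
    Megasphaera = "Firmicutes;Negativicutes;Veillonellales;Veillonellaceae",
    Selenomonas = "Firmicutes;Negativicutes;Selenomonadales;Selenomonadaceae",
    Megamonas = "Firmicutes;Negativicutes;Selenomonadales;Selenomonadaceae",
    Phascolarctobacterium = "Firmicutes;Negativicutes;Acidaminococcales;Acidaminococcaceae",
    Haemophilus = "Proteobacteria;Gammaproteobacteria;Pasteurellales;Pasteurellaceae",
    Aggregatibacter = "Proteobacteria;Gammaproteobacteria;Pasteurellales;Pasteurellaceae",
    Actinobacillus = "Proteobacteria;Gammaproteobacteria;Pasteurellales;Pasteurellaceae",
    Moraxella = "Proteobacteria;Gammaproteobacteria;Pseudomonadales;Moraxellaceae",
    Cardiobacterium = "Proteobacteria;Gammaproteobacteria;Cardiobacteriales;Cardiobacteriaceae",
    Lautropia = "Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae",
    Sutterella = "Proteobacteria;Betaproteobacteria;Burkholderiales;Sutterellaceae",
    Bilophila = "Proteobacteria;Deltaproteobacteria;Desulfovibrionales;Desulfovibrionaceae",
    Desulfovibrio = "Proteobacteria;Deltaproteobacteria;Desulfovibrionales;Desulfovibrionaceae",
    Campylobacter = "Proteobacteria;Epsilonproteobacteria;Campylobacterales;Campylobacteraceae",
    Fusobacterium = "Fusobacteria;Fusobacteriia;Fusobacteriales;Fusobacteriaceae",
    Leptotrichia = "Fusobacteria;Fusobacteriia;Fusobacteriales;Leptotrichiaceae",
    Porphyromonas = "Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae",
    Tannerella = "Bacteroidetes;Bacteroidia;Bacteroidales;Tannerellaceae",
    Parabacteroides = "Bacteroidetes;Bacteroidia;Bacteroidales;Tannerellaceae",
    Bacteroides = "Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae",
    Barnesiella = "Bacteroidetes;Bacteroidia;Bacteroidales;Barnesiellaceae",
    Butyricimonas = "Bacteroidetes;Bacteroidia;Bacteroidales;Odoribacteraceae",
    Odoribacter = "Bacteroidetes;Bacteroidia;Bacteroidales;Odoribacteraceae",
    Alistipes = "Bacteroidetes;Bacteroidia;Bacteroidales;Rikenellaceae",
    Capnocytophaga = "Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae",
    Bergeyella = "Bacteroidetes;Flavobacteriia;Flavobacteriales;Weeksellaceae",
    Akkermansia = "Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Akkermansiaceae",
    Treponema = "Spirochaetes;Spirochaetia;Spirochaetales;Treponemataceae",
    Methanobrevibacter = "Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae",
    Pyramidobacter = "Synergistetes;Synergistia;Synergistales;Synergistaceae",
    Cloacibacillus = "Synergistetes;Synergistia;Synergistales;Synergistaceae",
    Synergistes = "Synergistetes;Synergistia;Synergistales;Synergistaceae",
    Victivallis = "Lentisphaerae;Lentisphaeria;Victivallales;Victivallaceae",
    Christensenella = "Firmicutes;Clostridia;Clostridiales;Christensenellaceae",
    Peptostreptococcus = "Firmicutes;Clostridia;Clostridiales;Peptostreptococcaceae",
    Romboutsia = "Firmicutes;Clostridia;Clostridiales;Peptostreptococcaceae",
    Intestinibacter = "Firmicutes;Clostridia;Clostridiales;Peptostreptococcaceae",
    Filifactor = "Firmicutes;Clostridia;Clostridiales;Peptostreptococcaceae",
    Peptococcus = "Firmicutes;Clostridia;Clostridiales;Peptococcaceae",
    Parvimonas = "Firmicutes;Tissierellia;Tissierellales;Peptoniphilaceae",
    Mogibacterium = "Firmicutes;Clostridia;Clostridiales;Eubacteriaceae",
    Eubacterium_g5 = "Firmicutes;Clostridia;Clostridiales;Eubacteriaceae",
    Eubacterium_g11 = "Firmicutes;Clostridia;Clostridiales;Eubacteriaceae",
    Turicibacter = "Firmicutes;Erysipelotrichia;Erysipelotrichales;Turicibacteraceae",
    Holdemanella = "Firmicutes;Erysipelotrichia;Erysipelotrichales;Erysipelotrichaceae",
    Catenibacterium = "Firmicutes;Erysipelotrichia;Erysipelotrichales;Erysipelotrichaceae",
    Bulleidia = "Firmicutes;Erysipelotrichia;Erysipelotrichales;Erysipelotrichaceae",
    Solobacterium = "Firmicutes;Erysipelotrichia;Erysipelotrichales;Erysipelotrichaceae")
  lachno <- c("Blautia", "Dorea", "Roseburia", "Coprococcus", "Anaerostipes",
              "Butyricicoccus", "Oscillibacter", "Fusicatenibacter",
              "Agathobacter", "Lachnospira", "Lachnoclostridium",
              "Oribacterium", "Stomatobaculum", "Johnsonella", "Catonella",
              "Lachnoanaerobaculum", "Howardella")
  fam[lachno] <- "Firmicutes;Clostridia;Clostridiales;Lachnospiraceae"
  out <- vapply(taxa, function(t) {
    if (!is.na(fam[t])) paste0(fam[t], ";", t)
    else paste0("Bacteria;Unclassified;Unclassified;Unclassified;", t)
  }, character(1))
  names(out) <- taxa
  out
}

#' Generate a synthetic taxon-to-pathway gene-copy reference
#'
#' Non-negative integer gene-copy matrix with an expected fraction
#' `sparsity` of zero entries; non-zero entries are `1 + Poisson(2)`
#' copies. Deterministic under `seed`.
#'
#' @param n_taxa,n_pathways Positive dimensions.
#' @param sparsity Expected zero fraction, in `[0, 1)`. Default 0.3.
#' @param seed Integer seed.
#' @param taxon_ids,pathway_ids Optional id vectors (lengths must match
#'   the dimensions); defaults `taxon1..`, `ko1..`.
#' @return A `gene_copy_reference`.
#' @export
generate_pathway_reference <- function(n_taxa, n_pathways, sparsity = 0.3,
                                       seed = 1, taxon_ids = NULL,
                                       pathway_ids = NULL) {
  if (n_taxa < 1 || n_pathways < 1) stop("dimensions must be positive",
                                         call. = FALSE)
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)",
                                          call. = FALSE)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(n_taxa))
  if (is.null(pathway_ids)) pathway_ids <- sprintf("ko%05d", seq_len(n_pathways))
  stopifnot(length(taxon_ids) == n_taxa, length(pathway_ids) == n_pathways)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  m <- n_taxa * n_pathways
  copies <- matrix(stats::rbinom(m, 1, 1 - sparsity) *
                     (1 + stats::rpois(m, 2)),
                   n_taxa, n_pathways,
                   dimnames = list(taxon_ids, pathway_ids))
  gene_copy_reference(copies)
}
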