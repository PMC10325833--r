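test_that("pathway projection is the declared linear map", {
  tb <- random_rel_table(6, 4, seed = 1)
  # identity reference reproduces the abundance table
  id <- diag(4)
  dimnames(id) <- list(taxon_ids(tb), paste0("pw", 1:4))
  pt <- project_pathways(tb, gene_copy_reference(id))
  expect_equal(unname(pt$values), unname(tb$values), tolerance = 1e-12)
  # worked arithmetic: (0.5, 0.5) through rows (2,0) and (0,4)
  m <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s1", c("ta", "tb")))
  ref <- gene_copy_reference(matrix(c(2, 0, 0, 4), 2, 2, byrow = TRUE,
                                    dimnames = list(c("ta", "tb"),
                                                    c("p1", "p2"))))
  out <- project_pathways(abundance_table(m, "gut", "relative"), ref)
  expect_equal(unname(out$values[1, ]), c(1.0, 2.0))
  # all-zero reference -> all-zero pathways
  zref <- gene_copy_reference(matrix(0, 4, 3,
                                     dimnames = list(taxon_ids(tb),
                                                     paste0("z", 1:3))))
  expect_true(all(project_pathways(tb, zref)$values == 0))
  # missing taxon is named in the error
  small <- gene_copy_reference(id[1:3, ])
  expect_error(project_pathways(tb, small), taxon_ids(tb)[4])
  expect_error(project_pathways(make_table(matrix(1:4, 2, 2)), ref),
               "relative")
})

test_that("projection is linear in rowwise mixtures of tables", {
  a <- random_rel_table(5, 6, seed = 2)
  b <- random_rel_table(5, 6, seed = 3)
  ref <- generate_pathway_reference(6, 8, seed = 4,
                                    taxon_ids = taxon_ids(a))
  mixv <- 0.3 * a$values + 0.7 * b$values
  mix <- abundance_table(mixv, "gut", "relative")
  lhs <- project_pathways(mix, ref)$values
  rhs <- 0.3 * project_pathways(a, ref)$values +
    0.7 * project_pathways(b, ref)$values
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("pathway ranking is log-mean ordered and rescaling-stable", {
  v <- matrix(c(10, 20, 1, 2, 5, 5), 2, 3,
              dimnames = list(c("s1", "s2"), c("pwB", "pwC", "pwA")))
  pt <- structure(list(values = v, category = NULL, site = "gut"),
                  class = "pathway_table")
  r <- rank_pathways(pt, 3)
  expect_identical(r$pathway[1], "pwB")
  expect_error(rank_pathways(pt, 4), "top_n")
  # doubling shifts scores by log10(2), order unchanged
  pt2 <- pt; pt2$values <- 2 * v
  r2 <- rank_pathways(pt2, 3)
  expect_identical(r2$pathway, r$pathway)
  expect_equal(r2$log_score - r$log_score, rep(log10(2), 3),
               tolerance = 1e-10)
  # ties broken by pathway id
  vt <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("s1", "s2"), c("zz", "aa")))
  ptt <- structure(list(values = vt, category = NULL, site = "gut"),
                   class = "pathway_table")
  expect_identical(rank_pathways(ptt, 2)$pathway, c("aa", "zz"))
})

test_that("type enrichment finds driver-loaded pathways with the right type", {
  hits <- 0
  for (seed in 1:10) {
    spec <- cohort_preset("gut-paper", seed = seed)
    gen <- generate_cohort(spec)
    rel <- to_relative(gen$cohort$gut)
    taxa <- taxon_ids(rel)
    copies <- matrix(1, length(taxa), 5,
                     dimnames = list(taxa, paste0("pw", 1:5)))
    # pw1 loads only on the component-2 driver (Ruminococcus)
    copies[, 1] <- 0
    copies["Ruminococcus", 1] <- 10
    pt <- project_pathways(rel, gene_copy_reference(copies))
    fit <- type_communities(gen$cohort$gut, n_null = 0)
    enr <- type_enriched_pathways(pt, fit$types)
    row <- enr[enr$pathway == "pw1", ]
    # the type whose subjects carry component 2 should be representative
    comp2_type <- names(which.max(table(fit$types[gen$truth$gut_labels == 2])))
    if (row$significant && identical(row$representative_type, comp2_type)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("constant pathways and permuted labels stay non-significant", {
  set.seed(6)
  v <- cbind(flat = rep(2, 30), vary = rnorm(30, 5))
  rownames(v) <- sprintf("s%02d", 1:30)
  pt <- structure(list(values = v, category = NULL, site = "gut"),
                  class = "pathway_table")
  enr <- type_enriched_pathways(pt, rep(c("A", "B"), 15))
  flat <- enr[enr$pathway == "flat", ]
  expect_false(flat$significant)
  expect_identical(flat$H, 0)
  expect_true(is.na(flat$representative_type))
  # null labels on a structured table: raw rejections near alpha,
  # BH-significant calls essentially absent
  set.seed(9)
  raw <- c(); bh <- c()
  for (r in 1:30) {
    base <- random_rel_table(30, 5, seed = 100 + r)
    ref <- generate_pathway_reference(5, 20, seed = r,
                                      taxon_ids = taxon_ids(base))
    pt2 <- project_pathways(base, ref)
    enr2 <- type_enriched_pathways(pt2, sample(rep(c("A", "B", "C"), 10)))
    raw <- c(raw, enr2$p < 0.05)
    bh <- c(bh, enr2$significant)
  }
  expect_lt(abs(mean(raw) - 0.05), 0.04)
  expect_lt(mean(bh), 0.05)
})

test_that("taxon-pathway correlation recovers exclusive loadings", {
  ok <- 0
  for (seed in 1:10) {
    tb <- random_rel_table(40, 6, seed = seed)
    copies <- matrix(0, 6, 2,
                     dimnames = list(taxon_ids(tb), c("solo", "dead")))
    copies[1, "solo"] <- 5 # loads only on taxon 1
    pt <- project_pathways(tb, gene_copy_reference(copies))
    res <- suppressMessages(taxon_pathway_correlation(tb, pt))
    if (res$rho[1, "solo"] > 0.9) ok <- ok + 1
    expect_true(all(is.na(res$rho[, "dead"]))) # all-zero pathway
    expect_identical(dim(res$rho), c(6L, 2L))
  }
  expect_gte(ok, 9)
  # subset grid shape contract
  tb <- random_rel_table(20, 6, seed = 1)
  ref <- generate_pathway_reference(6, 7, seed = 2, taxon_ids = taxon_ids(tb))
  pt <- project_pathways(tb, ref)
  res <- taxon_pathway_correlation(tb, pt, taxa = taxon_ids(tb)[1:3],
                                   pathways = colnames(pt$values)[1:4])
  expect_identical(dim(res$rho), c(3L, 4L))
})

test_that("gene-copy reference TSV round-trips with categories", {
  ref <- generate_pathway_reference(8, 5, seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_copy_reference(ref, path)
  cat_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(pathway = colnames(ref$copies)[1:2],
                         category = c("Metabolism", "Cellular Processes")),
              cat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_gene_copy_reference(path, cat_path)
  expect_equal(back$copies, ref$copies)
  expect_identical(unname(back$category["ko00001"]), "Metabolism")
})
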