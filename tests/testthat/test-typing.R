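test_that("shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("jsd matches analytic values and its metric properties hold", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-8)
  # hand evaluation: H((0.75, 0.25)) - ln(2)/2
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.215762, tolerance = 1e-5)
  expect_error(jsd(c(1, 0), c(1, 0, 0)), "length")
  set.seed(11)
  for (i in 1:100) {
    a <- rgamma(6, 0.5); a <- a / sum(a)
    b <- rgamma(6, 0.5); b <- b / sum(b)
    v <- jsd(a, b)
    expect_gte(v, 0)
    expect_lte(v, log(2) + 1e-12)
    expect_equal(v, jsd(b, a))
  }
})

test_that("sqrt-JSD distance matrix is a metric on random tables", {
  tb <- random_rel_table(10, 20, seed = 5)
  d <- jsd_distance_matrix(tb)$values
  expect_equal(max(abs(d - t(d))), 0)
  expect_true(all(diag(d) == 0))
  # exhaustive triangle inequality
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  # identical and disjoint profiles
  m <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  rownames(m) <- c("a", "b", "c"); colnames(m) <- paste0("t", 1:4)
  d2 <- jsd_distance_matrix(abundance_table(m, "gut", "relative"))$values
  expect_equal(d2["a", "b"], 0, tolerance = 1e-8)
  expect_equal(d2["a", "c"], sqrt(log(2)), tolerance = 1e-6)
  expect_error(jsd_distance_matrix(random_rel_table(2, 4, 1)), "at least 3")
})

test_that("pam finds the exhaustive optimum on small instances", {
  # 1-D {0, 1, 10}, k = 1: exhaustive costs are 11, 10, 19 -> medoid 1
  d <- coord_dist(c(0, 1, 10))
  fit <- pam_medoids(d, 1)
  expect_identical(fit$medoid_idx, 2L)
  expect_equal(fit$cost, 10)
  # two tight triads, k = 2, against the C(6,2) brute force
  pts <- c(0, 0.1, 0.2, 50, 50.1, 50.2)
  d2 <- coord_dist(pts)
  fit2 <- pam_medoids(d2, 2)
  oracle <- brute_pam(d2, 2)
  expect_equal(fit2$cost, oracle$cost)
  expect_true(any(vapply(oracle$medoid_sets,
                         function(s) setequal(s, fit2$medoid_idx),
                         logical(1))))
  # k = n: every point its own medoid at zero cost
  fit3 <- pam_medoids(d2, 6)
  expect_equal(fit3$cost, 0)
  expect_identical(fit3$medoid_idx, 1:6)
  expect_error(pam_medoids(d2, 7), "between 1 and n")
})

test_that("pam is invariant to sample order up to relabeling", {
  set.seed(21)
  x <- c(rnorm(6, 0), rnorm(6, 5), rnorm(6, 12))
  d <- coord_dist(x)
  fit <- pam_medoids(d, 3)
  perm <- sample(length(x))
  dp <- dist_matrix(d$values[perm, perm])
  fitp <- pam_medoids(dp, 3)
  expect_equal(fitp$cost, fit$cost)
  expect_true(same_partition(fit$labels[perm], fitp$labels))
})

test_that("distance-form CH equals the centroid form on Euclidean data", {
  # worked 1-D example {0,1} vs {10,11}: B = 100, W = 1 -> CH = 200
  d <- coord_dist(c(0, 1, 10, 11))
  expect_equal(ch_index(d, c(1, 1, 2, 2)), 200, tolerance = 1e-8)
  # coincident points -> +Inf sentinel
  d0 <- coord_dist(rep(3, 5))
  expect_identical(ch_index(d0, c(1, 1, 2, 2, 2)), Inf)
  expect_error(ch_index(d, rep(1, 4)), "2 <= k")
  # random coordinates, random labelings
  set.seed(9)
  coords <- matrix(rnorm(60), 20, 3)
  dd <- coord_dist(coords)
  for (r in 1:50) {
    labels <- sample(1:3, 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(ch_index(dd, labels), ch_centroid(coords, labels),
                 tolerance = 1e-8)
  }
})

test_that("silhouette widths follow the definition and conventions", {
  d <- coord_dist(c(0, 1, 10, 11))
  s <- silhouette_widths(d, c(1, 1, 2, 2))
  expect_equal(s$mean, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-8)
  # singleton cluster member gets 0
  s2 <- silhouette_widths(d, c(1, 1, 1, 2))
  expect_equal(unname(s2$widths[4]), 0)
  expect_error(silhouette_widths(d, rep(1, 4)), "at least 2")
  # agreement with the cluster-package implementation on random data
  set.seed(3)
  dd <- coord_dist(matrix(rnorm(40), 20, 2))
  labels <- pam_medoids(dd, 3)$labels
  ours <- silhouette_widths(dd, labels)$widths
  ref <- cluster::silhouette(as.integer(labels),
                             as.dist(dd$values))[, "sil_width"]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("select_k recovers the planted number of blobs", {
  for (seed in 1:5) {
    set.seed(seed)
    x2 <- rbind(cbind(rnorm(15, 0), rnorm(15, 0)),
                cbind(rnorm(15, 8), rnorm(15, 0)))
    sel2 <- select_k(coord_dist(x2), 2:5)
    expect_identical(sel2$k, 2L)
    x3 <- rbind(cbind(rnorm(12, 0), rnorm(12, 0)),
                cbind(rnorm(12, 8), rnorm(12, 0)),
                cbind(rnorm(12, 0), rnorm(12, 8)))
    sel3 <- select_k(coord_dist(x3), 2:6)
    expect_identical(sel3$k, 3L)
    expect_identical(names(sel3$ch_by_k), as.character(2:6))
  }
  expect_error(select_k(coord_dist(1:10), integer(0)), "empty k range")
  expect_error(select_k(coord_dist(1:5), 2:5), "within")
})

test_that("the silhouette null test is deterministic and bounded", {
  tb <- random_rel_table(15, 12, seed = 8)
  r1 <- null_silhouette_test(tb, 2:4, n_null = 19, seed = 99)
  r2 <- null_silhouette_test(tb, 2:4, n_null = 19, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null, r2$null)
  expect_gte(r1$p, 1 / 20)
  expect_lte(r1$p, 1)
  expect_error(null_silhouette_test(tb, 2:4, n_null = 10), "at least 19")
  # p formula at the extremes
  expect_equal((1 + 0) / (1 + 99), 0.01)
  expect_equal((1 + sum(rep(1, 99) >= 0)) / (1 + 99), 1.0)
})

test_that("between-class analysis separates what it should", {
  tb <- random_rel_table(12, 6, seed = 4)
  # all samples one class -> zero between-class inertia
  b1 <- bca(tb, rep(1, 12))
  expect_equal(b1$between_inertia_ratio, 0)
  # two classes with zero within-class variance -> ratio 1
  m <- rbind(matrix(rep(c(0.7, 0.2, 0.1), each = 4), 4, 3),
             matrix(rep(c(0.1, 0.3, 0.6), each = 4), 4, 3))
  rownames(m) <- paste0("s", 1:8); colnames(m) <- paste0("t", 1:3)
  b2 <- bca(abundance_table(m, "gut", "relative"), rep(1:2, each = 4))
  expect_equal(b2$between_inertia_ratio, 1, tolerance = 1e-12)
  # k = 2: first axis parallel to the class-mean difference
  tb2 <- random_rel_table(20, 5, seed = 6)
  lab <- rep(1:2, each = 10)
  b3 <- bca(tb2, lab)
  xc <- scale(tb2$values, scale = FALSE)
  dmean <- colMeans(xc[lab == 1, ]) - colMeans(xc[lab == 2, ])
  cosang <- abs(sum(dmean * b3$axes[, 1])) /
    sqrt(sum(dmean^2) * sum(b3$axes[, 1]^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
  expect_lte(length(b3$eigenvalues), 1) # k - 1 axes at most
  expect_error(bca(tb2, factor(lab, levels = 1:3)), "empty class")
})

test_that("driver identification maximizes the in-vs-out contrast", {
  # single-taxon table: that taxon for every type
  m <- matrix(c(1, 1, 1, 1), 4, 1,
              dimnames = list(paste0("s", 1:4), "only"))
  tb <- abundance_table(m, "gut", "relative")
  drv <- identify_drivers(tb, c(1, 1, 2, 2))
  expect_identical(drv$driver, c("only", "only"))
  # two identical taxa columns: lexicographically first wins
  m2 <- cbind(a_tax = c(0.8, 0.8, 0.2, 0.2), b_tax = c(0.8, 0.8, 0.2, 0.2),
              c_tax = c(0.2, 0.2, 0.8, 0.8))
  m2 <- m2 / rowSums(m2)
  rownames(m2) <- paste0("s", 1:4)
  drv2 <- identify_drivers(abundance_table(m2, "gut", "relative"),
                           c(1, 1, 2, 2))
  expect_identical(drv2$driver[1], "a_tax")
  expect_identical(drv2$driver[2], "c_tax")
  expect_true(all(c("mean", "q1", "median", "q3", "min", "max") %in%
                    names(drv2)))
})

test_that("type_communities names types by descending size per site", {
  spec <- cohort_preset("gut-paper", seed = 3)
  gen <- generate_cohort(spec)
  fit <- type_communities(gen$cohort$gut, n_null = 0)
  sizes <- table(fit$types)
  expect_identical(names(sizes), paste0("E", seq_len(fit$k)))
  expect_true(all(diff(as.integer(sizes)) <= 0))
  ofit <- type_communities(gen$cohort$oral, n_null = 0)
  expect_true(all(grepl("^O", levels(ofit$types))))
  expect_identical(names(which.max(fit$ch_by_k)), as.character(fit$k))
  expect_output(print(fit), "Community typing")
  expect_output(summary(fit), "between-class inertia")
  paths <- write_typing(fit, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_identical(js$k, as.integer(fit$k))
})
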