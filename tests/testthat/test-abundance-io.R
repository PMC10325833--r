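test_that("construction enforces the table invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "a"), c("x", "y", "z")))
  expect_error(abundance_table(m, "gut", "counts"), "duplicated sample.*a")
  m2 <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "x", "z")))
  expect_error(abundance_table(m2, "gut", "counts"), "duplicated taxon.*x")
  m3 <- matrix(c(1, -1, 2, 3, 4, 5), 2, 3,
               dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(abundance_table(m3, "gut", "counts"), "negative")
  m4 <- matrix(c(0.5, 0.2, 0.4, 0.2, 0.2, 0.2), 2, 3,
               dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(abundance_table(m4, "gut", "relative"), "'a' sums to")
  ok <- matrix(c(0.5, 0.6, 0.3, 0.2, 0.2, 0.2), 2, 3,
               dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_s3_class(abundance_table(ok, "gut", "relative"), "abundance_table")
  expect_error(abundance_table(ok, "gut", "relative",
                               taxonomy = c(q = "a;b;c;d;q")),
               "unknown taxa")
})

test_that("to_relative normalizes rows and rejects empty samples", {
  tb <- make_table(rbind(c(2, 2, 4), c(1, 1, 2)), mode = "counts")
  rel <- to_relative(tb)
  expect_equal(unname(rel$values[1, ]), c(0.25, 0.25, 0.50))
  expect_equal(rel$mode, "relative")
  # already-normalized values passed as counts come out unchanged
  pre <- make_table(rbind(c(0.25, 0.25, 0.5), c(0.1, 0.4, 0.5)),
                    mode = "counts")
  expect_equal(to_relative(pre)$values, pre$values)
  zero <- make_table(rbind(c(1, 2, 3), c(0, 0, 0)), mode = "counts")
  expect_error(to_relative(zero), "s02")
})

test_that("low-abundance filter drops strictly-below-threshold taxa only", {
  m <- rbind(c(0.9998, 1e-4, 1e-4),
             c(0.9999, 1e-4, 0))
  m[2, ] <- m[2, ] / sum(m[2, ])
  colnames(m) <- c("big", "boundary", "tiny")
  rownames(m) <- c("a", "b")
  tb <- abundance_table(m, "gut", "relative")
  out <- filter_low_abundance(tb, 1e-4)
  expect_true("boundary" %in% taxon_ids(out))   # mean exactly 1e-4 kept
  expect_false("tiny" %in% taxon_ids(out))      # mean 5e-5 dropped
  # all above threshold -> identity
  tb2 <- random_rel_table(5, 4, seed = 1)
  expect_equal(filter_low_abundance(tb2, 1e-4)$values, tb2$values)
  expect_error(filter_low_abundance(tb2, 0), "threshold")
  expect_error(filter_low_abundance(tb2, 1), "threshold")
  expect_error(filter_low_abundance(to_relative(
    make_table(rbind(c(1, 2), c(3, 4)))), 2), "threshold")
  expect_error(filter_low_abundance(make_table(rbind(c(1, 2), c(3, 4))),
                                    1e-4), "relative")
})

test_that("raising the filter threshold never adds taxa back", {
  tb <- random_rel_table(12, 30, seed = 42)
  thresholds <- c(1e-5, 1e-4, 1e-3, 1e-2)
  kept <- lapply(thresholds, function(th)
    taxon_ids(filter_low_abundance(tb, th)))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  # relative -> filter leaves retained row sums <= 1
  f <- filter_low_abundance(tb, 1e-2)
  expect_true(all(rowSums(f$values) <= 1 + 1e-12))
})

test_that("TSV round-trip is exact and orientation is auto-detected", {
  tb <- make_table(matrix(c(5, 0, 3, 7, 2, 9), 2, 3), mode = "counts",
                   taxonomy = c(t01 = "F;C;O;Fam1;t01",
                                t03 = "F;C;O;Fam2;t03"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tb, path)
  back <- suppressMessages(read_abundance(path, site = "gut",
                                          mode = "counts"))
  expect_identical(back$values, tb$values)
  expect_identical(back$taxonomy, tb$taxonomy)
  # relative round-trip within 1e-12
  rel <- to_relative(tb)
  write_abundance(rel, path)
  back2 <- suppressMessages(read_abundance(path, "gut", "relative"))
  expect_equal(back2$values, rel$values, tolerance = 1e-12)
  # samples-as-rows sentinel
  df <- data.frame(sample_id = c("a", "b"), t1 = c(1, 2), t2 = c(3, 4))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  flipped <- suppressMessages(read_abundance(p2, "oral", "counts"))
  expect_identical(dim(flipped$values), c(2L, 2L))
  expect_equal(flipped$values["b", "t2"], 4)
  # duplicated taxon id in file
  writeLines(c("# a comment", "taxon_id\ts1\ts2", "tA\t1\t2", "tA\t3\t4"), p2)
  expect_error(suppressMessages(read_abundance(p2, "gut", "counts")),
               "duplicated id.*tA")
})

test_that("BIOM input is accepted read-only", {
  tb <- make_table(matrix(c(5, 1, 3, 7, 2, 9), 2, 3), mode = "counts")
  b <- biomformat::make_biom(t(tb$values)) # biom wants taxa x samples
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- read_abundance(path, site = "gut", mode = "counts")
  expect_equal(back$values[rownames(tb$values), colnames(tb$values)],
               tb$values)
})

test_that("align_pairs reorders, drops incomplete subjects and validates", {
  gut <- make_table(matrix(1:9, 3, 3,
                           dimnames = list(c("g1", "g2", "g3"), NULL)),
                    site = "gut")
  oral <- make_table(matrix(1:9, 3, 3,
                            dimnames = list(c("o1", "o2", "o3"), NULL)),
                     site = "oral")
  pairing <- data.frame(
    subject_id = rep(c("A", "B", "C"), 2),
    site = rep(c("gut", "oral"), each = 3),
    sample_id = c("g2", "g1", "g3", "o3", "o1", "o2"))
  ph <- align_pairs(gut, oral, pairing)
  expect_identical(ph$subjects, c("A", "B", "C"))
  expect_identical(rownames(ph$gut$values), c("g2", "g1", "g3"))
  expect_identical(rownames(ph$oral$values), c("o3", "o1", "o2"))
  # subject only in gut is dropped with a message
  pairing2 <- pairing[-4, ]
  expect_message(ph2 <- align_pairs(gut, oral, pairing2), "dropping.*A")
  expect_identical(ph2$subjects, c("B", "C"))
  # subject mapped to two gut samples
  bad <- rbind(pairing,
               data.frame(subject_id = "A", site = "gut", sample_id = "g3"))
  expect_error(align_pairs(gut, oral, bad), "more than one gut")
  # empty intersection
  none <- pairing[pairing$site == "gut", ]
  expect_error(suppressMessages(align_pairs(gut, oral, none)),
               "no paired subjects")
})

test_that("pairing files read into the long format align_pairs expects", {
  gp <- withr::local_tempfile(fileext = ".tsv")
  op <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(subject_id = c("A", "B"), sample_id = c("g1", "g2")),
              gp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subject_id = c("A", "B"), sample_id = c("o1", "o2")),
              op, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- read_pairing(gp, op)
  expect_identical(names(pr), c("subject_id", "site", "sample_id"))
  expect_identical(nrow(pr), 4L)
  expect_setequal(unique(pr$site), c("gut", "oral"))
})
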