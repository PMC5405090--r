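test_that("read_counts parses a toy table and sorts hours", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_toy_counts_file(path)
  cm <- read_counts(path, sample_id = "s1")
  expect_s3_class(cm, "count_matrix")
  expect_equal(nrow(cm), 3)
  expect_equal(timepoints(cm), c(3, 4, 5, 6, 8))
  expect_equal(sample_id(cm), "s1")
  expect_equal(unname(unclass(cm)["gB", ]), c(5, 10, 15, 20, 25))

  # comma dialect is sniffed
  pathc <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("\t", ",", readLines(path)), pathc)
  expect_equal(unclass(read_counts(pathc)), unclass(cm),
               ignore_attr = TRUE)

  # unsorted hour columns come back ascending
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\t8\t3\t5", "gX\t1\t2\t3"), path2)
  expect_equal(timepoints(read_counts(path2)), c(3, 5, 8))
  expect_equal(unname(unclass(read_counts(path2))[1, ]), c(2, 3, 1))
})

test_that("read_counts rejects malformed input with informative errors", {
  dup <- withr::local_tempfile()
  writeLines(c("gene_id\t3\t4", "gA\t1\t2", "gA\t3\t4"), dup)
  expect_error(read_counts(dup), "duplicate gene id.*gA")

  bad <- withr::local_tempfile()
  writeLines(c("gene_id\t3\t4", "gA\t1\tx"), bad)
  expect_error(read_counts(bad), "non-numeric.*gA")

  hdr <- withr::local_tempfile()
  writeLines(c("gene_id\t3\tlate", "gA\t1\t2"), hdr)
  expect_error(read_counts(hdr), "malformed header")
})

test_that("counts written by the generator round-trip losslessly", {
  sim <- simulate_dataset(simulation_spec(n_regulators = 2,
                                          targets_per_regulator = 2,
                                          n_null_genes = 5, seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(sim$counts, path)
  back <- read_counts(path, sample_id = sample_id(sim$counts))
  expect_identical(unclass(back), unclass(sim$counts))
  expect_equal(timepoints(back), timepoints(sim$counts))
})

test_that("size factors match a brute-force median-of-ratios oracle", {
  cm <- random_count_matrix(seed = 3)
  sf <- estimate_size_factors(cm)
  expect_equal(unname(sf), size_factor_oracle(unclass(cm)),
               tolerance = 1e-12)
  expect_true(all(sf > 0))

  # identical columns give unit factors
  same <- count_matrix(matrix(rep(c(3L, 7L, 11L), 4), nrow = 3,
                              dimnames = list(c("a", "b", "c"), NULL)),
                       timepoints = 1:4)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 4))

  # invariant to gene order
  perm <- unclass(cm)[sample(nrow(cm)), ]
  expect_equal(estimate_size_factors(count_matrix(perm, timepoints(cm))),
               sf)
})

test_that("size-factor ratios are scale-equivariant per column", {
  # size factors are relative depths, defined up to a common constant:
  # scaling one column by c multiplies that column's factor relative to
  # every other column by exactly c
  cm <- random_count_matrix(seed = 11)
  base <- estimate_size_factors(cm)
  for (j in c(1, 4)) {
    scaled <- unclass(cm)
    scaled[, j] <- scaled[, j] * 3L
    sf <- estimate_size_factors(count_matrix(scaled, timepoints(cm)))
    expect_equal(unname(sf[j] / sf[-j]), unname(3 * base[j] / base[-j]),
                 tolerance = 1e-12)
    # the unscaled columns keep their relative depths
    expect_equal(unname(outer(sf[-j], sf[-j], "/")),
                 unname(outer(base[-j], base[-j], "/")),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree with DESeq2 on the same table", {
  # odd gene count: the arithmetic median of ratios and DESeq2's median
  # of log ratios pick the same element (they differ in how an even-count
  # median interpolates)
  cm <- random_count_matrix(n_genes = 21, seed = 5)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = unclass(cm),
    colData = S4Vectors::DataFrame(row.names = colnames(cm)),
    design = ~1)
  dds <- DESeq2::estimateSizeFactors(dds)
  expect_equal(unname(estimate_size_factors(cm)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-8)
})

test_that("size factors error without an all-positive reference gene", {
  m <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  expect_error(estimate_size_factors(count_matrix(m, 1:2)),
               "no reference genes")
})

test_that("normalize_log applies log2(count/factor + pseudocount)", {
  m <- matrix(c(0L, 7L, 3L, 15L), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  cm <- count_matrix(m, timepoints = c(3, 4))
  expr <- normalize_log(cm, factors = c(1, 1))
  expect_equal(expr["a", 1], 0)          # log2(0 + 1)
  expect_equal(expr["a", 2], log2(4))    # count 3 -> log2(3 + 1)
  expect_equal(expr["b", 1], 3)          # count 7 -> log2(8)

  cm2 <- random_count_matrix(seed = 8)
  sf <- estimate_size_factors(cm2)
  expr2 <- normalize_log(cm2, sf, pseudocount = 0.5)
  manual <- log2(sweep(unclass(cm2), 2, sf, "/") + 0.5)
  expect_equal(unclass(expr2), manual, ignore_attr = TRUE)
  # exp-undo recovers counts / factor exactly
  expect_equal(sweep(2^unclass(expr2) - 0.5, 2, sf, "*"),
               unclass(cm2), ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(normalize_log(cm2, factors = c(0, 1, 1, 1, 1)), "positive")
})

test_that("filter_unexpressed drops exactly the all-zero genes", {
  set.seed(2)
  m <- matrix(rpois(50, 3), 10, 5,
              dimnames = list(sprintf("g%d", 1:10), c(3, 4, 5, 6, 8)))
  m[c(2, 5, 9), ] <- 0L
  m[4, ] <- c(0L, 0L, 1L, 0L, 0L)       # one flicker keeps a gene
  cm <- count_matrix(m)
  kept <- filter_unexpressed(cm)
  expect_equal(nrow(kept), 7)
  expect_false(any(c("g2", "g5", "g9") %in% rownames(kept)))
  expect_true("g4" %in% rownames(kept))
  # idempotent
  expect_identical(unclass(filter_unexpressed(kept)), unclass(kept))
})

test_that("select_timepoints restricts to the grid or errors", {
  m <- matrix(seq_len(14), 2, 7,
              dimnames = list(c("a", "b"), c(1, 2, 3, 4, 5, 6, 8)))
  cm <- count_matrix(m)
  sel <- select_timepoints(cm, c(3, 4, 5, 6, 8))
  expect_equal(timepoints(sel), c(3, 4, 5, 6, 8))
  expect_equal(ncol(sel), 5)
  expect_identical(unclass(select_timepoints(sel, c(3, 4, 5, 6, 8))),
                   unclass(sel))
  expect_error(select_timepoints(cm, c(3, 7)), "missing: 7")
})

test_that("normalized matrices round-trip through the commented format", {
  cm <- random_count_matrix(seed = 13)
  expr <- normalize_log(cm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_normalized(expr, path)
  expect_equal(readLines(path, n = 1), "#normalized log2")
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            row.names = 1)
  expect_equal(as.matrix(back), unclass(expr), ignore_attr = TRUE,
               tolerance = 1e-12)
})
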