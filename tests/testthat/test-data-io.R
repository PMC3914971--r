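test_that("matrix TSV reads in both orientations and validates labels", {
  vals <- matrix(c(2.1, 1.9, 2.5, 2.0, 2.2, 1.8), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("pA", "pB")))
  labs <- c("ACA", "SCC", "ACA")

  # samples-as-rows with embedded class column
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass\tpA\tpB",
               paste("s1", "ACA", "2.1", "2", sep = "\t"),
               paste("s2", "SCC", "1.9", "2.2", sep = "\t"),
               paste("s3", "ACA", "2.5", "1.8", sep = "\t")), f1)
  m1 <- read_cna_matrix(f1)
  expect_equal(dim(m1), c(3L, 2L))
  expect_equal(unname(m1$values), unname(vals))
  expect_identical(m1$labels, labs)

  # probes-as-rows with embedded class row transposes to the same object
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3",
               paste("class", "ACA", "SCC", "ACA", sep = "\t"),
               paste("pA", "2.1", "1.9", "2.5", sep = "\t"),
               paste("pB", "2", "2.2", "1.8", sep = "\t")), f2)
  m2 <- read_cna_matrix(f2, orientation = "probes")
  expect_equal(m2$values, m1$values)
  expect_identical(m2$labels, m1$labels)

  # separate two-column labels file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpA\tpB",
               paste("s1", "2.1", "2", sep = "\t"),
               paste("s2", "1.9", "2.2", sep = "\t"),
               paste("s3", "2.5", "1.8", sep = "\t")), f3)
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tACA", "s2\tSCC", "s3\tACA"), lf)
  m3 <- read_cna_matrix(f3, labels = lf)
  expect_equal(m3$values, m1$values)

  # missing label for one sample
  lf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tACA", "s2\tSCC"), lf2)
  expect_error(read_cna_matrix(f3, labels = lf2), "s3")
})

test_that("malformed matrix cells and duplicate ids are rejected by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass\tpA\tpB",
               paste("s1", "ACA", "2.1", "", sep = "\t"),
               paste("s2", "SCC", "1.9", "2.2", sep = "\t")), f)
  expect_error(read_cna_matrix(f), "pB")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tclass\tpA\tpB",
               paste("s1", "ACA", "2.1", "x2", sep = "\t"),
               paste("s2", "SCC", "1.9", "2.2", sep = "\t")), f2)
  expect_error(read_cna_matrix(f2), "s1")

  v <- matrix(1:4, 2, dimnames = list(c("s1", "s1"), c("a", "b")))
  expect_error(cna_matrix(v * 1.0, c("ACA", "SCC")), "s1")
  v2 <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("a", "a")))
  expect_error(cna_matrix(v2 * 1.0, c("ACA", "SCC")), "duplicate probe")
  v3 <- matrix(c(1, NA, 3, 4), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(cna_matrix(v3, c("ACA", "SCC")), "non-finite")
})

test_that("canonical write/read round-trips values and text", {
  out <- small_cohort(seed = 11, n_pos = 5L, n_neg = 4L, p_total = 8L,
                      n_informative = 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cna_matrix(out$matrix, f)
  back <- read_cna_matrix(f)
  expect_equal(back$values, out$matrix$values)
  expect_identical(back$labels, out$matrix$labels)

  # text-level round trip for finite decimal inputs
  v <- matrix(c(2.13, 1.9, 2.005, 2), 2,
              dimnames = list(c("s1", "s2"), c("pA", "pB")))
  m <- cna_matrix(v, c("ACA", "SCC"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cna_matrix(m, f1)
  write_cna_matrix(read_cna_matrix(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("IFS table export enforces the contract and round-trips", {
  tab <- structure(data.frame(i = 1:3, sn = c(0.5, 0.625, 0.75),
                              sp = c(0.4, 0.5, 0.6), acc = c(0.45, 0.57, 0.7),
                              mcc = c(0.1, 0.223, 0.31)),
                   class = c("ifs_table", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_table(tab, f)
  lines <- readLines(f)
  expect_length(lines, 4L)  # header + 3 rows
  back <- read_ifs_table(f)
  expect_equal(back$mcc, tab$mcc)
  expect_equal(back$sn, tab$sn)

  expect_error(write_ifs_table(tab[0, ], f), "empty")
  bad <- tab; bad$i <- 2:4
  expect_error(write_ifs_table(bad, f), "contiguous")
})

test_that("GMT parsing collapses duplicates and flags short lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("hsa04310\tWnt\tG1\tG2", "setB\tdesc\tG3\tG3"), f)
  sets <- read_gmt(f)
  expect_length(sets, 2L)
  expect_identical(sets[[1]]$members, c("G1", "G2"))
  expect_identical(sets[[2]]$members, "G3")

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tdesc\tG1", "short\tdesc"), f2)
  expect_error(read_gmt(f2), "line 2")

  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), f3)
  expect_identical(read_gmt(f3), list())

  # write_gmt round trip
  f4 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f4)
  expect_equal(read_gmt(f4), sets)
})
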