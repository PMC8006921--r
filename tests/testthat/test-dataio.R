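write_gct_fixture <- function(path, ids, symbols, m) {
  lines <- c("#1.2", paste(nrow(m), ncol(m), sep = "\t"),
             paste(c("NAME", "Description", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(ids[i], symbols[i], m[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}

test_that("GCT round-trips and reconciles permuted companion files by id", {
  m <- matrix(as.numeric(1:12), 3, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  ids <- c("P1", "P2", "P3")
  syms <- c("A", "B", "C")
  f1 <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f1, ids, syms, m)

  b <- read_expression(f1, format = "gct")
  expect_identical(dim(b$presence), c(3L, 4L))
  expect_identical(b$probe_ids, ids)
  expect_identical(b$sample_ids, paste0("S", 1:4))
  expect_equal(unname(b$presence), m, ignore_attr = TRUE)

  ## same matrix as variance companion, rows and columns permuted
  perm_r <- c(3, 1, 2); perm_c <- c(4, 2, 1, 3)
  f2 <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f2, ids[perm_r], syms[perm_r],
                    m[perm_r, perm_c, drop = FALSE])
  b2 <- read_expression(f1, f2, format = "gct")
  expect_equal(unname(b2$variance), m, ignore_attr = TRUE)

  ## unpermuted companion gives the identical bundle
  f3 <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f3, ids, syms, m)
  b3 <- read_expression(f1, f3, format = "gct")
  expect_identical(b2$variance, b3$variance)
})

test_that("expression readers reject malformed input with precise messages", {
  m <- matrix(as.numeric(1:8), 2, 4, dimnames = list(NULL, paste0("S", 1:4)))
  f <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f, c("P2", "P2"), c("A", "B"), m)
  expect_error(read_expression(f, format = "gct"), "P2")

  f2 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "1\t1", "NAME\tDescription\tS1", "P1\tA\t1"), f2)
  expect_error(read_expression(f2, format = "gct"), "#1.2")

  f3 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "1\t2", "NAME\tDescription\tS1\tS2",
               "P1\tA\t1\tabc"), f3)
  expect_error(read_expression(f3, format = "gct"), "abc")

  ## probe-set mismatch between the two files names the difference
  f4 <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f4, c("P1", "PX"), c("A", "B"), m)
  f5 <- withr::local_tempfile(fileext = ".gct")
  write_gct_fixture(f5, c("P1", "P2"), c("A", "B"), m)
  expect_error(read_expression(f5, f4, format = "gct"), "P2")
})

test_that("CLS and TSV phenotype dialects parse and validate", {
  f <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# case control", "case case control control"), f)
  ann <- read_phenotypes(f, format = "cls")
  expect_equal(nrow(ann), 4L)
  expect_identical(ann$group, c("case", "case", "control", "control"))
  expect_true(all(ann$sex == "unknown"))

  ## numeric labels map through the class-name line
  f2 <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# case control", "0 0 1 1"), f2)
  expect_identical(read_phenotypes(f2, format = "cls")$group, ann$group)

  f3 <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("5 2 1", "# case control", "case case control control"), f3)
  expect_error(read_phenotypes(f3, format = "cls"), "5 samples")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tsex", "a\tcase\tM", "b\tcase\tF",
               "c\tcontrol\tM", "d\tcontrol\tF"), f4)
  ann4 <- read_phenotypes(f4, format = "tsv")
  expect_identical(ann4$sex, c("male", "female", "male", "female"))

  f5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tsex", "a\tcase\tX"), f5)
  expect_error(read_phenotypes(f5, format = "tsv"), "allowed")
})

test_that("GMT parsing collapses duplicates, flags bad lines, handles empty", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc1\tA\tB\tC", "S2\tdesc2\tB\tD"), f)
  lib <- read_gmt(f)
  expect_length(lib, 2L)
  expect_identical(lib$sets$S1, c("A", "B", "C"))
  expect_identical(lib$sets$S2, c("B", "D"))

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tA\tB", f2)
  expect_warning(lib2 <- read_gmt(f2), "1 duplicate")
  expect_identical(lib2$sets$S1, c("A", "B"))
  expect_identical(attr(lib2, "n_duplicates"), 1L)

  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc", f3)
  expect_error(read_gmt(f3), "line 1")

  f4 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\td\tA", "S1\td\tB"), f4)
  expect_error(read_gmt(f4), "duplicate set name")

  f5 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), f5)
  expect_warning(lib5 <- read_gmt(f5), "empty")
  expect_length(lib5, 0L)
})

test_that("result writers use documented sort keys and round-trip", {
  screen <- data.frame(set = c("B", "A", "C"), n_hits = c(3L, 2L, 5L),
                       p = c(0.2, 0.01, 0.01), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(screen, f)
  back <- read_results(f)
  expect_identical(back$set, c("A", "C", "B"))  # p ascending, then set name
  expect_identical(back$p, c(0.01, 0.01, 0.2))

  calls <- data.frame(gene = c("G2", "G1"), score = c(1, -1),
                      direction = c("up", "down"), stringsAsFactors = FALSE)
  counts <- c(G1 = 5L, G2 = 1L)
  sig <- median_select(counts, structure(calls,
                                         class = c("gene_calls",
                                                   "data.frame")))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(sig, f2)
  back2 <- read_results(f2)
  expect_identical(names(back2), c("gene", "count", "direction", "selected"))
  expect_identical(back2$gene, c("G1", "G2"))
  expect_identical(back2$count, c(5L, 1L))
  expect_identical(back2$selected, c(TRUE, FALSE))

  ## write -> read -> write is byte-stable
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_results(back2, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("probe/sample order of inputs never changes downstream scores", {
  set.seed(7)
  fx <- random_filter_fixture(12)
  b <- fx$bundle
  perm_r <- sample(n_probes(b)); perm_c <- sample(n_samples(b))
  b_perm <- expression_bundle(b$probe_ids[perm_r],
                              b$gene_symbols[perm_r],
                              b$presence[perm_r, perm_c],
                              b$variance[perm_r, perm_c],
                              b$sample_ids[perm_c])
  r1 <- signal_to_noise(collapse_probes(b), fx$ann)
  r2 <- signal_to_noise(collapse_probes(b_perm), fx$ann)
  expect_equal(r1, r2, ignore_attr = TRUE)
})
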