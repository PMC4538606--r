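test_that("association tables deduplicate multi-evidence rows and expose neighbors", {
  path <- write_tsv_fixture(c("mirna\tdisease\tevidence",
                              "m1\td1\tPMID:1",
                              "m1\td1\tPMID:2",
                              "m2\td1\tPMID:3"))
  a <- read_association_table(path, "mirna", "disease",
                              columns = c("mirna", "disease"))
  expect_equal(n_edges(a), 2L)
  expect_equal(neighbors(a, "d1", side = "right"), c("m1", "m2"))
  expect_equal(neighbors(a, "m1", side = "left"), "d1")
  expect_equal(neighbors(a, "m9", side = "left"), character(0))
})

test_that("reader errors name the file for missing/empty/misdeclared inputs", {
  expect_error(read_association_table("does-not-exist.tsv", "a", "b"),
               "not found")
  empty <- write_tsv_fixture("mirna\tdisease")
  expect_error(read_association_table(empty, "mirna", "disease"),
               "no associations")
  path <- write_tsv_fixture(c("x\ty", "m1\td1"))
  expect_error(read_association_table(path, "mirna", "disease",
                                      columns = c("mirna", "disease")),
               "not found in")
})

test_that("labels are normalized and aliases applied on read", {
  path <- write_tsv_fixture(c("lncrna\tdisease",
                              " XIST \tBreast   Cancer",
                              "xist\tbreast cancer",
                              "H19\tbreast carcinoma"))
  ali <- data.frame(alias = "breast carcinoma", canonical = "breast cancer")
  a <- read_association_table(path, "lncrna", "disease", aliases = ali)
  expect_equal(n_edges(a), 2L)
  expect_setequal(a$edges$left, c("xist", "h19"))
  expect_equal(unique(a$edges$right), "breast cancer")
})

test_that("round-trip write/read reproduces the edge set and is idempotent", {
  a <- association_set(c("m1", "m2", "m3"), c("d1", "d1", "d2"),
                       "mirna", "disease")
  path <- tempfile(fileext = ".tsv")
  write_association_table(a, path)
  b <- read_association_table(path, "mirna", "disease")
  expect_equal(b$edges, a$edges)
  write_association_table(b, path)
  expect_equal(read_association_table(path, "mirna", "disease")$edges,
               a$edges)
})

test_that("miRNA genomic copies merge to the mature stem, idempotently", {
  a <- association_set(
    c("hsa-mir-125b-1", "hsa-mir-125b-2", "hsa-mir-21", "hsa-mir-7-1",
      "hsa-mir-7-2"),
    c("d1", "d1", "d1", "d1", "d2"),
    "mirna", "disease")
  m <- merge_mirna_copies(a)
  expect_setequal(
    paste(m$edges$left, m$edges$right),
    c("hsa-mir-125b d1", "hsa-mir-21 d1", "hsa-mir-7 d1", "hsa-mir-7 d2"))
  expect_equal(n_edges(m), 4L)
  expect_equal(merge_mirna_copies(m)$edges, m$edges)
  # names without a copy suffix, incl. single-digit mature names, untouched
  b <- association_set(c("hsa-mir-21", "hsa-mir-1"), c("d1", "d2"),
                       "mirna", "disease")
  expect_equal(merge_mirna_copies(b)$edges, b$edges)
  # disabling the rule is a no-op
  expect_equal(merge_mirna_copies(a, pattern = NULL)$edges, a$edges)
})

test_that("filter_to_universe keeps only in-universe gold pairs and never grows", {
  gold <- association_set(c("l1", "l2"), c("d1", "d9"), "lncrna", "disease")
  f <- filter_to_universe(gold, diseases = "d1", lncrnas = c("l1", "l2"))
  expect_equal(f$edges, data.frame(left = "l1", right = "d1"))
  expect_equal(n_edges(filter_to_universe(gold, "d1", character(0))), 0L)
  expect_lte(n_edges(f), n_edges(gold))
  empty <- filter_to_universe(gold, character(0), character(0))
  expect_equal(n_edges(filter_to_universe(empty, "d1", "l1")), 0L)
})

test_that("disease DAG inputs load multimaps and reject cyclic term graphs", {
  map <- write_tsv_fixture(c("disease\tterm", "A\ttA1", "A\ttA2", "B\ttB"))
  edg <- write_tsv_fixture(c("parent\tchild", "root\ttA1", "root\ttA2",
                             "root\ttB"))
  got <- read_disease_dag_inputs(map, edg)
  expect_equal(got$mapping$a, c("ta1", "ta2"))
  expect_equal(got$mapping$b, "tb")
  expect_equal(nrow(got$edges), 3L)

  cyc <- write_tsv_fixture(c("parent\tchild", "x\ty", "y\tx"))
  expect_error(read_disease_dag_inputs(map, cyc), "cyclic.*x|cyclic.*y")
})
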