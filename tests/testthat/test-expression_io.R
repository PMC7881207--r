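test_that("expression matrix TSV reading honors the contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2\tS3\tS4",
               "P1\t1.5\t2\t3\t4",
               "P2\t0\t-1\t2.25\t8",
               "P3\t5\t5\t5\t5"), f)
  m <- read_expression_matrix(f)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("P1", "P2", "P3"))
  expect_identical(m["P2", "S3"], 2.25)

  writeLines(c("probe_id\tS1\tS2", "P1\t1\t2", "P1\t3\t4"), f)
  expect_error(read_expression_matrix(f), "duplicate probe id.*P1")

  writeLines(c("probe_id\tS1\tS2", "P1\t1\t2", "P2\t3"), f)
  expect_error(read_expression_matrix(f), "ragged row.*line 3")

  writeLines("probe_id\tS1\tS2", f)
  expect_error(read_expression_matrix(f), "no data rows")

  writeLines(c("probe_id\tS1\tS2", "P1\tNA\t2", "P2\t3\t4"), f)
  expect_error(read_expression_matrix(f), "missing.*P1")
  expect_warning(m2 <- read_expression_matrix(f, missing_policy = "drop"),
                 "dropping 1")
  expect_identical(rownames(m2), "P2")
})

test_that("write/read round trip is bit-exact on random matrices", {
  set.seed(42)
  f <- withr::local_tempfile(fileext = ".tsv")
  for (i in 1:100) {
    m <- rand_expr(sample(1:12, 1), sample(2:8, 1))
    write_expression_matrix(m, f)
    expect_identical(read_expression_matrix(f), m)
  }
})

test_that("linear-scale input is log2(x+1) transformed at load", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2", "P1\t0\t3", "P2\t7\t15"), f)
  m <- read_expression_matrix(f, linear_scale = TRUE)
  expect_equal(unname(m), matrix(c(0, 3, 2, 4), nrow = 2, byrow = FALSE))
})

test_that("sample table parsing enforces the vocabulary", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\tstage\tsubject_id\tsmoking",
               "N1\tnormal\t2\tS1\tno",
               "N2\tnormal\t2\tS2\tno",
               "T1\ttumor\t2\tS1\tno",
               "T2\ttumor\t2\tS2\tNA"), f)
  st <- read_sample_table(f)
  expect_identical(sum(st$condition == "tumor"), 2L)
  expect_true(is.na(st$smoking[4]))
  expect_identical(st$stage, rep(2L, 4))

  g <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(st, g)
  expect_identical(read_sample_table(g), st)

  writeLines(c("sample_id\tcondition\tstage\tsubject_id\tsmoking",
               "T1\tTumour\t2\tS1\tno"), f)
  expect_error(read_sample_table(f), "condition outside")

  writeLines(c("sample_id\tcondition\tstage\tsubject_id\tsmoking",
               "T1\ttumor\t2\tS1\tno",
               "T1\ttumor\t3\tS2\tno"), f)
  expect_error(read_sample_table(f), "duplicate sample_id")
})

test_that("gene list files support comments and round trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# candidate TS genes", "TP53", "RB1  ", "", "APC # classic"), f)
  gl <- read_gene_list(f, name = "list1")
  expect_identical(gl$members, c("TP53", "RB1", "APC"))
  g <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(gl, g)
  expect_identical(read_gene_list(g, "list1")$members, gl$members)

  writeLines("# only a comment", f)
  expect_error(read_gene_list(f), "empty")
  expect_error(gene_list("x", c("A", "A")), "duplicate")
})

test_that("subset_stage filters without duplicating or reordering", {
  set.seed(7)
  m <- rand_expr(5, 10, sample_prefix = "X")
  st <- data.frame(sample_id = colnames(m),
                   condition = rep(c("normal", "tumor"), each = 5),
                   stage = c(rep(NA_integer_, 5), c(1L, 2L, 2L, 3L, 3L)),
                   subject_id = sprintf("S%02d", c(1:5, 1:5)),
                   smoking = "no")
  sub <- subset_stage(m, st, stage = 2)
  expect_identical(colnames(sub$matrix),
                   c(colnames(m)[1:5], colnames(m)[c(7, 8)]))
  expect_identical(sub$samples$sample_id, colnames(sub$matrix))
  sub_t <- subset_stage(m, st, stage = 2, include_normals = FALSE)
  expect_identical(ncol(sub_t$matrix), 2L)
  expect_error(subset_stage(m, st, stage = 4), "no tumor sample at stage 4")

  # counting oracle on random fixtures
  for (i in 1:50) {
    n_n <- sample(2:6, 1); n_t <- sample(2:8, 1)
    mm <- rand_expr(3, n_n + n_t)
    stages <- sample(1:3, n_t, replace = TRUE)
    tab <- data.frame(sample_id = colnames(mm),
                      condition = rep(c("normal", "tumor"), c(n_n, n_t)),
                      stage = c(rep(NA_integer_, n_n), stages),
                      subject_id = colnames(mm), smoking = "no")
    s <- stages[1]
    sub <- subset_stage(mm, tab, stage = s)
    expect_identical(ncol(sub$matrix), n_n + sum(stages == s))
  }
})

test_that("zscore_rows standardizes rows and is idempotent", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("P1", c("a", "b", "c")))
  expect_equal(unname(zscore_rows(m)), matrix(c(-1, 0, 1), nrow = 1))

  mc <- matrix(5, nrow = 1, ncol = 4,
               dimnames = list("P1", paste0("s", 1:4)))
  expect_warning(z <- zscore_rows(mc), "constant")
  expect_identical(unname(z), matrix(0, nrow = 1, ncol = 4))

  expect_error(zscore_rows(m[, 1, drop = FALSE]), "at least 2")

  set.seed(11)
  r <- rand_expr(30, 12)
  z <- zscore_rows(r)
  expect_true(max(abs(rowMeans(z))) < 1e-12)
  expect_true(max(abs(apply(z, 1, sd) - 1)) < 1e-12)
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)
})

test_that("collapse_probes keeps the max-variance representative", {
  m <- rbind(P1 = c(0, 2, 4, 6), P2 = c(1, 1.5, 2, 2.5), P3 = c(9, 9, 9, 8))
  colnames(m) <- paste0("s", 1:4)
  map <- c(P1 = "GENE1", P2 = "GENE1", P3 = "GENE2")
  out <- collapse_probes(m, map)
  expect_identical(rownames(out), c("GENE1", "GENE2"))
  expect_identical(unname(out["GENE1", ]), unname(m["P1", ]))  # var 20/3 > 5/12
  expect_identical(unname(out["GENE2", ]), unname(m["P3", ]))

  expect_error(collapse_probes(m, c(PX = "G")), "covers none")

  set.seed(5)
  for (i in 1:20) {
    mm <- rand_expr(15, 6)
    genes <- sample(sprintf("G%02d", 1:6), 15, replace = TRUE)
    map <- setNames(genes, rownames(mm))
    keep <- sample(rownames(mm), 10)
    out <- collapse_probes(mm, map[keep])
    expect_identical(nrow(out), length(unique(map[keep])))
  }
})
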