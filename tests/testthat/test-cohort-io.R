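test_that("expression TSV round-trips and collapses duplicate probes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ex <- toy_expr(matrix(c(1, 2, 3, 4, 5, 6), 3, 2), genes = c("A", "B", "C"),
                 samples = c("s1", "s2"))
  write_expression(ex, path)
  back <- read_expression(path, cohort = "c1")
  expect_equal(dim(back$values), c(3L, 2L))
  expect_equal(back$values, ex$values)

  # duplicate probe rows collapse to the per-sample maximum:
  # TP53 rows (1, 8) and (5, 2) -> (5, 8)
  writeLines(c("gene\ts1\ts2", "TP53\t1\t8", "KRAS\t3\t3", "TP53\t5\t2"),
             path)
  expect_message(dup <- read_expression(path), "collapsed 1 duplicate")
  expect_equal(unname(dup$values["TP53", ]), c(5, 8))
  expect_equal(gene_ids(dup), c("TP53", "KRAS"))
})

test_that("malformed expression files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  expect_error(read_expression(path), "empty")
  writeLines(c("gene\ts1", "A\tnot_a_number"), path)
  expect_error(read_expression(path), "s1")
})

test_that("median centering follows the stated conventions", {
  ex <- toy_expr(rbind(c(5, 5, 5), c(1, 2, 4)), genes = c("flat", "g"),
                 samples = c("a", "b", "c"))
  cen <- median_center(ex)
  expect_equal(unname(cen$values["flat", ]), c(0, 0, 0))
  expect_equal(unname(cen$values["g", ]), c(-1, 0, 2))

  # even n: mid-point median
  ex4 <- toy_expr(matrix(c(1, 2, 3, 10), 1), genes = "g",
                  samples = letters[1:4])
  expect_equal(unname(median_center(ex4)$values[1, ]),
               c(-1.5, -0.5, 0.5, 7.5))

  # idempotence for odd sample counts
  ex5 <- rand_expr(20, 7, seed = 3)
  once <- median_center(ex5)
  expect_equal(median_center(once)$values, once$values)
})

test_that("per-cohort centering commutes with pooling", {
  a <- rand_expr(30, 9, seed = 1, cohort = "A")
  b <- rand_expr(30, 12, seed = 2, cohort = "B")
  ca <- toy_clinical(time = rexp(9, 0.05), event = rbinom(9, 1, 0.5),
                     sample = sample_ids(a))
  ca$cohort <- "A"
  cb <- toy_clinical(time = rexp(12, 0.05), event = rbinom(12, 1, 0.5),
                     sample = sample_ids(b))
  cb$cohort <- "B"
  pooled <- pool_cohorts(list(list(expr = a, clinical = ca),
                              list(expr = b, clinical = cb)))
  lhs <- median_center(pooled$expr, per_cohort = TRUE)$values
  rhs <- cbind(median_center(a)$values, median_center(b)$values)
  colnames(rhs) <- colnames(lhs)
  expect_equal(lhs, rhs)
})

test_that("pooling restricts to the gene intersection", {
  a <- rand_expr(100, 5, seed = 1, cohort = "A")
  b <- rand_expr(80, 5, seed = 2, cohort = "B")
  rownames(b$values) <- c(sprintf("G%03d", 41:100), sprintf("X%02d", 1:20))
  cl <- function(e, co) {
    x <- toy_clinical(time = 1:5, event = rep(1, 5), sample = sample_ids(e))
    x$cohort <- co
    x
  }
  pooled <- pool_cohorts(list(list(expr = a, clinical = cl(a, "A")),
                              list(expr = b, clinical = cl(b, "B"))))
  expect_equal(nrow(pooled$expr$values), 60L)   # G041..G100
  expect_equal(ncol(pooled$expr$values), 10L)

  # pooling a cohort with itself doubles the samples
  a2 <- a; a2$cohort[] <- "A2"
  both <- pool_cohorts(list(list(expr = a, clinical = cl(a, "A")),
                            list(expr = a2, clinical = cl(a2, "A2"))))
  expect_equal(ncol(both$expr$values), 10L)
  expect_equal(nrow(both$expr$values), 100L)

  c_disjoint <- rand_expr(10, 5, seed = 3, cohort = "C")
  rownames(c_disjoint$values) <- sprintf("Z%02d", 1:10)
  expect_error(pool_cohorts(list(list(expr = a, clinical = cl(a, "A")),
                                 list(expr = c_disjoint,
                                      clinical = cl(c_disjoint, "C")))),
               "intersection")
})

test_that("NanoString normalization equalizes control geometric means", {
  counts <- rbind(T1 = c(100, 200), T2 = c(50, 100),
                  C1 = c(10, 20), C2 = c(40, 80))
  colnames(counts) <- c("sA", "sB")
  # sample B is exactly 2x sample A -> B is scaled by the factor that
  # matches A, i.e. both end identical before the log transform
  norm <- nanostring_normalize(counts, control_genes = c("C1", "C2"))
  expect_equal(norm$values[, "sA"], norm$values[, "sB"])

  # identical controls across samples -> nothing changes
  counts2 <- rbind(T1 = c(100, 300), C1 = c(10, 10), C2 = c(40, 40))
  colnames(counts2) <- c("sA", "sB")
  norm2 <- nanostring_normalize(counts2, control_genes = c("C1", "C2"))
  expect_equal(unname(norm2$values["T1", ]), log2(c(100, 300) + 1))

  # hand-computed scale factors for a 2x2 fixture:
  # gm(A) = sqrt(10*40) = 20, gm(B) = sqrt(20*80) = 40, mean = 30
  # -> A scaled by 1.5, B by 0.75
  expect_equal(unname(norm$values["T1", "sA"]), log2(100 * 1.5 + 1))
  expect_equal(unname(norm$values["T1", "sB"]), log2(200 * 0.75 + 1))

  # rescaling one sample's counts only rescales the whole normalized
  # matrix by a common factor: between-sample structure is preserved
  counts3 <- counts; counts3[, "sB"] <- counts3[, "sB"] * 7
  norm3 <- nanostring_normalize(counts3, c("C1", "C2"))
  ratio <- (2^norm3$values - 1) / (2^norm$values - 1)
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-10)

  bad <- counts; bad["C1", "sB"] <- 0
  expect_error(nanostring_normalize(bad, c("C1", "C2")), "sB")
})

test_that("gene mapping is case-insensitive and reports drops", {
  ex <- rand_expr(5, 4, seed = 1)
  rownames(ex$values) <- c("CCNB1", "AURKB", "NPY", "G1", "G2")
  sig <- gene_signature(c("Ccnb1", "Aurkb", "Missing1"), c(1, 1, -1))
  m <- map_gene_ids(sig, ex)
  expect_equal(m$signature$gene, c("CCNB1", "AURKB"))
  expect_equal(m$unmatched, "Missing1")

  sig17 <- htics_signature()
  ex2 <- rand_expr(20, 4, seed = 2)
  rownames(ex2$values) <- c(toupper(setdiff(sig17$gene, "Npy")),
                            sprintf("F%02d", 1:4))
  m2 <- map_gene_ids(sig17, ex2)
  expect_equal(nrow(m2$signature), 16L)
  expect_equal(m2$unmatched, "Npy")

  expect_error(map_gene_ids(gene_signature("ZZZ", 1), ex), "no signature gene")
})

test_that("shipped signature fixtures agree with the built-in constructors", {
  d <- system.file("extdata", package = "sigcore")
  htics <- read_signature(file.path(d, "htics.tsv"), name = "HTICS")
  expect_equal(as.data.frame(htics), as.data.frame(htics_signature()))
  expect_equal(nrow(htics), 17L)
  expect_equal(sum(htics$direction == 1), 8L)
  expect_equal(sum(htics$direction == -1), 9L)
  expect_setequal(unique(htics$pathway),
                  c("Cell Cycle", "Immune Response", "Cell Migration",
                    "Homeostasis", "Glycan Metabolism"))

  ns <- read_nanostring(file.path(d, "nanostring_synthetic.csv"))
  expect_equal(length(ns$control_genes), 4L)
  norm <- nanostring_normalize(ns)
  expect_true(all(is.finite(norm$values)))
})
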