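test_that("subset enumeration is complete and guarded", {
  expect_equal(enumerate_combinations(3), 1:7)
  expect_equal(enumerate_combinations(1), 1L)
  m17 <- enumerate_combinations(htics_signature())
  expect_equal(length(m17), 131071L)
  expect_equal(anyDuplicated(m17), 0L)
  expect_error(enumerate_combinations(25), "24")
})

test_that("mask encoding round-trips gene subsets", {
  sig <- core_signature()
  for (m in c(1L, 5L, 63L, 42L)) {
    genes <- mask_genes(m, sig)
    expect_equal(genes_mask(genes, sig), m)
  }
  expect_equal(mask_genes(63L, sig), sig$gene)
})

test_that("the sweep reproduces direct per-subset evaluation", {
  sig <- core_signature()
  co_a <- small_cohort(seed = 41, n = 80, n_genes = 60)
  co_b <- small_cohort(seed = 42, n = 80, n_genes = 60)
  rec <- evaluate_all(co_a$expr, co_a$clinical, co_b$expr, co_b$clinical,
                      sig)
  expect_equal(nrow(rec), 63L)
  centered <- median_center(co_a$expr, per_cohort = TRUE)
  for (m in c(1L, 7L, 21L, 63L, 10L)) {
    sub <- subset_signature(sig, mask_genes(m, sig))
    match <- ssm_scores(centered, sub)$match
    hr <- tryCatch(oe_hr(co_a$clinical$time_months, co_a$clinical$event,
                         match)$hr, error = function(e) NA_real_)
    expect_equal(rec$hr_mfs[rec$mask == m], hr, tolerance = 1e-12)
  }
  # determinism: a second sweep is bit-identical
  rec2 <- evaluate_all(co_a$expr, co_a$clinical, co_b$expr, co_b$clinical,
                       sig)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
})

test_that("oe and cox sweeps agree on which subsets carry signal", {
  sig <- subset_signature(core_signature(), core_signature()$gene[1:5],
                          name = "mini")
  co <- small_cohort(seed = 43, n = 150, n_genes = 60, beta = 2)
  oe <- evaluate_all(co$expr, co$clinical, signature = sig)
  cox <- evaluate_all(co$expr, co$clinical, signature = sig,
                      estimator = "cox")
  ok <- !is.na(oe$hr_mfs) & !is.na(cox$hr_mfs)
  expect_gt(stats::cor(log(oe$hr_mfs[ok]), log(cox$hr_mfs[ok])), 0.95)
})

test_that("pairwise co-occurrence equals brute-force double-loop counting", {
  sig <- gene_signature(c("A", "B", "C"), c(1, 1, -1))
  # records {AB, AC, ABC}: co(A,B) = 2/3, co(B,C) = 1/3
  rec <- data.frame(mask = c(3L, 5L, 7L))
  st <- pairwise_cooccurrence(rec, sig)
  expect_equal(st$cooccurrence["A", "B"], 100 * 2 / 3)
  expect_equal(st$cooccurrence["B", "C"], 100 * 1 / 3)
  expect_equal(st$cooccurrence, t(st$cooccurrence))
  expect_equal(st$threshold, st$mean_overlap + st$sd_overlap)

  # brute force on a random record set
  set.seed(44)
  sig6 <- subset_signature(htics_signature(), htics_signature()$gene[1:6],
                           name = "six")
  masks <- sample(1:63, 40, replace = TRUE)
  st6 <- pairwise_cooccurrence(data.frame(mask = masks), sig6)
  for (i in 1:5) for (j in (i + 1):6) {
    both <- sum(bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0 &
                bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0)
    expect_equal(st6$cooccurrence[i, j], 100 * both / length(masks))
  }
  # co-occurrence never exceeds either gene's frequency
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_lte(st6$cooccurrence[i, j],
               min(st6$gene_frequency[i], st6$gene_frequency[j]) + 1e-12)
  }
})

test_that("including every subset gives the combinatorial closed form", {
  k <- 5
  sig <- subset_signature(htics_signature(), htics_signature()$gene[1:k],
                          name = "five")
  st <- pairwise_cooccurrence(data.frame(mask = 1:(2^k - 1)), sig)
  expected <- 100 * 2^(k - 2) / (2^k - 1)
  off <- st$cooccurrence[upper.tri(st$cooccurrence)]
  expect_equal(off, rep(expected, length(off)))
  # every gene appears in 2^(k-1) of the 2^k - 1 subsets
  expect_equal(unname(st$gene_frequency),
               rep(100 * 2^(k - 1) / (2^k - 1), k))
})

test_that("core selection follows partner counts and frequency medians", {
  sig <- gene_signature(c("A", "B", "C", "D"), c(1, 1, -1, -1))
  # A pairs with B and C far above threshold; D mostly alone
  masks <- c(rep(3L, 10), rep(5L, 10), rep(7L, 5), 8L, 8L)
  st <- pairwise_cooccurrence(data.frame(mask = masks), sig)
  core1 <- select_core1(st, min_partners = 2)
  # brute-force partner counting
  above <- st$cooccurrence > st$threshold; diag(above) <- FALSE
  expect_equal(core1, names(which(rowSums(above) >= 2)))

  # degenerate: uniform frequencies leave nothing strictly above the median
  uni <- data.frame(mask = c(3L, 12L))   # AB and CD
  expect_length(select_core2(uni, sig, min_partners = 0), 0)
})

test_that("top-subset selection respects the reference and margin", {
  sig <- gene_signature(c("A", "B"), c(1, -1))
  rec <- data.frame(mask = 1:3, size = c(1L, 1L, 2L),
                    hr_mfs = c(4, 2, 3), p_mfs = c(0.01, 0.01, 0.01),
                    hr_os = c(5, 1, 4), p_os = c(0.01, 0.2, 0.01),
                    significant = c(TRUE, FALSE, TRUE))
  attr(rec, "signature") <- sig
  class(rec) <- c("combination_records", "data.frame")
  top <- select_top(rec)           # reference = full mask 3
  expect_equal(top$mask, c(1L, 3L))
  top_strict <- select_top(rec, reference = rec[1, ])
  expect_equal(top_strict$mask, 1L)
  top_loose <- select_top(rec, reference = rec[1, ], margin = 0.75)
  expect_equal(top_loose$mask, c(1L, 3L))
})

test_that("published Core1 and Core2 intersect in the six Core genes", {
  core <- intersect_cores(core1_signature()$gene, core2_signature()$gene)
  expect_setequal(core$gene,
                  c("Ccr2", "Nrp1", "Scrn1", "CD74", "Chaf1b", "Npy"))
  expect_equal(nrow(core), 6L)
  # directions carried from the parent signature
  expect_equal(as.data.frame(core), as.data.frame(core_signature()),
               ignore_attr = TRUE)
  expect_equal(nrow(intersect_cores(c("A", "B"), c("C", "D"))), 0L)
  same <- intersect_cores(core_signature()$gene, core_signature()$gene)
  expect_setequal(same$gene, core_signature()$gene)
})

test_that("pathway coverage and leave-one-pathway-out follow the annotation", {
  sig <- htics_signature()
  full <- pathway_coverage(data.frame(mask = bitwShiftL(1L, 17L) - 1L), sig)
  expect_equal(sum(full$per_record[1, ]), 5)
  atp7b <- pathway_coverage(data.frame(mask = genes_mask("Atp7b", sig)), sig)
  expect_equal(colnames(atp7b$per_record)[atp7b$per_record[1, ]],
               "Homeostasis")
  core_mask <- genes_mask(core_signature()$gene, sig)
  core_cov <- pathway_coverage(data.frame(mask = core_mask), sig)
  expect_setequal(colnames(core_cov$per_record)[core_cov$per_record[1, ]],
                  c("Cell Cycle", "Immune Response", "Cell Migration"))

  expect_equal(nrow(leave_one_pathway_out(sig, "Cell Cycle")), 13L)
  expect_equal(nrow(leave_one_pathway_out(sig, "Glycan Metabolism")), 16L)
  expect_error(leave_one_pathway_out(sig, "Angiogenesis"), "not present")
})
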