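test_that("Kaplan-Meier estimates match the product-limit formula", {
  # no events: curve stays at 1
  km0 <- km_estimate(c(5, 10, 15), c(0, 0, 0), rep("a", 3))
  expect_true(all(km0$surv == 1))

  # events at t = 1, 2 among n = 2 -> S(1) = 0.5, S(2) = 0
  km2 <- km_estimate(c(1, 2), c(1, 1), rep("a", 2))
  expect_equal(km2$surv, c(0.5, 0))

  # 5-sample mixed censoring, hand product-limit:
  # t=1 event (n=5): S=4/5; t=2 censored; t=3 event (n=3): S=4/5*2/3;
  # t=4 event (n=2): S=4/5*2/3*1/2; t=5 censored
  km5 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0), rep("a", 5))
  ev <- km5[km5$n_event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))

  expect_error(km_estimate(1:3, c(1, 1, 1), factor(rep("a", 3),
                                                   levels = c("a", "b"))),
               "group")
})

test_that("Gehan-Wilcoxon test detects separation and not identity", {
  # identical groups (same data under both labels) -> statistic 0
  time <- c(2, 4, 6, 8, 10); event <- c(1, 1, 0, 1, 0)
  ident <- wilcoxon_test(c(time, time), c(event, event),
                         rep(c("a", "b"), each = 5))
  expect_gte(ident$p, 0.99)

  # complete separation, n = 20
  sep <- wilcoxon_test(c(1:10, 101:110), rep(1, 20),
                       rep(c("a", "b"), each = 10))
  expect_lt(sep$p, 0.01)
})

test_that("O/E statistics agree with survdiff risk tables", {
  set.seed(11)
  time <- rexp(60, 0.05); event <- rbinom(60, 1, 0.6)
  group <- rep(c(FALSE, TRUE), 30)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  oe <- oe_hr(time, event, group)
  # survdiff's first stratum is group = FALSE; ours lists match first
  expect_equal(oe$O, unname(rev(sd$obs)))
  expect_equal(oe$E, unname(rev(sd$exp)), tolerance = 1e-10)
  expect_equal(oe$hr, (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1]),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(oe$p, stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)

  # identical groups -> HR exactly 1
  ident <- oe_hr(c(time, time), c(event, event),
                 rep(c(FALSE, TRUE), each = 60))
  expect_equal(ident$hr, 1)
})

test_that("Cox fit agrees with a hand-maximized partial likelihood", {
  # tie-free toy so Efron = Breslow = the textbook partial likelihood
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  z <- rep(c(0, 1), each = 4)
  neg_log_pl <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * z[i] - log(sum(exp(b * z[risk])))
    }
    -ll
  }
  opt <- stats::optimize(neg_log_pl, c(-5, 5))
  fit <- cox_hr(time, event, z == 1)
  expect_true(fit$estimable)
  expect_equal(fit$log_hr, opt$minimum, tolerance = 1e-4)

  # identical event patterns in both groups -> HR 1
  ident <- cox_hr(c(time, time), c(event, event), rep(c(FALSE, TRUE), each = 8))
  expect_equal(ident$hr, 1, tolerance = 1e-8)

  # no events in one group -> flagged, not an error
  ne <- cox_hr(time, c(1, 1, 1, 1, 0, 0, 0, 0), z == 1)
  expect_false(ne$estimable)
  expect_true(is.na(ne$hr))
})

test_that("hazard-ratio estimators obey label-swap antisymmetry and
           time-rescaling invariance", {
  set.seed(12)
  time <- rexp(80, 0.04); event <- rbinom(80, 1, 0.5)
  group <- rep(c(FALSE, TRUE), 40)
  cox1 <- cox_hr(time, event, group)
  cox2 <- cox_hr(time, event, !group)
  expect_equal(cox1$hr, 1 / cox2$hr, tolerance = 1e-6)
  oe1 <- oe_hr(time, event, group)
  oe2 <- oe_hr(time, event, !group)
  expect_equal(oe1$hr, 1 / oe2$hr, tolerance = 1e-10)
  cox_scaled <- cox_hr(time * 12, event, group)
  expect_equal(cox_scaled$hr, cox1$hr, tolerance = 1e-8)
})

test_that("O/E tracks Cox on large exponential cohorts", {
  set.seed(13)
  n <- 1500
  z <- rep(c(FALSE, TRUE), n / 2)
  t_event <- rexp(n, 0.01 * ifelse(z, 3, 1))
  censor <- runif(n, 0, 120)
  time <- pmin(t_event, censor); event <- as.integer(t_event <= censor)
  hr_cox <- cox_hr(time, event, z)$hr
  hr_oe <- oe_hr(time, event, z)$hr
  expect_lt(abs(log(hr_oe) - log(hr_cox)), log(1.15))
})

test_that("evaluate_signature inverts under direction flip and handles
           degenerate inputs", {
  co <- small_cohort(seed = 21, n = 120, n_genes = 100)
  sig <- htics_signature()
  sv <- evaluate_signature(co$expr, co$clinical, sig)
  expect_true(sv$evaluable)
  expect_true(sv$hr > 0 && is.finite(sv$hr))
  flipped <- gene_signature(sig$gene, -sig$direction, sig$pathway,
                            name = "flipped")
  sv_flip <- evaluate_signature(co$expr, co$clinical, flipped)
  # even n and odd signature size: no SSM ties, groups are exact complements
  expect_equal(sv_flip$hr, 1 / sv$hr, tolerance = 1e-6)

  # filtering to an empty subtype gives a structured non-evaluable result
  clin <- co$clinical; clin$her2_ihc <- "negative"
  empty <- evaluate_signature(co$expr, clin, sig,
                              subtype_filter(require_her2 = TRUE))
  expect_false(empty$evaluable)
  expect_match(empty$reason, "samples")
})

test_that("HER2 filtering by amplicon matches the planted subpopulation", {
  co <- small_cohort(seed = 22, n = 150, n_genes = 100, ihc_error_rate = 0)
  keep_ihc <- evaluate_signature(co$expr, co$clinical, htics_signature(),
                                 subtype_filter(require_her2 = TRUE,
                                                her2_source = "ihc"))
  keep_amp <- evaluate_signature(co$expr, co$clinical, htics_signature(),
                                 subtype_filter(require_her2 = TRUE,
                                                her2_source = "amplicon"))
  # with zero IHC noise and separable planting the two routes agree
  expect_equal(keep_amp$n_match + keep_amp$n_nomatch,
               keep_ihc$n_match + keep_ihc$n_nomatch)
})
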