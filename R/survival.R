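## Survival comparison of signature-match groups.
## Cox (via the survival package) is the reported estimator; a hand-rolled
## O/E (log-rank observed/expected) ratio is the fast estimator used inside
## permutation and combination sweeps. The weighted log-rank machinery is
## implemented here because the Gehan-Breslow-Wilcoxon weighting (weight =
## number at risk) is not survdiff's rho-family.

# shift zero follow-up times to keep their events (documented convention)
clean_times <- function(time) {
  time[time == 0] <- 0.01
  time
}

# Precomputed risk-set structure shared by all two-group statistics on a
# fixed cohort: samples sorted by time, tie blocks, per-block event totals.
surv_context <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  time <- clean_times(time)
  ord <- order(time)
  ts <- time[ord]
  ev <- as.integer(event[ord])
  n <- length(ts)
  ut <- unique(ts)
  block_start <- match(ut, ts)
  block_end <- c(block_start[-1L] - 1L, n)
  d <- as.integer(diff(c(0, cumsum(ev)[block_end])))
  keep <- d > 0L                               # only event times matter
  list(n = n, ord = ord, ev = ev,
       block_start = block_start[keep], block_end = block_end[keep],
       d = d[keep], Y = n - block_start[keep] + 1L,
       n_events = sum(ev))
}

# Observed/expected/variance per event-time block for group 1 (z == TRUE),
# plus Gehan (weight = number at risk) aggregates.
two_group_counts <- function(z, ctx) {
  zs <- as.logical(z)[ctx$ord]
  suffix1 <- rev(cumsum(rev(zs)))
  Y1 <- suffix1[ctx$block_start]
  cs <- c(0L, cumsum(zs & (ctx$ev == 1L)))
  O1u <- cs[ctx$block_end + 1L] - cs[ctx$block_start]
  E1u <- ctx$d * Y1 / ctx$Y
  Vu <- ifelse(ctx$Y > 1L,
               ctx$d * (Y1 / ctx$Y) * (1 - Y1 / ctx$Y) *
                 (ctx$Y - ctx$d) / (ctx$Y - 1L),
               0)
  O1 <- sum(O1u); E1 <- sum(E1u)
  O <- ctx$n_events
  list(O1 = O1, E1 = E1, O2 = O - O1, E2 = O - E1,
       V = sum(Vu),
       gehan_U = sum(ctx$Y * (O1u - E1u)),
       gehan_V = sum(ctx$Y^2 * Vu))
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates with right censoring, one curve per group,
#' via [survival::survfit()].
#'
#' @param time follow-up times (months); zero times are shifted to 0.01
#'   so their events are kept.
#' @param event 0/1 event indicators.
#' @param group group labels (factor/character/logical).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("every group needs >= 1 sample")
  fit <- survival::survfit(survival::Surv(clean_times(time), event) ~ group)
  if (is.null(fit$strata)) {
    grp <- rep(levels(group)[1], length(fit$time))
  } else {
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

#' Gehan-Breslow-Wilcoxon two-group survival test
#'
#' Weighted log-rank test with weight equal to the number at risk, which
#' emphasises early differences. Returns the chi-square p-value (1 df).
#'
#' @inheritParams km_estimate
#' @return list with `statistic` (chi-square), `p`, and the per-group
#'   observed/expected event counts.
#' @export
wilcoxon_test <- function(time, event, group) {
  z <- group_to_logical(group)
  ctx <- surv_context(time, event)
  cc <- two_group_counts(z, ctx)
  chi <- if (cc$gehan_V > 0) cc$gehan_U^2 / cc$gehan_V else 0
  list(statistic = chi,
       p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       observed = c(cc$O1, cc$O2), expected = c(cc$E1, cc$E2))
}

# two-group labels -> logical (TRUE = second level, the "match" group when
# logical input is given directly)
group_to_logical <- function(group) {
  if (is.logical(group)) return(group)
  f <- as.factor(group)
  if (nlevels(f) != 2L) stop("exactly two groups required")
  f == levels(f)[2L]
}

#' Cox proportional-hazards ratio between two groups
#'
#' Two-group Cox partial-likelihood fit (Efron ties) returning the
#' hazard ratio of group `TRUE` (signature match) over group `FALSE`,
#' with Wald 95% CI and p-value. When a group has no events the model is
#' flagged non-estimable rather than erroring.
#'
#' @inheritParams km_estimate
#' @param group logical (TRUE = match) or two-level factor; for a
#'   factor, the hazard ratio is second level vs first.
#' @return list with `hr`, `ci` (length-2), `p`, `log_hr`, `se`,
#'   `n_events` per group and `estimable`.
#' @export
cox_hr <- function(time, event, group) {
  z <- group_to_logical(group)
  ev_by <- c(sum(event[!z]), sum(event[z]))
  out <- list(hr = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
              log_hr = NA_real_, se = NA_real_,
              n_events = ev_by, estimable = FALSE)
  if (any(ev_by == 0L)) return(out)
  fit <- tryCatch(
    survival::coxph(survival::Surv(clean_times(time), event) ~ z,
                    ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(
        survival::Surv(clean_times(time), event) ~ z, ties = "efron"))
    })
  if (is.null(fit)) return(out)
  b <- unname(stats::coef(fit)[1]); se <- sqrt(stats::vcov(fit)[1, 1])
  if (!is.finite(b) || !is.finite(se)) return(out)
  list(hr = exp(b), ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(b / se)), log_hr = b, se = se,
       n_events = ev_by, estimable = TRUE)
}

#' Observed/expected hazard-ratio estimator
#'
#' The fast log-rank-based estimator
#' \eqn{HR = (O_1/E_1) / (O_2/E_2)} with O the observed and E the
#' log-rank expected event counts per group (group 1 = match). Used
#' inside permutation and combination sweeps where a Cox fit per draw
#' would dominate runtime; agrees with Cox asymptotically for moderate
#' hazard ratios.
#'
#' @inheritParams cox_hr
#' @return list with `hr`, `O` and `E` (length-2, match group first),
#'   `p` (log-rank chi-square p) and `estimable`.
#' @export
oe_hr <- function(time, event, group) {
  z <- group_to_logical(group)
  ctx <- surv_context(time, event)
  oe_from_counts(two_group_counts(z, ctx))
}

oe_from_counts <- function(cc) {
  if (cc$E1 == 0 || cc$E2 == 0)
    stop("expected event count is zero in a group; HR not estimable")
  hr <- (cc$O1 / cc$E1) / (cc$O2 / cc$E2)
  chi <- if (cc$V > 0) (cc$O1 - cc$E1)^2 / cc$V else 0
  list(hr = hr, O = c(cc$O1, cc$O2), E = c(cc$E1, cc$E2),
       p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       estimable = is.finite(hr) && hr > 0)
}

#' Patient-subtype filter
#'
#' @param require_her2 keep HER2-positive samples only.
#' @param require_er_negative keep ER-negative samples only.
#' @param her2_source `"ihc"` uses the clinical `her2_ihc` column;
#'   `"amplicon"` derives HER2 status from the 5-gene amplicon
#'   expression (see [call_her2()]).
#' @return list of class `subtype_filter`.
#' @export
subtype_filter <- function(require_her2 = FALSE, require_er_negative = FALSE,
                           her2_source = c("ihc", "amplicon")) {
  structure(list(require_her2 = require_her2,
                 require_er_negative = require_er_negative,
                 her2_source = match.arg(her2_source)),
            class = "subtype_filter")
}

# apply a subtype filter; returns kept sample ids
apply_subtype_filter <- function(expr, clinical, filter) {
  keep <- clinical$sample
  if (filter$require_her2) {
    if (filter$her2_source == "ihc") {
      keep <- intersect(keep, clinical$sample[clinical$her2_ihc == "positive"])
    } else {
      calls <- call_her2(amplicon_fold_changes(expr))
      keep <- intersect(keep, calls$sample_ids[calls$her2_call])
    }
  }
  if (filter$require_er_negative)
    keep <- intersect(keep, clinical$sample[clinical$er_status == "negative"])
  keep
}

#' Survival evaluation of a signature on a cohort
#'
#' End-to-end comparison of SSM match vs no-match groups: subtype
#' filtering, median centering, SSM classification, then Cox hazard
#' ratio, Gehan-Wilcoxon p, O/E components and Kaplan-Meier curves.
#'
#' @param expr an [expression_matrix()] of log2 values (not yet
#'   centered).
#' @param clinical clinical table (see [read_clinical()]).
#' @param signature a [gene_signature()].
#' @param filter a [subtype_filter()].
#' @param endpoint restrict to `"MFS"` or `"OS"` rows (`NULL` = all).
#' @param per_cohort_center center within cohorts (default) or across
#'   the pooled samples.
#' @return object of class `survival_comparison` with elements `hr`,
#'   `hr_ci`, `cox_p`, `wilcoxon_p`, `km`, `oe`, `n_match`,
#'   `n_nomatch`, `match` (named logical), `ssm`, `evaluable`.
#' @export
evaluate_signature <- function(expr, clinical, signature,
                               filter = subtype_filter(), endpoint = NULL,
                               per_cohort_center = TRUE) {
  clinical <- validate_clinical(clinical)
  if (!is.null(endpoint))
    clinical <- clinical[clinical$endpoint == endpoint, , drop = FALSE]
  keep <- apply_subtype_filter(expr, clinical, filter)
  keep <- intersect(keep, sample_ids(expr))
  clinical <- clinical[match(keep, clinical$sample), , drop = FALSE]
  non_eval <- structure(list(evaluable = FALSE, reason = "",
                             n_match = 0L, n_nomatch = 0L),
                        class = "survival_comparison")
  if (length(keep) < 4L) {
    non_eval$reason <- "fewer than 4 samples after filtering"
    return(non_eval)
  }
  sub <- expression_matrix(expr$values[, keep, drop = FALSE],
                           cohort = expr$cohort[keep])
  centered <- median_center(sub, per_cohort = per_cohort_center)
  res <- ssm_scores(centered, signature)
  match <- res$match
  if (min(sum(match), sum(!match)) < 2L) {
    non_eval$reason <- "fewer than 2 samples in an SSM group"
    non_eval$n_match <- sum(match); non_eval$n_nomatch <- sum(!match)
    return(non_eval)
  }
  time <- clinical$time_months; event <- clinical$event
  cox <- cox_hr(time, event, match)
  wil <- wilcoxon_test(time, event, match)
  oe <- tryCatch(oe_hr(time, event, match), error = function(e) NULL)
  km <- km_estimate(time, event, ifelse(match, "match", "no-match"))
  structure(list(evaluable = TRUE,
                 signature = res$signature,
                 n_match = sum(match), n_nomatch = sum(!match),
                 match = stats::setNames(match, keep),
                 ssm = stats::setNames(res$ssm, keep),
                 hr = cox$hr, hr_ci = cox$ci, cox_p = cox$p,
                 cox_estimable = cox$estimable,
                 wilcoxon_p = wil$p, oe = oe, km = km,
                 time = time, event = event),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  if (!x$evaluable) {
    cat("survival_comparison: non-evaluable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("survival_comparison ('%s'): %d match vs %d no-match\n",
                     "  Cox HR %.2f [%.2f, %.2f], p = %.3g; Wilcoxon p = %.3g\n"),
              signature_name(x$signature), x$n_match, x$n_nomatch,
              x$hr, x$hr_ci[1], x$hr_ci[2], x$cox_p, x$wilcoxon_p))
  invisible(x)
}
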