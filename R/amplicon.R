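#' HER2 amplicon calling configuration
#'
#' @param genes amplicon gene symbols (default [amplicon_genes()]).
#' @param fold_cutoff linear fold-change threshold; a gene counts as
#'   elevated when its fold change is strictly greater than this.
#' @param min_genes number of elevated genes required for a positive
#'   HER2 call (the "3 of 5" rule).
#' @return list of class `amplicon_config`.
#' @export
amplicon_config <- function(genes = amplicon_genes(), fold_cutoff = 2,
                            min_genes = 3L) {
  if (fold_cutoff <= 1) stop("fold_cutoff must exceed 1")
  min_genes <- as.integer(min_genes)
  if (min_genes < 1L || min_genes > length(genes))
    stop("min_genes must lie in [1, number of amplicon genes]")
  structure(list(genes = genes, fold_cutoff = fold_cutoff,
                 min_genes = min_genes),
            class = "amplicon_config")
}

#' Fold changes of the amplicon genes against the cohort median
#'
#' Fold change of gene g in sample s is
#' `2^(log2 value - median log2 value of g across the samples)`.
#' Medians are taken over the pooled sample set being called (the
#' default) or within each cohort.
#'
#' @param expr an [expression_matrix()] of log2 values.
#' @param cfg an [amplicon_config()].
#' @param per_cohort compute medians within cohorts.
#' @return object of class `amplicon_call` with `fold_change`
#'   (amplicon genes x samples, linear scale), `n_elevated` and
#'   `her2_call` unset until [call_her2()].
#' @export
amplicon_fold_changes <- function(expr, cfg = amplicon_config(),
                                  per_cohort = FALSE) {
  idx <- match(toupper(cfg$genes), toupper(gene_ids(expr)))
  if (anyNA(idx))
    stop("amplicon gene(s) missing from expression matrix: ",
         paste(cfg$genes[is.na(idx)], collapse = ", "))
  sub <- expression_matrix(expr$values[idx, , drop = FALSE],
                           cohort = expr$cohort)
  rownames(sub$values) <- cfg$genes
  centered <- median_center(sub, per_cohort = per_cohort)
  structure(list(sample_ids = sample_ids(expr),
                 fold_change = 2^centered$values,
                 n_elevated = NULL, her2_call = NULL, config = cfg),
            class = "amplicon_call")
}

#' Call HER2 status from amplicon fold changes
#'
#' A sample is HER2-positive when strictly more than `fold_cutoff`-fold
#' elevation is seen in at least `min_genes` of the amplicon genes.
#'
#' @param call an `amplicon_call` from [amplicon_fold_changes()].
#' @param cfg an [amplicon_config()] (defaults to the one stored in
#'   `call`).
#' @return the `amplicon_call` with `n_elevated` and `her2_call` filled.
#' @export
call_her2 <- function(call, cfg = call$config) {
  elevated <- call$fold_change > cfg$fold_cutoff
  call$n_elevated <- colSums(elevated)
  call$her2_call <- call$n_elevated >= cfg$min_genes
  call$config <- cfg
  call
}

#' @export
print.amplicon_call <- function(x, ...) {
  cat(sprintf("amplicon_call: %d samples", length(x$sample_ids)))
  if (!is.null(x$her2_call))
    cat(sprintf(", %d HER2+ (>%g-fold in >=%d of %d genes)",
                sum(x$her2_call), x$config$fold_cutoff, x$config$min_genes,
                length(x$config$genes)))
  cat("\n")
  invisible(x)
}

#' Concordance of expression-based HER2 calls with IHC labels
#'
#' Builds the 2x2 contingency table of amplicon call vs IHC status and
#' reports positive predictive value, sensitivity, specificity, overall
#' concordance rate, Cohen's kappa and the two-sided Fisher exact
#' p-value.
#'
#' @param calls logical vector of expression-based calls.
#' @param ihc logical vector of IHC labels (TRUE = HER2 positive);
#'   `NA`s are dropped pairwise.
#' @return list of class `concordance_report`.
#' @export
concordance <- function(calls, ihc) {
  keep <- !is.na(calls) & !is.na(ihc)
  calls <- as.logical(calls[keep]); ihc <- as.logical(ihc[keep])
  if (length(unique(ihc)) < 2L)
    stop("degenerate table: both IHC classes must be present")
  tp <- sum(calls & ihc);  fp <- sum(calls & !ihc)
  fn <- sum(!calls & ihc); tn <- sum(!calls & !ihc)
  tab <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                dimnames = list(call = c("positive", "negative"),
                                ihc = c("positive", "negative")))
  n <- sum(tab)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  structure(list(
    table = tab,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    concordance_rate = po,
    kappa = kappa,
    fisher_p = stats::fisher.test(tab)$p.value,
    n = n), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("concordance (n=%d): rate %.1f%%, kappa %.2f, ",
                     "PPV %.1f%%, sens %.1f%%, spec %.1f%%, Fisher p %.3g\n"),
              x$n, 100 * x$concordance_rate, x$kappa, 100 * x$ppv,
              100 * x$sensitivity, 100 * x$specificity, x$fisher_p))
  print(x$table)
  invisible(x)
}
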