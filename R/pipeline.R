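#' Run the full signature-interrogation analysis
#'
#' Orchestrates every stage on a paired MFS/OS cohort: SSM scoring and
#' survival evaluation of the target signature, ROC of outcome
#' aggressiveness, leave-one-pathway-out, the exhaustive sub-signature
#' sweep with Core1/Core2/Core extraction (cores re-evaluated with full
#' Cox), substitute discovery and substituted-signature agreement,
#' random-signature null ranking, and the permutation eFDR. Stage
#' failures are recorded in the manifest and dependent stages skipped.
#'
#' @param expr_mfs,clin_mfs MFS cohort (an [expression_matrix()] and
#'   clinical table, or file paths readable by [read_expression()] /
#'   [read_clinical()]).
#' @param expr_os,clin_os OS cohort (optional; `NULL` restricts the
#'   sweep and eFDR to the MFS endpoint).
#' @param signature target [gene_signature()] or signature TSV path.
#' @param candidates character vector of substitute candidates (optional).
#' @param pathway_map optional candidate pathway annotation (see
#'   [find_substitutes()]).
#' @param filter a [subtype_filter()] applied to the survival stages.
#' @param alpha significance level for the sweep.
#' @param n_random random signatures for the null ranking.
#' @param n_perm permutations for the eFDR.
#' @param seed integer seed used for all stochastic stages.
#' @param out_dir if non-NULL, per-stage TSVs plus a `report.json` are
#'   written there.
#' @return list of class `analysis_report` with one element per stage
#'   plus a `manifest` (inputs, seed, package version, stage timings
#'   and errors).
#' @export
run_full_analysis <- function(expr_mfs, clin_mfs, expr_os = NULL,
                              clin_os = NULL, signature = htics_signature(),
                              candidates = NULL, pathway_map = NULL,
                              filter = subtype_filter(), alpha = 0.05,
                              n_random = 1000L, n_perm = 1000L, seed = 1L,
                              out_dir = NULL) {
  if (is.character(expr_mfs)) expr_mfs <- read_expression(expr_mfs, cohort = "MFS")
  if (is.character(clin_mfs)) clin_mfs <- read_clinical(clin_mfs)
  if (is.character(expr_os)) expr_os <- read_expression(expr_os, cohort = "OS")
  if (is.character(clin_os)) clin_os <- read_clinical(clin_os)
  if (is.character(signature)) signature <- read_signature(signature)
  has_os <- !is.null(expr_os)

  report <- list()
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("sigcore")),
                   n_samples_mfs = ncol(expr_mfs$values),
                   n_samples_os = if (has_os) ncol(expr_os$values) else 0L,
                   signature = signature_name(signature),
                   alpha = alpha, n_random = n_random, n_perm = n_perm,
                   stages = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      ok = !inherits(res, "stage_error"),
      error = if (inherits(res, "stage_error")) res$message else NULL)
    res
  }

  report$survival_mfs <- run_stage("survival_mfs", function()
    evaluate_signature(expr_mfs, clin_mfs, signature, filter,
                       endpoint = "MFS"))
  if (has_os)
    report$survival_os <- run_stage("survival_os", function()
      evaluate_signature(expr_os, clin_os, signature, filter,
                         endpoint = "OS"))

  report$roc <- run_stage("roc", function() {
    sv <- report$survival_mfs
    if (inherits(sv, "stage_error") || !sv$evaluable)
      stop("MFS survival stage unavailable")
    outcome_roc(sv$ssm, sv$time, sv$event)
  })

  report$leave_one_pathway_out <- run_stage("leave_one_pathway_out", function() {
    paths <- unique(signature$pathway[!is.na(signature$pathway)])
    rows <- lapply(c("None", paths), function(p) {
      red <- if (p == "None") signature else leave_one_pathway_out(signature, p)
      sv <- evaluate_signature(expr_mfs, clin_mfs, red, filter,
                               endpoint = "MFS")
      auc <- if (sv$evaluable)
        outcome_roc(sv$ssm, sv$time, sv$event)$roc$auc else NA_real_
      data.frame(pathway_removed = p, n_genes = nrow(red),
                 hr = if (sv$evaluable) sv$hr else NA_real_,
                 cox_p = if (sv$evaluable) sv$cox_p else NA_real_,
                 auc = auc, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  report$combinations <- run_stage("combinations", function()
    evaluate_all(expr_mfs, clin_mfs, expr_os, clin_os, signature,
                 alpha = alpha))

  report$cores <- run_stage("cores", function() {
    rec <- report$combinations
    if (inherits(rec, "stage_error")) stop("combination sweep unavailable")
    sig_rec <- rec[rec$significant, , drop = FALSE]
    attr(sig_rec, "signature") <- signature
    class(sig_rec) <- class(rec)
    if (nrow(sig_rec) == 0L) stop("no significant combination")
    stats1 <- pairwise_cooccurrence(sig_rec, signature)
    core1 <- select_core1(stats1)
    top <- select_top(rec)
    core2 <- if (nrow(top) > 0L) select_core2(top, signature) else character(0)
    core <- intersect_cores(core1, core2, signature)
    reeval <- function(genes, nm) {
      if (length(genes) == 0L) return(NULL)
      evaluate_signature(expr_mfs, clin_mfs,
                         subset_signature(signature, genes, name = nm),
                         filter, endpoint = "MFS")
    }
    list(stats = stats1, core1 = core1, core2 = core2,
         core = core$gene, n_top = nrow(top),
         pathways = if (nrow(top) > 0L) pathway_coverage(top, signature) else NULL,
         core1_eval = reeval(core1, "Core1"),
         core2_eval = reeval(core2, "Core2"),
         core_eval = reeval(core$gene, "Core"))
  })

  report$substitution <- run_stage("substitution", function() {
    if (is.null(candidates)) stop("no candidate list supplied")
    map <- find_substitutes(expr_mfs, signature, candidates, pathway_map,
                            unique_substitutes = TRUE)
    alt <- apply_substitution(signature, map, "all",
                              name = paste0("Alt", signature_name(signature)))
    centered <- median_center(expr_mfs)
    agree <- score_agreement(centered, signature, alt)
    alt_eval <- evaluate_signature(expr_mfs, clin_mfs, alt, filter,
                                   endpoint = "MFS")
    list(map = map, alt_signature = alt,
         agreement_r = agree$r, agreement_auc = agree$auc,
         alt_eval = alt_eval)
  })

  report$null_ranking <- run_stage("null_ranking", function()
    empirical_fdr(expr_mfs, clin_mfs, signature, n_perm = n_random,
                  seed = seed))
  report$efdr <- run_stage("efdr", function()
    empirical_fdr(expr_mfs, clin_mfs, signature, n_perm = n_perm,
                  seed = seed + 1L))

  report$manifest <- manifest
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report stages:\n")
  for (nm in names(x$manifest$stages)) {
    st <- x$manifest$stages[[nm]]
    cat(sprintf("  %-22s %s (%.2fs)%s\n", nm,
                if (st$ok) "ok" else "FAILED", st$seconds,
                if (!st$ok) paste0(" - ", st$error) else ""))
  }
  invisible(x)
}

# per-stage TSVs plus a JSON summary
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sv <- report$survival_mfs
  if (inherits(sv, "survival_comparison") && sv$evaluable) {
    utils::write.table(
      data.frame(sample = names(sv$ssm), ssm = sv$ssm, match = sv$match),
      file.path(out_dir, "ssm_mfs.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(sv$km, file.path(out_dir, "km_mfs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (inherits(report$combinations, "combination_records"))
    write_records(report$combinations[report$combinations$significant, ],
                  file.path(out_dir, "significant_combinations.tsv"))
  if (!inherits(report$leave_one_pathway_out, "stage_error"))
    utils::write.table(report$leave_one_pathway_out,
                       file.path(out_dir, "leave_one_pathway_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(manifest = report$manifest)
  if (inherits(sv, "survival_comparison") && sv$evaluable)
    summary$survival_mfs <- list(hr = sv$hr, ci = sv$hr_ci, cox_p = sv$cox_p,
                                 wilcoxon_p = sv$wilcoxon_p,
                                 n_match = sv$n_match,
                                 n_nomatch = sv$n_nomatch)
  if (!inherits(report$roc, "stage_error"))
    summary$roc_auc <- report$roc$roc$auc
  if (!inherits(report$cores, "stage_error"))
    summary$cores <- list(core1 = report$cores$core1,
                          core2 = report$cores$core2,
                          core = report$cores$core)
  if (inherits(report$efdr, "null_distribution"))
    summary$efdr <- list(efdr = report$efdr$efdr,
                         n_better = report$efdr$n_better,
                         rank = report$efdr$rank,
                         target_hr = report$efdr$target_hr)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
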