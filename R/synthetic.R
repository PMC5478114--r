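#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis
#' assumes: log2 expression with unit-variance genes around a mean of
#' 7, equicorrelated pathway blocks (latent-factor construction: genes
#' of one pathway share pairwise correlation `block_rho`), a signed
#' signature risk score driving exponential proportional-hazards
#' survival with uniform censoring, a co-amplified 5-gene HER2 amplicon
#' subpopulation, and IHC labels that flip with a small error rate.
#'
#' @param n_samples cohort size.
#' @param n_genes total genes (noise genes fill up beyond signature,
#'   candidates and amplicon genes).
#' @param signature [gene_signature()] to plant (default
#'   [htics_signature()]).
#' @param informative_genes subset of signature genes that actually
#'   carry survival signal (default: all).
#' @param block_rho within-pathway pairwise correlation (0 <= rho < 1).
#' @param beta log-hazard coefficient on the planted risk score z
#'   (z = mean over informative genes of direction x standardized
#'   expression).
#' @param baseline_hazard events per month at z = 0.
#' @param censor_max_months censoring ~ Uniform(0, this).
#' @param frac_her2 fraction of samples with the planted amplicon gain.
#' @param amplicon_fold_range linear fold gain (low, high), one draw
#'   per amplified sample applied to all five amplicon genes.
#' @param amplicon_gene_sd residual SD of the amplicon genes' baseline
#'   log2 expression. Amplicon expression is strongly copy-number
#'   driven, so its residual spread is kept well below the global gene
#'   SD of 1; the default 0.25 makes planted gains of >= 4-fold cleanly
#'   separable by the 2-fold / 3-of-5 rule.
#' @param ihc_error_rate probability an IHC label contradicts the true
#'   amplification status.
#' @param frac_er_negative fraction labeled ER-negative.
#' @param n_candidates_per_pathway extra non-signature genes planted in
#'   each pathway block (substitute-discovery candidates).
#' @param endpoint endpoint label for the clinical table.
#' @param cohort cohort label.
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 300L, n_genes = 2000L,
                             signature = htics_signature(),
                             informative_genes = signature$gene,
                             block_rho = 0.5, beta = 1.0,
                             baseline_hazard = 0.01,
                             censor_max_months = 120,
                             frac_her2 = 0.25,
                             amplicon_fold_range = c(4, 8),
                             amplicon_gene_sd = 0.25,
                             ihc_error_rate = 0.05,
                             frac_er_negative = 0.5,
                             n_candidates_per_pathway = 8L,
                             endpoint = "MFS", cohort = "sim",
                             seed = NULL) {
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)")
  if (frac_her2 < 0 || frac_her2 > 1) stop("frac_her2 must lie in [0, 1]")
  if (any(amplicon_fold_range <= 1)) stop("amplicon folds must exceed 1")
  if (baseline_hazard <= 0 || censor_max_months <= 0 || ihc_error_rate < 0)
    stop("rates must be positive, error rate non-negative")
  if (!all(informative_genes %in% signature$gene))
    stop("informative_genes must be a subset of the signature genes")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic cohort
#'
#' See [synthetic_config()] for the generative model. The truth record
#' carries everything parameter-recovery tests need: the risk score z,
#' the planted SSM-match groups (classified with the informative
#' sub-signature on the generated matrix), the group hazard ratio
#' implied by z and beta, and the true amplification status.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `expr` ([expression_matrix()]), `clinical`
#'   (data.frame), `truth` (list: `z`, `planted_match`,
#'   `true_group_hr`, `her2_true`, `amplicon_fold`, `pathway_map`,
#'   `informative_genes`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(cfg$n_samples)
  sig <- cfg$signature
  samples <- sprintf("S%04d", seq_len(n))

  amp <- amplicon_genes()
  paths <- unique(sig$pathway[!is.na(sig$pathway)])
  cand <- list()
  for (p in paths) {
    if (cfg$n_candidates_per_pathway > 0L) {
      tag <- gsub("[^A-Za-z0-9]", "", p)
      cand[[p]] <- sprintf("Cand%s%02d", tag,
                           seq_len(cfg$n_candidates_per_pathway))
    } else cand[[p]] <- character(0)
  }
  special <- c(sig$gene, unlist(cand, use.names = FALSE), amp)
  n_noise <- max(0L, cfg$n_genes - length(special))
  noise <- if (n_noise > 0L) sprintf("GENE%04d", seq_len(n_noise)) else character(0)
  genes <- c(special, noise)

  v <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, samples))
  # pathway blocks: shared latent factor -> pairwise correlation block_rho
  rho <- cfg$block_rho
  for (p in paths) {
    members <- c(sig$gene[!is.na(sig$pathway) & sig$pathway == p], cand[[p]])
    if (length(members) > 1L && rho > 0) {
      f <- stats::rnorm(n)
      v[members, ] <- sqrt(rho) * matrix(f, length(members), n, byrow = TRUE) +
        sqrt(1 - rho) * v[members, , drop = FALSE]
    }
  }
  # amplicon genes: tight baseline plus a shared planted gain
  v[amp, ] <- cfg$amplicon_gene_sd *
    matrix(stats::rnorm(length(amp) * n), length(amp), n)
  her2_true <- stats::runif(n) < cfg$frac_her2
  fold <- rep(1, n)
  if (any(her2_true)) {
    fold[her2_true] <- stats::runif(sum(her2_true),
                                    cfg$amplicon_fold_range[1],
                                    cfg$amplicon_fold_range[2])
    v[amp, her2_true] <- v[amp, her2_true, drop = FALSE] +
      matrix(log2(fold[her2_true]), length(amp), sum(her2_true), byrow = TRUE)
  }
  values <- 7 + v

  # planted risk score: mean of direction x standardized expression over
  # the informative genes (generator-side standardization is exact)
  inf <- cfg$informative_genes
  dir_inf <- sig$direction[match(inf, sig$gene)]
  z <- colMeans(v[inf, , drop = FALSE] * dir_inf)

  rate <- cfg$baseline_hazard * exp(cfg$beta * z)
  t_event <- stats::rexp(n, rate)
  censor <- stats::runif(n, 0, cfg$censor_max_months)
  time <- pmin(t_event, censor)
  event <- as.integer(t_event <= censor)

  ihc <- her2_true
  flip <- stats::runif(n) < cfg$ihc_error_rate
  ihc[flip] <- !ihc[flip]
  er_neg <- stats::runif(n) < cfg$frac_er_negative

  expr <- expression_matrix(values, cohort = cfg$cohort,
                            platform = "synthetic")
  clinical <- data.frame(
    sample = samples, cohort = cfg$cohort, endpoint = cfg$endpoint,
    time_months = time, event = event,
    her2_ihc = ifelse(ihc, "positive", "negative"),
    er_status = ifelse(er_neg, "negative", "positive"),
    stringsAsFactors = FALSE)

  inf_sig <- subset_signature(sig, inf, name = "planted")
  planted <- ssm_scores(median_center(expr), inf_sig)$match
  true_hr <- if (length(unique(planted)) == 2L)
    exp(cfg$beta * (mean(z[planted]) - mean(z[!planted]))) else NA_real_
  pathway_map <- data.frame(
    gene = c(sig$gene, unlist(cand, use.names = FALSE)),
    pathway = c(sig$pathway, rep(paths, lengths(cand))),
    stringsAsFactors = FALSE)

  list(expr = expr, clinical = clinical,
       truth = list(z = stats::setNames(z, samples),
                    planted_match = stats::setNames(planted, samples),
                    true_group_hr = true_hr,
                    her2_true = stats::setNames(her2_true, samples),
                    amplicon_fold = stats::setNames(fold, samples),
                    pathway_map = pathway_map,
                    informative_genes = inf,
                    candidates = unlist(cand, use.names = FALSE)))
}

#' Calibrate beta for a target marginal group hazard ratio
#'
#' The marginal Cox hazard ratio between SSM-match groups is attenuated
#' relative to `exp(beta * difference in mean z)` because hazards vary
#' within each group. This helper finds the `beta` whose *fitted*
#' two-group Cox hazard ratio matches a target, by fixed-point
#' iteration on pilot cohorts (large n, signature genes only, so each
#' iteration is cheap). Deterministic given `seed`.
#'
#' @param target_hr desired match vs no-match Cox hazard ratio.
#' @param cfg a [synthetic_config()]; its `beta` is ignored.
#' @param n_pilot pilot cohort size per fit.
#' @param n_iter fixed-point iterations.
#' @param n_avg pilot fits averaged per iteration (reduces the Monte
#'   Carlo noise fed back into the update).
#' @param seed integer seed for the pilot cohorts.
#' @return calibrated beta (numeric scalar).
#' @export
calibrate_beta <- function(target_hr, cfg, n_pilot = 6000L, n_iter = 4L,
                           n_avg = 2L, seed = 1L) {
  pilot_cfg <- cfg
  pilot_cfg$n_samples <- as.integer(n_pilot)
  pilot_cfg$n_genes <- 0L            # signature + amplicon genes only
  pilot_cfg$n_candidates_per_pathway <- 0L
  pilot_cfg$frac_her2 <- 0
  planted_sig <- subset_signature(cfg$signature, cfg$informative_genes,
                                  name = "planted")
  fit_loghr <- function(beta, it) {
    vals <- numeric(n_avg)
    for (r in seq_len(n_avg)) {
      pilot_cfg$beta <- beta
      pilot_cfg$seed <- seed + 100L * it + r   # fresh pilot noise
      co <- generate_cohort(pilot_cfg)
      m <- ssm_scores(median_center(co$expr), planted_sig)$match
      fit <- cox_hr(co$clinical$time_months, co$clinical$event, m)
      vals[r] <- if (fit$estimable) fit$log_hr else NA_real_
    }
    mean(vals, na.rm = TRUE)
  }
  beta <- log(target_hr)             # start: no-attenuation guess / sd ~ 1
  for (it in seq_len(n_iter)) {
    lh <- fit_loghr(beta, it)
    if (!is.finite(lh) || lh <= 0) next
    beta <- beta * log(target_hr) / lh
  }
  beta
}

#' Write a self-contained fixture suite
#'
#' Emits a paired MFS-style and OS-style synthetic cohort plus
#' signature files, so every pipeline stage can be exercised from flat
#' files: `expr_mfs.tsv`, `clin_mfs.tsv`, `expr_os.tsv`, `clin_os.tsv`,
#' `htics.tsv`, `core.tsv`, `candidates.tsv`. Byte-identical for a
#' fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param cfg base [synthetic_config()]; the OS cohort reuses it with
#'   endpoint/cohort/seed adjusted.
#' @return named character vector of the files written.
#' @export
write_fixture_suite <- function(dir, seed = 1L,
                                cfg = synthetic_config(seed = seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg$seed <- seed; cfg$endpoint <- "MFS"; cfg$cohort <- "simMFS"
  mfs <- generate_cohort(cfg)
  cfg_os <- cfg; cfg_os$seed <- seed + 1L
  cfg_os$endpoint <- "OS"; cfg_os$cohort <- "simOS"
  os <- generate_cohort(cfg_os)
  files <- c(
    expr_mfs = file.path(dir, "expr_mfs.tsv"),
    clin_mfs = file.path(dir, "clin_mfs.tsv"),
    expr_os = file.path(dir, "expr_os.tsv"),
    clin_os = file.path(dir, "clin_os.tsv"),
    htics = file.path(dir, "htics.tsv"),
    core = file.path(dir, "core.tsv"),
    candidates = file.path(dir, "candidates.tsv"))
  write_expression(mfs$expr, files["expr_mfs"])
  write_clinical(mfs$clinical, files["clin_mfs"])
  write_expression(os$expr, files["expr_os"])
  write_clinical(os$clinical, files["clin_os"])
  write_signature(cfg$signature, files["htics"])
  write_signature(core_signature(), files["core"])
  utils::write.table(mfs$truth$pathway_map, files["candidates"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files
}
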