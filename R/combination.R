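#' Enumerate all non-empty gene subsets of a signature
#'
#' Subsets are encoded as integer bit masks: bit `i - 1` set means the
#' i-th signature gene is included. A k-gene signature yields
#' `2^k - 1` masks.
#'
#' @param k number of genes (or a [gene_signature()], whose length is
#'   used); must not exceed 24.
#' @return integer vector `1:(2^k - 1)`.
#' @export
enumerate_combinations <- function(k) {
  if (inherits(k, "gene_signature")) k <- nrow(k)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 24L)
    stop("k > 24 would enumerate > 16M subsets; pre-select a gene subset")
  seq_len(bitwShiftL(1L, k) - 1L)
}

#' Genes contained in a subset mask
#'
#' @param mask integer mask (or vector of masks).
#' @param signature the parent [gene_signature()].
#' @return character vector (single mask) or list of character vectors.
#' @export
mask_genes <- function(mask, signature) {
  one <- function(m) signature$gene[bitwAnd(m, bitwShiftL(1L, seq_len(nrow(signature)) - 1L)) > 0L]
  if (length(mask) == 1L) one(mask) else lapply(mask, one)
}

#' @rdname mask_genes
#' @param genes character vector of genes to encode.
#' @export
genes_mask <- function(genes, signature) {
  idx <- match(genes, signature$gene)
  if (anyNA(idx)) stop("gene(s) not in signature: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

# records x k logical membership matrix from bit masks
mask_membership <- function(masks, signature) {
  k <- nrow(signature)
  B <- vapply(seq_len(k),
              function(i) bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0L,
              logical(length(masks)))
  if (length(masks) == 1L) B <- matrix(B, nrow = 1L)
  colnames(B) <- signature$gene
  B
}

# Precompute what the sweep kernel needs for one endpoint: the per-gene
# score matrix (columns sorted by follow-up time) and the risk-set blocks.
build_sweep_context <- function(expr, clinical, signature,
                                per_cohort_center = TRUE) {
  clinical <- validate_clinical(clinical)
  keep <- intersect(sample_ids(expr), clinical$sample)
  if (length(keep) < 4L) stop("fewer than 4 samples shared by expression and clinical tables")
  clinical <- clinical[match(keep, clinical$sample), , drop = FALSE]
  sub <- expression_matrix(expr$values[, keep, drop = FALSE],
                           cohort = expr$cohort[keep])
  centered <- median_center(sub, per_cohort = per_cohort_center)
  mapped <- map_gene_ids(signature, centered)
  if (length(mapped$unmatched))
    stop("signature gene(s) absent from expression matrix: ",
         paste(mapped$unmatched, collapse = ", "))
  S <- mapped$signature$direction * sign(centered$values[mapped$signature$gene, , drop = FALSE])
  ctx <- surv_context(clinical$time_months, clinical$event)
  S <- S[, ctx$ord, drop = FALSE]
  storage.mode(S) <- "integer"
  list(S = S, ev = ctx$ev, bs = ctx$block_start - 1L, be = ctx$block_end - 1L,
       d = ctx$d, Y = ctx$Y,
       time = clinical$time_months, event = clinical$event,
       surv = ctx, samples = keep)
}

#' Survival-evaluate every sub-signature on MFS and OS cohorts
#'
#' Runs the full exhaustive sweep: for each of the `2^k - 1` non-empty
#' gene subsets, samples are SSM-classified with the sub-signature and
#' the match vs no-match hazard ratio and p-value are computed on each
#' endpoint. The default estimator is the fast O/E ratio with the
#' log-rank p (see [oe_hr()]); `estimator = "cox"` fits a Cox model per
#' subset and is only practical for small k. A subset is `significant`
#' when p < alpha on both endpoints.
#'
#' @param expr_mfs,clin_mfs expression and clinical data of the MFS
#'   cohort (already subtype-filtered as desired).
#' @param expr_os,clin_os the OS cohort; pass `NULL` for a
#'   single-endpoint sweep (significance then uses the MFS p only).
#' @param signature a [gene_signature()] of at most 24 genes, all
#'   present in both matrices.
#' @param alpha significance level (default 0.05).
#' @param estimator `"oe"` (fast, default) or `"cox"` (k <= 14).
#' @param per_cohort_center see [median_center()].
#' @return A data.frame of class `combination_records` with columns
#'   `mask`, `size`, `hr_mfs`, `p_mfs`, (`hr_os`, `p_os`,)
#'   `significant`; non-estimable subsets carry `NA` hazard ratios and
#'   `significant = FALSE`. The parent signature, alpha and estimator
#'   are kept as attributes.
#' @export
evaluate_all <- function(expr_mfs, clin_mfs, expr_os = NULL, clin_os = NULL,
                         signature, alpha = 0.05,
                         estimator = c("oe", "cox"),
                         per_cohort_center = TRUE) {
  estimator <- match.arg(estimator)
  k <- nrow(signature)
  masks <- enumerate_combinations(k)
  ctx1 <- build_sweep_context(expr_mfs, clin_mfs, signature,
                              per_cohort_center)
  two <- !is.null(expr_os)
  ctx2 <- if (two) build_sweep_context(expr_os, clin_os, signature,
                                       per_cohort_center) else list()
  if (estimator == "oe") {
    res <- sweep_subsets_cpp(ctx1, ctx2, k)
    rec <- data.frame(mask = masks, size = res$size,
                      hr_mfs = res$hr_mfs, p_mfs = res$p_mfs)
    if (two) { rec$hr_os <- res$hr_os; rec$p_os <- res$p_os }
  } else {
    if (k > 14L) stop("estimator 'cox' supports at most 14 genes; use 'oe'")
    cox_one <- function(ctx, mask) {
      bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
      g <- colSums(ctx$S[bits, , drop = FALSE]) >= 0
      # columns are time-sorted; time/event in original order
      z <- logical(length(g)); z[ctx$surv$ord] <- g
      fit <- cox_hr(ctx$time, ctx$event, z)
      c(if (fit$estimable) fit$hr else NA_real_,
        if (fit$estimable) fit$p else NA_real_)
    }
    m1 <- t(vapply(masks, function(m) cox_one(ctx1, m), numeric(2)))
    rec <- data.frame(mask = masks,
                      size = vapply(masks, function(m)
                        sum(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L),
                        integer(1)),
                      hr_mfs = m1[, 1], p_mfs = m1[, 2])
    if (two) {
      m2 <- t(vapply(masks, function(m) cox_one(ctx2, m), numeric(2)))
      rec$hr_os <- m2[, 1]; rec$p_os <- m2[, 2]
    }
  }
  sig <- !is.na(rec$p_mfs) & rec$p_mfs < alpha
  if (two) sig <- sig & !is.na(rec$p_os) & rec$p_os < alpha
  rec$significant <- sig
  attr(rec, "signature") <- signature
  attr(rec, "alpha") <- alpha
  attr(rec, "estimator") <- estimator
  class(rec) <- c("combination_records", "data.frame")
  message(sprintf("evaluate_all: %d subsets evaluated, %d significant (alpha = %g, %s)",
                  length(masks), sum(sig), alpha, estimator))
  rec
}

#' Write combination records as TSV
#'
#' Adds a human-readable `genes` column (symbols joined by "+").
#'
#' @param records a `combination_records` data.frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  signature <- attr(records, "signature")
  B <- mask_membership(records$mask, signature)
  genes <- apply(B, 1L, function(b) paste(signature$gene[b], collapse = "+"))
  out <- cbind(data.frame(genes = genes, stringsAsFactors = FALSE),
               as.data.frame(records))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise gene co-occurrence across sub-signatures
#'
#' For every gene pair (i, j), the percentage of the supplied records
#' (typically the significant ones) containing both genes. The mean and
#' SD are taken over the k(k-1)/2 distinct pairs; pairs above
#' mean + 1 SD are "partners", and each gene's partner count and overall
#' appearance frequency are reported.
#'
#' @param records a `combination_records` data.frame (pre-filtered to
#'   the subset of interest, e.g. `records[records$significant, ]`).
#' @param signature the parent [gene_signature()] (defaults to the one
#'   stored in `records`).
#' @return list of class `pairwise_stats`: `cooccurrence` (k x k %,
#'   symmetric), `mean_overlap`, `sd_overlap`, `threshold`
#'   (= mean + sd), `partner_count`, `gene_frequency` (%), `n_records`.
#' @export
pairwise_cooccurrence <- function(records,
                                  signature = attr(records, "signature")) {
  if (nrow(records) == 0L) stop("no records supplied")
  B <- mask_membership(records$mask, signature)
  n <- nrow(B)
  co <- 100 * crossprod(B) / n
  pairs <- co[upper.tri(co)]
  mean_overlap <- mean(pairs)
  sd_overlap <- stats::sd(pairs)
  threshold <- mean_overlap + sd_overlap
  above <- co > threshold
  diag(above) <- FALSE
  structure(list(cooccurrence = co,
                 mean_overlap = mean_overlap,
                 sd_overlap = sd_overlap,
                 threshold = threshold,
                 partner_count = rowSums(above),
                 gene_frequency = 100 * colMeans(B),
                 n_records = n),
            class = "pairwise_stats")
}

#' @export
print.pairwise_stats <- function(x, ...) {
  cat(sprintf(paste0("pairwise_stats over %d records: mean overlap %.2f%%,",
                     " SD %.2f%%, threshold %.2f%%\n"),
              x$n_records, x$mean_overlap, x$sd_overlap, x$threshold))
  invisible(x)
}

#' Core-gene selection from pairwise statistics
#'
#' `select_core1()` keeps genes whose co-occurrence exceeds the
#' mean + 1 SD threshold with at least `min_partners` other genes.
#' `select_core2()` first restricts the pairwise analysis to a
#' top-performing record set, then additionally requires a gene's
#' appearance frequency to be strictly above the median frequency.
#'
#' @param stats a `pairwise_stats` object.
#' @param min_partners minimum number of above-threshold partners.
#' @return character vector of gene symbols (possibly empty).
#' @export
select_core1 <- function(stats, min_partners = 2L) {
  names(stats$partner_count)[stats$partner_count >= min_partners]
}

#' Top-performing sub-signatures relative to a reference
#'
#' Keeps significant records whose hazard ratios on both endpoints are
#' at least `margin` times the reference record's (the full signature by
#' default): the subsets scoring "similar or better" than the parent.
#'
#' @param records a `combination_records` data.frame.
#' @param reference a single-row record to compare against; default is
#'   the full-signature mask.
#' @param margin multiplicative slack on the reference HRs (1 = must
#'   match or beat the reference).
#' @return the qualifying subset of `records`.
#' @export
select_top <- function(records, reference = NULL, margin = 1.0) {
  signature <- attr(records, "signature")
  if (is.null(reference)) {
    full <- bitwShiftL(1L, nrow(signature)) - 1L
    reference <- records[records$mask == full, , drop = FALSE]
    if (nrow(reference) == 0L) stop("full-signature record not found")
  }
  keep <- records$significant &
    !is.na(records$hr_mfs) & records$hr_mfs >= margin * reference$hr_mfs
  if ("hr_os" %in% names(records))
    keep <- keep & !is.na(records$hr_os) &
      records$hr_os >= margin * reference$hr_os
  out <- records[keep, , drop = FALSE]
  attr(out, "signature") <- signature
  class(out) <- class(records)
  out
}

#' @rdname select_core1
#' @param top_records the record subset returned by [select_top()].
#' @param signature the parent [gene_signature()].
#' @export
select_core2 <- function(top_records,
                         signature = attr(top_records, "signature"),
                         min_partners = 2L) {
  stats <- pairwise_cooccurrence(top_records, signature)
  freq <- stats$gene_frequency
  keep <- stats$partner_count >= min_partners & freq > stats::median(freq)
  names(freq)[keep]
}

#' Intersect two core gene sets
#'
#' @param core1,core2 character vectors of gene symbols.
#' @param signature parent [gene_signature()] supplying directions and
#'   pathways for the intersection.
#' @return a [gene_signature()] named "Core" (order as in the parent).
#' @export
intersect_cores <- function(core1, core2, signature = htics_signature()) {
  common <- intersect(core1, core2)
  if (length(common) == 0L) {
    out <- data.frame(gene = character(0), direction = integer(0),
                      pathway = character(0), stringsAsFactors = FALSE)
    class(out) <- c("gene_signature", "data.frame")
    attr(out, "name") <- "Core"
    return(out)
  }
  subset_signature(signature, common, name = "Core")
}

#' Pathway coverage of sub-signatures
#'
#' For each record, which of the parent signature's pathways have at
#' least one gene present; summarised as the fraction of records
#' containing each pathway and the distribution of per-record pathway
#' counts.
#'
#' @param records a `combination_records` data.frame.
#' @param signature parent [gene_signature()]; every gene must carry a
#'   pathway label.
#' @return list with `per_record` (records x pathways logical matrix),
#'   `pathway_fraction` (named fractions) and `n_pathways`
#'   (table of per-record pathway counts).
#' @export
pathway_coverage <- function(records,
                             signature = attr(records, "signature")) {
  if (anyNA(signature$pathway))
    stop("every signature gene needs a pathway label")
  B <- mask_membership(records$mask, signature)
  paths <- unique(signature$pathway)
  P <- vapply(paths, function(p) signature$pathway == p,
              logical(nrow(signature)))
  per_record <- (B %*% P) > 0
  colnames(per_record) <- paths
  list(per_record = per_record,
       pathway_fraction = colMeans(per_record),
       n_pathways = table(rowSums(per_record)))
}

#' Remove one pathway from a signature
#'
#' Leave-one-pathway-out: drops every gene annotated with the given
#' pathway, for downstream re-evaluation of the reduced signature.
#'
#' @param signature a [gene_signature()].
#' @param pathway pathway label to remove.
#' @return the reduced [gene_signature()].
#' @export
leave_one_pathway_out <- function(signature, pathway) {
  if (!(pathway %in% signature$pathway))
    stop("pathway not present in signature: ", pathway)
  keep <- signature$pathway != pathway
  if (!any(keep)) stop("removing '", pathway, "' would empty the signature")
  gene_signature(signature$gene[keep], signature$direction[keep],
                 signature$pathway[keep],
                 name = paste0(signature_name(signature), " minus ", pathway))
}
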