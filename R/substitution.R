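#' Find best-correlated substitutes for signature genes
#'
#' For every signature gene, scans a candidate gene list and picks the
#' candidate whose expression across samples has the highest Pearson
#' correlation with the signature gene (ties broken alphabetically).
#' With `method = "absolute"` the absolute correlation is maximised
#' instead. Candidates that are themselves signature genes are ignored.
#'
#' @param expr an [expression_matrix()] over which correlations are
#'   computed (typically the discovery data the signature came from).
#' @param signature a [gene_signature()].
#' @param candidates character vector of candidate gene symbols present
#'   in `expr`.
#' @param pathway_map optional named character vector / data.frame
#'   (`gene`, `pathway`) giving candidate pathway labels, used to flag
#'   whether a substitute shares the pathway of the gene it replaces.
#' @param method `"signed"` (default) or `"absolute"` correlation.
#' @param unique_substitutes when `TRUE`, no candidate is assigned to
#'   more than one signature gene: genes are processed in order of
#'   their best attainable correlation and each takes the strongest
#'   still-unused candidate. Needed when the whole map is applied at
#'   once (a signature cannot contain a gene twice).
#' @return data.frame of class `substitution_map` with columns `gene`,
#'   `substitute`, `r`, `pathway` (of the original gene),
#'   `substitute_pathway`, `same_pathway`.
#' @export
find_substitutes <- function(expr, signature, candidates,
                             pathway_map = NULL,
                             method = c("signed", "absolute"),
                             unique_substitutes = FALSE) {
  method <- match.arg(method)
  if (length(candidates) == 0L) stop("candidate list is empty")
  mapped <- map_gene_ids(signature, expr)
  sig <- mapped$signature
  cand_idx <- match(toupper(candidates), toupper(gene_ids(expr)))
  if (anyNA(cand_idx))
    stop("candidate gene(s) absent from expression matrix: ",
         paste(candidates[is.na(cand_idx)], collapse = ", "))
  cand <- gene_ids(expr)[cand_idx]
  cand <- setdiff(cand, sig$gene)
  if (length(cand) == 0L)
    stop("no candidate remains after excluding signature genes")
  if (ncol(expr$values) < 3L) stop("need >= 3 samples for correlation")
  # candidate x signature correlation matrix
  R <- stats::cor(t(expr$values[cand, , drop = FALSE]),
                  t(expr$values[sig$gene, , drop = FALSE]))
  score <- if (method == "absolute") abs(R) else R
  pm <- normalize_pathway_map(pathway_map)
  pick <- function(s, available) {
    s[!available] <- -Inf
    best <- which(s == max(s))
    best[order(cand[best])][1L]                   # alphabetical tie-break
  }
  available <- rep(TRUE, length(cand))
  chosen <- integer(nrow(sig))
  # with unique assignment, serve genes in order of best attainable r
  gene_order <- if (unique_substitutes)
    order(apply(score, 2L, max), decreasing = TRUE) else seq_len(nrow(sig))
  for (j in gene_order) {
    chosen[j] <- pick(score[, j], available)
    if (unique_substitutes) available[chosen[j]] <- FALSE
  }
  rows <- lapply(seq_len(nrow(sig)), function(j) {
    best <- chosen[j]
    sub_path <- if (!is.null(pm)) unname(pm[cand[best]]) else NA_character_
    data.frame(gene = sig$gene[j], substitute = cand[best],
               r = R[best, j], pathway = sig$pathway[j],
               substitute_pathway = sub_path,
               same_pathway = !is.na(sub_path) && !is.na(sig$pathway[j]) &&
                 sub_path == sig$pathway[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("substitution_map", "data.frame")
  out
}

normalize_pathway_map <- function(pathway_map) {
  if (is.null(pathway_map)) return(NULL)
  if (is.data.frame(pathway_map))
    return(stats::setNames(as.character(pathway_map$pathway),
                           pathway_map$gene))
  pathway_map
}

#' Apply a substitution map to a signature
#'
#' Replaces the requested genes by their mapped substitutes; each
#' substitute inherits the direction (and pathway slot) of the gene it
#' replaces, even when the two anti-correlate (such entries are worth
#' inspecting in the map's `r` column).
#'
#' @param signature a [gene_signature()].
#' @param map a `substitution_map` (or any data.frame with `gene` and
#'   `substitute` columns).
#' @param genes_to_replace character vector of genes to swap, or
#'   `"all"` to replace every gene that has a map entry... every gene in
#'   `signature` must then be covered by `map`.
#' @param name name of the resulting signature.
#' @return a [gene_signature()] with substitutes swapped in.
#' @export
apply_substitution <- function(signature, map, genes_to_replace = "all",
                               name = paste0(signature_name(signature), "m")) {
  if (identical(genes_to_replace, "all"))
    genes_to_replace <- signature$gene
  if (length(genes_to_replace) == 0L)
    return(signature)
  missing_entry <- setdiff(genes_to_replace, map$gene)
  if (length(missing_entry))
    stop("no substitution-map entry for: ",
         paste(missing_entry, collapse = ", "))
  gene_out <- signature$gene
  swap <- gene_out %in% genes_to_replace
  gene_out[swap] <- map$substitute[match(gene_out[swap], map$gene)]
  gene_signature(gene_out, signature$direction, signature$pathway,
                 name = name)
}

#' Agreement between two signatures' SSM scores
#'
#' Pearson correlation between the per-sample SSM scores of two
#' signatures on the same centered matrix, plus the AUC when signature
#' A's match call is taken as truth and signature B's SSM score as the
#' rating.
#'
#' @param centered a median-centered [expression_matrix()].
#' @param sig_a,sig_b two [gene_signature()]s evaluable on `centered`.
#' @return list with `r`, `auc`, and the two `ssm_result`s. `r` is `NA`
#'   (with a message) when either score vector is constant.
#' @export
score_agreement <- function(centered, sig_a, sig_b) {
  res_a <- ssm_scores(centered, sig_a)
  res_b <- ssm_scores(centered, sig_b)
  r <- if (stats::sd(res_a$ssm) == 0 || stats::sd(res_b$ssm) == 0) {
    message("score_agreement: constant SSM scores; correlation undefined")
    NA_real_
  } else {
    stats::cor(res_a$ssm, res_b$ssm)
  }
  auc <- if (length(unique(res_a$match)) < 2L) NA_real_ else
    auc_rank(res_b$ssm, res_a$match)$auc
  list(r = r, auc = auc, ssm_a = res_a, ssm_b = res_b)
}
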