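#' Signed gene signature
#'
#' A gene signature is an ordered list of gene symbols, each carrying a
#' direction (+1 for genes expected up-regulated in the high-risk state,
#' -1 for down-regulated) and a biological pathway label. Directions act
#' as the per-gene weights \eqn{I_n} of the SSM classifier.
#'
#' @param gene character vector of gene symbols (no duplicates).
#' @param direction integer/numeric vector of +1 / -1, one per gene.
#' @param pathway character vector of pathway labels, one per gene
#'   (`NA` allowed when no annotation exists).
#' @param name single string naming the signature.
#' @return An object of class `gene_signature`: a data.frame with columns
#'   `gene`, `direction`, `pathway` and a `name` attribute.
#' @examples
#' sig <- gene_signature(c("AURKB", "CCR2"), c(+1, -1),
#'                       c("Cell Cycle", "Immune Response"), name = "toy")
#' @export
gene_signature <- function(gene, direction, pathway = NA_character_,
                           name = "signature") {
  gene <- as.character(gene)
  if (length(gene) == 0L)
    stop("a gene signature must contain at least one gene")
  if (anyDuplicated(gene))
    stop("duplicate genes in signature: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  direction <- as.integer(direction)
  if (length(direction) != length(gene))
    stop("'direction' must have one entry per gene")
  if (!all(direction %in% c(-1L, 1L)))
    stop("directions must be +1 or -1")
  pathway <- rep_len(as.character(pathway), length(gene))
  out <- data.frame(gene = gene, direction = direction, pathway = pathway,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_signature", "data.frame")
  attr(out, "name") <- as.character(name)[1]
  out
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s': %d genes (%d up, %d down)\n",
              signature_name(x), nrow(x), sum(x$direction == 1L),
              sum(x$direction == -1L)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @rdname gene_signature
#' @param x a `gene_signature`.
#' @export
signature_name <- function(x) attr(x, "name")

#' Subset a signature by gene
#'
#' @param signature a [gene_signature()].
#' @param genes character vector of genes to keep (order of the parent
#'   signature is preserved).
#' @param name name for the reduced signature.
#' @return A `gene_signature` restricted to `genes`.
#' @export
subset_signature <- function(signature, genes,
                             name = paste0(signature_name(signature), "_subset")) {
  keep <- signature$gene %in% genes
  if (!any(keep)) stop("none of the requested genes are in the signature")
  gene_signature(signature$gene[keep], signature$direction[keep],
                 signature$pathway[keep], name = name)
}

#' The 17-gene HTICS signature
#'
#' The Her2-TIC-enriched signature for HER2-positive, ER-alpha-negative
#' breast cancer: 8 up-regulated and 9 down-regulated genes spanning five
#' pathways (Cell Cycle, Immune Response, Cell Migration, Homeostasis,
#' Glycan Metabolism). Symbols follow the original mouse nomenclature;
#' matching against human arrays is case-insensitive (see
#' [map_gene_ids()]).
#'
#' @return A [gene_signature()] of 17 entries.
#' @export
htics_signature <- function() {
  gene_signature(
    gene = c("Aurkb", "Ccna2", "Chaf1b", "Ccnb1",
             "Scrn1", "C1qb", "CD74", "Ccr2", "Itgb2", "Vcam1", "CD180", "CD72",
             "Npy", "Cldn8", "Nrp1",
             "Atp7b", "St8sia4"),
    direction = c(+1, +1, +1, +1,
                  +1, -1, -1, -1, -1, -1, -1, -1,
                  +1, +1, -1,
                  +1, -1),
    pathway = c(rep("Cell Cycle", 4),
                rep("Immune Response", 8),
                rep("Cell Migration", 3),
                "Homeostasis", "Glycan Metabolism"),
    name = "HTICS"
  )
}

#' Published HTICS core subsets
#'
#' `core1_signature()` is the 8-gene core extracted by pairwise
#' co-occurrence over all significant sub-signatures; `core2_signature()`
#' the 8-gene core from the top-performing sub-signatures;
#' `core_signature()` their 6-gene intersection (3 up: Chaf1b, Scrn1,
#' Npy; 3 down: Ccr2, CD74, Nrp1), which monitors the Cell Cycle,
#' Immune Response and Cell Migration pathways only.
#'
#' @return A [gene_signature()]; directions and pathways inherited from
#'   [htics_signature()].
#' @export
core1_signature <- function() {
  subset_signature(htics_signature(),
                   c("Ccr2", "Nrp1", "Scrn1", "Vcam1", "CD74", "Chaf1b",
                     "Npy", "CD180"),
                   name = "Core1")
}

#' @rdname core1_signature
#' @export
core2_signature <- function() {
  subset_signature(htics_signature(),
                   c("Scrn1", "Nrp1", "C1qb", "CD74", "Npy", "Chaf1b",
                     "St8sia4", "Ccr2"),
                   name = "Core2")
}

#' @rdname core1_signature
#' @export
core_signature <- function() {
  subset_signature(htics_signature(),
                   c("Chaf1b", "Scrn1", "Npy", "Ccr2", "CD74", "Nrp1"),
                   name = "Core")
}

#' Known substitute genes for HTICS members
#'
#' Best-correlated replacement genes documented for a subset of HTICS
#' members, with their pathway annotation. For four genes with weak FFPE
#' probe signal (Npy, Ccr2, CD180, CD72) the same-pathway substitutes
#' Spink5, Ctss, Aim2 and CD48 define the modified signature HTICSm.
#' The table is partial: replacements for the remaining HTICS genes were
#' never published as text and are not reconstructable here.
#'
#' @return data.frame with columns `gene`, `substitute`,
#'   `substitute_pathway`, `same_pathway`.
#' @export
known_substitutes <- function() {
  data.frame(
    gene       = c("Npy",    "Ccr2", "CD180", "CD72", "Chaf1b", "Nrp1",
                   "Cldn8",  "St8sia4", "Scrn1"),
    substitute = c("Spink5", "Ctss", "Aim2",  "CD48", "Kif11",  "Klrd1",
                   "Clu",    "Ncf4",    "Mphosph6"),
    substitute_pathway = c("Cell Migration", "Immune Response",
                           "Immune Response", "Immune Response",
                           "Cell Cycle", "Cell Migration",
                           "Cell Death", "Immune Response", NA),
    same_pathway = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default HER2 amplicon gene set
#'
#' The five co-amplified genes of the 17q12 ERBB2 amplicon whose joint
#' over-expression proxies HER2 receptor status on expression arrays.
#'
#' @return character vector of five gene symbols.
#' @export
amplicon_genes <- function() {
  c("ERBB2", "STARD3", "PERLD1", "GRB7", "C17orf37")
}
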