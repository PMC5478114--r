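#' Expression matrix container
#'
#' Thin container for a genes x samples matrix of log2 expression with
#' per-sample cohort labels. Row names are gene symbols, column names
#' sample identifiers.
#'
#' @param values numeric matrix (genes x samples) with dimnames.
#' @param cohort character vector of cohort labels, one per sample
#'   (recycled if length 1).
#' @param platform free-text platform tag.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cohort = "cohort1", platform = "") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids; collapse before construction")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  cohort <- rep_len(as.character(cohort), ncol(values))
  names(cohort) <- colnames(values)
  structure(list(values = values, cohort = cohort,
                 platform = as.character(platform)[1]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %d cohort(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$cohort))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a genes x samples expression table
#'
#' Reads a tab-separated table whose first column holds gene symbols and
#' whose header row holds sample identifiers. Duplicate gene rows (e.g.
#' multiple probes per symbol) are collapsed to their per-sample maximum,
#' keeping the strongest signal; the number of collapsed rows is reported
#' via `message()`.
#'
#' @param path file path of the TSV.
#' @param cohort cohort label applied to all samples in the file.
#' @param platform platform tag.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, cohort = basename(path), platform = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("parse error: '", path, "' is empty")
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("format error: expected a gene column plus >=1 sample column in ",
         path)
  genes <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("parse error: non-numeric value in column '%s', row %d ('%s')",
                   names(vals)[j], bad, v[bad]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    m <- collapse_duplicate_genes(m)
    message(sprintf("read_expression: collapsed %d duplicate gene row(s) by per-sample maximum",
                    n_dup))
  }
  expression_matrix(m, cohort = cohort, platform = platform)
}

# per-sample maximum over duplicated gene symbols
collapse_duplicate_genes <- function(m) {
  genes <- rownames(m)
  if (!anyDuplicated(genes)) return(m)
  idx <- split(seq_along(genes), genes)
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) m[i, ] else apply(m[i, , drop = FALSE], 2L, max)
  }, numeric(ncol(m))))
  # restore first-appearance order
  out[unique(genes), , drop = FALSE]
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical outcome table
#'
#' Columns: `sample`, `cohort`, `endpoint` (MFS or OS), `time_months`,
#' `event` (0/1), `her2_ihc` and `er_status`
#' (positive / negative / unknown).
#'
#' @param path file path of the TSV.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_clinical(tab)
}

#' @rdname read_clinical
#' @param clinical a clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_clinical
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample", "time_months", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (!("cohort" %in% names(clinical))) clinical$cohort <- "cohort1"
  if (!("endpoint" %in% names(clinical))) clinical$endpoint <- "MFS"
  for (col in c("her2_ihc", "er_status"))
    if (!(col %in% names(clinical))) clinical[[col]] <- "unknown"
  if (any(clinical$time_months < 0)) stop("time_months must be >= 0")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  if (!all(clinical$endpoint %in% c("MFS", "OS")))
    stop("endpoint must be 'MFS' or 'OS'")
  clinical
}

#' Read / write a signature definition table
#'
#' TSV with columns `gene`, `direction` (+1/-1) and `pathway`.
#'
#' @param path file path.
#' @param name signature name (defaults to the file base name).
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = sub("\\.tsv$", "", basename(path))) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "direction")
  if (!all(need %in% names(tab)))
    stop("signature table needs 'gene' and 'direction' columns")
  if (!("pathway" %in% names(tab))) tab$pathway <- NA_character_
  gene_signature(tab$gene, tab$direction, tab$pathway, name = name)
}

#' @rdname read_signature
#' @param signature a [gene_signature()].
#' @export
write_signature <- function(signature, path) {
  utils::write.table(as.data.frame(signature), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-center an expression matrix
#'
#' Subtracts, for every gene, the median log2 expression across samples
#' (within each cohort when `per_cohort = TRUE`), producing the centered
#' values \eqn{X_n} consumed by the SSM classifier. Even sample counts
#' use the mid-point median.
#'
#' @param expr an [expression_matrix()] of log2 values.
#' @param per_cohort center within each cohort separately (the
#'   convention for pooled multi-cohort analyses, where a gene's rank is
#'   defined relative to the median of its own cohort).
#' @return An [expression_matrix()] of centered values.
#' @export
median_center <- function(expr, per_cohort = FALSE) {
  v <- expr$values
  if (per_cohort) {
    for (ch in unique(expr$cohort)) {
      j <- which(expr$cohort == ch)
      med <- apply(v[, j, drop = FALSE], 1L, stats::median)
      v[, j] <- v[, j, drop = FALSE] - med
    }
  } else {
    v <- v - apply(v, 1L, stats::median)
  }
  expression_matrix(v, cohort = expr$cohort, platform = expr$platform)
}

#' Pool cohorts on their common genes
#'
#' Restricts each cohort to the gene intersection, prefixes sample ids
#' with their cohort label to keep them unique, and concatenates both
#' the expression matrices and the clinical tables.
#'
#' @param cohorts list of `list(expr = , clinical = )` pairs.
#' @return `list(expr = , clinical = )` for the pooled cohort.
#' @export
pool_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  genes <- Reduce(intersect, lapply(cohorts, function(co) gene_ids(co$expr)))
  if (length(genes) == 0L) stop("empty gene intersection across cohorts")
  exprs <- vector("list", length(cohorts))
  clins <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    ex <- cohorts[[i]]$expr
    cl <- validate_clinical(cohorts[[i]]$clinical)
    v <- ex$values[genes, , drop = FALSE]
    ch <- ex$cohort
    new_ids <- paste(ch, colnames(v), sep = ":")
    colnames(v) <- new_ids
    names(ch) <- new_ids
    exprs[[i]] <- list(values = v, cohort = ch)
    cl$sample <- paste(cl$cohort, cl$sample, sep = ":")
    clins[[i]] <- cl
  }
  values <- do.call(cbind, lapply(exprs, `[[`, "values"))
  cohort <- do.call(c, lapply(exprs, `[[`, "cohort"))
  list(expr = expression_matrix(values, cohort = cohort),
       clinical = do.call(rbind, clins))
}

#' Map signature genes onto an expression matrix
#'
#' Case-insensitive exact symbol matching (bridging mouse-style symbols
#' such as "Ccnb1" to human "CCNB1"). Unmatched genes are dropped from
#' the working signature and listed in the report; the working signature
#' keeps the matrix's spelling of each symbol.
#'
#' @param signature a [gene_signature()].
#' @param expr an [expression_matrix()].
#' @return `list(signature = working gene_signature, unmatched =
#'   character vector, n_matched = integer)`.
#' @export
map_gene_ids <- function(signature, expr) {
  g_expr <- gene_ids(expr)
  idx <- match(toupper(signature$gene), toupper(g_expr))
  matched <- !is.na(idx)
  if (!any(matched))
    stop("no signature gene matches the expression matrix")
  sig <- gene_signature(g_expr[idx[matched]],
                        signature$direction[matched],
                        signature$pathway[matched],
                        name = signature_name(signature))
  list(signature = sig,
       unmatched = signature$gene[!matched],
       n_matched = sum(matched))
}

#' Read a NanoString count table
#'
#' CSV with a `gene` column, an `is_control` flag column (TRUE for the
#' housekeeping controls) and one column of non-negative integer counts
#' per sample.
#'
#' @param path CSV path.
#' @return `list(counts = matrix, control_genes = character)`.
#' @export
read_nanostring <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("gene", "is_control") %in% names(tab)))
    stop("NanoString table needs 'gene' and 'is_control' columns")
  ctl <- as.logical(tab$is_control)
  m <- as.matrix(tab[, setdiff(names(tab), c("gene", "is_control")),
                     drop = FALSE])
  rownames(m) <- tab$gene
  if (any(m < 0)) stop("NanoString counts must be non-negative")
  list(counts = m, control_genes = tab$gene[ctl])
}

#' Normalize NanoString counts by housekeeping controls
#'
#' Scales every sample so that the geometric mean of its control-gene
#' counts equals the across-sample average of those geometric means,
#' then log2(count + 1)-transforms. This is the standard
#' geometric-mean-of-housekeepers normalization for nCounter data.
#'
#' @param counts non-negative count matrix (genes x samples), or the
#'   list returned by [read_nanostring()].
#' @param control_genes character vector of control genes (required when
#'   `counts` is a bare matrix).
#' @param cohort cohort label for the output matrix.
#' @return An [expression_matrix()] of log2 normalized counts.
#' @export
nanostring_normalize <- function(counts, control_genes = NULL,
                                 cohort = "nanostring") {
  if (is.list(counts) && !is.matrix(counts)) {
    control_genes <- counts$control_genes
    counts <- counts$counts
  }
  if (is.null(control_genes) || length(control_genes) == 0L)
    stop("control_genes must be a non-empty gene set")
  miss <- setdiff(control_genes, rownames(counts))
  if (length(miss))
    stop("control gene(s) absent from count table: ",
         paste(miss, collapse = ", "))
  ctl <- counts[control_genes, , drop = FALSE]
  zero <- colnames(counts)[apply(ctl, 2L, function(x) any(x == 0))]
  if (length(zero))
    stop("zero control count in sample(s): ", paste(zero, collapse = ", "))
  gm <- exp(colMeans(log(ctl)))
  scale_factor <- mean(gm) / gm
  norm <- sweep(counts, 2L, scale_factor, `*`)
  expression_matrix(log2(norm + 1), cohort = cohort, platform = "NanoString")
}
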