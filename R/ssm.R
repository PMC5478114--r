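#' Score for Signature Match (SSM)
#'
#' For each sample, every signature gene contributes
#' \eqn{I_n \cdot X_n / |X_n|} where \eqn{X_n} is the median-centered
#' log2 expression and \eqn{I_n = \pm 1} the expected direction; the SSM
#' score is the sum of these per-gene scores divided by the total weight
#' \eqn{\sum |I_n|}. A gene sitting exactly at the cohort median
#' (\eqn{X_n = 0}) contributes 0 to the numerator but remains in the
#' denominator (neutral evidence). Samples with SSM >= 0 are called a
#' match for the signature.
#'
#' @param centered an [expression_matrix()] of median-centered values
#'   (see [median_center()]).
#' @param signature a [gene_signature()]; genes are matched
#'   case-insensitively and missing genes are dropped (reducing the
#'   denominator to the number of genes present).
#' @return An object of class `ssm_result`: list with `sample_ids`,
#'   `per_gene_score` (genes x samples matrix of -1/0/+1), `ssm`
#'   (per-sample score in \[-1, 1\]), `match` (logical),
#'   `effective_weight` (denominator used) and `signature` (the working
#'   signature after gene mapping).
#' @examples
#' m <- matrix(c(0.5, 0.2, -1, 1), 2, 2,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' sig <- gene_signature(c("A", "B"), c(+1, -1))
#' ssm_scores(expression_matrix(m), sig)$ssm
#' @export
ssm_scores <- function(centered, signature) {
  mapped <- map_gene_ids(signature, centered)
  sig <- mapped$signature
  x <- centered$values[sig$gene, , drop = FALSE]
  score <- sig$direction * sign(x)    # I_n * X_n/|X_n|, 0 when X_n == 0
  weight <- nrow(sig)                 # sum(|I_n|) over genes present
  ssm <- colSums(score) / weight
  structure(list(sample_ids = colnames(x),
                 per_gene_score = score,
                 ssm = ssm,
                 match = classify_match(ssm),
                 effective_weight = weight,
                 signature = sig,
                 unmatched = mapped$unmatched),
            class = "ssm_result")
}

#' @export
print.ssm_result <- function(x, ...) {
  cat(sprintf("SSM ('%s', %d genes): %d samples, %d match / %d no-match\n",
              signature_name(x$signature), x$effective_weight,
              length(x$ssm), sum(x$match), sum(!x$match)))
  invisible(x)
}

#' Match call from SSM scores
#'
#' @param ssm numeric vector of SSM scores.
#' @return logical vector; `TRUE` (match) iff `ssm >= 0`.
#' @export
classify_match <- function(ssm) ssm >= 0
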