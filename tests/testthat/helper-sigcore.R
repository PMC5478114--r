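# small deterministic builders used across the suite

toy_expr <- function(values, genes = NULL, samples = NULL, cohort = "c1") {
  m <- as.matrix(values)
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(samples)) colnames(m) <- samples
  expression_matrix(m, cohort = cohort)
}

# random log2 matrix with named genes/samples
rand_expr <- function(n_genes, n_samples, seed = 1, cohort = "c1") {
  set.seed(seed)
  toy_expr(matrix(stats::rnorm(n_genes * n_samples, 7, 1), n_genes),
           genes = sprintf("G%03d", seq_len(n_genes)),
           samples = sprintf("s%03d", seq_len(n_samples)),
           cohort = cohort)
}

# small synthetic cohort for survival tests
small_cohort <- function(seed, n = 120, n_genes = 120, beta = 1.5, ...) {
  generate_cohort(synthetic_config(n_samples = n, n_genes = n_genes,
                                   beta = beta, seed = seed, ...))
}

# clinical frame from bare vectors
toy_clinical <- function(time, event, sample = sprintf("s%03d", seq_along(time)),
                         endpoint = "MFS", ...) {
  validate_clinical(data.frame(sample = sample, cohort = "c1",
                               endpoint = endpoint, time_months = time,
                               event = event, ...,
                               stringsAsFactors = FALSE))
}
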