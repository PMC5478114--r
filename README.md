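# sigcore

Tools for interrogating **signed multi-gene prognostic expression
signatures** in survival cohorts. The package was built around HTICS, a
17-gene signature (8 genes up-, 9 down-regulated in tumor-initiating
cells) that stratifies HER2⁺:ERα⁻ breast cancer patients into high- and
low-risk groups, but every function is generic over any signed
signature.

It is aimed at computational biologists who have normalized expression
tables plus clinical outcomes, and who want to (a) score samples
against a signature, (b) quantify its prognostic power, and (c) dissect
*which genes and pathways carry that power*.

## What it computes

**SSM — Score for Signature Match.** For sample *s*, with X<sub>n</sub>
the median-centered log2 expression of signature gene *n* and
I<sub>n</sub> = ±1 its expected direction,

```
SSM(s) = Σₙ Iₙ·Xₙ/|Xₙ|  /  Σₙ |Iₙ|      ∈ [−1, 1]
```

Samples with SSM ≥ 0 *match* the signature (high risk). Genes sitting
exactly at the median contribute 0 but stay in the denominator.

**Survival evaluation.** Match vs no-match groups are compared with
Kaplan–Meier curves, the Gehan–Breslow–Wilcoxon weighted log-rank test,
a Cox proportional-hazards ratio (Efron ties, Wald CI), and the fast
O/E estimator HR = (O₁/E₁)/(O₂/E₂) used inside permutation loops.

**HER2 amplicon calling.** A sample is HER2⁺ when strictly more than
2-fold elevated (vs the per-gene cohort median) in ≥ 3 of the five
amplicon genes ERBB2, STARD3, PERLD1, GRB7, C17orf37; concordance vs
IHC is reported as PPV/sensitivity/specificity/kappa/Fisher p.

**Sub-signature dissection.** All 2<sup>k</sup>−1 gene subsets
(131,071 for k = 17) are survival-evaluated on paired MFS/OS cohorts
via a Gray-code C++ sweep; pairwise co-occurrence across the
significant subsets (partner threshold = mean + 1 SD of the pairwise
overlaps) extracts Core1, the top-performing subsets yield Core2, and
their intersection is the minimal Core. Correlation-based substitute
discovery, composition-matched random-signature nulls and a
permutation empirical false detection rate (eFDR) complete the
toolbox, together with a synthetic-cohort generator that plants all of
the above structure for validation.

## Worked example

```r
library(sigcore)

# a synthetic 300-sample cohort with the HTICS signature planted
cfg <- synthetic_config(n_samples = 300, n_genes = 500, beta = 2, seed = 42)
co  <- generate_cohort(cfg)

sv <- evaluate_signature(co$expr, co$clinical, htics_signature())
sv
#> survival_comparison ('HTICS'): 148 match vs 152 no-match
#>   Cox HR 3.12 [2.17, 4.48], p = 7.62e-10; Wilcoxon p = 3.24e-10

outcome_roc(sv$ssm, sv$time, sv$event)$roc
#> roc_result: AUC = 0.713 (136 positive, 164 negative)

empirical_fdr(co$expr, co$clinical, htics_signature(),
              n_perm = 1000, seed = 7)
#> null_distribution: target HR 3.01 vs 1000 draws; rank 1, n_better 0, eFDR 0

calls <- call_her2(amplicon_fold_changes(co$expr))
concordance(calls$her2_call, co$clinical$her2_ihc == "positive")
#> concordance (n=300): rate 94.3%, kappa 0.82, PPV 94.2%, sens 77.8%,
#>                      spec 98.7%, Fisher p 1.12e-39
```

Reading the numbers: the SSM-match group progresses ~3× faster than
the no-match group (Cox HR 3.12, both tests highly significant); the
SSM score separates progressing from disease-free patients with AUC
0.71; none of 1000 composition-matched random signatures beats the
planted one (eFDR 0); and the expression-based HER2 call agrees with
the noisy simulated IHC labels at kappa 0.82.

The full dissection — leave-one-pathway-out, the 131,071-subset sweep,
Core1/Core2/Core extraction, substitutes, null ranking — runs as one
pipeline:

```r
report <- run_full_analysis(co$expr, co$clinical,
                            signature = htics_signature(),
                            candidates = co$truth$candidates,
                            pathway_map = co$truth$pathway_map,
                            seed = 1, out_dir = "results/")
```

Built-in fixtures: `htics_signature()`, `core1_signature()`,
`core2_signature()`, `core_signature()` (their 6-gene intersection),
`amplicon_genes()`, `known_substitutes()`; the same tables ship as TSV
under `inst/extdata/`, alongside a small **synthetic** NanoString count
table for `read_nanostring()` / `nanostring_normalize()`.

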