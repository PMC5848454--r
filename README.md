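# rbpknn

Inference of RNA-binding protein (RBP) sequence preferences from homologs.

Most RBPs have no measured binding preference: in vitro compendia such as
RNAcompete cover a few hundred proteins. `rbpknn` predicts the position
weight matrix (PWM) of a poorly studied RBP from the PWMs of its sequence
homologs, exploiting the co-evolution of RBPs and their binding motifs.

## The method

For a query protein *x* with homolog set *H*, each homolog receives a weight
*w* equal to its global-alignment percent identity to *x* (Needleman–Wunsch,
BLOSUM62, affine gaps). The inferred PWM is the similarity-weighted average
over the *K* nearest homologs:

    PWM_x(i, j) = Σ_p w_p · PWM_p(i, j) / Σ_p w_p ,   p = 1..K

*K* is chosen by 2-fold cross-validation against probe intensities when the
query has binding data, or fixed to 7 for novel proteins. Sequences are
scored with a PWM by the windowed-product scan

    y = (1/|s|) Σ_t f( Π_l PWM(index(s_l), l−t) ),
    f(a) = arcsinh(a) if a > 1, else 0,

so only windows scoring above the uniform background contribute (the PWM
must be on the background-ratio scale — entries are probability / 0.25).
The package also provides:

* a **mirror-tree co-evolution test** — Pearson correlation between the
  pairwise protein-similarity and motif-similarity matrices, with a
  permutation test (add-one p-value) and a one-sided parametric t test;
* conversion of a PWM into a **frozen k-mer score table** `φ` for the
  logistic binding model `F_seq(m) = 1 / (1 + exp(−b − φ_m))`, with a
  freeze-contract check for external trainers;
* an **evaluation harness**: 99.95th-percentile intensity clamping, seeded
  A/B probe splits, Pearson correlation, midrank ROC AUC, paired t tests,
  per-RBP aggregation;
* **seeded synthetic generators** for co-evolved protein/motif families and
  PWM-driven probe sets, so the full pipeline runs without external data;
* readers/writers for MEME minimal and tabular (`Pos A C G U`) motif
  formats, protein FASTA, and similarity-matrix TSV;
* a command line (`inst/scripts/rbpknn`) with `simulate`, `infer`, `score`,
  `coevo`, `eval`, and `benchmark` subcommands.

## A worked example

```r
library(rbpknn)

cfg <- synth_config(n_proteins = 10, probe_count = 500, seed = 42)
fam <- generate_family(cfg)                  # co-evolved family with PWMs
probes <- generate_probes(fam[[1]]$pwm, cfg) # probes driven by one motif

fit <- rbp_knn(fam[[1]], fam[-1], probes = probes, seed = 42)
fit
#> Homology-weighted KNN motif model for 'RBP001'
#>   K = 3 (cross-validated); motif width 7, scale probability
#>   nearest neighbors:
#>  rbp_id similarity
#>  RBP007       0.89
#>  RBP010       0.88
#>  RBP006       0.84

coevolution_test(fam, n_perm = 500, seed = 42)
#> Mirror-tree co-evolution test
#>   PCC = 0.8678 over 45 protein pairs
#>   permutation p = 0.001996 (500 permutations, seed 42)
#>   parametric p  = 6.068e-15 (anti-conservative; see docs)

eval_pcc(predict(fit, probes), probes$intensities)
#> PCC = 0.7115 (n = 500)
```

The fit reports which homologs drove the inference and the cross-validated
neighbor count; `coef(fit)` returns the inferred 4×7 PWM, `predict()` scores
new RNA sequences with it, and the co-evolution test shows that motif
similarity tracks protein similarity in this family (permutation p ≈ 0.002).

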