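---
title: "Inferring RBP sequence preferences from homologs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring RBP sequence preferences from homologs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpknn)
```

## The problem

Most RNA-binding proteins (RBPs) have no experimentally measured binding
preference: in vitro assays such as RNAcompete cover a few hundred proteins,
while genomes encode thousands. `rbpknn` addresses the poorly studied RBP by
exploiting co-evolution: if RBPs and their binding motifs diverge together,
then a protein's motif can be predicted from the motifs of its sequence
homologs — orthologs or paralogs with known position weight matrices (PWMs).

## The model

### Homology-weighted nearest-neighbor PWM inference

For a query protein $x$ with homolog set $H$, each homolog $h_i$ receives a
weight $w_i$ equal to the global-alignment percent identity between $x$ and
$h_i$. After sorting the homologs by $w_i$, the inferred PWM is the
cell-by-cell weighted average over the $K$ nearest:

$$\mathrm{PWM}^{x}(i,j) \;=\; \frac{\sum_{p=1}^{K} w^{p}\,
\mathrm{PWM}^{p}(i,j)}{\sum_{p=1}^{K} w^{p}}.$$

The weights are the raw identities in $[0,1]$ — no kernel, exponent, or
distance transform — so the estimator is a convex combination: every cell
lies within the range of the corresponding neighbor cells, and
probability-scale columns still sum to 1. All PWMs share a fixed width
(default $k = 7$), and averaging is cell-by-cell at that width; no offset
search or motif alignment is performed.

$K$ is chosen per query. When probe-level binding data exist for the query,
`select_opt_k()` runs cross-validation (default 2-fold): for each candidate
$K$ (default grid $1..\min(30, |H|)$; cross-validated optima in practice
range from 1 up to about 30), the PWM inferred from the homologs scores the
held-out probes and the Pearson correlation (PCC) with their measured
intensities is averaged over folds; `optK` is the argmax, ties going to the
smallest $K$. Because the PWM depends only on the homologs — never on the
query's probes — the folds differ only in which probes are scored;
cross-validation here protects the *choice of K*, not the PWM fit, from
overfitting the probe set. For a novel protein with no binding data,
`infer_novel()` uses a fixed $K = 7$, an empirical average of
cross-validated optima, clipped to the homolog pool size.

### Scoring RNA sequences with a PWM

A width-$k$ PWM on the *background-ratio* scale (entries are probabilities
divided by the uniform background 0.25) assigns each $k$-mer the product of
its matching entries. A sequence $s$ is scored by scanning all windows:

$$y \;=\; \frac{1}{|s|}\sum_{t=0}^{|s|-k}
f\!\Big(\prod_{l=t+1}^{t+k}\mathrm{PWM}(\mathrm{index}(s_l),\, l-t)\Big),
\qquad
f(a) = \begin{cases} \operatorname{arcsinh}(a), & a > 1\\ 0, & a \le 1.\end{cases}$$

Two consequences shape the implementation:

* **The gate forces the background-ratio scale.** On the probability scale a
  product of $k$ probabilities never exceeds 1, so $f$ would zero every
  window and $y \equiv 0$ identically. `score_sequence()` therefore rejects
  probability-scale PWMs with guidance, or converts them when
  `convert = TRUE`. The two scales are carried explicitly on every `pwm`
  object; conversion is multiplication/division by 0.25.
* **The normalizer is $|s|$, not the window count** $|s|-k+1$. The formula is
  implemented verbatim; for equal-length probe sets the two differ only by a
  constant factor and leave correlations and rankings unchanged.

Windows containing `N` score 0 (excluded by the gate) — a conservative
choice for ambiguous bases. RNA is single-stranded, so no reverse-complement
scan is performed. Windows are 0-based, half-open `[t, t + k)`.

### The mirror-tree co-evolution statistic

To test whether RBP sequences and their motifs co-evolve, the package
correlates two pairwise similarity matrices over the same $n$ proteins: the
protein matrix (global-alignment identity) and the motif matrix (by default
the Pearson correlation of the two flattened $4 \times k$ PWMs, mapped to
$[0,1]$ via $(r+1)/2$; the metric is pluggable, e.g. a per-column average
correlation). The statistic is the Pearson correlation over the
$n(n-1)/2$ upper-triangle pairs.

Significance comes from two tests:

* **Permutation (default):** the motif-to-protein assignment is shuffled
  `n_perm` times (default 1000) and the upper-tail p-value uses the add-one
  estimator $(1 + \#\{r_\mathrm{perm} \ge r_\mathrm{obs}\})/(1 +
  n_\mathrm{perm})$, which never returns 0.
* **Parametric:** a one-sided Student-$t$ transform of the correlation
  ($t = r\sqrt{(n_\mathrm{pairs}-2)/(1-r^2)}$, $n_\mathrm{pairs}-2$ df;
  one-sided because co-evolution predicts positive correlation). Matrix
  entries sharing a protein are not independent, so this test is
  anti-conservative; it is reported alongside, never instead of, the
  permutation p-value.

The machinery accepts externally computed protein similarity matrices
(`read_similarity_tsv()`), so stratified or speciation-controlled shuffle
designs can be layered on top by the user.

### The frozen k-mer table for the logistic binding model

Structure-aware k-mer models score a $k$-mer $m$ with a logistic function
$F^{seq}(m) = (1 + e^{-b - \phi_m})^{-1}$ over $4^k$ parameters $\phi$ plus a
bias $b$. `pwm_to_phi()` derives $\phi$ from an inferred PWM instead of
learning it: $\phi_m = \prod_l \mathrm{PWM}(\mathrm{index}(m_l), l)$, applied
verbatim on the PWM's own scale with no log transform (learned $\phi$ values
in such models can be negative; PWM-derived ones are positive products —
the table records its source scale). The table is created `frozen`: an
external trainer may update $b$ and any non-sequence parameters but must
leave $\phi$ bit-identical, which `freeze_contract_check()` verifies from
before/after snapshots. For probability-scale PWMs the $\phi$ values form a
product probability measure, so $\sum_m \phi_m = 1$ — a useful exactness
check. A size guard rejects $k > 10$ ($4^k$ entries). Training of structure
contexts, structure-profile prediction, and intensity regression belong to
the upstream k-mer model and are out of scope here; this module guarantees
only the interface such trainers need.

## Pairwise alignment

A compendium-scale workflow computes thousands of pairwise identities, so the
aligner is implemented in C++ (Gotoh's affine-gap global alignment):
BLOSUM62 substitution scores, gap open 10, gap extend 0.5 — ClustalW-like
defaults. Identity is defined as identical aligned columns divided by the
full alignment length, gap columns included — symmetric and bounded in
$[0,1]$. Two determinism details matter:

* Traceback ties prefer the diagonal; to keep `pairwise_identity()` exactly
  symmetric despite tie-breaking, the argument pair is canonicalized
  (lexicographically) before alignment.
* Ties in neighbor ranking are broken by ascending record id.

Users who prefer an external alignment pipeline can inject its similarity
matrix via `read_similarity_tsv()`; the internal aligner is the reproducible
default, validated in the test suite against an independent plain-R
dynamic-programming oracle.

## The evaluation harness

* `clamp_intensities()` caps intensities at the 99.95th percentile
  (type-7, linear interpolation — the ubiquitous default). One numerical
  subtlety: with interpolation, re-clamping clamped data can move the cap
  slightly unless $(n-1)p$ is an integer (e.g. $n = 10001$ at the default
  percentile), where the percentile is an exact order statistic and
  clamping is idempotent. The tests exercise idempotence at such sizes.
* `split_ab()` makes a seeded uniform ~50/50 probe split (set A gets the
  extra probe when $n$ is odd). The k-mer-coverage-balanced design used by
  the original probe-set authors is not reproduced; a uniform split is
  unbiased for the correlation comparisons made here.
* `eval_auc()` uses the midrank Mann–Whitney identity — exact under ties
  (each tied positive/negative pair counts 0.5) and verified against an
  all-pairs concordance oracle.
* `paired_ttest()` is the two-sided (optionally one-sided) paired Student
  t-test for method comparisons matched by experiment;
  `aggregate_mean_per_rbp()` collapses repeated test sets to one mean per
  protein first, so proteins with many test sets do not dominate.
* Clamping is applied per experiment before splitting (the order is not
  dictated by the protocol; clamping first keeps the cap independent of the
  split seed).

## Motif I/O and width harmonization

PWMs are read and written as cisBP-style tab-separated text
(`Pos A C G U`) and as MEME minimal motif files (RNA alphabet; DNA input is
accepted with T read as U). Position frequency matrices are converted by
`pfm_to_pwm()`: add a pseudocount (default 1) to every count, normalize
columns, then harmonize the width to $k = 7$. A wider matrix keeps the
contiguous window of maximal total information content (log base 2 against
the uniform background; ties go to the leftmost window); a narrower one is
padded with uniform columns, symmetrically, extra column on the right. The
exact conversion used to build the original compendium is not public; this
deterministic variant fixes only what the method requires — a common width
— and is flagged as a package choice. Window selection is invariant to
uniform scaling of the counts, and row order is fixed to A, C, G, U
throughout.

## The synthetic family generator

`generate_family()` emulates the statistical structure that the method
assumes in real compendium data — a homologous family whose motif divergence
tracks sequence divergence — without reproducing any real dataset:

* One ancestral protein (default 100 aa, the size of a small RNA-binding
  construct) and one ancestral PWM whose columns put 0.75–0.95 of their mass
  on a consensus base. The consensus range was set so that the generator's
  own contract holds: with no intensity noise, probes carrying one planted
  motif instance separate from unplanted ones with AUC above 0.9 at probe
  length 30. Weakly informative columns fail this because background-ratio
  products hover near the scan gate.
* Each descendant is mutated at a per-site rate drawn uniformly from
  $[0, \texttt{mutation\_rate}]$ (default bound 0.3), so one family spans a
  range of evolutionary distances — necessary for the mirror-tree statistic
  to have anything to correlate.
* Each descendant's PWM columns are mixed with Dirichlet noise
  (concentration 4 per base, so a full-strength perturbation is
  near-uniform) of magnitude
  $m_i = c \cdot d_i + (1 - c) \cdot u_i$, where $d_i$ is the realized
  sequence divergence, $u_i$ an independent uniform draw on the same range,
  and $c$ = `coevo_strength`. At $c = 1$ motif divergence is fully coupled
  to sequence divergence (and zero mutation yields identical clones); at
  $c = 0$ it is independent, the null of the permutation test.

`generate_probes()` emulates designed probe libraries: uniform-random RNA
(default 2000 probes of 35 nt, within the 30–41 nt range of designed
libraries), a motif instance sampled from the PWM planted at a random offset
in the first half (labeled bound), intensities equal to the scan score plus
Gaussian noise (`noise_sd`, default 0.1, roughly the scale of the scores
themselves).

What the generator does *not* emulate: k-mer-coverage-balanced probe
design, position biases, sequence composition of real transcriptomes,
family-specific substitution processes, or multi-domain proteins. Passing
tests therefore demonstrate correctness and calibration of the estimators
under the stated co-evolution model, not performance on real RNAcompete or
CLIP data.

## Problem sizes used in the checks

The shipped checks run the permutation-test calibration on 500 null
families of 20 proteins (1000 permutations each), the power check on 50
fully co-evolved families, the KNN-vs-1NN comparison on 20 families of 15
homologs with 2000 probes each (leave-one-out within each family, A/B probe
split, 2-fold cross-validation for optK), and optK recovery on 20 seeded
replicates. These sizes give stable rates (binomial standard errors of
about 0.01 on the calibration rate) while keeping the whole suite at
desk scale.

## Known limitations

* The method presumes motif-informative homologs exist; with none above the
  twilight zone of sequence identity the weighted average degrades toward a
  family-average motif.
* Fixed motif width (7): proteins with substantially longer or bimodal
  motifs are represented only approximately.
* The parametric co-evolution p-value ignores the dependence structure of
  similarity matrices; rely on the permutation test.
* The scan score treats windows independently and ignores RNA structure;
  structure-aware extensions consume the inferred PWM through the frozen
  k-mer table instead.

## A worked example

```{r example}
cfg <- synth_config(n_proteins = 10, probe_count = 500, seed = 42)
fam <- generate_family(cfg)
probes <- generate_probes(fam[[1]]$pwm, cfg)

fit <- rbp_knn(fam[[1]], fam[-1], probes = probes, seed = 42)
fit

res <- coevolution_test(fam, n_perm = 500, seed = 42)
res
```
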