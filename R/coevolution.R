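## Mirror-tree co-evolution statistic: Pearson correlation between the
## protein pairwise-similarity matrix and the motif pairwise-similarity
## matrix, over the off-diagonal upper-triangle pairs, with a permutation
## (assignment-shuffle) test and a parametric Student-t test.

#' Similarity between two PWMs
#'
#' Pearson correlation between the two 4 x k matrices flattened to
#' length-4k vectors, mapped to [0, 1] via (r + 1) / 2. The default metric
#' for the motif side of the mirror-tree statistic; a different metric can
#' be passed to [build_motif_similarity()].
#'
#' @param a,b [pwm()]s of equal width and scale.
#' @return similarity in [0, 1].
#' @export
pwm_similarity <- function(a, b) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (pwm_width(a) != pwm_width(b)) stop_input("PWM widths differ")
  if (pwm_scale(a) != pwm_scale(b)) stop_input("PWM scales differ")
  va <- as.vector(unclass(a)); vb <- as.vector(unclass(b))
  if (sd(va) == 0 || sd(vb) == 0)
    stop_degenerate("zero-variance PWM: similarity undefined")
  (cor(va, vb) + 1) / 2
}

#' Pairwise motif similarity matrix
#'
#' @param pwms list of [pwm()]s of common width and scale.
#' @param labels labels for the matrix; defaults to the motif ids.
#' @param metric symmetric function `(pwm, pwm) -> [0, 1]`
#'   (default [pwm_similarity()]).
#' @return a [similarity_matrix()].
#' @export
build_motif_similarity <- function(pwms, labels = NULL,
                                   metric = pwm_similarity) {
  n <- length(pwms)
  if (n < 2) stop_input("need at least 2 PWMs")
  if (is.null(labels)) labels <- vapply(pwms, motif_id, "")
  m <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- metric(pwms[[i]], pwms[[j]])
  similarity_matrix(m, labels)
}

.upper_vec <- function(m) m[upper.tri(m)]

#' Mirror-tree Pearson correlation between two similarity matrices
#'
#' The co-evolution statistic: Pearson correlation over the n(n-1)/2
#' off-diagonal upper-triangle pairs of a protein similarity matrix and a
#' motif similarity matrix sharing the same labels in the same order.
#'
#' @param protein_sim,motif_sim [similarity_matrix()] objects with
#'   identical labels, n >= 3.
#' @return list with `pcc` and `n_pairs`.
#' @export
mirror_tree_pcc <- function(protein_sim, motif_sim) {
  if (!identical(sim_labels(protein_sim), sim_labels(motif_sim)))
    stop_input("similarity matrices must share labels in the same order")
  n <- nrow(protein_sim)
  if (n < 3) stop_input("need at least 3 items")
  a <- .upper_vec(unclass(protein_sim))
  b <- .upper_vec(unclass(motif_sim))
  if (sd(a) == 0 || sd(b) == 0)
    stop_degenerate("zero variance in a similarity triangle")
  list(pcc = cor(a, b), n_pairs = length(a))
}

#' Permutation test for the mirror-tree statistic
#'
#' Shuffles the motif-to-protein assignment `n_perm` times (seeded),
#' recomputes the mirror-tree PCC for each shuffle, and returns the add-one
#' upper-tail p-value `(1 + #[perm >= observed]) / (1 + n_perm)`.
#'
#' @param protein_sim a [similarity_matrix()] over the proteins.
#' @param pwms list of [pwm()]s aligned (by position) to the protein labels.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param metric motif similarity metric, see [build_motif_similarity()].
#' @return the permutation p-value, with the observed PCC and the permuted
#'   PCCs attached as attributes `pcc` and `perm_pccs`.
#' @export
permutation_test <- function(protein_sim, pwms, n_perm = 1000, seed = 1,
                             metric = pwm_similarity) {
  n_perm <- .check_count(n_perm, "n_perm")
  n <- nrow(protein_sim)
  if (length(pwms) != n)
    stop_input("need exactly one PWM per protein, in label order")
  msim <- build_motif_similarity(pwms, labels = sim_labels(protein_sim),
                                 metric = metric)
  obs <- mirror_tree_pcc(protein_sim, msim)$pcc
  a <- .upper_vec(unclass(protein_sim))
  mm <- unclass(msim)
  ut <- upper.tri(mm)
  perm_pccs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(a, mm[p, p][ut])
  }, 0))
  p <- (1 + sum(perm_pccs >= obs)) / (1 + n_perm)
  structure(p, pcc = obs, perm_pccs = perm_pccs)
}

#' Parametric test for the mirror-tree correlation
#'
#' One-sided Student-t test of the correlation (co-evolution predicts a
#' positive r): `t = pcc * sqrt((n_pairs - 2) / (1 - pcc^2))` against a t
#' distribution with `n_pairs - 2` degrees of freedom. The matrix entries
#' are not independent, so this is anti-conservative; the permutation test
#' is the default in [coevolution_test()].
#'
#' @param pcc observed mirror-tree correlation.
#' @param n_pairs number of upper-triangle pairs (>= 3).
#' @return one-sided p-value; if `|pcc| = 1` the boundary value (0 for +1,
#'   1 for -1) is returned with attribute `degenerate = TRUE`.
#' @export
parametric_test <- function(pcc, n_pairs) {
  n_pairs <- .check_count(n_pairs, "n_pairs", min = 3)
  if (!is.numeric(pcc) || length(pcc) != 1 || is.na(pcc) || abs(pcc) > 1)
    stop_input("'pcc' must be a number in [-1, 1]")
  if (abs(pcc) == 1)
    return(structure(if (pcc > 0) 0 else 1, degenerate = TRUE))
  t_stat <- pcc * sqrt((n_pairs - 2) / (1 - pcc^2))
  pt(t_stat, df = n_pairs - 2, lower.tail = FALSE)
}

#' Co-evolution test between RBP sequences and their motifs
#'
#' Convenience wrapper: builds the protein similarity matrix (or accepts a
#' precomputed one), the motif similarity matrix, and runs the mirror-tree
#' statistic with both the permutation and the parametric test.
#'
#' @param records list of [rbp_record()]s with attached PWMs (n >= 3), or
#'   `NULL` if `protein_sim` and `pwms` are given directly.
#' @param protein_sim optional precomputed [similarity_matrix()] (e.g.
#'   imported from an external alignment tool).
#' @param pwms optional list of PWMs aligned to `protein_sim` labels.
#' @inheritParams permutation_test
#' @return object of class `coevolution_test`: `pcc`, `n_pairs`,
#'   `p_permutation`, `n_permutations`, `p_parametric`, `seed`.
#' @export
coevolution_test <- function(records = NULL, protein_sim = NULL, pwms = NULL,
                             n_perm = 1000, seed = 1,
                             metric = pwm_similarity) {
  if (!is.null(records)) {
    has_pwm <- vapply(records, function(r) inherits(r$pwm, "pwm"), TRUE)
    if (!all(has_pwm)) stop_input("every record needs an attached PWM")
    protein_sim <- build_similarity_matrix(records)
    pwms <- lapply(records, `[[`, "pwm")
  }
  if (is.null(protein_sim) || is.null(pwms))
    stop_input("supply 'records' or both 'protein_sim' and 'pwms'")
  msim <- build_motif_similarity(pwms, labels = sim_labels(protein_sim),
                                 metric = metric)
  mt <- mirror_tree_pcc(protein_sim, msim)
  p_perm <- permutation_test(protein_sim, pwms, n_perm = n_perm, seed = seed,
                             metric = metric)
  structure(list(pcc = mt$pcc, n_pairs = mt$n_pairs,
                 p_permutation = as.numeric(p_perm),
                 n_permutations = as.integer(n_perm),
                 p_parametric = as.numeric(parametric_test(mt$pcc,
                                                           mt$n_pairs)),
                 seed = as.integer(seed)),
            class = "coevolution_test")
}

#' @export
print.coevolution_test <- function(x, ...) {
  cat("Mirror-tree co-evolution test\n")
  cat(sprintf("  PCC = %.4f over %d protein pairs\n", x$pcc, x$n_pairs))
  cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
              x$p_permutation, x$n_permutations, x$seed))
  cat(sprintf("  parametric p  = %.4g (anti-conservative; see docs)\n",
              x$p_parametric))
  invisible(x)
}
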