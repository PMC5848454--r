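## Core estimator: the query's PWM is the similarity-weighted average of the
## K nearest homologs' PWMs,
##
##   PWM_x(i, j) = sum_p w_p PWM_p(i, j) / sum_p w_p,   p = 1..K,
##
## with w_p the global-alignment identity between the query and homolog p.
## K is chosen by cross-validation against probe intensities when binding
## data exist, or fixed (default 7) for novel proteins.

.new_knn_model <- function(query_id, K, neighbors, pwm, fixed_k = FALSE,
                           cv_table = NULL, opt_k = NULL) {
  structure(list(query_id = query_id, K = K,
                 neighbor_ids = neighbors$rbp_id,
                 neighbor_weights = neighbors$similarity,
                 pwm = pwm, fixed_k = fixed_k,
                 cv_table = cv_table, opt_k = opt_k),
            class = "knn_model")
}

## Weighted average of the top-K neighbor PWMs given a precomputed ranking.
.weighted_pwm <- function(neighbors, homolog_pwms, K, query_id) {
  top <- neighbors[seq_len(K), , drop = FALSE]
  w <- top$similarity
  sw <- sum(w)
  if (sw <= 0)
    stop_degenerate("all top-K similarity weights are zero")
  wn <- w / sw
  mats <- homolog_pwms[top$rbp_id]
  acc <- wn[1] * unclass(mats[[1]])
  if (K > 1) for (p in 2:K) acc <- acc + wn[p] * unclass(mats[[p]])
  pwm(acc, scale = pwm_scale(mats[[1]]),
      motif_id = paste0(query_id, "_knn"),
      tol = 1e-6)
}

.homolog_pwm_table <- function(homologs) {
  ids <- vapply(homologs, `[[`, "", "rbp_id")
  pwms <- lapply(homologs, `[[`, "pwm")
  widths <- vapply(pwms, pwm_width, 0L)
  scales <- vapply(pwms, pwm_scale, "")
  if (length(unique(widths)) != 1)
    stop_input("homolog PWMs must share a common width")
  if (length(unique(scales)) != 1)
    stop_input("homolog PWMs must share a common scale")
  names(pwms) <- ids
  pwms
}

#' Infer a query RBP's PWM from its K nearest homologs
#'
#' Ranks the homologs by global-alignment identity to the query and returns
#' the cell-by-cell similarity-weighted average of the top K homolog PWMs.
#' Raw identities in [0, 1] are used as weights, with no kernel or exponent.
#' The output scale equals the input scale, and probability-scale columns
#' still sum to 1 (the average is convex).
#'
#' @param query an [rbp_record()] (its own PWM, if any, is ignored).
#' @param homologs list of `rbp_record`s with attached PWMs of common width
#'   and scale, not containing the query.
#' @param K number of neighbors, `1 <= K <= length(homologs)`.
#' @return an object of class `knn_model`; `coef()` extracts the inferred
#'   PWM matrix and `$pwm` the full [pwm()].
#' @seealso [rbp_knn()] for the formula-free fitting front end,
#'   [select_opt_k()], [infer_novel()].
#' @export
knn_infer_pwm <- function(query, homologs, K) {
  K <- .check_count(K, "K")
  if (K > length(homologs))
    stop_input(sprintf("K = %d exceeds the homolog pool size %d", K,
                       length(homologs)))
  neighbors <- rank_neighbors(query, homologs)
  pwms <- .homolog_pwm_table(homologs)
  out_pwm <- .weighted_pwm(neighbors, pwms, K, query$rbp_id)
  .new_knn_model(query$rbp_id, K, neighbors[seq_len(K), , drop = FALSE],
                 out_pwm)
}

#' Select the number of neighbors by cross-validation
#'
#' For each candidate K, infers the PWM from the homologs, scores the
#' held-out probe fold with the arcsinh-gated scan, computes the Pearson
#' correlation (PCC) against the measured intensities, and averages over
#' folds. `optK` is the K with the highest mean PCC; ties go to the
#' smallest K. Fold assignment is a seeded uniform split of the probes.
#'
#' @inheritParams knn_infer_pwm
#' @param probes a [probe_set()] with intensities.
#' @param k_grid candidate K values (default `1:min(30, length(homologs))`).
#' @param folds number of CV folds (default 2).
#' @param seed seed for the fold split.
#' @return list with `opt_k` and `cv_table` (data.frame of K, per-fold PCC,
#'   mean PCC).
#' @export
select_opt_k <- function(query, homologs, probes, k_grid = NULL, folds = 2,
                         seed = 1) {
  if (!inherits(probes, "probe_set") || is.null(probes$intensities))
    stop_input("'probes' must be a probe_set with intensities")
  folds <- .check_count(folds, "folds", min = 2)
  n <- length(probes)
  if (n < folds) stop_input("fewer probes than folds")
  if (is.null(k_grid)) k_grid <- seq_len(min(30L, length(homologs)))
  k_grid <- sort(unique(vapply(k_grid, .check_count, 0L, name = "k_grid")))
  if (length(k_grid) == 0) stop_input("'k_grid' must be non-empty")
  if (max(k_grid) > length(homologs))
    stop_input("k_grid values must not exceed the homolog pool size")

  neighbors <- rank_neighbors(query, homologs)
  pwms <- .homolog_pwm_table(homologs)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  fold_pcc <- matrix(NA_real_, length(k_grid), folds)
  for (ki in seq_along(k_grid)) {
    pw <- .weighted_pwm(neighbors, pwms, k_grid[ki], query$rbp_id)
    y <- score_probeset(pw, probes, convert = TRUE)
    for (f in seq_len(folds)) {
      held <- fold_of == f
      yo <- y[held]
      io <- probes$intensities[held]
      if (sd(yo) > 0 && sd(io) > 0) fold_pcc[ki, f] <- cor(yo, io)
    }
  }
  mean_pcc <- rowMeans(fold_pcc)
  if (all(is.na(mean_pcc)))
    stop_degenerate("every candidate K gave degenerate (constant) scores")
  best <- which.max(ifelse(is.na(mean_pcc), -Inf, mean_pcc))
  cv <- data.frame(K = k_grid, fold_pcc, mean_pcc = mean_pcc)
  names(cv)[1 + seq_len(folds)] <- paste0("pcc_fold", seq_len(folds))
  list(opt_k = k_grid[best], cv_table = cv)
}

#' Infer a PWM for a novel RBP with a fixed K
#'
#' The data-free path for proteins with no binding data: K is fixed (default
#' 7, an empirical average of cross-validated optK values) and clipped to
#' the homolog pool size.
#'
#' @inheritParams knn_infer_pwm
#' @param fixed_K the fixed neighbor count (default 7).
#' @return a `knn_model` with `fixed_k = TRUE`.
#' @export
infer_novel <- function(query, homologs, fixed_K = 7) {
  fixed_K <- .check_count(fixed_K, "fixed_K")
  if (length(homologs) == 0) stop_input("empty homolog list")
  m <- knn_infer_pwm(query, homologs, K = min(fixed_K, length(homologs)))
  m$fixed_k <- TRUE
  m
}

#' Fit the homology-weighted KNN motif model
#'
#' Front end tying the pieces together. With `K` given, fits directly; with
#' `probes` given (and `K = NULL`), selects optK by cross-validation on the
#' probe intensities, then fits; with neither, falls back to the fixed-K
#' path for novel proteins ([infer_novel()]).
#'
#' @inheritParams select_opt_k
#' @param K number of neighbors, or `NULL` to choose from data.
#' @param fixed_K fixed K used when no probes are supplied (default 7).
#' @return an object of class `knn_model` with components `query_id`, `K`,
#'   `neighbor_ids`, `neighbor_weights`, `pwm`, `fixed_k`, `opt_k`,
#'   `cv_table`. Methods: [print()], [summary()], [coef()] (PWM matrix),
#'   [predict()] (scan scores for new sequences), [plot()] (per-position
#'   base probabilities).
#' @examples
#' fam <- generate_family(synth_config(n_proteins = 8, seed = 1))
#' fit <- rbp_knn(fam[[1]], fam[-1], K = 3)
#' fit
#' head(predict(fit, c("ACGUACGUACGU", "UUUUUUUUUUUU")))
#' @export
rbp_knn <- function(query, homologs, probes = NULL, K = NULL, k_grid = NULL,
                    folds = 2, fixed_K = 7, seed = 1) {
  if (!is.null(K)) return(knn_infer_pwm(query, homologs, K))
  if (!is.null(probes)) {
    sel <- select_opt_k(query, homologs, probes, k_grid = k_grid,
                        folds = folds, seed = seed)
    m <- knn_infer_pwm(query, homologs, sel$opt_k)
    m$opt_k <- sel$opt_k
    m$cv_table <- sel$cv_table
    return(m)
  }
  infer_novel(query, homologs, fixed_K = fixed_K)
}

#' @export
print.knn_model <- function(x, ...) {
  how <- if (x$fixed_k) "fixed" else if (!is.null(x$cv_table))
    "cross-validated" else "user-specified"
  cat(sprintf("Homology-weighted KNN motif model for '%s'\n", x$query_id))
  cat(sprintf("  K = %d (%s); motif width %d, scale %s\n", x$K, how,
              pwm_width(x$pwm), pwm_scale(x$pwm)))
  cat("  nearest neighbors:\n")
  nb <- data.frame(rbp_id = x$neighbor_ids,
                   similarity = round(x$neighbor_weights, 4))
  print(head(nb, 10), row.names = FALSE)
  if (x$K > 10) cat(sprintf("  ... and %d more\n", x$K - 10))
  invisible(x)
}

#' @export
#' @method summary knn_model
summary.knn_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_table)) {
    cat("\nCross-validation over K:\n")
    print(object$cv_table, row.names = FALSE, digits = 4)
  }
  cat("\nInferred PWM:\n")
  print(object$pwm)
  invisible(object)
}

#' @export
#' @method coef knn_model
coef.knn_model <- function(object, ...) {
  unclass(object$pwm)[, , drop = FALSE]
}

#' Predict scan scores for new RNA sequences
#'
#' Scores sequences with the inferred PWM via the arcsinh-gated windowed
#' scan (probability-scale PWMs are converted to background-ratio first).
#'
#' @param object a `knn_model`.
#' @param newdata a [probe_set()] or character vector of RNA sequences.
#' @param ... ignored.
#' @return numeric vector of scan scores.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  score_probeset(object$pwm, newdata, convert = TRUE)
}

#' Plot the inferred motif
#'
#' Stacked per-position base probabilities of the inferred PWM (base
#' graphics).
#'
#' @param x a `knn_model`.
#' @param ... passed to [graphics::barplot()].
#' @method plot knn_model
#' @export
plot.knn_model <- function(x, ...) {
  p <- unclass(pwm_convert_scale(x$pwm, "probability"))
  graphics::barplot(p, names.arg = seq_len(ncol(p)), legend.text = RNA_BASES,
                    xlab = "position", ylab = "probability",
                    main = sprintf("Inferred motif for %s (K = %d)",
                                   x$query_id, x$K), ...)
  invisible(x)
}
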