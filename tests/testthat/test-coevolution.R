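test_that("pwm_similarity is 1 for identical PWMs and symmetric", {
  set.seed(1)
  a <- random_pwm(7); b <- random_pwm(7)
  expect_equal(pwm_similarity(a, a), 1, tolerance = 1e-12)
  expect_identical(pwm_similarity(a, b), pwm_similarity(b, a))
  expect_error(pwm_similarity(a, random_pwm(5)),
               class = "rbpknn_input_error")
  flat <- pwm(matrix(0.25, 4, 7), "probability")
  expect_error(pwm_similarity(flat, a), class = "rbpknn_degenerate_error")
})

test_that("complementing a skewed motif pushes similarity below 0.5", {
  w <- matrix(0.03, 4, 7)
  w[1, ] <- 0.90  # strongly A-dominated
  w[2, ] <- 0.05
  w[4, ] <- 0.02
  a <- pwm(w, "probability")
  b <- pwm(w[c(4, 3, 2, 1), ], "probability")  # A<->U, C<->G swap
  expect_lt(pwm_similarity(a, b), 0.5)
})

test_that("mirror_tree_pcc reproduces hand-rolled Pearson over triangles", {
  set.seed(2)
  n <- 30
  mk_sim <- function() {
    m <- matrix(runif(n * n, 0.2, 0.9), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    similarity_matrix(m, sprintf("p%02d", 1:n))
  }
  a <- mk_sim(); b <- mk_sim()
  got <- mirror_tree_pcc(a, b)
  ua <- unclass(a)[upper.tri(a)]
  ub <- unclass(b)[upper.tri(b)]
  mr <- function(v) v - mean(v)
  hand <- sum(mr(ua) * mr(ub)) / sqrt(sum(mr(ua)^2) * sum(mr(ub)^2))
  expect_equal(got$pcc, hand, tolerance = 1e-12)
  expect_identical(got$n_pairs, as.integer(n * (n - 1) / 2))
  expect_lt(abs(got$pcc), 0.3)  # independent matrices
})

test_that("identical and anti-ordered matrices give PCC +1 / -1", {
  set.seed(3)
  n <- 6
  v <- runif(n * (n - 1) / 2, 0.2, 0.8)
  m1 <- diag(1, n); m1[upper.tri(m1)] <- v
  m1[lower.tri(m1)] <- t(m1)[lower.tri(m1)]
  m2 <- diag(1, n); m2[upper.tri(m2)] <- 1 - v
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  labs <- letters[1:n]
  s1 <- similarity_matrix(m1, labs); s2 <- similarity_matrix(m2, labs)
  expect_equal(mirror_tree_pcc(s1, s1)$pcc, 1, tolerance = 1e-12)
  expect_equal(mirror_tree_pcc(s1, s2)$pcc, -1, tolerance = 1e-12)
  expect_error(mirror_tree_pcc(s1, similarity_matrix(m2, rev(labs))),
               class = "rbpknn_input_error")
})

test_that("strong co-evolution is detected by the permutation test", {
  fam <- generate_family(synth_config(n_proteins = 20, coevo_strength = 1,
                                      seed = 11))
  res <- coevolution_test(fam, n_perm = 500, seed = 11)
  expect_lte(res$p_permutation, 0.01)
  expect_gt(res$pcc, 0.3)
  expect_identical(res$n_pairs, 190L)
})

test_that("the add-one permutation p-value has the stated form", {
  fam <- generate_family(synth_config(n_proteins = 12, coevo_strength = 1,
                                      seed = 13))
  psim <- build_similarity_matrix(fam)
  pwms <- lapply(fam, `[[`, "pwm")
  p1 <- permutation_test(psim, pwms, n_perm = 1, seed = 5)
  # strongly co-evolved observed value exceeds the single permuted one
  expect_identical(as.numeric(p1), 0.5)
  p <- permutation_test(psim, pwms, n_perm = 200, seed = 5)
  expect_identical(as.numeric(p),
                   (1 + sum(attr(p, "perm_pccs") >= attr(p, "pcc"))) / 201)
})

test_that("permutation p is invariant under joint relabeling", {
  fam <- generate_family(synth_config(n_proteins = 10, seed = 17))
  psim <- build_similarity_matrix(fam)
  pwms <- lapply(fam, `[[`, "pwm")
  p_a <- permutation_test(psim, pwms, n_perm = 100, seed = 3)
  o <- c(4, 1, 9, 7, 2, 10, 3, 5, 8, 6)
  psim2 <- similarity_matrix(unclass(psim)[o, o], rownames(psim)[o])
  p_b <- permutation_test(psim2, pwms[o], n_perm = 100, seed = 3)
  expect_equal(as.numeric(p_a), as.numeric(p_b), tolerance = 1e-12)
})

test_that("permuted statistics center on the null expectation", {
  fam <- generate_family(synth_config(n_proteins = 15, coevo_strength = 0,
                                      seed = 19))
  psim <- build_similarity_matrix(fam)
  p <- permutation_test(psim, lapply(fam, `[[`, "pwm"), n_perm = 2000,
                        seed = 7)
  perms <- attr(p, "perm_pccs")
  # CLT bound: mean of permuted PCCs ~ 0 within a few standard errors
  expect_lt(abs(mean(perms)), 4 * sd(perms) / sqrt(length(perms)))
})

test_that("parametric test follows the one-sided t distribution", {
  expect_equal(as.numeric(parametric_test(0, 10)), 0.5, tolerance = 1e-12)
  t99 <- 0.99 * sqrt((28 - 2) / (1 - 0.99^2))
  expect_equal(as.numeric(parametric_test(0.99, 28)),
               pt(t99, 26, lower.tail = FALSE), tolerance = 1e-15)
  expect_lt(parametric_test(0.99, 28), 1e-6)
  ps <- vapply(seq(-0.9, 0.9, by = 0.2),
               function(r) as.numeric(parametric_test(r, 20)), 0)
  expect_true(all(diff(ps) < 0))
  p1 <- parametric_test(1, 10)
  expect_identical(as.numeric(p1), 0)
  expect_true(attr(p1, "degenerate"))
  expect_identical(as.numeric(parametric_test(-1, 10)), 1)
  expect_error(parametric_test(1.2, 10), class = "rbpknn_input_error")
})

test_that("coevolution_test assembles a complete result object", {
  fam <- generate_family(synth_config(n_proteins = 8, seed = 23))
  res <- coevolution_test(fam, n_perm = 50, seed = 9)
  expect_s3_class(res, "coevolution_test")
  expect_true(res$p_permutation >= 0 && res$p_permutation <= 1)
  expect_true(res$p_parametric >= 0 && res$p_parametric <= 1)
  expect_identical(res$n_permutations, 50L)
  expect_identical(res$n_pairs, 28L)
  expect_output(print(res), "Mirror-tree")
  no_pwm <- lapply(fam, function(r) { r$pwm <- NULL; r })
  expect_error(coevolution_test(no_pwm), class = "rbpknn_input_error")
})
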