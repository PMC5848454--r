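# homologs with controlled sequences/PWMs
mk_homolog <- function(id, seq, w, scale = "probability")
  rbp_record(id, seq, pwm = pwm(w, scale = scale, motif_id = id))

test_that("K = 1 returns the nearest neighbor's PWM bit-exactly", {
  set.seed(1)
  fam <- tiny_family(n = 6, seed = 2)
  fit <- knn_infer_pwm(fam[[1]], fam[-1], K = 1)
  nearest <- Filter(function(r) r$rbp_id == fit$neighbor_ids[1], fam[-1])[[1]]
  expect_identical(c(unclass(fit$pwm)), c(unclass(nearest$pwm)))
})

test_that("equal weights average PWMs cell by cell", {
  q <- rbp_record("q", "MKVLAGHWYR")
  wa <- matrix(0.25, 4, 7); wa[, 1] <- c(1, 0, 0, 0)
  wb <- matrix(0.25, 4, 7); wb[, 1] <- c(0, 1, 0, 0)
  hom <- list(mk_homolog("h1", "MKVLAGHWYR", wa),
              mk_homolog("h2", "MKVLAGHWYR", wb))
  fit <- knn_infer_pwm(q, hom, K = 2)
  expect_equal(unname(unclass(fit$pwm)[, 1]), c(0.5, 0.5, 0, 0),
               tolerance = 1e-15)
})

test_that("weighted averaging matches the cell-by-cell oracle", {
  set.seed(3)
  for (rep in 1:20) {
    fam <- tiny_family(n = 7, seed = 100 + rep)
    K <- sample(2:6, 1)
    fit <- knn_infer_pwm(fam[[1]], fam[-1], K = K)
    mats <- lapply(fit$neighbor_ids, function(id)
      unclass(Filter(function(r) r$rbp_id == id, fam)[[1]]$pwm))
    expect_equal(mat(fit$pwm),
                 oracle_weighted_avg(fit$neighbor_weights, mats),
                 tolerance = 1e-12)
  }
})

test_that("inferred cells are convex combinations and scale is conserved", {
  set.seed(4)
  fam <- tiny_family(n = 10, seed = 5)
  fit <- knn_infer_pwm(fam[[1]], fam[-1], K = 5)
  mats <- lapply(fit$neighbor_ids, function(id)
    unclass(Filter(function(r) r$rbp_id == id, fam)[[1]]$pwm))
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  expect_true(all(unclass(fit$pwm) >= lo - 1e-12))
  expect_true(all(unclass(fit$pwm) <= hi + 1e-12))
  expect_equal(colSums(unclass(fit$pwm)), rep(1, 7), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("homolog list order does not change the inference", {
  fam <- tiny_family(n = 9, seed = 6)
  fit1 <- knn_infer_pwm(fam[[1]], fam[-1], K = 4)
  fit2 <- knn_infer_pwm(fam[[1]], rev(fam[-1]), K = 4)
  expect_identical(unclass(fit1$pwm), unclass(fit2$pwm))
  expect_identical(fit1$neighbor_ids, fit2$neighbor_ids)
})

test_that("averaging noisy homolog PWMs denoises as K grows", {
  # homolog PWMs are noisy copies of one truth; mean |error| of the
  # inferred PWM should fall from K = 1 toward the full pool
  n_hom <- 8
  errs <- matrix(0, 20, n_hom)
  set.seed(7)
  for (s in 1:20) {
    truth <- unclass(random_pwm(7))
    q <- rbp_record("q", random_aa(60))
    hom <- lapply(1:n_hom, function(i) {
      noisy <- truth + matrix(runif(28, 0, 0.4), 4, 7)
      noisy <- sweep(noisy, 2, colSums(noisy), "/")
      mk_homolog(sprintf("h%02d", i), random_aa(60), noisy)
    })
    for (K in 1:n_hom) {
      fit <- knn_infer_pwm(q, hom, K = K)
      errs[s, K] <- mean(abs(unclass(fit$pwm) - truth))
    }
  }
  avg <- colMeans(errs)
  expect_gt(avg[1], avg[n_hom])
  expect_lt(cor(avg, 1:n_hom, method = "spearman"), -0.8)
})

test_that("K bounds and degenerate weights are rejected", {
  fam <- tiny_family(n = 5, seed = 8)
  expect_error(knn_infer_pwm(fam[[1]], fam[-1], K = 5),
               class = "rbpknn_input_error")
  expect_error(knn_infer_pwm(fam[[1]], fam[-1], K = 0),
               class = "rbpknn_input_error")
})

test_that("select_opt_k with a single candidate returns it", {
  fam <- tiny_family(n = 6, seed = 9, probe_count = 60)
  probes <- generate_probes(fam[[2]]$pwm,
                            synth_config(probe_count = 60, seed = 9))
  sel <- select_opt_k(fam[[1]], fam[-1], probes, k_grid = 3)
  expect_identical(sel$opt_k, 3L)
  expect_identical(nrow(sel$cv_table), 1L)
})

test_that("select_opt_k is deterministic given a seed and validates input", {
  fam <- tiny_family(n = 6, seed = 10)
  probes <- generate_probes(fam[[1]]$pwm,
                            synth_config(probe_count = 80, seed = 10))
  s1 <- select_opt_k(fam[[1]], fam[-1], probes, seed = 42)
  s2 <- select_opt_k(fam[[1]], fam[-1], probes, seed = 42)
  expect_identical(s1, s2)
  labs_only <- probe_set(probes$sequences, labels = probes$labels)
  expect_error(select_opt_k(fam[[1]], fam[-1], labs_only),
               class = "rbpknn_input_error")
  two <- probes[1:2]
  expect_error(select_opt_k(fam[[1]], fam[-1], two, folds = 3),
               class = "rbpknn_input_error")
})

test_that("infer_novel fixes K and clips it to the pool", {
  fam <- tiny_family(n = 11, seed = 11)
  fit <- infer_novel(fam[[1]], fam[-1])
  expect_identical(fit$K, 7L)
  expect_true(fit$fixed_k)
  fit4 <- infer_novel(fam[[1]], fam[2:5])
  expect_identical(fit4$K, 4L)
  expect_error(infer_novel(fam[[1]], list()), class = "rbpknn_input_error")
})

test_that("rbp_knn dispatches between fixed, CV, and novel paths", {
  fam <- tiny_family(n = 8, seed = 12)
  probes <- generate_probes(fam[[1]]$pwm,
                            synth_config(probe_count = 80, seed = 12))
  direct <- rbp_knn(fam[[1]], fam[-1], K = 2)
  expect_identical(direct$K, 2L)
  cvfit <- rbp_knn(fam[[1]], fam[-1], probes = probes, seed = 1)
  expect_false(is.null(cvfit$cv_table))
  expect_identical(cvfit$K, cvfit$opt_k)
  novel <- rbp_knn(fam[[1]], fam[-1])
  expect_true(novel$fixed_k)
})

test_that("knn_model methods work", {
  fam <- tiny_family(n = 8, seed = 13)
  fit <- rbp_knn(fam[[1]], fam[-1], K = 3)
  expect_output(print(fit), "K = 3")
  expect_output(summary(fit), "Inferred PWM")
  expect_identical(dim(coef(fit)), c(4L, 7L))
  y <- predict(fit, c("ACGUACGUACGUACGU", "UUUUUUUUUUUUUUUU"))
  expect_length(y, 2)
  expect_true(all(y >= 0))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
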