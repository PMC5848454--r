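test_that("pfm_to_pwm applies add-pseudocount column normalization", {
  counts <- matrix(1, 4, 7)
  counts[, 3] <- c(10, 0, 0, 0)
  p <- pfm_to_pwm(pfm(counts), pseudocount = 1)
  expect_equal(unclass(p)[, 3], c(A = 11, C = 1, G = 1, U = 1) / 14)
  expect_equal(colSums(unclass(p)), rep(1, 7), tolerance = 1e-12)
})

test_that("uniform counts give all-ones background-ratio entries", {
  p <- pfm_to_pwm(pfm(matrix(1, 4, 7)), scale = "background_ratio")
  expect_equal(mat(p), matrix(1, 4, 7))
})

test_that("width trimming keeps the max-information window", {
  # 9 columns: flat flanks, 7-column peaked core
  core <- matrix(0.5, 4, 7)
  core[1, ] <- 20
  counts <- cbind(rep(3, 4), core, rep(3, 4))
  # brute-force oracle over the 3 candidate windows on the normalized matrix
  m <- counts + 1
  pr <- sweep(m, 2, colSums(m), "/")
  ic <- apply(pr, 2, function(col) sum(col * log2(col / 0.25)))
  wins <- vapply(1:3, function(j) sum(ic[j:(j + 6)]), 0)
  expect_identical(which.max(wins), 2L)
  p <- pfm_to_pwm(pfm(counts), target_width = 7)
  expect_equal(mat(p), unname(pr[, 2:8]), tolerance = 1e-12)
})

test_that("window choice is invariant to uniform count scaling", {
  set.seed(11)
  for (rep in 1:10) {
    counts <- matrix(runif(4 * 10, 0, 30), 4, 10)
    a <- pfm_to_pwm(pfm(counts), pseudocount = 0)
    b <- pfm_to_pwm(pfm(counts * 7.3), pseudocount = 0)
    expect_equal(unclass(a), unclass(b), tolerance = 1e-9)
  }
})

test_that("narrow PFMs are padded with uniform columns, extra on the right", {
  counts <- matrix(c(8, 1, 1, 1), 4, 6)
  p <- pfm_to_pwm(pfm(counts), target_width = 7, pseudocount = 0)
  expect_equal(unclass(p)[, 7], c(A = 0.25, C = 0.25, G = 0.25, U = 0.25))
  expect_false(any(unclass(p)[, 1] == 0.25))
  p5 <- pfm_to_pwm(pfm(counts[, 1:5]), target_width = 7, pseudocount = 0)
  expect_equal(unname(unclass(p5)[, c(1, 7)]), matrix(0.25, 4, 2))
})

test_that("all-zero column without pseudocount is a normalization error", {
  counts <- matrix(1, 4, 7); counts[, 2] <- 0
  expect_error(pfm_to_pwm(pfm(counts), pseudocount = 0),
               class = "rbpknn_degenerate_error")
  expect_silent(pfm_to_pwm(pfm(counts), pseudocount = 0.5))
})

test_that("pfm_to_pwm output satisfies the scale invariant for random PFMs", {
  set.seed(21)
  for (rep in 1:25) {
    x <- random_pfm(sample(3:12, 1))
    pp <- pfm_to_pwm(x, scale = "probability")
    pb <- pfm_to_pwm(x, scale = "background_ratio")
    expect_true(all(abs(colSums(unclass(pp)) - 1) < 1e-9))
    expect_true(all(abs(colMeans(unclass(pb)) - 1) < 1e-9))
    expect_true(all(unclass(pp) > 0))
  }
})

test_that("PWM text round-trips within 1e-6", {
  set.seed(31)
  x <- random_pwm(7)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwm_text(x, f)
  y <- read_pwm_text(f)
  expect_equal(unclass(y), unclass(x), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PWM text parsing rejects malformed files, accepts row probabilities", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG", "1\t0.5\t0.3\t0.2"), f)
  expect_error(read_pwm_text(f), class = "rbpknn_format_error")
  writeLines(c("Pos\tA\tC\tG\tU", "1\t0.7\t0.1\t0.1\t0.1"), f)
  expect_equal(unname(unclass(read_pwm_text(f))[, 1]), c(0.7, 0.1, 0.1, 0.1))
  writeLines(c("Pos\tA\tC\tG\tU", "1\t-0.1\t0.5\t0.3\t0.3"), f)
  expect_error(read_pwm_text(f), class = "rbpknn_format_error")
})

test_that("MEME minimal format round-trips and validates", {
  set.seed(41)
  pwms <- list(random_pwm(7, id = "m1"), random_pwm(7, id = "m2"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, f)
  back <- read_meme(f)
  expect_length(back, 2)
  expect_identical(vapply(back, motif_id, ""), c("m1", "m2"))
  expect_identical(vapply(back, pwm_width, 0L), c(7L, 7L))
  for (i in 1:2)
    expect_equal(unclass(back[[i]]), unclass(pwms[[i]]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  # missing alphabet
  writeLines(c("MEME version 4", "MOTIF x",
               "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25"), f)
  expect_error(read_meme(f), class = "rbpknn_format_error")
  # empty motif block
  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF x",
               "letter-probability matrix: alength= 4 w= 7"), f)
  expect_error(read_meme(f), class = "rbpknn_format_error")
  # DNA alphabet accepted (T treated as U)
  writeLines(c("MEME version 4", "ALPHABET= ACGT", "MOTIF y",
               "letter-probability matrix: alength= 4 w= 2",
               "0.7 0.1 0.1 0.1", "0.1 0.1 0.1 0.7"), f)
  y <- read_meme(f)[[1]]
  expect_equal(as.numeric(unclass(y)["U", 2]), 0.7)
})

test_that("filter_records matches both tags and preserves order", {
  recs <- list(rbp_record("a", "MKV", family = "RRM", construct = "FL"),
               rbp_record("b", "MKV", family = "KH", construct = "FL"),
               rbp_record("c", "MKV", family = "RRM", construct = "RBR"),
               rbp_record("d", "MKV", family = "RRM", construct = "FL"))
  got <- filter_records(recs, family = "RRM", construct = "FL")
  expect_identical(vapply(got, `[[`, "", "rbp_id"), c("a", "d"))
  expect_identical(filter_records(list(), "RRM", "FL"), list())
  expect_identical(filter_records(recs, family = "other"), list())
})

test_that("rbp_record validates the amino-acid alphabet", {
  expect_error(rbp_record("x", ""), class = "rbpknn_input_error")
  expect_error(rbp_record("x", "MKB2"), class = "rbpknn_input_error")
  r <- rbp_record("x", "mkvx")
  expect_identical(r$aa_sequence, "MKVX")
})

test_that("protein FASTA round-trips through records", {
  recs <- list(rbp_record("p1", "MKVLA"), rbp_record("p2", "MRVLG"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_rbp_fasta(recs, f)
  back <- read_rbp_fasta(f)
  expect_identical(vapply(back, `[[`, "", "rbp_id"), c("p1", "p2"))
  expect_identical(vapply(back, `[[`, "", "aa_sequence"), c("MKVLA", "MRVLG"))
})
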