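# Independent oracles and random-fixture builders. Each oracle is a plain,
# direct re-statement of the quantity under test, kept deliberately separate
# from the package implementation paths.

RNA <- c("A", "C", "G", "U")

# bare matrix of a pwm/pfm (drops class and scale/id attributes)
mat <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

random_rna <- function(len) paste(sample(RNA, len, replace = TRUE),
                                  collapse = "")

random_aa <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# random PWM via column-normalized positive entries
random_pwm <- function(k = 7, scale = "probability", id = "rnd") {
  m <- matrix(runif(4 * k, 0.05, 1), 4, k)
  m <- sweep(m, 2, colSums(m), "/")
  if (scale == "background_ratio") m <- m / 0.25
  pwm(m, scale = scale, motif_id = id)
}

random_pfm <- function(L = 7) pfm(matrix(runif(4 * L, 0, 20), 4, L))

# brute-force scan: explicit double loop over windows and positions
oracle_scan <- function(w, s) {
  chars <- strsplit(s, "")[[1]]
  chars[chars == "T"] <- "U"
  k <- ncol(w)
  L <- length(chars)
  total <- 0
  for (t in 0:(L - k)) {
    a <- 1
    for (l in 1:k) {
      ch <- chars[t + l]
      if (ch == "N") { a <- NA; break }
      a <- a * w[match(ch, RNA), l]
    }
    if (!is.na(a) && a > 1) total <- total + asinh(a)
  }
  unname(total / L)
}

# cell-by-cell weighted average, sum(w * p) / sum(w)
oracle_weighted_avg <- function(weights, mats) {
  out <- matrix(0, 4, ncol(mats[[1]]))
  for (i in 1:4) for (j in seq_len(ncol(out))) {
    num <- 0
    for (p in seq_along(mats)) num <- num + weights[p] * mats[[p]][i, j]
    out[i, j] <- num / sum(weights)
  }
  out
}

# all-pairs concordance AUC with ties counted 0.5
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# plain R Gotoh global aligner (affine gaps), written independently of the
# compiled path; returns identical columns / alignment length
oracle_nw_identity <- function(a, b, sub, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) { X[i + 1, 1] <- -(open + i * ext); tX[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { Y[1, j + 1] <- -(open + j * ext); tY[1, j + 1] <- 2L }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub[av[i], bv[j]]
    cand <- c(M[i, j], X[i, j], Y[i, j])
    tM[i + 1, j + 1] <- which.max(cand) - 1L
    M[i + 1, j + 1] <- max(cand) + s
    xo <- M[i, j + 1] - (open + ext); xe <- X[i, j + 1] - ext
    if (xo >= xe) { X[i + 1, j + 1] <- xo; tX[i + 1, j + 1] <- 0L }
    else          { X[i + 1, j + 1] <- xe; tX[i + 1, j + 1] <- 1L }
    yo <- M[i + 1, j] - (open + ext); ye <- Y[i + 1, j] - ext
    if (yo >= ye) { Y[i + 1, j + 1] <- yo; tY[i + 1, j + 1] <- 0L }
    else          { Y[i + 1, j + 1] <- ye; tY[i + 1, j + 1] <- 2L }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  layer <- which.max(fin) - 1L
  i <- n; j <- m; matches <- 0; len <- 0
  while (i > 0 || j > 0) {
    len <- len + 1
    if (layer == 0L) {
      from <- tM[i + 1, j + 1]
      if (av[i] == bv[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1; layer <- from
    } else if (layer == 1L) {
      from <- tX[i + 1, j + 1]; i <- i - 1; layer <- from
    } else {
      from <- tY[i + 1, j + 1]; j <- j - 1; layer <- from
    }
  }
  matches / len
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# small co-evolved family shortcut
tiny_family <- function(n = 8, seed = 1, coevo = 0.8, ...) {
  generate_family(synth_config(n_proteins = n, coevo_strength = coevo,
                               seed = seed, ...))
}
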