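## PWM -> k-mer score table for the logistic sequence model.
##
## The logistic model scores a k-mer m as F_seq(m) = 1 / (1 + exp(-b - phi_m))
## with one parameter phi_m per k-mer (4^k of them) plus a bias b. Here phi
## is not learned: it is derived from a PWM by multiplying the entries
## matching each base of m, then frozen, leaving only b (and, in the full
## structure-aware model, the non-sequence parameters) free to train.

#' All k-mers in lexicographic order (A < C < G < U)
#' @param k k-mer length.
#' @return character vector of 4^k k-mers.
#' @export
all_kmers <- function(k) {
  k <- .check_count(k, "k")
  g <- expand.grid(rep(list(1:4), k))
  do.call(paste0, lapply(k:1, function(j) RNA_BASES[g[[j]]]))
}

.new_kmer_table <- function(k, phi, b, frozen, source_scale = NA_character_) {
  structure(list(k = as.integer(k), phi = phi, b = as.numeric(b),
                 frozen = isTRUE(frozen), source_scale = source_scale),
            class = "kmer_score_table")
}

#' Convert a PWM into a frozen k-mer score table
#'
#' Scores every possible k-mer m by the product of the PWM entries matching
#' its bases, phi_m = prod_l PWM(index(m_l), l), and returns the 4^k-entry
#' table with `frozen = TRUE` and bias `b = 0`. The products are taken on
#' the PWM's own scale, verbatim; for a probability-scale PWM the phi values
#' form a product probability measure and sum to 1.
#'
#' @param x a [pwm()] with width at most 10 (the table has 4^k entries).
#' @return an object of class `kmer_score_table` with fields `k`, `phi`
#'   (named numeric, lexicographic k-mer order), `b`, `frozen`.
#' @export
pwm_to_phi <- function(x) {
  stopifnot(inherits(x, "pwm"))
  k <- pwm_width(x)
  if (k > 10)
    stop_input(sprintf("width %d exceeds the 4^k table size guard (k <= 10)",
                       k))
  w <- unclass(x)
  g <- expand.grid(rep(list(1:4), k))
  v <- rep(1, 4^k)
  for (l in seq_len(k)) v <- v * w[g[[k - l + 1]], l]
  names(v) <- do.call(paste0, lapply(k:1, function(j) RNA_BASES[g[[j]]]))
  .new_kmer_table(k, v, b = 0, frozen = TRUE, source_scale = pwm_scale(x))
}

#' @export
print.kmer_score_table <- function(x, ...) {
  cat(sprintf("k-mer score table: k = %d (%d entries), b = %g, %s\n",
              x$k, length(x$phi), x$b,
              if (x$frozen) "phi frozen" else "phi free"))
  print(head(round(x$phi, 6)))
  invisible(x)
}

#' Logistic sequence preference of a k-mer
#'
#' `F_seq(m) = (1 + exp(-b - phi_m))^-1`, the probability that k-mer m is
#' bound under the logistic sequence model.
#'
#' @param table a [pwm_to_phi()] table.
#' @param kmer RNA string of length `table$k` (no N).
#' @return probability in (0, 1).
#' @export
f_seq <- function(table, kmer) {
  stopifnot(inherits(table, "kmer_score_table"))
  kmer <- chartr("tT", "uU", toupper(kmer))
  if (nchar(kmer) != table$k)
    stop_input(sprintf("k-mer length %d != table k %d", nchar(kmer), table$k))
  j <- match(kmer, names(table$phi))
  if (is.na(j)) stop_input(sprintf("unknown k-mer '%s'", kmer))
  plogis(table$b + table$phi[[j]])
}

#' Check the frozen-phi training contract
#'
#' Given snapshots of the table taken before and after an external training
#' step, returns TRUE iff every phi entry is bit-identical while the bias b
#' is free to differ — the contract a structure-aware trainer must honor
#' when phi is supplied by a PWM instead of being learned.
#'
#' @param before,after two `kmer_score_table` snapshots of the same table.
#' @return logical.
#' @export
freeze_contract_check <- function(before, after) {
  stopifnot(inherits(before, "kmer_score_table"),
            inherits(after, "kmer_score_table"))
  if (before$k != after$k) stop_input("snapshots have different k")
  identical(before$phi, after$phi)
}

#' Read/write a k-mer score table as TSV
#'
#' One header comment line carrying k, b and the frozen flag, a column
#' header, then one `(kmer, phi)` row per k-mer.
#'
#' @param path file path.
#' @return `read_kmer_table`: a `kmer_score_table`.
#' @export
read_kmer_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^#[[:space:]]*k=([0-9]+)[[:space:]]+b=([-0-9.eE+]+)[[:space:]]+frozen=([A-Za-z]+)",
    hdr))[[1]]
  if (length(m) != 4) stop_format("missing '# k=.. b=.. frozen=..' header")
  d <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  if (!all(c("kmer", "phi") %in% names(d)))
    stop_format("expected columns 'kmer' and 'phi'")
  k <- as.integer(m[2])
  if (nrow(d) != 4^k) stop_format(sprintf("expected %d rows, found %d",
                                          4^k, nrow(d)))
  phi <- d$phi
  names(phi) <- d$kmer
  phi <- phi[order(names(phi), method = "radix")]
  .new_kmer_table(k, phi, b = as.numeric(m[3]),
                  frozen = identical(toupper(m[4]), "TRUE"))
}

#' @rdname read_kmer_table
#' @param table a `kmer_score_table`.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d b=%s frozen=%s", table$k,
                     sprintf("%.10g", table$b),
                     table$frozen), con)
  writeLines("kmer\tphi", con)
  writeLines(paste(names(table$phi),
                   sprintf("%.10g", table$phi),
                   sep = "\t"), con)
  invisible(path)
}
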