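## PWM scan scoring: windowed products through an arcsinh gate.
##
## A sequence s of length |s| is scanned with a width-k PWM; each window's
## score is the product of the PWM entries matching its bases, gated by
## f(a) = arcsinh(a) for a > 1 and 0 otherwise, and the gated scores are
## summed and divided by |s|. The gate makes the probability scale useless
## (products of k probabilities never exceed 1), so scoring demands the
## background-ratio scale, where entries above 1 mark enriched bases.

#' RNA probe set
#'
#' RNA sequences with continuous binding intensities and/or binary
#' bound/unbound labels. At least one of `intensities`/`labels` must be
#' present. Sequences use the alphabet A, C, G, U (T is read as U; N is
#' allowed and excludes the windows covering it from scoring).
#'
#' @param sequences character vector of RNA sequences.
#' @param intensities optional numeric vector, same length.
#' @param labels optional 0/1 vector, same length.
#' @return an object of class `probe_set`.
#' @export
probe_set <- function(sequences, intensities = NULL, labels = NULL) {
  sequences <- toupper(chartr("tT", "uU", as.character(sequences)))
  if (is.null(intensities) && is.null(labels))
    stop_input("provide at least one of 'intensities' or 'labels'")
  n <- length(sequences)
  if (!is.null(intensities)) {
    if (!is.numeric(intensities) || length(intensities) != n)
      stop_input("'intensities' must be numeric and match 'sequences'")
  }
  if (!is.null(labels)) {
    if (length(labels) != n || !all(labels %in% c(0, 1)))
      stop_input("'labels' must be 0/1 and match 'sequences'")
    labels <- as.integer(labels)
  }
  bad <- grepl("[^ACGUN]", sequences)
  if (any(bad))
    stop_input(sprintf("probe %d contains invalid RNA characters",
                       which(bad)[1]))
  structure(list(sequences = sequences, intensities = intensities,
                 labels = labels), class = "probe_set")
}

#' @export
length.probe_set <- function(x) length(x$sequences)

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("Probe set: %d sequences (lengths %d-%d)%s%s\n",
              length(x),
              min(nchar(x$sequences)), max(nchar(x$sequences)),
              if (is.null(x$intensities)) "" else ", with intensities",
              if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' Subset a probe set
#' @param x a [probe_set()].
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.probe_set` <- function(x, i, ...) {
  structure(list(sequences = x$sequences[i],
                 intensities = x$intensities[i],
                 labels = x$labels[i]), class = "probe_set")
}

#' Score a single k-mer with a PWM
#'
#' The k-mer score is the product over positions of the PWM entry matching
#' each base.
#'
#' @param x a [pwm()].
#' @param kmer RNA string of length `pwm_width(x)`, no N.
#' @return the product score.
#' @export
score_kmer <- function(x, kmer) {
  stopifnot(inherits(x, "pwm"))
  idx <- seq_to_index(kmer)
  k <- pwm_width(x)
  if (length(idx) != k)
    stop_input(sprintf("k-mer length %d != PWM width %d", length(idx), k))
  if (anyNA(idx)) stop_input("k-mer must not contain N")
  prod(unclass(x)[cbind(idx, seq_len(k))])
}

## Core scan over an index vector; returns the y score.
.scan_index <- function(w, idx) {
  L <- length(idx)
  k <- ncol(w)
  nwin <- L - k + 1
  p <- w[idx[seq_len(nwin)], 1]
  if (k > 1) for (l in 2:k) p <- p * w[idx[l:(nwin + l - 1)], l]
  keep <- !is.na(p) & p > 1
  sum(asinh(p[keep])) / L
}

#' Scan score of an RNA sequence under a PWM
#'
#' Slides the PWM across every window of the sequence, takes each window's
#' product score, passes it through the gate `f(a) = arcsinh(a)` for
#' `a > 1` (0 otherwise), sums, and divides by the sequence length. Windows
#' containing N score 0. The PWM must be on the background-ratio scale: on
#' the probability scale every window product is at most 1 and the gate
#' zeroes the score identically; pass `convert = TRUE` to rescale
#' automatically.
#'
#' @param x a [pwm()] on the background-ratio scale.
#' @param s RNA string with `nchar(s) >= pwm_width(x)`.
#' @param convert if TRUE, a probability-scale PWM is converted to
#'   background-ratio before scanning.
#' @return the nonnegative scan score y.
#' @export
score_sequence <- function(x, s, convert = FALSE) {
  stopifnot(inherits(x, "pwm"))
  if (pwm_scale(x) != "background_ratio") {
    if (convert) x <- pwm_convert_scale(x, "background_ratio")
    else stop_input(paste("score_sequence requires a background-ratio PWM;",
                          "probability-scale products never exceed the gate.",
                          "Use pwm_convert_scale() or convert = TRUE"))
  }
  idx <- seq_to_index(s)
  if (length(idx) < pwm_width(x))
    stop_input(sprintf("sequence length %d < PWM width %d",
                       length(idx), pwm_width(x)))
  .scan_index(unclass(x), idx)
}

#' Scan scores for a whole probe set
#'
#' Vectorized [score_sequence()] over the probes, order preserved.
#' Equal-length probes are scored in a single vectorized pass.
#'
#' @param x a [pwm()] (background-ratio scale, or `convert = TRUE`).
#' @param probes a [probe_set()] or character vector of RNA sequences.
#' @inheritParams score_sequence
#' @return numeric vector of y scores, one per probe.
#' @export
score_probeset <- function(x, probes, convert = FALSE) {
  stopifnot(inherits(x, "pwm"))
  if (pwm_scale(x) != "background_ratio") {
    if (convert) x <- pwm_convert_scale(x, "background_ratio")
    else stop_input("score_probeset requires a background-ratio PWM (or convert = TRUE)")
  }
  seqs <- if (inherits(probes, "probe_set")) probes$sequences
          else toupper(chartr("tT", "uU", as.character(probes)))
  n <- length(seqs)
  if (n == 0) return(numeric(0))
  w <- unclass(x)
  k <- ncol(w)
  lens <- nchar(seqs)
  if (any(lens < k))
    stop_input(sprintf("probe %d is shorter than the PWM width %d",
                       which(lens < k)[1], k))
  out <- numeric(n)
  for (L in unique(lens)) {
    at <- which(lens == L)
    chars <- matrix(match(
      unlist(strsplit(seqs[at], "", fixed = TRUE), use.names = FALSE),
      RNA_BASES), nrow = length(at), ncol = L, byrow = TRUE)
    ## N -> NA; anything else was rejected by probe_set/seq_to_index upstream,
    ## but guard here for raw character input
    if (any(is.na(chars))) {
      raw <- matrix(unlist(strsplit(seqs[at], "", fixed = TRUE)),
                    nrow = length(at), byrow = TRUE)
      if (any(is.na(chars) & raw != "N"))
        stop_input("probe sequences contain invalid RNA characters")
    }
    acc <- numeric(length(at))
    for (t in 0:(L - k)) {
      p <- w[chars[, t + 1], 1]
      if (k > 1) for (l in 2:k) p <- p * w[chars[, t + l], l]
      keep <- !is.na(p) & p > 1
      acc[keep] <- acc[keep] + asinh(p[keep])
    }
    out[at] <- acc / L
  }
  out
}
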