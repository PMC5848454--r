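## Protein sequence similarity: global-alignment percent identity used both
## as the KNN weight and as the protein side of the mirror-tree statistic.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

.aa_to_index <- function(s, alphabet) {
  idx <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx))
    stop_input("sequence contains characters outside the BLOSUM62 alphabet")
  idx
}

#' Global-alignment percent identity between two protein sequences
#'
#' Aligns the sequences globally (Needleman-Wunsch with affine gaps, Gotoh
#' algorithm; BLOSUM62, gap open 10, gap extend 0.5 — ClustalW-like
#' defaults) and returns identical aligned positions divided by the full
#' alignment length, gap columns included. The result is symmetric and in
#' [0, 1]: argument order is canonicalized before aligning so that
#' tie-broken tracebacks cannot break symmetry.
#'
#' @param seq_a,seq_b amino-acid strings (non-empty).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_input("sequences must be non-empty")
  sub <- .blosum62()
  if (seq_b < seq_a) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  a <- .aa_to_index(seq_a, rownames(sub))
  b <- .aa_to_index(seq_b, rownames(sub))
  nw_identity_cpp(a, b, sub, gap_open, gap_extend)
}

#' Global alignment details (score, matches, alignment length)
#'
#' Lower-level companion of [pairwise_identity()], exposing the alignment
#' score and counts. Not symmetric under tie-broken tracebacks; prefer
#' [pairwise_identity()] for similarity values.
#'
#' @inheritParams pairwise_identity
#' @return list with `score`, `matches`, `length`, `identity`.
#' @export
align_global <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_input("sequences must be non-empty")
  sub <- .blosum62()
  nw_align_cpp(.aa_to_index(seq_a, rownames(sub)),
               .aa_to_index(seq_b, rownames(sub)),
               sub, gap_open, gap_extend)
}

#' Similarity matrix container
#'
#' Symmetric pairwise similarity over labeled items, unit diagonal, entries
#' in [0, 1].
#'
#' @param values n x n numeric matrix.
#' @param labels item identifiers (length n, unique).
#' @return an object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop_input("similarity matrix must be square")
  if (length(labels) != n) stop_input("'labels' length must match dimension")
  if (anyDuplicated(labels)) stop_input("labels must be unique")
  if (anyNA(values)) stop_input("similarity entries must be non-missing")
  if (max(abs(values - t(values))) > 1e-12)
    stop_input("similarity matrix must be symmetric (tol 1e-12)")
  if (any(abs(diag(values) - 1) > 1e-12))
    stop_input("similarity matrix diagonal must be 1")
  if (any(values < 0) || any(values > 1))
    stop_input("similarity entries must lie in [0, 1]")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("similarity_matrix", "matrix"))
}

#' @export
print.similarity_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Similarity matrix over %d items\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

sim_labels <- function(x) rownames(x)

#' Pairwise protein similarity matrix over RBP records
#'
#' Entry (i, j) is [pairwise_identity()] between records i and j; the
#' diagonal is 1.
#'
#' @param records list of at least two [rbp_record()]s with unique ids.
#' @inheritParams pairwise_identity
#' @return a [similarity_matrix()] labeled by `rbp_id`.
#' @export
build_similarity_matrix <- function(records, gap_open = 10, gap_extend = 0.5) {
  n <- length(records)
  if (n < 2) stop_input("need at least 2 records")
  ids <- vapply(records, `[[`, "", "rbp_id")
  if (anyDuplicated(ids)) stop_input("duplicate rbp_id in records")
  seqs <- vapply(records, `[[`, "", "aa_sequence")
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[i], seqs[j],
                                              gap_open, gap_extend)
    }
  }
  similarity_matrix(m, ids)
}

#' Rank homologs by similarity to a query
#'
#' Computes the similarity of each homolog to the query and sorts in
#' descending order; ties are broken by ascending `rbp_id` for determinism.
#' Every homolog must carry a PWM (they are about to be averaged).
#'
#' @param query an [rbp_record()].
#' @param homologs list of `rbp_record`s with attached PWMs, excluding the
#'   query itself.
#' @return data.frame with columns `rbp_id`, `similarity`, in rank order.
#' @export
rank_neighbors <- function(query, homologs) {
  if (length(homologs) == 0) stop_input("empty homolog list")
  ids <- vapply(homologs, `[[`, "", "rbp_id")
  if (query$rbp_id %in% ids)
    stop_input("query must be excluded from the homolog list")
  has_pwm <- vapply(homologs, function(h) inherits(h$pwm, "pwm"), TRUE)
  if (!all(has_pwm))
    stop_input(sprintf("homolog(s) without an attached PWM: %s",
                       paste(ids[!has_pwm], collapse = ", ")))
  sims <- vapply(homologs, function(h)
    pairwise_identity(query$aa_sequence, h$aa_sequence), 0)
  o <- order(-sims, ids)
  data.frame(rbp_id = ids[o], similarity = sims[o],
             stringsAsFactors = FALSE)
}

#' Read/write a labeled similarity matrix as TSV
#'
#' Square tab-separated matrix with labels as both the header row and the
#' first column, so externally computed similarities (e.g. from a multiple
#' alignment tool) can be injected in place of the internal aligner.
#'
#' @param path file path.
#' @return `read_similarity_tsv`: a [similarity_matrix()].
#' @export
read_similarity_tsv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  d <- read.delim(path, row.names = 1, check.names = FALSE)
  if (nrow(d) != ncol(d)) stop_format("similarity TSV must be square")
  if (!identical(rownames(d), colnames(d)))
    stop_format("row and column labels must match")
  similarity_matrix(as.matrix(d), rownames(d))
}

#' @rdname read_similarity_tsv
#' @param x a [similarity_matrix()].
#' @export
write_similarity_tsv <- function(x, path) {
  write.table(unclass(x), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}
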