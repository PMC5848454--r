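## Motif containers and I/O: position frequency matrices (PFMs), position
## weight matrices (PWMs), RBP records, and readers/writers for tabular
## PWM text and MEME minimal motif format.

#' Position frequency matrix
#'
#' A 4 x L matrix of nonnegative per-position base counts or frequencies,
#' rows fixed to A, C, G, U.
#'
#' @param counts numeric 4 x L matrix (L >= 1), all entries >= 0.
#' @param source_id identifier of the experiment/motif the counts came from.
#' @return an object of class `pfm`.
#' @export
pfm <- function(counts, source_id = "") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop_input("a PFM must have exactly 4 rows (A,C,G,U)")
  if (ncol(counts) < 1) stop_input("a PFM must have at least 1 column")
  if (anyNA(counts) || !is.numeric(counts))
    stop_input("PFM entries must be numeric and non-missing")
  if (any(counts < 0)) stop_input("PFM entries must be >= 0")
  rownames(counts) <- RNA_BASES
  colnames(counts) <- NULL
  structure(counts, source_id = as.character(source_id),
            class = c("pfm", "matrix"))
}

#' Position weight matrix
#'
#' A 4 x k matrix of per-position base weights with an explicit scale:
#' `"probability"` columns sum to 1; `"background_ratio"` entries are
#' probability / 0.25, so each column's mean is 1 and informative entries
#' exceed 1. The scan score ([score_sequence()]) requires the
#' background-ratio scale because its gate discards window products <= 1.
#'
#' @param weights numeric 4 x k matrix, rows A, C, G, U.
#' @param scale `"probability"` or `"background_ratio"`.
#' @param motif_id motif identifier.
#' @param tol tolerance for the column-sum (or column-mean) check.
#' @return an object of class `pwm`.
#' @seealso [pfm_to_pwm()], [pwm_convert_scale()]
#' @export
pwm <- function(weights, scale = c("probability", "background_ratio"),
                motif_id = "", tol = 1e-6) {
  scale <- match.arg(scale)
  weights <- as.matrix(weights)
  if (nrow(weights) != 4) stop_input("a PWM must have exactly 4 rows (A,C,G,U)")
  if (ncol(weights) < 1) stop_input("a PWM must have width >= 1")
  if (anyNA(weights) || !is.numeric(weights) || any(!is.finite(weights)))
    stop_input("PWM entries must be finite numbers")
  if (any(weights < 0)) stop_input("PWM entries must be >= 0")
  chk <- if (scale == "probability") colSums(weights) else colMeans(weights)
  if (any(abs(chk - 1) > tol))
    stop_input(sprintf(
      "PWM columns violate the '%s' scale (max deviation %.3g)",
      scale, max(abs(chk - 1))))
  rownames(weights) <- RNA_BASES
  colnames(weights) <- NULL
  structure(weights, scale = scale, motif_id = as.character(motif_id),
            class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, digits = 4, ...) {
  cat(sprintf("PWM '%s': width %d, scale %s\n", motif_id(x), pwm_width(x),
              pwm_scale(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' PWM accessors
#' @param x a `pwm`.
#' @return width (integer), scale (character), or motif id (character).
#' @export
pwm_width <- function(x) ncol(x)

#' @rdname pwm_width
#' @export
pwm_scale <- function(x) attr(x, "scale")

#' @rdname pwm_width
#' @export
motif_id <- function(x) attr(x, "motif_id") %||% attr(x, "source_id") %||% ""

#' Convert a PWM between probability and background-ratio scales
#'
#' Background-ratio entries are probabilities divided by the uniform
#' background 0.25.
#'
#' @param x a `pwm`.
#' @param scale target scale.
#' @return a `pwm` on the requested scale.
#' @export
pwm_convert_scale <- function(x, scale = c("probability", "background_ratio")) {
  scale <- match.arg(scale)
  if (pwm_scale(x) == scale) return(x)
  w <- if (scale == "background_ratio") unclass(x) / 0.25 else unclass(x) * 0.25
  pwm(w, scale = scale, motif_id = motif_id(x))
}

## Per-column information content (bits) against the uniform background.
.column_ic <- function(p) {
  apply(p, 2, function(col) {
    nz <- col > 0
    sum(col[nz] * log2(col[nz] / 0.25))
  })
}

#' Convert a PFM to a fixed-width PWM
#'
#' Adds a pseudocount, normalizes columns to probabilities, and harmonizes
#' the width: if the PFM is wider than `target_width`, the contiguous window
#' with maximal total information content is retained (ties broken leftmost);
#' if narrower, uniform columns are padded symmetrically (the extra column on
#' the right when the deficit is odd).
#'
#' @param x a [pfm()].
#' @param target_width desired motif width (default 7).
#' @param pseudocount nonnegative value added to every count before
#'   normalization (default 1).
#' @param scale output scale, see [pwm()].
#' @return a `pwm` of width `target_width`.
#' @export
pfm_to_pwm <- function(x, target_width = 7, pseudocount = 1,
                       scale = c("probability", "background_ratio")) {
  scale <- match.arg(scale)
  if (!inherits(x, "pfm")) x <- pfm(x)
  target_width <- .check_count(target_width, "target_width")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop_input("'pseudocount' must be a nonnegative number")
  m <- unclass(x) + pseudocount
  cs <- colSums(m)
  if (any(cs == 0))
    stop_degenerate("cannot normalize: all-zero column with pseudocount 0")
  p <- sweep(m, 2, cs, "/")
  L <- ncol(p)
  if (L > target_width) {
    ic <- .column_ic(p)
    win_ic <- vapply(seq_len(L - target_width + 1),
                     function(j) sum(ic[j:(j + target_width - 1)]), 0)
    j <- which.max(win_ic)  # ties -> leftmost
    p <- p[, j:(j + target_width - 1), drop = FALSE]
  } else if (L < target_width) {
    extra <- target_width - L
    left <- extra %/% 2
    right <- extra - left
    u <- matrix(0.25, 4, 1)
    p <- cbind(u[, rep(1, left), drop = FALSE], p,
               u[, rep(1, right), drop = FALSE])
  }
  if (scale == "background_ratio") p <- p / 0.25
  pwm(p, scale = scale, motif_id = attr(x, "source_id") %||% "")
}

#' Read and write PWMs as tab-separated text
#'
#' The format is one header row `Pos A C G U` followed by one row per motif
#' position (1-based position index, then the four base weights).
#'
#' @param path file path.
#' @param scale scale to stamp on the parsed PWM (the format itself carries
#'   no scale metadata).
#' @param motif_id motif id; defaults to the file name.
#' @return `read_pwm_text`: a `pwm`. `write_pwm_text`: `path`, invisibly.
#' @export
read_pwm_text <- function(path, scale = c("probability", "background_ratio"),
                          motif_id = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop_format("PWM text file has no data rows")
  fields <- strsplit(trimws(lines), "\\s+")
  hdr <- toupper(fields[[1]])
  if (length(hdr) != 5 || hdr[1] != "POS" ||
      !all(hdr[2:4] == c("A", "C", "G")) || !(hdr[5] %in% c("U", "T")))
    stop_format("expected header 'Pos A C G U' with 4 value columns")
  rows <- fields[-1]
  if (any(lengths(rows) != 5))
    stop_format("every PWM row must have a position and 4 values")
  vals <- suppressWarnings(
    t(vapply(rows, function(r) as.numeric(r[2:5]), numeric(4))))
  if (anyNA(vals)) stop_format("non-numeric PWM entry")
  if (any(vals < 0)) stop_format("negative PWM entry")
  pwm(t(vals), scale = scale,
      motif_id = motif_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_pwm_text
#' @param x a `pwm` to write.
#' @export
write_pwm_text <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  w <- unclass(x)
  lines <- c(paste(c("Pos", "A", "C", "G", "U"), collapse = "\t"),
             vapply(seq_len(ncol(w)), function(j)
               paste(c(j, sprintf("%.10g", w[, j])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write MEME minimal motif files
#'
#' Parses/emits the MEME minimal format with an RNA alphabet. On read, a DNA
#' alphabet (`ACGT`) is accepted and T is treated as U. Motif columns are
#' letter probabilities, one row per motif position.
#'
#' @param path file path.
#' @return `read_meme`: a list of `pwm` (probability scale). `write_meme`:
#'   `path`, invisibly.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  alpha <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (length(alpha) == 0)
    stop_format("MEME file is missing the 'ALPHABET=' line")
  ab <- toupper(gsub("\\s", "", sub("^ALPHABET\\s*=", "", alpha[1])))
  if (!ab %in% c("ACGU", "ACGT"))
    stop_format(sprintf("unsupported MEME alphabet '%s'", ab))
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0) stop_format("MEME file contains no MOTIF blocks")
  ends <- c(motif_at[-1] - 1, length(lines))
  pwms <- vector("list", length(motif_at))
  for (i in seq_along(motif_at)) {
    block <- lines[motif_at[i]:ends[i]]
    id <- strsplit(block[1], "\\s+")[[1]][2]
    if (is.na(id)) id <- sprintf("motif_%d", i)
    lp <- grep("^letter-probability matrix", block)
    if (length(lp) == 0)
      stop_format(sprintf("motif '%s': missing letter-probability matrix", id))
    body <- block[-seq_len(lp[1])]
    num <- grepl("^[-+0-9.eE][-+0-9.eE[:space:]]*$", body) & nzchar(body)
    ## matrix rows are the leading run of numeric lines
    run <- cumprod(num) == 1
    rows <- body[run]
    if (length(rows) == 0)
      stop_format(sprintf("motif '%s': empty probability matrix", id))
    vals <- strsplit(rows, "\\s+")
    if (any(lengths(vals) != 4))
      stop_format(sprintf("motif '%s': each row needs 4 probabilities", id))
    mat <- t(vapply(vals, as.numeric, numeric(4)))
    pwms[[i]] <- pwm(t(mat), scale = "probability", motif_id = id)
  }
  pwms
}

#' @rdname read_meme
#' @param pwms a `pwm` or list of `pwm`s; background-ratio PWMs are written
#'   as probabilities.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- c("MEME version 4", "", "ALPHABET= ACGU", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 U 0.25", "")
  for (p in pwms) {
    stopifnot(inherits(p, "pwm"))
    p <- pwm_convert_scale(p, "probability")
    w <- unclass(p)
    out <- c(out,
             sprintf("MOTIF %s", motif_id(p)),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(w)),
             vapply(seq_len(ncol(w)), function(j)
               paste(sprintf("%.10g", w[, j]),
                     collapse = " "), ""),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' An RBP record
#'
#' Bundles one RNA-binding protein: identifier, amino-acid sequence, domain
#' family and construct tags, species, and (optionally) its PWM.
#'
#' @param rbp_id unique identifier.
#' @param aa_sequence amino-acid sequence (20 standard residues plus X).
#' @param family domain family tag, typically `"RRM"`, `"KH"`, or `"other"`.
#' @param construct `"FL"` (full length), `"RBR"` (RNA-binding region), or
#'   `"other"`.
#' @param species species name.
#' @param pwm optional attached [pwm()].
#' @return an object of class `rbp_record`.
#' @export
rbp_record <- function(rbp_id, aa_sequence, family = "other",
                       construct = "other", species = NA_character_,
                       pwm = NULL) {
  aa_sequence <- toupper(as.character(aa_sequence))
  if (length(aa_sequence) != 1 || !nzchar(aa_sequence))
    stop_input("'aa_sequence' must be a non-empty string")
  chars <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop_input(sprintf("invalid amino-acid character(s): %s",
                       paste(bad, collapse = ", ")))
  if (!is.null(pwm) && !inherits(pwm, "pwm"))
    stop_input("'pwm' must be a pwm object or NULL")
  structure(list(rbp_id = as.character(rbp_id),
                 aa_sequence = aa_sequence,
                 family = as.character(family),
                 construct = as.character(construct),
                 species = as.character(species),
                 pwm = pwm),
            class = "rbp_record")
}

#' @export
print.rbp_record <- function(x, ...) {
  cat(sprintf("RBP %s [%s/%s, %s]: %d aa, PWM %s\n", x$rbp_id, x$family,
              x$construct, x$species, nchar(x$aa_sequence),
              if (is.null(x$pwm)) "absent" else "attached"))
  invisible(x)
}

#' Filter RBP records by family and construct
#'
#' Keeps records whose tags match the requested family and construct,
#' preserving input order. A `NULL` filter matches everything, so curated
#' subsets such as "RRM family, full-length constructs only" can be carved
#' out of a mixed library.
#'
#' @param records list of [rbp_record()]s.
#' @param family,construct tags to keep, or `NULL` for no constraint.
#' @return the matching sublist.
#' @export
filter_records <- function(records, family = NULL, construct = NULL) {
  stopifnot(is.list(records))
  keep <- vapply(records, function(r) {
    (is.null(family) || r$family == family) &&
      (is.null(construct) || r$construct == construct)
  }, TRUE)
  records[keep]
}

#' Read protein sequences into RBP records
#'
#' Reads a protein FASTA (via Biostrings) and wraps each sequence in an
#' [rbp_record()]. Record ids are the first whitespace-delimited token of
#' each FASTA header.
#'
#' @param path FASTA file.
#' @inheritParams rbp_record
#' @return list of `rbp_record`.
#' @export
read_rbp_fasta <- function(path, family = "other", construct = "other",
                           species = NA_character_) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop_format("FASTA file contains no sequences")
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  lapply(seq_along(seqs), function(i)
    rbp_record(ids[i], as.character(seqs[[i]]), family = family,
               construct = construct, species = species))
}

#' Write RBP records to FASTA
#' @param records list of [rbp_record()]s.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_rbp_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "aa_sequence"))
  names(seqs) <- vapply(records, `[[`, "", "rbp_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Attach PWMs to records by motif id
#'
#' Matches each record's `rbp_id` against the motif ids of a PWM library and
#' attaches the matching PWM.
#'
#' @param records list of [rbp_record()]s.
#' @param pwms list of [pwm()]s.
#' @param require_all error if a record has no matching motif (default TRUE).
#' @return list of records with `pwm` fields filled.
#' @export
attach_pwms <- function(records, pwms, require_all = TRUE) {
  ids <- vapply(pwms, motif_id, "")
  lapply(records, function(r) {
    j <- match(r$rbp_id, ids)
    if (is.na(j)) {
      if (require_all)
        stop_input(sprintf("no motif found for record '%s'", r$rbp_id))
      return(r)
    }
    r$pwm <- pwms[[j]]
    r
  })
}
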