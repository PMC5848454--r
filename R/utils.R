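## internal helpers: condition classes, seeded evaluation, alphabet maps

RNA_BASES <- c("A", "C", "G", "U")

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

AA20 <- AA_ALPHABET[AA_ALPHABET != "X"]

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_cond <- function(type, msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("rbpknn_", type, "_error"),
                                "rbpknn_error"),
                      call = call))
}

stop_input <- function(msg) .stop_cond("input", msg, sys.call(-1))
stop_format <- function(msg) .stop_cond("format", msg, sys.call(-1))
stop_degenerate <- function(msg) .stop_cond("degenerate", msg, sys.call(-1))

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_input("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## Map an RNA/DNA string to row indices 1..4 (A,C,G,U); T reads as U and
## N becomes NA. Any other character is rejected.
seq_to_index <- function(s) {
  chars <- strsplit(chartr("tT", "uU", toupper(s)), "", fixed = TRUE)[[1]]
  idx <- match(chars, RNA_BASES)
  bad <- is.na(idx) & chars != "N"
  if (any(bad))
    stop_input(sprintf("invalid RNA character(s): %s",
                       paste(unique(chars[bad]), collapse = ", ")))
  idx
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stop_input(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x))
    stop_input(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}
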