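#' Round half away from zero
#'
#' Deterministic rounding used for copy-number state assignment: ties at
#' .5 always round up (base `round()` rounds to even, which would make
#' state calls depend on parity).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Derive a reproducible sub-stream seed
#'
#' Stable 31-bit string hash of `(seed, ...)` so that each (sample, stage)
#' pair gets its own RNG stream: adding or reordering samples never
#' perturbs the draws of another sample.
#'
#' @param seed integer master seed.
#' @param ... further components (sample id, stage name) coerced to
#'   character.
#' @return integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG stream
#'
#' Saves and restores `.Random.seed` so simulator sub-stages do not
#' interfere with the caller's RNG state.
#'
#' @param seed integer passed to `set.seed()`.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' GC fraction of nucleotide sequences
#'
#' @param seq character vector of A/C/G/T sequences.
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  n <- Biostrings::letterFrequency(x, letters = c("G", "C"))
  as.numeric(rowSums(n)) / Biostrings::width(x)
}

# apportion n into integer counts proportional to probs (largest remainder)
largest_remainder <- function(probs, n) {
  raw <- probs / sum(probs) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)
    base[idx[seq_len(rem)]] <- base[idx[seq_len(rem)]] + 1
  }
  base
}

# stopifnot-style check with a formatted message
check_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# intersect [s1,e1) with [s2,e2); returns c(start,end) or NULL
interval_intersect <- function(s1, e1, s2, e2) {
  s <- max(s1, s2)
  e <- min(e1, e2)
  if (s < e) c(s, e) else NULL
}
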