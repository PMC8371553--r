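#' @importFrom data.table data.table := setkey setkeyv rbindlist as.data.table
#'   fwrite fread setorder setorderv copy setnames
#' @importFrom stats plogis qlogis rbinom rpois pchisq phyper runif setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  vapply(x, function(s) {
    ch <- COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]
    paste(rev(unname(ch)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Run `expr` with a deterministic RNG state derived from `seed`, leaving the
# caller's RNG untouched. All stochastic operations in the package go through
# this so that every stage is a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a stage offset, kept within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + as.double(offset)) %% 2147483647)
}

assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop(sprintf("'%s' must be a fraction in %s0,1%s, got %s", name,
                 if (allow_zero) "[" else "(", if (allow_one) "]" else ")",
                 deparse(x)), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
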