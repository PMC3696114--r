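# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Strict alphabet {A,C,G,T,N}; everything else errors upstream at read time.
#'
#' @param x a single DNA string.
#' @return the reverse complement as a single string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# vectorised revcomp over a character vector of sequences
revcomp_all <- function(x) {
  vapply(x, revcomp, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# complement (no reversal) of a base vector
comp_chars <- function(ch) unname(COMP[ch])

#' Round half away from zero
#'
#' The rounding convention used for all reported percentages and table
#' values (unlike [round()], which rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `x` rounded.
#' @export
#' @examples
#' round_half_up(0.125, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# seed scoping: set a per-stream seed, restore the caller's RNG state when the
# calling generator exits. `stream` offsets keep generators independent while
# fanned out from one global seed.
local_seed <- function(seed, stream = 0L, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  withr::local_seed(
    (as.integer(seed) + 7919L * as.integer(stream)) %% .Machine$integer.max,
    .local_envir = envir
  )
  invisible(NULL)
}

# positions (0-based) covered by a possibly origin-wrapping half-open interval
interval_positions <- function(start, end, n) {
  if (end > start) {
    seq.int(start, end - 1L)
  } else {
    c(seq.int(start, n - 1L), if (end > 0L) seq.int(0L, end - 1L))
  }
}

# length of a possibly wrapping half-open interval on a circle of size n
interval_length <- function(start, end, n) {
  if (end > start) end - start else n - start + end
}

# substring of a circular sequence, 0-based half-open with wrap support
circular_substr <- function(x, start, end, n = nchar(x)) {
  if (end > start) {
    substr(x, start + 1L, end)
  } else {
    paste0(substr(x, start + 1L, n), substr(x, 1L, end))
  }
}

# does half-open [s1,e1) (non-wrapping) intersect [s2,e2) (non-wrapping)?
iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# is [s1,e1) wholly inside [s2,e2)? (non-wrapping intervals)
iv_within <- function(s1, e1, s2, e2) s1 >= s2 & e1 <= e2

`%||%` <- function(a, b) if (is.null(a)) b else a
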