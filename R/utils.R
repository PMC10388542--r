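#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl pmap imap keep compact
NULL

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character string (IUPAC ACGTN only)
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_chars <- function(x) chartr("ACGTN", "TGCAN", x)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' G+C content of a sequence, as a percentage
#'
#' Rounded half-up to two decimals at reporting time; the unrounded value is
#' available with `digits = NA`.
#' @param seq DNA string.
#' @param digits decimals to round to (half-up), or `NA` for unrounded.
#' @return numeric percentage.
#' @export
gc_percent <- function(seq, digits = 2) {
  n <- nchar(seq)
  gc <- sum(Biostrings::letterFrequency(Biostrings::DNAString(seq), c("G", "C")))
  pct <- 100 * gc / n
  if (is.na(digits)) pct else round_half_up(pct, digits)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# substring of a circular sequence; start is 0-based, may exceed length
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  start <- start %% n
  if (start + len <= n) {
    substr(seq, start + 1, start + len)
  } else {
    paste0(substr(seq, start + 1, n), circ_substr(seq, 0, start + len - n))
  }
}

# random DNA with an exact G+C base count (hit by construction, not expectation)
rand_dna <- function(n, gc = 38.5) {
  n_gc <- round(gc / 100 * n)
  cls <- sample(c(rep("S", n_gc), rep("W", n - n_gc)))
  s <- sum(cls == "S")
  out <- character(n)
  out[cls == "S"] <- sample(c("G", "C"), s, replace = TRUE)
  out[cls == "W"] <- sample(c("A", "T"), n - s, replace = TRUE)
  chars_seq(out)
}

# deterministic sub-seed for a named substream, kept below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.double(seed) * 7919 + h * 104729) %% (2^31 - 1)
}

is_dna <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) > 0L &&
    !grepl("[^ACGTN]", x)
}

assert_dna <- function(x, what = "sequence") {
  if (!is_dna(x)) {
    abort(paste0(what, " must be a non-empty DNA string over {A,C,G,T,N}"))
  }
  invisible(x)
}
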