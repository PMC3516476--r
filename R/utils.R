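# Internal string / coordinate helpers shared by all detectors.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character strings over the alphabet {A,C,G,T,N}.
#'
#' @param x A single nucleotide string.
#' @return The reverse complement as a character string.
#' @export
#' @examples
#' revcomp("GGTTCA")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## split a string into a character vector of single bases
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

c2s <- function(x) paste0(x, collapse = "")

## complement of a base vector (no reversal)
comp_chars <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

## validate an A/C/G/T/N string, error otherwise
check_dna <- function(x, what = "sequence") {
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nzchar(bad))
    stop(sprintf("invalid character '%s' in %s (alphabet is A,C,G,T,N)", bad, what),
         call. = FALSE)
  invisible(x)
}

## 1-based circular normalization: map any integer position onto [1, len]
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

## circular distance between two positions on a molecule of length len
circ_dist <- function(a, b, len) {
  d <- abs(a - b) %% len
  pmin(d, len - d)
}

## split a possibly wrapping 1-based inclusive interval into linear pieces
## returns a 2-column matrix (start, end), one or two rows
interval_pieces <- function(start, end, len, wraps = FALSE) {
  if (!wraps && start <= end) return(cbind(start = start, end = end))
  rbind(cbind(start = start, end = len), cbind(start = 1L, end = end))
}

## do two (possibly wrapping) intervals on the same molecule overlap?
intervals_overlap <- function(s1, e1, w1, s2, e2, w2, len) {
  a <- interval_pieces(s1, e1, len, w1)
  b <- interval_pieces(s2, e2, len, w2)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      if (a[i, 1L] <= b[j, 2L] && b[j, 1L] <= a[i, 2L]) return(TRUE)
  FALSE
}

## run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Shannon entropy (bits/symbol) of a nucleotide string
seq_entropy <- function(x) {
  ch <- s2c(x)
  p <- table(ch) / length(ch)
  -sum(p * log2(p))
}
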