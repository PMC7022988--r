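DNA_BASES <- c("A", "C", "G", "T")

# complement index: A<->T, C<->G in the fixed base order above
COMP_IDX <- c(4L, 3L, 2L, 1L)

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# DNA string -> integer codes (A=1, C=2, G=3, T=4; anything else NA)
dna_codes <- function(s) {
  lookup <- rep(NA_integer_, 256L)
  lookup[utf8ToInt("A")] <- 1L
  lookup[utf8ToInt("C")] <- 2L
  lookup[utf8ToInt("G")] <- 3L
  lookup[utf8ToInt("T")] <- 4L
  lookup[utf8ToInt("a")] <- 1L
  lookup[utf8ToInt("c")] <- 2L
  lookup[utf8ToInt("g")] <- 3L
  lookup[utf8ToInt("t")] <- 4L
  lookup[utf8ToInt(s)]
}

codes_to_dna <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

# draw a random DNA string of length n with base probabilities p (A,C,G,T)
random_dna <- function(n, p = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L ||
      grepl("[^ACGTacgt]", x)) {
    stop(what, " must be a nonempty A/C/G/T string", call. = FALSE)
  }
}
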