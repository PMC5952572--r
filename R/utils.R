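#' @importFrom stats lm coef optimize rbinom rmultinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Canonicalize RNA sequences to the DNA alphabet
#'
#' Sequencers emit DNA-alphabet reads, so all sequences handled by the
#' package are stored as uppercase DNA (`U -> T`).
#'
#' @param x character vector of nucleotide sequences (DNA or RNA alphabet).
#' @return character vector in uppercase DNA alphabet.
#' @export
rna_to_dna <- function(x) {
  chartr("u", "t", toupper(chartr("U", "T", x)))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Shannon entropy of the mononucleotide composition
#'
#' @param x a single DNA sequence.
#' @return entropy in bits per symbol.
#' @export
shannon_entropy <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  p <- table(strsplit(x, "", fixed = TRUE)[[1L]])
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Length of the longest homopolymer run
#'
#' @param x a single DNA sequence.
#' @return integer run length.
#' @export
longest_homopolymer <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  max(rle(strsplit(x, "", fixed = TRUE)[[1L]])$lengths)
}

#' Length of the longest exact common substring of two sequences
#'
#' Used by the primer-based contaminant matching rule: a read is assigned
#' to an assay when it shares an identical alignment of at least
#' `min_overlap` nucleotides with the assay primer. Equivalent to
#' 100%-identity local alignment for substitution-free blocks.
#'
#' @param a,b single character strings.
#' @return integer: longest common substring length (0 when none).
#' @export
longest_common_substring <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  if (na > nb) { tmp <- a; a <- b; b <- tmp; tmp <- na; na <- nb; nb <- tmp }
  # a is the shorter string; scan its substrings longest-first
  for (len in seq.int(na, 1L)) {
    starts <- seq_len(na - len + 1L)
    subs <- unique(substring(a, starts, starts + len - 1L))
    for (s in subs) {
      if (grepl(s, b, fixed = TRUE)) return(len)
    }
  }
  0L
}

# Deterministic 31-bit seed stream derived from a master seed.
derive_seed <- function(master, i) {
  s <- (as.numeric(master) %% 2147483647) * 1009 + as.numeric(i) * 9973
  as.integer(s %% 2147483629 + 1)
}

# Random DNA strings (uses the current RNG state).
random_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep.int(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1L))
}

# Per-base Phred+33 quality char for an integer score.
phred_char <- function(q) intToUtf8(q + 33L)
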