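#' Normalize a nucleotide string to uppercase RNA
#'
#' Inputs are accepted in DNA or RNA alphabet and converted to uppercase
#' RNA (T becomes U). Any character outside A/C/G/U after conversion is an
#' error: the pipeline operates on unambiguous sequence only.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in uppercase RNA alphabet.
#' @export
normalize_rna <- function(x) {
  if (!is.character(x)) stop("sequence input must be character")
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-ACGU character in sequence(s): ", paste(head(x[bad], 3), collapse = ", "))
  }
  out
}

#' Reverse complement of RNA strings
#'
#' @param x Character vector of RNA sequences (A/C/G/U).
#' @return Character vector of reverse complements, RNA alphabet.
#' @export
rc_rna <- function(x) {
  x <- normalize_rna(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# Random RNA string(s) drawn uniformly over the given alphabet.
# Uses the current RNG state; callers seed.
random_rna <- function(n_chars, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n_chars, replace = TRUE), collapse = "")
}

# All 0-based start positions of `pattern` in `subject`, overlapping allowed.
# Patterns are plain ACGU strings, so a zero-width lookahead is safe.
find_all_0based <- function(subject, pattern) {
  if (nchar(pattern) == 0 || nchar(pattern) > nchar(subject)) return(integer(0))
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}
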