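#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Errors on any character outside
#' A/C/G/U/T.
#'
#' @param x Character scalar, a nucleotide sequence.
#' @return Character scalar over \{A,C,G,U\}.
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "T", toupper(x))
  x <- gsub("[[:space:]]", "", x)
  bad <- regmatches(x, regexpr("[^ACGUT]", x))
  if (length(bad) > 0 && nzchar(bad)) {
    stop("invalid nucleotide character '", bad, "' in sequence", call. = FALSE)
  }
  chartr("T", "U", x)
}

#' Reverse complement of an RNA or DNA sequence
#'
#' @param x Character scalar.
#' @param alphabet Output alphabet, `"RNA"` (default) or `"DNA"`.
#' @return Character scalar, the reverse complement.
#' @export
reverse_complement <- function(x, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  x <- normalize_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  if (alphabet == "DNA") chartr("U", "T", rc) else rc
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Watson-Crick complement of single bases (RNA alphabet)
complement_base <- function(b) {
  unname(c(A = "U", U = "A", G = "C", C = "G", T = "A")[b])
}
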