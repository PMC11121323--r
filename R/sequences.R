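#' @importFrom Biostrings DNAString reverseComplement GENETIC_CODE IUPAC_CODE_MAP
NULL

DNA_BASES <- c("A", "C", "G", "T")

# One-letter -> three-letter amino acid codes (Ter for stop).
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

be_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bescreen_error")))
}

assert_string1 <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    be_stop(sprintf("%s must be a single string", what), "bescreen_domain_error")
  }
}

#' Complement a vector of single bases
#' @noRd
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Reverse complement of a nucleotide sequence
#'
#' Accepts the full 15-letter IUPAC alphabet (degenerate letters are
#' complemented, e.g. R <-> Y). Case-insensitive; the result is uppercase.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("TTGAAGCATTCGGACAAACA")
#' @export
revcomp <- function(seq) {
  assert_string1(seq, "seq")
  s <- toupper(seq)
  if (nchar(s) == 0L) return("")
  if (grepl("[^ACGTRYSWKMBDHVN]", s)) {
    be_stop(sprintf("non-nucleotide character in sequence %s", dQuote(seq)),
            "bescreen_parse_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a single codon with the standard genetic code
#'
#' @param codon A 3-letter ACGT string (case-insensitive).
#' @return One-letter amino acid code ("*" for stop).
#' @examples
#' translate_codon("ATG")
#' @export
translate_codon <- function(codon) {
  assert_string1(codon, "codon")
  s <- toupper(codon)
  if (nchar(s) != 3L || grepl("[^ACGT]", s)) {
    be_stop(sprintf("codon must be 3 bases over ACGT, got %s", dQuote(codon)),
            "bescreen_parse_error")
  }
  unname(Biostrings::GENETIC_CODE[s])
}

#' Three-letter amino acid code
#' @param aa one-letter amino acid code (or "*")
#' @return three-letter code, "Ter" for stop
#' @export
aa_three <- function(aa) {
  out <- AA_THREE[aa]
  if (any(is.na(out))) {
    be_stop(sprintf("unknown amino acid code %s", dQuote(aa[is.na(out)][1])),
            "bescreen_domain_error")
  }
  unname(out)
}

#' Match a sequence against a degenerate IUPAC pattern
#'
#' Position-wise match of a concrete ACGT sequence against an equal-length
#' IUPAC pattern (N = ACGT, R = AG, Y = CT, ...). Case-insensitive. Used for
#' PAM screening.
#'
#' @param pattern IUPAC pattern string.
#' @param seq Concrete ACGT string of the same length.
#' @return `TRUE` iff every base lies in its pattern letter's allowed set.
#' @examples
#' iupac_match("NNGRRT", "TAGAGT")
#' iupac_match("NNNRRT", "TTTAAT")
#' @export
iupac_match <- function(pattern, seq) {
  assert_string1(pattern, "pattern")
  assert_string1(seq, "seq")
  p <- toupper(pattern)
  s <- toupper(seq)
  if (nchar(p) != nchar(s)) {
    be_stop(sprintf("pattern (%d nt) and sequence (%d nt) differ in length",
                    nchar(p), nchar(s)), "bescreen_domain_error")
  }
  if (nchar(p) == 0L) return(TRUE)
  pl <- strsplit(p, "", fixed = TRUE)[[1]]
  sl <- strsplit(s, "", fixed = TRUE)[[1]]
  allowed <- Biostrings::IUPAC_CODE_MAP[pl]
  if (anyNA(allowed)) {
    be_stop(sprintf("invalid IUPAC letter %s in pattern",
                    dQuote(pl[is.na(allowed)][1])), "bescreen_parse_error")
  }
  if (any(!sl %in% DNA_BASES)) {
    be_stop(sprintf("sequence must be concrete ACGT, got %s",
                    dQuote(sl[!sl %in% DNA_BASES][1])), "bescreen_parse_error")
  }
  all(mapply(function(set, base) grepl(base, set, fixed = TRUE), allowed, sl))
}
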