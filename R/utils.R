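# Shared low-level helpers: alphabets, reverse complement, phred codecs,
# seed-scoped RNG. Coordinates everywhere are 0-based, half-open, in the
# reference frame of the relevant locus alignment.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# characters treated as "no call" when comparing aligned columns
MISSING_CHARS <- c("N", "?", "-")

REF_ALPHABET <- c(names(IUPAC_CODES), "-", "?")
READ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalise a vector of sequence strings
#'
#' Upper-cases, maps `?` to `N` (both mean "no call"; `-` is kept as a called
#' deletion) and validates against an alphabet.
#' @param x character vector of sequences.
#' @param alphabet allowed single characters after upper-casing.
#' @param what label used in error messages.
#' @return upper-cased character vector.
#' @keywords internal
normalise_seq <- function(x, alphabet = REF_ALPHABET, what = "sequence") {
  x <- str_to_upper(x)
  bad <- vapply(str_split(x, ""), function(ch) {
    w <- which(!ch %in% alphabet)
    if (length(w)) w[1] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    abort(sprintf(
      "illegal character '%s' at position %d of %s %d",
      substr(x[i], bad[i], bad[i]), bad[i], what, i
    ))
  }
  x
}

#' Reverse complement of DNA strings (IUPAC-aware)
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode / encode phred+33 quality strings
#' @param qual character vector of phred+33 encoded quality strings.
#' @return `phred_decode()`: list of integer vectors; `phred_encode()`: character vector.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' @rdname phred_decode
#' @param scores list of integer phred scores (each in \[0, 93\]).
#' @export
phred_encode <- function(scores) {
  vapply(scores, function(s) {
    stopifnot(all(s >= 0L & s <= 93L))
    rawToChar(as.raw(s + 33L))
  }, character(1))
}

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
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
  force(code)
}

# split sequences of equal length into a character matrix (rows = sequences)
seq_matrix <- function(seqs, ids = names(seqs)) {
  lens <- str_length(seqs)
  if (length(unique(lens)) > 1) {
    abort("sequences must have equal (aligned) length")
  }
  m <- do.call(rbind, str_split(seqs, ""))
  rownames(m) <- ids
  m
}

# round half away from zero to `digits` decimals
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
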