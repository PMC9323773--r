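# Sequence encoding and FASTA helpers.
#
# Internally every sequence is a plain character scalar; alignment code works
# on integer codes indexing the rows of the active substitution matrix.
# Nucleotides use codes A=0, C=1, G=2, T=3, N=4 (N is a wildcard: it aligns as
# a mismatch and never counts towards identity). Amino acids use the row order
# of the BLOSUM62 matrix shipped with Biostrings.

.NT_LETTERS <- c("A", "C", "G", "T", "N")

.aa_matrix_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.aa_matrix_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
    # stop codons terminate open reading: make '*' unalignable so a local
    # alignment can never span a stop in any frame
    mat["*", ] <- -1e6
    mat[, "*"] <- -1e6
    storage.mode(mat) <- "double"
    .aa_matrix_env$mat <- mat
  }
  .aa_matrix_env$mat
}

.aa_letters <- function() rownames(.blosum62())

#' @noRd
encode_dna <- function(x, allow_other = FALSE, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("%s must be a single non-empty nucleotide string", what),
          class = "hervtrace_input_error")
  }
  raw <- charToRaw(toupper(x))
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt("N") + 1L] <- 4L
  codes <- lut[as.integer(raw) + 1L]
  if (anyNA(codes)) {
    if (allow_other) {
      codes[is.na(codes)] <- 4L
    } else {
      bad <- rawToChar(raw[which(is.na(codes))[1L]])
      abort(sprintf("invalid symbol '%s' in %s (alphabet is A/C/G/T/N)", bad, what),
            class = "hervtrace_input_error")
    }
  }
  codes
}

#' @noRd
encode_aa <- function(x, what = "protein") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("%s must be a single non-empty protein string", what),
          class = "hervtrace_input_error")
  }
  letters <- .aa_letters()
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], letters)
  codes[is.na(codes)] <- match("X", letters)
  codes - 1L
}

.nt_submatrix <- function(match_score, mismatch_score) {
  m <- matrix(mismatch_score, 5L, 5L, dimnames = list(.NT_LETTERS, .NT_LETTERS))
  diag(m) <- match_score
  m["N", "N"] <- mismatch_score   # N never scores as a match
  m
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate one frame of a forward-oriented nucleotide string.
# offset in 0:2; returns a character scalar (may contain '*' and 'X').
# Uses a cached codon lookup (the standard genetic code); codons containing
# ambiguity symbols translate to X.
.codon_env <- new.env(parent = emptyenv())

.codon_lookup <- function() {
  if (is.null(.codon_env$lut)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$lut <- setNames(as.character(gc), names(gc))
  }
  .codon_env$lut
}

.translate_frame <- function(x, offset) {
  n <- nchar(x)
  naa <- (n - offset) %/% 3L
  if (naa < 1L) return("")
  sub <- substr(x, offset + 1L, offset + 3L * naa)
  codons <- substring(sub, seq.int(1L, 3L * naa, 3L), seq.int(3L, 3L * naa, 3L))
  aa <- .codon_lookup()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Read sequences from a FASTA file
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] returning named character vectors, the
#' representation the rest of the package works with.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta_dna
#' @export
read_fasta_aa <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
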