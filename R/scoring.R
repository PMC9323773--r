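# Scoring schemes and Karlin-Altschul statistics.

#' Alignment scoring schemes
#'
#' A scoring scheme bundles the substitution scores, affine gap penalties and
#' Karlin-Altschul constants used to turn raw Smith-Waterman scores into bit
#' scores and e-values. A gap of length L costs `gap_open + L * gap_extend`
#' (BLAST convention), so `gap_extend <= gap_open` keeps long gaps no cheaper
#' per column than short ones.
#'
#' `nt_scoring()` is a megablast-like nucleotide scheme (+1/-2, gap open and
#' extend 2.5, lambda 1.28 nats, K 0.46). `protein_scoring()` uses BLOSUM62
#' with the ungapped Karlin-Altschul constants (lambda 0.318 nats, K 0.134);
#' gapped alignment is permitted within one reading frame only.
#'
#' @param match_score,mismatch_score Nucleotide match/mismatch scores
#'   (`match_score > 0 > mismatch_score`).
#' @param gap_open,gap_extend Non-negative gap penalties, BLAST convention.
#' @param lambda Karlin-Altschul lambda in nats per raw-score unit.
#' @param k_const Karlin-Altschul K.
#' @param seed_k Word size for the seed-and-extend heuristic used on inputs
#'   too large for full dynamic programming.
#' @return An object of class `scoring_scheme`.
#' @export
nt_scoring <- function(match_score = 1L, mismatch_score = -2L,
                       gap_open = 2.5, gap_extend = 2.5,
                       lambda = 1.28, k_const = 0.46, seed_k = 12L) {
  stopifnot(match_score > 0, mismatch_score < 0,
            gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open,
            is.finite(lambda), lambda > 0, is.finite(k_const), k_const > 0)
  structure(list(
    alphabet = "nt",
    match_score = match_score, mismatch_score = mismatch_score,
    gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, k_const = k_const,
    protein_matrix_id = NA_character_,
    submat = .nt_submatrix(match_score, mismatch_score),
    wildcard = 4L, alphabet_size = 4L, seed_k = as.integer(seed_k),
    seed_min_score = 24
  ), class = "scoring_scheme")
}

#' @rdname nt_scoring
#' @export
protein_scoring <- function(gap_open = 11, gap_extend = 1,
                            lambda = 0.318, k_const = 0.134, seed_k = 4L) {
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open,
            is.finite(lambda), lambda > 0, is.finite(k_const), k_const > 0)
  mat <- .blosum62()
  structure(list(
    alphabet = "aa",
    match_score = NA_integer_, mismatch_score = NA_integer_,
    gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, k_const = k_const,
    protein_matrix_id = "BLOSUM62",
    submat = mat,
    wildcard = match("X", rownames(mat)) - 1L,
    alphabet_size = 20L,   # seeds drawn from unambiguous residues only
    seed_k = as.integer(seed_k),
    seed_min_score = 45    # below this a heuristic hit is noise, not signal
  ), class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme: %s, gap %g/%g, lambda %g, K %g>\n",
              if (x$alphabet == "nt")
                sprintf("nt %+d/%+d", x$match_score, x$mismatch_score)
              else x$protein_matrix_id,
              x$gap_open, x$gap_extend, x$lambda, x$k_const))
  invisible(x)
}

#' Search parameters for local alignment
#'
#' @param evalue_cutoff Maximum e-value for a reported hit (default `1e-5`,
#'   the cutoff used throughout the discovery pipeline).
#' @param min_raw_score Minimum raw alignment score.
#' @param frames Subset of `c(-3,-2,-1,1,2,3)`; reading frames searched in
#'   translated mode.
#' @return An object of class `search_params`.
#' @export
search_params <- function(evalue_cutoff = 1e-5, min_raw_score = 0,
                          frames = c(1L, 2L, 3L, -1L, -2L, -3L)) {
  stopifnot(evalue_cutoff > 0, all(frames %in% c(-3:-1, 1:3)))
  structure(list(evalue_cutoff = evalue_cutoff,
                 min_raw_score = min_raw_score,
                 frames = as.integer(frames)),
            class = "search_params")
}

# bit = (lambda * S - ln K) / ln 2 ; E = K m n exp(-lambda S)
.bit_score <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$k_const)) / log(2)
}

.e_value <- function(raw, m, n, scoring) {
  scoring$k_const * as.numeric(m) * as.numeric(n) * exp(-scoring$lambda * raw)
}
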