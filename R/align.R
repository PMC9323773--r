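# Pairwise local alignment: full dynamic programming on small inputs,
# seed-and-extend with banded dynamic programming on large ones. Every
# reported hit carries the true affine-gap Smith-Waterman score of its
# alignment path; the heuristic only decides where to look.

.FULL_DP_CELLS <- 2.5e5

# Cluster exact k-mer seeds into candidate alignment regions.
# seeds: 2-column 0-based (q_pos, s_pos) matrix. Returns list of clusters,
# each with s_lo, s_hi, d_lo, d_hi (diagonal range, d = s - q).
.cluster_seeds <- function(seeds, qlen, diag_tol = 64L, gap_tol = NULL) {
  if (nrow(seeds) == 0L) return(list())
  if (is.null(gap_tol)) gap_tol <- max(1000L, qlen)
  d <- seeds[, 2L] - seeds[, 1L]
  ord <- order(d, seeds[, 2L])
  d <- d[ord]; sp <- seeds[ord, 2L]; qp <- seeds[ord, 1L]
  grp <- cumsum(c(1L, diff(d) > diag_tol))
  out <- list()
  for (g in split(seq_along(d), grp)) {
    o2 <- g[order(sp[g])]
    sub <- cumsum(c(1L, diff(sp[o2]) > gap_tol))
    for (h in split(o2, sub)) {
      if (length(h) < 2L) next  # singleton seeds are almost surely noise
      out[[length(out) + 1L]] <- list(
        s_lo = min(sp[h]), s_hi = max(sp[h]),
        d_lo = min(d[h]), d_hi = max(d[h]))
    }
  }
  out
}

# Core multi-hit local aligner on encoded sequences. Returns a list of hits:
# score, q_start, q_end, s_start, s_end, cols, ids, gaps (0-based half-open).
.sw_hits <- function(qc, sc, scoring, band_pad = 75L, k = NULL,
                     full_dp_cells = .FULL_DP_CELLS) {
  m <- length(qc); n <- length(sc)
  if (m == 0L || n == 0L) return(list())
  submat <- scoring$submat
  hits <- list()
  if (as.numeric(m) * n <= full_dp_cells) {
    h <- .cpp_sw_align(qc, sc, submat, scoring$gap_open, scoring$gap_extend,
                       FALSE, 0L, 0L, scoring$wildcard)
    if (h$score > 0) hits <- list(h)
  } else {
    if (is.null(k)) k <- scoring$seed_k
    seeds <- .cpp_find_seeds(qc, sc, k, scoring$alphabet_size)
    min_keep <- scoring$seed_min_score
    align_window <- function(ws, we, d_lo_abs, d_hi_abs, depth) {
      if (we - ws < k || depth > 4L) return(invisible())
      win <- sc[(ws + 1L):we]
      h <- .cpp_sw_align(qc, win, submat, scoring$gap_open, scoring$gap_extend,
                         TRUE, d_lo_abs - ws, d_hi_abs - ws, scoring$wildcard)
      if (h$score <= min_keep) return(invisible())
      h$s_start <- h$s_start + ws
      h$s_end <- h$s_end + ws
      hits[[length(hits) + 1L]] <<- h
      # a stop codon or indel-free break can split one co-linear match into
      # several segments within the same seed cluster: recurse on both sides
      align_window(ws, h$s_start, d_lo_abs, d_hi_abs, depth + 1L)
      align_window(h$s_end, we, d_lo_abs, d_hi_abs, depth + 1L)
      invisible()
    }
    for (cl in .cluster_seeds(seeds, m)) {
      ws <- max(0L, cl$s_lo - m - 50L)
      we <- min(n, cl$s_hi + k + m + 50L)
      align_window(ws, we, cl$d_lo - band_pad, cl$d_hi + band_pad + k, 0L)
    }
    hits <- .dedupe_hits(hits)
  }
  hits
}

# Drop hits whose query and subject footprints both overlap a higher-scoring
# kept hit by more than half of the shorter span.
.dedupe_hits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  ord <- order(-map_dbl(hits, "score"))
  kept <- list()
  for (i in ord) {
    h <- hits[[i]]
    dup <- FALSE
    for (kh in kept) {
      qo <- min(h$q_end, kh$q_end) - max(h$q_start, kh$q_start)
      so <- min(h$s_end, kh$s_end) - max(h$s_start, kh$s_start)
      qmin <- min(h$q_end - h$q_start, kh$q_end - kh$q_start)
      smin <- min(h$s_end - h$s_start, kh$s_end - kh$s_start)
      if (qo > 0.5 * qmin && so > 0.5 * smin) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- h
  }
  kept
}

.EMPTY_HITS <- tibble::tibble(
  query_id = character(), subject_id = character(),
  q_start = integer(), q_end = integer(),
  s_start = integer(), s_end = integer(), strand = character(),
  frame = integer(), aligned_cols = integer(), identities = integer(),
  identity_pct = double(), q_cov_pct = double(), s_cov_pct = double(),
  raw_score = double(), bit_score = double(), e_value = double())

.hit_tibble <- function(hits, query_id, subject_id, strand, qlen, slen,
                        m, n, scoring, frame = NA_integer_) {
  if (length(hits) == 0L) return(.EMPTY_HITS)
  q_start <- vapply(hits, function(h) as.integer(h$q_start), 0L)
  q_end <- vapply(hits, function(h) as.integer(h$q_end), 0L)
  s_start <- vapply(hits, function(h) as.integer(h$s_start), 0L)
  s_end <- vapply(hits, function(h) as.integer(h$s_end), 0L)
  cols <- vapply(hits, function(h) as.integer(h$cols), 0L)
  ids <- vapply(hits, function(h) as.integer(h$ids), 0L)
  raw <- vapply(hits, function(h) h$score, 0.0)
  new_tibble(list(
    query_id = rep_len(query_id, length(hits)),
    subject_id = rep_len(subject_id, length(hits)),
    q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
    strand = rep_len(strand, length(hits)),
    frame = rep_len(as.integer(frame), length(hits)),
    aligned_cols = cols, identities = ids,
    identity_pct = 100 * ids / cols,
    q_cov_pct = 100 * (q_end - q_start) / qlen,
    s_cov_pct = 100 * (s_end - s_start) / slen,
    raw_score = raw,
    bit_score = .bit_score(raw, scoring),
    e_value = .e_value(raw, m, n, scoring)), nrow = length(hits))
}

#' Nucleotide-nucleotide local alignment
#'
#' Searches both strands of `subject` for local alignments to `query` and
#' returns one row per hit, sorted by descending bit score. Small problems are
#' solved by full affine-gap Smith-Waterman dynamic programming; larger ones
#' by exact k-mer seeding followed by banded dynamic programming, so every
#' reported score is the true score of the reported alignment path.
#'
#' Coordinates are 0-based half-open on the forward strand of each sequence;
#' `strand` gives the subject orientation of the hit.
#'
#' @param query,subject Nucleotide strings (alphabet A/C/G/T/N; N aligns as a
#'   mismatch and never counts as an identity).
#' @param scoring A [nt_scoring()] scheme.
#' @param params A [search_params()] object; hits with e-value above
#'   `params$evalue_cutoff` are excluded.
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A tibble of pairwise hits (one row per hit).
#' @export
local_align_nt <- function(query, subject, scoring = nt_scoring(),
                           params = search_params(),
                           query_id = "query", subject_id = "subject") {
  qc <- encode_dna(query, what = "query")
  sc <- encode_dna(subject, what = "subject")
  qlen <- length(qc); slen <- length(sc)
  res <- list()
  for (strand in c("+", "-")) {
    if (strand == "+") {
      codes <- sc
    } else {
      codes <- rev(sc)
      codes <- ifelse(codes == 4L, 4L, 3L - codes)  # reverse complement, N fixed
    }
    hits <- .sw_hits(qc, codes, scoring)
    tb <- .hit_tibble(hits, query_id, subject_id, strand, qlen, slen,
                      m = qlen, n = slen, scoring = scoring)
    if (strand == "-" && nrow(tb) > 0L) {
      tb <- tb %>% mutate(s_start2 = slen - .data$s_end,
                          s_end = slen - .data$s_start,
                          s_start = .data$s_start2) %>%
        select(-"s_start2")
    }
    res[[strand]] <- tb
  }
  bind_rows(res) %>%
    filter(.data$e_value <= params$evalue_cutoff,
           .data$raw_score >= params$min_raw_score) %>%
    select(-"frame") %>%
    arrange(desc(.data$bit_score))
}

#' Protein vs translated-nucleotide local search
#'
#' Translates `subject_nt` in the requested reading frames (stop codons are
#' unalignable, so alignments never cross them) and aligns every reference
#' protein against each frame. Subject coordinates are reported in nucleotide
#' space on the forward strand; the reading frame is recoverable from the
#' `frame` column. Identity and coverage are computed in amino-acid columns.
#'
#' @param subject_nt Nucleotide string to be searched.
#' @param protein_refs Named character vector of reference proteins.
#' @param scoring A [protein_scoring()] scheme.
#' @param params A [search_params()] object (`frames` selects reading frames).
#' @param subject_id Identifier carried into the result.
#' @return A tibble of pairwise hits sorted by descending bit score, with
#'   `s_start`/`s_end` in forward-strand nucleotide coordinates and
#'   `q_start`/`q_end` in amino-acid coordinates on the reference.
#' @export
translated_search <- function(subject_nt, protein_refs,
                              scoring = protein_scoring(),
                              params = search_params(),
                              subject_id = "subject") {
  if (length(protein_refs) == 0L) {
    abort("protein reference panel is empty", class = "hervtrace_input_error")
  }
  if (is.null(names(protein_refs)) || any(!nzchar(names(protein_refs)))) {
    names(protein_refs) <- paste0("ref", seq_along(protein_refs))
  }
  sc_chr <- toupper(subject_nt)
  slen <- nchar(sc_chr)
  if (slen == 0L) abort("empty subject sequence", class = "hervtrace_input_error")
  n_space <- max(1L, slen %/% 3L)
  out <- list()
  rc_chr <- NULL
  for (fr in sort(unique(params$frames))) {
    offset <- abs(fr) - 1L
    if (fr > 0L) {
      aa <- .translate_frame(sc_chr, offset)
    } else {
      if (is.null(rc_chr)) rc_chr <- revcomp(sc_chr)
      aa <- .translate_frame(rc_chr, offset)
    }
    if (nchar(aa) == 0L) next
    fc <- encode_aa(aa, what = "translated frame")
    for (ri in seq_along(protein_refs)) {
      qc <- encode_aa(protein_refs[[ri]], what = names(protein_refs)[ri])
      hits <- .sw_hits(qc, fc, scoring)
      if (length(hits) == 0L) next
      tb <- .hit_tibble(hits, names(protein_refs)[ri], subject_id,
                        if (fr > 0L) "+" else "-",
                        qlen = length(qc), slen = nchar(aa),
                        m = length(qc), n = n_space,
                        scoring = scoring, frame = fr)
      # amino-acid frame coordinates -> forward-strand nucleotide coordinates
      nt_start <- offset + 3L * tb$s_start
      nt_end <- offset + 3L * tb$s_end
      if (fr < 0L) {
        tmp <- slen - nt_end
        nt_end <- slen - nt_start
        nt_start <- tmp
      }
      tb$s_start <- nt_start
      tb$s_end <- nt_end
      out[[length(out) + 1L]] <- tb
    }
  }
  if (length(out) == 0L) {
    return(.hit_tibble(list(), "q", "s", "+", 1, 1, 1, 1, scoring))
  }
  bind_rows(out) %>%
    filter(.data$e_value <= params$evalue_cutoff,
           .data$raw_score >= params$min_raw_score) %>%
    arrange(desc(.data$bit_score))
}
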