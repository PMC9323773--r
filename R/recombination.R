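# Inter-element recombination detection from LTR discordance.
#
# At integration a provirus carries two identical LTRs; afterwards they drift
# apart slowly, so an element's own two LTRs should match each other better
# than anything else in the genome. Recombination between two same-family
# elements swaps sequence between them, leaving each with one LTR that now
# matches the other element's LTR better than its own partner. Calls require
# the reciprocal pattern: both LTRs of one element map to the two distinct
# LTRs of the other, with every cross score strictly exceeding both elements'
# own-pair scores.

#' Extract per-element LTR records
#'
#' One 5' and one 3' record per element, both oriented along the element
#' strand. Elements missing an LTR annotation are skipped with a warning.
#'
#' @param elements Element tibble with `element_id`, `species`, `contig`,
#'   `strand`, `ltr5_start`/`ltr5_end`/`ltr3_start`/`ltr3_end` and a
#'   `classification` (or `class`) column.
#' @param genomes Named list (by species) of named contig vectors.
#' @return Tibble `element_id`, `species`, `classification`, `side`
#'   (`"5p"`/`"3p"`), `sequence`.
#' @export
extract_ltr_records <- function(elements, genomes) {
  cls <- if ("classification" %in% names(elements)) elements$classification
         else elements$class
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    r <- elements[i, ]
    if (anyNA(c(r$ltr5_start, r$ltr5_end, r$ltr3_start, r$ltr3_end))) {
      warn(sprintf("element %s lacks an LTR annotation; skipped", r$element_id))
      next
    }
    contig_seq <- genomes[[r$species]][[r$contig]]
    s5 <- substr(contig_seq, r$ltr5_start + 1L, r$ltr5_end)
    s3 <- substr(contig_seq, r$ltr3_start + 1L, r$ltr3_end)
    if (r$strand == "-") { s5 <- revcomp(s5); s3 <- revcomp(s3) }
    rows[[length(rows) + 1L]] <- tibble(
      element_id = r$element_id, species = r$species,
      classification = cls[i], side = c("5p", "3p"),
      sequence = c(s5, s3))
  }
  bind_rows(rows)
}

#' Pairwise LTR bit-score matrix for one stratum
#'
#' Best-local-hit bit scores between every pair of LTR records of a
#' (species, classification) stratum; self-comparisons are excluded. Both
#' orientations are searched and the better score kept.
#'
#' @param records LTR record tibble from [extract_ltr_records()] (one
#'   stratum).
#' @param scoring A [nt_scoring()] scheme.
#' @return An object of class `ltr_score_matrix`: list with `records` and
#'   the symmetric `bits` matrix.
#' @export
ltr_score_matrix <- function(records, scoring = nt_scoring()) {
  n <- nrow(records)
  codes <- lapply(records$sequence, function(s) encode_dna(s, what = "LTR"))
  rc <- lapply(codes, function(x) {
    y <- rev(x); ifelse(y == 4L, 4L, 3L - y)
  })
  bits <- matrix(0, n, n)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      raw <- max(.cpp_sw_score(codes[[i]], codes[[j]], scoring$submat,
                               scoring$gap_open, scoring$gap_extend,
                               FALSE, 0L, 0L),
                 .cpp_sw_score(codes[[i]], rc[[j]], scoring$submat,
                               scoring$gap_open, scoring$gap_extend,
                               FALSE, 0L, 0L))
      bits[i, j] <- bits[j, i] <- .bit_score(raw, scoring)
    }
  }
  key <- paste(records$element_id, records$side, sep = ":")
  dimnames(bits) <- list(key, key)
  structure(list(records = records, bits = bits,
                 lens = nchar(records$sequence), scoring = scoring),
            class = "ltr_score_matrix")
}

# minimum bit score at which a hit between records i and j is significant
# at the given e-value (Karlin-Altschul search space = product of lengths)
.signif_bit <- function(m, i, j, evalue = 1e-5) {
  sc <- m$scoring
  raw_min <- log(sc$k_const * m$lens[i] * m$lens[j] / evalue) / sc$lambda
  .bit_score(raw_min, sc)
}

.own_pair_score <- function(m, eid) {
  i5 <- which(m$records$element_id == eid & m$records$side == "5p")
  i3 <- which(m$records$element_id == eid & m$records$side == "3p")
  m$bits[i5, i3]
}

#' Flag elements with non-clustered LTR pairs
#'
#' An element is non-clustered when some other element's LTR scores strictly
#' higher against one of its LTRs than its own partner LTR does -- the
#' score-based surrogate for a 5'/3' pair failing to form a cherry on an LTR
#' tree.
#'
#' @param m An [ltr_score_matrix()].
#' @return Tibble `element_id`, `species`, `classification`, `nonclustered`,
#'   `own_pair_bit`, `best_cross_bit`.
#' @export
flag_nonclustered <- function(m) {
  stopifnot(inherits(m, "ltr_score_matrix"))
  rec <- m$records
  eids <- unique(rec$element_id)
  rows <- lapply(eids, function(eid) {
    own <- .own_pair_score(m, eid)
    mine <- which(rec$element_id == eid)
    others <- which(rec$element_id != eid)
    cross <- if (length(others) > 0L) max(m$bits[mine, others]) else -Inf
    tibble(element_id = eid,
           species = rec$species[mine[1L]],
           classification = rec$classification[mine[1L]],
           own_pair_bit = own, best_cross_bit = cross,
           nonclustered = cross > own)
  })
  bind_rows(rows)
}

#' Detect reciprocal LTR-swap recombination
#'
#' Emits a call for an unordered element pair when each LTR of one element
#' scores strictly higher against a distinct LTR of the other element than
#' both elements' own 5'-3' pairs do (ties never flag).
#'
#' @param m An [ltr_score_matrix()].
#' @return Tibble of calls: `element_1`, `element_2`, `matching` (e.g.
#'   `"5p->3p,3p->5p"`), own-pair and cross scores.
#' @export
detect_recombination <- function(m) {
  stopifnot(inherits(m, "ltr_score_matrix"))
  rec <- m$records
  eids <- unique(rec$element_id)
  idx <- function(eid, side) which(rec$element_id == eid & rec$side == side)
  calls <- list()
  for (i in seq_len(max(0L, length(eids) - 1L))) {
    for (j in (i + 1L):length(eids)) {
      e1 <- eids[i]; e2 <- eids[j]
      own1 <- .own_pair_score(m, e1)
      own2 <- .own_pair_score(m, e2)
      a5 <- idx(e1, "5p"); a3 <- idx(e1, "3p")
      b5 <- idx(e2, "5p"); b3 <- idx(e2, "3p")
      # cross matches must beat both own pairs and be significant hits in
      # their own right (the e-value cutoff of every search in the pipeline)
      floor_bit <- max(own1, own2)
      sig_straight <- max(.signif_bit(m, a5, b5), .signif_bit(m, a3, b3))
      sig_crossed <- max(.signif_bit(m, a5, b3), .signif_bit(m, a3, b5))
      m_straight <- min(m$bits[a5, b5], m$bits[a3, b3])
      m_crossed <- min(m$bits[a5, b3], m$bits[a3, b5])
      if (m_straight <= sig_straight) m_straight <- -Inf
      if (m_crossed <= sig_crossed) m_crossed <- -Inf
      best <- max(m_straight, m_crossed)
      if (is.finite(best) && best > floor_bit) {
        straight <- m_straight >= m_crossed
        calls[[length(calls) + 1L]] <- tibble(
          element_1 = e1, element_2 = e2,
          species = rec$species[a5],
          classification = rec$classification[a5],
          matching = if (straight) "5p->5p,3p->3p" else "5p->3p,3p->5p",
          own_pair_bit_1 = own1, own_pair_bit_2 = own2,
          cross_bit_5p = if (straight) m$bits[a5, b5] else m$bits[a5, b3],
          cross_bit_3p = if (straight) m$bits[a3, b3] else m$bits[a3, b5])
      }
    }
  }
  if (length(calls) == 0L) {
    return(tibble(element_1 = character(), element_2 = character(),
                  species = character(), classification = character(),
                  matching = character(), own_pair_bit_1 = double(),
                  own_pair_bit_2 = double(), cross_bit_5p = double(),
                  cross_bit_3p = double()))
  }
  bind_rows(calls)
}

#' Run recombination detection over a cohort
#'
#' Stratifies elements by (species, classification) -- recombination is only
#' meaningful between similar elements within one genome -- builds the LTR
#' score matrix of each stratum with at least two elements, flags
#' non-clustered LTR pairs and emits reciprocal-match calls.
#'
#' @param elements Element tibble (see [extract_ltr_records()]).
#' @param genomes Named list (by species) of named contig vectors.
#' @param scoring A [nt_scoring()] scheme.
#' @return An object of class `herv_recombination`: list with `calls`,
#'   `nonclustered`, and `summary` (involved-element counts by species and
#'   classification).
#' @export
find_recombination <- function(elements, genomes, scoring = nt_scoring()) {
  records <- extract_ltr_records(elements, genomes)
  if (nrow(records) == 0L) {
    abort("no elements with LTR annotations", class = "hervtrace_input_error")
  }
  strata <- records %>%
    group_by(.data$species, .data$classification) %>%
    group_split()
  calls <- list(); flags <- list()
  for (st in strata) {
    if (length(unique(st$element_id)) < 2L) {
      # singletons are trivially clustered
      flags[[length(flags) + 1L]] <- tibble(
        element_id = unique(st$element_id), species = st$species[1L],
        classification = st$classification[1L],
        own_pair_bit = NA_real_, best_cross_bit = NA_real_,
        nonclustered = FALSE)
      next
    }
    m <- ltr_score_matrix(st, scoring)
    flags[[length(flags) + 1L]] <- flag_nonclustered(m)
    calls[[length(calls) + 1L]] <- detect_recombination(m)
  }
  empty_calls <- tibble(element_1 = character(), element_2 = character(),
                        species = character(), classification = character(),
                        matching = character(), own_pair_bit_1 = double(),
                        own_pair_bit_2 = double(), cross_bit_5p = double(),
                        cross_bit_3p = double())
  calls <- bind_rows(c(list(empty_calls), calls))
  nonclustered <- bind_rows(flags)
  structure(list(calls = calls, nonclustered = nonclustered,
                 summary = summarize_recombination(calls, elements)),
            class = "herv_recombination")
}

#' Summarise recombination involvement
#'
#' Counts elements involved in at least one call, by species and
#' classification.
#'
#' @param calls Call tibble from [detect_recombination()].
#' @param elements Element tibble (defines the full species/class grid).
#' @return Tibble `species`, `classification`, `n_elements`.
#' @export
summarize_recombination <- function(calls, elements) {
  cls <- if ("classification" %in% names(elements)) elements$classification
         else elements$class
  grid <- elements %>%
    mutate(classification = cls) %>%
    distinct(.data$species, .data$classification)
  involved <- tibble(element_id = c(calls$element_1, calls$element_2),
                     species = c(calls$species, calls$species),
                     classification = c(calls$classification,
                                        calls$classification)) %>%
    distinct()
  counts <- involved %>% count(.data$species, .data$classification,
                               name = "n_elements")
  grid %>%
    left_join(counts, by = c("species", "classification")) %>%
    mutate(n_elements = ifelse(is.na(.data$n_elements), 0L,
                               .data$n_elements)) %>%
    arrange(.data$species, .data$classification)
}

#' @export
print.herv_recombination <- function(x, ...) {
  cat(sprintf("<herv_recombination: %d call(s), %d/%d elements nonclustered>\n",
              nrow(x$calls), sum(x$nonclustered$nonclustered),
              nrow(x$nonclustered)))
  invisible(x)
}
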