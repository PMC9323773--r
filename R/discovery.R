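# RT-anchored provirus discovery: translated screening, hit merging,
# competitive host/virus filtering, flank extension, LTR boundary detection,
# internal gene annotation, full-length calling and supergroup classification.

#' Discovery pipeline configuration
#'
#' Defaults follow the screening protocol: e-value cutoff 1e-5 for every
#' homology search, merging of hits separated by less than 1000 bp, 10,000 bp
#' flank extension for LTR detection, and a 100-amino-acid minimum for
#' retained gene annotations. LTR detector bounds are LTR-Harvest-like
#' defaults (length 100-3000 bp, >= 80% identity between the two repeats).
#'
#' @param evalue_cutoff E-value cutoff for all searches.
#' @param merge_gap_bp Hits closer than this many bp are merged (strictly
#'   less-than rule).
#' @param extension_bp Extension on each side of an RT candidate for LTR
#'   search.
#' @param min_gene_aa Minimum translated length of a retained gene annotation.
#' @param ltr_min_len,ltr_max_len Admissible LTR lengths (bp).
#' @param ltr_min_identity_pct Minimum identity between the paired repeats.
#' @param ltr_search_window_bp Search window on each side (defaults to
#'   `extension_bp`).
#' @param classify_min_identity_pct Minimum RT identity to assign a
#'   supergroup; below it the element is labelled `Unknown`.
#' @return An object of class `discovery_config`.
#' @export
discovery_config <- function(evalue_cutoff = 1e-5, merge_gap_bp = 1000L,
                             extension_bp = 10000L, min_gene_aa = 100L,
                             ltr_min_len = 100L, ltr_max_len = 3000L,
                             ltr_min_identity_pct = 80,
                             ltr_search_window_bp = NULL,
                             classify_min_identity_pct = 60) {
  stopifnot(evalue_cutoff > 0, merge_gap_bp > 0, extension_bp > 0,
            min_gene_aa > 0, ltr_min_len > 0, ltr_max_len >= ltr_min_len,
            ltr_min_identity_pct > 0, classify_min_identity_pct > 0)
  if (is.null(ltr_search_window_bp)) ltr_search_window_bp <- extension_bp
  structure(list(evalue_cutoff = evalue_cutoff,
                 merge_gap_bp = as.integer(merge_gap_bp),
                 extension_bp = as.integer(extension_bp),
                 min_gene_aa = as.integer(min_gene_aa),
                 ltr_min_len = as.integer(ltr_min_len),
                 ltr_max_len = as.integer(ltr_max_len),
                 ltr_min_identity_pct = ltr_min_identity_pct,
                 ltr_search_window_bp = as.integer(ltr_search_window_bp),
                 classify_min_identity_pct = classify_min_identity_pct),
            class = "discovery_config")
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || length(genome) == 0L || any(!nzchar(genome))) {
    abort("genome must be a non-empty named character vector or DNAStringSet",
          class = "hervtrace_input_error")
  }
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  genome
}

#' Screen a genome for reverse-transcriptase footprints
#'
#' Runs the translated search of every RT reference against each contig and
#' returns the deduplicated nucleotide footprints of hits passing the e-value
#' cutoff.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @param rt_panel Named character vector of RT reference proteins.
#' @param cfg A [discovery_config()].
#' @return Tibble of intervals: `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `best_ref`, `best_bit`.
#' @export
screen_rt <- function(genome, rt_panel, cfg = discovery_config()) {
  genome <- .as_genome(genome)
  if (length(rt_panel) == 0L) {
    abort("RT panel is empty", class = "hervtrace_input_error")
  }
  params <- search_params(evalue_cutoff = cfg$evalue_cutoff)
  out <- imap(genome, function(seq, contig) {
    hits <- translated_search(seq, rt_panel, params = params,
                              subject_id = contig)
    if (nrow(hits) == 0L) return(NULL)
    hits <- hits %>%
      group_by(.data$s_start, .data$s_end, .data$strand) %>%
      slice(1L) %>% ungroup()
    tibble(contig = contig, start = hits$s_start, end = hits$s_end,
           strand = hits$strand, best_ref = hits$query_id,
           best_bit = hits$bit_score)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), best_ref = character(),
                  best_bit = double()))
  }
  out %>%
    distinct(.data$contig, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) %>%
    arrange(.data$contig, .data$start)
}

#' Merge nearby intervals
#'
#' Coordinate-merges intervals on the same contig whose gap is strictly less
#' than `merge_gap_bp` (the footprint union is preserved; output is sorted and
#' any permutation of the input yields the same result).
#'
#' @param intervals Tibble with `contig`, `start`, `end` (0-based half-open)
#'   and optionally `strand`.
#' @param merge_gap_bp Merge threshold in bp.
#' @return Tibble `contig`, `start`, `end`, `strand` (`.` when merged inputs
#'   disagree), `n_merged`.
#' @export
merge_hits <- function(intervals, merge_gap_bp = 1000L) {
  if (nrow(intervals) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), n_merged = integer()))
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  out <- intervals %>%
    group_by(.data$contig) %>%
    group_split() %>%
    map(function(df) {
      ir <- IRanges::IRanges(df$start + 1L, df$end)
      red <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp)
      ov <- IRanges::findOverlaps(ir, red, maxgap = merge_gap_bp - 1L)
      grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
      tibble(contig = df$contig[1L],
             start = IRanges::start(red) - 1L,
             end = IRanges::end(red),
             strand = vapply(seq_along(red), function(i) {
               s <- unique(df$strand[grp == i])
               if (length(s) == 1L) s else "."
             }, ""),
             n_merged = as.integer(table(factor(grp, seq_along(red)))))
    }) %>%
    bind_rows() %>%
    arrange(.data$contig, .data$start)
  out
}

#' Competitive best-hit filtering of RT candidates
#'
#' Labels each candidate interval by the reference panel (ERV, host, or other
#' virus) holding its best translated-search bit score; ties are resolved
#' conservatively in favour of retention (erv > other_virus > host). Only
#' `category == "erv"` candidates survive into later stages.
#'
#' @param intervals Tibble of merged candidate intervals.
#' @param genome Named character vector of contigs.
#' @param erv_refs,host_refs,other_virus_refs Protein panels (may be empty).
#' @param cfg A [discovery_config()].
#' @return `intervals` with `best_ref`, `best_bit`, `category`, `survives`.
#' @export
competitive_filter <- function(intervals, genome, erv_refs, host_refs,
                               other_virus_refs, cfg = discovery_config()) {
  genome <- .as_genome(genome)
  params <- search_params(evalue_cutoff = cfg$evalue_cutoff)
  panels <- list(erv = erv_refs, other_virus = other_virus_refs,
                 host = host_refs)  # tie-break priority order
  res <- pmap(intervals[, c("contig", "start", "end")],
              function(contig, start, end) {
    seq <- substr(genome[[contig]], start + 1L, end)
    tops <- map(panels, function(p) {
      if (length(p) == 0L) return(NULL)
      h <- translated_search(seq, p, params = params)
      if (nrow(h) == 0L) NULL else h[1L, ]
    })
    best <- tibble(category = names(panels),
                   bit = unname(map_dbl(tops, ~ if (is.null(.x)) -Inf else .x$bit_score)),
                   ref = unname(map_chr(tops, ~ if (is.null(.x)) NA_character_ else .x$query_id)))
    win <- best[which.max(best$bit), ]  # which.max takes the first max: ties
    tibble(best_ref = win$ref, best_bit = win$bit, category = win$category)
  })
  bind_cols(intervals %>% select(-dplyr::any_of(c("best_ref", "best_bit"))),
            bind_rows(res)) %>%
    mutate(category = ifelse(is.finite(.data$best_bit), .data$category,
                             "other_virus"),
           survives = .data$category == "erv" & is.finite(.data$best_bit))
}

#' Detect the LTR pair flanking an RT candidate
#'
#' Extends the candidate footprint by `extension_bp` on each side (clipped at
#' contig edges) and searches for the highest-scoring pair of direct repeats
#' with one copy on each side of the footprint, admissible length, length
#' ratio at most 2, and identity at least `ltr_min_identity_pct`.
#'
#' @param candidate One-row tibble (or list) with `contig`, `start`, `end`.
#' @param genome Named character vector of contigs.
#' @param cfg A [discovery_config()].
#' @param scoring Nucleotide scoring scheme.
#' @return One-row tibble `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`
#'   (absolute, 0-based half-open), `ltr_identity_pct`; or `NULL` when no
#'   qualifying pair exists.
#' @export
extend_and_find_ltrs <- function(candidate, genome, cfg = discovery_config(),
                                 scoring = nt_scoring()) {
  genome <- .as_genome(genome)
  contig_seq <- genome[[candidate$contig]]
  clen <- nchar(contig_seq)
  ext <- cfg$ltr_search_window_bp
  ls <- max(0L, candidate$start - ext)
  left <- substr(contig_seq, ls + 1L, candidate$start)
  rs <- candidate$end
  right <- substr(contig_seq, rs + 1L, min(clen, candidate$end + ext))
  if (nchar(left) < cfg$ltr_min_len || nchar(right) < cfg$ltr_min_len) {
    return(NULL)
  }
  qc <- encode_dna(left, allow_other = TRUE, what = "left flank")
  sc <- encode_dna(right, allow_other = TRUE, what = "right flank")
  hits <- .sw_hits(qc, sc, scoring)
  if (length(hits) == 0L) return(NULL)
  best <- NULL
  for (h in hits) {
    h <- .refine_repeat_ends(h, left, right, scoring)
    qw <- h$q_end - h$q_start
    sw <- h$s_end - h$s_start
    if (h$cols == 0L) next
    idpct <- 100 * h$ids / h$cols
    ok <- qw >= cfg$ltr_min_len && qw <= cfg$ltr_max_len &&
      sw >= cfg$ltr_min_len && sw <= cfg$ltr_max_len &&
      max(qw, sw) <= 2L * min(qw, sw) &&
      idpct >= cfg$ltr_min_identity_pct
    if (ok && (is.null(best) || h$score > best$score)) best <- h
  }
  if (is.null(best)) return(NULL)
  tibble(ltr5_start = ls + best$q_start, ltr5_end = ls + best$q_end,
         ltr3_start = rs + best$s_start, ltr3_end = rs + best$s_end,
         ltr_identity_pct = 100 * best$ids / best$cols)
}

# Local alignment endpoints can drift past a repeat boundary by chance:
# gapped extension through unrelated sequence occasionally strings together
# a barely-positive tail (a mismatch bridge followed by a chance match run),
# and Smith-Waterman keeps any tail with net score > 0. A genuine repeat at
# the >= 80% pair identity the detector demands scores well above
# 0.35 * k over any terminal segment of k columns (+1/-2 scoring breaks
# even with that line at ~78% identity), so terminal segments at or below
# it are trimmed and the boundary moves inward to the next match.
.refine_repeat_ends <- function(h, left, right, scoring, ratio = 0.35,
                                max_trim = 60L) {
  lsub <- substr(left, h$q_start + 1L, h$q_end)
  rsub <- substr(right, h$s_start + 1L, h$s_end)
  p <- Biostrings::pairwiseAlignment(
    lsub, rsub, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match_score, mismatch = scoring$mismatch_score,
      baseOnly = FALSE),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1L]]
  m <- a == b & a != "-"
  n <- length(m)
  col_score <- ifelse(m, scoring$match_score, scoring$mismatch_score)
  kmax <- max(1L, min(max_trim, n - 1L))
  k <- seq_len(kmax)
  # trim the longest terminal segment whose net score sits at or below the
  # admissibility line ratio * length
  pre <- cumsum(col_score)[k]
  lo <- 1L
  weak <- which(pre <= ratio * k)
  if (length(weak) > 0L) lo <- max(weak) + 1L
  suf <- cumsum(rev(col_score))[k]
  hi <- n
  weak <- which(suf <= ratio * k)
  if (length(weak) > 0L) hi <- n - max(weak)
  while (lo <= n && !m[lo]) lo <- lo + 1L       # boundary sits on a match
  while (hi >= 1L && !m[hi]) hi <- hi - 1L
  if (lo > hi) { h$cols <- 0L; return(h) }
  trim_head_q <- sum(a[seq_len(lo - 1L)] != "-")
  trim_head_s <- sum(b[seq_len(lo - 1L)] != "-")
  trim_tail_q <- sum(a[seq_len(n - hi) + hi] != "-")
  trim_tail_s <- sum(b[seq_len(n - hi) + hi] != "-")
  h$q_start <- h$q_start + trim_head_q
  h$s_start <- h$s_start + trim_head_s
  h$q_end <- h$q_end - trim_tail_q
  h$s_end <- h$s_end - trim_tail_s
  h$cols <- hi - lo + 1L
  h$ids <- sum(m[lo:hi])
  h
}

#' Annotate retroviral genes inside an element
#'
#' Searches each gene panel against the internal region between the two LTRs,
#' merges hit footprints per gene (same strictly-less-than gap rule as
#' [merge_hits()]) and retains annotations translating to at least
#' `min_gene_aa` amino acids.
#'
#' @param element_span One-row tibble with `contig`, `start`, `end` bounding
#'   the internal region (between LTR inner boundaries).
#' @param genome Named character vector of contigs.
#' @param gene_panels Named list of protein panels for `gag`, `pro`, `pol`,
#'   `env`.
#' @param cfg A [discovery_config()].
#' @return Tibble `gene`, `start`, `end` (absolute), `strand`, `aa_length`,
#'   `best_bit`.
#' @export
annotate_genes <- function(element_span, genome, gene_panels,
                           cfg = discovery_config()) {
  genome <- .as_genome(genome)
  seq <- substr(genome[[element_span$contig]], element_span$start + 1L,
                element_span$end)
  params <- search_params(evalue_cutoff = cfg$evalue_cutoff)
  out <- imap(gene_panels, function(panel, gene) {
    if (length(panel) == 0L) return(NULL)
    hits <- translated_search(seq, panel, params = params)
    if (nrow(hits) == 0L) return(NULL)
    ir <- IRanges::IRanges(hits$s_start + 1L, hits$s_end)
    red <- IRanges::reduce(ir, min.gapwidth = cfg$merge_gap_bp)
    ov <- IRanges::findOverlaps(ir, red, maxgap = cfg$merge_gap_bp - 1L)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    tibble(gene = gene,
           start = element_span$start + IRanges::start(red) - 1L,
           end = element_span$start + IRanges::end(red),
           strand = vapply(seq_along(red), function(i) {
             h <- hits[grp == i, ]
             h$strand[which.max(h$bit_score)]
           }, ""),
           aa_length = as.integer((IRanges::width(red)) %/% 3L),
           best_bit = vapply(seq_along(red), function(i)
             max(hits$bit_score[grp == i]), 0.0))
  })
  bind_rows(out) %>%
    filter(.data$aa_length >= cfg$min_gene_aa) %>%
    arrange(.data$start)
}

#' Full-length call from gene content and order
#'
#' An element is full-length when a pol annotation carrying an RT domain hit
#' exists and the genes present, read along the element strand, appear in an
#' order consistent with gag-pro-pol-env (a subsequence; adjacent duplicate
#' annotations of one gene do not break the order).
#'
#' @param genes Gene annotation tibble (from [annotate_genes()]) with a
#'   logical `has_rt` column on pol rows.
#' @param strand Element strand (`"+"` or `"-"`); order is read 5' to 3'.
#' @return `TRUE` or `FALSE`.
#' @export
call_full_length <- function(genes, strand = "+") {
  if (nrow(genes) == 0L) return(FALSE)
  if (!"has_rt" %in% names(genes)) genes$has_rt <- FALSE
  if (!any(genes$gene == "pol" & genes$has_rt)) return(FALSE)
  ord <- order(if (strand == "-") -genes$start else genes$start)
  idx <- match(genes$gene[ord], c("gag", "pro", "pol", "env"))
  if (anyNA(idx)) return(FALSE)
  all(diff(idx) >= 0L)
}

#' Classify an element by its RT domain
#'
#' Nearest-reference classification: the supergroup of the highest-identity
#' RT reference, provided identity reaches `classify_min_identity_pct`;
#' otherwise `"Unknown"`. Ties break by higher bit score, then lexicographic
#' label, so the call is deterministic.
#'
#' @param rt_seq Nucleotide sequence of the element's RT footprint.
#' @param rt_panel Named character vector of RT references; names are
#'   supergroup labels.
#' @param cfg A [discovery_config()].
#' @return A supergroup label (character scalar).
#' @export
classify_element <- function(rt_seq, rt_panel, cfg = discovery_config()) {
  if (is.null(rt_seq) || !nzchar(rt_seq)) {
    abort("element has no RT footprint; cannot classify",
          class = "hervtrace_input_error")
  }
  hits <- translated_search(rt_seq, rt_panel,
                            params = search_params(evalue_cutoff = 1e3))
  if (nrow(hits) == 0L) return("Unknown")
  best <- hits %>%
    group_by(.data$query_id) %>%
    slice(which.max(.data$bit_score)) %>%
    ungroup() %>%
    arrange(desc(.data$identity_pct), desc(.data$bit_score), .data$query_id)
  if (best$identity_pct[1L] < cfg$classify_min_identity_pct) return("Unknown")
  best$query_id[1L]
}

#' Run the full discovery pipeline on one genome
#'
#' Chains RT screening, merging, competitive filtering, LTR detection, gene
#' annotation, full-length calling and classification. Candidates with
#' qualifying LTRs but failing the full-length test are retained with
#' `is_full_length = FALSE` so that every filter is auditable.
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @param panels Named list of protein panels: `rt` (names = supergroup
#'   labels), `gag`, `pro`, `pol`, `env`, `host`, `other_virus`.
#' @param cfg A [discovery_config()].
#' @param species Species label used in element identifiers.
#' @return An object of class `herv_discovery`: list with `elements` (tibble,
#'   one row per element with LTR coordinates, classification and
#'   `is_full_length`), `candidates`, and `stage_counts`.
#' @export
discover_hervs <- function(genome, panels, cfg = discovery_config(),
                           species = "unknown_species") {
  genome <- .as_genome(genome)
  stopifnot(all(c("rt", "gag", "pro", "pol", "env") %in% names(panels)))
  rt_int <- screen_rt(genome, panels$rt, cfg)
  merged <- merge_hits(rt_int, cfg$merge_gap_bp)
  filt <- if (nrow(merged) > 0L) {
    competitive_filter(merged, genome, panels$rt,
                       panels$host %||% character(),
                       panels$other_virus %||% character(), cfg)
  } else merged %>% mutate(survives = logical(0))
  cands <- filt %>% filter(.data$survives)

  gene_panels <- panels[c("gag", "pro", "pol", "env")]
  params <- search_params(evalue_cutoff = cfg$evalue_cutoff)
  rows <- list()
  n_with_ltr <- 0L
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    ltrs <- extend_and_find_ltrs(cand, genome, cfg)
    if (is.null(ltrs)) next
    n_with_ltr <- n_with_ltr + 1L
    span <- tibble(contig = cand$contig, start = ltrs$ltr5_end,
                   end = ltrs$ltr3_start)
    internal_seq <- substr(genome[[cand$contig]], span$start + 1L, span$end)
    rt_hits <- translated_search(internal_seq, panels$rt, params = params)
    if (nrow(rt_hits) == 0L) next
    rt_best <- rt_hits[1L, ]
    strand <- rt_best$strand
    rt_start <- span$start + rt_best$s_start
    rt_end <- span$start + rt_best$s_end
    genes <- annotate_genes(span, genome, gene_panels, cfg)
    if (nrow(genes) > 0L) {
      genes$has_rt <- genes$gene == "pol" &
        pmin(genes$end, rt_end) - pmax(genes$start, rt_start) > 0L
    }
    full <- call_full_length(genes, strand)
    rt_seq <- substr(genome[[cand$contig]], rt_start + 1L, rt_end)
    classification <- classify_element(rt_seq, panels$rt, cfg)
    # extend_and_find_ltrs reports left/right repeats; re-label them 5'/3'
    # along the element strand
    if (strand == "-") {
      l5s <- ltrs$ltr3_start; l5e <- ltrs$ltr3_end
      l3s <- ltrs$ltr5_start; l3e <- ltrs$ltr5_end
    } else {
      l5s <- ltrs$ltr5_start; l5e <- ltrs$ltr5_end
      l3s <- ltrs$ltr3_start; l3e <- ltrs$ltr3_end
    }
    rows[[length(rows) + 1L]] <- tibble(
      element_id = sprintf("%s_%s_%d-%d-%s", species, cand$contig,
                           ltrs$ltr5_start + 1L, ltrs$ltr3_end,
                           classification),
      species = species, contig = cand$contig,
      start = ltrs$ltr5_start, end = ltrs$ltr3_end, strand = strand,
      ltr5_start = l5s, ltr5_end = l5e,
      ltr3_start = l3s, ltr3_end = l3e,
      ltr_identity_pct = ltrs$ltr_identity_pct,
      rt_start = rt_start, rt_end = rt_end,
      classification = classification, is_full_length = full,
      n_genes = nrow(genes), genes = list(genes))
  }
  elements <- bind_rows(rows)
  if (nrow(elements) > 1L) {
    # de-duplicate by footprint overlap (same locus reached from two seeds)
    keep <- rep(TRUE, nrow(elements))
    elements <- elements %>% arrange(.data$contig, .data$start)
    for (j in 2:nrow(elements)) {
      prev <- max(which(keep[seq_len(j - 1L)]))
      same <- elements$contig[j] == elements$contig[prev]
      if (same && elements$start[j] < elements$end[prev]) keep[j] <- FALSE
    }
    elements <- elements[keep, ]
  }
  stage_counts <- tibble(
    stage = c("rt_hits", "merged", "erv_candidates", "with_ltr_pair",
              "elements", "full_length"),
    n = c(nrow(rt_int), nrow(merged), nrow(cands), n_with_ltr,
          nrow(elements),
          sum(elements[["is_full_length"]] %||% logical(0))))
  structure(list(elements = elements, candidates = filt,
                 stage_counts = stage_counts, config = cfg,
                 species = species),
            class = "herv_discovery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.herv_discovery <- function(x, ...) {
  cat(sprintf("<herv_discovery: %s>\n", x$species))
  print(x$stage_counts)
  invisible(x)
}

#' Export discovered elements
#'
#' `write_elements_bed()` writes BED6 (0-based half-open; name =
#' `element_id`, score = rounded LTR identity). `write_elements_gtf()` writes
#' a GTF-like 1-based inclusive table with `element_id`, `classification` and
#' `is_full_length` attributes.
#'
#' @param x A `herv_discovery` object or element tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(x, path) {
  el <- if (inherits(x, "herv_discovery")) x$elements else x
  df <- data.frame(el$contig, el$start, el$end, el$element_id,
                   round(el$ltr_identity_pct), el$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_elements_bed
#' @export
write_elements_gtf <- function(x, path) {
  el <- if (inherits(x, "herv_discovery")) x$elements else x
  attr_str <- sprintf(
    'element_id "%s"; classification "%s"; is_full_length "%s";',
    el$element_id, el$classification, el$is_full_length)
  df <- data.frame(el$contig, "hervtrace", "ERV_element", el$start + 1L,
                   el$end, ".", el$strand, ".", attr_str)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a key/value discovery configuration file
#'
#' YAML mirror of [discovery_config()]; unknown keys raise an error listing
#' the valid ones.
#'
#' @param path Path to a YAML file.
#' @return A `discovery_config` object.
#' @export
read_discovery_config <- function(path) {
  vals <- yaml::read_yaml(path)
  valid <- names(formals(discovery_config))
  bad <- setdiff(names(vals), valid)
  if (length(bad) > 0L) {
    abort(sprintf("invalid config key(s): %s (valid keys: %s)",
                  paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
          class = "hervtrace_input_error")
  }
  do.call(discovery_config, vals)
}
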