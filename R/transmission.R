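# Vertical-transmission inference: flanked-element extraction, the
# three-condition orthologous-pair test, pair-graph clustering into events,
# and MRCA dating on a timed species tree.

#' Thresholds of the orthologous-pair test
#'
#' The three acceptance conditions for a cross-species element pair:
#' (1) the element sequences align with coverage (of the shorter element) and
#' identity both at least `element_min_cov_pct` / `element_min_identity_pct`;
#' (2) each flank pair (upstream-upstream, downstream-downstream) matches with
#' identity above `flank_min_identity_pct`; (3) both flank alignments cover
#' more than `flank_min_cov_both_pct` of the shorter flank and at least one
#' covers `flank_min_cov_one_pct` or more.
#'
#' @param element_min_cov_pct,element_min_identity_pct Condition 1 thresholds.
#' @param flank_min_identity_pct Condition 2 threshold (strictly greater
#'   than).
#' @param flank_min_cov_both_pct,flank_min_cov_one_pct Condition 3 thresholds.
#' @param min_flank_bp Flanks clipped below this length auto-fail condition 3.
#' @return An object of class `vt_thresholds`.
#' @export
vt_thresholds <- function(element_min_cov_pct = 90,
                          element_min_identity_pct = 90,
                          flank_min_identity_pct = 90,
                          flank_min_cov_both_pct = 25,
                          flank_min_cov_one_pct = 80,
                          min_flank_bp = 250L) {
  vals <- c(element_min_cov_pct, element_min_identity_pct,
            flank_min_identity_pct, flank_min_cov_both_pct,
            flank_min_cov_one_pct)
  stopifnot(all(vals > 0), all(vals <= 100))
  structure(list(element_min_cov_pct = element_min_cov_pct,
                 element_min_identity_pct = element_min_identity_pct,
                 flank_min_identity_pct = flank_min_identity_pct,
                 flank_min_cov_both_pct = flank_min_cov_both_pct,
                 flank_min_cov_one_pct = flank_min_cov_one_pct,
                 min_flank_bp = as.integer(min_flank_bp)),
            class = "vt_thresholds")
}

#' Extract element and flank sequences
#'
#' Adds the element sequence and its upstream/downstream flanks (target
#' length `flank_bp`, clipped at contig edges) to an element table. All
#' sequences are oriented 5' to 3' on the element strand, so orthologous
#' pairs compare on the plus strand.
#'
#' @param elements Element tibble (e.g. `tidy()` of a discovery result, or
#'   the simulator truth table) with `species`, `contig`, `start`, `end`,
#'   `strand`, `element_id`.
#' @param genomes Named list (by species) of named contig character vectors.
#' @param flank_bp Flank length target.
#' @return `elements` with list columns `element_seq`, `upstream_seq`,
#'   `downstream_seq` (character), plus `upstream_len`, `downstream_len`.
#' @export
extract_flanked <- function(elements, genomes, flank_bp = 2000L) {
  stopifnot(all(c("species", "contig", "start", "end", "strand",
                  "element_id") %in% names(elements)))
  n <- nrow(elements)
  elem <- up <- dn <- character(n)
  for (i in seq_len(n)) {
    r <- elements[i, ]
    g <- genomes[[r$species]]
    if (is.null(g)) abort(sprintf("no genome for species '%s'", r$species),
                          class = "hervtrace_input_error")
    contig_seq <- g[[r$contig]]
    clen <- nchar(contig_seq)
    e <- substr(contig_seq, r$start + 1L, r$end)
    left <- substr(contig_seq, max(0L, r$start - flank_bp) + 1L, r$start)
    right <- substr(contig_seq, r$end + 1L, min(clen, r$end + flank_bp))
    if (r$strand == "-") {
      e <- revcomp(e)
      tmp <- left
      left <- revcomp(right)
      right <- revcomp(tmp)
    }
    elem[i] <- e; up[i] <- left; dn[i] <- right
  }
  elements$element_seq <- elem
  elements$upstream_seq <- up
  elements$downstream_seq <- dn
  elements$upstream_len <- nchar(up)
  elements$downstream_len <- nchar(dn)
  elements
}

# Precompute integer encodings for one flanked element (both element strands;
# flanks are compared in element orientation, plus strand)
.pair_precompute <- function(row) {
  ec <- if (nzchar(row$element_seq))
    encode_dna(row$element_seq, what = "element") else integer(0)
  rc <- rev(ec)
  rc <- ifelse(rc == 4L, 4L, 3L - rc)
  list(element_id = row$element_id, species = row$species,
       elem = ec, elem_rc = rc,
       up = if (nzchar(row$upstream_seq))
         encode_dna(row$upstream_seq, what = "flank") else integer(0),
       dn = if (nzchar(row$downstream_seq))
         encode_dna(row$downstream_seq, what = "flank") else integer(0))
}

# best hit between encoded sequences passing the e-value cutoff
.best_hit_codes <- function(qc, sc, scoring, evalue_cutoff = 1e-5) {
  if (length(qc) == 0L || length(sc) == 0L) return(NULL)
  hits <- .sw_hits(qc, sc, scoring)
  if (length(hits) == 0L) return(NULL)
  best <- hits[[which.max(map_dbl(hits, "score"))]]
  if (.e_value(best$score, length(qc), length(sc), scoring) > evalue_cutoff) {
    return(NULL)
  }
  best
}

# Fraction of query positions covered by exact shared k-mers: a cheap upper
# bound on pairwise identity. Sequences at >= 90% identity put roughly half
# their positions inside exact 12-mers; below ~80% identity the fraction
# collapses, so a tiny fraction proves condition 1 cannot hold.
.seed_support <- function(qc, sc, k = 12L) {
  if (length(qc) < k || length(sc) < k) return(0)
  seeds <- .cpp_find_seeds(qc, sc, k, 4L)
  if (nrow(seeds) == 0L) return(0)
  length(unique(seeds[, 1L])) / max(1L, length(qc) - k + 1L)
}

# core three-condition test on precomputed encodings
.pair_test_core <- function(pa, pb, thresholds, scoring) {
  # condition 1: element coverage (of the shorter) and identity; orthologs
  # are extracted in element orientation, so the plus strand is tried first
  # and the reverse orientation only as a fallback
  eh <- NULL
  if (.seed_support(pa$elem, pb$elem) >= 0.05) {
    eh <- .best_hit_codes(pa$elem, pb$elem, scoring)
  }
  if (is.null(eh) && .seed_support(pa$elem, pb$elem_rc) >= 0.05) {
    eh <- .best_hit_codes(pa$elem, pb$elem_rc, scoring)
  }
  shorter <- min(length(pa$elem), length(pb$elem))
  el_cov <- el_id <- 0
  if (!is.null(eh) && shorter > 0L) {
    span <- if (length(pa$elem) <= length(pb$elem)) eh$q_end - eh$q_start
            else eh$s_end - eh$s_start
    el_cov <- 100 * span / shorter
    el_id <- 100 * eh$ids / eh$cols
  }
  cond1 <- el_cov >= thresholds$element_min_cov_pct &&
    el_id >= thresholds$element_min_identity_pct

  flank_stats <- function(fa, fb) {
    la <- length(fa); lb <- length(fb)
    if (la < thresholds$min_flank_bp || lb < thresholds$min_flank_bp) {
      return(c(id = 0, cov = 0, ok = 0))
    }
    h <- .best_hit_codes(fa, fb, scoring)
    if (is.null(h)) return(c(id = 0, cov = 0, ok = 1))
    shorter_f <- min(la, lb)
    span <- if (la <= lb) h$q_end - h$q_start else h$s_end - h$s_start
    c(id = 100 * h$ids / h$cols, cov = 100 * span / shorter_f, ok = 1)
  }
  upf <- flank_stats(pa$up, pb$up)
  dnf <- flank_stats(pa$dn, pb$dn)
  cond2 <- upf[["id"]] > thresholds$flank_min_identity_pct &&
    dnf[["id"]] > thresholds$flank_min_identity_pct
  cond3 <- upf[["ok"]] == 1 && dnf[["ok"]] == 1 &&
    upf[["cov"]] > thresholds$flank_min_cov_both_pct &&
    dnf[["cov"]] > thresholds$flank_min_cov_both_pct &&
    max(upf[["cov"]], dnf[["cov"]]) >= thresholds$flank_min_cov_one_pct

  tibble(element_a = pa$element_id, element_b = pb$element_id,
         species_a = pa$species, species_b = pb$species,
         element_cov_pct = el_cov, element_identity_pct = el_id,
         up_flank_identity_pct = upf[["id"]], up_flank_cov_pct = upf[["cov"]],
         dn_flank_identity_pct = dnf[["id"]], dn_flank_cov_pct = dnf[["cov"]],
         cond_element = cond1, cond_flank_identity = cond2,
         cond_flank_cov = cond3,
         accepted = cond1 && cond2 && cond3)
}

#' Three-condition orthologous-pair test
#'
#' Tests whether two flanked elements from different species descend from the
#' same germline integration. All three condition flags are evaluated and
#' reported even when the pair fails; a missing flank (element at a contig
#' edge) fails condition 3 rather than raising an error. Coverage is always
#' measured against the shorter sequence of the pair. The test is symmetric
#' in its arguments.
#'
#' @param a,b One-row tibbles from [extract_flanked()].
#' @param thresholds A [vt_thresholds()] object.
#' @param scoring A [nt_scoring()] scheme.
#' @return One-row tibble: `element_a`, `element_b`, `species_a`,
#'   `species_b`, `cond_element`, `cond_flank_identity`, `cond_flank_cov`,
#'   `accepted`, plus the measured identities/coverages.
#' @export
ortholog_pair_test <- function(a, b, thresholds = vt_thresholds(),
                               scoring = nt_scoring()) {
  if (a$species == b$species) {
    abort("same-species pairs are paralogy candidates, not orthologs",
          class = "hervtrace_input_error")
  }
  .pair_test_core(.pair_precompute(a), .pair_precompute(b),
                  thresholds, scoring)
}

#' Cluster accepted pairs into transmission events
#'
#' Events are the connected components of the graph whose nodes are elements
#' and whose edges are accepted orthologous pairs; single-element components
#' are discarded.
#'
#' @param pairs Tibble of pair-test results (only `accepted` rows are used).
#' @return Tibble `event_id`, `element_id` (one row per member element).
#' @export
build_event_graph <- function(pairs) {
  acc <- pairs %>% filter(.data$accepted)
  if (nrow(acc) == 0L) {
    return(tibble(event_id = character(), element_id = character()))
  }
  g <- igraph::graph_from_data_frame(
    acc[, c("element_a", "element_b")], directed = FALSE)
  comp <- igraph::components(g)
  tibble(event_id = sprintf("vt%03d", unname(comp$membership)),
         element_id = names(comp$membership)) %>%
    group_by(.data$event_id) %>% filter(n() >= 2L) %>% ungroup() %>%
    arrange(.data$event_id, .data$element_id)
}

#' Date an event at the MRCA of its species set
#'
#' @param species Character vector of species in the event (tree leaves).
#' @param tree A timed species tree.
#' @return One-row tibble `mrca_node`, `mrca_label`, `age_mya`.
#' @export
map_event_to_tree <- function(species, tree) {
  species <- unique(species)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0L) {
    abort(sprintf("species not in tree: %s", paste(missing, collapse = ", ")),
          class = "hervtrace_input_error")
  }
  ages <- node_ages(tree)
  if (length(species) == 1L) {
    node <- match(species, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, species)
  }
  tibble(mrca_node = node, mrca_label = ages$label[node],
         age_mya = ages$age_mya[node])
}

#' Identify vertical-transmission events in a cohort
#'
#' Runs the orthologous-pair test over all cross-species element pairs,
#' clusters accepted pairs into events, and dates each event at the MRCA of
#' the species carrying its members (a minimum integration age).
#'
#' @param elements Element tibble (see [extract_flanked()]; must carry a
#'   `classification` or `class` column for summaries).
#' @param genomes Named list (by species) of named contig vectors.
#' @param tree A timed species tree containing every species.
#' @param thresholds A [vt_thresholds()] object.
#' @param scoring A [nt_scoring()] scheme.
#' @param flank_bp Flank length target.
#' @return An object of class `herv_transmission`: list with `pairs` (all
#'   tested pairs with flags), `events` (one row per event: members,
#'   species set, MRCA node and age), `members`, and `tree`.
#' @export
find_transmission_events <- function(elements, genomes, tree,
                                     thresholds = vt_thresholds(),
                                     scoring = nt_scoring(),
                                     flank_bp = 2000L) {
  validate_timed_tree(tree)
  cls_col <- if ("classification" %in% names(elements)) "classification"
             else if ("class" %in% names(elements)) "class" else NULL
  fl <- extract_flanked(elements, genomes, flank_bp)
  n <- nrow(fl)
  pre <- lapply(seq_len(n), function(i) .pair_precompute(fl[i, ]))
  pair_rows <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      if (j > n) break
      if (fl$species[i] == fl$species[j]) next
      pair_rows[[length(pair_rows) + 1L]] <-
        .pair_test_core(pre[[i]], pre[[j]], thresholds, scoring)
    }
  }
  pairs <- if (length(pair_rows) > 0L) bind_rows(pair_rows) else
    tibble(element_a = character(), element_b = character(),
           species_a = character(), species_b = character(),
           accepted = logical())
  members <- build_event_graph(pairs)
  elem_meta <- fl %>%
    select("element_id", "species",
           classification = dplyr::all_of(cls_col %||% "element_id"))
  if (is.null(cls_col)) elem_meta$classification <- NA_character_
  members <- members %>% left_join(elem_meta, by = "element_id")
  events <- members %>%
    group_by(.data$event_id) %>%
    summarise(n_elements = n(),
              species_set = paste(sort(unique(.data$species)), collapse = ","),
              n_species = length(unique(.data$species)),
              classification = names(sort(table(.data$classification),
                                          decreasing = TRUE))[1L],
              .groups = "drop")
  if (nrow(events) > 0L) {
    dating <- bind_rows(lapply(strsplit(events$species_set, ","),
                               map_event_to_tree, tree = tree))
    events <- bind_cols(events, dating)
  } else {
    events <- events %>% mutate(mrca_node = integer(), mrca_label = character(),
                                age_mya = double())
  }
  structure(list(pairs = pairs, events = events, members = members,
                 tree = tree, thresholds = thresholds),
            class = "herv_transmission")
}

#' Summarise events per tree node and elements per species
#'
#' @param x A `herv_transmission` object.
#' @return List of two tibbles: `per_node` (every tree node with its age and
#'   event count, split by majority classification) and `per_species`
#'   (vertically-transmitted element counts by species and classification).
#' @export
summarize_events <- function(x) {
  stopifnot(inherits(x, "herv_transmission"))
  ages <- node_ages(x$tree)
  counts <- x$events %>% count(.data$mrca_node, .data$classification)
  per_node <- ages %>%
    left_join(counts, by = c(node = "mrca_node")) %>%
    mutate(classification = ifelse(is.na(.data$n), NA_character_,
                                   .data$classification),
           n_events = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    select("node", "label", "age_mya", "classification", "n_events")
  per_species <- x$members %>%
    count(.data$species, .data$classification, name = "n_elements")
  list(per_node = per_node, per_species = per_species)
}

#' @export
print.herv_transmission <- function(x, ...) {
  cat(sprintf("<herv_transmission: %d pairs tested, %d accepted, %d events>\n",
              nrow(x$pairs), sum(x$pairs$accepted), nrow(x$events)))
  invisible(x)
}
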