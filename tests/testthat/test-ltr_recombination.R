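# LTR-discordance recombination detection.

mk_elements <- function(ltr_pairs, species = "sp1", class = "HERVHF",
                        internal_bp = 3000L) {
  # build a single-contig genome holding elements with the given LTR pairs
  seqs <- character(0)
  rows <- list()
  pos <- 0L
  for (i in seq_along(ltr_pairs)) {
    spacer <- random_dna(1000)
    internal <- random_dna(internal_bp)
    l5 <- ltr_pairs[[i]][[1]]
    l3 <- ltr_pairs[[i]][[2]]
    el <- paste0(l5, internal, l3)
    start <- pos + 1000L
    rows[[i]] <- tibble::tibble(
      element_id = sprintf("E%02d", i), species = species, contig = "c1",
      start = start, end = start + nchar(el), strand = "+",
      classification = class,
      ltr5_start = start, ltr5_end = start + nchar(l5),
      ltr3_start = start + nchar(el) - nchar(l3),
      ltr3_end = start + nchar(el))
    seqs <- c(seqs, spacer, el)
    pos <- start + nchar(el)
  }
  genome <- paste(c(seqs, random_dna(500)), collapse = "")
  list(elements = dplyr::bind_rows(rows),
       genomes = setNames(list(c(c1 = genome)), species))
}

test_that("intact twin LTRs cluster; an exchanged pair yields one reciprocal call", {
  set.seed(401)
  ltrA <- random_dna(400)
  ltrB <- random_dna(400)
  # two elements, twin LTRs slightly diverged within each pair
  intact <- mk_elements(list(list(ltrA, mutate_dna(ltrA, 10)),
                             list(ltrB, mutate_dna(ltrB, 10))))
  rec <- extract_ltr_records(intact$elements, intact$genomes)
  m <- ltr_score_matrix(rec)
  fl <- flag_nonclustered(m)
  expect_false(any(fl$nonclustered))
  expect_equal(nrow(detect_recombination(m)), 0L)

  # exchange the 5' LTRs: both elements flagged, exactly one crossed call
  swapped <- mk_elements(list(list(mutate_dna(ltrB, 8), mutate_dna(ltrA, 10)),
                              list(mutate_dna(ltrA, 8), mutate_dna(ltrB, 10))))
  m2 <- ltr_score_matrix(extract_ltr_records(swapped$elements,
                                             swapped$genomes))
  fl2 <- flag_nonclustered(m2)
  expect_true(all(fl2$nonclustered))
  calls <- detect_recombination(m2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$matching, "5p->3p,3p->5p")
  expect_true(all(c(calls$cross_bit_5p, calls$cross_bit_3p) >
                    c(calls$own_pair_bit_1, calls$own_pair_bit_2)))

  # one-sided similarity only: 5p shared but both 3p LTRs pair with their
  # own partners -> nonclustered flags possible, but no reciprocal call
  ltrC <- random_dna(400)
  oneside <- mk_elements(list(list(ltrC, mutate_dna(ltrC, 8)),
                              list(mutate_dna(ltrC, 8), mutate_dna(ltrC, 6))))
  m3 <- ltr_score_matrix(extract_ltr_records(oneside$elements,
                                             oneside$genomes))
  # element pairs share ancestry here, so own and cross scores interleave;
  # the reciprocal two-sided rule must not fire on a construct where each
  # element's own pair is its best partner
  own1 <- hervtrace:::.own_pair_score(m3, "E01")
  calls3 <- detect_recombination(m3)
  if (nrow(calls3) > 0L) {
    expect_true(all(calls3$cross_bit_5p > own1))
  }
})

test_that("an element missing an LTR is skipped with a warning", {
  set.seed(402)
  x <- mk_elements(list(list(random_dna(400), random_dna(400))))
  x$elements$ltr3_start[1] <- NA_integer_
  expect_warning(rec <- extract_ltr_records(x$elements, x$genomes), "skipped")
  expect_equal(nrow(rec), 0L)
})

test_that("planted swaps are called with no spurious calls, matching truth", {
  sg <- simulate_genome(12, classes = "HERVHF", age_my = 10, seed = 41,
                        segment_length_bp = 90000L,
                        n_recombination_swaps = 2L)
  rc <- find_recombination(sg$truth$insertions, sg$genomes)
  truth <- sg$truth$recombination
  expect_equal(nrow(rc$calls), 2L)
  got_pairs <- apply(rc$calls[, c("element_1", "element_2")], 1,
                     function(x) paste(sort(x), collapse = "|"))
  want_pairs <- apply(truth[, c("element_1", "element_2")], 1,
                      function(x) paste(sort(x), collapse = "|"))
  expect_setequal(got_pairs, want_pairs)
  # flagged set contains every element involved in a swap
  involved <- unique(c(truth$element_1, truth$element_2))
  flagged <- rc$nonclustered$element_id[rc$nonclustered$nonclustered]
  expect_true(all(involved %in% flagged))
  # summary counts equal truth involved-element counts
  expect_equal(sum(rc$summary$n_elements), length(involved))
})

test_that("no-recombination strata yield zero calls", {
  for (seed in 42:44) {
    sg <- simulate_genome(6, classes = "HERVK", age_my = 10, seed = seed,
                          segment_length_bp = 50000L)
    rc <- find_recombination(sg$truth$insertions, sg$genomes)
    expect_equal(nrow(rc$calls), 0L)
  }
})

test_that("score-based flags agree with the NJ sibling-pairing oracle", {
  sg <- simulate_genome(8, classes = "HERVHF", age_my = 10, seed = 45,
                        segment_length_bp = 70000L,
                        n_recombination_swaps = 2L)
  rec <- extract_ltr_records(sg$truth$insertions, sg$genomes)
  m <- ltr_score_matrix(rec)
  fl <- flag_nonclustered(m)
  cherries <- oracle_nj_cherries(rec)
  agree <- mean(!fl$nonclustered == cherries[fl$element_id])
  expect_gte(agree, 0.95)
})

test_that("relabelling elements permutes but never changes the call set", {
  sg <- simulate_genome(8, classes = "HERVHF", age_my = 10, seed = 46,
                        segment_length_bp = 70000L,
                        n_recombination_swaps = 2L)
  el <- sg$truth$insertions
  rc1 <- find_recombination(el, sg$genomes)
  el2 <- el[rev(seq_len(nrow(el))), ]
  el2$element_id <- paste0("X_", el2$element_id)
  rc2 <- find_recombination(el2, sg$genomes)
  k1 <- sort(apply(rc1$calls[, c("element_1", "element_2")], 1,
                   function(x) paste(sort(x), collapse = "|")))
  k2 <- sort(apply(rc2$calls[, c("element_1", "element_2")], 1,
                   function(x) paste(sort(sub("^X_", "", x)), collapse = "|")))
  expect_equal(k1, k2)
})

test_that("recombination summaries count involved elements by stratum", {
  empty <- summarize_recombination(
    detect_recombination(structure(list(records = tibble::tibble(
      element_id = character(), species = character(),
      classification = character(), side = character(),
      sequence = character()), bits = matrix(0, 0, 0)),
      class = "ltr_score_matrix")),
    tibble::tibble(species = "sp1", classification = "HERVHF"))
  expect_equal(empty$n_elements, 0L)

  calls <- tibble::tibble(element_1 = "E01", element_2 = "E02",
                          species = "sp1", classification = "HERVHF",
                          matching = "5p->3p,3p->5p",
                          own_pair_bit_1 = 1, own_pair_bit_2 = 1,
                          cross_bit_5p = 9, cross_bit_3p = 9)
  s <- summarize_recombination(
    calls, tibble::tibble(species = "sp1", classification = "HERVHF"))
  expect_equal(s$n_elements, 2L)
})
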