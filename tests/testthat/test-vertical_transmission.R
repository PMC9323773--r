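# Orthologous-pair testing, event graph clustering and MRCA dating.

mk_flanked <- function(id, sp, elem, up, dn) {
  tibble::tibble(element_id = id, species = sp, element_seq = elem,
                 upstream_seq = up, downstream_seq = dn,
                 upstream_len = nchar(up), downstream_len = nchar(dn))
}

test_that("pair test accepts identical orthologs and reports failing flags", {
  set.seed(301)
  elem <- random_dna(5000); up <- random_dna(2000); dn <- random_dna(2000)
  a <- mk_flanked("A", "sp1", elem, up, dn)
  b <- mk_flanked("B", "sp2", elem, up, dn)
  r <- ortholog_pair_test(a, b)
  expect_true(r$accepted)
  expect_true(all(c(r$cond_element, r$cond_flank_identity, r$cond_flank_cov)))
  expect_equal(r$element_identity_pct, 100)

  # identical elements with unrelated flanks: condition flags (T, F, F)
  b2 <- mk_flanked("B", "sp2", elem, random_dna(2000), random_dna(2000))
  r2 <- ortholog_pair_test(a, b2)
  expect_false(r2$accepted)
  expect_true(r2$cond_element)
  expect_false(r2$cond_flank_identity)
  expect_false(r2$cond_flank_cov)

  # same-species pairs are rejected as paralogy candidates
  expect_error(ortholog_pair_test(a, mk_flanked("C", "sp1", elem, up, dn)),
               class = "hervtrace_input_error")

  # a clipped flank fails condition 3 without raising
  b3 <- mk_flanked("B", "sp2", elem, substr(up, 1, 100), dn)
  r3 <- ortholog_pair_test(a, b3)
  expect_false(r3$cond_flank_cov)
  expect_false(r3$accepted)
})

test_that("pair test is symmetric in its arguments", {
  set.seed(302)
  for (rep in 1:4) {
    elem <- random_dna(4000)
    up <- random_dna(1800); dn <- random_dna(2000)
    a <- mk_flanked("A", "sp1", mutate_dna(elem, 120),
                    mutate_dna(up, 50), mutate_dna(dn, 60))
    b <- mk_flanked("B", "sp2", mutate_dna(elem, 120),
                    mutate_dna(up, 50), mutate_dna(dn, 60))
    ab <- ortholog_pair_test(a, b)
    ba <- ortholog_pair_test(b, a)
    expect_equal(ab$accepted, ba$accepted)
    expect_equal(
      c(ab$cond_element, ab$cond_flank_identity, ab$cond_flank_cov),
      c(ba$cond_element, ba$cond_flank_identity, ba$cond_flank_cov))
    expect_equal(ab$element_identity_pct, ba$element_identity_pct,
                 tolerance = 1e-6)
  }
})

test_that("divergence thresholds separate recent from ancient orthologs", {
  set.seed(303)
  elem <- random_dna(5000); up <- random_dna(2000); dn <- random_dna(2000)
  # ~6% element and ~4% flank divergence: inside the acceptance envelope
  a <- mk_flanked("A", "sp1", elem, up, dn)
  b <- mk_flanked("B", "sp2", mutate_dna(elem, 300),
                  mutate_dna(up, 80), mutate_dna(dn, 80))
  expect_true(ortholog_pair_test(a, b)$accepted)
  # ~12% flank divergence: flank identity drops below 90, condition 2 fails
  b2 <- mk_flanked("B", "sp2", mutate_dna(elem, 300),
                   mutate_dna(up, 240), mutate_dna(dn, 240))
  r2 <- ortholog_pair_test(a, b2)
  expect_false(r2$cond_flank_identity)
  expect_false(r2$accepted)
})

test_that("events are connected components, discarding singletons", {
  p <- function(a, b, sa, sb) {
    tibble::tibble(element_a = a, element_b = b, species_a = sa,
                   species_b = sb, accepted = TRUE)
  }
  ev <- build_event_graph(dplyr::bind_rows(p("A", "B", "s1", "s2"),
                                           p("B", "C", "s2", "s3")))
  expect_equal(length(unique(ev$event_id)), 1L)
  expect_setequal(ev$element_id, c("A", "B", "C"))

  expect_equal(nrow(build_event_graph(p("A", "B", "s1", "s2")[0, ])), 0L)

  # a 17-species chain collapses into a single event spanning 17 species
  sp <- sprintf("sp%02d", 1:17)
  ids <- sprintf("E%02d", 1:17)
  chain <- dplyr::bind_rows(lapply(1:16, function(i)
    p(ids[i], ids[i + 1], sp[i], sp[i + 1])))
  ev17 <- build_event_graph(chain)
  expect_equal(length(unique(ev17$event_id)), 1L)
  expect_equal(nrow(ev17), 17L)
})

test_that("MRCA dating matches the fixture tree and a brute-force oracle", {
  tree <- fixture_tree()
  hg <- map_event_to_tree(c("Homo_sapiens", "Gorilla_gorilla_gorilla"), tree)
  expect_equal(hg$age_mya, 9.1)
  expect_equal(hg$mrca_label, "homininae")

  # spanning the root gives the root age
  root <- map_event_to_tree(c("Homo_sapiens", "Macaca_mulatta"), tree)
  expect_equal(root$age_mya, 29.4)

  expect_error(map_event_to_tree(c("Homo_sapiens", "Mus_musculus"), tree),
               "Mus_musculus")

  # random 3-leaf subsets on random ultrametric trees: MRCA age equals the
  # maximum pairwise divergence time (half the cophenetic distance)
  set.seed(304)
  for (rep in 1:10) {
    rt <- ape::rcoal(8)
    dmat <- ape::cophenetic.phylo(rt)
    leaves <- sample(rt$tip.label, 3)
    got <- map_event_to_tree(leaves, rt)$age_mya
    expect_equal(got, max(dmat[leaves, leaves]) / 2, tolerance = 1e-8)
  }
})

test_that("event ages never decrease when adding species outside the clade", {
  tree <- fixture_tree()
  set.seed(305)
  for (rep in 1:10) {
    base <- sample(tree$tip.label, 2)
    extra <- sample(setdiff(tree$tip.label, base), 1)
    age0 <- map_event_to_tree(base, tree)$age_mya
    age1 <- map_event_to_tree(c(base, extra), tree)$age_mya
    expect_gte(age1, age0)
  }
})

test_that("zero-divergence cohort recovers every planted event at its node", {
  tree <- ape::keep.tip(fixture_tree(),
                        c("Homo_sapiens", "Pan_troglodytes",
                          "Gorilla_gorilla_gorilla"))
  plan <- tibble::tibble(
    group_id = c("gA", "gB", "gC"),
    node = c("homininae", "homininae", "hominini"),
    class = c("HERVHF", "HERVK", "HERVHF"),
    age_my = 0, missing = "")
  cfg <- simulation_config(seed = 11, tree = tree, segment_length_bp = 25000L,
                           insertions = plan, substitution_rate = 0)
  coh <- simulate_cohort(cfg)
  # rate 0: orthologous copies are byte-identical across species
  fl <- extract_flanked(coh$truth$insertions, coh$genomes)
  for (g in unique(fl$group_id)) {
    seqs <- unique(fl$element_seq[fl$group_id == g])
    expect_equal(length(seqs), 1L)
  }
  vt <- find_transmission_events(coh$truth$insertions, coh$genomes, tree)
  expect_equal(nrow(vt$events), 3L)
  # every planted (same-group, cross-species) pair is accepted
  grp <- setNames(coh$truth$insertions$group_id,
                  coh$truth$insertions$element_id)
  planted <- vt$pairs[grp[vt$pairs$element_a] == grp[vt$pairs$element_b], ]
  expect_gt(nrow(planted), 0L)
  expect_true(all(planted$accepted))
  # and no cross-group pair sneaks in
  expect_true(all(!vt$pairs$accepted[grp[vt$pairs$element_a] !=
                                       grp[vt$pairs$element_b]]))
  got <- vt$events %>%
    dplyr::left_join(
      vt$members %>% dplyr::distinct(.data$event_id, .data$classification),
      by = c("event_id", "classification"))
  expect_setequal(vt$events$mrca_label,
                  c("homininae", "homininae", "hominini"))
  expect_equal(sort(table(vt$events$mrca_label), decreasing = TRUE)[["homininae"]], 2L)

  # summaries: two events at one node count as 2; totals match
  s <- summarize_events(vt)
  expect_equal(sum(s$per_node$n_events), 3L)
  expect_equal(sum(s$per_species$n_elements), nrow(vt$members))
  # per-node table lists every tree node even with zero events
  expect_true(all(node_ages(tree)$node %in% s$per_node$node))
})
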