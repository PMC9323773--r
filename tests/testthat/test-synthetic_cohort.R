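# Ground-truth simulator: determinism, orthology structure, divergence
# calibration, panels, and config validation.

test_that("identical configs give byte-identical cohorts", {
  cfg <- simulation_config(seed = 99, segment_length_bp = 30000L,
                           insertions = default_insertion_plan()[c(7, 9), ])
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$panels, b$panels)
})

test_that("insertions appear in all and only the descendant leaves", {
  coh <- simulate_cohort(simulation_config(seed = 7))
  tree <- coh$config$tree
  plan <- coh$config$insertions
  truth <- coh$truth$insertions
  for (k in seq_len(nrow(plan))) {
    node <- hervtrace:::.node_by_label(tree, plan$node[k])
    want <- setdiff(hervtrace:::.node_leaves(tree, node),
                    trimws(strsplit(plan$missing[k], ",")[[1]]))
    got <- truth$species[truth$group_id == plan$group_id[k]]
    expect_setequal(got, want)
  }
  # coordinates are valid and the element sequence matches its recorded span
  for (i in sample(nrow(truth), 5)) {
    r <- truth[i, ]
    g <- coh$genomes[[r$species]][[r$contig]]
    expect_lte(r$end, nchar(g))
    expect_equal(r$end - r$start, coh$layout$total)
  }
})

test_that("leaf-leaf divergence matches the 2 x rate x time expectation", {
  # two leaves at 10 MY divergence, rate 0.002/site/MY: expected identity
  # ~ 96% (Jukes-Cantor, small-rate); checked by direct mismatch counting
  tree <- ape::read.tree(text = "(A:10,B:10);")
  plan <- tibble::tibble(group_id = "g1", node = "node1", class = "HERVHF",
                         age_my = 0, missing = "")
  tree$node.label <- "node1"
  obs <- replicate(25, {
    seed <- sample.int(1e6, 1)
    cfg <- simulation_config(seed = seed, tree = tree,
                             segment_length_bp = 12000L, insertions = plan)
    coh <- simulate_cohort(cfg)
    tr <- coh$truth$insertions
    fa <- coh$genomes[["A"]][["seg1"]]; fb <- coh$genomes[["B"]][["seg1"]]
    a <- substr(fa, tr$start[tr$species == "A"] + 1, tr$end[tr$species == "A"])
    b <- substr(fb, tr$start[tr$species == "B"] + 1, tr$end[tr$species == "B"])
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    mean(va == vb)
  })
  expect_equal(mean(obs) * 100, 96, tolerance = 0.011)
})

test_that("panels round-trip: planted pol translates back to the panel protein", {
  tree <- hervtrace:::.single_tip_tree("spX")
  plan <- tibble::tibble(group_id = "g1", node = "spX", class = "HERVK",
                         age_my = 0, missing = "")
  cfg <- simulation_config(seed = 12, tree = tree, segment_length_bp = 15000L,
                           insertions = plan, substitution_rate = 0)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth$insertions[1, ]
  g <- coh$genomes[["spX"]][["seg1"]]
  elem <- substr(g, tr$start + 1, tr$end)
  if (tr$strand == "-") elem <- revcomp(elem)
  lay <- coh$layout
  pol <- lay$genes[lay$genes$gene == "pol", ]
  pol_nt <- substr(elem, pol$start + 1, pol$end)
  expect_equal(hervtrace:::.translate_frame(pol_nt, 0),
               coh$panels$pol[["HERVK_pol"]])
  # decoy host proteins never appear inside planted elements
  for (hp in coh$panels$host[1:2]) {
    frames <- vapply(0:2, function(o) hervtrace:::.translate_frame(elem, o), "")
    expect_false(any(grepl(substr(hp, 1, 30), frames, fixed = TRUE)))
  }
})

test_that("rate 0 drives classification to 100% correct labels cohort-wide", {
  tree <- hervtrace:::.single_tip_tree("spX")
  plan <- tibble::tibble(group_id = sprintf("g%d", 1:4), node = "spX",
                         class = c("HERVHF", "HERVK", "HUERSP", "HSERVIII"),
                         age_my = 0, missing = "")
  cfg <- simulation_config(seed = 13, tree = tree, segment_length_bp = 40000L,
                           insertions = plan, substitution_rate = 0)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth$insertions
  lay <- coh$layout
  pol <- lay$genes[lay$genes$gene == "pol", ]
  for (i in seq_len(nrow(tr))) {
    g <- coh$genomes[["spX"]][["seg1"]]
    elem <- substr(g, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") elem <- revcomp(elem)
    rt_nt <- substr(elem, pol$start + 1, pol$end)
    expect_equal(classify_element(rt_nt, coh$panels$rt), tr$class[i])
  }
})

test_that("ncRNA truth records respect their containment relations", {
  sg <- simulate_genome(6, classes = "HERVHF", age_my = 3, seed = 14,
                        segment_length_bp = 60000L)
  nc <- sg$truth$ncrna
  ins <- sg$truth$insertions
  for (i in which(nc$relation == "contains")) {
    el <- ins[ins$element_id == nc$element_id[i], ]
    expect_lte(nc$start[i], el$start)
    expect_gte(nc$end[i], el$end)
    expect_equal(nc$strand[i], el$strand)
  }
  opp <- nc[nc$relation == "opposite_strand", ]
  el <- ins[ins$element_id == opp$element_id, ]
  expect_false(opp$strand == el$strand)
})

test_that("over-full segments and unknown nodes raise config errors", {
  tree <- hervtrace:::.single_tip_tree("spX")
  plan <- tibble::tibble(group_id = sprintf("g%d", 1:10), node = "spX",
                         class = "HERVHF", age_my = 0, missing = "")
  cfg <- simulation_config(seed = 15, tree = tree, segment_length_bp = 9000L,
                           insertions = plan)
  expect_error(simulate_cohort(cfg), class = "hervtrace_config_error")
  expect_error(
    simulation_config(seed = 1, insertions = tibble::tibble(
      group_id = "g1", node = "not_a_node", class = "HERVHF", age_my = 0,
      missing = "")),
    class = "hervtrace_config_error")
})

test_that("zero swaps means zero recombination calls downstream", {
  sg <- simulate_genome(4, classes = "HERVHF", age_my = 8, seed = 16,
                        segment_length_bp = 40000L)
  expect_equal(nrow(sg$truth$recombination), 0L)
  rc <- find_recombination(sg$truth$insertions, sg$genomes)
  expect_equal(nrow(rc$calls), 0L)
})
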