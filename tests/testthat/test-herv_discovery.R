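# Discovery pipeline: merging, screening, competitive filtering, LTR
# detection, gene annotation, full-length calling, classification.

test_that("merge_hits applies the strictly-less-than gap rule", {
  iv <- tibble::tibble(contig = "c1", start = c(100L, 900L), end = c(200L, 1000L))
  m <- merge_hits(iv, 1000L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 1000L))

  # gap of exactly 1000 bp stays unmerged
  iv2 <- tibble::tibble(contig = "c1", start = c(100L, 1200L), end = c(200L, 1300L))
  m2 <- merge_hits(iv2, 1000L)
  expect_equal(nrow(m2), 2L)

  # identical coordinates on different contigs are never merged
  iv3 <- tibble::tibble(contig = c("c1", "c2"), start = c(100L, 100L),
                        end = c(200L, 200L))
  expect_equal(nrow(merge_hits(iv3, 1000L)), 2L)

  # empty input, empty output
  expect_equal(nrow(merge_hits(iv[0, ], 1000L)), 0L)
})

test_that("merge_hits is order-invariant and preserves the footprint union", {
  set.seed(201)
  iv <- tibble::tibble(
    contig = sample(c("c1", "c2"), 30, TRUE),
    start = sample.int(50000L, 30))
  iv$end <- iv$start + sample(50:900, 30, TRUE)
  ref <- merge_hits(iv, 1000L)
  for (r in 1:5) {
    perm <- iv[sample.int(nrow(iv)), ]
    expect_equal(merge_hits(perm, 1000L), ref)
  }
  # union preserved: every input interval lies inside some merged interval
  for (i in seq_len(nrow(iv))) {
    hit <- ref[ref$contig == iv$contig[i] & ref$start <= iv$start[i] &
                 ref$end >= iv$end[i], ]
    expect_equal(nrow(hit), 1L)
  }
  # pairwise gaps >= threshold within each contig
  for (ct in unique(ref$contig)) {
    d <- ref[ref$contig == ct, ]
    if (nrow(d) > 1L) expect_true(all(d$start[-1] - d$end[-nrow(d)] >= 1000L))
  }
})

test_that("screen_rt finds embedded RT footprints and nothing in ERV-free sequence", {
  set.seed(202)
  rt <- random_protein(250)
  rt_nt <- back_translate(rt)
  genome <- c(c1 = paste0(random_dna(4000), rt_nt, random_dna(3000),
                          revcomp(rt_nt), random_dna(2000)))
  iv <- screen_rt(genome, c(HERVHF = rt))
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(4000L, 7750L))
  expect_equal(iv$end, c(4750L, 8500L))
  expect_setequal(iv$strand, c("-", "+"))

  # ERV-free control at genomic GC: no footprint passes e <= 1e-5
  empty <- screen_rt(c(c1 = random_dna(30000, gc = 0.41)), c(HERVHF = rt))
  expect_equal(nrow(empty), 0L)
})

test_that("competitive filter assigns best-panel category with conservative ties", {
  set.seed(203)
  erv_rt <- random_protein(250)
  host_prot <- random_protein(300)
  genome <- c(c1 = paste0(random_dna(1000), back_translate(host_prot),
                          random_dna(1000), back_translate(erv_rt),
                          random_dna(1000)))
  iv <- tibble::tibble(contig = "c1",
                       start = c(1000L, 2900L),
                       end = c(1900L, 3650L))
  res <- competitive_filter(iv, genome, c(rtA = erv_rt),
                            c(hostA = host_prot), character())
  expect_equal(res$category, c("host", "erv"))
  expect_equal(res$survives, c(FALSE, TRUE))

  # engineered tie: identical protein in both panels -> erv retained
  res_tie <- competitive_filter(iv[2, ], genome, c(rtA = erv_rt),
                                c(hostA = erv_rt), character())
  expect_equal(res_tie$category, "erv")
  expect_true(res_tie$survives)
  # both panels truly score equally (independent oracle on the translated hit)
  submat <- hervtrace:::.blosum62()
  seqnt <- substr(genome[["c1"]], 2901, 3650)
  fr <- vapply(0:2, function(o)
    oracle_sw_score_aa(erv_rt, hervtrace:::.translate_frame(seqnt, o), submat),
    0.0)
  expect_gt(max(fr), 0)
})

test_that("LTR pair detection recovers planted direct repeats", {
  set.seed(204)
  ltr <- random_dna(400)
  internal <- random_dna(4000)
  # mismatching bases at every repeat boundary, so the local alignment of the
  # two identical copies cannot extend past them and recovery is exact
  genome <- c(c1 = paste0(random_dna(2996), "AAAA", ltr, "CCCC", internal,
                          "GGGG", ltr, "TTTT", random_dna(2996)))
  cand <- tibble::tibble(contig = "c1", start = 4600L, end = 5400L)
  ltrs <- extend_and_find_ltrs(cand, genome)
  expect_false(is.null(ltrs))
  expect_equal(ltrs$ltr5_start, 3000L)
  expect_equal(ltrs$ltr5_end, 3400L)
  expect_equal(ltrs$ltr3_start, 7408L)
  expect_equal(ltrs$ltr3_end, 7808L)
  expect_equal(ltrs$ltr_identity_pct, 100)

  # diverged repeats (~97% pair identity, as for a few-MY-old element):
  # boundaries within +/- 5 bp in nearly all replicates (end mutations can
  # legitimately trim the local alignment by a few bases)
  ok <- 0L
  for (r in 1:6) {
    ltr2 <- mutate_dna(ltr, 12)
    g2 <- c(c1 = paste0(random_dna(3000), ltr, internal, ltr2,
                        random_dna(3000)))
    l2 <- extend_and_find_ltrs(cand, g2)
    expect_false(is.null(l2))
    if (abs(l2$ltr5_start - 3000L) <= 5L && abs(l2$ltr3_end - 7800L) <= 5L)
      ok <- ok + 1L
  }
  expect_gte(ok, 5L)

  # repeat-free flanks: nothing qualifies
  g3 <- c(c1 = random_dna(12000))
  expect_null(extend_and_find_ltrs(cand, g3))
})

test_that("gene annotation merges split hits and enforces the 100-aa rule", {
  set.seed(205)
  gag <- random_protein(450)
  pol <- random_protein(300)
  panels <- list(gag = c(HERVX_gag = gag), pro = character(),
                 pol = c(HERVX_pol = pol), env = character())
  genome <- c(c1 = paste0(random_dna(500), back_translate(gag),
                          random_dna(400), back_translate(pol),
                          random_dna(500)))
  span <- tibble::tibble(contig = "c1", start = 0L,
                         end = nchar(genome[["c1"]]))
  ann <- annotate_genes(span, genome, panels)
  expect_equal(ann$gene, c("gag", "pol"))
  expect_equal(ann$start, c(500L, 2250L))
  expect_true(all(ann$aa_length >= c(450L, 300L) - 1L))

  # an 80-aa fragment does not survive the length rule
  frag <- substr(gag, 1, 80)
  g2 <- c(c1 = paste0(random_dna(500), back_translate(frag), random_dna(500)))
  span2 <- tibble::tibble(contig = "c1", start = 0L, end = nchar(g2[["c1"]]))
  expect_equal(nrow(annotate_genes(span2, g2, panels)), 0L)

  # pol split by a 200-bp insertion merges back into one annotation
  half1 <- substr(pol, 1, 150); half2 <- substr(pol, 151, 300)
  g3 <- c(c1 = paste0(random_dna(500), back_translate(half1), random_dna(200),
                      back_translate(half2), random_dna(500)))
  span3 <- tibble::tibble(contig = "c1", start = 0L, end = nchar(g3[["c1"]]))
  ann3 <- annotate_genes(span3, g3, panels)
  expect_equal(nrow(ann3), 1L)
  expect_equal(ann3$gene, "pol")
  expect_gte(ann3$aa_length, 300L)
})

test_that("full-length call requires RT-bearing pol and canonical gene order", {
  g <- function(genes, starts, has_rt = genes == "pol") {
    tibble::tibble(gene = genes, start = starts, end = starts + 300L,
                   has_rt = has_rt)
  }
  expect_true(call_full_length(g(c("gag", "pol", "env"), c(0L, 1000L, 2000L))))
  expect_false(call_full_length(g(c("env", "pol", "gag"), c(0L, 1000L, 2000L))))
  expect_true(call_full_length(g("pol", 0L)))
  # same genes read on the minus strand reverse their order
  expect_true(call_full_length(g(c("env", "pol", "gag"), c(0L, 1000L, 2000L)),
                               strand = "-"))
  # pol without an RT hit is not full-length
  expect_false(call_full_length(g("pol", 0L, has_rt = FALSE)))
  expect_false(call_full_length(g("pol", 0L)[0, ]))
})

test_that("classification is nearest-RT-reference with threshold and deterministic ties", {
  set.seed(206)
  panel <- c(HERVHF = random_protein(250), HERVK = random_protein(250),
             HUERSP = random_protein(250))
  expect_equal(classify_element(back_translate(panel[["HERVHF"]]), panel),
               "HERVHF")
  # ~10% amino-acid divergence still classifies to the nearest reference
  mut <- mutate_protein(panel[["HERVK"]], 25)
  expect_equal(classify_element(back_translate(mut), panel), "HERVK")
  # confirm HERVK really is the nearest reference with the alignment oracle
  submat <- hervtrace:::.blosum62()
  sc <- vapply(panel, function(p) oracle_sw_score_aa(mut, p, submat), 0.0)
  expect_equal(names(which.max(sc)), "HERVK")
  # far from everything -> Unknown
  expect_equal(classify_element(back_translate(random_protein(250)), panel),
               "Unknown")
  expect_error(classify_element("", panel), class = "hervtrace_input_error")
})

test_that("discovery recovers a planted cohort and is deterministic", {
  sg <- simulate_genome(4, classes = c("HERVHF", "HERVK"), age_my = 5,
                        seed = 31, segment_length_bp = 45000)
  disc <- discover_hervs(sg$genomes[[1]], sg$panels, species = "Homo_sapiens")
  truth <- sg$truth$insertions
  expect_equal(nrow(disc$elements), 4L)
  expect_true(all(disc$elements$is_full_length))
  el <- disc$elements[order(disc$elements$start), ]
  tr <- truth[order(truth$start), ]
  expect_equal(el$classification, tr$class)
  expect_true(all(abs(el$start - tr$start) <= 5L))
  expect_true(all(abs(el$end - tr$end) <= 5L))
  expect_equal(el$strand, tr$strand)
  # stage counts never increase along the filter funnel
  expect_true(all(diff(disc$stage_counts$n) <= 0L))
  # idempotence: an identical rerun reproduces identical element records
  disc2 <- discover_hervs(sg$genomes[[1]], sg$panels, species = "Homo_sapiens")
  expect_equal(disc2$elements, disc$elements)
})

test_that("discovery config files round-trip and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("evalue_cutoff: 1.0e-5", "merge_gap_bp: 1000",
               "extension_bp: 10000"), path)
  cfg <- read_discovery_config(path)
  expect_equal(cfg$extension_bp, 10000L)
  writeLines("not_a_key: 1", path)
  expect_error(read_discovery_config(path), "valid keys")
})
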