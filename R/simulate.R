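# Synthetic cohort simulator.
#
# Simulates orthologous genomic segments evolving along a timed species tree
# with planted proviral insertions (two identical LTRs flanking
# leader-gag-pro-pol-env-trailer internals), per-branch neutral substitution
# (Jukes-Cantor, indels off by default), optional LTR swaps emulating
# inter-element recombination, and ncRNA annotations containing a configured
# fraction of elements. Emits per-species sequences plus truth tables so every
# pipeline stage can be scored against known ground truth.

.SUPERGROUPS <- c("MLLV", "HERVERI", "HERVFRDLIKE", "HEPSI", "HUERSP",
                  "HERVW9", "HERVIPADP", "MER50like", "HERVHF", "HERVK",
                  "HSERVIII")

.DNA <- c("A", "C", "G", "T")

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rand_dna_vec <- function(n, gc = 0.41) {
  sample(.DNA, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.rand_protein <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

# stop-free back-translation with random synonymous codons
.back_translate_vec <- function(protein, codons = .codon_table()) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  unlist(lapply(aa, function(a) {
    strsplit(sample(codons[[a]], 1L), "", fixed = TRUE)[[1L]]
  }), use.names = FALSE)
}

# per-site substitution at probability p, uniform over the three other bases
.mutate_sites <- function(v, p) {
  if (p <= 0) return(v)
  idx <- which(runif(length(v)) < p)
  if (length(idx) == 0L) return(v)
  shift <- sample(1:3, length(idx), replace = TRUE)
  cur <- match(v[idx], .DNA)
  v[idx] <- .DNA[((cur - 1L + shift) %% 4L) + 1L]
  v
}

.revcomp_vec <- function(v) {
  rev(chartr("ACGT", "TGCA", v))
}

#' Default insertion plan of the fixture cohort
#'
#' Twelve orthology groups: two on each internal branch of the fixture tree
#' (29.4 through 6.7 MYA) and one species-private insertion each in
#' *Homo sapiens* and *Macaca mulatta*. One homininae-branch group is marked
#' lost in *Pan troglodytes*, leaving a Homo+Gorilla ortholog pair whose
#' surviving-species MRCA sits at the 9.1 MYA split.
#'
#' @return A tibble with columns `group_id`, `node`, `class`, `age_my`,
#'   `missing` (comma-separated species lost after insertion).
#' @export
default_insertion_plan <- function() {
  tibble(
    group_id = sprintf("g%02d", 1:12),
    node = c("catarrhini", "catarrhini", "hominoidea", "hominoidea",
             "hominidae", "hominidae", "homininae", "homininae",
             "hominini", "hominini", "Homo_sapiens", "Macaca_mulatta"),
    class = c("HERVHF", "HSERVIII", "HERVHF", "HERVK", "HERVHF", "HUERSP",
              "HERVHF", "HERVIPADP", "HERVHF", "HERVW9", "HERVK", "HERVHF"),
    age_my = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 3),
    missing = c("", "", "", "", "", "", "Pan_troglodytes", "", "", "", "", "")
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the cohort simulator. Defaults are the fixture study
#' conditions: the six-primate tree, a 60 kb ancestral segment, the
#' [default_insertion_plan()], 400 bp LTRs, a gag(450aa)-pro(150aa)-pol(850aa,
#' with a 250aa RT core)-env(500aa) internal layout, and a neutral
#' substitution rate of 0.002 substitutions/site/MY (Jukes-Cantor, no indels).
#'
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param tree A timed species tree (`ape::phylo`, branch lengths in MY).
#' @param segment_length_bp Length of the ancestral background segment.
#' @param insertions Insertion plan tibble (see [default_insertion_plan()]).
#' @param ltr_length_bp LTR length; both LTRs are identical at insertion.
#' @param leader_bp,trailer_bp Untranslated spacers inside the provirus.
#' @param gene_lengths_aa Named lengths of gag, pro, pol, env in amino acids.
#' @param rt_aa Length of the RT core embedded in pol.
#' @param substitution_rate Substitutions/site/MY on every branch.
#' @param indel_rate Reserved; indels are off (0) in this model.
#' @param n_recombination_swaps Number of same-species 5' LTR swaps planted
#'   after the leaves are generated.
#' @param swap_divergence_pct Substitution percentage applied to each swapped
#'   LTR copy (emulates post-recombination divergence).
#' @param ncrna_containment_fraction Fraction of the annotated species'
#'   elements fully contained in a same-strand ncRNA.
#' @param n_ncrna_decoys Number of element-free decoy ncRNA features.
#' @param ncrna_species Species annotated with ncRNAs (default: first tip).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              tree = fixture_tree(),
                              segment_length_bp = 60000L,
                              insertions = default_insertion_plan(),
                              ltr_length_bp = 400L,
                              leader_bp = 300L,
                              trailer_bp = 100L,
                              gene_lengths_aa = c(gag = 450L, pro = 150L,
                                                  pol = 850L, env = 500L),
                              rt_aa = 250L,
                              substitution_rate = 0.002,
                              indel_rate = 0,
                              n_recombination_swaps = 0L,
                              swap_divergence_pct = 2,
                              ncrna_containment_fraction = 0.5,
                              n_ncrna_decoys = 4L,
                              ncrna_species = NULL) {
  validate_timed_tree(tree)
  stopifnot(segment_length_bp > 0, ltr_length_bp >= 50,
            substitution_rate >= 0, indel_rate >= 0,
            all(c("gag", "pro", "pol", "env") %in% names(gene_lengths_aa)),
            rt_aa < gene_lengths_aa[["pol"]],
            all(c("group_id", "node", "class", "age_my") %in% names(insertions)))
  if (!"missing" %in% names(insertions)) insertions$missing <- ""
  known <- node_ages(tree)$label
  bad <- setdiff(insertions$node, known)
  if (length(bad) > 0L) {
    abort(sprintf("insertion node(s) not in tree: %s",
                  paste(bad, collapse = ", ")), class = "hervtrace_config_error")
  }
  structure(list(
    seed = as.integer(seed), tree = tree,
    segment_length_bp = as.integer(segment_length_bp),
    insertions = as_tibble(insertions),
    ltr_length_bp = as.integer(ltr_length_bp),
    leader_bp = as.integer(leader_bp), trailer_bp = as.integer(trailer_bp),
    gene_lengths_aa = gene_lengths_aa, rt_aa = as.integer(rt_aa),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    n_recombination_swaps = as.integer(n_recombination_swaps),
    swap_divergence_pct = swap_divergence_pct,
    ncrna_containment_fraction = ncrna_containment_fraction,
    n_ncrna_decoys = as.integer(n_ncrna_decoys),
    ncrna_species = ncrna_species
  ), class = "simulation_config")
}

# ---- reference proteome -----------------------------------------------------
# Generated first under the config seed so emit_reference_panels() reproduces
# the exact panels without running the full simulation.

.gen_proteome <- function(cfg) {
  gl <- cfg$gene_lengths_aa
  codons <- .codon_table()
  classes <- list()
  for (cl in .SUPERGROUPS) {
    rt <- .rand_protein(cfg$rt_aa)
    pol_n <- .rand_protein((gl[["pol"]] - cfg$rt_aa) %/% 2L)
    pol_c <- .rand_protein(gl[["pol"]] - cfg$rt_aa - nchar(pol_n))
    prot <- list(
      gag = .rand_protein(gl[["gag"]]),
      pro = .rand_protein(gl[["pro"]]),
      pol = paste0(pol_n, rt, pol_c),
      env = .rand_protein(gl[["env"]]),
      rt = rt)
    rt_nt_offset <- cfg$leader_bp + 3L * (gl[["gag"]] + gl[["pro"]] +
                                            nchar(pol_n))
    classes[[cl]] <- list(proteins = prot,
                          rt_offset = rt_nt_offset,      # from internal start
                          rt_len_nt = 3L * cfg$rt_aa)
  }
  host <- setNames(lapply(sample(300:600, 8, replace = TRUE), .rand_protein),
                   paste0("host_", 1:8))
  virus <- setNames(lapply(sample(300:500, 5, replace = TRUE), .rand_protein),
                    paste0("exo_virus_", 1:5))
  list(classes = classes,
       host = unlist(host), other_virus = unlist(virus))
}

.panels_from_proteome <- function(prot) {
  cls <- prot$classes
  list(
    rt = vapply(cls, function(x) x$proteins$rt, ""),
    gag = setNames(vapply(cls, function(x) x$proteins$gag, ""),
                   paste0(names(cls), "_gag")),
    pro = setNames(vapply(cls, function(x) x$proteins$pro, ""),
                   paste0(names(cls), "_pro")),
    pol = setNames(vapply(cls, function(x) x$proteins$pol, ""),
                   paste0(names(cls), "_pol")),
    env = setNames(vapply(cls, function(x) x$proteins$env, ""),
                   paste0(names(cls), "_env")),
    host = prot$host,
    other_virus = prot$other_virus)
}

#' Reference protein panels of a simulation
#'
#' Regenerates (deterministically, from the config seed) the protein panels
#' matching the planted elements: the labelled RT panel used for screening and
#' classification, per-gene panels (gag/pro/pol/env) for each of the 11
#' supergroups, and host / exogenous-virus decoys for the competitive filter.
#'
#' @param cfg A [simulation_config()].
#' @return A named list of named character vectors (`rt`, `gag`, `pro`,
#'   `pol`, `env`, `host`, `other_virus`).
#' @export
emit_reference_panels <- function(cfg) {
  .with_seed(cfg$seed, .panels_from_proteome(.gen_proteome(cfg)))
}

# ---- element construction ---------------------------------------------------

.element_layout <- function(cfg) {
  gl <- cfg$gene_lengths_aa
  L <- cfg$ltr_length_bp
  gene_bp <- 3L * c(gl[["gag"]], gl[["pro"]], gl[["pol"]], gl[["env"]])
  total <- 2L * L + cfg$leader_bp + sum(gene_bp) + cfg$trailer_bp
  starts <- L + cfg$leader_bp + cumsum(c(0L, gene_bp[-4L]))
  list(total = total, ltr_len = L,
       genes = tibble(gene = c("gag", "pro", "pol", "env"),
                      start = starts, end = starts + gene_bp))
}

# Build one fresh element instance (element-strand orientation, + sense).
# Each insertion gets its own LTR, spacers and synonymous back-translation,
# so copies of a family share proteins but diverge at silent sites -- as real
# same-family proviruses do.
.new_element_vec <- function(class, proteome, cfg) {
  cls <- proteome$classes[[class]]
  codons <- .codon_table()
  ltr <- .rand_dna_vec(cfg$ltr_length_bp)
  c(ltr, .rand_dna_vec(cfg$leader_bp),
    .back_translate_vec(cls$proteins$gag, codons),
    .back_translate_vec(cls$proteins$pro, codons),
    .back_translate_vec(cls$proteins$pol, codons),
    .back_translate_vec(cls$proteins$env, codons),
    .rand_dna_vec(cfg$trailer_bp), ltr)
}

# sample an insertion point outside existing features (with buffer), away
# from segment edges
.sample_position <- function(seq_len, feats, buffer = 2500L, edge = 3000L) {
  occ <- IRanges::IRanges(start = integer(0), width = integer(0))
  if (nrow(feats) > 0L) {
    occ <- IRanges::IRanges(start = pmax(1L, feats$start + 1L - buffer),
                            end = pmin(seq_len, feats$end + buffer))
  }
  allowed <- IRanges::setdiff(IRanges::IRanges(edge + 1L, seq_len - edge),
                              IRanges::reduce(occ))
  if (length(allowed) == 0L || sum(IRanges::width(allowed)) < 1L) {
    abort("no room left for another insertion; reduce n or enlarge the segment",
          class = "hervtrace_config_error")
  }
  w <- IRanges::width(allowed)
  g <- sample.int(length(w), 1L, prob = w)
  IRanges::start(allowed)[g] - 1L + sample.int(w[g], 1L)  # 0-based
}

.insert_element <- function(state, group_id, class, proteome, cfg, age_my) {
  elem <- .new_element_vec(class, proteome, cfg)
  if (age_my > 0) elem <- .mutate_sites(elem, cfg$substitution_rate * age_my)
  strand <- sample(c("+", "-"), 1L)
  placed <- if (strand == "+") elem else .revcomp_vec(elem)
  pos <- .sample_position(length(state$seq), state$feats)
  len <- length(placed)
  state$seq <- c(state$seq[seq_len(pos)], placed,
                 if (pos < length(state$seq))
                   state$seq[(pos + 1L):length(state$seq)])
  if (nrow(state$feats) > 0L) {
    shift <- state$feats$start >= pos
    state$feats$start[shift] <- state$feats$start[shift] + len
    state$feats$end[shift] <- state$feats$end[shift] + len
  }
  state$feats <- bind_rows(state$feats,
                           tibble(group_id = group_id, class = class,
                                  start = pos, end = pos + len,
                                  strand = strand))
  state
}

.excise_feature <- function(state, row) {
  s <- state$feats$start[row]; e <- state$feats$end[row]
  state$seq <- c(state$seq[seq_len(s)],
                 if (e < length(state$seq)) state$seq[(e + 1L):length(state$seq)])
  state$feats <- state$feats[-row, , drop = FALSE]
  shift <- state$feats$start >= e
  state$feats$start[shift] <- state$feats$start[shift] - (e - s)
  state$feats$end[shift] <- state$feats$end[shift] - (e - s)
  state
}

# ---- cohort simulation ------------------------------------------------------

#' Simulate a multi-species cohort with known ground truth
#'
#' Evolves an ancestral segment down the configured species tree. An insertion
#' assigned to node N is planted once, in the ancestral sequence at N, and is
#' therefore present at orthologous positions (identical flanking context) in
#' all and only N's descendant leaves -- except leaves listed in its `missing`
#' field, where the element is excised (lineage loss). Sequences then diverge
#' independently along each branch at the configured substitution rate, so the
#' expected leaf-leaf divergence of any orthologous region is
#' `2 * rate * t(MRCA)`.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `herv_cohort`: list with `genomes` (named list
#'   of single-contig named character vectors), `truth` (tibbles
#'   `insertions`, `recombination`, `ncrna`), `panels`
#'   (see [emit_reference_panels()]), `layout`, and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    proteome <- .gen_proteome(cfg)
    tree <- cfg$tree
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    ages <- node_ages(tree)
    ins <- cfg$insertions
    ins$node_num <- vapply(ins$node, function(l) .node_by_label(tree, l), 0L)

    leaf_states <- vector("list", ntip)
    recurse <- function(node, state) {
      for (k in which(ins$node_num == node)) {
        state <- .insert_element(state, ins$group_id[k], ins$class[k],
                                 proteome, cfg, ins$age_my[k])
      }
      if (node <= ntip) {
        sp <- tree$tip.label[node]
        lost <- ins$group_id[vapply(strsplit(ins$missing, ","), function(m)
          sp %in% trimws(m), TRUE)]
        for (g in lost) {
          row <- which(state$feats$group_id == g)
          if (length(row) == 1L) state <- .excise_feature(state, row)
        }
        leaf_states[[node]] <<- state
        return(invisible())
      }
      kids <- tree$edge[tree$edge[, 1L] == node, 2L]
      for (child in kids) {
        elen <- tree$edge.length[which(tree$edge[, 1L] == node &
                                         tree$edge[, 2L] == child)]
        child_state <- state
        child_state$seq <- .mutate_sites(child_state$seq,
                                         cfg$substitution_rate * elen)
        recurse(child, child_state)
      }
      invisible()
    }
    root_state <- list(seq = .rand_dna_vec(cfg$segment_length_bp),
                       feats = tibble(group_id = character(),
                                      class = character(), start = integer(),
                                      end = integer(), strand = character()))
    recurse(root, root_state)

    layout <- .element_layout(cfg)
    genomes <- list()
    truth_rows <- list()
    for (i in seq_len(ntip)) {
      sp <- tree$tip.label[i]
      st <- leaf_states[[i]]
      genomes[[sp]] <- setNames(paste(st$seq, collapse = ""), "seg1")
      if (nrow(st$feats) > 0L) {
        f <- st$feats
        L <- layout$ltr_len
        truth_rows[[sp]] <- f %>%
          mutate(species = sp, contig = "seg1",
                 element_id = sprintf("%s_%s_%d-%d-%s", sp, .data$contig,
                                      .data$start + 1L, .data$end, .data$class),
                 ltr5_start = ifelse(.data$strand == "+", .data$start, .data$end - L),
                 ltr5_end = ifelse(.data$strand == "+", .data$start + L, .data$end),
                 ltr3_start = ifelse(.data$strand == "+", .data$end - L, .data$start),
                 ltr3_end = ifelse(.data$strand == "+", .data$end, .data$start + L))
      }
    }
    truth_ins <- bind_rows(truth_rows) %>%
      left_join(select(ins, "group_id", "node"), by = "group_id") %>%
      select("group_id", "node", "class", "species", "contig", "element_id",
             "start", "end", "strand", "ltr5_start", "ltr5_end",
             "ltr3_start", "ltr3_end")

    swaps <- .plant_swaps(genomes, truth_ins, cfg)
    genomes <- swaps$genomes
    truth_rec <- swaps$truth

    ncr <- .plant_ncrna(truth_ins, genomes, cfg)

    structure(list(genomes = genomes,
                   truth = list(insertions = truth_ins,
                                recombination = truth_rec,
                                ncrna = ncr),
                   panels = .panels_from_proteome(proteome),
                   layout = layout, config = cfg),
              class = "herv_cohort")
  })
}

# swap 5' LTR sequences between pairs of same-species same-class elements
.plant_swaps <- function(genomes, truth_ins, cfg) {
  empty <- tibble(species = character(), element_1 = character(),
                  element_2 = character(), swapped_side = character())
  n <- cfg$n_recombination_swaps
  if (n == 0L || nrow(truth_ins) == 0L) {
    return(list(genomes = genomes, truth = empty))
  }
  strata <- truth_ins %>% group_by(.data$species, .data$class) %>%
    filter(n() >= 2L) %>% ungroup()
  pool <- strata %>% distinct(.data$species, .data$class)
  if (nrow(pool) == 0L) abort("no stratum with >= 2 same-class elements",
                              class = "hervtrace_config_error")
  rows <- list()
  used <- character(0)
  stratum_i <- rep(seq_len(nrow(pool)), length.out = max(n, nrow(pool)))
  planted <- 0L
  for (si in stratum_i) {
    if (planted >= n) break
    st <- strata %>% filter(.data$species == pool$species[si],
                            .data$class == pool$class[si],
                            !(.data$element_id %in% used))
    if (nrow(st) < 2L) next
    pair <- st[sample.int(nrow(st), 2L), ]
    g <- genomes[[pair$species[1L]]]
    seqv <- strsplit(g[["seg1"]], "", fixed = TRUE)[[1L]]
    get_ltr5 <- function(r) {
      v <- seqv[(r$ltr5_start + 1L):r$ltr5_end]
      if (r$strand == "-") .revcomp_vec(v) else v
    }
    put_ltr5 <- function(r, v) {
      if (r$strand == "-") v <- .revcomp_vec(v)
      seqv[(r$ltr5_start + 1L):r$ltr5_end] <<- v
    }
    a <- pair[1L, ]; b <- pair[2L, ]
    la <- get_ltr5(a); lb <- get_ltr5(b)
    pmut <- cfg$swap_divergence_pct / 100
    put_ltr5(a, .mutate_sites(lb, pmut))
    put_ltr5(b, .mutate_sites(la, pmut))
    genomes[[pair$species[1L]]]["seg1"] <- paste(seqv, collapse = "")
    used <- c(used, pair$element_id)
    rows[[length(rows) + 1L]] <- tibble(species = a$species,
                                        element_1 = a$element_id,
                                        element_2 = b$element_id,
                                        swapped_side = "5p")
    planted <- planted + 1L
  }
  if (planted < n) {
    abort(sprintf("could only plant %d of %d requested swaps", planted, n),
          class = "hervtrace_config_error")
  }
  list(genomes = genomes, truth = bind_rows(empty, bind_rows(rows)))
}

# ncRNA features: same-strand containers for a fraction of one species'
# elements, one opposite-strand container (strand-rule control), and
# element-free decoys
.plant_ncrna <- function(truth_ins, genomes, cfg) {
  empty <- tibble(ncrna_id = character(), species = character(),
                  contig = character(), start = integer(), end = integer(),
                  strand = character(), element_id = character(),
                  relation = character())
  sp <- cfg$ncrna_species
  if (is.null(sp)) sp <- names(genomes)[1L]
  elems <- truth_ins %>% filter(.data$species == sp)
  glen <- nchar(genomes[[sp]][["seg1"]])
  rows <- list()
  k <- 0L
  if (nrow(elems) > 0L && cfg$ncrna_containment_fraction > 0) {
    n_cont <- max(1L, round(cfg$ncrna_containment_fraction * nrow(elems)))
    picked <- elems[sample.int(nrow(elems), n_cont), ]
    for (j in seq_len(nrow(picked))) {
      r <- picked[j, ]
      k <- k + 1L
      rows[[k]] <- tibble(
        ncrna_id = sprintf("SIMNC%04d", k), species = sp, contig = "seg1",
        start = max(0L, r$start - sample(200:2000, 1L)),
        end = min(glen, r$end + sample(200:2000, 1L)),
        strand = r$strand, element_id = r$element_id, relation = "contains")
    }
    # opposite-strand container: overlaps fully but must never pair
    r <- elems[sample.int(nrow(elems), 1L), ]
    k <- k + 1L
    rows[[k]] <- tibble(
      ncrna_id = sprintf("SIMNC%04d", k), species = sp, contig = "seg1",
      start = max(0L, r$start - 300L), end = min(glen, r$end + 300L),
      strand = if (r$strand == "+") "-" else "+",
      element_id = r$element_id, relation = "opposite_strand")
  }
  if (cfg$n_ncrna_decoys > 0L) {
    occ <- IRanges::IRanges(elems$start + 1L, elems$end)
    free <- IRanges::setdiff(IRanges::IRanges(1L, glen), occ)
    free <- free[IRanges::width(free) > 4000L]
    for (d in seq_len(cfg$n_ncrna_decoys)) {
      if (length(free) == 0L) break
      g <- sample.int(length(free), 1L)
      w <- sample(500:3000, 1L)
      s0 <- IRanges::start(free)[g] - 1L +
        sample.int(IRanges::width(free)[g] - w, 1L)
      k <- k + 1L
      rows[[k]] <- tibble(ncrna_id = sprintf("SIMNC%04d", k), species = sp,
                          contig = "seg1", start = s0, end = s0 + w,
                          strand = sample(c("+", "-"), 1L),
                          element_id = NA_character_, relation = "none")
    }
  }
  bind_rows(empty, bind_rows(rows))
}

#' Simulate a single genome with planted elements
#'
#' Single-species convenience wrapper: plants `n_elements` proviruses (classes
#' cycled from `classes`) into one random segment, each aged `age_my` million
#' years (twin-LTR divergence accrues at `2 * rate * age`).
#'
#' @param n_elements Number of planted full-length elements.
#' @param classes Supergroup labels to cycle through.
#' @param age_my Element age(s) in MY, recycled across elements.
#' @param species Species label used in identifiers.
#' @param segment_length_bp Background segment length.
#' @param n_recombination_swaps,swap_divergence_pct See [simulation_config()].
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `herv_cohort` object with a single genome.
#' @export
simulate_genome <- function(n_elements, classes = "HERVHF", age_my = 5,
                            species = "Homo_sapiens",
                            segment_length_bp = 150000L,
                            n_recombination_swaps = 0L,
                            swap_divergence_pct = 2,
                            seed = 1L, ...) {
  plan <- tibble(
    group_id = sprintf("e%03d", seq_len(n_elements)),
    node = species,
    class = rep_len(classes, n_elements),
    age_my = rep_len(age_my, n_elements),
    missing = "")
  tree <- .single_tip_tree(species)
  cfg <- simulation_config(seed = seed, tree = tree,
                           segment_length_bp = segment_length_bp,
                           insertions = plan,
                           n_recombination_swaps = n_recombination_swaps,
                           swap_divergence_pct = swap_divergence_pct, ...)
  simulate_cohort(cfg)
}

# a rooted one-tip tree (zero-length stem) for single-genome simulations
.single_tip_tree <- function(species) {
  tree <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = species,
               Nnode = 1L, edge.length = 0, node.label = "root")
  class(tree) <- "phylo"
  tree
}

#' @export
print.herv_cohort <- function(x, ...) {
  cat(sprintf("<herv_cohort: %d genome(s), %d planted element(s), %d swap(s), %d ncRNA feature(s)>\n",
              length(x$genomes), nrow(x$truth$insertions),
              nrow(x$truth$recombination), nrow(x$truth$ncrna)))
  invisible(x)
}
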