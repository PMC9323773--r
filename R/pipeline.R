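# Pipeline driver: file-based subcommands chaining the analysis stages, with
# a reproducible run manifest. A thin command-line wrapper around this
# function ships in inst/scripts/hervtrace.R.

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

.require_inputs <- function(inputs, keys) {
  for (k in keys) {
    p <- inputs[[k]]
    if (is.null(p)) {
      abort(sprintf("missing required input '%s'", k),
            class = "hervtrace_input_error")
    }
    if (!all(file.exists(p))) {
      abort(sprintf("input file not found: %s",
                    paste(p[!file.exists(p)], collapse = ", ")),
            class = "hervtrace_input_error")
    }
  }
}

.manifest <- function(command, seed, inputs, config, stage_counts, out_dir) {
  files <- as.character(unlist(inputs, use.names = FALSE))
  files <- files[!is.na(files) & file.exists(files)]
  files <- files[!dir.exists(files)]
  manifest <- list(
    command = command,
    seed = as.integer(seed),
    inputs = as.list(unlist(inputs)),
    input_md5 = as.list(tools::md5sum(files)),
    config = config,
    stage_counts = stage_counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  manifest
}

.read_genomes_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (length(paths) == 0L) {
    abort(sprintf("no FASTA files in %s", dir), class = "hervtrace_input_error")
  }
  setNames(lapply(paths, read_fasta_dna),
           sub("\\.(fa|fasta)$", "", basename(paths)))
}

# Elements written by `discover`: full TSV (preferred) or BED6 (coordinates,
# id, strand; species and classification recovered from the element name).
.read_elements_file <- function(path, species_names) {
  first <- readLines(path, n = 1L)
  if (grepl("^element_id\t", first)) {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("contig", "start", "end", "element_id", "score",
                       "strand")
  cls <- stringr::str_match(bed$element_id, "-([A-Za-z0-9]+)$")[, 2L]
  sp <- rep(NA_character_, nrow(bed))
  for (s in species_names) {
    sp[startsWith(bed$element_id, paste0(s, "_"))] <- s
  }
  if (anyNA(sp)) {
    abort("could not match element names to any genome species",
          class = "hervtrace_input_error")
  }
  tibble(element_id = bed$element_id, species = sp, contig = bed$contig,
         start = as.integer(bed$start), end = as.integer(bed$end),
         strand = bed$strand,
         classification = ifelse(is.na(cls), "Unknown", cls))
}

#' Run one pipeline stage
#'
#' File-in, file-out driver for the analysis stages. Every run writes its
#' artifacts plus a `manifest.yml` (command, seed, input checksums, config
#' snapshot, stage counts) into `out_dir`; identical inputs and seed give
#' byte-identical outputs.
#'
#' Subcommands and their required `inputs` entries:
#' \describe{
#'   \item{simulate}{optional `config` (simulation YAML); writes per-species
#'     genome FASTAs under `genomes/`, protein panels under `panels/`, and
#'     the truth tables.}
#'   \item{discover}{`genome` (FASTA), `panels` (directory with rt/gag/pro/
#'     pol/env/host/other_virus FASTAs); writes `elements.tsv`,
#'     `elements.bed`, `elements.gtf`, `stage_counts.tsv`.}
#'   \item{transmit}{`elements` (TSV or BED), `genomes` (directory),
#'     `tree` (newick); writes `pairs.tsv`, `events.tsv`, `per_node.tsv`,
#'     `per_species.tsv`.}
#'   \item{recombine}{`elements` (TSV with LTR coordinates), `genomes`
#'     (directory); writes `recombination_calls.tsv`, `nonclustered.tsv`,
#'     `recombination_summary.tsv`.}
#'   \item{ncrna}{`table` (annotation TSV); writes the validated table and
#'     per-chromosome / per-class summaries.}
#'   \item{report}{summarises whatever stage outputs exist in `out_dir` into
#'     `report.pdf` and `report_counts.tsv`.}
#' }
#'
#' @param subcommand One of `simulate`, `discover`, `transmit`, `recombine`,
#'   `ncrna`, `report`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing any randomness.
#' @param inputs Named list of input paths (see above).
#' @param config Optional path to a YAML configuration for the stage.
#' @param species Species label for `discover`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "discover", "transmit",
                                        "recombine", "ncrna", "report"),
                         out_dir, seed = 1L, inputs = list(), config = NULL,
                         species = "unknown_species") {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- tibble(stage = character(), n = integer())

  if (subcommand == "simulate") {
    if (!is.null(config)) {
      .require_inputs(list(config = config), "config")
      vals <- yaml::read_yaml(config)
      if (!is.null(vals$tree)) vals$tree <- read_timed_tree(vals$tree)
      if (!is.null(vals$insertions)) {
        vals$insertions <- as_tibble(as.data.frame(
          lapply(purrr::transpose(vals$insertions), unlist)))
      }
      vals$seed <- seed
      cfg <- do.call(simulation_config, vals)
    } else {
      cfg <- simulation_config(seed = seed)
    }
    coh <- simulate_cohort(cfg)
    gdir <- file.path(out_dir, "genomes")
    pdir <- file.path(out_dir, "panels")
    dir.create(gdir, showWarnings = FALSE)
    dir.create(pdir, showWarnings = FALSE)
    for (sp in names(coh$genomes)) {
      write_fasta(coh$genomes[[sp]], file.path(gdir, paste0(sp, ".fasta")))
    }
    for (pn in names(coh$panels)) {
      write_fasta(coh$panels[[pn]], file.path(pdir, paste0(pn, ".fasta")),
                  type = "aa")
    }
    ape::write.tree(cfg$tree, file.path(out_dir, "tree.nwk"))
    .write_tsv(coh$truth$insertions, file.path(out_dir, "truth_insertions.tsv"))
    .write_tsv(coh$truth$recombination,
               file.path(out_dir, "truth_recombination.tsv"))
    .write_tsv(coh$truth$ncrna, file.path(out_dir, "truth_ncrna.tsv"))
    counts <- tibble(stage = c("species", "insertions", "swaps", "ncrna"),
                     n = c(length(coh$genomes), nrow(coh$truth$insertions),
                           nrow(coh$truth$recombination),
                           nrow(coh$truth$ncrna)))
  }

  if (subcommand == "discover") {
    .require_inputs(inputs, c("genome", "panels"))
    genome <- read_fasta_dna(inputs$genome)
    panel_files <- list.files(inputs$panels, pattern = "\\.(fa|fasta)$",
                              full.names = TRUE)
    panels <- setNames(lapply(panel_files, read_fasta_aa),
                       sub("\\.(fa|fasta)$", "", basename(panel_files)))
    cfg <- if (is.null(config)) discovery_config()
           else read_discovery_config(config)
    disc <- discover_hervs(genome, panels, cfg, species = species)
    .write_tsv(disc$elements %>% select(-"genes"),
               file.path(out_dir, "elements.tsv"))
    write_elements_bed(disc, file.path(out_dir, "elements.bed"))
    write_elements_gtf(disc, file.path(out_dir, "elements.gtf"))
    .write_tsv(disc$stage_counts, file.path(out_dir, "stage_counts.tsv"))
    counts <- disc$stage_counts
  }

  if (subcommand == "transmit") {
    .require_inputs(inputs, c("elements", "genomes", "tree"))
    genomes <- .read_genomes_dir(inputs$genomes)
    elements <- .read_elements_file(inputs$elements, names(genomes))
    tree <- read_timed_tree(inputs$tree)
    vt <- find_transmission_events(elements, genomes, tree)
    s <- summarize_events(vt)
    .write_tsv(vt$pairs, file.path(out_dir, "pairs.tsv"))
    .write_tsv(vt$events, file.path(out_dir, "events.tsv"))
    .write_tsv(s$per_node, file.path(out_dir, "per_node.tsv"))
    .write_tsv(s$per_species, file.path(out_dir, "per_species.tsv"))
    counts <- tibble(stage = c("pairs_tested", "pairs_accepted", "events"),
                     n = c(nrow(vt$pairs), sum(vt$pairs$accepted),
                           nrow(vt$events)))
  }

  if (subcommand == "recombine") {
    .require_inputs(inputs, c("elements", "genomes"))
    genomes <- .read_genomes_dir(inputs$genomes)
    elements <- .read_elements_file(inputs$elements, names(genomes))
    rc <- find_recombination(elements, genomes)
    .write_tsv(rc$calls, file.path(out_dir, "recombination_calls.tsv"))
    .write_tsv(rc$nonclustered, file.path(out_dir, "nonclustered.tsv"))
    .write_tsv(rc$summary, file.path(out_dir, "recombination_summary.tsv"))
    counts <- tibble(stage = c("elements", "nonclustered", "calls"),
                     n = c(nrow(rc$nonclustered),
                           sum(rc$nonclustered$nonclustered),
                           nrow(rc$calls)))
  }

  if (subcommand == "ncrna") {
    .require_inputs(inputs, "table")
    tbl <- validate_ncrna_table(read_herv_ncrna_table(inputs$table))
    .write_tsv(tbl, file.path(out_dir, "ncrna_table_validated.tsv"))
    .write_tsv(summarize_by_chromosome(tbl),
               file.path(out_dir, "ncrna_by_chromosome.tsv"))
    .write_tsv(summarize_by_class(tbl),
               file.path(out_dir, "ncrna_by_class.tsv"))
    counts <- tibble(stage = c("records", "consistent"),
                     n = c(nrow(tbl), sum(tbl$consistent)))
  }

  if (subcommand == "report") {
    plots <- list()
    path <- function(f) file.path(out_dir, f)
    if (file.exists(path("elements.tsv"))) {
      el <- readr::read_tsv(path("elements.tsv"), show_col_types = FALSE)
      plots$classification <- plot_classification(el)
      counts <- bind_rows(counts, tibble(stage = "elements", n = nrow(el)))
    }
    if (file.exists(path("per_node.tsv"))) {
      pn <- readr::read_tsv(path("per_node.tsv"), show_col_types = FALSE)
      counts <- bind_rows(counts,
                          tibble(stage = "events", n = sum(pn$n_events)))
    }
    if (file.exists(path("recombination_summary.tsv"))) {
      rs <- readr::read_tsv(path("recombination_summary.tsv"),
                            show_col_types = FALSE)
      plots$recombination <- plot_recombination_summary(rs)
      counts <- bind_rows(counts, tibble(stage = "recombination_involved",
                                         n = sum(rs$n_elements)))
    }
    if (file.exists(path("ncrna_table_validated.tsv"))) {
      tbl <- readr::read_tsv(path("ncrna_table_validated.tsv"),
                             show_col_types = FALSE)
      plots$ncrna <- plot_ncrna_chromosomes(tbl)
      counts <- bind_rows(counts,
                          tibble(stage = "ncrna_records", n = nrow(tbl)))
    }
    .write_tsv(counts, path("report_counts.tsv"))
    if (length(plots) > 0L) {
      grDevices::pdf(path("report.pdf"), width = 7, height = 5)
      for (p in plots) print(p)
      grDevices::dev.off()
    }
  }

  invisible(.manifest(subcommand, seed, inputs,
                      if (is.null(config)) list() else config,
                      counts, out_dir))
}
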