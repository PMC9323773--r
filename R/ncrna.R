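# ncRNA co-option calling: strand-aware full-containment intersection and
# the per-chromosome / per-supergroup summaries of the annotated table.

#' Read a HERV/ncRNA annotation table
#'
#' Parses the packaged annotation table (or any file in the same dialect):
#' tab-separated columns `Chromosome`, `Start`, `End`, `HERVname`, `Strand`,
#' `Related-ncRNA`, with 1-based inclusive coordinates (genome-browser
#' convention) converted to 0-based half-open on read. The element's own
#' coordinates and supergroup are parsed from `HERVname`
#' (`species_chrom_start-end-CLASS`).
#'
#' @param path Path to the TSV; defaults to the packaged table.
#' @return A tibble with one row per record: ncRNA interval (`start`, `end`),
#'   HERV interval (`herv_start`, `herv_end`), shared `strand`,
#'   `classification`, `chromosome`, `herv_id`, `ncrna_id`.
#' @export
read_herv_ncrna_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "herv_ncrna_table.tsv",
                        package = "hervtrace", mustWork = TRUE)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expected <- c("Chromosome", "Start", "End", "HERVname", "Strand",
                "Related-ncRNA")
  if (!all(expected %in% names(raw))) {
    abort(sprintf("annotation table must have columns: %s",
                  paste(expected, collapse = ", ")),
          class = "hervtrace_input_error")
  }
  coords <- stringr::str_match(raw$HERVname,
                               "_([0-9]+)-([0-9]+)-([A-Za-z0-9]+)$")
  cls <- coords[, 4L]
  bad <- is.na(cls)
  if (any(bad)) {
    warn(sprintf("%d record(s) with unparseable element names counted as Unknown",
                 sum(bad)))
    cls[bad] <- "Unknown"
  }
  tibble(
    chromosome = raw$Chromosome,
    start = as.integer(raw$Start) - 1L,      # 1-based inclusive -> half-open
    end = as.integer(raw$End),
    herv_id = raw$HERVname,
    strand = raw$Strand,
    ncrna_id = raw$`Related-ncRNA`,
    herv_start = as.integer(coords[, 2L]) - 1L,
    herv_end = as.integer(coords[, 3L]),
    classification = cls)
}

#' Validate printed intervals of an annotation table
#'
#' Flags records whose printed ncRNA span and element span do not physically
#' overlap (they are retained for the summaries -- the table is an annotation
#' record, not an intersection result -- but cannot satisfy the containment
#' contract).
#'
#' @param tbl A tibble from [read_herv_ncrna_table()].
#' @return `tbl` with a logical `consistent` column.
#' @export
validate_ncrna_table <- function(tbl) {
  tbl %>%
    mutate(consistent = pmin(.data$end, .data$herv_end) -
             pmax(.data$start, .data$herv_start) >= 1L)
}

#' Strand-aware full-containment intersection
#'
#' Reports feature pairs on the same contig and strand that overlap by at
#' least 1 bp with at least one feature 100% contained in the other (its
#' overlap coverage is exactly 100%). The containment rule is evaluated on
#' the features' full genomic spans.
#'
#' @param hervs,ncrnas Feature tibbles with `id`, `contig`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`/`"-"`; strandless features are
#'   an error).
#' @return Tibble of pairs: `herv_id`, `ncrna_id`, `overlap_bp`,
#'   `herv_cov_pct`, `ncrna_cov_pct`, `strand`.
#' @export
containment_intersect <- function(hervs, ncrnas) {
  for (df in list(hervs, ncrnas)) {
    if (!all(c("id", "contig", "start", "end", "strand") %in% names(df))) {
      abort("feature sets need id, contig, start, end, strand columns",
            class = "hervtrace_input_error")
    }
    if (any(!df$strand %in% c("+", "-"))) {
      abort("strand-aware intersection requires every feature stranded (+/-)",
            class = "hervtrace_input_error")
    }
  }
  if (nrow(hervs) == 0L || nrow(ncrnas) == 0L) {
    return(tibble(herv_id = character(), ncrna_id = character(),
                  overlap_bp = integer(), herv_cov_pct = double(),
                  ncrna_cov_pct = double(), strand = character()))
  }
  gr_h <- GenomicRanges::GRanges(hervs$contig,
                                 IRanges::IRanges(hervs$start + 1L, hervs$end),
                                 strand = hervs$strand)
  gr_n <- GenomicRanges::GRanges(ncrnas$contig,
                                 IRanges::IRanges(ncrnas$start + 1L, ncrnas$end),
                                 strand = ncrnas$strand)
  ov <- GenomicRanges::findOverlaps(gr_h, gr_n, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  inter <- IRanges::pintersect(IRanges::ranges(gr_h)[qh],
                               IRanges::ranges(gr_n)[sh])
  overlap_bp <- IRanges::width(inter)
  herv_w <- hervs$end - hervs$start
  ncrna_w <- ncrnas$end - ncrnas$start
  herv_cov <- 100 * overlap_bp / herv_w[qh]
  ncrna_cov <- 100 * overlap_bp / ncrna_w[sh]
  keep <- overlap_bp >= 1L & (herv_cov == 100 | ncrna_cov == 100)
  tibble(herv_id = hervs$id[qh][keep],
         ncrna_id = ncrnas$id[sh][keep],
         overlap_bp = as.integer(overlap_bp[keep]),
         herv_cov_pct = herv_cov[keep],
         ncrna_cov_pct = ncrna_cov[keep],
         strand = hervs$strand[qh][keep])
}

#' Per-chromosome counts of annotated elements
#'
#' @param tbl Annotation tibble (needs `chromosome` and `herv_id`).
#' @return Tibble `chromosome`, `n` sorted by descending count.
#' @export
summarize_by_chromosome <- function(tbl) {
  if (nrow(tbl) == 0L) return(tibble(chromosome = character(), n = integer()))
  tbl %>%
    distinct(.data$chromosome, .data$herv_id) %>%
    count(.data$chromosome, name = "n") %>%
    arrange(desc(.data$n), .data$chromosome)
}

#' Per-supergroup counts of annotated elements
#'
#' The supergroup is parsed from the element-name suffix after the final
#' hyphen; unparseable names count under `Unknown` (with a warning at read
#' time).
#'
#' @param tbl Annotation tibble (needs `herv_id`; `classification` is parsed
#'   from names when absent).
#' @return Tibble `classification`, `n`; counts sum to the record count.
#' @export
summarize_by_class <- function(tbl) {
  if (nrow(tbl) == 0L) {
    return(tibble(classification = character(), n = integer()))
  }
  if (!"classification" %in% names(tbl)) {
    cls <- stringr::str_match(tbl$herv_id, "-([A-Za-z0-9]+)$")[, 2L]
    cls[is.na(cls)] <- "Unknown"
    tbl$classification <- cls
  }
  tbl %>%
    count(.data$classification, name = "n") %>%
    arrange(desc(.data$n), .data$classification)
}

#' Co-option calls between discovered elements and ncRNA annotations
#'
#' Convenience wrapper pairing a discovery result (or element tibble) with an
#' ncRNA feature table via [containment_intersect()].
#'
#' @param elements Element tibble with `element_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param ncrnas ncRNA feature tibble with `ncrna_id` (or `id`), `contig`,
#'   `start`, `end`, `strand`.
#' @return The containment pair tibble.
#' @export
call_ncrna_cooption <- function(elements, ncrnas) {
  h <- tibble(id = elements$element_id, contig = elements$contig,
              start = elements$start, end = elements$end,
              strand = elements$strand)
  nid <- if ("ncrna_id" %in% names(ncrnas)) ncrnas$ncrna_id else ncrnas$id
  n <- tibble(id = nid, contig = ncrnas$contig, start = ncrnas$start,
              end = ncrnas$end, strand = ncrnas$strand)
  containment_intersect(h, n)
}
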