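# broom-style accessors: tidy() returns the per-record tibble of a result,
# glance() a one-row summary.

#' @export
tidy.herv_discovery <- function(x, ...) x$elements

#' @export
glance.herv_discovery <- function(x, ...) {
  tibble(species = x$species,
         n_candidates = x$stage_counts$n[x$stage_counts$stage == "erv_candidates"],
         n_elements = nrow(x$elements),
         n_full_length = sum(x$elements[["is_full_length"]] %||% logical(0)),
         n_classes = length(unique(x$elements[["classification"]] %||% character(0))))
}

#' @export
tidy.herv_transmission <- function(x, ...) x$events

#' @export
glance.herv_transmission <- function(x, ...) {
  tibble(n_pairs_tested = nrow(x$pairs),
         n_pairs_accepted = sum(x$pairs$accepted),
         n_events = nrow(x$events),
         n_elements = nrow(x$members),
         max_age_mya = if (nrow(x$events) > 0L) max(x$events$age_mya) else NA_real_)
}

#' @export
tidy.herv_recombination <- function(x, ...) x$calls

#' @export
glance.herv_recombination <- function(x, ...) {
  tibble(n_calls = nrow(x$calls),
         n_elements_involved = length(unique(c(x$calls$element_1,
                                               x$calls$element_2))),
         n_elements = nrow(x$nonclustered),
         pct_nonclustered = 100 * mean(x$nonclustered$nonclustered))
}

#' @export
tidy.herv_cohort <- function(x, ...) x$truth$insertions

#' @export
glance.herv_cohort <- function(x, ...) {
  tibble(n_species = length(x$genomes),
         n_orthology_groups = length(unique(x$truth$insertions$group_id)),
         n_elements = nrow(x$truth$insertions),
         n_recombination_swaps = nrow(x$truth$recombination),
         n_ncrna = nrow(x$truth$ncrna),
         substitution_rate = x$config$substitution_rate)
}
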