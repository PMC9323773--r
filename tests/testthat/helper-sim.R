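# Small sequence constructors used across the test files.

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(n) {
  paste(sample(Biostrings::AA_STANDARD, n, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions (indel-free), never to the same base
mutate_dna <- function(x, n_sub, positions = NULL) {
  v <- strsplit(x, "")[[1]]
  if (is.null(positions)) positions <- sample(length(v), n_sub)
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

mutate_protein <- function(x, n_sub) {
  v <- strsplit(x, "")[[1]]
  aas <- Biostrings::AA_STANDARD
  for (p in sample(length(v), n_sub)) v[p] <- sample(setdiff(aas, v[p]), 1)
  paste(v, collapse = "")
}

# deterministic (given the RNG state) stop-free back-translation
back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(by_aa[[a]], 1), ""), collapse = "")
}
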