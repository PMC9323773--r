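# Time-calibrated species trees: parsing, validation and node ages.

#' Read a time-calibrated species tree
#'
#' Reads a newick tree whose branch lengths are in million years (MY) and
#' validates that it is rooted and ultrametric (leaves at age 0, node ages
#' equal to divergence times).
#'
#' @param path Path to a newick file.
#' @param tol Ultrametricity tolerance (relative, passed to
#'   [ape::is.ultrametric()]).
#' @return An `ape::phylo` tree.
#' @export
read_timed_tree <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  validate_timed_tree(tree, tol = tol)
  tree
}

#' @rdname read_timed_tree
#' @param tree An `ape::phylo` object.
#' @export
validate_timed_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("not a phylo tree", class = "hervtrace_input_error")
  if (length(tree$tip.label) < 2L) return(invisible(tree))  # degenerate single-genome tree
  if (!ape::is.rooted(tree)) abort("species tree must be rooted", class = "hervtrace_input_error")
  if (!ape::is.ultrametric(tree, tol = tol)) {
    abort("species tree must be ultrametric (node ages in MY)",
          class = "hervtrace_input_error")
  }
  invisible(tree)
}

#' Node ages of a timed tree
#'
#' @param tree An ultrametric `ape::phylo` tree with branch lengths in MY.
#' @return A tibble with one row per node (leaves included): `node` (ape node
#'   number), `label`, `age_mya`.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) paste0("node", seq_len(tree$Nnode))
              else tree$node.label)
  tibble(node = seq_along(ages), label = labels,
         age_mya = ifelse(seq_along(ages) <= ntip, 0, ages))
}

#' The packaged six-primate fixture tree
#'
#' A rooted ultrametric tree of six catarrhine primates with splits at 6.7,
#' 9.1, 15.8, 20.2 and 29.4 MYA (hominin through catarrhine depths), used as
#' the default species tree of the cohort simulator. Internal nodes are
#' labelled (`hominini`, `homininae`, `hominidae`, `hominoidea`,
#' `catarrhini`).
#'
#' @return An `ape::phylo` tree.
#' @export
fixture_tree <- function() {
  read_timed_tree(system.file("extdata", "primate_tree.nwk",
                              package = "hervtrace", mustWork = TRUE))
}

# resolve a node label (tip or internal) to an ape node number
.node_by_label <- function(tree, label) {
  ages <- node_ages(tree)
  hit <- which(ages$label == label)
  if (length(hit) != 1L) {
    abort(sprintf("unknown tree node label '%s'", label),
          class = "hervtrace_input_error")
  }
  ages$node[hit]
}

# leaves descending from a node (including the node itself if a leaf)
.node_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  desc <- ape::extract.clade(tree, node)$tip.label
  desc
}
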