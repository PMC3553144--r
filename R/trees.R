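#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()]; internal-node labels are
#' interpreted as bipartition support values where numeric.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Write a tree in Newick format
#'
#' Support values (if present in `tree$node.label`) are written as
#' internal-node labels. Writing and re-reading a tree reproduces the same
#' canonical string.
#'
#' @param tree an [ape::phylo] tree; every leaf must be labelled.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("every leaf must be labelled before writing Newick")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Newick string for a tree (canonical form)
#' @param tree an [ape::phylo] tree.
#' @return single Newick string.
#' @export
newick_string <- function(tree) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("every leaf must be labelled")
  ape::write.tree(tree)
}

# unrooted bipartitions as canonical strings (smaller side, sorted labels)
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) <= 1L || length(other) <= 1L) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = ",") < paste(other, collapse = ",")))
      side else other
    out <- c(out, paste(key, collapse = ","))
  }
  unique(out)
}
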