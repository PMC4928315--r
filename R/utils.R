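# Shared helpers: tree invariants, random sequence, coordinate conversions.

#' Root-to-node path lengths of a rooted tree
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return numeric vector of depths indexed by node number (tips first).
#' @export
nodeDepths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  root <- ape::Ntip(tree) + 1L
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    depth[ch] <- depth[p] + ord$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Check that a tree is a valid timed species tree
#'
#' Verifies the invariants assumed throughout: rooted, strictly bifurcating,
#' branch lengths present and non-negative, ultrametric within a relative
#' tolerance, unique tip labels.
#'
#' @param tree an `ape::phylo`.
#' @param rel_tol relative tolerance on root-to-tip depth spread.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
assertTimedTree <- function(tree, rel_tol = 1e-9) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree must be rooted and strictly bifurcating")
  d <- nodeDepths(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(d)) > rel_tol * max(d))
    stop("tree is not ultrametric within tolerance")
  invisible(TRUE)
}

#' Random DNA sequence
#'
#' i.i.d. background sequence with configurable GC content (used for
#' intergenic flanks in synthetic contigs).
#'
#' @param n length in bp.
#' @param gc GC content in `[0, 1]`.
#' @return a single character string.
#' @export
randomDna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Reverse-complement of a plain character string.
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# Derive a bounded child seed from a base seed and a stage offset.
childSeed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483587L
}

# Stable gene id
.geneId <- function(species, contig, start, end, strand) {
  sprintf("%s:%s:%d-%d(%s)", species, contig, start, end, strand)
}
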